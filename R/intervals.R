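#' Genome layout: chromosome lengths plus optional excluded regions
#'
#' A lightweight container pairing an ordered chromosome -> length map with an
#' optional set of excluded regions (e.g. assembly gaps) that the shuffle null
#' must avoid.
#'
#' @param lengths named numeric/integer vector of chromosome lengths in bp;
#'   all lengths must be positive and names non-empty and unique.
#' @param excluded optional `GRanges` of regions unavailable for placement;
#'   must lie within the declared chromosome lengths.
#' @return an object of class `genome_layout` with elements `lengths`
#'   (named integer) and `excluded` (`GRanges` or `NULL`).
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths, excluded = NULL) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names in layout")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  lengths <- setNames(as.integer(lengths), names(lengths))
  if (!is.null(excluded)) {
    stopifnot(methods::is(excluded, "GRanges"))
    chr <- as.character(seqnames(excluded))
    if (!all(chr %in% names(lengths)))
      stop("excluded regions on chromosomes absent from the layout")
    if (any(end(excluded) > lengths[chr]))
      stop("excluded regions extend past their chromosome length")
  }
  structure(list(lengths = lengths, excluded = excluded),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$lengths), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total")
  if (!is.null(x$excluded)) cat(";", length(x$excluded), "excluded region(s)")
  cat("\n")
  invisible(x)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path tab-separated file with columns chromosome name and length.
#' @return a [genome_layout].
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  genome_layout(setNames(df$length, df$chrom))
}

#' Write a chromosome-sizes table
#'
#' @param layout a [genome_layout].
#' @param path output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  write.table(data.frame(names(layout$lengths), unname(layout$lengths)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.bed_ncols <- c(bed3 = 3L, bed4 = 4L, bed5 = 5L, bed6 = 6L, narrowPeak = 10L)

#' Read BED / narrowPeak intervals
#'
#' Coordinates in the file are 0-based half-open (BED convention) and are
#' converted to the 1-based closed `GRanges` representation. For narrowPeak
#' input, columns 7-10 are kept as metadata columns (`signalValue`, `pValue`,
#' `qValue`) and the summit offset is converted to an absolute 0-based
#' position (`summit`; `NA` when the file records -1).
#'
#' @param path path to an existing BED-like file.
#' @param dialect one of `"bed3"`, `"bed4"`, `"bed5"`, `"bed6"`,
#'   `"narrowPeak"`; lines must carry at least that many tab-separated fields.
#' @return a sorted `GRanges`; the file's basename is recorded in
#'   `metadata(x)$provenance`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", p)
#' read_bed(p, "bed3")
#' @export
read_bed <- function(path, dialect = c("bed6", "bed3", "bed4", "bed5",
                                       "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  ncol_needed <- .bed_ncols[[dialect]]
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GRanges()
    S4Vectors::metadata(gr)$provenance <- basename(path)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncol_needed))
    stop(sprintf("parse error at line %d of %s: %d field(s), %s needs %d",
                 which(nf < ncol_needed)[1], basename(path),
                 nf[which(nf < ncol_needed)[1]], dialect, ncol_needed))
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- get_col(1)
  start0 <- suppressWarnings(as.numeric(get_col(2)))
  end0 <- suppressWarnings(as.numeric(get_col(3)))
  bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: non-integer coordinates",
                 bad[1], basename(path)))
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop(sprintf(
      "parse error at line %d of %s: invalid interval [%s, %s)",
      bad[1], basename(path), get_col(2)[bad[1]], get_col(3)[bad[1]]))
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (ncol_needed >= 4L) names(gr) <- get_col(4)
  if (ncol_needed >= 5L) gr$score <- suppressWarnings(as.numeric(get_col(5)))
  if (ncol_needed >= 6L) {
    str <- get_col(6)
    str[!str %in% c("+", "-")] <- "*"
    strand(gr) <- str
  }
  if (dialect == "narrowPeak") {
    gr$signalValue <- as.numeric(get_col(7))
    gr$pValue <- as.numeric(get_col(8))
    gr$qValue <- as.numeric(get_col(9))
    peak <- as.integer(get_col(10))
    gr$summit <- ifelse(peak < 0, NA_integer_, start0 + peak)
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$provenance <- basename(path)
  gr
}

#' Write intervals as BED6
#'
#' The inverse of [read_bed()]: `GRanges` coordinates are emitted 0-based
#' half-open. Missing names become `"."` and missing scores `0`.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  nm <- if (is.null(names(gr))) rep(".", length(gr)) else names(gr)
  sc <- if (!is.null(gr$score)) ifelse(is.na(gr$score), 0, gr$score) else
    rep(0, length(gr))
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   nm, sc, str)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals, optionally bridging small gaps
#'
#' Returns the minimal sorted, non-overlapping set whose union equals the
#' input union, fusing intervals separated by at most `max_gap` bp. Under
#' half-open semantics, book-ended intervals (gap 0) fuse at `max_gap = 0`.
#' Strand is ignored.
#'
#' @param gr a `GRanges`.
#' @param max_gap non-negative gap (bp) over which intervals still fuse.
#' @return a sorted, strand-less `GRanges`.
#' @export
merge_intervals <- function(gr, max_gap = 0L) {
  stopifnot(max_gap >= 0)
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  reduce(gr, min.gapwidth = max_gap + 1L, ignore.strand = TRUE)
}

#' Count query intervals overlapping a subject set
#'
#' Number of intervals of `query` sharing at least `min_bp` bases with at
#' least one interval of `subject`; each query interval counts at most once.
#' This is the observed statistic of [permutation_overlap_test()].
#'
#' @param query,subject `GRanges`.
#' @param min_bp minimum shared bases (default 1, i.e. any overlap).
#' @return integer count, between 0 and `length(query)`.
#' @export
overlap_count <- function(query, subject, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  sum(.count_hits(query, subject, min_bp) > 0L)
}

# countOverlaps on a shared seqlevel universe (chromosomes are compared as
# exact strings; disjoint chromosome sets are a normal, silent case)
.count_hits <- function(query, subject, min_bp = 1L) {
  lv <- union(seqlevels(query), seqlevels(subject))
  seqlevels(query) <- lv
  seqlevels(subject) <- lv
  countOverlaps(query, subject, minoverlap = min_bp, ignore.strand = TRUE)
}
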