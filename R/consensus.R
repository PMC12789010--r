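#' Consensus peaks across replicate peak sets
#'
#' Under the default base-resolution definition, a consensus peak is a maximal
#' genomic run of positions covered by at least `min_support` distinct
#' replicates. Each replicate set is first collapsed with [merge_intervals()]
#' so a replicate contributes at most 1 to the per-base support. The
#' peak-level alternative (`method = "peak"`) instead keeps every replicate
#' peak that overlaps peaks from at least `min_support - 1` other replicates,
#' then merges the survivors.
#'
#' @param replicates list of `GRanges`, one per replicate.
#' @param min_support required number of supporting replicates (>= 1).
#' @param method `"base"` (default, base-resolution support runs) or
#'   `"peak"` (peak-level cross-replicate support).
#' @return a sorted, non-overlapping `GRanges` with metadata column `support`
#'   (maximum replicate support within the run). `min_support` greater than
#'   the number of replicates yields an empty set with a warning.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' consensus_peaks(list(r, r, r), min_support = 2)
#' @export
consensus_peaks <- function(replicates, min_support = 2L,
                            method = c("base", "peak")) {
  method <- match.arg(method)
  stopifnot(is.list(replicates), length(replicates) >= 1, min_support >= 1)
  if (min_support > length(replicates)) {
    warning("min_support (", min_support, ") exceeds number of replicates (",
            length(replicates), "); returning empty consensus")
    return(GRanges(support = integer(0)))
  }
  reps <- lapply(replicates, merge_intervals)
  chroms <- sort(unique(unlist(lapply(reps, function(r)
    as.character(seqnames(r))))))
  if (length(chroms) == 0L) return(GRanges(support = integer(0)))
  # align all replicates on a shared seqinfo so per-base coverages add up
  maxend <- vapply(chroms, function(ch) max(unlist(lapply(reps, function(r)
    c(0L, end(r)[as.character(seqnames(r)) == ch])))), numeric(1))
  reps <- lapply(reps, function(r) {
    seqlevels(r) <- chroms
    GenomeInfoDb::seqlengths(r) <- maxend
    r
  })
  cvg <- Reduce(`+`, lapply(reps, coverage))
  if (method == "peak") {
    kept <- lapply(seq_along(reps), function(i) {
      support1 <- Reduce(`+`, lapply(reps[-i], function(o)
        as.integer(countOverlaps(reps[[i]], o, ignore.strand = TRUE) > 0L)))
      if (is.null(support1)) support1 <- integer(length(reps[[i]]))
      reps[[i]][support1 >= min_support - 1L]
    })
    out <- merge_intervals(do.call(c, kept))
  } else {
    sl <- slice(cvg, lower = min_support)
    irl <- as(sl, "IRangesList")
    out <- GRanges(rep(names(irl), lengths(irl)),
                   unlist(irl, use.names = FALSE))
  }
  if (length(out)) {
    och <- as.character(seqnames(out))
    support <- integer(length(out))
    for (ch in unique(och)) {
      idx <- och == ch
      support[idx] <- as.integer(viewMaxs(Views(cvg[[ch]],
                                                ranges(out)[idx])))
    }
    out$support <- support
    names(out) <- NULL
    out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  } else out$support <- integer(0)
  out
}

#' Read minimal gene models
#'
#' Accepts either a five-column tab-separated table with header
#' `gene_id, chrom, tss, strand, body` (body as `start-end`, 0-based
#' half-open; `tss` 0-based) or a GTF file restricted to `gene` records
#' (requires the rtracklayer package).
#'
#' @param path input file; `.gtf`/`.gff` suffixes trigger GTF parsing.
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`, `body_start`, `body_end` (0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GTF input requires the rtracklayer package")
    g <- rtracklayer::import(path)
    g <- g[g$type == "gene"]
    id <- if (!is.null(g$gene_id)) g$gene_id else names(g)
    minus <- as.character(strand(g)) == "-"
    return(data.frame(
      gene_id = as.character(id),
      chrom = as.character(seqnames(g)),
      tss = ifelse(minus, end(g) - 1L, start(g) - 1L),
      strand = as.character(strand(g)),
      body_start = start(g) - 1L, body_end = end(g),
      stringsAsFactors = FALSE))
  }
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric",
                                  "character", "character"))
  stopifnot(all(c("gene_id", "chrom", "tss", "strand", "body") %in%
                  names(df)))
  body <- strsplit(df$body, "-", fixed = TRUE)
  df$body_start <- as.numeric(vapply(body, `[[`, character(1), 1))
  df$body_end <- as.numeric(vapply(body, `[[`, character(1), 2))
  df$body <- NULL
  df
}

.gene_bodies_gr <- function(genes) {
  GRanges(genes$chrom, IRanges(genes$body_start + 1L, genes$body_end))
}

.promoter_gr <- function(genes, halfwidth) {
  # window [tss - hw, tss + hw) in 0-based coords, strand-agnostic
  GRanges(genes$chrom,
          IRanges(pmax(genes$tss - halfwidth, 0) + 1L, genes$tss + halfwidth))
}

#' Classify peaks by genomic region
#'
#' A peak overlapping any promoter window (TSS +/- `promoter_halfwidth`) is
#' `promoter`; otherwise a peak overlapping a gene body is `intronic/genic`;
#' all remaining peaks are `intergenic`. Precedence is
#' promoter > genic > intergenic, so the classes partition the peak set.
#'
#' @param peaks `GRanges`.
#' @param genes gene-model data.frame as from [read_gene_models()].
#' @param gene_bodies optional `GRanges` of gene bodies; defaults to the
#'   bodies in `genes`.
#' @param promoter_halfwidth promoter half-width in bp (default 1000,
#'   i.e. +/- 1 kb of TSS).
#' @return factor of region classes, one per peak, levels
#'   `promoter`, `intronic/genic`, `intergenic`.
#' @export
annotate_region <- function(peaks, genes, gene_bodies = NULL,
                            promoter_halfwidth = 1000L) {
  stopifnot(promoter_halfwidth > 0)
  if (is.null(gene_bodies)) gene_bodies <- .gene_bodies_gr(genes)
  prom <- .promoter_gr(genes, promoter_halfwidth)
  cls <- rep("intergenic", length(peaks))
  cls[.count_hits(peaks, gene_bodies) > 0] <- "intronic/genic"
  cls[.count_hits(peaks, prom) > 0] <- "promoter"
  factor(cls, levels = c("promoter", "intronic/genic", "intergenic"))
}

#' Assign peaks to the gene with the nearest TSS
#'
#' Each peak is assigned to the gene whose TSS is nearest (distance 0 when
#' the TSS falls inside the peak), provided the distance is within
#' `max_distance`; exact ties assign all tied genes. The union of assigned
#' genes over all peaks is the "bound gene set".
#'
#' @param peaks `GRanges`; unnamed peaks get ids `peak_1, ...`.
#' @param genes gene-model data.frame as from [read_gene_models()].
#' @param max_distance maximum TSS distance in bp (default 100 kb).
#' @return data.frame with one row per (peak, assigned gene):
#'   `peak_id`, `gene_id`, `distance`.
#' @export
assign_to_genes <- function(peaks, genes, max_distance = 1e5) {
  stopifnot(max_distance >= 0)
  ids <- if (is.null(names(peaks))) paste0("peak_", seq_along(peaks)) else
    names(peaks)
  out <- vector("list", length(peaks))
  pchrom <- as.character(seqnames(peaks))
  s0 <- start(peaks) - 1L  # 0-based
  e0 <- end(peaks)         # half-open end
  for (chrom in unique(pchrom)) {
    gi <- which(genes$chrom == chrom)
    if (!length(gi)) next
    tss <- genes$tss[gi]
    for (p in which(pchrom == chrom)) {
      d <- pmax(0, pmax(s0[p] - tss, tss - (e0[p] - 1L)))
      dmin <- min(d)
      if (dmin <= max_distance) {
        hit <- gi[d == dmin]
        out[[p]] <- data.frame(peak_id = ids[p],
                               gene_id = genes$gene_id[hit],
                               distance = dmin,
                               stringsAsFactors = FALSE)
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  do.call(rbind, out)
}

#' Bound gene set induced by a peak-to-gene assignment
#'
#' @param assignment data.frame from [assign_to_genes()].
#' @return character vector of unique gene ids.
#' @export
bound_genes <- function(assignment) sort(unique(assignment$gene_id))
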