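.BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Counts are converted to per-position probabilities after adding a
#' pseudocount, and log-odds scores (bits, log2 probability over background)
#' are precomputed.
#'
#' @param counts 4 x W numeric matrix of base counts (or probabilities),
#'   rows in A, C, G, T order; W >= 4.
#' @param id motif identifier.
#' @param background base frequencies for A, C, G, T (default uniform).
#' @param pseudocount added to every count before normalization
#'   (default 0.01).
#' @return an object of class `pwm` with elements `id`, `prob` (4 x W),
#'   `log_odds` (bits), `background`, `pseudocount`, `width`.
#' @export
pwm_from_counts <- function(counts, id = "motif",
                            background = rep(0.25, 4), pseudocount = 0.01) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 4, all(counts >= 0),
            length(background) == 4, all(background > 0),
            pseudocount >= 0)
  background <- background / sum(background)
  dimnames(counts) <- list(.BASES, NULL)
  prob <- sweep(counts + pseudocount, 2,
                colSums(counts + pseudocount), "/")
  if (any(prob <= 0)) stop("zero probability after pseudocount; increase it")
  structure(list(id = id, prob = prob,
                 log_odds = log2(prob / background),
                 background = setNames(background, .BASES),
                 pseudocount = pseudocount, width = ncol(prob)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, consensus %s, max score %.2f bits\n",
              x$id, x$width, consensus_string(x), max_score(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm a [pwm_from_counts()] object.
#' @return character string of length `pwm$width`.
#' @export
consensus_string <- function(pwm)
  paste(.BASES[apply(pwm$prob, 2, which.max)], collapse = "")

#' Maximum attainable log-odds score of a PWM (bits)
#' @param pwm a [pwm_from_counts()] object.
#' @export
max_score <- function(pwm) sum(apply(pwm$log_odds, 2, max))

#' Read PWMs from a JASPAR-format file
#'
#' Parses the raw-count JASPAR text dialect: a `>ID name` header followed by
#' four rows `A [ 1 2 ... ]` ... `T [ ... ]` (brackets optional).
#'
#' @param path input file; may contain several motifs.
#' @inheritParams pwm_from_counts
#' @return named list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif header in ", path)
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    j <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    id <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]][1]
    block <- lines[(i + 1):j]
    if (length(block) < 4) stop("motif ", id, ": expected 4 base rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = parts[1], counts = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, .BASES))
      stop("motif ", id, ": rows must be labelled A/C/G/T")
    mat <- do.call(rbind, lapply(.BASES, function(b)
      rows[[match(b, bases)]]$counts))
    out[[id]] <- pwm_from_counts(mat, id, background, pseudocount)
  }
  out
}

#' Read PWMs from MEME minimal-motif text
#'
#' Parses `MOTIF <id>` blocks with their `letter-probability matrix` sections
#' (alphabet assumed ACGT). Probabilities are rescaled by the header's
#' `nsites` (default 100 when absent) so pseudocount regularization acts on
#' effective counts.
#'
#' @inheritParams read_jaspar
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF block in ", path)
  out <- list()
  for (i in starts) {
    id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1]][1]
    m <- grep("^letter-probability matrix", lines[(i + 1):length(lines)])[1]
    if (is.na(m)) stop("motif ", id, ": missing letter-probability matrix")
    j <- i + m
    w <- as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[j]))
    nsites <- if (grepl("nsites\\s*=", lines[j]))
      as.numeric(sub(".*nsites\\s*=\\s*([0-9.]+).*", "\\1", lines[j])) else
        100
    rows <- lines[(j + 1):(j + w)]
    mat <- vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]), numeric(4))
    out[[id]] <- pwm_from_counts(mat * nsites, id, background, pseudocount)
  }
  out
}

# integer-encode a DNA character string; ambiguous bases -> NA
.encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], .BASES)
}

# log-odds scores at every offset of an encoded sequence (NA-safe: windows
# containing ambiguous bases score -Inf)
.score_positions <- function(codes, lod) {
  w <- ncol(lod)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (k in seq_len(w)) {
    v <- unname(lod[codes[k:(k + n - 1L)], k])
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

#' Scan a PWM over container intervals
#'
#' Scores every offset of both strands inside each container and reports
#' positions with log-odds score at or above `threshold`. Reverse-strand
#' hits are reported on forward-strand coordinates.
#'
#' @param containers `GRanges` of container intervals (peaks); names are
#'   used as container ids (defaults to `peak_1, ...`).
#' @param sequences a `Biostrings::DNAStringSet` (named by chromosome) or a
#'   FASTA file path.
#' @param pwm a `pwm` object.
#' @param threshold minimum log-odds score in bits.
#' @return `GRanges` of hits with metadata columns `motif_id`, `score`
#'   (bits) and `container`; hit strand records the matching strand.
#' @export
scan_pwm <- function(containers, sequences, pwm, threshold) {
  stopifnot(is.finite(threshold))
  if (is.character(sequences)) sequences <- readDNAStringSet(sequences)
  ids <- if (is.null(names(containers)))
    paste0("peak_", seq_along(containers)) else names(containers)
  w <- pwm$width
  h_chrom <- character(0); h_start <- integer(0)
  h_strand <- character(0); h_score <- numeric(0); h_cont <- character(0)
  for (i in seq_along(containers)) {
    chrom <- as.character(seqnames(containers)[i])
    if (!chrom %in% names(sequences))
      stop("container ", ids[i], ": chromosome ", chrom, " not in sequences")
    if (end(containers)[i] > length(sequences[[chrom]]) ||
        start(containers)[i] < 1L)
      stop("container ", ids[i], " exceeds sequence bounds on ", chrom)
    s <- as.character(subseq(sequences[[chrom]],
                             start(containers)[i], end(containers)[i]))
    L <- nchar(s)
    if (L < w) next
    fwd <- .score_positions(.encode_seq(s), pwm$log_odds)
    rev <- .score_positions(
      .encode_seq(as.character(reverseComplement(DNAString(s)))),
      pwm$log_odds)
    off_f <- which(fwd >= threshold)
    off_r <- which(rev >= threshold)
    if (!length(off_f) && !length(off_r)) next
    # reverse offset j (1-based in revcomp) covers forward [L-j-w+2, L-j+1]
    st <- c(start(containers)[i] + off_f - 1L,
            start(containers)[i] + (L - off_r - w + 1L))
    h_chrom <- c(h_chrom, rep(chrom, length(st)))
    h_start <- c(h_start, st)
    h_strand <- c(h_strand, rep(c("+", "-"),
                                c(length(off_f), length(off_r))))
    h_score <- c(h_score, fwd[off_f], rev[off_r])
    h_cont <- c(h_cont, rep(ids[i], length(st)))
  }
  if (!length(h_start))
    return(GRanges(motif_id = character(0), score = numeric(0),
                   container = character(0)))
  out <- GRanges(h_chrom, IRanges(h_start, width = w), strand = h_strand,
                 motif_id = pwm$id, score = h_score, container = h_cont)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

.container_ids <- function(containers) {
  if (is.null(names(containers))) paste0("peak_", seq_along(containers))
  else names(containers)
}

.check_hit_containers <- function(hits, ids) {
  if (length(hits) == 0L) return(character(0))
  hc <- hits$container
  if (is.null(hc)) stop("hits lack a 'container' metadata column")
  unknown <- setdiff(unique(hc), ids)
  if (length(unknown))
    stop("hit(s) reference unknown container(s): ",
         paste(head(unknown, 3), collapse = ", "))
  hc
}

#' Classify containers by two-motif co-occurrence
#'
#' Each container is labelled by presence/absence of at least one A hit and
#' at least one B hit, giving the four classes A-only / B-only / both /
#' neither. Duplicate hits within a container and hit order are irrelevant.
#'
#' @param containers `GRanges` of containers (peaks); names are container
#'   ids.
#' @param hits_a,hits_b hit `GRanges` as from [scan_pwm()] (only the
#'   `container` column is used, so footprint BED imports work equally).
#' @return an object of class `cooccurrence_table`: counts `n_a_only`,
#'   `n_b_only`, `n_both`, `n_neither`, `total`, and `percent` (same order,
#'   summing to 100).
#' @export
classify_cooccurrence <- function(containers, hits_a, hits_b) {
  ids <- .container_ids(containers)
  in_a <- ids %in% .check_hit_containers(hits_a, ids)
  in_b <- ids %in% .check_hit_containers(hits_b, ids)
  cls <- ifelse(in_a & in_b, "both",
                ifelse(in_a, "a_only", ifelse(in_b, "b_only", "neither")))
  counts <- c(a_only = sum(cls == "a_only"), b_only = sum(cls == "b_only"),
              both = sum(cls == "both"), neither = sum(cls == "neither"))
  structure(list(n_a_only = counts[["a_only"]],
                 n_b_only = counts[["b_only"]],
                 n_both = counts[["both"]],
                 n_neither = counts[["neither"]],
                 total = length(ids),
                 percent = 100 * counts / max(length(ids), 1L),
                 class_per_container = setNames(cls, ids)),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf(
    "co-occurrence over %d containers: A-only %d (%.1f%%), B-only %d (%.1f%%), both %d (%.1f%%), neither %d (%.1f%%)\n",
    x$total, x$n_a_only, x$percent[["a_only"]], x$n_b_only,
    x$percent[["b_only"]], x$n_both, x$percent[["both"]],
    x$n_neither, x$percent[["neither"]]))
  invisible(x)
}

#' Compare two co-occurrence tables by chi-squared test
#'
#' Pearson chi-squared (no continuity correction) on the 2 x 4
#' condition-by-class contingency table.
#'
#' @param table_x,table_y `cooccurrence_table` objects.
#' @return a `contingency_result` (see [crosstab_chi2()]) with df 3.
#' @export
compare_cooccurrence <- function(table_x, table_y) {
  m <- rbind(x = c(table_x$n_a_only, table_x$n_b_only, table_x$n_both,
                   table_x$n_neither),
             y = c(table_y$n_a_only, table_y$n_b_only, table_y$n_both,
                   table_y$n_neither))
  colnames(m) <- c("a_only", "b_only", "both", "neither")
  if (table_x$total == 0 || table_y$total == 0)
    stop("degenerate co-occurrence table (total = 0)")
  .chi2_on_matrix(m)
}

#' Per-container nearest-pair distance between two motif hit sets
#'
#' For every container holding at least one A hit and at least one B hit,
#' emits the minimum distance over all A x B hit pairs. The default
#' convention is center-to-center with centers at
#' `floor((start0 + end0) / 2)` in 0-based coordinates; `"edge"` measures
#' the gap between the closest hit edges (0 for touching or overlapping
#' hits).
#'
#' @inheritParams classify_cooccurrence
#' @param convention `"center"` (default) or `"edge"`.
#' @return an object of class `spacing_distribution`: integer `distances`
#'   (one per contributing container), `median`, and `modal_bin`
#'   (`[lo, hi)` bounds of the most populated 5-bp histogram bin).
#' @export
pair_distance_distribution <- function(containers, hits_a, hits_b,
                                       convention = c("center", "edge")) {
  convention <- match.arg(convention)
  ids <- .container_ids(containers)
  ca <- .check_hit_containers(hits_a, ids)
  cb <- .check_hit_containers(hits_b, ids)
  shared <- intersect(unique(ca), unique(cb))
  dist_one <- function(id) {
    a <- hits_a[ca == id]
    b <- hits_b[cb == id]
    if (convention == "center") {
      # 0-based center: floor((start0 + end0)/2) = floor((start1-1 + end1)/2)
      cen_a <- floor((start(a) - 1L + end(a)) / 2)
      cen_b <- floor((start(b) - 1L + end(b)) / 2)
      min(abs(outer(cen_a, cen_b, "-")))
    } else {
      # gap between closest edges; 0 for touching or overlapping hits
      g1 <- outer(start(b), end(a), "-") - 1L  # b to the right of a
      g2 <- t(outer(start(a), end(b), "-")) - 1L  # a to the right of b
      min(pmax(pmax(g1, g2), 0L))
    }
  }
  d <- vapply(shared, dist_one, numeric(1))
  spacing_distribution(as.integer(d))
}

#' Construct a spacing distribution from raw distances
#'
#' The modal bin uses 5-bp bins centered on multiples of 5 (bin `k` covers
#' `[5k - 2, 5k + 3)`): centering avoids the degenerate case of a true mode
#' sitting exactly on a bin edge, where edge-aligned bins would split its
#' mass evenly between two bins.
#'
#' @param distances non-negative integer distances in bp.
#' @return a `spacing_distribution` object with `distances`, `median`, and
#'   `modal_bin` (`lo`/`hi` half-open bounds, `center`).
#' @export
spacing_distribution <- function(distances) {
  stopifnot(all(distances >= 0))
  md <- if (length(distances)) median(distances) else NA_real_
  modal <- if (length(distances)) {
    bin <- as.integer(round_half_away(distances / 5))
    mb <- as.integer(names(which.max(table(bin))))
    c(lo = mb * 5L - 2L, hi = mb * 5L + 3L, center = mb * 5L)
  } else c(lo = NA_integer_, hi = NA_integer_, center = NA_integer_)
  structure(list(distances = as.integer(distances), median = md,
                 modal_bin = modal),
            class = "spacing_distribution")
}

#' @export
print.spacing_distribution <- function(x, ...) {
  cat(sprintf(
    "spacing distribution: %d pair(s), median %.1f bp, modal 5-bp bin [%d, %d)\n",
    length(x$distances), x$median, x$modal_bin[["lo"]], x$modal_bin[["hi"]]))
  invisible(x)
}

# asymptotic two-sided Kolmogorov tail: Q(lambda) = 2 sum (-1)^{k-1} e^{-2k^2 lambda^2}
.kolmogorov_tail <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over all observed points of the absolute difference of
#' the two empirical CDFs (well defined with ties). The two-sided p-value
#' uses the exact conditional null distribution when the effective sample
#' size `m*n/(m+n)` is below 35 and the pooled sample is tie-free, and the
#' asymptotic Kolmogorov distribution at `lambda = sqrt(n_eff) * D`
#' otherwise.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `statistic` (D), `p.value`, `n_x`, `n_y`, `method`
#'   (`"exact"` or `"asymptotic"`).
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(c(x, y))))
  pts <- sort(unique(c(x, y)))
  D <- max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  m <- length(x); n <- length(y)
  n_eff <- m * n / (m + n)
  ties <- anyDuplicated(c(x, y)) > 0
  if (n_eff < 35 && !ties) {
    p <- psmirnov(D, sizes = c(m, n), lower.tail = FALSE)
    method <- "exact"
  } else {
    p <- .kolmogorov_tail(sqrt(n_eff) * D)
    method <- "asymptotic"
  }
  list(statistic = D, p.value = p, n_x = m, n_y = n, method = method)
}
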