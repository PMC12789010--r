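# Brute-force reference implementations, deliberately independent of the
# package's GRanges-backed code paths: everything here works on plain
# integer vectors / per-base membership on a small toy genome.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# random interval set on a toy genome (1-based closed GRanges)
rand_intervals <- function(n, chrom_lengths, max_w = 100) {
  chrom <- sample(names(chrom_lengths), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  w <- pmin(w, chrom_lengths[chrom])
  s <- vapply(seq_len(n), function(i)
    sample.int(chrom_lengths[[chrom[i]]] - w[i] + 1L, 1L), integer(1))
  GRanges(chrom, IRanges(s, width = w))
}

# quadratic pairwise overlap count
bf_overlap_count <- function(a, b, min_bp = 1L) {
  ac <- as.character(seqnames(a)); bc <- as.character(seqnames(b))
  n <- 0L
  for (i in seq_along(a)) {
    hit <- FALSE
    for (j in seq_along(b)) {
      if (ac[i] != bc[j]) next
      ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
      if (ov >= min_bp) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}

# per-base membership merge on a toy genome; gaps <= max_gap fuse
bf_merge <- function(gr, chrom_lengths, max_gap = 0L) {
  out <- list()
  for (chrom in sort(names(chrom_lengths))) {
    cov <- logical(chrom_lengths[[chrom]])
    idx <- as.character(seqnames(gr)) == chrom
    for (i in which(idx)) cov[start(gr)[i]:end(gr)[i]] <- TRUE
    if (!any(cov)) next
    pos <- which(cov)
    brk <- which(diff(pos) > max_gap + 1L)
    s <- pos[c(1L, brk + 1L)]
    e <- pos[c(brk, length(pos))]
    out[[chrom]] <- data.frame(chrom = chrom, s = s, e = e)
  }
  if (!length(out)) return(GRanges())
  df <- do.call(rbind, out)
  GRanges(df$chrom, IRanges(df$s, df$e))
}

# per-base replicate-support consensus on a toy genome
bf_consensus <- function(replicates, chrom_lengths, k) {
  out <- list()
  for (chrom in sort(names(chrom_lengths))) {
    support <- integer(chrom_lengths[[chrom]])
    for (r in replicates) {
      cov <- logical(chrom_lengths[[chrom]])
      idx <- as.character(seqnames(r)) == chrom
      for (i in which(idx)) cov[start(r)[i]:end(r)[i]] <- TRUE
      support <- support + cov
    }
    pos <- which(support >= k)
    if (!length(pos)) next
    brk <- which(diff(pos) > 1L)
    out[[chrom]] <- data.frame(chrom = chrom,
                               s = pos[c(1L, brk + 1L)],
                               e = pos[c(brk, length(pos))])
  }
  if (!length(out)) return(GRanges())
  df <- do.call(rbind, out)
  GRanges(df$chrom, IRanges(df$s, df$e))
}

# per-position PWM rescan of one sequence string (both strands),
# scoring with plain prod/log arithmetic on character vectors
bf_scan_offsets <- function(seq_string, pwm, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_one <- function(chars) {
    if (any(!chars %in% names(comp))) return(-Inf)
    s <- 0
    for (k in seq_along(chars))
      s <- s + log2(pwm$prob[chars[k], k] / pwm$background[[chars[k]]])
    unname(s)
  }
  chars <- strsplit(seq_string, "")[[1]]
  w <- pwm$width
  L <- length(chars)
  res <- list()
  for (off in seq_len(L - w + 1L)) {
    win <- chars[off:(off + w - 1L)]
    sf <- score_one(win)
    sr <- score_one(rev(unname(comp[win])))
    if (!is.na(sf) && sf >= threshold)
      res[[length(res) + 1L]] <- c(off = off, strand = 1, score = sf)
    if (!is.na(sr) && sr >= threshold)
      res[[length(res) + 1L]] <- c(off = off, strand = -1, score = sr)
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# ECDF sup-distance evaluated by direct counting at every sample point
bf_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# deterministic toy GRanges from 0-based half-open triples
gr0 <- function(chrom, start0, end0) {
  GRanges(chrom, IRanges(start0 + 1, end0))
}
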