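#' Example PRDM1-like and RUNX-like position weight matrices
#'
#' Two synthetic, consensus-style count matrices used by the simulator and
#' the examples: an A-rich interferon-like PRDM1 proxy (consensus
#' `AAAGTGAAAGT`) and a short RUNX-core proxy (consensus `TGTGGTTT`). They
#' are deliberately information-rich so planted instances are rediscovered
#' at the consensus-score threshold; they are not the curated database
#' matrices.
#'
#' @param counts per-position count mass on the consensus base (default 97,
#'   with 1 on each other base).
#' @return named list of two [pwm_from_counts()] objects, `prdm1_like` and
#'   `runx_like`.
#' @export
example_pwms <- function(counts = 97) {
  from_consensus <- function(cons, id) {
    bases <- strsplit(cons, "")[[1]]
    m <- matrix(1, 4, length(bases), dimnames = list(.BASES, NULL))
    m[cbind(match(bases, .BASES), seq_along(bases))] <- counts
    pwm_from_counts(m, id)
  }
  list(prdm1_like = from_consensus("AAAGTGAAAGT", "prdm1_like"),
       runx_like = from_consensus("TGTGGTTT", "runx_like"))
}

#' Simulate a random genome
#'
#' Uniform-base random sequences with a matching layout; byte-identical for
#' identical seeds.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp (unnamed
#'   vectors get names `chr1, chr2, ...`).
#' @param seed integer seed (required).
#' @return list with `layout` (a [genome_layout()]) and `sequences`
#'   (a `DNAStringSet`).
#' @examples
#' g <- simulate_genome(c(chr1 = 2e4), seed = 1)
#' @export
simulate_genome <- function(chrom_lengths, seed) {
  stopifnot(!missing(seed))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  with_seed(seed, {
    seqs <- DNAStringSet(vapply(chrom_lengths, function(L)
      paste(sample(.BASES, L, replace = TRUE), collapse = ""),
      character(1)))
    list(layout = genome_layout(chrom_lengths), sequences = seqs)
  })
}

# place n non-overlapping intervals of width w per chromosome,
# proportionally to chromosome length; classic gap-allocation draw with a
# 1 bp minimum spacer so placed peaks never become book-ended
.place_nonoverlapping <- function(layout, n, w) {
  L <- layout$lengths
  cap <- (L + 1) %/% (w + 1)
  if (n > sum(cap)) stop("requested peaks exceed genome capacity")
  per <- floor(n * L / sum(L))
  # distribute the remainder, respecting capacity
  per <- pmin(per, cap)
  while (sum(per) < n) {
    room <- which(per < cap)
    take <- room[order(L[room] / (per[room] + 1), decreasing = TRUE)][1]
    per[take] <- per[take] + 1L
  }
  pieces <- lapply(names(L)[per > 0], function(chrom) {
    k <- per[[chrom]]
    slack <- L[[chrom]] - k * (w + 1L) + 1L
    gaps <- sort(sample.int(slack + 1, k, replace = TRUE) - 1L)
    start0 <- gaps + (seq_len(k) - 1L) * (w + 1L)
    data.frame(chrom = chrom, start = start0 + 1)
  })
  df <- do.call(rbind, pieces)
  GRanges(df$chrom, IRanges(df$start, width = w))
}

#' Simulate peaks with planted motif content
#'
#' Places non-overlapping, fixed-width container peaks on the genome and
#' plants exact per-class motif content: `a_only` peaks receive one
#' instance of `pwm_a`'s consensus, `b_only` one of `pwm_b`'s, `both` one
#' of each at a center-to-center distance drawn from
#' `Normal(spacing_mean, spacing_sd)` rounded to integer bp and truncated
#' to the feasible range (at least the wider motif width, at most what the
#' peak can hold), and `neither` peaks are left as background. Instances
#' overwrite the background sequence so [scan_pwm()] at the consensus
#' threshold rediscovers them.
#'
#' @param genome list from [simulate_genome()] (`layout` + `sequences`).
#' @param class_counts named integer vector with entries `a_only`,
#'   `b_only`, `both`, `neither` (exact planted counts).
#' @param pwm_a,pwm_b `pwm` objects (defaults: [example_pwms()]).
#' @param peak_width container width in bp (default 200).
#' @param spacing_mean,spacing_sd spacing model for `both` peaks in bp
#'   (defaults 25 and 2).
#' @param seed integer seed (required).
#' @return list with `containers` (named `GRanges`, `class` metadata
#'   column), `hits_a`, `hits_b` (planted hit `GRanges` in [scan_pwm()]
#'   layout), `truth` (data.frame: `peak_id`, `class`, `distance`), and
#'   `sequences` (the genome sequences with instances embedded).
#' @export
simulate_peaks_with_motifs <- function(genome, class_counts,
                                       pwm_a = example_pwms()$prdm1_like,
                                       pwm_b = example_pwms()$runx_like,
                                       peak_width = 200L,
                                       spacing_mean = 25, spacing_sd = 2,
                                       seed) {
  stopifnot(!missing(seed),
            setequal(names(class_counts),
                     c("a_only", "b_only", "both", "neither")),
            all(class_counts >= 0))
  n <- sum(class_counts)
  wa <- pwm_a$width; wb <- pwm_b$width
  wmax <- max(wa, wb)
  stopifnot(peak_width >= wa + wb + 2)
  with_seed(seed, {
    containers <- .place_nonoverlapping(genome$layout, n, peak_width)
    names(containers) <- sprintf("peak_%04d", seq_len(n))
    cls <- sample(rep(names(class_counts), class_counts))
    containers$class <- cls
    seqs <- genome$sequences
    cons_a <- consensus_string(pwm_a)
    cons_b <- consensus_string(pwm_b)
    mid <- start(containers) + peak_width %/% 2  # 1-based peak centers
    hit_rows_a <- hit_rows_b <- list()
    distance <- rep(NA_integer_, n)
    plant <- function(chrom, start1, instance) {
      seqs[[chrom]] <<- replaceAt(
        seqs[[chrom]], IRanges(start1, width = nchar(instance)), instance)
    }
    for (i in seq_len(n)) {
      chrom <- as.character(seqnames(containers)[i])
      if (cls[i] == "a_only") {
        sa <- mid[i] - wa %/% 2
        plant(chrom, sa, cons_a)
        hit_rows_a[[length(hit_rows_a) + 1]] <-
          list(chrom = chrom, start = sa, w = wa, id = names(containers)[i])
      } else if (cls[i] == "b_only") {
        sb <- mid[i] - wb %/% 2
        plant(chrom, sb, cons_b)
        hit_rows_b[[length(hit_rows_b) + 1]] <-
          list(chrom = chrom, start = sb, w = wb, id = names(containers)[i])
      } else if (cls[i] == "both") {
        d_lo <- wmax
        d_hi <- peak_width - wa %/% 2 - wb %/% 2 - 2L
        d <- round_half_away(rnorm(1, spacing_mean, spacing_sd))
        d <- as.integer(min(max(d, d_lo), d_hi))
        # centers (0-based) placed symmetrically around the peak center
        ca0 <- (mid[i] - 1L) - (d + 1L) %/% 2
        cb0 <- ca0 + d
        # instance start so that floor((start0+end0)/2) lands on the center:
        # center0 = start0 + floor(w/2)
        sa <- ca0 - wa %/% 2 + 1L
        sb <- cb0 - wb %/% 2 + 1L
        plant(chrom, sa, cons_a)
        plant(chrom, sb, cons_b)
        distance[i] <- d
        hit_rows_a[[length(hit_rows_a) + 1]] <-
          list(chrom = chrom, start = sa, w = wa, id = names(containers)[i])
        hit_rows_b[[length(hit_rows_b) + 1]] <-
          list(chrom = chrom, start = sb, w = wb, id = names(containers)[i])
      }
    }
    to_gr <- function(rows, pwm) {
      if (!length(rows))
        return(GRanges(motif_id = character(0), score = numeric(0),
                       container = character(0)))
      gr <- GRanges(vapply(rows, `[[`, character(1), "chrom"),
                    IRanges(vapply(rows, `[[`, numeric(1), "start"),
                            width = vapply(rows, `[[`, numeric(1), "w")),
                    strand = "+",
                    motif_id = pwm$id,
                    score = sum(apply(pwm$log_odds, 2, max)),
                    container = vapply(rows, `[[`, character(1), "id"))
      gr
    }
    list(containers = containers,
         hits_a = to_gr(hit_rows_a, pwm_a),
         hits_b = to_gr(hit_rows_b, pwm_b),
         truth = data.frame(peak_id = names(containers), class = cls,
                            distance = distance,
                            stringsAsFactors = FALSE),
         sequences = seqs)
  })
}

#' Simulate replicate peak sets from true containers
#'
#' Each replicate detects each container independently with
#' `detection_prob` and jitters both boundaries by rounded
#' `Normal(0, jitter_sd)` (half-away-from-zero rounding), clipped to keep
#' the interval non-empty and on-chromosome.
#'
#' @param containers `GRanges` of true peaks.
#' @param layout a [genome_layout()] (for clipping).
#' @param n_replicates number of replicates (default 3).
#' @param detection_prob per-peak detection probability in [0, 1]
#'   (0 yields empty replicates).
#' @param jitter_sd boundary jitter standard deviation in bp.
#' @param seed integer seed (required).
#' @return list of `GRanges`, one per replicate; each carries the detected
#'   containers' names.
#' @export
simulate_replicates <- function(containers, layout, n_replicates = 3L,
                                detection_prob = 0.8, jitter_sd = 10,
                                seed) {
  stopifnot(!missing(seed), detection_prob >= 0, detection_prob <= 1,
            jitter_sd >= 0)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      keep <- runif(length(containers)) < detection_prob
      gr <- containers[keep]
      if (!length(gr)) return(GRanges())
      L <- layout$lengths[as.character(seqnames(gr))]
      s <- start(gr) + round_half_away(rnorm(length(gr), 0, jitter_sd))
      e <- end(gr) + round_half_away(rnorm(length(gr), 0, jitter_sd))
      s <- pmax(1, pmin(s, L - 1))
      e <- pmax(s + 1, pmin(e, L))
      GRanges(seqnames(gr), IRanges(s, e), class = gr$class)
    })
  })
}

#' Simulate class-conditional chromatin accessibility
#'
#' In probability mode, each container is accessible with its class's
#' probability; in counts mode, exactly the requested number of containers
#' per class is accessible. Accessible containers receive one overlapping
#' ATAC peak (the container widened by `flank` bp each side); inaccessible
#' containers receive none. ATAC peaks are clipped at neighboring
#' containers so an accessible container's peak never leaks into an
#' inaccessible neighbor.
#'
#' @param containers `GRanges` with a `class` metadata column (or any
#'   single-class set when `spec` is unnamed).
#' @param spec in `"prob"` mode, named per-class accessibility
#'   probabilities; in `"counts"` mode, named per-class accessible counts.
#'   A single unnamed value applies to all containers.
#' @param mode `"prob"` (default) or `"counts"`.
#' @param flank bp added to each side of accessible containers to form the
#'   ATAC peak (default 50).
#' @param seed integer seed (required).
#' @return list with `atac` (`GRanges`) and `labels` (factor
#'   `accessible`/`CCR` per container, the simulation truth).
#' @export
simulate_accessibility <- function(containers, spec, mode = c("prob",
                                                              "counts"),
                                   flank = 50L, seed) {
  mode <- match.arg(mode)
  stopifnot(!missing(seed))
  cls <- containers$class
  if (is.null(cls)) cls <- rep("all", length(containers))
  if (is.null(names(spec)) && length(spec) == 1L)
    spec <- setNames(rep(spec, length(unique(cls))), unique(cls))
  stopifnot(all(unique(cls) %in% names(spec)))
  with_seed(seed, {
    acc <- logical(length(containers))
    for (k in unique(cls)) {
      idx <- which(cls == k)
      if (mode == "prob") {
        stopifnot(spec[[k]] >= 0, spec[[k]] <= 1)
        acc[idx] <- runif(length(idx)) < spec[[k]]
      } else {
        stopifnot(spec[[k]] <= length(idx))
        acc[sample(idx, spec[[k]])] <- TRUE
      }
    }
    # per-container flank budget: stop at the nearest neighboring container
    n <- length(containers)
    lo <- start(containers) - flank
    hi <- end(containers) + flank
    ch <- as.character(seqnames(containers))
    ord <- order(ch, start(containers))
    och <- ch[ord]
    same_prev <- c(FALSE, och[-1] == och[-n])
    prev_end <- c(NA_integer_, end(containers)[ord][-n])
    next_start <- c(start(containers)[ord][-1], NA_integer_)
    same_next <- c(och[-n] == och[-1], FALSE)
    lo[ord] <- ifelse(same_prev, pmax(lo[ord], prev_end + 1L), lo[ord])
    hi[ord] <- ifelse(same_next, pmin(hi[ord], next_start - 1L), hi[ord])
    atac <- GRanges(ch[acc], IRanges(pmax(1L, lo[acc]), hi[acc]))
    list(atac = atac,
         labels = factor(ifelse(acc, "accessible", "CCR"),
                         levels = c("accessible", "CCR")))
  })
}

#' Simulate a differential-expression table with class-conditional direction
#'
#' Each gene's direction is drawn from its class's `(p_up, p_down)`;
#' up/down genes receive `log2fc = +/- effect` plus small noise and
#' `padj ~ U(0, 0.05)`, while ns genes receive `log2fc ~ Normal(0, 0.1)`
#' and `padj ~ U(0.05, 1)`.
#'
#' @param classes named character/factor vector: class per gene id.
#' @param p_up,p_down named per-class probabilities (a single unnamed value
#'   recycles to all classes); `p_up + p_down <= 1` per class.
#' @param effect log2 fold-change magnitude for up/down genes
#'   (default 1.5).
#' @param seed integer seed (required).
#' @return data.frame with columns `gene`, `log2fc`, `padj` and the truth
#'   column `true_direction`.
#' @export
simulate_deg <- function(classes, p_up, p_down, effect = 1.5, seed) {
  stopifnot(!missing(seed), !is.null(names(classes)))
  cls <- as.character(classes)
  expand <- function(p) {
    if (is.null(names(p)) && length(p) == 1L)
      p <- setNames(rep(p, length(unique(cls))), unique(cls))
    stopifnot(all(unique(cls) %in% names(p)))
    p
  }
  p_up <- expand(p_up); p_down <- expand(p_down)
  stopifnot(all(p_up[unique(cls)] + p_down[unique(cls)] <= 1))
  with_seed(seed, {
    n <- length(classes)
    u <- runif(n)
    dir <- ifelse(u < p_up[cls], "up",
                  ifelse(u < p_up[cls] + p_down[cls], "down", "ns"))
    lfc <- rnorm(n, 0, 0.1)
    lfc[dir == "up"] <- effect + rnorm(sum(dir == "up"), 0, 0.1)
    lfc[dir == "down"] <- -effect + rnorm(sum(dir == "down"), 0, 0.1)
    padj <- runif(n, 0.05, 1)
    padj[dir != "ns"] <- runif(sum(dir != "ns"), 0, 0.05)
    data.frame(gene = names(classes), log2fc = lfc, padj = padj,
               true_direction = dir, stringsAsFactors = FALSE)
  })
}

#' Simulate a pair of identifier sets with fixed overlap
#'
#' @param size_a,size_b set cardinalities.
#' @param overlap shared cardinality, at most `min(size_a, size_b)`.
#' @param seed integer seed (required; ids are shuffled deterministically).
#' @param prefix id prefix.
#' @return list of character vectors `a` and `b` with exactly the requested
#'   cardinalities and intersection.
#' @examples
#' s <- simulate_set_pair(30, 40, 12, seed = 1)
#' set_overlap_summary(s$a, s$b)$percent_a_shared  # 40
#' @export
simulate_set_pair <- function(size_a, size_b, overlap, seed,
                              prefix = "id") {
  if (overlap > min(size_a, size_b))
    stop("overlap exceeds the smaller set size")
  stopifnot(!missing(seed), size_a >= 0, size_b >= 0, overlap >= 0)
  total <- size_a + size_b - overlap
  ids <- sprintf("%s_%05d", prefix, seq_len(total))
  with_seed(seed, {
    ids <- sample(ids)
    shared <- ids[seq_len(overlap)]
    only_a <- ids[overlap + seq_len(size_a - overlap)]
    only_b <- ids[size_a + seq_len(size_b - overlap)]
    list(a = c(shared, only_a), b = c(shared, only_b))
  })
}
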