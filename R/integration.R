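# shared chi-squared core: validates the table, checks expected counts,
# and runs the uncorrected (or Yates-corrected) Pearson test
.chi2_on_matrix <- function(m, correct = FALSE) {
  stopifnot(is.matrix(m), all(m >= 0))
  total <- sum(m)
  if (total == 0) stop("empty contingency table (total = 0)")
  expected <- outer(rowSums(m), colSums(m)) / total
  if (any(expected == 0))
    stop("expected count of 0 in the contingency table; ",
         "pool sparse categories before testing")
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  structure(list(observed = m, expected = expected,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p.value = ct$p.value),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  print(x$observed)
  invisible(x)
}

#' Partition bound sites into accessible regions and CCRs
#'
#' A bound site overlapping at least one ATAC peak (by at least `min_bp`
#' bases) is called accessible; sites with no overlapping ATAC peak are
#' closed chromatin regions (CCRs).
#'
#' @param bound `GRanges` of TF-bound sites.
#' @param atac `GRanges` of ATAC (accessibility) peaks.
#' @param min_bp minimum shared bases (default 1).
#' @return list with `labels` (factor `accessible`/`CCR` per site),
#'   `n_accessible`, `n_ccr`, `accessible_percent`, `ccr_percent`.
#' @export
classify_accessibility <- function(bound, atac, min_bp = 1L) {
  acc <- .count_hits(bound, atac, min_bp) > 0
  n <- length(bound)
  list(labels = factor(ifelse(acc, "accessible", "CCR"),
                       levels = c("accessible", "CCR")),
       n_accessible = sum(acc), n_ccr = sum(!acc),
       accessible_percent = if (n) 100 * sum(acc) / n else NA_real_,
       ccr_percent = if (n) 100 * sum(!acc) / n else NA_real_)
}

#' Chi-squared test on a cross-tabulation of two labelings
#'
#' Pearson chi-squared without continuity correction (Yates correction
#' available for 2 x 2 tables via `correct = TRUE`) on the contingency
#' table of two categorical labelings of the same items. A precomputed
#' contingency matrix may be passed as `row_labels` with
#' `col_labels = NULL`.
#'
#' @param row_labels categorical vector (or a contingency matrix).
#' @param col_labels categorical vector of the same length, or `NULL`.
#' @param correct apply Yates continuity correction (2 x 2 only).
#' @return an object of class `contingency_result`: `observed`, `expected`,
#'   `statistic`, `df` = (r-1)(c-1), `p.value`.
#' @examples
#' crosstab_chi2(matrix(c(20, 10, 10, 20), 2))
#' @export
crosstab_chi2 <- function(row_labels, col_labels = NULL, correct = FALSE) {
  if (is.matrix(row_labels) && is.null(col_labels))
    return(.chi2_on_matrix(row_labels, correct))
  if (length(row_labels) != length(col_labels))
    stop("row and column labelings must have the same length")
  m <- as.matrix(table(row_labels, col_labels))
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 categories in each labeling")
  .chi2_on_matrix(m, correct)
}

#' Read a differential-expression table
#'
#' @param path tab-separated file with header columns `gene`, `log2fc`,
#'   `padj` (extra columns are kept).
#' @return data.frame with unique gene ids.
#' @export
read_deg_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("duplicated gene ids in DEG table")
  df
}

#' Call differential-expression direction per gene
#'
#' A gene is `up` when its fold change exceeds `min_fold` with
#' `padj < max_padj`, `down` when the fold change is below `1/min_fold`
#' with `padj < max_padj`, and `ns` otherwise (including missing `padj`).
#' The default thresholds are fold change > 1.5 and adjusted p < 0.05.
#'
#' @param deg data.frame with columns `gene`, `log2fc`, `padj`.
#' @param min_fold fold-change threshold (> 1); applied symmetrically.
#' @param max_padj adjusted-p threshold in (0, 1].
#' @return the input with an added factor column `direction`
#'   (levels `up`, `down`, `ns`).
#' @export
deg_filter <- function(deg, min_fold = 1.5, max_padj = 0.05) {
  stopifnot(min_fold > 1, max_padj > 0, max_padj <= 1,
            all(c("gene", "log2fc", "padj") %in% names(deg)))
  fold <- 2^deg$log2fc
  sig <- !is.na(deg$padj) & deg$padj < max_padj
  dir <- ifelse(sig & fold > min_fold, "up",
                ifelse(sig & fold < 1 / min_fold, "down", "ns"))
  deg$direction <- factor(dir, levels = c("up", "down", "ns"))
  deg
}

#' Expression direction by binding/footprint class
#'
#' Cross-tabulates per-gene site classes (e.g. "PRDM1 footprint only" vs
#' "PRDM1 + AP-1 footprints") against DEG direction. Genes classified but
#' absent from the DEG table are counted as `ns` (with a message); the
#' chi-squared test is computed on the class-by-{up, down} table, excluding
#' `ns`, and empty classes are dropped from the test with a warning.
#'
#' @param site_classes named character/factor vector: class per gene id.
#' @param deg DEG data.frame; passed through [deg_filter()] if it lacks a
#'   `direction` column.
#' @param min_fold,max_padj thresholds forwarded to [deg_filter()].
#' @return list with `proportions` (data.frame of per-class counts and
#'   percentages of up/down/ns) and `test` (a `contingency_result`, or
#'   `NULL` when fewer than two classes have up/down calls).
#' @export
direction_by_class <- function(site_classes, deg, min_fold = 1.5,
                               max_padj = 0.05) {
  stopifnot(!is.null(names(site_classes)))
  if (is.null(deg$direction)) deg <- deg_filter(deg, min_fold, max_padj)
  dir <- setNames(as.character(deg$direction), deg$gene)
  genes <- names(site_classes)
  missing <- !genes %in% names(dir)
  if (any(missing))
    message(sum(missing), " classified gene(s) absent from the DEG table; ",
            "counted as ns")
  gdir <- ifelse(missing, "ns", dir[genes])
  cls <- as.character(site_classes)
  tab <- table(class = cls,
               direction = factor(gdir, levels = c("up", "down", "ns")))
  prop <- as.data.frame.matrix(tab)
  prop <- cbind(class = rownames(prop), prop,
                100 * prop / pmax(rowSums(prop), 1))
  names(prop) <- c("class", "n_up", "n_down", "n_ns",
                   "pct_up", "pct_down", "pct_ns")
  rownames(prop) <- NULL
  updown <- as.matrix(tab[, c("up", "down"), drop = FALSE])
  empty <- rowSums(updown) == 0
  if (any(empty)) {
    warning("class(es) with no up/down calls excluded from the test: ",
            paste(rownames(updown)[empty], collapse = ", "))
    updown <- updown[!empty, , drop = FALSE]
  }
  test <- if (nrow(updown) >= 2 && all(colSums(updown) > 0))
    .chi2_on_matrix(updown) else NULL
  list(proportions = prop, test = test)
}

#' Overlap summary of two identifier sets
#'
#' Identifiers are normalized (whitespace trimmed, upper-cased) before
#' exact matching.
#'
#' @param a,b character vectors of identifiers (duplicates collapse).
#' @return list with `n_a`, `n_b`, `n_shared`, `percent_a_shared`,
#'   `percent_b_shared`.
#' @examples
#' set_overlap_summary(c("TP53", "MYC"), c("myc", "BCL6"))
#' @export
set_overlap_summary <- function(a, b) {
  a <- unique(toupper(trimws(a)))
  b <- unique(toupper(trimws(b)))
  shared <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_shared = shared,
       percent_a_shared = if (length(a)) 100 * shared / length(a) else
         NA_real_,
       percent_b_shared = if (length(b)) 100 * shared / length(b) else
         NA_real_)
}

#' Filter proteins enriched in a tagged sample over control
#'
#' Keeps proteins whose pseudocount-stabilized normalized-count ratio
#' (tagged vs control) strictly exceeds `min_ratio` — "more than
#' `min_ratio`-fold", so a ratio exactly at the threshold is dropped.
#'
#' @param counts data.frame with columns `protein`, `count_tagged`,
#'   `count_control` (normalized peptide counts, >= 0).
#' @param min_ratio fold-enrichment threshold (default 2).
#' @param pseudocount added to both counts to stabilize zero controls
#'   (default 0.5; set to 0 for raw ratios).
#' @return character vector of enriched protein ids.
#' @export
protein_enrichment_filter <- function(counts, min_ratio = 2,
                                      pseudocount = 0.5) {
  stopifnot(all(c("protein", "count_tagged", "count_control") %in%
                  names(counts)))
  if (any(counts$count_tagged < 0 | counts$count_control < 0))
    stop("negative peptide counts")
  ratio <- (counts$count_tagged + pseudocount) /
    (counts$count_control + pseudocount)
  counts$protein[ratio > min_ratio]
}
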