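test_that("accessibility partition labels sites and sums to 100%", {
  bound <- gr0("chr1", c(100, 300, 500), c(200, 400, 600))
  atac <- gr0("chr1", 120, 180)
  r <- classify_accessibility(bound, atac)
  expect_equal(as.character(r$labels), c("accessible", "CCR", "CCR"))
  expect_equal(r$accessible_percent + r$ccr_percent, 100)
  # empty ATAC set -> 100% CCR
  expect_equal(classify_accessibility(bound, GRanges())$ccr_percent, 100)
  # site fully inside an ATAC peak is accessible
  expect_equal(as.character(
    classify_accessibility(gr0("chr1", 150, 160),
                           gr0("chr1", 100, 200))$labels), "accessible")
})

test_that("engineered CCR counts reproduce the printed percentage", {
  n <- 2137; n_ccr <- 430
  bound <- GRanges("chr1", IRanges(seq_len(n) * 1000, width = 200))
  atac <- granges(bound[seq_len(n - n_ccr)])
  r <- classify_accessibility(bound, atac)
  expect_equal(round(r$ccr_percent, 1), 20.1)
})

test_that("crosstab chi-squared matches the closed form", {
  r <- crosstab_chi2(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1)
  r0 <- crosstab_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  expect_error(crosstab_chi2(c("a", "b"), c("x", "y", "z")), "same length")
  expect_error(crosstab_chi2(matrix(c(5, 5, 0, 0), 2)), "pool")
  expect_error(crosstab_chi2(matrix(0, 2, 2)), "empty")
})

test_that("crosstab equals hand-computed sums over random all-positive tables", {
  withr::local_seed(8)
  for (i in 1:40) {
    m <- matrix(sample(5:60, 4), 2)
    r <- crosstab_chi2(m)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(r$statistic, sum((m - e)^2 / e), tolerance = 1e-10)
    expect_equal(r$expected, e)
    # label-vector route agrees with the matrix route
    rows <- rep(rep(c("r1", "r2"), each = 2), as.vector(t(m)))
    cols <- rep(rep(c("c1", "c2"), 2), as.vector(t(m)))
    expect_equal(crosstab_chi2(rows, cols)$statistic, r$statistic)
  }
})

test_that("deg_filter applies the fold-change and padj thresholds", {
  deg <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    log2fc = c(1.0, 0.485, -2, -1.2, 2),
    padj = c(0.01, 0.001, NA, 0.2, 0.04))
  d <- deg_filter(deg)
  expect_equal(as.character(d$direction),
               c("up",    # fold 2 > 1.5, significant
                 "ns",    # fold ~1.4 below threshold despite tiny padj
                 "ns",    # missing padj
                 "ns",    # padj above threshold
                 "up"))
  d2 <- deg_filter(deg[c(4, 1, 3, 2, 5), ])
  expect_equal(table(d2$direction), table(d$direction))  # order-invariant
  expect_equal(as.character(deg_filter(data.frame(
    gene = "g", log2fc = -1, padj = 0.01))$direction), "down")
  expect_error(deg_filter(deg, min_fold = 1), "min_fold")
})

test_that("direction_by_class recovers planted per-class up-proportions", {
  withr::local_seed(19)
  n <- 400
  classes <- setNames(rep(c("both", "a_only"), each = n),
                      paste0("g", seq_len(2 * n)))
  deg <- simulate_deg(classes, p_up = c(both = 0.6, a_only = 0.2),
                      p_down = 0.1, seed = 23)
  r <- direction_by_class(classes, deg)
  p_both <- r$proportions$pct_up[r$proportions$class == "both"] / 100
  p_a <- r$proportions$pct_up[r$proportions$class == "a_only"] / 100
  expect_lt(abs(p_both - 0.6), 3 * sqrt(0.6 * 0.4 / n))
  expect_lt(abs(p_a - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(r$test$p.value, 0.01)
})

test_that("direction_by_class handles missing genes and degenerate classes", {
  classes <- setNames(c("x", "x", "y", "y"), paste0("g", 1:4))
  deg <- data.frame(gene = c("g1", "g2", "g3"),
                    log2fc = c(2, -2, 2), padj = c(0.01, 0.01, 0.01))
  expect_message(r <- direction_by_class(classes, deg), "absent")
  expect_equal(r$proportions$n_ns[r$proportions$class == "y"], 1)
  one_dir <- data.frame(gene = paste0("g", 1:4), log2fc = c(2, 2, 0, 0),
                        padj = c(0.01, 0.01, 0.9, 0.9))
  expect_warning(r2 <- direction_by_class(classes, one_dir),
                 "excluded from the test")
  expect_null(r2$test)
})

test_that("set overlap summaries reproduce printed percentages and symmetry", {
  s <- simulate_set_pair(1772, 3586, 1651, seed = 1, prefix = "gene")
  r <- set_overlap_summary(s$a, s$b)
  expect_equal(r$n_shared, 1651)
  expect_equal(round(r$percent_a_shared, 1), 93.2)
  sw <- set_overlap_summary(s$b, s$a)
  expect_equal(sw$percent_b_shared, r$percent_a_shared)
  expect_equal(set_overlap_summary(c("a", "b"), c("c", "d"))$n_shared, 0)
  expect_equal(set_overlap_summary(c("a"), c("a", "b"))$percent_a_shared,
               100)
  # whitespace/case normalization before matching
  expect_equal(set_overlap_summary(c(" TP53", "myc"),
                                   c("tp53 ", "MYC"))$n_shared, 2)
})

test_that("protein enrichment keeps strictly more-than-threshold ratios", {
  counts <- data.frame(protein = c("A", "B", "C"),
                       count_tagged = c(10, 8, 3),
                       count_control = c(4, 4, 0))
  expect_setequal(protein_enrichment_filter(counts, pseudocount = 0),
                  c("A", "C"))  # 2.5 kept, exactly 2.0 dropped, 3/0 = Inf
  expect_setequal(protein_enrichment_filter(counts, pseudocount = 0.5),
                  c("A", "C"))  # (3+.5)/(0+.5) = 7 kept
  expect_error(protein_enrichment_filter(
    data.frame(protein = "X", count_tagged = -1, count_control = 2)),
    "negative")
})
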