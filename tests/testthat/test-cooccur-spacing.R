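# minimal hit builder: a hit GRanges carrying only what the classifier uses
mk_hits <- function(containers, ids) {
  if (!length(ids))
    return(GRanges(motif_id = character(0), score = numeric(0),
                   container = character(0)))
  idx <- match(ids, names(containers))
  h <- granges(containers[idx])
  h$motif_id <- "m"; h$score <- 1; h$container <- ids
  h
}

test_that("co-occurrence classification covers the four classes", {
  cont <- GRanges("chr1", IRanges(c(1, 101, 201, 301), width = 50))
  names(cont) <- paste0("p", 1:4)
  tab <- classify_cooccurrence(cont, mk_hits(cont, c("p1", "p3")),
                               mk_hits(cont, c("p2", "p3")))
  expect_equal(tab$n_a_only, 1)
  expect_equal(tab$n_b_only, 1)
  expect_equal(tab$n_both, 1)
  expect_equal(tab$n_neither, 1)
  expect_equal(sum(tab$percent), 100)
  stray <- GRanges("chr1", IRanges(1, 10), motif_id = "m", score = 1,
                   container = "p9")
  expect_error(classify_cooccurrence(cont, mk_hits(cont, "p1"), stray),
               "unknown container")
})

test_that("classification is invariant to hit order and duplication", {
  cont <- GRanges("chr1", IRanges(c(1, 101, 201), width = 50))
  names(cont) <- paste0("p", 1:3)
  a1 <- mk_hits(cont, c("p1", "p2"))
  a2 <- mk_hits(cont, c("p2", "p1", "p1", "p2", "p2"))
  b <- mk_hits(cont, "p2")
  t1 <- classify_cooccurrence(cont, a1, b)
  t2 <- classify_cooccurrence(cont, a2, b)
  expect_equal(t1$percent, t2$percent)
  expect_equal(t1$n_both, 1)
})

test_that("planted class counts reproduce the printed motif percentages", {
  counts <- c(a_only = 593, b_only = 97, both = 171, neither = 139)
  cont <- GRanges("chr1", IRanges(seq_len(sum(counts)) * 100, width = 50))
  names(cont) <- sprintf("p%04d", seq_along(cont))
  cls <- rep(names(counts), counts)
  a_ids <- names(cont)[cls %in% c("a_only", "both")]
  b_ids <- names(cont)[cls %in% c("b_only", "both")]
  tab <- classify_cooccurrence(cont, mk_hits(cont, a_ids),
                               mk_hits(cont, b_ids))
  expect_equal(round(tab$percent[["a_only"]], 1), 59.3)
  expect_equal(round(tab$percent[["b_only"]], 1), 9.7)
  expect_equal(round(tab$percent[["both"]], 1), 17.1)
  expect_equal(round(tab$percent[["neither"]], 1), 13.9)
})

test_that("compare_cooccurrence runs a df-3 chi-squared on the 2x4 table", {
  cont <- GRanges("chr1", IRanges(1:40 * 100, width = 50))
  names(cont) <- paste0("p", 1:40)
  cls <- rep(c("a_only", "b_only", "both", "neither"), each = 10)
  a <- mk_hits(cont, names(cont)[cls %in% c("a_only", "both")])
  b <- mk_hits(cont, names(cont)[cls %in% c("b_only", "both")])
  tab <- classify_cooccurrence(cont, a, b)
  same <- compare_cooccurrence(tab, tab)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$df, 3)
  # all-zero class column -> error advising pooling
  tab0 <- classify_cooccurrence(cont, a, mk_hits(cont, character(0)))
  tab0b <- tab0; tab0b$n_a_only <- tab0b$n_a_only + 5
  expect_error(compare_cooccurrence(tab0, tab0b), "pool")
})

test_that("pair distances use floor-center arithmetic per container", {
  cont <- GRanges("chr1", IRanges(1, 300)); names(cont) <- "p1"
  a <- GRanges("chr1", IRanges(101, 110), motif_id = "a", score = 1,
               container = "p1")  # 0-based [100,110): center 105
  b <- GRanges("chr1", IRanges(126, 135), motif_id = "b", score = 1,
               container = "p1")  # 0-based [125,135): center 130
  d <- pair_distance_distribution(cont, a, b)
  expect_equal(d$distances, 25L)
  # edge convention: gap between closest edges
  de <- pair_distance_distribution(cont, a, b, convention = "edge")
  expect_equal(de$distances, 15L)
  # overlapping hits clamp to 0 under the edge convention
  b2 <- GRanges("chr1", IRanges(105, 114), motif_id = "b", score = 1,
                container = "p1")
  expect_equal(
    pair_distance_distribution(cont, a, b2, convention = "edge")$distances,
    0L)
  # no container with both motifs -> empty distribution
  empty <- pair_distance_distribution(cont, a, a[0])
  expect_length(empty$distances, 0)
  expect_true(is.na(empty$median))
})

test_that("nearest pair is selected when containers hold multiple hits", {
  cont <- GRanges("chr1", IRanges(1, 500)); names(cont) <- "p1"
  a <- GRanges("chr1", IRanges(c(101, 301), width = 10),
               motif_id = "a", score = 1, container = c("p1", "p1"))
  b <- GRanges("chr1", IRanges(c(131, 321), width = 10),
               motif_id = "b", score = 1, container = c("p1", "p1"))
  # all pairwise center distances: 30, 220, 170, 20 -> min 20
  expect_equal(pair_distance_distribution(cont, a, b)$distances, 20L)
})

test_that("ks_two_sample computes the ECDF sup and sensible p-values", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, c(4, 5, 6))$statistic, 1)
  expect_error(ks_two_sample(numeric(0), x), "non-empty")
  r <- ks_two_sample(c(1, 5, 7), c(2, 3, 9))
  expect_equal(r$statistic, ks_two_sample(c(2, 3, 9), c(1, 5, 7))$statistic)
  expect_true(r$statistic >= 0 && r$statistic <= 1)
})

test_that("KS D matches the brute-force ECDF oracle; exact p matches ks.test", {
  withr::local_seed(91)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    r <- ks_two_sample(x, y)
    expect_equal(r$statistic, bf_ks_D(x, y), tolerance = 1e-12)
    if (r$method == "exact")
      expect_equal(r$p.value, stats::ks.test(x, y)$p.value,
                   tolerance = 1e-9)
  }
  # large tie-free samples: asymptotic p close to ks.test's
  x <- rnorm(200); y <- rnorm(150, 0.2)
  r <- ks_two_sample(x, y)
  expect_equal(r$method, "asymptotic")
  expect_equal(r$p.value, stats::ks.test(x, y)$p.value, tolerance = 0.05)
  # ties fall back to the asymptotic route without error
  expect_no_error(ks_two_sample(c(1, 1, 2, 3, 3), c(1, 2, 2, 4)))
})

test_that("modal spacing bin is centered and contains a planted 25 bp mode", {
  withr::local_seed(77)
  d <- pmax(0, round(rnorm(500, 25, 2)))
  sd_ <- spacing_distribution(d)
  expect_equal(sd_$modal_bin[["center"]], 25L)
  expect_true(sd_$modal_bin[["lo"]] <= 25 && 25 < sd_$modal_bin[["hi"]])
  expect_error(spacing_distribution(c(3, -1)), ">= 0")
})
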