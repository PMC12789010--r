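test_that("simulated genomes are deterministic with near-uniform composition", {
  g1 <- simulate_genome(c(chr1 = 1e5, chr2 = 1e5), seed = 5)
  g2 <- simulate_genome(c(chr1 = 1e5, chr2 = 1e5), seed = 5)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_equal(width(g1$sequences), c(1e5, 1e5), ignore_attr = TRUE)
  comp <- Biostrings::alphabetFrequency(g1$sequences, collapse = TRUE)
  freq <- comp[c("A", "C", "G", "T")] / 2e5
  expect_true(all(abs(freq - 0.25) < 0.01))
  g3 <- simulate_genome(c(chr1 = 1e5, chr2 = 1e5), seed = 6)
  expect_false(identical(as.character(g1$sequences),
                         as.character(g3$sequences)))
  # unnamed lengths get default chromosome names
  expect_named(simulate_genome(c(2e4, 1e4), seed = 1)$sequences,
               c("chr1", "chr2"))
})

test_that("planted class counts are recovered exactly from truth hits", {
  g <- simulate_genome(c(chr1 = 2e5, chr2 = 1e5), seed = 2)
  counts <- c(a_only = 60, b_only = 25, both = 30, neither = 15)
  sim <- simulate_peaks_with_motifs(g, counts, seed = 3)
  tab <- classify_cooccurrence(sim$containers, sim$hits_a, sim$hits_b)
  expect_equal(tab$n_a_only, 60)
  expect_equal(tab$n_b_only, 25)
  expect_equal(tab$n_both, 30)
  expect_equal(tab$n_neither, 15)
  expect_equal(as.vector(table(sim$truth$class)[c("a_only", "b_only",
                                                  "both", "neither")]),
               unname(counts))
  # containers do not overlap each other
  expect_equal(sum(width(reduce(sim$containers))),
               sum(width(sim$containers)))
  # determinism
  sim2 <- simulate_peaks_with_motifs(g, counts, seed = 3)
  expect_identical(sim$truth, sim2$truth)
  expect_error(simulate_peaks_with_motifs(
    g, c(a_only = 1e5, b_only = 0, both = 0, neither = 0), seed = 1),
    "capacity")
})

test_that("zero spacing-sd plants every pair at exactly the mean distance", {
  g <- simulate_genome(c(chr1 = 1e5), seed = 4)
  sim <- simulate_peaks_with_motifs(
    g, c(a_only = 0, b_only = 0, both = 40, neither = 0),
    spacing_mean = 25, spacing_sd = 0, seed = 5)
  expect_true(all(sim$truth$distance == 25))
  d <- pair_distance_distribution(sim$containers, sim$hits_a, sim$hits_b)
  expect_true(all(d$distances == 25))
})

test_that("the scanner rediscovers planted instances at consensus threshold", {
  g <- simulate_genome(c(chr1 = 4e5), seed = 6)
  counts <- c(a_only = 100, b_only = 50, both = 50, neither = 30)
  sim <- simulate_peaks_with_motifs(g, counts, seed = 7)
  pws <- example_pwms()
  ha <- scan_pwm(sim$containers, sim$sequences, pws$prdm1_like,
                 max_score(pws$prdm1_like))
  hb <- scan_pwm(sim$containers, sim$sequences, pws$runx_like,
                 max_score(pws$runx_like))
  planted_a <- unique(sim$hits_a$container)
  planted_b <- unique(sim$hits_b$container)
  expect_gte(mean(planted_a %in% ha$container), 0.99)
  expect_gte(mean(planted_b %in% hb$container), 0.99)
})

test_that("replicate simulation hits the binomial consensus expectation", {
  g <- simulate_genome(c(chr1 = 1e6, chr2 = 1e6), seed = 8)
  sim <- simulate_peaks_with_motifs(
    g, c(a_only = 0, b_only = 0, both = 0, neither = 1000), seed = 9)
  # perfect detection, no jitter: consensus equals the containers
  reps <- simulate_replicates(sim$containers, g$layout, 3,
                              detection_prob = 1, jitter_sd = 0, seed = 10)
  cp <- consensus_peaks(reps, 2)
  expect_equal(as.character(granges(cp)),
               unname(as.character(granges(sim$containers))))
  # detection p: P(peak in >= 2 of 3 replicates) = 3p^2(1-p) + p^3
  p <- 0.8
  reps <- simulate_replicates(sim$containers, g$layout, 3,
                              detection_prob = p, jitter_sd = 0, seed = 11)
  cp <- consensus_peaks(reps, 2)
  expected <- 3 * p^2 * (1 - p) + p^3
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(length(cp) / 1000 - expected), 3 * se)
  # detection 0: empty replicates, empty consensus
  reps0 <- simulate_replicates(sim$containers, g$layout, 3,
                               detection_prob = 0, seed = 12)
  expect_true(all(lengths(reps0) == 0))
  expect_length(consensus_peaks(reps0, 2), 0)
})

test_that("accessibility simulation honors probabilities and exact counts", {
  g <- simulate_genome(c(chr1 = 6e5), seed = 13)
  sim <- simulate_peaks_with_motifs(
    g, c(a_only = 250, b_only = 0, both = 250, neither = 0), seed = 14)
  # P(accessible) = 1 -> no CCR at all
  acc1 <- simulate_accessibility(sim$containers, 1, seed = 15)
  expect_equal(classify_accessibility(sim$containers,
                                      acc1$atac)$ccr_percent, 0)
  # class-conditional probabilities land within binomial tolerance
  acc <- simulate_accessibility(sim$containers,
                                c(a_only = 0.6, both = 0.9), seed = 16)
  lab <- classify_accessibility(sim$containers, acc$atac)$labels
  expect_identical(as.character(lab), as.character(acc$labels))
  p_a <- mean(lab[sim$containers$class == "a_only"] == "accessible")
  expect_lt(abs(p_a - 0.6), 3 * sqrt(0.6 * 0.4 / 250))
  # exact-counts mode
  accc <- simulate_accessibility(sim$containers,
                                 c(a_only = 200, both = 100),
                                 mode = "counts", seed = 17)
  expect_equal(sum(accc$labels == "accessible"), 300)
})

test_that("DEG simulation respects class-conditional certainty and filters", {
  classes <- setNames(rep(c("x", "y"), each = 50), paste0("g", 1:100))
  deg <- simulate_deg(classes, p_up = c(x = 1, y = 0), p_down = 0,
                      seed = 18)
  d <- deg_filter(deg)
  expect_true(all(d$direction[d$gene %in% paste0("g", 1:50)] == "up"))
  expect_true(all(d$direction[d$gene %in% paste0("g", 51:100)] == "ns"))
  expect_identical(deg, simulate_deg(classes, p_up = c(x = 1, y = 0),
                                     p_down = 0, seed = 18))
})

test_that("set-pair simulation enforces feasibility and exact cardinalities", {
  s <- simulate_set_pair(30, 40, 12, seed = 19)
  expect_length(s$a, 30)
  expect_length(s$b, 40)
  expect_length(intersect(s$a, s$b), 12)
  expect_equal(set_overlap_summary(s$a, s$b)$percent_a_shared, 40)
  expect_error(simulate_set_pair(10, 5, 8, seed = 1), "exceeds")
  s0 <- simulate_set_pair(10, 10, 0, seed = 2)
  expect_length(intersect(s0$a, s0$b), 0)
})
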