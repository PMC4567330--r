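test_that("interval score arithmetic matches its definition", {
  expect_equal(interval_score(c(1, 1, 1, 1), 0.5, 1, 4), 4.0)
  expect_equal(interval_score(rep(0, 5), 1, 2, 4), 0)
  expect_error(interval_score(1:3, 0, 1, 2), "sigma")
  expect_error(interval_score(1:3, 1, 0, 2), "i <= j")
  # brute force over all 6 sub-intervals of a 3-probe vector
  r <- c(0.9, 0.1, 0.8)
  scores <- c(interval_score(r, 0.3, 1, 1), interval_score(r, 0.3, 2, 2),
              interval_score(r, 0.3, 3, 3), interval_score(r, 0.3, 1, 2),
              interval_score(r, 0.3, 2, 3), interval_score(r, 0.3, 1, 3))
  expect_equal(max(scores), interval_score(r, 0.3, 1, 3))
  expect_equal(max(scores), 6 / sqrt(3))
})

test_that("a noise-free planted block is recovered with closed-form score", {
  y <- numeric(100); y[41:60] <- 1.0
  p <- toy_profile(y)
  segs <- detect_aberrations(p, sigma = 0.1)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$probe_from, 41L)
  expect_equal(segs$probe_to, 60L)
  expect_equal(segs$score, 20 * 10 / sqrt(20))
  expect_equal(segs$mean_log2, 1.0)

  expect_equal(nrow(detect_aberrations(toy_profile(numeric(100)),
                                       sigma = 0.1)), 0L)
})

test_that("disjoint planted blocks give exactly their true boundaries", {
  y <- numeric(200); y[21:40] <- 0.8; y[151:170] <- -0.9
  p <- toy_profile(y, grid_design(200L))
  segs <- detect_aberrations(p, sigma = 0.1)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$probe_from, c(21L, 151L))
  expect_equal(segs$probe_to, c(40L, 170L))
  expect_equal(sign(segs$mean_log2), c(1, -1))
})

test_that("exact mode equals an independent brute-force maximizer", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    y <- rnorm(n)
    if (rep %% 2 == 0) {
      at <- sample.int(n - 10, 1)
      y[at:(at + 9)] <- y[at:(at + 9)] + 1.5
    }
    got <- cnamcr:::.max_interval_exact(y, 1)
    want <- brute_max_interval(y, 1)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_identical(c(got$from, got$to), c(want$from, want$to))
  }
})

test_that("detection is sign-symmetric: negation swaps gains and losses", {
  set.seed(13)
  y <- rnorm(300, sd = 0.1)
  y[50:80] <- y[50:80] + 1; y[200:215] <- y[200:215] - 1.2
  p <- toy_profile(y, grid_design(300L))
  pn <- toy_profile(-y, grid_design(300L))
  a <- detect_aberrations(p, sigma = 0.1)
  b <- detect_aberrations(pn, sigma = 0.1)
  expect_equal(a[c("probe_from", "probe_to", "score")],
               b[c("probe_from", "probe_to", "score")])
  expect_equal(a$mean_log2, -b$mean_log2)
})

test_that("emitted segments score above threshold and never overlap", {
  set.seed(21)
  y <- rnorm(400, sd = 0.15)
  for (at in c(30, 150, 300)) y[at:(at + 14)] <- y[at:(at + 14)] + 0.9
  p <- toy_profile(y, grid_design(400L))
  segs <- detect_aberrations(p, threshold = 6)
  expect_true(all(segs$score >= 6))
  if (nrow(segs) > 1) {
    segs <- segs[order(segs$probe_from), ]
    expect_true(all(segs$probe_from[-1] > segs$probe_to[-nrow(segs)]))
  }
})

test_that("an uncentralized profile warns but still segments", {
  y <- numeric(50); y[10:20] <- 1
  p <- array_profile("S1", grid_design(50L), y)
  expect_warning(segs <- detect_aberrations(p, sigma = 0.1), "centralized")
  expect_equal(nrow(segs), 1L)
})

test_that("fuzzy-zero filter follows its quality formula", {
  seg <- function(mean_log2, n) data.frame(
    sample_id = "S1", chrom = "chr1", start = 0, end = n * 100,
    probe_from = 1L, probe_to = n, n_probes = n, mean_log2 = mean_log2,
    score = 10, stringsAsFactors = FALSE)
  segs <- rbind(seg(0.05, 10000L), seg(1.0, 20L))
  # nu = 0 disables the correction for anything already past threshold
  expect_equal(nrow(fuzzy_zero_filter(segs, nu = 0, sigma = 0.2,
                                      threshold = 6)), 2L)
  out <- fuzzy_zero_filter(segs, nu = 0.05, sigma = 0.2, threshold = 6)
  # long low-amplitude segment: quality ~= 0.05/sqrt(4e-6 + 2.5e-3) ~= 1 -> drop
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_log2, 1.0)
  expect_equal(out$fuzzy_quality, 1 / sqrt(0.2^2 / 20 + 0.05^2),
               tolerance = 1e-12)
  expect_equal(out$fuzzy_quality, 14.907, tolerance = 1e-3)
  expect_error(fuzzy_zero_filter(segs, nu = -1, sigma = 0.2), "nu")
})

test_that("reporting filters and amplitude classes are bit-exact", {
  seg <- function(mean_log2, n) data.frame(
    sample_id = "S1", chrom = "chr1", start = 0, end = n * 100,
    probe_from = 1L, probe_to = n, n_probes = n, mean_log2 = mean_log2,
    score = 10, stringsAsFactors = FALSE)
  segs <- do.call(rbind, list(
    seg(-0.9, 5L),    # loss, deletion
    seg(0.3, 2L),     # dropped: probe filter
    seg(0.24, 50L),   # dropped: amplitude filter (< 0.25 exclusive)
    seg(0.25, 3L),    # kept: both boundaries inclusive
    seg(0.8, 4L),     # amplification at the exact cutoff
    seg(-0.79, 4L),   # loss, below deletion cutoff
    seg(0.5, 10L)))   # plain gain
  out <- filter_and_classify(segs)
  expect_equal(out$mean_log2, c(-0.9, 0.25, 0.8, -0.79, 0.5))
  expect_equal(out$direction, c("loss", "gain", "gain", "loss", "gain"))
  expect_equal(out$amplitude_class,
               c("deletion", "gain", "amplification", "loss", "gain"))
})

test_that("aberration summary counts and lengths follow the calls", {
  calls <- data.frame(sample_id = "S1", chrom = "chr1",
                      start = c(0, 1000), end = c(100, 1300),
                      n_probes = c(3L, 5L), mean_log2 = c(0.5, 0.6),
                      score = 10, direction = "gain",
                      amplitude_class = "gain", stringsAsFactors = FALSE)
  s <- aberration_summary(calls)
  expect_equal(s$cohort$mean_count[s$cohort$direction == "gain"], 2)
  expect_equal(s$cohort$median_length[s$cohort$direction == "gain"], 200)
  expect_true(is.na(s$cohort$median_length[s$cohort$direction == "loss"]))
  empty <- aberration_summary(calls[0, ], sample_ids = "S1")
  expect_equal(empty$cohort$mean_count, c(0, 0))
  expect_true(all(is.na(empty$cohort$median_length)))
})

test_that("summary of a perfectly recovered cohort equals the truth summary", {
  d <- grid_design(300L, spacing = 1000L)
  catalog <- data.frame(
    aberration_id = c("g1", "l1"), chrom = "chr1",
    start = c(50000, 200000), end = c(80000, 215000),
    direction = c("gain", "loss"), true_log2 = c(0.8, -0.8),
    prev_intestinal = 1, prev_diffuse = 1, prev_mixed = 1)
  sim <- simulate_cohort(list(d), catalog, n_samples_per_platform = 3L,
                         noise_sd = 0, curvature = 0, offset_sd = 0, seed = 6)
  calls <- do.call(rbind, lapply(sim$profiles, function(p) {
    p$state$centralized <- TRUE
    filter_and_classify(detect_aberrations(p, sigma = 0.05))
  }))
  s <- aberration_summary(calls, sim$truth$samples$sample_id)
  expect_equal(s$cohort$mean_count, c(1, 1))
  # recovered boundaries are the covered-probe hulls of the planted events
  expect_equal(sort(unique(calls$start)), c(50000, 200000))
  expect_equal(sort(unique(calls$end)), c(79060, 214060))
})
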