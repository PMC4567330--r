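test_that("Fisher's exact matches hypergeometric enumeration", {
  tab <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher.test(tab)$p.value, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_oracle(tab), 2 / 252, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    x <- rbinom(n, 1, 0.4); y <- rbinom(n, 1, 0.5)
    t2 <- table(factor(x, 0:1), factor(y, 0:1))
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher.test(t2)$p.value, fisher_oracle(t2),
                 tolerance = 1e-9)
  }
})

test_that("Lauren association switches between chi-square and Fisher", {
  set.seed(2)
  sids <- sprintf("S%02d", 1:60)
  types <- rep(c("diffuse", "intestinal", "mixed"), c(28, 28, 4))
  # strong association for gene A (large counts -> chi-square)
  hasA <- ifelse(types == "intestinal", runif(60) < 0.8, runif(60) < 0.2)
  # sparse gene B (small counts -> Fisher)
  hasB <- c(rep(TRUE, 3), rep(FALSE, 57))
  status <- rbind(
    data.frame(sample_id = sids, gene = "A", has_cna = hasA),
    data.frame(sample_id = sids, gene = "B", has_cna = hasB))
  out <- lauren_association(status, setNames(types, sids))
  expect_equal(out$test[out$gene == "A"], "chisq")
  expect_lt(out$p[out$gene == "A"], 0.01)
  expect_equal(out$test[out$gene == "B"], "fisher")

  # identical distribution in both types -> p ~= 1; empty margin -> NA
  same <- data.frame(sample_id = sids, gene = "C",
                     has_cna = rep(c(TRUE, FALSE), 30))
  out2 <- lauren_association(same, setNames(rep(c("diffuse", "intestinal"),
                                                each = 30), sids))
  expect_gt(out2$p, 0.5)
  none <- data.frame(sample_id = sids, gene = "D", has_cna = FALSE)
  expect_warning(out3 <- lauren_association(none, setNames(types, sids)),
                 "empty margin")
  expect_true(is.na(out3$p))
})

test_that("co-occurrence Fisher test: identical vectors give the minimal p", {
  a <- rep(c(TRUE, FALSE), each = 10)
  r <- gain_cooccurrence(a, a)
  # minimal attainable two-sided p at margins 10/10: 2/choose(20,10)
  expect_equal(r$p, fisher_oracle(table(factor(a, c(FALSE, TRUE)),
                                        factor(a, c(FALSE, TRUE)))),
               tolerance = 1e-12)
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_warning(r2 <- gain_cooccurrence(rep(TRUE, 10), a[1:10]), "margin")
  expect_true(is.na(r2$p))
})

test_that("co-occurrence p-values are roughly uniform under independence", {
  set.seed(31)
  ps <- replicate(1000, {
    a <- rbinom(1000, 1, 0.5) == 1
    b <- rbinom(1000, 1, 0.5) == 1
    suppressWarnings(gain_cooccurrence(a, b)$p)
  })
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(ks.test(ps, "punif"))
  # Fisher p-values are discrete and conservative; distance stays modest
  expect_lte(unname(ks$statistic), 0.1)
  expect_lte(mean(ps < 0.05), 0.06)
})

test_that("age correlation applies the Bonferroni cap and rule", {
  set.seed(6)
  ages <- rnorm(30, 60, 8)
  m <- cbind(g1 = ages * 0.01 + rnorm(30, sd = 1e-6),  # near-perfect r
             g2 = rnorm(30), g3 = rep(0, 30))
  out <- age_correlation(m, ages, m_genes = 15)
  expect_equal(out$r[out$gene == "g1"], 1, tolerance = 1e-4)
  expect_equal(out$p_bonferroni,
               pmin(1, out$p_raw * 15))
  expect_true(is.na(out$r[out$gene == "g3"]))
  # monotone and capped
  expect_true(all(out$p_bonferroni >= out$p_raw | is.na(out$p_raw)))
  expect_true(all(out$p_bonferroni <= 1, na.rm = TRUE))
})

test_that("clustering recovers planted blocks and ignores input order", {
  set.seed(41)
  block1 <- matrix(rnorm(10 * 4, mean = 1, sd = 0.05), 10)   # 8q24+20q-like
  block2 <- matrix(rnorm(10 * 4, mean = 0, sd = 0.05), 10)
  m <- rbind(block1, block2)
  rownames(m) <- sprintf("S%02d", 1:20)
  colnames(m) <- paste0("g", 1:4)
  cl <- cluster_samples(m, k = 2)
  grp <- cl$clusters
  expect_length(unique(grp[1:10]), 1L)
  expect_length(unique(grp[11:20]), 1L)
  expect_false(grp[1] == grp[11])

  perm <- sample.int(20)
  cl2 <- cluster_samples(m[perm, ], k = 2)
  expect_equal(cl2$clusters[names(grp)], grp)
  expect_identical(cl2$order, cl$order)

  # identical rows merge first, at height 0
  m2 <- m; m2[2, ] <- m2[1, ]
  hc <- cluster_samples(m2, k = 2)$hclust
  expect_equal(hc$height[1], 0)
  expect_error(cluster_samples(m[1, , drop = FALSE]), "two samples")
  expect_warning(cluster_samples(rbind(c(1, NA), c(0, 0), c(2, 2))),
                 "imputed")
})

test_that("log-rank: identical groups give p = 1, separated groups p < 0.05", {
  same <- km_logrank(rep(c("A", "B"), each = 3),
                     rep(c(1, 2, 3), 2), rep(1, 6))
  expect_equal(same$chisq, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)

  sep <- km_logrank(rep(c("A", "B"), each = 3), c(1, 2, 3, 4, 5, 6),
                    rep(1, 6))
  expect_lt(sep$p, 0.05)

  nil <- km_logrank(rep(c("A", "B"), each = 3), c(1, 2, 3, 4, 5, 6),
                    rep(0, 6))
  expect_true(is.na(nil$p))
  expect_warning(km_logrank(c("A", rep("B", 5)), 1:6, rep(1, 6)),
                 "fewer than two")
})

test_that("log-rank p agrees with a permutation approximation", {
  set.seed(55)
  time <- c(rexp(10, 1 / 20), rexp(10, 1 / 40))
  event <- rbinom(20, 1, 0.8)
  group <- rep(c("A", "B"), each = 10)
  obs <- km_logrank(group, time, event)
  perm <- replicate(1000, {
    km_logrank(sample(group), time, event)$chisq
  })
  p_perm <- mean(perm >= obs$chisq - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.05)
})

test_that("size-stratified platform comparison flags only the small-loss bin", {
  mk <- function(n_small, prefix) {
    lens <- c(rep(2500, n_small),        # 1-5 kb losses
              rep(25000, 150),           # 10-50 kb
              rep(2e5, 150))             # >= 100 kb
    data.frame(sample_id = paste0(prefix, seq_along(lens)),
               chrom = "chr1", start = 0, end = lens,
               n_probes = 4L, mean_log2 = -0.6, score = 10,
               direction = "loss", amplitude_class = "loss")
  }
  dense <- mk(40, "D")    # extra planted 1-5 kb losses
  sparse <- mk(2, "S")
  out <- size_stratified_platform_comparison(dense, sparse)
  small_bin <- out[out$bin == "[1e+03,5e+03)", ]
  big_bin <- out[out$bin == "[1e+05,Inf)", ]
  expect_lt(small_bin$p, 0.05)
  expect_gt(big_bin$p, 0.05)

  # identical call sets -> no bin is significant
  out_same <- size_stratified_platform_comparison(dense, dense)
  expect_true(all(out_same$p > 0.99 | is.na(out_same$p)))
  expect_error(size_stratified_platform_comparison(dense, sparse,
                                                   bins = numeric(0)),
               "bins")
  expect_error(size_stratified_platform_comparison(dense[0, ], sparse),
               "non-empty")
})
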