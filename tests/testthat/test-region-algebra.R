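call_row <- function(sample, start, end, mean_log2 = 0.6, chrom = "chr1",
                     platform = "pf1") {
  data.frame(sample_id = sample, platform_id = platform, chrom = chrom,
             start = start, end = end, n_probes = 5L, mean_log2 = mean_log2,
             score = 10,
             direction = if (mean_log2 >= 0) "gain" else "loss",
             amplitude_class = if (abs(mean_log2) >= 0.8) {
               if (mean_log2 >= 0) "amplification" else "deletion"
             } else if (mean_log2 >= 0) "gain" else "loss",
             stringsAsFactors = FALSE)
}

test_that("reciprocal overlap arithmetic", {
  expect_equal(reciprocal_overlap(c(0, 100), c(0, 100)), 1.0)
  expect_equal(reciprocal_overlap(c(0, 100), c(50, 150)), 0.5)
  expect_equal(reciprocal_overlap(c(0, 100), c(90, 200)), 10 / 110)
  expect_equal(reciprocal_overlap(c(0, 100), c(200, 300)), 0)
  expect_equal(reciprocal_overlap(c(0, 100), c(0, 100),
                                  chrom_a = "chr1", chrom_b = "chr2"), 0)
})

test_that("CNARs require strictly more than the overlap threshold", {
  calls <- rbind(call_row("S1", 100, 200), call_row("S2", 100, 200))
  cn <- build_cnar(calls, "gain", n_cohort = 10)
  expect_length(cn, 1L)
  expect_equal(cn[[1]]$frequency, 0.2)
  expect_equal(c(cn[[1]]$start, cn[[1]]$end), c(100, 200))

  # overlap exactly 0.9 is not "more than 90 percent": no CNAR
  boundary <- rbind(call_row("S1", 100, 200), call_row("S2", 105, 195))
  expect_equal(reciprocal_overlap(c(100, 200), c(105, 195)), 0.9)
  expect_length(build_cnar(boundary, "gain", n_cohort = 10), 0L)
})

test_that("CNAR components take the transitive closure and the union hull", {
  # A~B and B~C overlap > 0.9 but A~C do not
  a <- call_row("S1", 1000, 2000)
  b <- call_row("S2", 1050, 2050)
  cc <- call_row("S3", 1105, 2105)
  expect_gt(reciprocal_overlap(c(1000, 2000), c(1050, 2050)), 0.9)
  expect_lt(reciprocal_overlap(c(1000, 2000), c(1105, 2105)), 0.9)
  cn <- build_cnar(rbind(a, b, cc), "gain", n_cohort = 3)
  expect_length(cn, 1L)
  expect_equal(cn[[1]]$n_support, 3L)
  expect_equal(c(cn[[1]]$start, cn[[1]]$end), c(1000, 2105))
})

test_that("CNAR construction is independent of input row order", {
  set.seed(8)
  calls <- do.call(rbind, lapply(1:12, function(i)
    call_row(paste0("S", i), 1000 + 7 * i, 2000 + 7 * i)))
  cn1 <- build_cnar(calls, "gain", n_cohort = 12)
  cn2 <- build_cnar(calls[sample.int(12), ], "gain", n_cohort = 12)
  expect_equal(lapply(cn1, function(r) c(r$start, r$end, r$n_support)),
               lapply(cn2, function(r) c(r$start, r$end, r$n_support)))
})

test_that("MCR is the intersection of all member segments", {
  mk_cnar <- function(pf, members) {
    structure(list(kind = "CNAR", chrom = "chr1",
                   start = min(members$start), end = max(members$end),
                   direction = "gain", members = members,
                   samples = unique(members$sample_id),
                   n_support = length(unique(members$sample_id)),
                   frequency = NA, platforms = pf),
              class = "RecurrentRegion")
  }
  m1 <- data.frame(sample_id = c("A1", "A2"), chrom = "chr1",
                   start = c(100, 100), end = c(200, 200))
  m2 <- data.frame(sample_id = c("B1", "B2"), chrom = "chr1",
                   start = c(150, 150), end = c(250, 250))
  m3 <- data.frame(sample_id = c("C1", "C2"), chrom = "chr1",
                   start = c(120, 120), end = c(220, 220))
  byp <- list(pf1 = list(mk_cnar("pf1", m1)), pf2 = list(mk_cnar("pf2", m2)),
              pf3 = list(mk_cnar("pf3", m3)))
  mcr <- build_mcr(byp, n_cohort = 6)
  expect_length(mcr, 1L)
  expect_equal(c(mcr[[1]]$start, mcr[[1]]$end), c(150, 200))
  expect_equal(mcr[[1]]$n_support, 6L)
  expect_setequal(mcr[[1]]$platforms, c("pf1", "pf2", "pf3"))
  # every member contains the MCR and lies within some CNAR hull
  expect_true(all(mcr[[1]]$members$start <= 150 & mcr[[1]]$members$end >= 200))

  # empty common intersection -> no MCR
  m2b <- data.frame(sample_id = c("B1", "B2"), chrom = "chr1",
                    start = c(195, 290), end = c(290, 340))
  byp$pf2 <- list(mk_cnar("pf2", m2b))
  expect_length(build_mcr(byp, n_cohort = 6), 0L)

  # platform missing from the group -> no MCR when all are required
  expect_length(build_mcr(byp["pf1"], n_cohort = 6,
                          require_platforms = c("pf1", "pf2")), 0L)
})

test_that("build_mcr agrees with a brute-force oracle on random instances", {
  set.seed(123)
  for (i in 1:60) {
    inst <- random_cnar_instance()
    got <- build_mcr(inst, n_cohort = 100)
    want <- oracle_mcr(inst, n_cohort = 100)
    expect_length(got, length(want))
    for (k in seq_along(want)) {
      expect_equal(c(got[[k]]$start, got[[k]]$end),
                   c(want[[k]]$start, want[[k]]$end))
      expect_identical(got[[k]]$samples, want[[k]]$samples)
    }
  }
})

test_that("recurrence thresholds honor the exclusive/inclusive conventions", {
  reg <- function(n) structure(list(kind = "MCR", chrom = "chr1", start = 0,
                                    end = 100, direction = "gain",
                                    n_support = n, frequency = n / 88),
                               class = "RecurrentRegion")
  regions <- list(reg(18L), reg(17L), reg(9L))
  ex <- recurrence_table(regions, 88, min_freq = 0.20, inclusive = FALSE)
  expect_equal(ex$n_support, 18L)          # 18/88 = 20.45% > 20%
  expect_equal(ex$percent, 20)
  inc <- recurrence_table(regions, 88, min_freq = 0.10, inclusive = TRUE)
  expect_equal(sort(inc$n_support), c(9L, 17L, 18L))  # 9/88 = 10.2% >= 10%
  expect_error(recurrence_table(regions, 0), "n_cohort")
})

test_that("gene annotation separates contained from overlapping genes", {
  genes <- data.frame(gene = c("IN", "EDGE", "OUT"), chrom = "chr1",
                      start = c(10, 25, 40), end = c(20, 40, 50))
  region <- list(chrom = "chr1", start = 5, end = 30)
  ann <- annotate_genes(region, genes)
  expect_equal(ann$contained, "IN")
  expect_equal(ann$overlapping, "EDGE")
})

test_that("amplification/deletion tables pick out high-amplitude events", {
  # 12 of 100 samples carry a +1.0 event on every platform
  calls <- do.call(rbind, lapply(1:12, function(i)
    rbind(call_row(paste0("S", i), 5000, 8000, 1.0, platform = "pf1"),
          call_row(paste0("S", i), 5000, 8000, 1.0, platform = "pf2"))))
  out <- amplification_deletion_regions(calls, n_cohort = 100)
  expect_equal(nrow(out$amplification), 1L)
  expect_equal(out$amplification$frequency, 0.12)
  expect_equal(nrow(out$deletion), 0L)

  # +0.5 gains never reach the amplification table
  low <- do.call(rbind, lapply(1:12, function(i)
    call_row(paste0("S", i), 5000, 8000, 0.5)))
  out_low <- amplification_deletion_regions(low, n_cohort = 100)
  expect_equal(nrow(out_low$amplification), 0L)

  # symmetry: negating the calls maps amplifications onto deletions
  neg <- calls
  neg$mean_log2 <- -neg$mean_log2
  neg$direction <- "loss"
  neg$amplitude_class <- "deletion"
  out_neg <- amplification_deletion_regions(neg, n_cohort = 100)
  expect_equal(out_neg$deletion[c("start", "end", "frequency")],
               out$amplification[c("start", "end", "frequency")])
})
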