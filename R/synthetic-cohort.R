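#' Construct an array profile
#'
#' An `ArrayProfile` holds one sample's per-probe log2 tumor/normal ratios,
#' aligned to a [probe_design()], plus an optional intensity covariate and the
#' normalization state. Normalization flags are monotone: stages set them and
#' never unset them.
#'
#' @param sample_id,platform_id Identifiers.
#' @param design The `ProbeDesign` the ratios are aligned to.
#' @param log2_ratios Numeric vector, one value per design probe.
#' @param intensity Optional per-probe intensity covariate (used by
#'   [lowess_correct()]).
#' @param tissue `"tumor"` or `"normal"`.
#' @return An object of class `ArrayProfile`.
#' @export
array_profile <- function(sample_id, design, log2_ratios, intensity = NULL,
                          tissue = "tumor", platform_id = design$platform_id) {
  stopifnot(inherits(design, "ProbeDesign"))
  n <- nrow(design$probes)
  if (length(log2_ratios) != n)
    stop("log2_ratios length must equal the design probe count")
  if (!is.null(intensity) && length(intensity) != n)
    stop("intensity length must equal the design probe count")
  structure(
    list(sample_id = sample_id, platform_id = platform_id, tissue = tissue,
         design = design, log2_ratios = as.numeric(log2_ratios),
         intensity = if (is.null(intensity)) NULL else as.numeric(intensity),
         state = list(lowess_done = FALSE, quantile_done = FALSE,
                      centralized = FALSE, offset = 0)),
    class = "ArrayProfile"
  )
}

#' @export
print.ArrayProfile <- function(x, ...) {
  cat(sprintf("ArrayProfile %s [%s, %s]: %d probes; lowess=%s quantile=%s centered=%s\n",
              x$sample_id, x$platform_id, x$tissue, length(x$log2_ratios),
              x$state$lowess_done, x$state$quantile_done, x$state$centralized))
  invisible(x)
}

#' Default planted-aberration catalog
#'
#' A catalog of gains and losses over the [default_genome()] emulating the
#' aberration spectrum of a gastric-cancer cohort: gains are longer and more
#' prevalent in intestinal-type than diffuse-type samples, losses tend to be
#' short and type-neutral, and one high-amplitude amplification and one
#' deletion (|log2| >= 0.8) are included. Prevalences are per Lauren type.
#'
#' @return Data frame with columns `aberration_id`, `chrom`, `start`, `end`,
#'   `direction`, `true_log2`, `prev_intestinal`, `prev_diffuse`, `prev_mixed`.
#' @export
default_aberration_catalog <- function() {
  df <- read.delim(text = "
aberration_id\tchrom\tstart\tend\tdirection\ttrue_log2\tprev_intestinal\tprev_diffuse\tprev_mixed
gain_chr1a\tchr1\t1500000\t1800000\tgain\t0.60\t0.45\t0.25\t0.30
gain_chr1b\tchr1\t4000000\t4040000\tgain\t0.70\t0.30\t0.15\t0.20
amp_chr2\tchr2\t2200000\t2450000\tgain\t1.30\t0.15\t0.08\t0.10
gain_chr2\tchr2\t6000000\t6300000\tgain\t0.50\t0.35\t0.20\t0.25
gain_chr3a\tchr3\t500000\t560000\tgain\t0.80\t0.25\t0.12\t0.20
gain_chr3b\tchr3\t6500000\t6560000\tgain\t0.60\t0.30\t0.18\t0.25
loss_chr1\tchr1\t7000000\t7020000\tloss\t-0.80\t0.20\t0.20\t0.20
loss_chr2\tchr2\t8200000\t8420000\tloss\t-0.60\t0.39\t0.43\t0.40
del_chr3\tchr3\t3000000\t3250000\tloss\t-1.20\t0.12\t0.12\t0.12
loss_chr3\tchr3\t9000000\t9012000\tloss\t-0.70\t0.22\t0.22\t0.22
", stringsAsFactors = FALSE)
  df
}

#' Default three-platform designs
#'
#' Probe densities mirror the three-array structure of the study cohort
#' (dense, medium, sparse) at desk scale: 10,000 / 5,000 / 1,500 probes over
#' the 30 Mb mini-genome.
#'
#' @param genome Genome table.
#' @param seed Integer seed.
#' @return Named list of three [probe_design()] objects.
#' @export
default_designs <- function(genome = default_genome(), seed = 1L) {
  list(
    `aCGH-400K` = make_platform_design("aCGH-400K", genome, 10000L, seed = seed),
    `aCGH-244K` = make_platform_design("aCGH-244K", genome, 5000L, seed = seed + 1L),
    `aCGH-60K`  = make_platform_design("aCGH-60K", genome, 1500L, seed = seed + 2L)
  )
}

.lauren_levels <- c("diffuse", "intestinal", "mixed")

# exact-count type assignment following the study composition 43/41/4 of 88,
# permuted so platform blocks are not type-confounded
.assign_lauren <- function(n, probs) {
  counts <- floor(n * probs)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * probs - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(.lauren_levels, times = counts))
}

#' Simulate a multi-platform aCGH cohort with known ground truth
#'
#' Each sample is assigned a Lauren type, carries each catalog aberration with
#' the type's prevalence, and its per-probe log2 ratio is
#' `carried true_log2 + array offset + curvature * f(intensity) + noise`,
#' where `f` is a mean-zero quadratic in the probe's log10 channel intensity
#' (so the within-array lowess stage has a realistic trend to remove) and the
#' array offset is a global Normal(0, `offset_sd`) shift (what centralization
#' removes). Clinical covariates (age, survival) are drawn per sample.
#'
#' @param designs List of [probe_design()] objects, one per platform.
#' @param catalog Aberration catalog as from [default_aberration_catalog()].
#' @param n_samples_per_platform Integer vector parallel to `designs`; default
#'   30/10/48 mirroring the study's 400K/244K/60K arms (88 samples).
#' @param noise_sd Per-probe Gaussian noise standard deviation.
#' @param curvature Coefficient of the quadratic intensity trend.
#' @param offset_sd Standard deviation of the per-array offset.
#' @param lauren_probs Named numeric: type composition of the cohort.
#' @param seed Integer seed; output is bitwise-reproducible given the seed.
#' @return List with `profiles` (list of [array_profile()]) and `truth`, a
#'   `CohortTruth` list holding `samples` (sample table with type, age,
#'   survival, offset), `carriers` (sample x aberration pairs) and `catalog`.
#' @export
simulate_cohort <- function(designs = default_designs(),
                            catalog = default_aberration_catalog(),
                            n_samples_per_platform = c(30L, 10L, 48L),
                            noise_sd = 0.15, curvature = 0.15, offset_sd = 0.1,
                            lauren_probs = c(diffuse = 43, intestinal = 41,
                                             mixed = 4) / 88,
                            seed = 1L) {
  if (!is.list(designs) || !all(vapply(designs, inherits, TRUE, "ProbeDesign")))
    stop("designs must be a list of ProbeDesign objects")
  if (length(n_samples_per_platform) != length(designs))
    stop("n_samples_per_platform must parallel designs")
  if (noise_sd < 0 || offset_sd < 0) stop("noise_sd and offset_sd must be >= 0")
  n_total <- sum(n_samples_per_platform)
  if (n_total == 0L && nrow(catalog) == 0L)
    stop("empty catalog with zero samples: nothing to simulate")
  prev_cols <- paste0("prev_", .lauren_levels)
  if (nrow(catalog) > 0L) {
    stopifnot(all(c("aberration_id", "chrom", "start", "end", "true_log2")
                  %in% names(catalog)))
    prevs <- unlist(catalog[intersect(prev_cols, names(catalog))])
    if (length(prevs) && (any(prevs < 0) || any(prevs > 1)))
      stop("prevalences must lie in [0, 1]")
  }
  set.seed(seed)
  types <- .assign_lauren(n_total, lauren_probs[.lauren_levels])
  sample_ids <- sprintf("S%03d", seq_len(n_total))
  platform_of <- rep(vapply(designs, `[[`, "", "platform_id"),
                     times = n_samples_per_platform)
  age <- round(pmax(26, rnorm(n_total, mean = 60, sd = 10)))
  # survival in months: exponential with ~30-month median, administrative
  # censoring at a uniform 6-84 month follow-up
  event_time <- rexp(n_total, rate = log(2) / 30)
  followup <- runif(n_total, 6, 84)
  survival_time <- pmax(0.1, pmin(event_time, followup))
  event <- as.integer(event_time <= followup)
  offsets <- rnorm(n_total, 0, offset_sd)

  carriers <- vector("list", n_total)
  profiles <- vector("list", n_total)
  idx <- 0L
  for (d in seq_along(designs)) {
    design <- designs[[d]]
    pr <- design$probes
    n_probes <- nrow(pr)
    for (s in seq_len(n_samples_per_platform[d])) {
      idx <- idx + 1L
      type <- types[idx]
      if (nrow(catalog) > 0L) {
        p_carry <- catalog[[paste0("prev_", type)]]
        if (is.null(p_carry)) p_carry <- rep(0, nrow(catalog))
        carried <- which(rbinom(nrow(catalog), 1L, p_carry) == 1L)
      } else carried <- integer(0)
      truth_lr <- numeric(n_probes)
      for (a in carried) {
        hit <- pr$chrom == catalog$chrom[a] &
          pr$start >= catalog$start[a] & pr$end <= catalog$end[a]
        truth_lr[hit] <- truth_lr[hit] + catalog$true_log2[a]
      }
      intensity <- log10(rlnorm(n_probes, meanlog = log(500), sdlog = 0.8))
      ic <- intensity - mean(intensity)
      quad <- ic^2 - mean(ic^2)
      lr <- truth_lr + offsets[idx] + curvature * quad +
        rnorm(n_probes, 0, noise_sd)
      carriers[[idx]] <- if (length(carried))
        data.frame(sample_id = sample_ids[idx],
                   aberration_id = catalog$aberration_id[carried]) else NULL
      profiles[[idx]] <- array_profile(sample_ids[idx], design, lr,
                                       intensity = intensity)
    }
  }
  truth <- structure(list(
    samples = data.frame(sample_id = sample_ids, platform_id = platform_of,
                         lauren_type = types, age = age,
                         survival_time = survival_time, event = event,
                         offset = offsets, stringsAsFactors = FALSE),
    carriers = if (length(cc <- Filter(Negate(is.null), carriers)))
      do.call(rbind, cc) else
      data.frame(sample_id = character(0), aberration_id = character(0)),
    catalog = catalog
  ), class = "CohortTruth")
  list(profiles = profiles, truth = truth)
}

#' Planted dosage at gene loci
#'
#' For each sample and gene, the summed `true_log2` of carried aberrations
#' whose interval covers the gene midpoint.
#'
#' @param truth `CohortTruth` from [simulate_cohort()].
#' @param genes Data frame with `gene`, `chrom`, `start`, `end`.
#' @return Numeric matrix samples x genes.
#' @export
true_dosage <- function(truth, genes) {
  sids <- truth$samples$sample_id
  m <- matrix(0, length(sids), nrow(genes),
              dimnames = list(sids, genes$gene))
  if (nrow(truth$carriers) == 0L) return(m)
  mid <- (genes$start + genes$end) / 2
  for (g in seq_len(nrow(genes))) {
    cov <- truth$catalog$chrom == genes$chrom[g] &
      truth$catalog$start <= mid[g] & truth$catalog$end > mid[g]
    for (a in which(cov)) {
      hit <- truth$carriers$sample_id[
        truth$carriers$aberration_id == truth$catalog$aberration_id[a]]
      m[hit, g] <- m[hit, g] + truth$catalog$true_log2[a]
    }
  }
  m
}

#' Simulate qPCR Ct tables with gene-dosage coupling
#'
#' Emits tumor/normal Ct values for each gene and a reference gene such that
#' the expected log2 fold change equals `beta * (planted log2 dosage at the
#' gene) + baseline`. Genes with `beta = 0` are dosage-decoupled.
#'
#' @param truth `CohortTruth`.
#' @param genes Data frame with `gene`, `chrom`, `start`, `end`, `beta` and
#'   optionally `baseline` (log2 shift applied to all samples).
#' @param noise_sd Standard deviation of Gaussian noise added to the log2
#'   fold change (via the tumor Ct).
#' @param seed Integer seed.
#' @return Data frame `sample_id`, `gene`, `ct_t`, `ct_n`, `ref_ct_t`,
#'   `ref_ct_n`.
#' @export
simulate_expression <- function(truth, genes, noise_sd = 0.25, seed = 1L) {
  stopifnot(all(c("gene", "chrom", "start", "end", "beta") %in% names(genes)))
  if (any(!is.finite(genes$beta))) stop("coupling exponents must be finite")
  genome <- truth$catalog
  # genes must lie on known chromosomes within plausible bounds; the truth
  # object does not carry the genome table, so validate against sample design
  # coordinates via the catalog chrom set plus non-negative coordinates
  if (any(genes$start < 0) || any(genes$end <= genes$start))
    stop("gene outside genome: bad interval coordinates")
  baseline <- if (is.null(genes$baseline)) rep(0, nrow(genes)) else genes$baseline
  dosage <- true_dosage(truth, genes)
  set.seed(seed)
  sids <- truth$samples$sample_id
  out <- expand.grid(sample_id = sids, gene = genes$gene,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g_idx <- match(out$gene, genes$gene)
  exp_l2fc <- genes$beta[g_idx] * dosage[cbind(match(out$sample_id, sids), g_idx)] +
    baseline[g_idx]
  noise <- if (noise_sd > 0) rnorm(nrow(out), 0, noise_sd) else 0
  ct_n <- 25
  ref_ct <- 20
  out$ct_t <- ct_n - (exp_l2fc + noise)
  out$ct_n <- ct_n
  out$ref_ct_t <- ref_ct
  out$ref_ct_n <- ref_ct
  out
}

#' Simulate MLPA peak-height tables
#'
#' Tumor and matched-normal peak heights for a set of gene probes plus
#' internal control probes. Gene-probe heights scale with the planted copy
#' ratio `2^log2`; control probes are copy-neutral. A per-sample global scale
#' factor emulates reaction efficiency differences.
#'
#' @param truth `CohortTruth`.
#' @param gene_probes Data frame with `gene`, `chrom`, `start`, `end`.
#' @param samples Sample ids to assay (default: all).
#' @param n_controls Number of internal control probes.
#' @param noise_cv Coefficient of variation of multiplicative peak noise.
#' @param seed Integer seed.
#' @return Long data frame `sample_id`, `tissue`, `probe`, `gene`, `height`,
#'   `is_control`.
#' @export
simulate_mlpa <- function(truth, gene_probes, samples = NULL,
                          n_controls = 14L, noise_cv = 0.05, seed = 1L) {
  if (is.null(samples)) samples <- truth$samples$sample_id
  dosage <- true_dosage(truth, gene_probes)
  set.seed(seed)
  rows <- list()
  base <- 1000
  probes <- c(sprintf("ctrl_%02d", seq_len(n_controls)), gene_probes$gene)
  is_ctrl <- c(rep(TRUE, n_controls), rep(FALSE, nrow(gene_probes)))
  genes <- c(rep(NA_character_, n_controls), gene_probes$gene)
  for (s in samples) {
    scale_t <- rlnorm(1, 0, 0.2)
    scale_n <- rlnorm(1, 0, 0.2)
    copy_ratio <- 2^dosage[s, ]
    mult <- function(n) rlnorm(n, 0, noise_cv)
    h_t <- base * scale_t * c(rep(1, n_controls), copy_ratio) * mult(length(probes))
    h_n <- base * scale_n * rep(1, length(probes)) * mult(length(probes))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, tissue = rep(c("tumor", "normal"), each = length(probes)),
      probe = rep(probes, 2L), gene = rep(genes, 2L),
      height = c(h_t, h_n), is_control = rep(is_ctrl, 2L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
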