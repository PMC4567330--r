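#' Interval score
#'
#' Noise-standardized interval statistic behind ADM-style aberration
#' detection: `|sum(r[i..j]) / sigma| / sqrt(j - i + 1)`. A run of probes
#' whose mean is `m` scores `|m| * sqrt(len) / sigma`, so long coherent
#' deviations outscore isolated outliers.
#'
#' @param ratios Numeric vector of log2 ratios.
#' @param sigma Per-array probe noise (e.g. from [estimate_probe_noise()]).
#' @param i,j 1-based inclusive interval bounds.
#' @return The score (non-negative).
#' @export
interval_score <- function(ratios, sigma, i, j) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (i < 1 || j > length(ratios) || i > j) stop("need 1 <= i <= j <= n")
  abs(sum(ratios[i:j]) / sigma) / sqrt(j - i + 1)
}

.detect_chrom <- function(x, sigma, threshold, finder) {
  n <- length(x)
  out <- list()
  recurse <- function(lo, hi) {
    if (hi < lo) return(invisible())
    seg <- finder(x[lo:hi], sigma)
    if (seg$to < seg$from || seg$score < threshold) return(invisible())
    from <- lo + seg$from - 1L
    to <- lo + seg$to - 1L
    out[[length(out) + 1L]] <<- c(from = from, to = to, score = seg$score)
    recurse(lo, from - 1L)
    recurse(to + 1L, hi)
  }
  recurse(1L, n)
  out
}

#' Detect aberrant intervals in one profile
#'
#' Per chromosome, the maximum-score interval (signed sums, so gains and
#' losses are found symmetrically) is extracted greedily: if its score
#' reaches `threshold` it is recorded and the search recurses on the flanking
#' probe runs. `method = "exact"` enumerates all O(n^2) intervals;
#' `method = "fast"` scans a multi-resolution candidate family with local
#' exact refinement and is intended for dense arrays. Score ties are broken
#' by leftmost start, then shortest interval.
#'
#' @param profile A normalized [array_profile()]. A warning (not an error) is
#'   emitted if the profile has not been centralized.
#' @param threshold Detection threshold on the interval score (default 6.0,
#'   the ADM-2 sensitivity threshold used throughout).
#' @param method `"exact"` or `"fast"`.
#' @param sigma Probe noise; defaults to [estimate_probe_noise()] on the
#'   profile.
#' @return Data frame of segments: `sample_id`, `chrom`, `start`, `end`
#'   (base pairs, half-open, on probe boundaries), `probe_from`, `probe_to`
#'   (global probe indices), `n_probes`, `mean_log2`, `score`.
#' @export
detect_aberrations <- function(profile, threshold = 6.0,
                               method = c("exact", "fast"), sigma = NULL) {
  method <- match.arg(method)
  if (threshold <= 0) stop("threshold must be > 0")
  if (!isTRUE(profile$state$centralized))
    warning("profile is not centralized; detection assumes a zero baseline")
  if (is.null(sigma)) sigma <- estimate_probe_noise(profile)
  if (sigma <= 0) stop("sigma must be > 0")
  finder <- if (method == "exact") .max_interval_exact else .max_interval_fast
  pr <- profile$design$probes
  y <- profile$log2_ratios
  chrom_f <- factor(pr$chrom, levels = unique(pr$chrom))
  res <- list()
  for (ch in levels(chrom_f)) {
    idx <- which(chrom_f == ch)
    segs <- .detect_chrom(y[idx], sigma, threshold, finder)
    for (s in segs) {
      from <- idx[s[["from"]]]; to <- idx[s[["to"]]]
      res[[length(res) + 1L]] <- data.frame(
        sample_id = profile$sample_id, chrom = ch,
        start = pr$start[from], end = pr$end[to],
        probe_from = from, probe_to = to,
        n_probes = to - from + 1L,
        mean_log2 = mean(y[from:to]), score = s[["score"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      probe_from = integer(0), probe_to = integer(0),
                      n_probes = integer(0), mean_log2 = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, levels(chrom_f)), out$start), ]
  rownames(out) <- NULL
  out
}

#' Fuzzy-zero segment filter
#'
#' Post-hoc significance correction: each segment's quality is recomputed as
#' `|mean_log2| / sqrt(sigma^2 / n_probes + nu^2)` and segments below the
#' detection threshold are dropped. The `nu^2` term inflates the variance of
#' long segments, whose nominal standard error `sigma/sqrt(n)` becomes
#' unrealistically small, so long low-amplitude calls are penalized most.
#' With `nu = 0` the filter reduces to the original score criterion and
#' passes every emitted segment.
#'
#' @param segments Segment data frame from [detect_aberrations()].
#' @param nu Baseline uncertainty; a sensible cohort default is the robust
#'   standard deviation of per-array centralization offsets
#'   (see [cohort_fuzzy_nu()]).
#' @param sigma Probe noise used at detection time.
#' @param threshold Detection threshold (default 6.0).
#' @return Filtered segment data frame with a `fuzzy_quality` column.
#' @export
fuzzy_zero_filter <- function(segments, nu, sigma, threshold = 6.0) {
  if (nu < 0) stop("nu must be >= 0")
  if (nrow(segments) == 0L) return(segments)
  q <- abs(segments$mean_log2) / sqrt(sigma^2 / segments$n_probes + nu^2)
  segments$fuzzy_quality <- q
  out <- segments[q >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort-level fuzzy-zero baseline
#'
#' Robust standard deviation (MAD) of the per-array centralization offsets,
#' the natural scale of residual baseline uncertainty after [centralize()].
#'
#' @param profiles List of centralized profiles.
#' @return Non-negative scalar `nu`.
#' @export
cohort_fuzzy_nu <- function(profiles) {
  offs <- vapply(profiles, function(p) p$state$offset, 0)
  mad(offs, center = 0)
}

#' Filter segments and classify amplitude
#'
#' Applies the reporting filters (minimum probes per region, minimum absolute
#' mean log2 ratio, both inclusive: a segment at exactly 0.25 is kept) and
#' labels each call: direction by sign of the mean, amplitude class
#' `amplification`/`deletion` when `|mean_log2| >= amp_cut`, else
#' `gain`/`loss`.
#'
#' @param segments Segment data frame.
#' @param min_probes Minimum probes per region (default 3).
#' @param min_abs_mean Minimum |mean log2| (default 0.25).
#' @param amp_cut Amplification/deletion cutoff on |mean log2| (default 0.8).
#' @return Data frame of CNA calls with `direction` and `amplitude_class`.
#' @export
filter_and_classify <- function(segments, min_probes = 3L,
                                min_abs_mean = 0.25, amp_cut = 0.8) {
  if (min_probes <= 0 || min_abs_mean <= 0 || amp_cut <= 0)
    stop("thresholds must be positive")
  keep <- segments$n_probes >= min_probes &
    abs(segments$mean_log2) >= min_abs_mean
  out <- segments[keep, , drop = FALSE]
  out$direction <- ifelse(out$mean_log2 >= 0, "gain", "loss")
  out$amplitude_class <- ifelse(
    abs(out$mean_log2) >= amp_cut,
    ifelse(out$direction == "gain", "amplification", "deletion"),
    out$direction)
  rownames(out) <- NULL
  out
}

#' Per-sample and cohort aberration summary
#'
#' @param calls CNA call data frame (possibly several samples).
#' @param sample_ids Optional full cohort sample id vector so samples with no
#'   calls appear with zero counts.
#' @return List with `per_sample` (sample x direction counts and median
#'   lengths) and `cohort` (mean count and median length per direction;
#'   medians are `NA` when there are no calls).
#' @export
aberration_summary <- function(calls, sample_ids = unique(calls$sample_id)) {
  dirs <- c("gain", "loss")
  per <- expand.grid(sample_id = sample_ids, direction = dirs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per$n <- 0L
  per$median_length <- NA_real_
  for (r in seq_len(nrow(per))) {
    sel <- calls$sample_id == per$sample_id[r] &
      calls$direction == per$direction[r]
    per$n[r] <- sum(sel)
    if (any(sel))
      per$median_length[r] <- median(calls$end[sel] - calls$start[sel])
  }
  cohort <- data.frame(direction = dirs,
                       mean_count = NA_real_, median_length = NA_real_)
  for (k in seq_along(dirs)) {
    sel <- calls$direction == dirs[k]
    cohort$mean_count[k] <- sum(sel) / max(length(sample_ids), 1L)
    if (any(sel))
      cohort$median_length[k] <- median(calls$end[sel] - calls$start[sel])
  }
  list(per_sample = per, cohort = cohort)
}
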