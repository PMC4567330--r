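#' Within-array lowess intensity correction
#'
#' Fits a robust locally weighted regression of the log2 ratio on the probe
#' intensity covariate and subtracts the fitted trend. The mean of the fitted
#' curve is removed before subtraction, so the array's global level is
#' preserved (centering is [centralize()]'s job, not the smoother's).
#'
#' @param profile An [array_profile()] with an `intensity` covariate.
#' @param span Lowess span (fraction of probes in each local fit).
#' @param on_degenerate What to do when the covariate is constant:
#'   `"error"` (default) or `"identity"` (return the profile unchanged).
#' @return The corrected profile with `state$lowess_done = TRUE`.
#' @export
lowess_correct <- function(profile, span = 0.3,
                           on_degenerate = c("error", "identity")) {
  on_degenerate <- match.arg(on_degenerate)
  if (is.null(profile$intensity))
    stop("no intensity covariate on this profile; skip the lowess stage")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  x <- profile$intensity
  y <- profile$log2_ratios
  if (var(x) == 0) {
    if (on_degenerate == "error")
      stop("intensity covariate is constant; nothing to smooth against")
    profile$state$lowess_done <- TRUE
    return(profile)
  }
  fit <- stats::lowess(x, y, f = span, iter = 3L)
  fitted <- approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
  profile$log2_ratios <- y - (fitted - mean(fitted))
  profile$state$lowess_done <- TRUE
  profile
}

#' Quantile normalization between arrays
#'
#' Replaces each array's sorted log2 values by the across-array mean of order
#' statistics (ties get the average), so all arrays share one empirical
#' distribution while within-array ranks are preserved. Applied per platform:
#' all profiles must share a probe design.
#'
#' @param profiles List of [array_profile()] objects from one platform.
#' @return The list with normalized ratios and `state$quantile_done = TRUE`.
#' @export
quantile_normalize <- function(profiles) {
  if (length(profiles) < 2L) stop("quantile normalization needs >= 2 profiles")
  platforms <- vapply(profiles, `[[`, "", "platform_id")
  if (length(unique(platforms)) != 1L)
    stop("mixed platforms in one quantile_normalize call; normalize per platform")
  n <- lengths(lapply(profiles, `[[`, "log2_ratios"))
  if (length(unique(n)) != 1L) stop("profiles have unequal probe counts")
  m <- vapply(profiles, `[[`, numeric(n[1]), "log2_ratios")
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  for (i in seq_along(profiles)) {
    profiles[[i]]$log2_ratios <- norm[, i]
    profiles[[i]]$state$quantile_done <- TRUE
  }
  profiles
}

#' Centralize a profile at its modal (copy-neutral) state
#'
#' Estimates the mode of the log2 ratio distribution by kernel density and
#' subtracts it, so the diploid state (copy number 2, log2(2/2) = 0) sits at
#' zero. When the density has several modes of (numerically) equal height the
#' one nearest zero wins and a warning is emitted.
#'
#' @param profile An [array_profile()].
#' @param bandwidth Kernel bandwidth; default Silverman's rule on the ratios.
#' @return Profile with the offset subtracted, recorded in `state$offset`,
#'   and `state$centralized = TRUE`.
#' @export
centralize <- function(profile, bandwidth = NULL) {
  y <- profile$log2_ratios
  if (length(unique(y)) == 1L) {
    warning("all log2 ratios identical; offset set to that value")
    offset <- y[1]
  } else {
    if (is.null(bandwidth)) bandwidth <- bw.nrd0(y)
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    d <- density(y, bw = bandwidth, n = 2048L)
    # local maxima of the density curve; modes of (numerically) equal height
    # are tied and the one nearest zero wins
    dy <- d$y
    peaks <- which(dy >= c(-Inf, dy[-length(dy)]) & dy >= c(dy[-1], -Inf))
    tied <- peaks[dy[peaks] >= max(dy) * (1 - 1e-6)]
    if (length(tied) > 1L) {
      offset <- d$x[tied][which.min(abs(d$x[tied]))]
      warning("multiple density modes of equal height; tie broken toward 0")
    } else {
      offset <- d$x[which.max(dy)]
    }
  }
  profile$log2_ratios <- y - offset
  profile$state$offset <- profile$state$offset + offset
  profile$state$centralized <- TRUE
  profile
}

#' Derivative log-ratio spread (DLRS) noise estimate
#'
#' Robust per-array probe noise: successive probe differences are taken within
#' chromosomes (never across a chromosome boundary), and
#' `sigma = 1.4826 * median(|d - median(d)|) / sqrt(2)`, floored at 1e-6.
#' A single copy-number step among thousands of probes contributes only a few
#' outlying differences, which the median absolute deviation ignores.
#'
#' @param profile An [array_profile()].
#' @return Noise standard deviation estimate (dimensionless, log2 scale).
#' @export
estimate_probe_noise <- function(profile) {
  y <- profile$log2_ratios
  if (length(y) < 3L) stop("need >= 3 probes to estimate noise")
  chrom <- profile$design$probes$chrom
  d <- unlist(lapply(split(y, factor(chrom, levels = unique(chrom))), diff),
              use.names = FALSE)
  if (length(d) == 0L) return(1e-6)
  sigma <- 1.4826 * median(abs(d - median(d))) / sqrt(2)
  max(sigma, 1e-6)
}

#' Run the full normalization stack on one platform's profiles
#'
#' lowess (if intensities present) -> quantile between arrays -> centralize.
#'
#' @param profiles List of profiles from one platform.
#' @param span,bandwidth Passed to the stages.
#' @param skip_lowess Skip the intensity correction.
#' @return List of normalized profiles.
#' @export
normalize_profiles <- function(profiles, span = 0.3, bandwidth = NULL,
                               skip_lowess = FALSE) {
  if (!skip_lowess)
    profiles <- lapply(profiles, function(p)
      if (is.null(p$intensity)) p else lowess_correct(p, span = span))
  if (length(profiles) >= 2L) profiles <- quantile_normalize(profiles)
  lapply(profiles, centralize, bandwidth = bandwidth)
}
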