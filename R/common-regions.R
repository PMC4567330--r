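#' Per-sample genomic context
#'
#' The "context" of a sample is its genome-wide aberration burden in one
#' direction: the fraction of the design's probes covered by that sample's
#' direction-matched calls. Samples that are globally noisy or highly
#' rearranged contribute weaker evidence at any single locus.
#'
#' @param calls CNA call data frame for the cohort (one platform).
#' @param design The platform [probe_design()].
#' @param direction `"gain"` or `"loss"`.
#' @param sample_ids Cohort sample ids (default: those present in `calls`).
#' @return Named numeric vector `g` of per-sample covered fractions.
#' @export
genome_context <- function(calls, design, direction,
                           sample_ids = unique(calls$sample_id)) {
  cov <- .probe_carrier_matrix(calls, design, direction, sample_ids)
  colMeans(cov)
}

# probes x samples logical matrix: probe covered by a direction-matched call
.probe_carrier_matrix <- function(calls, design, direction, sample_ids) {
  pr <- design$probes
  n <- nrow(pr)
  m <- matrix(FALSE, n, length(sample_ids),
              dimnames = list(NULL, sample_ids))
  sel <- calls$direction == direction & calls$sample_id %in% sample_ids
  cc <- calls[sel, , drop = FALSE]
  for (r in seq_len(nrow(cc))) {
    hit <- pr$chrom == cc$chrom[r] & pr$start >= cc$start[r] &
      pr$start < cc$end[r]
    m[hit, cc$sample_id[r]] <- TRUE
  }
  m
}

#' Poisson-binomial tail probabilities
#'
#' Exact distribution of a sum of independent Bernoulli trials with success
#' probabilities `g`, by dynamic programming over samples.
#'
#' @param g Probability vector.
#' @return Numeric vector `tail` of length `length(g) + 1`;
#'   `tail[k + 1] = P(K >= k)` for `k = 0..S`.
#' @export
poisson_binomial_tail <- function(g) {
  stopifnot(all(g >= 0 & g <= 1))
  f <- 1
  for (p in g) f <- c(f * (1 - p), 0) + c(0, f * p)
  rev(cumsum(rev(f)))
}

#' Context-corrected per-probe p-values
#'
#' At each probe, the observed carrier count `K` is referred to the
#' Poisson-binomial null in which sample `s` covers any given probe with its
#' context probability `g_s` (see [genome_context()]):
#' `p = P(K' >= K)`. Probes nobody covers get `p = 1`.
#'
#' @inheritParams genome_context
#' @return Numeric vector of per-probe p-values (length = probe count).
#' @export
context_pvalues <- function(calls, design, direction,
                            sample_ids = unique(calls$sample_id)) {
  if (length(sample_ids) < 1L) stop("need at least one sample")
  cov <- .probe_carrier_matrix(calls, design, direction, sample_ids)
  g <- colMeans(cov)
  tail <- poisson_binomial_tail(g)
  K <- rowSums(cov)
  tail[K + 1L]
}

#' Detect context-corrected common aberrations
#'
#' Maximal runs of consecutive probes (within a chromosome) with context
#' p-value below `alpha` become candidate regions. A sample is retained as a
#' member only if one of its direction-matched calls has reciprocal overlap
#' at least `overlap` with the candidate; candidates with fewer than two
#' members are dropped.
#'
#' @inheritParams genome_context
#' @param alpha Per-probe significance level (default 0.05).
#' @param overlap Reciprocal-overlap membership threshold (default 0.9).
#' @param adjust `"none"` (default; raw per-probe p-values) or `"BH"` for a
#'   Benjamini-Hochberg adjustment across probes before thresholding.
#' @return Data frame of common aberrations: `chrom`, `start`, `end`,
#'   `direction`, `n_support`, `p_min`, `members` (comma-separated ids).
#' @export
detect_common <- function(calls, design, direction, alpha = 0.05,
                          overlap = 0.9, adjust = c("none", "BH"),
                          sample_ids = unique(calls$sample_id)) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (overlap <= 0 || overlap > 1) stop("overlap must be in (0, 1]")
  p <- context_pvalues(calls, design, direction, sample_ids)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  pr <- design$probes
  sig <- p < alpha
  out <- list()
  for (ch in unique(pr$chrom)) {
    idx <- which(pr$chrom == ch)
    r <- rle(sig[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      gi <- idx[starts[k]:ends[k]]
      reg_start <- pr$start[gi[1]]
      reg_end <- pr$end[gi[length(gi)]]
      cand <- c(chrom = ch, start = reg_start, end = reg_end)
      sel <- calls$direction == direction & calls$chrom == ch &
        calls$sample_id %in% sample_ids
      cc <- calls[sel, , drop = FALSE]
      ro <- vapply(seq_len(nrow(cc)), function(i)
        reciprocal_overlap(c(reg_start, reg_end),
                           c(cc$start[i], cc$end[i])), 0)
      members <- unique(cc$sample_id[ro >= overlap])
      if (length(members) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = reg_start, end = reg_end, direction = direction,
        n_support = length(members), p_min = min(p[gi]),
        members = paste(sort(members), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_support = integer(0), p_min = numeric(0),
                      members = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
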