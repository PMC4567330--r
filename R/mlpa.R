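#' Population-normalize MLPA peak heights
#'
#' Within each sample, every probe's peak height is divided by the mean height
#' of the internal control probes (removing global reaction-scale effects);
#' the result is then divided by the median of the same quantity across a
#' reference population of normal-tissue profiles, giving a ratio of 1 for a
#' copy-neutral probe.
#'
#' @param profile Long data frame for one sample/tissue: columns `probe`,
#'   `gene`, `height`, `is_control`.
#' @param reference_population Long data frame of reference profiles (same
#'   columns plus `sample_id`), typically all normal-tissue profiles.
#' @return Data frame `probe`, `gene`, `ratio` for the non-control probes.
#' @export
normalize_peaks <- function(profile, reference_population) {
  stopifnot(all(c("probe", "height", "is_control") %in% names(profile)))
  if (nrow(reference_population) == 0L) stop("reference population is empty")
  if (!any(profile$is_control)) stop("profile has no control probes")
  ctrl_scale <- function(df) {
    cm <- mean(df$height[df$is_control])
    if (!is.finite(cm) || cm == 0) stop("zero control-probe mean")
    cm
  }
  rel <- profile$height / ctrl_scale(profile)
  ref_rel <- do.call(rbind, lapply(
    split(reference_population, reference_population$sample_id),
    function(df) {
      s <- ctrl_scale(df)
      data.frame(probe = df$probe, rel = df$height / s,
                 stringsAsFactors = FALSE)
    }))
  ref_med <- tapply(ref_rel$rel, ref_rel$probe, median)
  sel <- !profile$is_control
  probes <- profile$probe[sel]
  if (any(is.na(ref_med[probes])))
    stop("reference population lacks some probes of this profile")
  data.frame(probe = probes,
             gene = if (is.null(profile$gene)) NA else profile$gene[sel],
             ratio = as.numeric(rel[sel] / ref_med[probes]),
             stringsAsFactors = FALSE)
}

#' Three-state MLPA copy-number call
#'
#' Ratios below 0.75 are called `deletion`, above 1.25 `amplification`, and
#' anything within \[0.75, 1.25\] (boundaries inclusive) `normal`.
#'
#' @param ratio Numeric vector of population-normalized peak ratios.
#' @return Character vector of calls.
#' @export
call_mlpa <- function(ratio) {
  if (any(ratio < 0)) stop("negative peak ratio")
  ifelse(ratio < 0.75, "deletion",
         ifelse(ratio > 1.25, "amplification", "normal"))
}

#' Call MLPA status for all tumor samples in a run
#'
#' Convenience wrapper: normalizes every tumor profile against the run's
#' normal-tissue profiles and applies [call_mlpa()].
#'
#' @param mlpa Long MLPA table from [simulate_mlpa()] or a reader:
#'   `sample_id`, `tissue`, `probe`, `gene`, `height`, `is_control`.
#' @param reference Optional reference table; default all `tissue == "normal"`
#'   rows of `mlpa`.
#' @return Data frame `sample_id`, `gene`, `probe`, `ratio`, `status`.
#' @export
mlpa_call_table <- function(mlpa, reference = NULL) {
  if (is.null(reference)) reference <- mlpa[mlpa$tissue == "normal", ]
  tum <- mlpa[mlpa$tissue == "tumor", ]
  out <- lapply(split(tum, tum$sample_id), function(df) {
    r <- normalize_peaks(df, reference)
    data.frame(sample_id = df$sample_id[1], gene = r$gene, probe = r$probe,
               ratio = r$ratio, status = call_mlpa(r$ratio),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concordance between MLPA and aCGH calls
#'
#' Cross-tabulates three-state calls per (sample, gene) key and reports the
#' agreement fraction; optionally stratifies by aCGH segment length so
#' short-segment calls (the ones most likely to be array artifacts) can be
#' audited separately.
#'
#' @param mlpa_calls Data frame `sample_id`, `gene`, `status`.
#' @param acgh_calls Data frame `sample_id`, `gene`, `status`, optionally
#'   `length` (bp of the underlying segment; `NA` for "normal").
#' @param size_bins Optional numeric breaks in bp (e.g.
#'   `c(1e3, 5e3, 1e4, 5e4, 1e5, Inf)`) for length stratification.
#' @return List with `table` (3x3 contingency), `agreement`, `n`, and when
#'   `size_bins` is given, `by_size`: per-bin n and agreement.
#' @export
mlpa_concordance <- function(mlpa_calls, acgh_calls, size_bins = NULL) {
  merged <- merge(mlpa_calls[, c("sample_id", "gene", "status")],
                  acgh_calls, by = c("sample_id", "gene"),
                  suffixes = c("_mlpa", "_acgh"))
  if (nrow(merged) == 0L) stop("no shared (sample, gene) keys")
  lev <- c("deletion", "normal", "amplification")
  tab <- table(mlpa = factor(merged$status_mlpa, lev),
               acgh = factor(merged$status_acgh, lev))
  out <- list(table = tab,
              agreement = mean(merged$status_mlpa == merged$status_acgh),
              n = nrow(merged))
  if (!is.null(size_bins)) {
    if (is.null(merged$length)) stop("size stratification needs a length column")
    bin <- cut(merged$length, breaks = size_bins, right = FALSE)
    by_size <- do.call(rbind, lapply(levels(bin), function(b) {
      sel <- !is.na(bin) & bin == b
      data.frame(bin = b, n = sum(sel),
                 agreement = if (any(sel))
                   mean(merged$status_mlpa[sel] == merged$status_acgh[sel])
                 else NA_real_)
    }))
    out$by_size <- by_size
  }
  out
}

#' aCGH three-state status at gene loci
#'
#' For each sample and gene: `deletion` if a loss-direction call covers the
#' gene's full interval, `amplification` if a gain-direction call does, else
#' `normal`. The segment length is reported for stratified concordance.
#'
#' @param calls CNA call data frame.
#' @param genes Data frame `gene`, `chrom`, `start`, `end`.
#' @param sample_ids Samples to report (default: those in `calls`).
#' @return Data frame `sample_id`, `gene`, `status`, `length`.
#' @export
acgh_gene_status <- function(calls, genes, sample_ids = unique(calls$sample_id)) {
  out <- expand.grid(sample_id = sample_ids, gene = genes$gene,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$status <- "normal"
  out$length <- NA_real_
  for (r in seq_len(nrow(out))) {
    g <- genes[genes$gene == out$gene[r], ]
    sel <- calls$sample_id == out$sample_id[r] & calls$chrom == g$chrom &
      calls$start <= g$start & calls$end >= g$end
    if (!any(sel)) next
    hit <- calls[sel, ][1, ]
    out$status[r] <- if (hit$direction == "loss") "deletion" else "amplification"
    out$length[r] <- hit$end - hit$start
  }
  out
}
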