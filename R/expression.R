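#' Fold change from Ct values (delta-delta-Ct)
#'
#' `FC = 2^-ddCt` with
#' `ddCt = (Ct_gene,T - Ct_ref,T) - (Ct_gene,N - Ct_ref,N)`, assuming an
#' amplification efficiency of 2. Rows with a missing Ct are skipped with a
#' warning.
#'
#' @param ct Data frame with columns `ct_t`, `ct_n`, `ref_ct_t`, `ref_ct_n`
#'   (plus any id columns, carried through).
#' @return Input rows (complete ones) with `ddct`, `fc` and `log2_fc` added.
#' @export
fold_change <- function(ct) {
  need <- c("ct_t", "ct_n", "ref_ct_t", "ref_ct_n")
  stopifnot(all(need %in% names(ct)))
  ok <- stats::complete.cases(ct[, need])
  if (any(!ok))
    warning(sprintf("%d record(s) with missing Ct skipped", sum(!ok)))
  out <- ct[ok, , drop = FALSE]
  out$ddct <- (out$ct_t - out$ref_ct_t) - (out$ct_n - out$ref_ct_n)
  out$log2_fc <- -out$ddct
  out$fc <- 2^out$log2_fc
  rownames(out) <- NULL
  out
}

#' One-sample direction test on log2 fold changes
#'
#' Two-sided one-sample t-test of the mean log2 FC against 0. The label is
#' `"Up"` if `p < alpha` and the mean is positive, `"Down"` if `p < alpha`
#' and the mean is negative, otherwise `"-"`. A zero-variance vector with a
#' nonzero mean is labeled by its sign with `p = 0` (and a warning); an
#' all-zero vector gives `t = 0, p = 1, "-"`.
#'
#' @param log2_fcs Numeric vector (n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `df`, `p`, `mean`, `label`.
#' @export
fc_direction_test <- function(log2_fcs, alpha = 0.05) {
  n <- length(log2_fcs)
  if (n < 2L) stop("need at least two fold changes")
  m <- mean(log2_fcs)
  if (sd(log2_fcs) == 0) {
    if (m == 0) return(list(t = 0, df = n - 1L, p = 1, mean = 0, label = "-"))
    warning("zero variance with nonzero mean; p set to 0 by convention")
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, mean = m,
                label = if (m > 0) "Up" else "Down"))
  }
  tt <- t.test(log2_fcs, mu = 0)
  label <- if (tt$p.value < alpha) (if (m > 0) "Up" else "Down") else "-"
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = m, label = label)
}

#' CNA-stratified expression table
#'
#' For each gene, reports the one-sample direction test on log2 fold changes
#' overall and within the without-CNA / with-CNA strata, mirroring the
#' "Total Number (Without CNA + with CNA)" layout used for gene-dosage
#' association reporting. Strata with fewer than two samples get a missing
#' p-value and label `"-"`.
#'
#' @param fcs Data frame `sample_id`, `gene`, `log2_fc`.
#' @param cna_status Data frame `sample_id`, `gene`, `has_cna` (logical:
#'   a same-direction CNA call covers the gene in that sample).
#' @param alpha Significance level.
#' @return Data frame, one row per gene: `n_total`, `n_without`, `n_with`,
#'   `label_all`, `p_all`, `label_without`, `p_without`, `label_with`,
#'   `p_with`.
#' @export
stratified_expression_table <- function(fcs, cna_status, alpha = 0.05) {
  merged <- merge(fcs, cna_status, by = c("sample_id", "gene"))
  if (any(is.na(merged$has_cna)))
    stop("CNA status missing for some samples with a fold change")
  run <- function(v) {
    if (length(v) < 2L) return(list(p = NA_real_, label = "-"))
    r <- fc_direction_test(v, alpha)
    list(p = r$p, label = r$label)
  }
  out <- lapply(split(merged, merged$gene), function(df) {
    a <- run(df$log2_fc)
    w0 <- run(df$log2_fc[!df$has_cna])
    w1 <- run(df$log2_fc[df$has_cna])
    data.frame(gene = df$gene[1], n_total = nrow(df),
               n_without = sum(!df$has_cna), n_with = sum(df$has_cna),
               label_all = a$label, p_all = a$p,
               label_without = w0$label, p_without = w0$p,
               label_with = w1$label, p_with = w1$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation of CNA level with expression fold change
#'
#' @param cna_log2 Per-sample CNA log2 ratio at the gene.
#' @param log2_fc Per-sample expression log2 fold change.
#' @return List with `r` and `p` (two-sided).
#' @export
cna_expression_correlation <- function(cna_log2, log2_fc) {
  if (length(cna_log2) != length(log2_fc)) stop("vectors must be paired")
  if (length(cna_log2) < 3L) stop("need at least three paired values")
  if (var(cna_log2) == 0) stop("cna_log2 is constant; correlation undefined")
  if (var(log2_fc) == 0) stop("log2_fc is constant; correlation undefined")
  ct <- cor.test(cna_log2, log2_fc, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Same-direction CNA status of genes per sample
#'
#' A sample "has the CNA" at a gene when one of its calls in the specified
#' direction covers the gene's whole interval.
#'
#' @param calls CNA call data frame.
#' @param genes Data frame `gene`, `chrom`, `start`, `end`, `direction`
#'   (the direction of interest per gene).
#' @param sample_ids Cohort sample ids.
#' @return Data frame `sample_id`, `gene`, `has_cna`.
#' @export
gene_cna_status <- function(calls, genes, sample_ids = unique(calls$sample_id)) {
  out <- expand.grid(sample_id = sample_ids, gene = genes$gene,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$has_cna <- FALSE
  for (r in seq_len(nrow(out))) {
    g <- genes[genes$gene == out$gene[r], ]
    out$has_cna[r] <- any(calls$sample_id == out$sample_id[r] &
                            calls$direction == g$direction &
                            calls$chrom == g$chrom &
                            calls$start <= g$start & calls$end >= g$end)
  }
  out
}
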