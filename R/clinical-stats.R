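#' Association of CNA status with Lauren type
#'
#' Per gene, a 2x2 table (CNA present/absent x diffuse/intestinal) is tested
#' with Pearson's chi-square (with continuity correction) when all expected
#' counts are at least 5, otherwise with the two-sided Fisher's exact test.
#' Mixed-type samples are excluded from the 2x2.
#'
#' @param status Data frame `sample_id`, `gene`, `has_cna`.
#' @param types Named character vector (or data frame `sample_id`,
#'   `lauren_type`) of Lauren types per sample.
#' @return Data frame `gene`, `test` ("chisq"/"fisher"), `p` (NA with a
#'   warning when a table margin is empty).
#' @export
lauren_association <- function(status, types) {
  if (is.data.frame(types))
    types <- setNames(types$lauren_type, types$sample_id)
  out <- lapply(split(status, status$gene), function(df) {
    ty <- types[df$sample_id]
    keep <- ty %in% c("diffuse", "intestinal")
    tab <- table(factor(df$has_cna[keep], c(FALSE, TRUE)),
                 factor(ty[keep], c("diffuse", "intestinal")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning(sprintf("empty margin for gene %s; p set to NA", df$gene[1]))
      return(data.frame(gene = df$gene[1], test = NA_character_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expd >= 5)) {
      data.frame(gene = df$gene[1], test = "chisq",
                 p = suppressWarnings(chisq.test(tab)$p.value),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = df$gene[1], test = "fisher",
                 p = fisher.test(tab)$p.value, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Co-occurrence of two binary CNA statuses
#'
#' Two-sided Fisher's exact test on the 2x2 co-occurrence table of two
#' per-sample indicator vectors (e.g. gains at two loci).
#'
#' @param status_a,status_b Logical vectors of equal length.
#' @return List with `p` and the 2x2 `table`; `p` is NA (with warning) when
#'   either vector is constant.
#' @export
gain_cooccurrence <- function(status_a, status_b) {
  if (length(status_a) != length(status_b)) stop("vectors must be paired")
  tab <- table(factor(status_a, c(FALSE, TRUE)),
               factor(status_b, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; Fisher p set to NA")
    return(list(p = NA_real_, table = tab))
  }
  list(p = fisher.test(tab)$p.value, table = tab)
}

#' Age correlation of CNA levels with Bonferroni correction
#'
#' Pearson correlation of each gene's per-sample CNA log2 level with age;
#' raw p-values are Bonferroni-corrected by multiplying by the number of
#' tested genes (capped at 1).
#'
#' @param cna_log2 Numeric matrix, samples x genes.
#' @param ages Numeric vector of patient ages (parallel to rows).
#' @param m_genes Number of tests for the correction (default `ncol`).
#' @return Data frame `gene`, `r`, `p_raw`, `p_bonferroni`.
#' @export
age_correlation <- function(cna_log2, ages, m_genes = ncol(cna_log2)) {
  if (m_genes < 1) stop("m_genes must be >= 1")
  stopifnot(nrow(cna_log2) == length(ages))
  out <- lapply(colnames(cna_log2), function(g) {
    x <- cna_log2[, g]
    if (var(x) == 0 || var(ages) == 0)
      return(data.frame(gene = g, r = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_, stringsAsFactors = FALSE))
    ct <- cor.test(x, ages, method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p_raw = ct$p.value,
               p_bonferroni = min(1, ct$p.value * m_genes),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hierarchical clustering of samples by CNA profile
#'
#' Agglomerative clustering with Euclidean distance and average linkage
#' (both configurable). Missing values are imputed as 0 (copy-neutral) with
#' a warning.
#'
#' @param cna_log2 Numeric matrix, samples x genes, rownames = sample ids.
#' @param k Number of clusters to cut (default 4).
#' @param method Linkage (default `"average"`).
#' @param metric Distance metric (default `"euclidean"`).
#' @return List with `hclust` (the tree), `order` (leaf sample ids) and
#'   `clusters` (named integer assignment).
#' @export
cluster_samples <- function(cna_log2, k = 4L, method = "average",
                            metric = "euclidean") {
  if (nrow(cna_log2) < 2L) stop("need at least two samples to cluster")
  if (any(is.na(cna_log2))) {
    warning("missing CNA values imputed as 0 (copy-neutral)")
    cna_log2[is.na(cna_log2)] <- 0
  }
  if (is.null(rownames(cna_log2)))
    rownames(cna_log2) <- sprintf("S%03d", seq_len(nrow(cna_log2)))
  # sort rows by id so input order never affects tie resolution in hclust
  cna_log2 <- cna_log2[order(rownames(cna_log2)), , drop = FALSE]
  hc <- hclust(dist(cna_log2, method = metric), method = method)
  k <- min(k, nrow(cna_log2))
  list(hclust = hc, order = hc$labels[hc$order], clusters = cutree(hc, k = k))
}

#' Kaplan-Meier curves and log-rank test between two groups
#'
#' @param group Binary (logical or two-level) label per sample.
#' @param survival_time Follow-up time (months).
#' @param event Death indicator (1 = event, 0 = censored).
#' @return List with `fit` (a `survfit` object), `chisq` (1-df log-rank
#'   statistic) and `p`. With identical event histories the statistic is 0
#'   and p = 1; with no events at all p is NA.
#' @export
km_logrank <- function(group, survival_time, event) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("need exactly two groups")
  if (min(table(group)) < 2L)
    warning("a group has fewer than two samples; estimates are unstable")
  fit <- survival::survfit(survival::Surv(survival_time, event) ~ group)
  if (sum(event) == 0)
    return(list(fit = fit, chisq = NA_real_, p = NA_real_))
  sd <- survival::survdiff(survival::Surv(survival_time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(fit = fit, chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Size-stratified comparison of loss prevalence between platform groups
#'
#' For each segment-length bin, cross-tabulates how many loss calls from each
#' platform group fall inside vs outside the bin and tests the 2x2 with
#' chi-square (Fisher fallback when an expected count is below 5). Used to
#' audit whether a dense-probe platform sees a different small-loss spectrum
#' than sparser platforms.
#'
#' @param calls_a,calls_b CNA call data frames for the two platform groups.
#' @param bins Numeric break points in bp, e.g.
#'   `c(1e3, 5e3, 1e4, 5e4, 1e5, Inf)`.
#' @param direction Direction compared (default `"loss"`).
#' @return Data frame per bin: `bin`, `n_a`, `n_b`, `test`, `p`
#'   (NA with a note attribute for empty bins).
#' @export
size_stratified_platform_comparison <- function(calls_a, calls_b,
                                                bins = c(1e3, 5e3, 1e4, 5e4,
                                                         1e5, Inf),
                                                direction = "loss") {
  if (length(bins) < 2L) stop("bins must define at least one interval")
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L)
    stop("both call sets must be non-empty")
  la <- calls_a$end[calls_a$direction == direction] -
    calls_a$start[calls_a$direction == direction]
  lb <- calls_b$end[calls_b$direction == direction] -
    calls_b$start[calls_b$direction == direction]
  ba <- cut(la, breaks = bins, right = FALSE)
  bb <- cut(lb, breaks = bins, right = FALSE)
  out <- lapply(levels(ba), function(b) {
    na <- sum(ba == b, na.rm = TRUE)
    nb <- sum(bb == b, na.rm = TRUE)
    if (na + nb == 0L)
      return(data.frame(bin = b, n_a = 0L, n_b = 0L, test = "skipped",
                        p = NA_real_, stringsAsFactors = FALSE))
    tab <- matrix(c(na, length(la) - na, nb, length(lb) - nb), 2,
                  byrow = TRUE)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expd >= 5)) {
      data.frame(bin = b, n_a = na, n_b = nb, test = "chisq",
                 p = suppressWarnings(chisq.test(tab)$p.value),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(bin = b, n_a = na, n_b = nb, test = "fisher",
                 p = fisher.test(tab)$p.value, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
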