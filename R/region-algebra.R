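#' Reciprocal overlap of two genomic intervals
#'
#' `min(|a ∩ b| / |a|, |a ∩ b| / |b|)`; 0 for disjoint intervals or
#' different chromosomes.
#'
#' @param a,b Numeric `c(start, end)` (half-open), or `c(chrom, start, end)`
#'   via the `chrom_a`/`chrom_b` arguments.
#' @param chrom_a,chrom_b Optional chromosome labels; if they differ the
#'   overlap is 0 (documented behaviour, not an error).
#' @return Fraction in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b, chrom_a = NULL, chrom_b = NULL) {
  if (!is.null(chrom_a) && !is.null(chrom_b) && chrom_a != chrom_b) return(0)
  inter <- min(a[2], b[2]) - max(a[1], b[1])
  if (inter <= 0) return(0)
  min(inter / (a[2] - a[1]), inter / (b[2] - b[1]))
}

# union-find over 1..n
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 0L)
}

#' Build copy-number alteration regions (CNARs)
#'
#' Same-direction calls are linked when their reciprocal overlap is strictly
#' greater than `overlap_threshold` ("more than 90 percent"), and each
#' transitive-closure component supported by at least two distinct samples
#' becomes a CNAR whose interval is the union hull of its member segments.
#'
#' @param calls CNA call data frame (direction-filtered internally).
#' @param direction `"gain"` or `"loss"`.
#' @param overlap_threshold Strict lower bound on reciprocal overlap
#'   (default 0.9).
#' @param n_cohort Cohort size for the frequency denominator.
#' @return List of `RecurrentRegion` objects (`kind = "CNAR"`), each a list
#'   with `chrom`, `start`, `end`, `direction`, `members` (call rows),
#'   `samples`, `n_support`, `frequency`, `platforms`.
#' @export
build_cnar <- function(calls, direction, overlap_threshold = 0.9, n_cohort) {
  cc <- calls[calls$direction == direction, , drop = FALSE]
  out <- list()
  for (ch in unique(cc$chrom)) {
    sub <- cc[cc$chrom == ch, , drop = FALSE]
    m <- nrow(sub)
    if (m == 0L) next
    edges <- matrix(integer(0), 0, 2)
    if (m > 1L) {
      pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      keep <- vapply(seq_len(nrow(pairs)), function(k) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        reciprocal_overlap(c(sub$start[i], sub$end[i]),
                           c(sub$start[j], sub$end[j])) > overlap_threshold
      }, TRUE)
      edges <- pairs[keep, , drop = FALSE]
    }
    comp <- .components(m, edges)
    for (cid in unique(comp)) {
      rows <- sub[comp == cid, , drop = FALSE]
      samples <- unique(rows$sample_id)
      if (length(samples) < 2L) next
      platforms <- if (is.null(rows$platform_id)) character(0) else
        unique(rows$platform_id)
      out[[length(out) + 1L]] <- structure(list(
        kind = "CNAR", chrom = ch,
        start = min(rows$start), end = max(rows$end),
        direction = direction, members = rows, samples = sort(samples),
        n_support = length(samples),
        frequency = length(samples) / n_cohort,
        platforms = platforms), class = "RecurrentRegion")
    }
  }
  ord <- order(vapply(out, `[[`, "", "chrom"), vapply(out, `[[`, 0, "start"))
  out[ord]
}

#' Build minimal common regions (MCRs) across platforms
#'
#' CNARs from different platforms (same chromosome and direction) are grouped
#' by any positive reciprocal overlap (transitive closure). For each group
#' observed on all required platforms, the MCR is the intersection of *all*
#' member segments of the group's CNARs — the region every supporting sample
#' shares completely. Groups whose member segments have an empty common
#' intersection are dropped. MCR frequency is the number of distinct
#' supporting samples (whose call fully covers the MCR; this is every member
#' sample, since the MCR is the members' intersection) over the cohort size.
#'
#' @param cnars_by_platform Named list (platform -> list of CNARs from
#'   [build_cnar()]).
#' @param n_cohort Total cohort size.
#' @param require_platforms Platforms an MCR must be observed on; default all
#'   names of `cnars_by_platform`.
#' @param n_by_platform Optional named vector of per-platform sample counts;
#'   when given, a per-platform frequency breakdown is attached.
#' @return List of `RecurrentRegion` objects (`kind = "MCR"`) with the CNAR
#'   fields plus `platforms` and optionally `freq_by_platform`.
#' @export
build_mcr <- function(cnars_by_platform, n_cohort,
                      require_platforms = names(cnars_by_platform),
                      n_by_platform = NULL) {
  flat <- list()
  for (pf in names(cnars_by_platform))
    for (r in cnars_by_platform[[pf]]) {
      r$platform <- pf
      flat[[length(flat) + 1L]] <- r
    }
  if (!length(flat)) return(list())
  key <- paste(vapply(flat, `[[`, "", "chrom"),
               vapply(flat, `[[`, "", "direction"))
  out <- list()
  for (k in unique(key)) {
    grp <- flat[key == k]
    m <- length(grp)
    edges <- matrix(integer(0), 0, 2)
    if (m > 1L) {
      pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      keep <- vapply(seq_len(nrow(pairs)), function(e) {
        i <- grp[[pairs[e, 1]]]; j <- grp[[pairs[e, 2]]]
        reciprocal_overlap(c(i$start, i$end), c(j$start, j$end)) > 0
      }, TRUE)
      edges <- pairs[keep, , drop = FALSE]
    }
    comp <- .components(m, edges)
    for (cid in unique(comp)) {
      members_cnar <- grp[comp == cid]
      platforms <- unique(vapply(members_cnar, `[[`, "", "platform"))
      if (!all(require_platforms %in% platforms)) next
      segs <- do.call(rbind, lapply(members_cnar, `[[`, "members"))
      mcr_start <- max(segs$start)
      mcr_end <- min(segs$end)
      if (mcr_end <= mcr_start) next
      samples <- sort(unique(segs$sample_id))
      reg <- structure(list(
        kind = "MCR", chrom = members_cnar[[1]]$chrom,
        start = mcr_start, end = mcr_end,
        direction = members_cnar[[1]]$direction,
        members = segs, samples = samples, n_support = length(samples),
        frequency = length(samples) / n_cohort,
        platforms = sort(platforms)), class = "RecurrentRegion")
      if (!is.null(n_by_platform)) {
        pf_of_seg <- if (is.null(segs$platform_id)) NULL else segs$platform_id
        if (!is.null(pf_of_seg)) {
          fb <- vapply(names(n_by_platform), function(pf)
            length(unique(segs$sample_id[pf_of_seg == pf])) /
              n_by_platform[[pf]], 0)
          reg$freq_by_platform <- fb
        }
      }
      out[[length(out) + 1L]] <- reg
    }
  }
  ord <- order(vapply(out, `[[`, "", "chrom"), vapply(out, `[[`, 0, "start"))
  out[ord]
}

#' @export
print.RecurrentRegion <- function(x, ...) {
  cat(sprintf("%s %s:%d-%d %s  support %d (%.1f%%)\n", x$kind, x$chrom,
              x$start, x$end, x$direction, x$n_support, 100 * x$frequency))
  invisible(x)
}

#' Tabulate recurrent regions above a frequency threshold
#'
#' @param regions List of `RecurrentRegion` objects.
#' @param n_cohort Cohort size (used to recompute the exact fraction).
#' @param min_freq Frequency threshold (e.g. 0.20 or 0.10).
#' @param inclusive If `FALSE` (default) keep regions with frequency strictly
#'   greater than `min_freq` (the ">20%" convention); if `TRUE` keep `>=`
#'   (the ">=10%" convention).
#' @return Data frame `kind`, `chrom`, `start`, `end`, `direction`,
#'   `n_support`, `frequency`, `percent` (rounded).
#' @export
recurrence_table <- function(regions, n_cohort, min_freq = 0.20,
                             inclusive = FALSE) {
  if (n_cohort <= 0) stop("n_cohort must be > 0")
  if (!length(regions))
    return(data.frame(kind = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      direction = character(0), n_support = integer(0),
                      frequency = numeric(0), percent = numeric(0)))
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(kind = r$kind, chrom = r$chrom, start = r$start, end = r$end,
               direction = r$direction, n_support = r$n_support,
               frequency = r$n_support / n_cohort,
               stringsAsFactors = FALSE)))
  keep <- if (inclusive) df$frequency >= min_freq else df$frequency > min_freq
  df <- df[keep, , drop = FALSE]
  df$percent <- round(100 * df$frequency)
  rownames(df) <- NULL
  df
}

#' Annotate a region with gene models
#'
#' Splits genes into those fully contained in the region (the convention used
#' to flag genes whose whole sequence is altered) and those merely
#' overlapping it.
#'
#' @param region A `RecurrentRegion` or list/row with `chrom`, `start`, `end`.
#' @param genes Data frame `gene`, `chrom`, `start`, `end`.
#' @return List with character vectors `contained` and `overlapping`.
#' @export
annotate_genes <- function(region, genes) {
  same <- genes$chrom == region$chrom
  inter <- pmin(genes$end, region$end) - pmax(genes$start, region$start)
  contained <- same & genes$start >= region$start & genes$end <= region$end
  overlapping <- same & inter > 0 & !contained
  list(contained = genes$gene[contained],
       overlapping = genes$gene[overlapping])
}

#' Recurrent amplification/deletion regions
#'
#' Reruns the CNAR/MCR construction restricted to high-amplitude calls
#' (|mean log2| >= `cutoff`: amplitude classes `amplification`/`deletion`)
#' and applies the inclusive frequency filter (default >= 10%).
#'
#' @param calls Cohort CNA calls with `platform_id` and `amplitude_class`.
#' @param n_cohort Cohort size.
#' @param cutoff Amplitude cutoff (informational; classes are taken from
#'   `amplitude_class`, which encodes the same rule).
#' @param min_freq Inclusive frequency threshold (default 0.10).
#' @param overlap_threshold CNAR linkage threshold.
#' @param require_platforms Platforms required for an MCR (default: all
#'   platforms present in `calls`).
#' @return List with data frames `amplification` and `deletion`
#'   (recurrence tables of the corresponding MCRs).
#' @export
amplification_deletion_regions <- function(calls, n_cohort, cutoff = 0.8,
                                           min_freq = 0.10,
                                           overlap_threshold = 0.9,
                                           require_platforms = NULL) {
  platforms <- unique(calls$platform_id)
  if (is.null(require_platforms)) require_platforms <- platforms
  one <- function(class, direction) {
    sub <- calls[calls$amplitude_class == class, , drop = FALSE]
    cnars <- lapply(setNames(platforms, platforms), function(pf)
      build_cnar(sub[sub$platform_id == pf, , drop = FALSE], direction,
                 overlap_threshold, n_cohort))
    mcrs <- build_mcr(cnars, n_cohort, require_platforms = require_platforms)
    recurrence_table(mcrs, n_cohort, min_freq = min_freq, inclusive = TRUE)
  }
  list(amplification = one("amplification", "gain"),
       deletion = one("deletion", "loss"))
}
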