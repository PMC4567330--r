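#' Construct a probe design
#'
#' A `ProbeDesign` fixes the genomic layout of one array platform: an ordered
#' set of probe intervals over a genome. All probe coordinates are 0-based,
#' half-open (BED convention).
#'
#' @param platform_id Character scalar naming the platform (e.g. `"aCGH-400K"`).
#' @param probes Data frame with columns `chrom`, `start`, `end` (base pairs).
#' @param genome Data frame with columns `chrom`, `length` (base pairs).
#' @return An object of class `ProbeDesign`: a list with elements
#'   `platform_id`, `probes` (sorted, with a `probe_id` column) and `genome`.
#' @export
probe_design <- function(platform_id, probes, genome) {
  stopifnot(is.character(platform_id), length(platform_id) == 1L)
  stopifnot(all(c("chrom", "start", "end") %in% names(probes)))
  stopifnot(all(c("chrom", "length") %in% names(genome)))
  if (nrow(probes) < 1L) stop("probe design needs at least one probe")
  if (any(probes$end <= probes$start) || any(probes$start < 0))
    stop("probe intervals must be half-open with end > start >= 0")
  chrom_len <- setNames(genome$length, genome$chrom)
  if (!all(probes$chrom %in% genome$chrom))
    stop("probes reference chromosomes absent from the genome")
  if (any(probes$end > chrom_len[probes$chrom]))
    stop("probes extend beyond their chromosome length")
  ord <- order(match(probes$chrom, genome$chrom), probes$start)
  probes <- probes[ord, c("chrom", "start", "end"), drop = FALSE]
  rownames(probes) <- NULL
  if (is.null(probes$probe_id))
    probes$probe_id <- sprintf("%s_p%06d", platform_id, seq_len(nrow(probes)))
  dup <- duplicated(probes[, c("chrom", "start")])
  probes <- probes[!dup, , drop = FALSE]
  rownames(probes) <- NULL
  structure(
    list(platform_id = platform_id, probes = probes, genome = genome),
    class = "ProbeDesign"
  )
}

#' @export
print.ProbeDesign <- function(x, ...) {
  cat(sprintf("ProbeDesign '%s': %d probes, %d chromosomes (%.1f Mb)\n",
              x$platform_id, nrow(x$probes), nrow(x$genome),
              sum(x$genome$length) / 1e6))
  invisible(x)
}

#' Default desk-scale mini-genome
#'
#' Three autosome-like chromosomes of 10 Mb each. Sex chromosomes are excluded
#' by design: the frequency analyses downstream are autosome-focused and this
#' avoids ploidy bookkeeping.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in base pairs.
#' @return Data frame with columns `chrom`, `length`.
#' @export
default_genome <- function(n_chrom = 3L, chrom_length = 1e7) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length = rep(chrom_length, n_chrom))
}

#' Generate a platform probe design
#'
#' Probes are allocated to chromosomes proportionally to length (largest
#' remainder) and placed either uniformly at random (deduplicated, sorted) or
#' on a regular grid when `grid = TRUE`.
#'
#' @param platform_id Platform label.
#' @param genome Data frame `chrom`/`length` as from [default_genome()].
#' @param n_probes Total number of probes across the genome.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param grid If `TRUE`, probes start at `0, L/n, 2L/n, ...` per chromosome.
#' @param probe_width Probe interval width in base pairs.
#' @return A [probe_design()] object.
#' @export
make_platform_design <- function(platform_id, genome, n_probes, seed = 1L,
                                 grid = FALSE, probe_width = 60L) {
  if (nrow(genome) == 0L) stop("genome must be non-empty")
  if (n_probes < 1L) stop("n_probes must be >= 1")
  share <- genome$length / sum(genome$length)
  n_chr <- floor(n_probes * share)
  rem <- n_probes - sum(n_chr)
  if (rem > 0) {
    extra <- order(n_probes * share - n_chr, decreasing = TRUE)[seq_len(rem)]
    n_chr[extra] <- n_chr[extra] + 1L
  }
  set.seed(seed)
  pieces <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    len <- genome$length[i]
    k <- n_chr[i]
    if (k == 0L) next
    avail <- len - probe_width + 1
    if (avail < k)
      stop(sprintf("n_probes exceeds available distinct positions on %s",
                   genome$chrom[i]))
    starts <- if (grid) {
      floor(len / k) * (seq_len(k) - 1L)
    } else {
      sort(sample.int(avail, k) - 1L)
    }
    pieces[[i]] <- data.frame(chrom = genome$chrom[i], start = starts,
                              end = pmin(starts + probe_width, len))
  }
  probe_design(platform_id, do.call(rbind, pieces), genome)
}
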