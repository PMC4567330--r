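#' Read a probe-level TSV into a design + profile pair
#'
#' Expected header: `probe_id`, `chrom`, `start`, `end`, `log2_ratio` and
#' optionally `intensity`. Coordinates are 0-based half-open. Rows must be
#' sorted by (chromosome, start) unless `sort = TRUE`; malformed numeric
#' fields are reported with their line numbers.
#'
#' @param path File path.
#' @param genome Optional genome table; defaults to per-chromosome maxima of
#'   the probe ends.
#' @param sample_id,platform_id Identifiers for the resulting profile.
#' @param sort Re-sort unsorted input instead of rejecting it.
#' @return List with `design` ([probe_design()]) and `profile`
#'   ([array_profile()]).
#' @export
read_probe_table <- function(path, genome = NULL, sample_id = basename(path),
                             platform_id = "unknown", sort = FALSE) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(raw)))
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s at line %s", col,
                   paste(bad + 1L, collapse = ", ")))  # +1 for the header
    v
  }
  start <- num("start"); end <- num("end"); lr <- num("log2_ratio")
  intensity <- if ("intensity" %in% names(raw)) num("intensity") else NULL
  if (anyDuplicated(raw$probe_id))
    stop("duplicate probe ids in ", path)
  ord <- order(match(raw$chrom, unique(raw$chrom)), start)
  if (!identical(ord, seq_along(start))) {
    if (!sort) stop("probe table is not sorted; pass sort = TRUE to re-sort")
    raw <- raw[ord, ]; start <- start[ord]; end <- end[ord]; lr <- lr[ord]
    if (!is.null(intensity)) intensity <- intensity[ord]
  }
  if (is.null(genome)) {
    genome <- do.call(rbind, lapply(split(end, raw$chrom), function(e)
      data.frame(length = max(e))))
    genome <- data.frame(chrom = rownames(genome), length = genome$length)
    genome <- genome[match(unique(raw$chrom), genome$chrom), ]
  }
  design <- probe_design(platform_id,
                         data.frame(chrom = raw$chrom, start = start,
                                    end = end, probe_id = raw$probe_id),
                         genome)
  profile <- array_profile(sample_id, design, lr, intensity = intensity)
  list(design = design, profile = profile)
}

#' Write a profile as a probe-level TSV
#'
#' @param profile An [array_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(profile, path) {
  pr <- profile$design$probes
  df <- data.frame(probe_id = pr$probe_id, chrom = pr$chrom,
                   start = pr$start, end = pr$end,
                   log2_ratio = profile$log2_ratios)
  if (!is.null(profile$intensity)) df$intensity <- profile$intensity
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write CNA calls in SEG format
#'
#' Columns: sample, chrom, start, end, n_probes, mean log2.
#'
#' @param calls CNA call / segment data frame.
#' @param path Output path.
#' @export
write_seg <- function(calls, path) {
  df <- data.frame(sample = calls$sample_id, chrom = calls$chrom,
                   start = calls$start, end = calls$end,
                   n_probes = calls$n_probes, mean_log2 = calls$mean_log2)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file written by [write_seg()]
#'
#' @param path File path.
#' @return Data frame with `sample_id`, `chrom`, `start`, `end`, `n_probes`,
#'   `mean_log2`.
#' @export
read_seg <- function(path) {
  df <- read.delim(path)
  data.frame(sample_id = as.character(df$sample), chrom = df$chrom,
             start = df$start, end = df$end, n_probes = df$n_probes,
             mean_log2 = df$mean_log2, stringsAsFactors = FALSE)
}

#' Write regions as BED6
#'
#' Score column carries the frequency as a percentage with two decimals
#' (e.g. frequency 0.4318 becomes `"43.18"`); strand is `"."`.
#'
#' @param regions Data frame with `chrom`, `start`, `end`, `direction` and
#'   either `frequency` or `score`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(regions)) {
    score <- if (!is.null(regions$frequency))
      sprintf("%.2f", 100 * regions$frequency) else
      sprintf("%.2f", regions$score)
    name <- if (!is.null(regions$direction))
      sprintf("%s_%d", regions$direction, seq_len(nrow(regions))) else
      sprintf("region_%d", seq_len(nrow(regions)))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.", regions$chrom,
                       as.integer(regions$start), as.integer(regions$end),
                       name, score), con)
  }
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' Houses every stated analysis threshold with its default: segmentation
#' score 6.0; reporting filters >= 3 probes and |mean log2| >= 0.25;
#' amplification/deletion at |log2| >= 0.8; common-aberration alpha 0.05 and
#' overlap 0.9; recurrence > 20% (exclusive) and >= 10% (inclusive, for
#' amplifications/deletions); MLPA 0.75/1.25.
#'
#' @param seed Integer master seed.
#' @param outdir Output directory.
#' @param ... Overrides for any default listed above (see the function body
#'   for names), plus generator settings `noise_sd`, `curvature`,
#'   `offset_sd`, `n_samples_per_platform`, and stage switches `run_mlpa`,
#'   `run_expression`, `run_clinical`.
#' @return Validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "results", ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    threshold = 6.0, min_probes = 3L, min_abs_mean = 0.25, amp_cut = 0.8,
    alpha = 0.05, overlap = 0.9,
    recurrence_freq = 0.20, amp_del_freq = 0.10,
    span = 0.3, skip_lowess = FALSE, method = "exact",
    noise_sd = 0.15, curvature = 0.15, offset_sd = 0.1,
    n_samples_per_platform = c(30L, 10L, 48L),
    run_mlpa = TRUE, run_expression = TRUE, run_clinical = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  with(cfg, {
    if (threshold <= 0) stop("threshold must be > 0")
    if (min_abs_mean <= 0 || amp_cut <= 0) stop("amplitude cutoffs must be > 0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
    if (overlap <= 0 || overlap > 1) stop("overlap must be in (0,1]")
    if (recurrence_freq < 0 || recurrence_freq > 1 ||
        amp_del_freq < 0 || amp_del_freq > 1)
      stop("recurrence thresholds must be fractions in [0,1]")
    if (noise_sd < 0 || offset_sd < 0) stop("noise parameters must be >= 0")
  })
  structure(cfg, class = "PipelineConfig")
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> normalize (per platform) -> segment + filter -> common
#' aberrations -> CNAR/MCR recurrence tables, then (as configured) MLPA
#' validation, expression association and clinical statistics. All outputs
#' are TSV/BED/JSON files under `config$outdir`, plus `manifest.json`
#' recording seeds and thresholds. A stage failure aborts with the stage
#' name; outputs of completed stages are preserved.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory results (`cohort`, `calls`,
#'   `common`, `mcr_table`, ...); side effect: files in `config$outdir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("cnamcr")),
                   seed = config$seed,
                   thresholds = config[c("threshold", "min_probes",
                                         "min_abs_mean", "amp_cut", "alpha",
                                         "overlap", "recurrence_freq",
                                         "amp_del_freq")],
                   stages = character(0))
  note <- function(s) manifest$stages <<- c(manifest$stages, s)

  cohort <- stage("simulate", {
    designs <- default_designs(seed = config$seed)
    simulate_cohort(designs, n_samples_per_platform =
                      config$n_samples_per_platform,
                    noise_sd = config$noise_sd, curvature = config$curvature,
                    offset_sd = config$offset_sd, seed = config$seed)
  })
  note("simulate")
  truth <- cohort$truth
  platforms <- unique(truth$samples$platform_id)

  profiles <- stage("normalize", {
    out <- cohort$profiles
    for (pf in platforms) {
      idx <- which(truth$samples$platform_id == pf)
      out[idx] <- normalize_profiles(out[idx], span = config$span,
                                     skip_lowess = config$skip_lowess)
    }
    out
  })
  note("normalize")

  calls <- stage("segment", {
    nu <- cohort_fuzzy_nu(profiles)
    res <- lapply(profiles, function(p) {
      sigma <- estimate_probe_noise(p)
      segs <- detect_aberrations(p, threshold = config$threshold,
                                 method = config$method, sigma = sigma)
      segs <- fuzzy_zero_filter(segs, nu = nu, sigma = sigma,
                                threshold = config$threshold)
      cl <- filter_and_classify(segs, min_probes = config$min_probes,
                                min_abs_mean = config$min_abs_mean,
                                amp_cut = config$amp_cut)
      if (nrow(cl)) cl$platform_id <- p$platform_id
      cl
    })
    do.call(rbind, Filter(nrow, res))
  })
  note("segment")
  write_seg(calls, file.path(config$outdir, "calls.seg"))
  summ <- aberration_summary(calls, truth$samples$sample_id)
  write.table(summ$cohort, file.path(config$outdir, "aberration_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  designs <- profiles[!duplicated(vapply(profiles, `[[`, "", "platform_id"))]
  designs <- setNames(lapply(designs, `[[`, "design"),
                      vapply(designs, `[[`, "", "platform_id"))
  common <- stage("common", {
    do.call(rbind, lapply(platforms, function(pf) {
      sids <- truth$samples$sample_id[truth$samples$platform_id == pf]
      do.call(rbind, lapply(c("gain", "loss"), function(dir)
        detect_common(calls[calls$platform_id == pf, , drop = FALSE],
                      designs[[pf]], dir, alpha = config$alpha,
                      overlap = config$overlap, sample_ids = sids)))
    }))
  })
  note("common")
  write_regions_bed(transform(common, frequency = n_support /
                                nrow(truth$samples)),
                    file.path(config$outdir, "common_aberrations.bed"))

  n_cohort <- nrow(truth$samples)
  regions <- stage("regions", {
    mcrs <- list()
    for (dir in c("gain", "loss")) {
      cnars <- lapply(designs, function(d)
        build_cnar(calls[calls$platform_id == d$platform_id, , drop = FALSE],
                   dir, overlap_threshold = config$overlap, n_cohort))
      mcrs[[dir]] <- build_mcr(cnars, n_cohort)
    }
    tab <- recurrence_table(c(mcrs$gain, mcrs$loss), n_cohort,
                            min_freq = config$recurrence_freq,
                            inclusive = FALSE)
    ampdel <- amplification_deletion_regions(calls, n_cohort,
                                             cutoff = config$amp_cut,
                                             min_freq = config$amp_del_freq,
                                             overlap_threshold = config$overlap)
    list(mcrs = mcrs, table = tab, ampdel = ampdel)
  })
  note("regions")
  write.table(regions$table, file.path(config$outdir, "mcr_recurrence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_regions_bed(regions$table, file.path(config$outdir, "mcr.bed"))

  result <- list(cohort = cohort, profiles = profiles, calls = calls,
                 summary = summ, common = common, regions = regions)

  if (isTRUE(config$run_mlpa)) {
    result$mlpa <- stage("mlpa", {
      genes <- .pipeline_genes(truth$catalog)
      mlpa <- simulate_mlpa(truth, genes,
                            samples = head(truth$samples$sample_id, 6L),
                            seed = config$seed + 1L)
      mcalls <- mlpa_call_table(mlpa)
      astat <- acgh_gene_status(calls, genes,
                                sample_ids = unique(mcalls$sample_id))
      conc <- mlpa_concordance(mcalls, astat,
                               size_bins = c(1e3, 5e3, 1e4, 5e4, 1e5, Inf))
      list(calls = mcalls, concordance = conc)
    })
    note("mlpa")
  } else note("mlpa:skipped")

  if (isTRUE(config$run_expression)) {
    result$expression <- stage("expression", {
      genes <- .pipeline_genes(truth$catalog)
      genes$beta <- rep_len(c(1, 0), nrow(genes))
      ct <- simulate_expression(truth, genes, seed = config$seed + 2L)
      fcs <- fold_change(ct)
      status <- gene_cna_status(calls, genes,
                                sample_ids = truth$samples$sample_id)
      tab <- stratified_expression_table(fcs, status)
      write.table(tab, file.path(config$outdir, "expression_association.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
    note("expression")
  } else note("expression:skipped")

  if (isTRUE(config$run_clinical)) {
    result$clinical <- stage("clinical", {
      genes <- .pipeline_genes(truth$catalog)
      status <- gene_cna_status(calls, genes,
                                sample_ids = truth$samples$sample_id)
      assoc <- lauren_association(status, truth$samples[, c("sample_id",
                                                            "lauren_type")])
      dosage <- true_dosage(truth, genes)
      agec <- age_correlation(dosage, truth$samples$age)
      myc_like <- genes$gene[1]
      grp <- status$has_cna[status$gene == myc_like][
        match(truth$samples$sample_id,
              status$sample_id[status$gene == myc_like])]
      surv <- km_logrank(grp, truth$samples$survival_time,
                         truth$samples$event)
      list(lauren = assoc, age = agec, survival = surv[c("chisq", "p")])
    })
    note("clinical")
  } else note("clinical:skipped")

  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

# one synthetic "gene" per catalog aberration, centered inside it, with the
# aberration's direction attached (for status lookups)
.pipeline_genes <- function(catalog) {
  mid <- (catalog$start + catalog$end) / 2
  half <- pmin(5e3, (catalog$end - catalog$start) / 4)
  data.frame(gene = paste0("g_", catalog$aberration_id),
             chrom = catalog$chrom,
             start = floor(mid - half), end = ceiling(mid + half),
             direction = catalog$direction, stringsAsFactors = FALSE)
}
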