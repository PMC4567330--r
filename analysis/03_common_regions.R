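#!/usr/bin/env Rscript
# Stage 3: cross-sample statistics and recurrent-region extraction.
#
# Context-corrected common aberrations per platform (Poisson-binomial null,
# p < 0.05, reciprocal overlap >= 0.9 for membership), then CNARs (> 90%
# reciprocal overlap, transitive closure) per platform, cross-platform MCRs
# (intersection of all member segments, observed on all three platforms),
# the > 20% recurrence table and the >= 10% amplification/deletion tables.

suppressPackageStartupMessages(library(cnamcr))

SEED <- 20150911L
dir.create("results", showWarnings = FALSE)

designs <- default_designs(seed = SEED)
cohort <- simulate_cohort(designs, seed = SEED)
truth <- cohort$truth
calls <- read_seg("results/calls.seg")
# re-attach classification columns (SEG keeps the core fields only)
calls$direction <- ifelse(calls$mean_log2 >= 0, "gain", "loss")
calls$amplitude_class <- ifelse(abs(calls$mean_log2) >= 0.8,
                                ifelse(calls$direction == "gain",
                                       "amplification", "deletion"),
                                calls$direction)
calls$platform_id <- truth$samples$platform_id[
  match(calls$sample_id, truth$samples$sample_id)]
n_cohort <- nrow(truth$samples)

common <- do.call(rbind, lapply(names(designs), function(pf) {
  sids <- truth$samples$sample_id[truth$samples$platform_id == pf]
  do.call(rbind, lapply(c("gain", "loss"), function(dir)
    detect_common(calls[calls$platform_id == pf, ], designs[[pf]], dir,
                  sample_ids = sids)))
}))
write_regions_bed(transform(common, frequency = n_support / n_cohort),
                  "results/common_aberrations.bed")
cat(sprintf("%d common aberration regions across platforms\n", nrow(common)))

mcrs <- list()
for (dir in c("gain", "loss")) {
  cnars <- lapply(designs, function(d)
    build_cnar(calls[calls$platform_id == d$platform_id, ], dir,
               n_cohort = n_cohort))
  cat(sprintf("%s CNARs per platform: %s\n", dir,
              paste(vapply(cnars, length, 0L), collapse = "/")))
  mcrs[[dir]] <- build_mcr(cnars, n_cohort)
}
tab <- recurrence_table(c(mcrs$gain, mcrs$loss), n_cohort, min_freq = 0.20)
write.table(tab, "results/mcr_recurrence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_regions_bed(tab, "results/mcr.bed")
cat(sprintf("recurrent (>20%%) MCRs: %d\n", nrow(tab)))
print(tab)

# gene annotation of the recurrent MCRs against the planted-gene models
genes <- cnamcr:::.pipeline_genes(truth$catalog)
for (i in seq_len(nrow(tab))) {
  ann <- annotate_genes(tab[i, ], genes)
  cat(sprintf("  %s:%d-%d %s  contained: %s\n", tab$chrom[i], tab$start[i],
              tab$end[i], tab$direction[i],
              paste(ann$contained, collapse = ",")))
}

ampdel <- amplification_deletion_regions(calls, n_cohort)
cat(sprintf("amplification MCRs (>=10%%): %d; deletion MCRs: %d\n",
            nrow(ampdel$amplification), nrow(ampdel$deletion)))
write.table(rbind(ampdel$amplification, ampdel$deletion),
            "results/amp_del_regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/common_aberrations.bed, mcr_recurrence.tsv, mcr.bed,",
    "amp_del_regions.tsv\n")
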