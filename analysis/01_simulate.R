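#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 88 tumor/normal aCGH profiles on three platforms (30 x dense, 10 x medium,
# 48 x sparse), with planted gains/losses whose prevalence differs by Lauren
# type, intensity-dependent curvature, array offsets and probe noise, plus
# matched clinical covariates. Ground truth is written alongside so every
# later stage can be audited. All later stages re-derive the cohort from
# SEED, so no bulky per-probe tables need to be serialized.

suppressPackageStartupMessages(library(cnamcr))

SEED <- 20150911L
dir.create("results", showWarnings = FALSE)

designs <- default_designs(seed = SEED)
cohort <- simulate_cohort(designs, seed = SEED)
truth <- cohort$truth

cat(sprintf("simulated %d samples on %d platforms (%s)\n",
            nrow(truth$samples), length(designs),
            paste(names(designs), collapse = ", ")))
print(table(truth$samples$lauren_type))
cat(sprintf("planted aberrations: %d (%d gains, %d losses); %d carrier pairs\n",
            nrow(truth$catalog), sum(truth$catalog$true_log2 > 0),
            sum(truth$catalog$true_log2 < 0), nrow(truth$carriers)))

write.table(truth$samples, "results/clinical.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$catalog, "results/truth_catalog.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(truth$carriers, "results/truth_carriers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_probe_table(cohort$profiles[[1]], "results/example_profile.tsv")
cat("wrote results/clinical.tsv, truth_catalog.tsv, truth_carriers.tsv,",
    "example_profile.tsv\n")
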