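#!/usr/bin/env Rscript
# Stage 6: clinicopathological association of the CNA calls.
#
# Per-gene 2x2 association of CNA status with Lauren type (chi-square or
# Fisher), co-occurrence of gains at different loci, Bonferroni-corrected
# age correlation, hierarchical clustering of samples by planted dosage,
# and Kaplan-Meier/log-rank survival by CNA status at the first gain locus.

suppressPackageStartupMessages(library(cnamcr))

SEED <- 20150911L
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(default_designs(seed = SEED), seed = SEED)
truth <- cohort$truth
calls <- read_seg("results/calls.seg")
calls$direction <- ifelse(calls$mean_log2 >= 0, "gain", "loss")

genes <- cnamcr:::.pipeline_genes(truth$catalog)
status <- gene_cna_status(calls, genes, sample_ids = truth$samples$sample_id)

assoc <- suppressWarnings(
  lauren_association(status, truth$samples[, c("sample_id", "lauren_type")]))
write.table(assoc, "results/lauren_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CNA status vs Lauren type (diffuse vs intestinal):\n")
print(assoc)

# co-occurrence of the two large planted gains
wide <- function(g) {
  v <- status$has_cna[status$gene == g]
  names(v) <- status$sample_id[status$gene == g]
  v[truth$samples$sample_id]
}
co <- suppressWarnings(gain_cooccurrence(wide(genes$gene[1]),
                                         wide(genes$gene[4])))
cat(sprintf("\nco-occurrence of %s and %s gains: Fisher p = %.3g\n",
            genes$gene[1], genes$gene[4], co$p))

dosage <- true_dosage(truth, genes)
agec <- age_correlation(dosage, truth$samples$age)
write.table(agec, "results/age_correlation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nage correlation: %d genes, min Bonferroni p = %.2f\n",
            nrow(agec), min(agec$p_bonferroni, na.rm = TRUE)))

cl <- cluster_samples(dosage, k = 4)
clust_tab <- data.frame(sample_id = names(cl$clusters),
                        cluster = unname(cl$clusters))
write.table(clust_tab, "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("hierarchical clustering: %d samples in %d clusters (%s)\n",
            nrow(clust_tab), length(unique(clust_tab$cluster)),
            paste(table(clust_tab$cluster), collapse = "/")))

grp <- wide(genes$gene[1])
surv <- km_logrank(grp, truth$samples$survival_time, truth$samples$event)
cat(sprintf("log-rank, survival by %s status: chisq = %.2f, p = %.3f\n",
            genes$gene[1], surv$chisq, surv$p))
cat("wrote results/lauren_association.tsv, age_correlation.tsv, clusters.tsv\n")
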