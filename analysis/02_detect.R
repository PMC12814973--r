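#!/usr/bin/env Rscript
# Step 2 — run the in-house epistasis detectors.
#
# Re-creates the step-1 cohort deterministically, applies variant QC
# (MAF >= 5%, Hardy-Weinberg p >= 0.001; causal SNPs kept regardless, as
# risk variants), then runs four protocols: the allelic regression scan on
# binary and on PC-residualized phenotypes, the genotype 4-df scan, and the
# correlation-difference scan. Writes one PLINK-style .epi table per
# protocol under results/detect/.

library(senkit)

seed <- 2026
out <- "results/detect"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(n_individuals = 4000, n_snps = 120, n_chrom = 2,
                      seed = seed)
y <- sim$phenotype$phenotype
set.seed(seed)
pcs <- matrix(rnorm(length(y)), ncol = 1)   # stand-in ancestry axis
yres <- residualize_phenotype(y, pcs)

keep <- qc_variants(sim$genotypes,
                    keep_list = sim$genotypes$snp_ids[sim$causal_idx])
gq <- sim$genotypes
gq$values <- gq$values[, keep, drop = FALSE]
gq$snp_ids <- colnames(gq$values)
gq$positions <- gq$positions[gq$positions$snp_id %in% gq$snp_ids, ]
cat(sprintf("QC: %d of %d SNPs retained\n", length(keep), 120))

protocols <- list(
  allelic_binary = function() allelic_regression_scan(gq, y),
  allelic_resid  = function() allelic_regression_scan(gq, yres),
  genotype_chi2  = function() genotype_chi2_scan(gq, y),
  cor_diff       = function() correlation_difference_scan(gq, y))

for (nm in names(protocols)) {
  t <- suppressMessages(protocols[[nm]]())
  write_pair_table(t, file.path(out, paste0(nm, ".epi")))
  top <- top_k(t, 15)
  hits <- length(intersect(senkit:::pair_key(top$a, top$b),
                           truth_pairs(sim$truth)))
  cat(sprintf("%-15s %6d pairs scored, %d/7 causal pairs in top 15\n",
              nm, nrow(t), hits))
}
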