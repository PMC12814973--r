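#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Genotypes for 4000 individuals x 120 SNPs on two synthetic chromosomes,
# with twelve causal loci (two marginal, four epistatic pairs, one triplet
# sharing a locus with the joint-recessive pair) and binary phenotypes under
# the multiplicative penetrance models. Writes the cohort and the truth set
# under results/data/.

library(senkit)

seed <- 2026
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(n_individuals = 4000, n_snps = 120, n_chrom = 2,
                      seed = seed)
write_genotypes(sim$genotypes, sim$phenotype, out)
write.table(as.data.frame(sim$truth), file.path(out, "truth_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d individuals, %d SNPs, prevalence %.3f\n",
            nrow(sim$genotypes$values), ncol(sim$genotypes$values),
            mean(sim$phenotype$phenotype)))
cat(sprintf("truth: %d causal pairs over %d epistatic loci\n",
            nrow(sim$truth),
            length(unique(c(sim$truth$snp_a, sim$truth$snp_b)))))
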