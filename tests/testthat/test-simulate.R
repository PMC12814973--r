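test_that("genotypes follow Hardy-Weinberg proportions at the requested MAF", {
  g <- simulate_genotypes(10000, 50, maf_range = c(0.05, 0.5),
                          causal_maf_range = c(0.1, 0.3),
                          causal_idx = 1:10, seed = 42)
  expect_equal(dim(g$values), c(10000, 50))
  expect_true(all(g$values %in% 0:2))
  # sample allele frequency within 3 SE of the simulated MAF
  p_hat <- colMeans(g$values) / 2
  se <- sqrt(g$maf * (1 - g$maf) / (2 * 10000))
  expect_true(all(abs(p_hat - g$maf) <= 3.5 * se))
  expect_true(all(g$maf[1:10] >= 0.1 & g$maf[1:10] <= 0.3))
  # degenerate MAF range 0.5: genotype frequencies (.25, .5, .25)
  g5 <- simulate_genotypes(20000, 2, maf_range = c(0.5, 0.5), seed = 1)
  freq <- table(factor(g5$values[, 1], levels = 0:2)) / 20000
  expect_true(all(abs(as.numeric(freq) - c(0.25, 0.5, 0.25)) < 0.02))
  # positions strictly increasing within a chromosome
  pos <- g$positions
  expect_true(all(tapply(pos$pos, pos$chrom, function(x) all(diff(x) > 0))))
})

test_that("genotype simulation is bit-reproducible and validates inputs", {
  a <- simulate_genotypes(100, 10, seed = 7)
  b <- simulate_genotypes(100, 10, seed = 7)
  expect_identical(a$values, b$values)
  expect_error(simulate_genotypes(1, 10), "n_individuals")
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "interval")
  expect_error(simulate_genotypes(10, 5, causal_idx = 9), "out of range")
})

test_that("penetrance models apply the documented risk factors", {
  values <- rbind(c(0L, 2L, 1L), c(1L, 1L, 0L), c(2L, 2L, 2L), c(0L, 0L, 0L))
  rf <- function(kind, loci, alpha) {
    senkit:::risk_factor(epistasis_model(kind, loci, alpha), values)
  }
  expect_equal(rf("marginal", 1, 4), c(1, 3, 5, 1))
  # joint dominance needs >=1 alt allele at BOTH loci
  expect_equal(rf("joint_dominant", c(1, 2), 3), c(1, 4, 4, 1))
  expect_equal(rf("joint_recessive", c(1, 2), 3), c(1, 1, 4, 1))
  expect_equal(rf("multiplicative", c(1, 2), 3), c(1, 4^(1 / 4), 4, 1))
  expect_equal(rf("exponential", c(1, 2), 3), c(1, exp(3 / 4), exp(3), 1))
  expect_equal(rf("triplet", c(1, 2, 3), 3), c(1, 1, 4, 1))
  expect_error(epistasis_model("triplet", c(1, 2), 3), "3 locus")
  expect_error(epistasis_model("marginal", c(1, 2), 3), "1 locus")
  expect_error(epistasis_model("joint_dominant", c(1, 1), 3), "distinct")
})

test_that("phenotypes hit the baseline prevalence with no genetic effect", {
  g <- simulate_genotypes(20000, 5, seed = 3)
  ph <- simulate_phenotypes(g, list(), baseline = 0.3, seed = 4)
  expect_true(abs(mean(ph$phenotype$phenotype) - 0.3) <
                3 * sqrt(0.3 * 0.7 / 20000))
  expect_equal(nrow(ph$truth), 0)
  expect_error(simulate_phenotypes(g, list(), baseline = 1.2), "baseline")
})

test_that("with all effects at zero the phenotype is independent of genotype", {
  g <- simulate_genotypes(3000, 200, seed = 11)
  models <- list(epistasis_model("marginal", 1, 0),
                 epistasis_model("joint_dominant", c(2, 3), 0))
  ph <- simulate_phenotypes(g, models, baseline = 0.4, seed = 12)
  y <- ph$phenotype$phenotype
  pvals <- apply(g$values, 2, function(col) {
    suppressWarnings(stats::chisq.test(table(col, y))$p.value)
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("study design yields 10 epistatic loci and 7 causal pairs", {
  des <- study_design(100)
  kinds <- vapply(des$models, `[[`, "", "kind")
  expect_equal(sum(kinds == "marginal"), 2)
  ts <- truth_set(des$models, sprintf("snp%04d", 1:100))
  expect_equal(nrow(ts), 7)   # 4 two-way pairs + 3 pairs within the triplet
  epi_snps <- unique(c(ts$snp_a, ts$snp_b))
  expect_equal(length(epi_snps), 10)
  expect_setequal(unique(ts$model_kind),
                  c("joint_dominant", "exponential", "multiplicative",
                    "joint_recessive", "triplet"))
  # pairs are unordered-unique and canonical
  expect_true(all(ts$snp_a < ts$snp_b))
  expect_false(any(duplicated(pair_key(ts$snp_a, ts$snp_b))))
})

test_that("excess risk clamping is rejected as a configuration error", {
  g <- simulate_genotypes(2000, 4, maf_range = c(0.4, 0.5), seed = 5)
  strong <- list(epistasis_model("marginal", 1, 50))
  expect_error(simulate_phenotypes(g, strong, baseline = 0.5, seed = 1),
               "risk exceeds 1")
})

test_that("synthetic protocol outputs honor the overlap target", {
  sim <- simulate_study(200, 20, seed = 9)
  # overlap 1, noise 0: identical top-k content
  out <- simulate_protocol_outputs(sim$truth, sim$genotypes$snp_ids,
                                   n_protocols = 3, k = 30, overlap = 1,
                                   noise = 0, seed = 2)
  keys <- lapply(out, function(t) sort(pair_key(t$a, t$b)))
  expect_identical(keys[[1]], keys[[2]])
  expect_identical(keys[[1]], keys[[3]])
  # causal pairs present at noise 0
  expect_true(all(truth_pairs(sim$truth) %in% keys[[1]]))
  # overlap 0: intersection near the hypergeometric expectation k^2 / P
  empty_truth <- as_truth_set(data.frame(snp_a = character(),
                                         snp_b = character()))
  ks <- replicate(30, {
    o <- simulate_protocol_outputs(empty_truth, sim$genotypes$snp_ids,
                                   n_protocols = 2, k = 30, overlap = 0,
                                   noise = 1, seed = sample.int(1e6, 1))
    length(intersect(pair_key(o[[1]]$a, o[[1]]$b), pair_key(o[[2]]$a, o[[2]]$b)))
  })
  expected <- 30^2 / choose(20, 2)  # ~4.7
  expect_lt(abs(mean(ks) - expected), 3 * stats::sd(ks) / sqrt(30))
  # single protocol: no pairwise constraint, still k rows
  one <- simulate_protocol_outputs(sim$truth, sim$genotypes$snp_ids,
                                   n_protocols = 1, k = 10, seed = 3)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]), 10)
  expect_error(simulate_protocol_outputs(sim$truth, sim$genotypes$snp_ids,
                                         n_protocols = 2, k = 1000),
               "exceeds")
})

test_that("simulated gene maps honor the flank rule and whitelist probability", {
  pos <- toy_positions(sprintf("s%02d", 1:30))
  ann <- simulate_gene_map(pos, n_genes = 6, flank = 0, whitelist_prob = 1,
                           seed = 4)
  # flank 0: every mapped SNP lies inside its gene interval
  for (i in seq_len(nrow(ann$map))) {
    gi <- ann$genes[ann$genes$gene_id == ann$map$gene_id[i], ]
    p <- pos$pos[pos$snp_id == ann$map$snp_id[i]]
    expect_true(p >= gi$start && p <= gi$end)
  }
  # inclusion probability 1: whitelist is all gene pairs
  expect_equal(nrow(ann$whitelist), choose(6, 2))
  # a large flank makes assignments many-to-many
  ann2 <- simulate_gene_map(pos, n_genes = 6, flank = 5e4, seed = 4)
  expect_true(any(duplicated(ann2$map$snp_id)))
})
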