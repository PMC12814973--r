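test_that("residualization returns logistic response residuals", {
  set.seed(1)
  y <- rbinom(500, 1, 0.4)
  # intercept-only fit: residual = y - mean(y)
  r <- residualize_phenotype(y, matrix(0, 500, 1))
  expect_equal(r$values, y - mean(y), tolerance = 1e-6)
  expect_identical(r$semantics, "residualized")
  # independent covariates: residuals uncorrelated with them
  X <- matrix(rnorm(1000), ncol = 2)
  r2 <- residualize_phenotype(y, X)
  for (j in 1:2)
    expect_lt(abs(cor(r2$values, X[, j])), 3 / sqrt(500))
  # perfect separation must error, as must rank deficiency
  expect_error(residualize_phenotype(y, cbind(ifelse(y == 1, 5, -5))),
               "separation")
  expect_error(residualize_phenotype(y, cbind(X[, 1], X[, 1])),
               "rank deficient")
})

test_that("variant QC applies MAF and HWE filters with a keep list", {
  g <- simulate_genotypes(100, 2, seed = 1)
  # hand-built columns: monomorphic; exact HWE at MAF .5; all heterozygous
  g$values <- cbind(rep(0L, 100),
                    rep(c(0L, 1L, 1L, 2L), 25),
                    rep(1L, 100))
  colnames(g$values) <- c("mono", "hwe_ok", "all_het")
  keep <- qc_variants(g)
  expect_identical(names(keep), "hwe_ok")
  # all-heterozygous: HWE chi-square equals n, p << 0.001
  expect_false("all_het" %in% names(keep))
  # keep list overrides both filters
  keep2 <- qc_variants(g, keep_list = c("mono", "all_het"))
  expect_setequal(names(keep2), c("mono", "hwe_ok", "all_het"))
})

test_that("binary allelic scan matches an individual-level glm oracle", {
  sim <- simulate_study(400, 15, seed = 21)
  y <- sim$phenotype$phenotype
  t <- suppressMessages(allelic_regression_scan(sim$genotypes, y))
  # oracle: per-pair individual-level logistic LR test
  for (i in sample(nrow(t), 8)) {
    g1 <- sim$genotypes$values[, t$a[i]]
    g2 <- sim$genotypes$values[, t$b[i]]
    full <- glm(y ~ g1 + g2 + I(g1 * g2), family = binomial())
    null <- glm(y ~ g1 + g2, family = binomial())
    p_oracle <- pchisq(null$deviance - full$deviance, 1, lower.tail = FALSE)
    expect_equal(t$score[i], p_oracle, tolerance = 1e-6)
  }
  expect_identical(score_semantics(t), "p_raw")
  # sorted ascending by p
  expect_true(!is.unsorted(t$score))
})

test_that("residualized-phenotype scan uses OLS on the product term", {
  sim <- simulate_study(400, 14, seed = 22)
  y <- sim$phenotype$phenotype
  yr <- residualize_phenotype(y, matrix(rnorm(400), ncol = 1))
  t <- suppressMessages(allelic_regression_scan(sim$genotypes, yr))
  i <- 3
  g1 <- sim$genotypes$values[, t$a[i]]
  g2 <- sim$genotypes$values[, t$b[i]]
  fit <- lm(yr$values ~ g1 + g2 + I(g1 * g2))
  p_oracle <- anova(fit)["I(g1 * g2)", "Pr(>F)"]
  expect_equal(t$score[i], p_oracle, tolerance = 1e-8)
})

test_that("4-df genotype scan equals the contingency-table LR oracle", {
  # common variants: no genotype class is sparse, so no collapsing happens
  # and the scan must equal the plain two-factor logistic LR test
  g <- simulate_genotypes(2000, 8, maf_range = c(0.3, 0.5), seed = 23)
  set.seed(23)
  y <- rbinom(2000, 1, 0.4)
  t <- suppressMessages(genotype_chi2_scan(g, y))
  for (i in sample(nrow(t), 6)) {
    g1 <- factor(g$values[, t$a[i]], levels = 0:2)
    g2 <- factor(g$values[, t$b[i]], levels = 0:2)
    full <- glm(y ~ g1 * g2, family = binomial())
    null <- glm(y ~ g1 + g2, family = binomial())
    df <- null$df.residual - full$df.residual
    p_oracle <- pchisq(null$deviance - full$deviance, df, lower.tail = FALSE)
    expect_equal(t$score[i], p_oracle, tolerance = 1e-5)
  }
})

test_that("sparse homozygote classes are dominance-collapsed before testing", {
  # one rare variant: its homozygous-alternate class is merged into the
  # heterozygous class, matching a dominance-coded factor oracle
  g <- simulate_genotypes(1500, 2, maf_range = c(0.3, 0.5), seed = 29)
  g$values[, 2] <- rbinom(1500, 2, 0.06)
  colnames(g$values) <- g$snp_ids <- c("common", "rare")
  set.seed(29)
  y <- rbinom(1500, 1, 0.4)
  t <- suppressMessages(genotype_chi2_scan(g, y))
  g1 <- factor(g$values[, "common"], levels = 0:2)
  g2 <- factor(pmin(g$values[, "rare"], 1), levels = 0:1)
  full <- glm(y ~ g1 * g2, family = binomial())
  null <- glm(y ~ g1 + g2, family = binomial())
  df <- null$df.residual - full$df.residual
  expect_equal(df, 2)
  p_oracle <- pchisq(null$deviance - full$deviance, df, lower.tail = FALSE)
  expect_equal(t$score[1], p_oracle, tolerance = 1e-5)
})

test_that("degenerate inputs are rejected or skipped", {
  sim <- simulate_study(200, 14, seed = 24)
  y <- sim$phenotype$phenotype
  expect_error(allelic_regression_scan(sim$genotypes, rep(1, 200)), "constant")
  expect_error(genotype_chi2_scan(sim$genotypes, y + 1), "binary")
  # identical columns: pair skipped with a message
  g <- sim$genotypes
  g$values <- cbind(g$values[, 1], g$values[, 1])
  colnames(g$values) <- c("dup1", "dup2")
  expect_message(t <- allelic_regression_scan(g, y), "collinear")
  expect_equal(nrow(t), 0)
})

test_that("correlation-difference scan reproduces the Fisher-z arithmetic", {
  # r_cases = .5, r_controls = 0, both classes of size 103:
  # z = atanh(.5) / sqrt(2/100) = 3.884, p = 1.03e-4
  z <- atanh(0.5) / sqrt(1 / 100 + 1 / 100)
  expect_equal(z, 3.884, tolerance = 1e-3)
  expect_equal(2 * pnorm(-abs(z)), 1.03e-4, tolerance = 1e-2)
  # packaged scan agrees with a direct computation on simulated data
  sim <- simulate_study(600, 14, seed = 25)
  y <- sim$phenotype$phenotype
  t <- suppressMessages(correlation_difference_scan(sim$genotypes, y))
  i <- 5
  g1 <- sim$genotypes$values[, t$a[i]]; g2 <- sim$genotypes$values[, t$b[i]]
  zo <- (atanh(cor(g1[y == 1], g2[y == 1])) -
           atanh(cor(g1[y == 0], g2[y == 0]))) /
    sqrt(1 / (sum(y) - 3) + 1 / (sum(1 - y) - 3))
  expect_equal(t$score[i], 2 * pnorm(-abs(zo)), tolerance = 1e-10)
  # label swap flips z but preserves p
  t_sw <- suppressMessages(correlation_difference_scan(sim$genotypes, 1 - y))
  expect_equal(t$score, t_sw$score, tolerance = 1e-10)
})

test_that("scan tables are unordered-unique and tie-broken lexicographically", {
  sim <- simulate_study(200, 14, seed = 26)
  y <- sim$phenotype$phenotype
  for (t in list(suppressMessages(allelic_regression_scan(sim$genotypes, y)),
                 suppressMessages(genotype_chi2_scan(sim$genotypes, y)),
                 suppressMessages(correlation_difference_scan(sim$genotypes, y)))) {
    expect_false(any(duplicated(pair_key(t$a, t$b))))
    expect_true(all(t$a < t$b))
    o <- order(t$score, t$a, t$b)
    expect_equal(o, seq_len(nrow(t)))
  }
})

test_that("all three detectors control type-I error on null data", {
  # 64 null SNPs -> 2016 pairs; phenotype independent of genotype
  g <- simulate_genotypes(800, 64, seed = 31)
  set.seed(32)
  y <- rbinom(800, 1, 0.5)
  tol <- 3 * sqrt(0.05 * 0.95 / 2016)
  for (t in list(suppressMessages(allelic_regression_scan(g, y)),
                 suppressMessages(genotype_chi2_scan(g, y)),
                 suppressMessages(correlation_difference_scan(g, y)))) {
    expect_lt(abs(mean(t$score < 0.05) - 0.05), tol)
  }
})

test_that("residualization removes a covariate-driven spurious interaction", {
  # confounder raises phenotype and both genotypes jointly
  set.seed(41)
  n <- 3000
  u <- rnorm(n)
  maf <- plogis(u)  # individual-specific allele dosage propensity
  g <- simulate_genotypes(n, 6, seed = 41)
  g$values[, 1] <- rbinom(n, 2, 0.2 + 0.5 * plogis(2 * u))
  g$values[, 2] <- rbinom(n, 2, 0.2 + 0.5 * plogis(2 * u))
  y <- rbinom(n, 1, plogis(-1 + 2 * u))
  raw <- suppressMessages(allelic_regression_scan(g, y))
  res <- residualize_phenotype(y, cbind(u))
  adj <- suppressMessages(allelic_regression_scan(g, res))
  key <- pair_key(g$snp_ids[1], g$snp_ids[2])
  p_raw <- raw$score[pair_key(raw$a, raw$b) == key]
  p_adj <- adj$score[pair_key(adj$a, adj$b) == key]
  expect_gt(p_adj, 0.001)       # no longer significant after correction
})
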