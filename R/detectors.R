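#' Residualize a binary phenotype on covariates
#'
#' Fits a logistic regression of the phenotype on the covariates (with
#' intercept) and returns the response residuals, observed minus fitted
#' probability — the continuous "corrected" phenotype used by detectors that
#' cannot take covariates.
#'
#' @param y numeric 0/1 phenotype vector.
#' @param covariates numeric matrix, rows aligned with `y`.
#' @return list with `values` (the residuals) and `semantics`
#'   (`"residualized"`).
#' @export
residualize_phenotype <- function(y, covariates) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(y))
    stop("covariates must have one row per phenotype value")
  # constant columns duplicate the intercept; drop them
  keep <- apply(covariates, 2, function(x) stats::sd(x) > 0)
  X <- cbind(1, covariates[, keep, drop = FALSE])
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("logistic fit did not converge (perfect separation?)", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic fit did not converge (perfect separation?)")
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10))
    stop("logistic fit did not converge (perfect separation?)")
  list(values = y - fit$fitted.values, semantics = "residualized")
}

#' Variant quality control: MAF and Hardy-Weinberg filters
#'
#' Drops SNPs with minor allele frequency below `maf_min` or whose genotype
#' counts deviate from Hardy-Weinberg proportions (1-df chi-squared
#' goodness-of-fit p-value below `hwe_alpha`). SNPs on `keep_list` are
#' retained regardless — risk variants of interest survive QC. Monomorphic
#' SNPs always fail the MAF filter.
#'
#' @param genotypes a [simulate_genotypes()]-style object.
#' @param maf_min MAF cutoff in `[0, 0.5]` (default 0.05).
#' @param hwe_alpha HWE p-value cutoff (default 0.001).
#' @param keep_list SNP ids exempt from both filters.
#' @return integer vector of retained column indices (named by SNP id).
#' @export
qc_variants <- function(genotypes, maf_min = 0.05, hwe_alpha = 0.001,
                        keep_list = character(0)) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  values <- genotypes$values
  keep <- vapply(seq_len(ncol(values)), function(j) {
    g <- values[, j]
    g <- g[!is.na(g)]
    n <- length(g)
    n2 <- sum(g == 2L); n1 <- sum(g == 1L); n0 <- n - n1 - n2
    p <- (2 * n2 + n1) / (2 * n)     # alt allele frequency
    maf <- min(p, 1 - p)
    if (maf < maf_min) return(FALSE)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((c(n0, n1, n2) - expd)^2 / expd)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE) >= hwe_alpha
  }, logical(1))
  keep[colnames(values) %in% keep_list] <- TRUE
  out <- which(keep)
  names(out) <- colnames(values)[out]
  out
}

#' @keywords internal
default_pair_source <- function(snp_ids, pair_source) {
  if (is.null(pair_source)) {
    if (length(snp_ids) > 1500)
      stop("all-pairs scan above 1500 SNPs; supply a candidate pair list")
    cmb <- utils::combn(snp_ids, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  } else {
    data.frame(a = as.character(pair_source[[1]]),
               b = as.character(pair_source[[2]]), stringsAsFactors = FALSE)
  }
}

# 3 x 3 x 2 cross-tabulation of two genotype columns against a binary
# phenotype, as a 9 x 2 matrix of (control, case) counts per genotype cell.
#' @keywords internal
pair_cell_counts <- function(g1, g2, y) {
  ok <- !is.na(g1) & !is.na(g2)
  cell <- g1[ok] * 3L + g2[ok] + 1L          # 1..9
  idx <- cell + 9L * y[ok]                    # controls 1..9, cases 10..18
  cnt <- tabulate(idx, nbins = 18L)
  matrix(cnt, nrow = 9, ncol = 2, dimnames = list(NULL, c("control", "case")))
}

#' @keywords internal
finalize_scan <- function(rows, descriptor) {
  if (!length(rows))
    return(pair_score_table(character(0), character(0), numeric(0),
                            "p_raw", descriptor))
  df <- do.call(rbind, rows)
  pair_score_table(df$a, df$b, df$p, "p_raw", descriptor)
}

#' Allelic (additive-coding) interaction scan
#'
#' Per pair, fits a regression of the phenotype on the two additive genotype
#' codings and their product, and scores the pair by the p-value of the 1-df
#' test on the product term: logistic regression for a binary phenotype
#' (fitted on the collapsed 3 x 3 genotype table, which is likelihood-
#' equivalent to the individual-level fit), ordinary least squares for a
#' residualized continuous phenotype. Pairs with collinear codings are
#' skipped with a message.
#'
#' @param genotypes a [simulate_genotypes()]-style object.
#' @param y phenotype: binary 0/1 vector or a [residualize_phenotype()]
#'   result.
#' @param pair_source optional two-column data.frame of candidate pairs;
#'   default all pairs (panels up to 1500 SNPs).
#' @param descriptor optional [protocol_descriptor()].
#' @return [pair_score_table()] with `p_raw` semantics, ascending p.
#' @export
allelic_regression_scan <- function(genotypes, y, pair_source = NULL,
                                    descriptor = NULL) {
  values <- genotypes$values
  continuous <- is.list(y) && identical(y$semantics, "residualized")
  yy <- if (continuous) y$values else y
  if (!continuous && !all(yy %in% c(0, 1)))
    stop("y must be binary 0/1 or a residualized phenotype")
  if (length(unique(yy)) < 2) stop("phenotype is constant")
  prs <- default_pair_source(colnames(values), pair_source)
  g12 <- expand.grid(g1 = 0:2, g2 = 0:2)   # cell order matches pair_cell_counts
  rows <- vector("list", nrow(prs))
  for (i in seq_len(nrow(prs))) {
    g1 <- values[, prs$a[i]]; g2 <- values[, prs$b[i]]
    p <- if (continuous) {
      ok <- !is.na(g1) & !is.na(g2)
      X <- cbind(1, g1[ok], g2[ok], g1[ok] * g2[ok])
      if (qr(X)$rank < 4L) NA_real_ else {
        fit <- stats::lm.fit(X, yy[ok])
        rss1 <- sum(fit$residuals^2)
        fit0 <- stats::lm.fit(X[, 1:3, drop = FALSE], yy[ok])
        rss0 <- sum(fit0$residuals^2)
        df2 <- sum(ok) - 4L
        f <- (rss0 - rss1) / (rss1 / df2)
        stats::pf(f, 1, df2, lower.tail = FALSE)
      }
    } else {
      cnt <- pair_cell_counts(g1, g2, yy)
      nz <- rowSums(cnt) > 0
      X <- cbind(1, g12$g1, g12$g2, g12$g1 * g12$g2)[nz, , drop = FALSE]
      if (qr(X)$rank < 4L) NA_real_ else {
        cc <- cnt[nz, , drop = FALSE]
        ll1 <- cell_logistic_loglik(X, cc)
        ll0 <- cell_logistic_loglik(X[, 1:3, drop = FALSE], cc)
        stats::pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
      }
    }
    if (is.na(p)) {
      message("skipping collinear pair ", prs$a[i], "-", prs$b[i])
      next
    }
    rows[[i]] <- data.frame(a = prs$a[i], b = prs$b[i], p = p,
                            stringsAsFactors = FALSE)
  }
  finalize_scan(Filter(Negate(is.null), rows), descriptor)
}

# Maximized binomial log-likelihood of a logistic model on collapsed cells:
# counts is a cells x 2 matrix (control, case). Identical, up to a constant,
# to the individual-level logistic likelihood.
#' @keywords internal
cell_logistic_loglik <- function(X, counts) {
  n <- rowSums(counts)
  fit <- suppressWarnings(
    stats::glm.fit(X, counts[, "case"] / n, weights = n,
                   family = stats::binomial()))
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  sum(counts[, "case"] * log(mu) + counts[, "control"] * log(1 - mu))
}

#' Genotype-level 4-df interaction scan
#'
#' Per pair, a likelihood-ratio chi-squared test with 4 degrees of freedom
#' comparing the saturated logistic model on the 3 x 3 genotype table
#' against the main-effects model (additive-plus-dominance per locus, i.e.
#' both loci as factors, no interaction). Tests interactions at the genotype
#' rather than allele level. Sparse genotype categories break the
#' chi-squared approximation, so a locus's homozygous-alternate class is
#' merged into its heterozygous class when it holds fewer than `min_count`
#' individuals (the usual dominance collapsing for sparse tables); missing
#' or merged rows/columns shrink the test df accordingly (noted by message).
#'
#' @inheritParams allelic_regression_scan
#' @param y binary 0/1 phenotype vector.
#' @param min_count minimum marginal count for the homozygous-alternate
#'   genotype class before it is merged into the heterozygous class;
#'   default `ceiling(sqrt(2 * n))`, which keeps every expected cell of the
#'   3 x 3 x 2 table above 1 under the null with balanced classes
#'   (Cochran-style validity condition for the chi-squared approximation).
#' @return [pair_score_table()] with `p_raw` semantics.
#' @export
genotype_chi2_scan <- function(genotypes, y, pair_source = NULL,
                               min_count = NULL, descriptor = NULL) {
  values <- genotypes$values
  if (!all(y %in% c(0, 1))) stop("y must be strictly binary 0/1")
  if (length(unique(y)) < 2) stop("phenotype is constant")
  if (is.null(min_count)) min_count <- ceiling(sqrt(2 * length(y)))
  prs <- default_pair_source(colnames(values), pair_source)
  rows <- vector("list", nrow(prs))
  for (i in seq_len(nrow(prs))) {
    g1 <- values[, prs$a[i]]; g2 <- values[, prs$b[i]]
    cnt <- pair_cell_counts(g1, g2, y)
    # 3 x 3 x 2 array: [g1 level, g2 level, phenotype class]
    A <- array(cnt, dim = c(3, 3, 2))
    if (sum(A[3, , ]) < min_count) {
      A[2, , ] <- A[2, , ] + A[3, , ]
      A <- A[-3, , , drop = FALSE]
    }
    if (sum(A[, dim(A)[2], ]) < min_count && dim(A)[2] == 3) {
      A[, 2, ] <- A[, 2, ] + A[, 3, ]
      A <- A[, -3, , drop = FALSE]
    }
    l1 <- dim(A)[1]; l2 <- dim(A)[2]
    cc <- cbind(control = as.vector(A[, , 1]), case = as.vector(A[, , 2]))
    lv <- expand.grid(g1 = seq_len(l1), g2 = seq_len(l2))
    nz <- rowSums(cc) > 0
    Xm <- stats::model.matrix(~ factor(g1) + factor(g2), lv)[nz, , drop = FALSE]
    qx <- qr(Xm)
    rk <- qx$rank
    df <- sum(nz) - rk
    if (df < 1) {
      message("skipping degenerate pair ", prs$a[i], "-", prs$b[i])
      next
    }
    # collapsed or missing rows/columns reduce the df below 4
    if (df < 4)
      message("reduced df (", df, ") for pair ", prs$a[i], "-", prs$b[i])
    cc <- cc[nz, , drop = FALSE]
    ll0 <- cell_logistic_loglik(Xm[, qx$pivot[seq_len(rk)], drop = FALSE], cc)
    # saturated model: exact cell-wise MLE
    n <- rowSums(cc)
    mu <- pmin(pmax(cc[, "case"] / n, 1e-12), 1 - 1e-12)
    ll1 <- sum(cc[, "case"] * log(mu) + cc[, "control"] * log(1 - mu))
    p <- stats::pchisq(2 * (ll1 - ll0), df = df, lower.tail = FALSE)
    rows[[i]] <- data.frame(a = prs$a[i], b = prs$b[i], p = p,
                            stringsAsFactors = FALSE)
  }
  finalize_scan(Filter(Negate(is.null), rows), descriptor)
}

#' Correlation-difference (Fisher z) interaction scan
#'
#' Per pair, compares the Pearson correlation of the two genotype codings in
#' cases against controls via Fisher's z transform:
#' `z = (atanh(r_cases) - atanh(r_controls)) /
#'  sqrt(1/(n_cases-3) + 1/(n_controls-3))`,
#' scored by the two-sided normal p-value. A case/control correlation shift
#' signals genotype-combination enrichment in one class. Pairs with a
#' zero-variance SNP within a class are skipped with a message.
#'
#' @inheritParams genotype_chi2_scan
#' @return [pair_score_table()] with `p_raw` semantics.
#' @export
correlation_difference_scan <- function(genotypes, y, pair_source = NULL,
                                        descriptor = NULL) {
  values <- genotypes$values
  if (!all(y %in% c(0, 1))) stop("y must be strictly binary 0/1")
  n_ca <- sum(y == 1); n_co <- sum(y == 0)
  if (n_ca < 4 || n_co < 4) stop("need at least 4 individuals per class")
  prs <- default_pair_source(colnames(values), pair_source)
  snps <- unique(c(prs$a, prs$b))
  Vca <- values[y == 1, snps, drop = FALSE]
  Vco <- values[y == 0, snps, drop = FALSE]
  sd_ca <- apply(Vca, 2, stats::sd, na.rm = TRUE)
  sd_co <- apply(Vco, 2, stats::sd, na.rm = TRUE)
  r_ca <- suppressWarnings(stats::cor(Vca, use = "pairwise.complete.obs"))
  r_co <- suppressWarnings(stats::cor(Vco, use = "pairwise.complete.obs"))
  se <- sqrt(1 / (n_ca - 3) + 1 / (n_co - 3))
  rows <- vector("list", nrow(prs))
  for (i in seq_len(nrow(prs))) {
    a <- prs$a[i]; b <- prs$b[i]
    if (sd_ca[a] == 0 || sd_ca[b] == 0 || sd_co[a] == 0 || sd_co[b] == 0) {
      message("skipping zero-variance pair ", a, "-", b)
      next
    }
    z <- (atanh(r_ca[a, b]) - atanh(r_co[a, b])) / se
    rows[[i]] <- data.frame(a = a, b = b,
                            p = 2 * stats::pnorm(-abs(z)),
                            stringsAsFactors = FALSE)
  }
  finalize_scan(Filter(Negate(is.null), rows), descriptor)
}
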