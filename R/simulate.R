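#' Simulate a genotype panel under Hardy-Weinberg proportions
#'
#' Each SNP draws a per-SNP minor allele frequency uniformly from `maf_range`
#' (causal SNPs from `causal_maf_range`) and genotypes are sampled as
#' Binomial(2, MAF) counts of the alternate allele, i.e. linkage-equilibrium
#' Hardy-Weinberg genotypes coded 0/1/2. Positions are laid out on
#' `n_chrom` synthetic chromosomes at a fixed spacing so positional gene
#' mapping and region filters can be exercised.
#'
#' @param n_individuals number of individuals (rows), at least 2.
#' @param n_snps number of SNPs (columns).
#' @param maf_range interval in (0, 0.5] for background SNP MAFs.
#' @param causal_maf_range interval in (0, 0.5] for SNPs in `causal_idx`.
#' @param causal_idx integer column indices treated as causal.
#' @param n_chrom number of synthetic chromosomes to spread SNPs over.
#' @param spacing base-pair spacing between adjacent SNPs (1-based positions).
#' @param missing_rate fraction of entries set to `NA`, uniformly at random.
#' @param seed integer seed; the simulation is bit-reproducible given it.
#' @return object of class `genotype_matrix`: list with `values`
#'   (individuals x SNPs integer matrix, SNP ids as colnames), `snp_ids`,
#'   `positions` (data.frame `snp_id`, `chrom`, `pos`; 1-based), and `maf`
#'   (the per-SNP simulated MAFs).
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5),
                               causal_maf_range = c(0.1, 0.3),
                               causal_idx = integer(0),
                               n_chrom = 1L, spacing = 5000L,
                               missing_rate = 0, seed = 1L) {
  check_range <- function(r, nm) {
    if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
      stop(nm, " must be an interval within (0, 0.5]")
  }
  if (n_individuals < 2) stop("n_individuals must be at least 2")
  check_range(maf_range, "maf_range")
  check_range(causal_maf_range, "causal_maf_range")
  if (length(causal_idx) && (any(causal_idx < 1) || any(causal_idx > n_snps)))
    stop("causal_idx out of range")
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  if (length(causal_idx))
    maf[causal_idx] <- stats::runif(length(causal_idx),
                                    causal_maf_range[1], causal_maf_range[2])
  values <- matrix(stats::rbinom(n_individuals * n_snps, 2L,
                                 rep(maf, each = n_individuals)),
                   nrow = n_individuals, ncol = n_snps)
  if (missing_rate > 0) {
    miss <- stats::runif(length(values)) < missing_rate
    values[miss] <- NA_integer_
  }
  snp_ids <- sprintf("snp%04d", seq_len(n_snps))
  colnames(values) <- snp_ids
  chrom <- rep(seq_len(n_chrom), length.out = n_snps)
  chrom <- sort(chrom)
  pos <- integer(n_snps)
  for (c_ in unique(chrom)) {
    idx <- which(chrom == c_)
    pos[idx] <- seq_along(idx) * spacing
  }
  structure(list(values = values, snp_ids = snp_ids,
                 positions = data.frame(snp_id = snp_ids,
                                        chrom = paste0("chr", chrom),
                                        pos = pos,
                                        stringsAsFactors = FALSE),
                 maf = maf),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$positions$chrom))))
  invisible(x)
}

.model_kinds <- c("marginal", "joint_dominant", "joint_recessive",
                  "multiplicative", "exponential", "triplet")

#' Specify a penetrance model acting on one, two or three loci
#'
#' The model contributes a multiplicative risk factor on top of the baseline
#' disease probability (see [simulate_phenotypes()]):
#' \describe{
#'   \item{marginal}{factor \eqn{1 + \alpha g / 2} for genotype g at one locus}
#'   \item{joint_dominant}{\eqn{1+\alpha} if both loci carry at least one
#'     alternate allele, else 1}
#'   \item{joint_recessive}{\eqn{1+\alpha} if both loci are homozygous
#'     alternate, else 1}
#'   \item{multiplicative}{\eqn{(1+\alpha)^{g_1 g_2 / 4}}}
#'   \item{exponential}{\eqn{\exp(\alpha g_1 g_2 / 4)}}
#'   \item{triplet}{\eqn{1+\alpha} if all three loci carry at least one
#'     alternate allele, else 1}
#' }
#'
#' @param kind model kind, one of `r paste(.model_kinds, collapse = ", ")`.
#' @param loci integer locus (column) indices: 1 for marginal, 3 for triplet,
#'   2 otherwise; must be distinct.
#' @param alpha non-negative effect size.
#' @return object of class `epistasis_model`.
#' @export
epistasis_model <- function(kind, loci, alpha) {
  kind <- match.arg(kind, .model_kinds)
  loci <- as.integer(loci)
  need <- switch(kind, marginal = 1L, triplet = 3L, 2L)
  if (length(loci) != need)
    stop(sprintf("model '%s' needs %d locus/loci, got %d", kind, need, length(loci)))
  if (anyDuplicated(loci)) stop("model loci must be distinct")
  if (alpha < 0) stop("alpha must be non-negative")
  structure(list(kind = kind, loci = loci, alpha = alpha),
            class = "epistasis_model")
}

#' @keywords internal
risk_factor <- function(model, values) {
  a <- model$alpha
  g <- values[, model$loci, drop = FALSE]
  g[is.na(g)] <- 0L  # missing genotypes contribute no risk
  switch(model$kind,
    marginal        = 1 + a * g[, 1] / 2,
    joint_dominant  = ifelse(g[, 1] >= 1 & g[, 2] >= 1, 1 + a, 1),
    joint_recessive = ifelse(g[, 1] == 2 & g[, 2] == 2, 1 + a, 1),
    multiplicative  = (1 + a)^(g[, 1] * g[, 2] / 4),
    exponential     = exp(a * g[, 1] * g[, 2] / 4),
    triplet         = ifelse(g[, 1] >= 1 & g[, 2] >= 1 & g[, 3] >= 1, 1 + a, 1))
}

#' Derive the causal unordered SNP pairs implied by a model list
#'
#' Two-locus models contribute their pair; a triplet contributes its three
#' member pairs; marginal models contribute none.
#'
#' @param models list of [epistasis_model()] objects.
#' @param snp_ids SNP identifiers indexed by the model loci.
#' @return object of class `truth_set`: data.frame with columns `snp_a`,
#'   `snp_b` (canonical unordered), `model_kind`; duplicates collapsed.
#' @export
truth_set <- function(models, snp_ids) {
  rows <- list()
  for (m in models) {
    if (m$kind == "marginal") next
    ids <- snp_ids[m$loci]
    prs <- if (length(ids) == 2) matrix(ids, ncol = 2) else t(utils::combn(ids, 2))
    rows[[length(rows) + 1L]] <-
      data.frame(snp_a = pmin(prs[, 1], prs[, 2]),
                 snp_b = pmax(prs[, 1], prs[, 2]),
                 model_kind = m$kind, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_a = character(), snp_b = character(),
               model_kind = character(), stringsAsFactors = FALSE)
  out <- out[!duplicated(pair_key(out$snp_a, out$snp_b)), , drop = FALSE]
  out <- out[order(out$snp_a, out$snp_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("truth_set", "data.frame"))
}

#' Canonical pair keys of a truth set
#' @param truth a [truth_set()].
#' @return character vector of pair keys.
#' @export
truth_pairs <- function(truth) pair_key(truth$snp_a, truth$snp_b)

#' Simulate binary phenotypes under multiplicative penetrance models
#'
#' Per-individual disease probability is the baseline risk multiplied by each
#' model's risk factor (see [epistasis_model()]), clamped at `1 - 1e-6`.
#' If more than `max_clamp_frac` of individuals clamp, the configuration is
#' rejected: that much saturation means the requested effect sizes are not
#' representable as probabilities.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param models list of [epistasis_model()] objects (may be empty).
#' @param baseline baseline disease probability in (0, 1).
#' @param max_clamp_frac maximum tolerated fraction of clamped individuals.
#' @param seed integer seed.
#' @return list with `phenotype` (data.frame `sample_id`, `phenotype` in
#'   {0,1}), `risk` (the per-individual probabilities), and `truth`
#'   (the [truth_set()] of causal pairs).
#' @export
simulate_phenotypes <- function(genotypes, models, baseline = 0.1,
                                max_clamp_frac = 0.01, seed = 1L) {
  if (baseline <= 0 || baseline >= 1) stop("baseline must be in (0, 1)")
  values <- genotypes$values
  for (m in models) {
    if (any(m$loci < 1) || any(m$loci > ncol(values)))
      stop("model loci outside the genotype panel")
  }
  risk <- rep(baseline, nrow(values))
  for (m in models) risk <- risk * risk_factor(m, values)
  clamped <- risk > 1 - 1e-6
  if (mean(clamped) > max_clamp_frac)
    stop(sprintf(paste0("risk exceeds 1 for %.1f%% of individuals ",
                        "(limit %.1f%%); reduce alpha or baseline"),
                 100 * mean(clamped), 100 * max_clamp_frac))
  risk[clamped] <- 1 - 1e-6
  set.seed(seed)
  y <- stats::rbinom(length(risk), 1L, risk)
  list(phenotype = data.frame(sample_id = sprintf("ind%05d", seq_along(y)),
                              phenotype = y, stringsAsFactors = FALSE),
       risk = risk,
       truth = truth_set(models, genotypes$snp_ids))
}

#' The study's simulation design: marginal plus five epistatic models
#'
#' Mirrors the simulated architecture used throughout the package: two
#' independent marginal-effect SNPs (effect size `alpha_marginal`) and ten
#' epistatic loci arranged as joint-dominant, exponential, multiplicative and
#' joint-recessive pairs plus a three-way interaction that shares one locus
#' with the joint-recessive pair (effect size `alpha_epistatic`), so the
#' truth set holds 4 two-way pairs and the 3 pairs within the triplet.
#'
#' @param n_snps size of the SNP panel the loci are placed in.
#' @param alpha_marginal,alpha_epistatic effect sizes.
#' @return list with `models` (list of [epistasis_model()]) and `causal_idx`
#'   (the 12 causal column indices, evenly spread over the panel).
#' @export
study_design <- function(n_snps, alpha_marginal = 5, alpha_epistatic = 3) {
  if (n_snps < 12) stop("study design needs at least 12 SNPs")
  idx <- unique(round(seq(1, n_snps, length.out = 12)))
  if (length(idx) < 12) stop("could not place 12 distinct causal loci")
  models <- list(
    epistasis_model("marginal", idx[1], alpha_marginal),
    epistasis_model("marginal", idx[2], alpha_marginal),
    epistasis_model("joint_dominant", idx[3:4], alpha_epistatic),
    epistasis_model("exponential", idx[5:6], alpha_epistatic),
    epistasis_model("multiplicative", idx[7:8], alpha_epistatic),
    epistasis_model("joint_recessive", idx[9:10], alpha_epistatic),
    # the triplet reuses the second joint-recessive locus: 10 epistatic SNPs
    epistasis_model("triplet", c(idx[11], idx[12], idx[10]), alpha_epistatic))
  list(models = models, causal_idx = idx)
}

#' Simulate the full study dataset (genotypes, phenotypes, truth)
#'
#' Convenience wrapper: [study_design()] loci, genotypes with causal MAFs in
#' `causal_maf_range`, and binary phenotypes under the penetrance models.
#' The study default baseline is 0.02 with a 10% clamp budget (covering the configuration's worst-case MAF draw): multiplicative
#' stacking of the marginal and epistatic factors gives rare multi-hit
#' genotypes a risk product above 1, which the simulator reads as full
#' penetrance; the budget admits those individuals while still rejecting
#' configurations where saturation would distort the architecture.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_phenotypes
#' @param alpha_marginal,alpha_epistatic effect sizes passed to [study_design()].
#' @return list with `genotypes`, `phenotype`, `risk`, `truth`, `models`,
#'   `causal_idx`.
#' @export
simulate_study <- function(n_individuals = 10000, n_snps = 1000,
                           causal_maf_range = c(0.1, 0.3),
                           alpha_marginal = 5, alpha_epistatic = 3,
                           baseline = 0.02, max_clamp_frac = 0.1,
                           n_chrom = 1L, seed = 1L) {
  des <- study_design(n_snps, alpha_marginal, alpha_epistatic)
  g <- simulate_genotypes(n_individuals, n_snps,
                          causal_maf_range = causal_maf_range,
                          causal_idx = des$causal_idx,
                          n_chrom = n_chrom, seed = seed)
  ph <- simulate_phenotypes(g, des$models, baseline = baseline,
                            max_clamp_frac = max_clamp_frac,
                            seed = seed + 1L)
  c(list(genotypes = g), ph, des)
}

#' Generate synthetic ranked protocol outputs with controlled overlap
#'
#' Produces `n_protocols` ranked pair tables over the pair universe of
#' `snp_ids`. Each table's top-k content is the union of a shared core
#' (`round(overlap * k)` pairs common to all protocols) and an independent
#' uniform sample from the remaining pairs, so the expected pairwise top-k
#' intersection is about `overlap * k` (and `k^2 / |universe|` at
#' `overlap = 0`). Each causal pair is then forced into each list with
#' probability `1 - noise`, displacing the worst-ranked non-causal entry,
#' and placed uniformly within the top 10% of ranks.
#'
#' @param truth a [truth_set()] (may have zero rows).
#' @param snp_ids the SNP universe; must cover the truth SNPs.
#' @param n_protocols number of tables M >= 1.
#' @param k list length.
#' @param overlap target shared fraction in [0, 1].
#' @param noise per-protocol probability of missing a causal pair.
#' @param semantics score semantics of the emitted tables.
#' @param seed integer seed.
#' @return list of M [pair_score_table()]s (scores increase with rank for
#'   p-type semantics, decrease for weight).
#' @export
simulate_protocol_outputs <- function(truth, snp_ids, n_protocols, k = 100,
                                      overlap = 0.5, noise = 0.1,
                                      semantics = "p_raw", seed = 1L) {
  if (n_protocols < 1) stop("n_protocols must be >= 1")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  tkeys <- truth_pairs(truth)
  tsnps <- unique(c(truth$snp_a, truth$snp_b))
  if (!all(tsnps %in% snp_ids)) stop("universe must cover the truth SNPs")
  n <- length(snp_ids)
  n_pairs <- n * (n - 1) / 2
  if (k > n_pairs) stop("k exceeds the number of pairs in the universe")
  cmb <- utils::combn(sort(snp_ids), 2)
  universe <- paste(cmb[1, ], cmb[2, ], sep = "|")
  set.seed(seed)
  s <- round(overlap * k)
  core <- sample(universe, s)
  rest <- setdiff(universe, core)
  if (length(rest) < k - s && n_protocols > 1)
    stop("overlap target infeasible for this k and universe size")
  lists <- vector("list", n_protocols)
  for (m in seq_len(n_protocols)) {
    own <- if (k - s > 0) sample(rest, k - s) else character(0)
    content <- c(core, own)
    content <- sample(content)  # random rank order
    for (tk in tkeys) {
      if (stats::runif(1) < noise) next
      if (!(tk %in% content)) {
        # displace a deterministic non-causal entry (the lexicographically
        # largest), so protocols sharing content keep sharing it
        victims <- setdiff(content, tkeys)
        content <- content[content != max(victims)]
      } else {
        content <- content[content != tk]
      }
      at <- sample(max(1L, ceiling(0.1 * k)), 1)
      content <- append(content, tk, after = at - 1L)
    }
    prs <- split_pair_key(content)
    score <- if (semantics %in% c("weight", "mean")) {
      if (semantics == "weight") 1 - (seq_len(k) - 0.5) / (k + 1)
      else (seq_len(k) - 0.5) / (k + 1)
    } else (seq_len(k) - 0.5) / (n_pairs + 1)
    lists[[m]] <- pair_score_table(prs$a, prs$b, score, semantics,
                                   descriptor = protocol_descriptor(
                                     tool = sprintf("synthetic%02d", m)))
  }
  lists
}

#' Simulate gene annotation, positional SNP-to-gene map and whitelist
#'
#' Genes tile each simulated chromosome as contiguous intervals covering 80%
#' of each slot (so some SNPs fall between genes); SNPs are assigned to every
#' gene whose interval, extended by `flank` on both sides, contains them
#' (1-based inclusive). The candidate gene-pair whitelist — a stand-in for a
#' prior-evidence database — is a Bernoulli(`whitelist_prob`) subset of all
#' gene pairs.
#'
#' @param snp_positions data.frame (`snp_id`, `chrom`, `pos`) as produced by
#'   [simulate_genotypes()].
#' @param n_genes total number of genes (>= 2), split across chromosomes
#'   proportionally to their SNP counts.
#' @param flank flank in base pairs for the positional rule.
#' @param whitelist_prob inclusion probability for the whitelist.
#' @param seed integer seed.
#' @return list with `genes` (data.frame `chrom`, `start`, `end`, `gene_id`),
#'   `map` (a [gene_map()], strategy `"positional"`), and `whitelist`
#'   (a [gene_pair_whitelist()]).
#' @export
simulate_gene_map <- function(snp_positions, n_genes, flank = 10000,
                              whitelist_prob = 0.3, seed = 1L) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  set.seed(seed)
  chroms <- unique(snp_positions$chrom)
  counts <- table(factor(snp_positions$chrom, levels = chroms))
  alloc <- pmax(1L, round(n_genes * as.numeric(counts) / sum(counts)))
  genes <- list()
  gid <- 0L
  for (i in seq_along(chroms)) {
    pos <- snp_positions$pos[snp_positions$chrom == chroms[i]]
    span_lo <- min(pos); span_hi <- max(pos)
    w <- (span_hi - span_lo + 1) / alloc[i]
    for (j in seq_len(alloc[i])) {
      gid <- gid + 1L
      start <- round(span_lo + (j - 1) * w)
      genes[[gid]] <- data.frame(chrom = chroms[i], start = start,
                                 end = round(start + 0.8 * w),
                                 gene_id = sprintf("gene%03d", gid),
                                 stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  map <- map_snps_to_genes(snp_positions, genes, flank = flank)
  gp <- utils::combn(sort(genes$gene_id), 2)
  keep <- stats::runif(ncol(gp)) <= whitelist_prob
  wl <- gene_pair_whitelist(gp[1, keep], gp[2, keep])
  list(genes = genes, map = map, whitelist = wl)
}
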