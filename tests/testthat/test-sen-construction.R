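test_that("pair tables canonicalize, deduplicate and validate scores", {
  t <- pair_score_table(c("b", "c"), c("a", "a"), c(0.2, 0.1), "p_raw")
  expect_equal(t$a, c("a", "a"))
  expect_equal(t$b, c("c", "b"))       # sorted by p then lexicographic
  expect_error(pair_score_table("a", "a", 0.1, "p_raw"), "self pairs")
  expect_error(pair_score_table(c("a", "b"), c("b", "a"), c(0.1, 0.2), "p_raw"),
               "duplicate")
  expect_error(pair_score_table("a", "b", 1.5, "p_raw"), "\\[0, 1\\]")
  expect_error(pair_score_table("a", "b", 1.5, "run_count"), "integer")
})

test_that("HLA filter removes a pair only when both SNPs are in the region", {
  pos <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4", "s5"),
    chrom = c("chr6", "chr6", "chr2", "chr6", "chr6"),
    pos = c(26e6, 30e6, 1e6, 25e6, 34e6), stringsAsFactors = FALSE)
  t <- pair_score_table(c("s1", "s1", "s4"), c("s2", "s3", "s5"),
                        c(0.1, 0.2, 0.3), "p_raw")
  out <- filter_hla(t, pos)
  # both-inside removed; one-inside kept; exact 25/34 Mb bounds inclusive
  expect_equal(pair_key(out$a, out$b), "s1|s3")
  expect_error(filter_hla(pair_score_table("s1", "zz", 0.1, "p_raw"), pos),
               "zz")
})

test_that("LD filter drops pairs above r2 = 0.75 with a strict inequality", {
  set.seed(5)
  n <- 10000
  v <- cbind(a = rbinom(n, 2, 0.3), b = 0L, c = rbinom(n, 2, 0.3))
  v[, "b"] <- v[, "a"]                        # perfect LD with a
  g <- list(values = v)
  t <- pair_score_table(c("a", "a"), c("b", "c"), c(0.1, 0.2), "p_raw")
  out <- filter_ld(t, g)
  expect_equal(pair_key(out$a, out$b), "a|c") # independent pair kept
  # boundary: r^2 exactly at the threshold is kept
  x <- rep(0:1, each = 4)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  g2 <- list(values = cbind(p = rep(x, 50), q = rep(y, 50)))
  r2 <- cor(g2$values[, 1], g2$values[, 2], use = "complete.obs")^2
  t2 <- pair_score_table("p", "q", 0.5, "p_raw")
  expect_equal(nrow(filter_ld(t2, g2, r2_max = r2)), 1)
  expect_equal(nrow(filter_ld(t2, g2, r2_max = r2 - 1e-9)), 0)
})

test_that("gene mapping expands pairs, drops self pairs, honors whitelists", {
  map <- gene_map(c("s1", "s2", "s2", "s3", "s4"),
                  c("G1", "G2", "G3", "G1", "G4"))
  t <- pair_score_table(c("s1", "s1", "s1"), c("s2", "s3", "s4"),
                        c(0.01, 0.02, 0.03), "p_raw")
  gp <- map_pairs_to_genes(t, map)
  keys <- pair_key(gp$gene_a, gp$gene_b)
  # s1-s2 -> (G1,G2),(G1,G3); s1-s3 -> G1xG1 self-pair dropped; s1-s4 -> (G1,G4)
  expect_setequal(keys, c("G1|G2", "G1|G3", "G1|G4"))
  wl <- gene_pair_whitelist("G1", "G2")
  fmap <- gene_map(map$snp_id, map$gene_id, "functional")
  expect_error(map_pairs_to_genes(t, fmap), "whitelist")
  gpf <- map_pairs_to_genes(t, fmap, wl)
  expect_equal(pair_key(gpf$gene_a, gpf$gene_b), "G1|G2")
})

test_that("min-p aggregation matches a brute-force group-by oracle", {
  gp <- map_pairs_to_genes(random_pair_table(n_snps = 10, n_pairs = 30, seed = 2),
                           gene_map(sprintf("s%02d", 1:10),
                                    rep(sprintf("G%d", 1:5), 2)))
  agg <- aggregate_min_p(gp)
  oracle <- tapply(gp$score, pair_key(gp$gene_a, gp$gene_b), min)
  expect_equal(length(agg$score), length(oracle))
  expect_equal(agg$score[match(names(oracle), pair_key(agg$gene_a, agg$gene_b))],
               as.numeric(oracle))
  # single contributor unchanged; explicit min example
  t <- structure(data.frame(gene_a = c("A", "A", "A"), gene_b = c("B", "B", "B"),
                            score = c(0.01, 0.001, 0.5),
                            snp_pair = c("x|y", "u|v", "w|z")),
                 semantics = "p_raw", class = c("gene_pair_table", "data.frame"))
  expect_equal(aggregate_min_p(t)$score, 0.001)
  wt <- random_pair_table(semantics = "weight", seed = 3)
  expect_error(aggregate_min_p(wt), "p-type")
})

test_that("theoretical thresholds reproduce the Bonferroni formulas", {
  expect_equal(threshold_positional(15354), 0.05 / 117864981)
  expect_equal(threshold_positional(2), 0.05)
  expect_equal(threshold_positional(3), 0.05 / 3)
  expect_equal(threshold_functional(18763), 0.05 / 18763)
  expect_equal(threshold_functional(1), 0.05)
  expect_equal(threshold_functional(50), 0.001)
  expect_error(threshold_positional(1), "at least 2")
  expect_error(threshold_functional(0), "at least 1")
})

test_that("binarization applies each tool-specific significance rule", {
  mk <- function(score, sem) {
    idx <- seq_along(score)
    structure(data.frame(gene_a = sprintf("A%d", idx),
                         gene_b = sprintf("B%d", idx), score = score),
              semantics = sem, class = c("gene_pair_table", "data.frame"))
  }
  # adjusted p: 0.05 cutoff
  s <- binarize(mk(c(0.01, 0.04999, 0.05, 0.9), "p_adjusted"))
  expect_equal(nrow(s$edges), 2)
  # raw p: explicit theoretical threshold required
  expect_error(binarize(mk(0.01, "p_raw")), "threshold")
  expect_equal(nrow(binarize(mk(c(1e-12, 1e-3), "p_raw"),
                             threshold = 1e-6)$edges), 1)
  # run count: at least 2 runs
  expect_equal(nrow(binarize(mk(c(1, 2, 10), "run_count"))$edges), 2)
  # weight: >= 0.7 * max, the max itself always passes
  expect_equal(nrow(binarize(mk(c(1.0, 0.71, 0.69), "weight"))$edges), 2)
  # mean: strength = 1/(1+mean) then 0.7 * max(strength)
  expect_equal(1 / (1 + 0), 1)
  expect_equal(1 / (1 + 1), 0.5)
  s <- binarize(mk(c(0, 0.4, 1.2), "mean"))   # strengths 1, .714, .455
  expect_equal(nrow(s$edges), 2)
  # empty table: empty SEN, no error
  expect_equal(nrow(binarize(mk(numeric(0), "p_adjusted"))$edges), 0)
})

test_that("binarization is monotone in its thresholds", {
  set.seed(8)
  t <- structure(data.frame(gene_a = sprintf("A%d", 1:50),
                            gene_b = sprintf("B%d", 1:50),
                            score = runif(50)),
                 semantics = "p_raw", class = c("gene_pair_table", "data.frame"))
  thresholds <- sort(runif(10))
  sizes <- vapply(thresholds,
                  function(th) nrow(binarize(t, threshold = th)$edges),
                  numeric(1))
  expect_true(!is.unsorted(sizes))  # lowering the threshold never adds edges
  wt <- structure(data.frame(gene_a = sprintf("A%d", 1:50),
                             gene_b = sprintf("B%d", 1:50),
                             score = runif(50)),
                  semantics = "weight", class = c("gene_pair_table", "data.frame"))
  sizes_w <- vapply(c(0.5, 0.7, 0.9, 1),
                    function(f) nrow(binarize(wt, frac = f)$edges), numeric(1))
  expect_true(!is.unsorted(rev(sizes_w)))
})

test_that("redundancy filter keeps greedily by ascending p", {
  t <- pair_score_table(c("A", "A", "D"), c("B", "C", "E"),
                        c(0.001, 0.01, 0.005), "p_raw")
  out <- antepiseeker_redundancy_filter(t)
  expect_setequal(pair_key(out$a, out$b), c("A|B", "D|E"))
  # disjoint pairs all kept
  t2 <- pair_score_table(c("A", "C"), c("B", "D"), c(0.5, 0.1), "p_raw")
  expect_equal(nrow(antepiseeker_redundancy_filter(t2)), 2)
  # tie on shared SNP: lexicographic winner kept
  t3 <- pair_score_table(c("A", "A"), c("C", "B"), c(0.01, 0.01), "p_raw")
  out3 <- antepiseeker_redundancy_filter(t3)
  expect_equal(pair_key(out3$a, out3$b), "A|B")
})

test_that("SNP-set expansion emits all within-set pairs at the region p", {
  out <- expand_casmap_sets(list(list(snps = c("s1", "s2", "s3"), p = 0.01)))
  expect_setequal(pair_key(out$a, out$b), c("s1|s2", "s1|s3", "s2|s3"))
  expect_true(all(out$score == 0.01))
  # shared pair takes the minimum region p
  out2 <- expand_casmap_sets(list(list(snps = c("s1", "s2"), p = 0.01),
                                  list(snps = c("s1", "s2", "s4"), p = 0.001)))
  expect_equal(out2$score[pair_key(out2$a, out2$b) == "s1|s2"], 0.001)
  expect_message(out3 <- expand_casmap_sets(list(list(snps = "s1", p = 0.1))),
                 "singleton")
  expect_equal(nrow(out3), 0)
})

test_that("SENs forbid self loops and deduplicate edges", {
  expect_error(sen("A", "A"), "self loops")
  s <- sen(c("A", "B", "B"), c("B", "A", "C"))
  expect_equal(nrow(s$edges), 2)
  expect_error(sen("A", "B", nodes = "A"), "outside")
})

test_that("the construction pipeline audits stages in the fixed order", {
  sim <- simulate_study(500, 20, n_chrom = 2, seed = 61)
  y <- sim$phenotype$phenotype
  t <- suppressMessages(allelic_regression_scan(sim$genotypes, y))
  ann <- simulate_gene_map(sim$genotypes$positions, n_genes = 8, seed = 61)
  built <- build_sen(t, genotypes = sim$genotypes,
                     snp_positions = sim$genotypes$positions,
                     map = ann$map,
                     threshold = threshold_positional(
                       length(unique(ann$map$gene_id))))
  expect_s3_class(built$sen, "sen")
  expect_equal(built$audit$stages,
               c("RawPairs", "HLA", "LD", "Mapping", "Self-interaction",
                 "Threshold"))
  cnt <- built$audit$counts
  # non-increasing except at the mapping expansion
  expect_true(all(diff(cnt[-4]) <= 0 | c(FALSE, FALSE, TRUE, FALSE)))
  expect_error(stage_audit(c(RawPairs = 5, HLA = 7)), "grew")
})
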