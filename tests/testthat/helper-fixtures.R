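# Shared fixture builders; all randomness goes through the supplied seed.

random_pair_table <- function(n_snps = 12, n_pairs = 20, semantics = "p_raw",
                              seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n_snps))
  cmb <- combn(ids, 2)
  take <- sample(ncol(cmb), n_pairs)
  score <- switch(semantics,
    weight = runif(n_pairs, 0, 2),
    run_count = sample(0:10, n_pairs, replace = TRUE),
    mean = runif(n_pairs, 0, 5),
    runif(n_pairs))
  pair_score_table(cmb[1, take], cmb[2, take], score, semantics)
}

random_sen <- function(genes, edge_prob = 0.3, seed = 1, descriptor = NULL) {
  set.seed(seed)
  cmb <- combn(genes, 2)
  keep <- runif(ncol(cmb)) < edge_prob
  sen(cmb[1, keep], cmb[2, keep], nodes = genes, descriptor = descriptor)
}

# Two groups of SENs with disjoint edge cores: each member keeps a core edge
# with probability `within` and picks up an edge of the *other* group's core
# with probability `between`.
planted_sen_groups <- function(n_per_group = 6, n_genes = 30,
                               within = 0.8, between = 0.1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  cmb <- combn(genes, 2)
  n_edges <- ncol(cmb)
  half <- seq_len(n_edges %/% 2)
  core1 <- intersect(which(runif(n_edges) < 0.6), half)
  core2 <- intersect(which(runif(n_edges) < 0.6), setdiff(seq_len(n_edges), half))
  make_group <- function(core, other, n) {
    lapply(seq_len(n), function(i) {
      keep <- c(core[runif(length(core)) < within],
                other[runif(length(other)) < between])
      sen(cmb[1, keep], cmb[2, keep], nodes = genes)
    })
  }
  list(group1 = make_group(core1, core2, n_per_group),
       group2 = make_group(core2, core1, n_per_group))
}

toy_positions <- function(ids, chrom = "chr1", start = 1e4, step = 1e4) {
  data.frame(snp_id = ids, chrom = chrom,
             pos = seq(start, by = step, length.out = length(ids)),
             stringsAsFactors = FALSE)
}
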