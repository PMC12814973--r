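#' Pairwise distance matrix between SENs
#'
#' Default metric is the Jaccard distance on edge sets,
#' `1 - |E_i n E_j| / |E_i u E_j|`, natural for binarized networks and
#' insensitive to the node universe, so networks of very different sizes
#' remain comparable. Two empty networks are at distance 0.
#'
#' @param sens list of [sen()] objects (>= 2).
#' @param metric currently `"jaccard_edge"`.
#' @return symmetric numeric matrix with zero diagonal, networks named by
#'   their descriptor tools, attribute `metric` set.
#' @export
network_distance_matrix <- function(sens, metric = "jaccard_edge") {
  metric <- match.arg(metric, "jaccard_edge")
  if (length(sens) < 2) stop("need at least 2 networks")
  nm <- vapply(seq_along(sens), function(i) {
    d <- sens[[i]]$descriptor
    if (!is.null(d)) paste0(d$tool, "_", d$mapping) else sprintf("sen%02d", i)
  }, "")
  nm <- make.unique(nm)
  edges <- lapply(sens, sen_edges)
  M <- length(sens)
  d <- matrix(0, M, M, dimnames = list(nm, nm))
  for (i in seq_len(M - 1)) for (j in seq(i + 1, M)) {
    u <- length(union(edges[[i]], edges[[j]]))
    dij <- if (u == 0) 0 else 1 - length(intersect(edges[[i]], edges[[j]])) / u
    d[i, j] <- dij; d[j, i] <- dij
  }
  structure(d, metric = metric)
}

# PERMANOVA-style pseudo-F for a 2-group labelling of a distance matrix:
# F = (SS_total - SS_within) / (g - 1) / (SS_within / (n - g)), with
# SS computed from squared distances (Gower).
#' @keywords internal
pseudo_f <- function(d, grp) {
  n <- nrow(d)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  g_n <- length(unique(grp))
  if (n - g_n <= 0 || ss_within <= .Machine$double.eps)
    return((ss_total - ss_within) * .Machine$double.xmax^0.25)
  ((ss_total - ss_within) / (g_n - 1)) / (ss_within / (n - g_n))
}

# Null distribution for the pseudo-F of a tree-derived split. The observed
# split is the average-linkage root split of the node's submatrix, i.e. a
# data-optimized bipartition, so comparing it against plain label
# permutations is anti-conservative. Under scheme "structural" each
# permutation shuffles the dissimilarity entries (preserving symmetry and
# the zero diagonal), rebuilds the tree and scores the permuted tree's own
# root split, so the null statistic is equally selection-optimized. Scheme
# "label" is the plain label permutation, kept for comparison.
#' @keywords internal
permutation_split_p <- function(d, grp, n_perm,
                                scheme = c("structural", "label")) {
  scheme <- match.arg(scheme)
  obs <- pseudo_f(d, grp)
  n <- length(grp)
  ut <- upper.tri(d)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    f <- if (scheme == "label") {
      pseudo_f(d, grp[sample.int(n)])
    } else {
      dp <- matrix(0, n, n)
      dp[ut] <- sample(d[ut])
      dp <- dp + t(dp)
      hc <- stats::hclust(stats::as.dist(dp), method = "average")
      root_grp <- stats::cutree(hc, k = 2)
      pseudo_f(dp, root_grp)
    }
    if (f >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_perm)
}

#' Cluster SENs by permutation-tested hierarchical splitting
#'
#' Builds an average-linkage tree on the network distance matrix, then walks
#' it top-down: at each candidate node the two-branch split is scored by a
#' PERMANOVA-style pseudo-F on the distances and compared against `n_perm`
#' permutations; the split is accepted when the permutation p-value
#' is below `alpha`, and the traversal recurses into accepted branches.
#' Because the tested split is itself tree-optimized, the default null
#' (`perm_scheme = "structural"`) shuffles the dissimilarity entries,
#' rebuilds the tree and scores the permuted tree's own root split, keeping
#' observed and null statistics equally selection-optimized; plain label
#' permutation (anti-conservative here) is available as `"label"`.
#' Tested p-values are Holm-corrected afterwards and splits losing
#' significance are pruned (with their descendants). Singleton clusters can
#' arise when a sibling branch splits off significantly. Nodes with fewer
#' than `2 * min_size` members are not tested further when both children
#' would fall below `min_size`; groups of fewer than 3 networks are never
#' tested.
#'
#' @param d distance matrix from [network_distance_matrix()].
#' @param alpha significance level for a split (default 0.05).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param min_size minimum child size for a tested split (default 1,
#'   allowing singletons).
#' @param holm apply Holm correction across the tested splits.
#' @param perm_scheme `"structural"` (default) or `"label"`; see Details.
#' @param seed integer seed; the procedure is deterministic given it.
#' @return object of class `cluster_result`: list with `assignment` (named
#'   integer cluster per network), `hclust` (the tree), `tests` (data.frame
#'   of tested splits: node size, pseudo-F, raw and Holm-adjusted p,
#'   accepted flag) and `parameters`.
#' @export
netanova_cluster <- function(d, alpha = 0.05, n_perm = 999, min_size = 1,
                             holm = TRUE, perm_scheme = c("structural", "label"),
                             seed = 1L) {
  perm_scheme <- match.arg(perm_scheme)
  if (n_perm < 99) stop("n_perm must be >= 99")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  n <- nrow(d)
  set.seed(seed)
  # members below each merge node
  members <- function(node) {
    if (node < 0) return(-node)
    unlist(lapply(hc$merge[node, ], members))
  }
  tests <- list()
  accepted_splits <- list()
  recurse <- function(node) {
    if (node < 0) return()
    left <- members(hc$merge[node, 1])
    right <- members(hc$merge[node, 2])
    all_m <- c(left, right)
    if (length(all_m) < 3) return()
    if (length(left) < min_size || length(right) < min_size) return()
    sub <- d[all_m, all_m, drop = FALSE]
    grp <- c(rep(1L, length(left)), rep(2L, length(right)))
    if (all(sub == 0)) return()   # indistinguishable networks: no test
    pv <- permutation_split_p(sub, grp, n_perm, scheme = perm_scheme)
    tests[[length(tests) + 1L]] <<- data.frame(
      node = node, n = length(all_m), n_left = length(left),
      n_right = length(right), pseudo_f = pseudo_f(sub, grp), p = pv,
      stringsAsFactors = FALSE)
    if (pv < alpha) {
      accepted_splits[[length(accepted_splits) + 1L]] <<- node
      recurse(hc$merge[node, 1])
      recurse(hc$merge[node, 2])
    }
  }
  recurse(nrow(hc$merge))
  tests_df <- if (length(tests)) do.call(rbind, tests) else
    data.frame(node = integer(), n = integer(), n_left = integer(),
               n_right = integer(), pseudo_f = numeric(), p = numeric())
  if (nrow(tests_df)) {
    tests_df$p_holm <- if (holm) stats::p.adjust(tests_df$p, "holm") else tests_df$p
    tests_df$accepted <- tests_df$node %in% unlist(accepted_splits) &
      tests_df$p_holm < alpha
    # pruning: a split only stands if every ancestor split stands
    anc_ok <- function(node) {
      parent <- which(hc$merge[, 1] == node | hc$merge[, 2] == node)
      if (!length(parent)) return(TRUE)
      row <- match(parent, tests_df$node)
      if (is.na(row) || !tests_df$accepted[row]) return(FALSE)
      anc_ok(parent)
    }
    tests_df$accepted <- tests_df$accepted &
      vapply(tests_df$node, anc_ok, logical(1))
  } else {
    tests_df$p_holm <- numeric(0)
    tests_df$accepted <- logical(0)
  }
  # derive the partition: cut at every accepted split
  assignment <- rep(1L, n)
  if (any(tests_df$accepted)) {
    for (node in tests_df$node[tests_df$accepted]) {
      left <- members(hc$merge[node, 1])
      # peel the left branch into a fresh cluster id
      assignment[left] <- max(assignment) + 1L
    }
    assignment <- match(assignment, unique(assignment))
  }
  names(assignment) <- rownames(d)
  structure(list(assignment = assignment, hclust = hc, tests = tests_df,
                 parameters = list(alpha = alpha, n_perm = n_perm,
                                   min_size = min_size, holm = holm,
                                   perm_scheme = perm_scheme, seed = seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("cluster_result: %d network(s) in %d cluster(s); %d split(s) tested\n",
              length(x$assignment), k, nrow(x$tests)))
  invisible(x)
}

#' Export a clustering dendrogram in Newick format
#'
#' @param result a [netanova_cluster()] result.
#' @param path output file.
#' @return `path`, invisibly; a sidecar `<path>.clusters.tsv` maps each
#'   network to its cluster id.
#' @export
write_dendrogram <- function(result, path) {
  phy <- ape::as.phylo(result$hclust)
  ape::write.tree(phy, file = path)
  utils::write.table(
    data.frame(network = names(result$assignment),
               cluster = result$assignment),
    paste0(path, ".clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize protocol properties within clusters
#'
#' Cross-tabulates each descriptor field (tool category, mapping strategy,
#' phenotype correction, exhaustive flag) against the cluster assignment —
#' the substrate for asking which protocol properties drive cluster
#' formation.
#'
#' @param result a [netanova_cluster()] result.
#' @param descriptors list of [protocol_descriptor()]s, one per network, in
#'   the order of the distance matrix.
#' @return data.frame (`cluster`, `field`, `value`, `count`, `fraction`).
#' @export
annotate_clusters <- function(result, descriptors) {
  if (length(descriptors) != length(result$assignment))
    stop("need one descriptor per network")
  if (any(vapply(descriptors, is.null, logical(1))))
    stop("missing descriptor")
  fields <- c("category", "mapping", "corrected", "exhaustive")
  rows <- list()
  for (cl in sort(unique(result$assignment))) {
    idx <- which(result$assignment == cl)
    for (f in fields) {
      vals <- vapply(descriptors[idx], function(d) as.character(d[[f]]), "")
      tab <- table(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, field = f, value = names(tab),
        count = as.integer(tab), fraction = as.numeric(tab) / length(idx),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
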