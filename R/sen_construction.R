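#' SNP-to-gene map
#'
#' Many-to-many assignment of SNPs to genes, with the mapping strategy
#' recorded (`"positional"` for boundary-plus-flank assignment,
#' `"functional"` for eQTL-style assignment restricted by a candidate
#' gene-pair whitelist).
#'
#' @param snp_id,gene_id character vectors (recycled to equal length).
#' @param strategy `"positional"` or `"functional"`.
#' @return a `gene_map`: data.frame (`snp_id`, `gene_id`) with attribute
#'   `strategy`; duplicate records rejected.
#' @export
gene_map <- function(snp_id, gene_id, strategy = c("positional", "functional")) {
  strategy <- match.arg(strategy)
  df <- data.frame(snp_id = as.character(snp_id),
                   gene_id = as.character(gene_id), stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("duplicate (snp, gene) records in gene map")
  structure(df, strategy = strategy, class = c("gene_map", "data.frame"))
}

#' Candidate gene-pair whitelist
#'
#' Unordered, unique gene pairs with prior evidence for interaction; used to
#' restrict functional-strategy gene pairs.
#'
#' @param gene_a,gene_b character vectors.
#' @return a `gene_pair_whitelist`: data.frame of canonical unordered pairs.
#' @export
gene_pair_whitelist <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) stop("whitelist must not contain self pairs")
  df <- data.frame(gene_a = pmin(gene_a, gene_b),
                   gene_b = pmax(gene_a, gene_b), stringsAsFactors = FALSE)
  df <- df[!duplicated(pair_key(df$gene_a, df$gene_b)), , drop = FALSE]
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gene_pair_whitelist", "data.frame"))
}

#' Positional SNP-to-gene assignment
#'
#' A SNP is assigned to every gene whose interval (1-based inclusive),
#' extended by `flank` base pairs on both sides, contains its position on
#' the same chromosome. Many-to-many by design: overlapping gene intervals
#' yield multiple assignments.
#'
#' @param snp_positions data.frame (`snp_id`, `chrom`, `pos`).
#' @param genes data.frame (`chrom`, `start`, `end`, `gene_id`), 1-based
#'   inclusive intervals.
#' @param flank flank in base pairs (default the 10 kb positional rule).
#' @return a [gene_map()] with strategy `"positional"`.
#' @export
map_snps_to_genes <- function(snp_positions, genes, flank = 10000) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- snp_positions$chrom == genes$chrom[i] &
      snp_positions$pos >= genes$start[i] - flank &
      snp_positions$pos <= genes$end[i] + flank
    if (!any(hit)) return(NULL)
    data.frame(snp_id = snp_positions$snp_id[hit], gene_id = genes$gene_id[i],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(snp_id = character(), gene_id = character(),
                                    stringsAsFactors = FALSE)
  gene_map(df$snp_id, df$gene_id, "positional")
}

#' Remove pairs with both SNPs in the HLA region
#'
#' A pair is rejected if and only if *both* its SNPs fall inside the region
#' (default chr6:25-34 Mb, 1-based inclusive bounds): main and interaction
#' effects are hard to separate there. One SNP inside does not trigger
#' removal.
#'
#' @param pairs a [pair_score_table()].
#' @param snp_positions data.frame (`snp_id`, `chrom`, `pos`) covering every
#'   SNP in `pairs`.
#' @param chrom,start,end the region (defaults chr6, 25e6, 34e6).
#' @return filtered [pair_score_table()].
#' @export
filter_hla <- function(pairs, snp_positions, chrom = "chr6",
                       start = 25e6, end = 34e6) {
  ids <- unique(c(pairs$a, pairs$b))
  missing <- setdiff(ids, snp_positions$snp_id)
  if (length(missing))
    stop("position unknown for SNP(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  inside <- snp_positions$chrom == chrom &
    snp_positions$pos >= start & snp_positions$pos <= end
  in_region <- snp_positions$snp_id[inside]
  drop <- pairs$a %in% in_region & pairs$b %in% in_region
  subset_pair_table(pairs, !drop)
}

#' @keywords internal
subset_pair_table <- function(pairs, keep) {
  out <- as.data.frame(pairs)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, semantics = attr(pairs, "semantics"),
            descriptor = attr(pairs, "descriptor"),
            class = c("pair_score_table", "data.frame"))
}

#' Remove SNP pairs in high linkage disequilibrium
#'
#' LD is measured as the squared Pearson correlation of the two 0/1/2
#' genotype columns on the analysis sample itself; a pair is removed iff
#' r-squared strictly exceeds `r2_max` (a pair at exactly the bound is
#' kept). Zero-variance columns get r-squared 0.
#'
#' @param pairs a [pair_score_table()].
#' @param genotypes a [simulate_genotypes()]-style object (or any list with
#'   a `values` matrix whose colnames cover the SNPs in `pairs`).
#' @param r2_max LD threshold (default 0.75).
#' @return filtered [pair_score_table()].
#' @export
filter_ld <- function(pairs, genotypes, r2_max = 0.75) {
  values <- genotypes$values
  missing <- setdiff(unique(c(pairs$a, pairs$b)), colnames(values))
  if (length(missing))
    stop("genotypes missing for SNP(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  r2 <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- values[, pairs$a[i]]; y <- values[, pairs$b[i]]
    if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
      return(0)
    stats::cor(x, y, use = "complete.obs")^2
  }, numeric(1))
  subset_pair_table(pairs, r2 <= r2_max)
}

#' Expand SNP pairs to gene pairs through a SNP-to-gene map
#'
#' Each SNP pair expands to every combination of the genes its two SNPs map
#' to. Self gene pairs are removed (within-gene epistasis needs special
#' treatment), and under the functional strategy gene pairs absent from the
#' whitelist are dropped. Contributing SNP pairs are recorded per gene pair.
#'
#' @param pairs a [pair_score_table()].
#' @param map a [gene_map()].
#' @param whitelist a [gene_pair_whitelist()]; required when the map strategy
#'   is `"functional"`.
#' @return a `gene_pair_table`: data.frame (`gene_a`, `gene_b`, `score`,
#'   `snp_pair`) with one row per (gene pair, contributing SNP pair),
#'   semantics inherited from `pairs`.
#' @export
map_pairs_to_genes <- function(pairs, map, whitelist = NULL) {
  strategy <- attr(map, "strategy")
  if (identical(strategy, "functional") && is.null(whitelist))
    stop("functional mapping requires a gene-pair whitelist")
  genes_of <- split(map$gene_id, map$snp_id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- genes_of[[pairs$a[i]]]; gb <- genes_of[[pairs$b[i]]]
    if (is.null(ga) || is.null(gb)) return(NULL)
    grid <- expand.grid(ga = ga, gb = gb, stringsAsFactors = FALSE)
    if (!nrow(grid)) return(NULL)
    data.frame(gene_a = pmin(grid$ga, grid$gb), gene_b = pmax(grid$ga, grid$gb),
               score = pairs$score[i],
               snp_pair = pair_key(pairs$a[i], pairs$b[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), snp_pair = character(),
                      stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("gene_a", "gene_b", "snp_pair")]), , drop = FALSE]
  n_with_self <- nrow(out)
  out <- out[out$gene_a != out$gene_b, , drop = FALSE]  # self-interactions out
  if (!is.null(whitelist)) {
    ok <- pair_key(out$gene_a, out$gene_b) %in%
      pair_key(whitelist$gene_a, whitelist$gene_b)
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, semantics = attr(pairs, "semantics"),
            descriptor = attr(pairs, "descriptor"),
            n_with_self = n_with_self,
            class = c("gene_pair_table", "data.frame"))
}

#' Aggregate SNP-pair p-values to gene-pair p-values by the minimum
#'
#' The gene-pair p-value is the minimum over the p-values of the SNP pairs
#' mapped to it.
#'
#' @param t a `gene_pair_table` with p-type semantics (see
#'   [map_pairs_to_genes()]).
#' @return a `gene_pair_table` with one record per gene pair; `snp_pair`
#'   lists the contributors comma-separated, `n_snp_pairs` counts them.
#' @export
aggregate_min_p <- function(t) {
  sem <- attr(t, "semantics")
  if (!sem %in% c("p_raw", "p_adjusted"))
    stop("min-p aggregation needs p-type scores; use the weight/run-count ",
         "rules in binarize() for '", sem, "' semantics")
  if (!nrow(t)) return(t)
  key <- pair_key(t$gene_a, t$gene_b)
  sp <- split(seq_len(nrow(t)), key)
  rows <- lapply(sp, function(idx) {
    data.frame(gene_a = t$gene_a[idx[1]], gene_b = t$gene_b[idx[1]],
               score = min(t$score[idx]),
               snp_pair = paste(sort(unique(t$snp_pair[idx])), collapse = ","),
               n_snp_pairs = length(unique(t$snp_pair[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, semantics = sem, descriptor = attr(t, "descriptor"),
            class = c("gene_pair_table", "data.frame"))
}

#' Theoretical significance threshold for the positional strategy
#'
#' Bonferroni over all gene pairs formable from the distinct genes in the
#' positional map: `0.05 / choose(n_genes, 2)`.
#'
#' @param n_genes number of distinct genes in the positional map (>= 2).
#' @return the threshold.
#' @export
threshold_positional <- function(n_genes) {
  if (n_genes < 2) stop("need at least 2 genes")
  0.05 / choose(n_genes, 2)
}

#' Theoretical significance threshold for the functional strategy
#'
#' Bonferroni over the candidate gene pairs: whitelisted pairs whose two
#' genes are both present in the functional map: `0.05 / n_candidate_pairs`.
#'
#' @param n_candidate_pairs number of candidate gene pairs (>= 1).
#' @return the threshold.
#' @export
threshold_functional <- function(n_candidate_pairs) {
  if (n_candidate_pairs < 1) stop("need at least 1 candidate gene pair")
  0.05 / n_candidate_pairs
}

#' Count candidate gene pairs for the functional threshold
#'
#' Whitelisted gene pairs with both genes present in the functional map.
#'
#' @param map a [gene_map()].
#' @param whitelist a [gene_pair_whitelist()].
#' @return integer count.
#' @export
count_candidate_pairs <- function(map, whitelist) {
  present <- unique(map$gene_id)
  sum(whitelist$gene_a %in% present & whitelist$gene_b %in% present)
}

#' Binarize a gene-pair table into a statistical epistasis network
#'
#' Tool-specific significance rules, keyed by the table's score semantics:
#' \describe{
#'   \item{p_adjusted}{edge iff adjusted p < 0.05}
#'   \item{p_raw}{edge iff p < `threshold` (a theoretical Bonferroni
#'     threshold, see [threshold_positional()] / [threshold_functional()])}
#'   \item{run_count}{edge iff the pair appeared in at least 2 runs}
#'   \item{weight}{edge iff weight >= 0.7 x max observed weight}
#'   \item{mean}{strength = 1 / (1 + mean); edge iff strength >= 0.7 x max
#'     observed strength}
#' }
#' The 0.7-max cutoffs use >= so the maximal element itself always passes;
#' the maxima are computed over the supplied (post-mapping) table.
#'
#' @param t a `gene_pair_table` (or [pair_score_table()] for SNP-level SENs).
#' @param threshold raw-p significance threshold; required for `p_raw`.
#' @param min_runs run-count rule cutoff (default 2).
#' @param frac weight/strength rule fraction (default 0.7).
#' @param nodes optional node universe; defaults to the genes in `t`.
#' @return a [sen()].
#' @export
binarize <- function(t, threshold = NULL, min_runs = 2, frac = 0.7,
                     nodes = NULL) {
  sem <- attr(t, "semantics")
  if (is.null(sem)) stop("table has no score semantics")
  acol <- if ("gene_a" %in% names(t)) "gene_a" else "a"
  bcol <- if ("gene_b" %in% names(t)) "gene_b" else "b"
  if (!nrow(t)) {
    return(sen(character(0), character(0),
               nodes = nodes %||% character(0),
               descriptor = attr(t, "descriptor")))
  }
  keep <- switch(sem,
    p_adjusted = t$score < 0.05,
    p_raw = {
      if (is.null(threshold))
        stop("raw p-values require an explicit theoretical threshold")
      t$score < threshold
    },
    run_count = t$score >= min_runs,
    weight = t$score >= frac * max(t$score),
    mean = {
      strength <- 1 / (1 + t$score)
      strength >= frac * max(strength)
    },
    stop("no binarization rule for semantics '", sem, "'"))
  sen(t[[acol]][keep], t[[bcol]][keep],
      nodes = nodes %||% sort(unique(c(t[[acol]], t[[bcol]]))),
      descriptor = attr(t, "descriptor"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Binary statistical epistasis network
#'
#' Undirected simple graph on gene (or SNP) identifiers: an edge marks a
#' significant interaction under some protocol. Self loops are forbidden and
#' edges are unordered-unique.
#'
#' @param a,b identifier vectors of edge endpoints.
#' @param nodes node universe (defaults to the endpoints); endpoints outside
#'   it are an error.
#' @param descriptor optional [protocol_descriptor()].
#' @return object of class `sen`: list with `nodes` (character), `edges`
#'   (data.frame `a`, `b`, canonical), `descriptor`.
#' @export
sen <- function(a, b, nodes = NULL, descriptor = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (any(a == b)) stop("self loops are not allowed")
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "|"))
  edges <- data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- if (is.null(nodes)) sort(unique(c(a, b))) else
    sort(unique(as.character(nodes)))
  if (!all(c(edges$a, edges$b) %in% nodes))
    stop("edge endpoints outside the node universe")
  structure(list(nodes = nodes, edges = edges, descriptor = descriptor),
            class = "sen")
}

#' @export
print.sen <- function(x, ...) {
  cat(sprintf("sen: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Canonical edge keys of a SEN
#' @param x a [sen()].
#' @return character vector of `"a|b"` keys.
#' @export
sen_edges <- function(x) pair_key(x$edges$a, x$edges$b)

#' Greedy redundancy filter on ranked SNP pairs
#'
#' Walks pairs by ascending p-value (ties broken lexicographically) and keeps
#' a pair only if neither of its SNPs already occurs in a kept pair with a
#' lower p-value — removing pairs that reuse a SNP already claimed by a
#' stronger pair, to curb gene-level false positives from hub SNPs.
#'
#' @param pairs a [pair_score_table()] with p-type semantics.
#' @return filtered [pair_score_table()].
#' @export
antepiseeker_redundancy_filter <- function(pairs) {
  sem <- attr(pairs, "semantics")
  if (!sem %in% c("p_raw", "p_adjusted"))
    stop("redundancy filter needs p-type scores")
  o <- order(pairs$score, pairs$a, pairs$b)
  seen <- character(0)
  keep <- logical(nrow(pairs))
  for (i in o) {
    if (!(pairs$a[i] %in% seen) && !(pairs$b[i] %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, pairs$a[i], pairs$b[i])
    }
  }
  subset_pair_table(pairs, keep)
}

#' Expand significant SNP sets to pairwise interactions
#'
#' Region-based search output (a set of SNPs with one region p-value) is
#' expanded so every unordered pair within a set carries the region's
#' p-value; a pair reached by several sets keeps the smallest p. Singleton
#' sets are skipped.
#'
#' @param sets list of `list(snps = <ids>, p = <region p>)`.
#' @param descriptor optional [protocol_descriptor()].
#' @return a [pair_score_table()] with `p_raw` semantics.
#' @export
expand_casmap_sets <- function(sets, descriptor = NULL) {
  best <- new.env(parent = emptyenv())
  for (s in sets) {
    snps <- unique(as.character(s$snps))
    if (length(snps) < 2) {
      message("skipping singleton SNP set")
      next
    }
    cmb <- utils::combn(sort(snps), 2)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "|")
      prev <- best[[key]]
      if (is.null(prev) || s$p < prev) best[[key]] <- s$p
    }
  }
  keys <- ls(best)
  if (!length(keys))
    return(pair_score_table(character(0), character(0), numeric(0),
                            "p_raw", descriptor))
  prs <- split_pair_key(keys)
  pair_score_table(prs$a, prs$b,
                   vapply(keys, function(k) best[[k]], numeric(1)),
                   "p_raw", descriptor)
}

#' Build a SEN from raw detector output through the full filter chain
#'
#' Applies the fixed pipeline order: raw pairs, HLA-region filter, LD filter,
#' SNP-to-gene mapping (with self-interaction removal), min-p aggregation
#' (for p-type scores) and the significance rule — and records the table
#' size after each stage in a stage audit.
#'
#' @param pairs a [pair_score_table()].
#' @param genotypes genotype panel for the LD filter (`NULL` to skip).
#' @param snp_positions SNP positions for the HLA filter (`NULL` to skip).
#' @param map a [gene_map()].
#' @param whitelist whitelist for functional maps.
#' @param threshold,min_runs,frac passed to [binarize()].
#' @param redundancy_filter apply [antepiseeker_redundancy_filter()] first.
#' @return list with `sen` (the [sen()]) and `audit` (a [stage_audit()]).
#' @export
build_sen <- function(pairs, genotypes = NULL, snp_positions = NULL,
                      map, whitelist = NULL, threshold = NULL,
                      min_runs = 2, frac = 0.7, redundancy_filter = FALSE) {
  counts <- c(RawPairs = nrow(pairs))
  if (redundancy_filter) pairs <- antepiseeker_redundancy_filter(pairs)
  if (!is.null(snp_positions)) pairs <- filter_hla(pairs, snp_positions)
  counts <- c(counts, HLA = nrow(pairs))
  if (!is.null(genotypes)) pairs <- filter_ld(pairs, genotypes)
  counts <- c(counts, LD = nrow(pairs))
  gp <- map_pairs_to_genes(pairs, map, whitelist)
  counts <- c(counts, Mapping = attr(gp, "n_with_self"),
              `Self-interaction` = nrow(gp))
  sem <- attr(gp, "semantics")
  if (sem %in% c("p_raw", "p_adjusted")) gp <- aggregate_min_p(gp)
  net <- binarize(gp, threshold = threshold, min_runs = min_runs, frac = frac)
  counts <- c(counts, Threshold = nrow(net$edges))
  list(sen = net, audit = stage_audit(counts))
}
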