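#' Stage audit of the SEN construction pipeline
#'
#' Ordered record counts through the fixed pipeline stages (RawPairs, HLA,
#' LD, Mapping, Self-interaction, Threshold). Counts must be non-increasing
#' from stage to stage except at Mapping, where the SNP-pair to gene-pair
#' expansion may grow the table.
#'
#' @param counts named numeric vector of per-stage record counts, in
#'   pipeline order.
#' @return object of class `stage_audit`.
#' @export
stage_audit <- function(counts) {
  stages <- names(counts)
  if (is.null(stages)) stop("counts must be named by stage")
  for (i in seq_along(counts)[-1]) {
    if (stages[i] == "Mapping") next
    if (counts[i] > counts[i - 1])
      stop(sprintf("stage %s grew the table (%d -> %d)",
                   stages[i], counts[i - 1], counts[i]))
  }
  structure(list(stages = stages, counts = unname(counts)),
            class = "stage_audit")
}

#' @export
print.stage_audit <- function(x, ...) {
  cat("stage audit:\n")
  for (i in seq_along(x$stages))
    cat(sprintf("  %-18s %d\n", x$stages[i], x$counts[i]))
  invisible(x)
}

#' @export
as.data.frame.stage_audit <- function(x, ...) {
  data.frame(stage = x$stages, count = x$counts, stringsAsFactors = FALSE)
}

#' Precision of a ranked list or network against the simulated truth
#'
#' For a ranked list, the fraction of the top-k entries that are true causal
#' pairs, `|top-k n truth| / k`. For a SEN, the fraction of its edges that
#' are true pairs.
#'
#' @param x a [pair_score_table()], [top_k()] list, or [sen()].
#' @param truth a non-empty [truth_set()].
#' @param k cutoff for ranked inputs (>= 1); ignored for SENs.
#' @return proportion in `[0, 1]`.
#' @export
precision_against_truth <- function(x, truth, k = NULL) {
  if (!nrow(truth)) stop("truth set is empty")
  tp <- truth_pairs(truth)
  if (inherits(x, "sen")) {
    e <- sen_edges(x)
    if (!length(e)) return(0)
    return(length(intersect(e, tp)) / length(e))
  }
  if (is.null(k) || k < 1) stop("k must be >= 1 for ranked inputs")
  lst <- if (inherits(x, "top_k_list")) utils::head(x, k) else top_k(x, k)
  length(intersect(pair_key(lst$a, lst$b), tp)) / k
}

#' Graph statistics of a SEN
#'
#' Node/edge counts, connected components with their sizes, per-node degree
#' and the hub set (nodes attaining the maximum degree). Isolated nodes in
#' the node universe count as singleton components.
#'
#' @param x a [sen()].
#' @return list with `n_nodes`, `n_edges`, `n_components`,
#'   `component_sizes` (decreasing), `degree` (named), `hubs`,
#'   `max_degree`.
#' @export
network_summary <- function(x) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = data.frame(name = x$nodes))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  md <- if (length(deg)) max(deg) else 0L
  list(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
       n_components = comp$no,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       degree = deg, hubs = names(deg)[deg == md & md > 0],
       max_degree = as.integer(md))
}

#' Write a SEN as an edge-list TSV (and optionally GML)
#'
#' @param x a [sen()].
#' @param path edge-list output path (TSV, columns `gene_a`, `gene_b`).
#'   Isolated nodes are preserved in a `<path>.nodes.tsv` sidecar.
#' @param gml optional path for a GML export.
#' @return `path`, invisibly.
#' @export
write_sen <- function(x, path, gml = NULL) {
  utils::write.table(data.frame(gene_a = x$edges$a, gene_b = x$edges$b),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(node = x$nodes), paste0(path, ".nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gml)) {
    g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                       vertices = data.frame(name = x$nodes))
    igraph::write_graph(g, gml, format = "gml")
  }
  invisible(path)
}

#' Read a SEN written by [write_sen()]
#' @param path edge-list path.
#' @param descriptor optional [protocol_descriptor()].
#' @return a [sen()].
#' @export
read_sen <- function(path, descriptor = NULL) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  nodes_path <- paste0(path, ".nodes.tsv")
  nodes <- if (file.exists(nodes_path))
    utils::read.table(nodes_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)$node
  else NULL
  sen(edges[[1]], edges[[2]], nodes = nodes, descriptor = descriptor)
}

#' Write a genotype panel to disk
#'
#' Tab-separated genotype matrix with a SNP-id header plus a BED-like
#' sidecar of 1-based SNP positions and a two-column phenotype table.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param phenotype optional phenotype data.frame (`sample_id`, `phenotype`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genotypes <- function(genotypes, phenotype = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(genotypes$values, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genotypes$positions, file.path(dir, "snp_positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(phenotype))
    utils::write.table(phenotype, file.path(dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Default demo pipeline configuration
#'
#' A desk-scale end-to-end configuration: simulate the study design at a
#' reduced size, run the three in-house detectors on binary and residualized
#' phenotypes, build positional SENs, compare top-k lists, cluster the SENs
#' and aggregate the largest cluster.
#'
#' @param n_individuals,n_snps simulation size.
#' @param k top-k list length for the comparison stage.
#' @param n_perm permutations for the clustering stage.
#' @param seed master seed.
#' @return config list understood by [run_pipeline()].
#' @export
demo_config <- function(n_individuals = 2000, n_snps = 60, k = 100,
                        n_perm = 199, seed = 1L) {
  list(n_individuals = n_individuals, n_snps = n_snps, k = k,
       n_perm = n_perm, seed = seed, n_genes = 20, flank = 2000,
       baseline = 0.02, alpha_marginal = 5, alpha_epistatic = 3)
}

#' @keywords internal
validate_config <- function(config) {
  required <- c("n_individuals", "n_snps", "k", "n_perm", "seed", "n_genes",
                "flank", "baseline", "alpha_marginal", "alpha_epistatic")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  invisible(config)
}

#' Run the demonstration pipeline end to end
#'
#' Simulate genotypes and phenotypes under the study design, run the three
#' in-house detectors (allelic regression on binary and residualized
#' phenotypes, the genotype 4-df scan, the correlation-difference scan),
#' build positional gene-level SENs through the filter chain, compare top-k
#' lists (co-occurrence, Canberra, Jaccard, recurrent pairs), cluster the
#' SENs and aggregate them (union / intersection / majority / LCA).
#' Deterministic given the config seed. If `out_dir` is given, all artifacts
#' are written beneath it.
#'
#' @param config a config list, see [demo_config()]; or a path to a YAML
#'   file holding one.
#' @param out_dir optional artifact directory.
#' @return list with `data` (simulation), `tables` (detector outputs),
#'   `sens`, `audits`, `comparison` (matrices + recurrent pairs),
#'   `clustering`, `aggregation`, `evaluation` (precision per detector).
#' @export
run_pipeline <- function(config = demo_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- config$seed
  sim <- simulate_study(n_individuals = config$n_individuals,
                        n_snps = config$n_snps,
                        alpha_marginal = config$alpha_marginal,
                        alpha_epistatic = config$alpha_epistatic,
                        baseline = config$baseline, seed = seed)
  y <- sim$phenotype$phenotype
  pcs <- matrix(stats::rnorm(length(y)), ncol = 1)  # stand-in covariate
  yres <- residualize_phenotype(y, pcs)
  keep <- qc_variants(sim$genotypes,
                      keep_list = sim$genotypes$snp_ids[sim$causal_idx])
  gq <- sim$genotypes
  gq$values <- gq$values[, keep, drop = FALSE]
  gq$snp_ids <- colnames(gq$values)
  gq$positions <- gq$positions[gq$positions$snp_id %in% gq$snp_ids, ]
  desc <- function(tool, corrected = FALSE, exhaustive = TRUE,
                   category = "Statistic")
    protocol_descriptor(tool, category = category, mapping = "positional",
                        corrected = corrected, exhaustive = exhaustive)
  tables <- list(
    allelic_binary = allelic_regression_scan(gq, y,
      descriptor = desc("allelic_binary")),
    allelic_resid = allelic_regression_scan(gq, yres,
      descriptor = desc("allelic_resid", corrected = TRUE)),
    genotype_chi2 = genotype_chi2_scan(gq, y,
      descriptor = desc("genotype_chi2")),
    cor_diff = correlation_difference_scan(gq, y,
      descriptor = desc("cor_diff", exhaustive = FALSE)))
  ann <- simulate_gene_map(gq$positions, n_genes = config$n_genes,
                           flank = config$flank, seed = seed)
  thr <- threshold_positional(length(unique(ann$map$gene_id)))
  built <- lapply(tables, function(t)
    build_sen(t, genotypes = gq, snp_positions = gq$positions,
              map = ann$map, threshold = thr))
  sens <- lapply(built, `[[`, "sen")
  audits <- lapply(built, `[[`, "audit")
  lists <- lapply(tables, top_k, k = config$k)
  comparison <- list(cooccurrence = cooccurrence_matrix(lists),
                     canberra = canberra_resemblance(lists, k = config$k),
                     jaccard = jaccard_matrix(lists),
                     recurrent = recurrent_pairs(lists))
  d <- network_distance_matrix(sens)
  clustering <- netanova_cluster(d, n_perm = config$n_perm, seed = seed)
  biggest <- as.integer(names(which.max(table(clustering$assignment))))
  members <- which(clustering$assignment == biggest)
  aggregation <- NULL
  if (length(members) >= 2) {
    em <- build_edge_matrix(sens[members])
    n_patterns <- nrow(unique(as.data.frame(em)))
    lca <- suppressWarnings(lca_fit(em, n_classes = min(2, n_patterns),
                                    seed = seed))
    aggregation <- list(edge_matrix = em,
                        union = aggregate_simple(em, "union"),
                        intersection = aggregate_simple(em, "intersection"),
                        majority = aggregate_simple(em, "majority"),
                        lca_model = lca,
                        lca = lca_summary_network(lca, em))
  }
  evaluation <- data.frame(
    protocol = names(tables),
    precision_top15 = vapply(tables, precision_against_truth,
                             numeric(1), truth = sim$truth, k = 15))
  rownames(evaluation) <- NULL
  out <- list(data = sim, tables = tables, sens = sens, audits = audits,
              comparison = comparison, clustering = clustering,
              aggregation = aggregation, evaluation = evaluation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      write_pair_table(tables[[nm]], file.path(out_dir, paste0(nm, ".epi")))
    for (nm in names(sens))
      write_sen(sens[[nm]], file.path(out_dir, paste0(nm, "_sen.tsv")))
    for (nm in names(comparison)[1:3])
      write_similarity_matrix(comparison[[nm]],
                              file.path(out_dir, paste0(nm, ".tsv")))
    utils::write.table(comparison$recurrent,
                       file.path(out_dir, "recurrent_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_dendrogram(clustering, file.path(out_dir, "dendrogram.nwk"))
    if (!is.null(aggregation))
      for (nm in c("union", "intersection", "majority", "lca"))
        write_sen(aggregation[[nm]],
                  file.path(out_dir, paste0("aggregate_", nm, ".tsv")))
    utils::write.table(evaluation, file.path(out_dir, "precision.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    audit_df <- do.call(rbind, lapply(names(audits), function(nm)
      cbind(protocol = nm, as.data.frame(audits[[nm]]))))
    utils::write.table(audit_df, file.path(out_dir, "stage_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
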