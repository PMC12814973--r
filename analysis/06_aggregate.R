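#!/usr/bin/env Rscript
# Step 6 — aggregate the largest homogeneous cluster and evaluate.
#
# Builds the edge-by-network indicator matrix for the largest cluster,
# aggregates it by union, intersection, majority vote and latent-class link
# prediction (class count chosen by BIC up to 3), summarizes each consensus
# network, and scores every protocol's precision against the simulated
# truth. Writes everything under results/aggregate/.

library(senkit)

seed <- 2026
out <- "results/aggregate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

files <- list.files("results/sens", pattern = "_sen\\.tsv$", full.names = TRUE)
sens <- lapply(files, read_sen)
names(sens) <- sub("_sen\\.tsv$", "", basename(files))

assign_tab <- read.table("results/cluster/assignment.tsv", header = TRUE,
                         sep = "\t")
biggest <- names(which.max(table(assign_tab$cluster)))
members <- which(assign_tab$cluster == as.integer(biggest))
cat(sprintf("aggregating cluster %s with %d SENs\n", biggest,
            length(members)))

if (length(members) >= 2) {
  em <- build_edge_matrix(sens[members])
  sel <- select_n_classes(em, c_max = min(3, nrow(unique(as.data.frame(em)))),
                          n_restarts = 5, seed = seed)
  cat("BIC table:\n"); print(sel$bic_table)
  lca <- sel$models[[as.character(sel$n_classes)]]
  nets <- list(union = aggregate_simple(em, "union"),
               intersection = aggregate_simple(em, "intersection"),
               majority = aggregate_simple(em, "majority"),
               lca = lca_summary_network(lca, em))
  for (nm in names(nets)) {
    write_sen(nets[[nm]], file.path(out, paste0(nm, ".tsv")))
    ns <- network_summary(nets[[nm]])
    cat(sprintf("%-13s %3d edges, %2d components, largest %d, hubs: %s\n",
                nm, ns$n_edges, ns$n_components,
                if (length(ns$component_sizes)) max(ns$component_sizes) else 0,
                paste(ns$hubs, collapse = ",")))
  }
}

# SNP-level evaluation: fraction of each protocol's top 15 ranked pairs
# that are planted causal pairs
truth <- as_truth_set(read.table("results/data/truth_pairs.tsv",
                                 header = TRUE, sep = "\t"))
epi <- list.files("results/detect", pattern = "\\.epi$", full.names = TRUE)
prec <- data.frame(
  protocol = sub("\\.epi$", "", basename(epi)),
  precision_top15 = vapply(epi, function(f)
    precision_against_truth(read_pair_table(f, "p_raw"), truth, k = 15),
    numeric(1)))
write.table(prec, file.path(out, "precision.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top-15 precision against the simulated truth:\n")
print(prec, row.names = FALSE)
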