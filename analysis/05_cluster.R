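#!/usr/bin/env Rscript
# Step 5 — cluster the SENs into homogeneous groups.
#
# Reads the step-3 SENs, computes the Jaccard edge-set distance matrix,
# runs the permutation-tested hierarchical clustering and annotates the
# clusters with protocol properties. Writes the assignment, split tests and
# Newick dendrogram under results/cluster/.

library(senkit)

seed <- 2026
out <- "results/cluster"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

files <- list.files("results/sens", pattern = "_sen\\.tsv$", full.names = TRUE)
descs <- lapply(files, function(f)
  protocol_descriptor(sub("_sen\\.tsv$", "", basename(f)),
                      corrected = grepl("resid", f),
                      exhaustive = !grepl("cor_diff", f)))
sens <- Map(read_sen, files, descs)

d <- network_distance_matrix(sens)
res <- netanova_cluster(d, alpha = 0.05, n_perm = 999, seed = seed)
print(res)
print(res$tests)

write.table(data.frame(network = names(res$assignment),
                       cluster = res$assignment),
            file.path(out, "assignment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(res$tests, file.path(out, "split_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_dendrogram(res, file.path(out, "dendrogram.nwk"))
write.table(annotate_clusters(res, unname(descs)),
            file.path(out, "cluster_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d cluster(s) over %d SENs\n",
            length(unique(res$assignment)), length(sens)))
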