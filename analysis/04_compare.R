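#!/usr/bin/env Rscript
# Step 4 — protocol-level comparison of ranked outputs.
#
# Reads the step-2 .epi tables, takes each protocol's top-100 SNP-pair list
# and computes the three similarity views: co-occurrence counts, Canberra
# rank resemblance, and Jaccard similarity — plus the recurrent-pair tally.
# Writes the matrices under results/compare/.

library(senkit)

out <- "results/compare"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
k <- 100

files <- list.files("results/detect", pattern = "\\.epi$", full.names = TRUE)
lists <- lapply(files, function(f) {
  nm <- sub("\\.epi$", "", basename(f))
  top_k(read_pair_table(f, "p_raw", descriptor = protocol_descriptor(nm)), k)
})

co <- cooccurrence_matrix(lists)
cb <- canberra_resemblance(lists, k = k)
jc <- jaccard_matrix(lists)
rec <- recurrent_pairs(lists)

write_similarity_matrix(co, file.path(out, "cooccurrence.tsv"))
write_similarity_matrix(cb, file.path(out, "canberra.tsv"))
write_similarity_matrix(jc, file.path(out, "jaccard.tsv"))
write.table(rec, file.path(out, "recurrent_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("shared pairs in top", k, "lists:\n")
print(co)
cat(sprintf("most similar pair of protocols: J = %.2f\n",
            max(jc[upper.tri(jc)])))
cat(sprintf("%d pairs recur in at least 2 protocols; top recurrence = %d\n",
            sum(rec$n_lists >= 2), max(rec$n_lists)))
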