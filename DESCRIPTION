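Package: senkit
Title: Construction, Comparison and Aggregation of Statistical Epistasis Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for characterizing and reducing heterogeneity across
    epistasis-detection protocols. Builds gene-level statistical epistasis
    networks (SENs) from ranked SNP-pair outputs via quality-control filters,
    SNP-to-gene mapping and tool-specific significance rules; compares
    protocols through co-occurrence counts, Canberra rank resemblance and
    Jaccard similarity of top-k lists; clusters SENs with a permutation-tested
    hierarchical procedure; and aggregates homogeneous clusters into consensus
    networks by union, intersection, majority vote or latent class analysis.
    Includes a penetrance-model simulator of epistatic genotype-phenotype data
    and lightweight in-house epistasis scanners so the full pipeline runs
    without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
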