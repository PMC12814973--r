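---
title: "Methods: comparing, clustering and aggregating statistical epistasis networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing, clustering and aggregating statistical epistasis networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senkit)
```

## The problem

Genome-wide association interaction studies (GWAIS) search for pairs of
genetic loci whose joint effect on a phenotype exceeds their additive
contributions. Many detection tools exist, differing in test statistic,
search strategy, phenotype handling and multiple-testing treatment, and
their ranked outputs overlap only partially. A *statistical epistasis
network* (SEN) — a graph whose nodes are genes and whose edges mark
significant interactions under one protocol — gives these heterogeneous
outputs a common representation, so that protocols can be compared,
clustered into homogeneous groups, and the groups summarized into consensus
networks. senkit implements that workflow end to end, together with a
penetrance-model simulator and three in-house scanners so every stage runs
without external tools or restricted data.

## The simulator

`simulate_genotypes()` draws per-SNP minor allele frequencies uniformly
(background SNPs from (0.05, 0.5), causal SNPs from (0.1, 0.3)) and samples
0/1/2 genotypes as Binomial(2, MAF), i.e. Hardy–Weinberg proportions in
linkage equilibrium. Positions are laid on synthetic chromosomes at fixed
spacing so the positional gene mapping and region filters have coordinates
to work with. We deliberately simulate linkage-equilibrium genotypes: a
population-specific LD structure would require an external haplotype
corpus, and none of the quantities checked here depend on LD beyond the
pair filter, which is exercised with explicitly constructed correlated
columns. Passing tests therefore say nothing about behavior under realistic
LD, admixture or genotyping error.

`simulate_phenotypes()` composes per-model multiplicative risk factors on a
baseline probability $\beta$:

| model            | factor                                  |
|------------------|-----------------------------------------|
| marginal         | $1 + \alpha g/2$                        |
| joint dominant   | $1+\alpha$ if both loci carry $\geq 1$ alternate allele |
| joint recessive  | $1+\alpha$ if both loci are homozygous alternate |
| multiplicative   | $(1+\alpha)^{g_1 g_2/4}$                |
| exponential      | $\exp(\alpha g_1 g_2/4)$                |
| triplet          | $1+\alpha$ if all three loci carry $\geq 1$ alternate allele |

The study design (`study_design()`) uses two marginal SNPs at
$\alpha = 5$ and five epistatic models at $\alpha = 3$ — joint-dominant,
exponential, multiplicative and joint-recessive pairs plus a triplet that
shares one locus with the joint-recessive pair — so ten distinct loci carry
epistatic effects and the truth set holds $4 + \binom{3}{2} = 7$ causal
pairs. The $\alpha$ values are labels of effect strength in this
parametrization, not calibrated penetrances.

**Baseline and clamping.** Multiplying factors of this size stacks quickly:
an individual hitting the joint-dominant effect ($\times 4$) and both
marginal effects ($\times 3.5$ each) multiplies the baseline by 49. At any
baseline large enough to yield cases, a tail of multi-hit individuals
exceeds probability 1. We set the study baseline to $\beta = 0.02$
(cohort prevalence ≈ 0.11–0.15) and read individuals whose risk product
passes 1 as fully penetrant, clamping at $1-10^{-6}$. The study wrapper
budgets 10% of individuals for clamping — above the configuration's
worst case over causal-MAF draws (~8%) — while `simulate_phenotypes()`
itself defaults to a strict 1% budget, so a user combining strong effects
with a high baseline is warned that the probabilities saturate. The
clamped tail slightly compresses the largest effects; detectability
ordering is unaffected.

`simulate_protocol_outputs()` generates ranked protocol outputs with a
controllable pairwise top-$k$ overlap: a shared core of
$\mathrm{round}(\mathrm{overlap}\cdot k)$ pairs plus independent uniform
samples, so at overlap 0 the expected intersection is the hypergeometric
$k^2/\binom{|U|}{2}$. Causal pairs are inserted near the top with
probability $1-\mathrm{noise}$ per protocol.

## Detectors

Three scanners cover the main methodological families, all returning
unordered-pair-unique tables sorted by ascending p (ties broken
lexicographically):

* **Allelic regression** — logistic (binary trait) or ordinary least
  squares (residualized trait) on additive codings $g_1, g_2$ and their
  product; the score is the 1-df likelihood-ratio (or F) p-value of the
  product term. For binary traits the fit collapses onto the
  $3\times3$ genotype table, which is likelihood-equivalent to the
  individual-level fit and makes an exhaustive scan cheap.
* **Genotype 4-df scan** — likelihood-ratio test of the saturated logistic
  model on the $3\times3$ table against the two-factor main-effects model.
  The $\chi^2_4$ approximation fails when genotype cells are nearly empty
  (it is visibly anti-conservative at desk scale), so a locus's
  homozygous-alternate class is merged into its heterozygous class whenever
  its marginal count falls below $\lceil\sqrt{2n}\rceil$; this keeps every
  expected cell above 1 under a balanced null, and the test df shrinks
  accordingly. After collapsing, measured type-I error sits within
  $\pm 3\,\mathrm{SE}$ of 0.05 across seeds, and planted-pair power is
  unchanged.
* **Correlation difference** — Fisher-z comparison of the Pearson
  correlation of genotype codings between cases and controls,
  $z = (\mathrm{atanh}\,r_{\text{ca}} - \mathrm{atanh}\,r_{\text{co}})/
  \sqrt{1/(n_{\text{ca}}-3) + 1/(n_{\text{co}}-3)}$; chosen for its
  closed-form p-value and vectorized evaluation.

Phenotype residualization (`residualize_phenotype()`) regresses the binary
trait on covariates by logistic regression and returns response residuals;
this is what lets covariate-free detectors operate on
population-structure-corrected phenotypes. Variant QC drops SNPs with
MAF < 5% or Hardy–Weinberg goodness-of-fit p < 0.001. The QC wording we
implement is the standard convention — variants are removed when they
*violate* Hardy–Weinberg equilibrium — with a keep-list override for known
risk variants.

## SEN construction

The pipeline order is fixed and audited: raw pairs → HLA filter → LD
filter → gene mapping (with self-interaction removal) → min-p aggregation →
significance rule. Choices worth stating:

* HLA filter removes a pair only when *both* SNPs lie in chr6:25–34 Mb,
  with inclusive bounds at both ends.
* LD is the squared Pearson correlation of genotype columns on the analysis
  sample itself; removal needs $r^2 > 0.75$ strictly, so a pair at exactly
  the bound survives.
* Positional mapping assigns a SNP to every gene interval extended by
  ±10 kb (1-based, inclusive); mapping is many-to-many, and gene pairs are
  canonical unordered pairs. Functional-strategy gene pairs must also
  appear in the candidate whitelist.
* Gene-pair p-values are minima over contributing SNP-pair p-values.
  Theoretical thresholds are Bonferroni: $0.05/\binom{G}{2}$ over the
  positional gene count, $0.05/|U|$ over the functional candidate pairs.
* Binarization rules by score semantics: adjusted p < 0.05; raw p below the
  theoretical threshold; run count ≥ 2; weight ≥ 0.7·max; for mean-type
  scores, strength $= 1/(1+\mathrm{mean})$ then the same 0.7·max rule. The
  0.7·max cutoffs use ≥ (the maximal element always passes) and the
  maxima are taken over the post-mapping table.
* The redundancy filter for region-seeded searches is formalized as a
  greedy walk by ascending p: a pair is kept only if neither SNP is already
  claimed by a kept pair; ties break lexicographically.

## Comparing protocols

Top-$k$ lists (default $k$ mirrors the customary 1000; shorter tables are
used whole) are compared three ways: shared-pair counts, Jaccard
similarity, and a Canberra distance on rank vectors built over the union of
the two lists, with absent pairs ranked $k+1$. The Canberra construction
for partially overlapping lists is a convention we fixed (rank-vector over
union, absent = $k+1$, positional ranks by default with average ranks
within tied scores as an option for tools that emit many tied p-values);
it weighs disagreements near the top of the lists most.

## Clustering SENs

Networks are compared by Jaccard distance on edge sets over the union node
universe, which keeps networks of very different sizes comparable. The
clustering is a permutation-tested top-down traversal of an average-linkage
tree. At each node the two-branch split is scored by a PERMANOVA-style
pseudo-F computed from the distances. Because that split is the tree's own
best bipartition, comparing it against plain label permutations is
anti-conservative — we measured threefold type-I inflation. The default
null therefore re-optimizes under permutation: each iteration shuffles the
dissimilarity entries, rebuilds the tree and scores the permuted tree's
root split. With this scheme the empirical false-split rate over
homogeneous collections is at or below nominal, and two groups of networks
built from disjoint edge cores (80% within-group edge retention, 10%
cross-contamination) are recovered exactly. Tested splits are
Holm-corrected and splits losing significance are pruned together with
their descendants; a singleton can become a cluster when its sibling branch
splits off significantly. This procedure is a declared stand-in for
published network-ANOVA clustering, not a re-implementation of it.

## Aggregating a homogeneous cluster

The cluster's edge-by-network indicator matrix (rows = union edge set)
feeds four aggregators. Union, intersection and majority (strictly more
than half; exact ties excluded by default) obey
intersection ⊆ majority ⊆ union by construction, which the tests verify by
exhaustive enumeration of row patterns. Latent class analysis fits a
mixture of independent Bernoulli products by EM — classes are groups of
edges with a shared reporting profile across networks. Defaults: two
classes (a consistently-reported class and an idiosyncratic one), BIC
selection as an override, ten random restarts, convergence at
$10^{-8}$ absolute log-likelihood change, $\theta$ clamped to
$[10^{-6}, 1-10^{-6}]$. The summary network takes the class with the
highest mean reporting probability as the signal class (ties broken toward
the larger prevalence) and keeps edges whose posterior for that class
exceeds 0.5. Candidate edges are the union of cluster edges; all-zero
indicator rows carry no information under this likelihood and cannot occur
in matrices built from networks.

## Problem sizes

The shipped analysis scripts and tests run at desk scale, chosen so the
full suite completes in minutes while keeping every statistical property
measurable: cohorts of 400–10 000 individuals; panels of 14–120 SNPs
(the power checks use 10 000 × 30 over 20 seeded replicates); null
calibration on 2016 pairs; clustering calibration over 40 homogeneous and
20 planted-partition replicates; LCA recovery on 500-row matrices over 20
replicates. All generators, scans and permutation procedures are
bit-reproducible under their seed arguments.

## Known limitations

* Linkage-equilibrium genotypes; no admixture, relatedness or missingness
  structure beyond a uniform missing rate.
* The effect-size parametrization is monotone and interpretable but not a
  reproduction of any external simulator's internal risk model.
* The clustering stand-in fixes distance, linkage and testing scheme by
  declared choices; other reasonable choices (complete linkage, weighted
  distances, label permutations) are configurable but not defaults.
* Gene-level evaluation against a SNP-level truth set requires a mapping
  convention; the analysis scripts evaluate precision at the SNP level
  where the truth is defined.
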