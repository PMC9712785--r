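---
title: "Methods: circRNA-centred ceRNA network construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA-centred ceRNA network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spongenet)
```

This vignette documents the statistical model, the analysis procedure,
and the design decisions behind `spongenet`. It is the reference for
*why* each default is what it is; the function reference documents the
*how*.

## The ceRNA model

A competing endogenous RNA (ceRNA) relationship is a triple
(circRNA, miRNA, mRNA) in which both the circRNA and the mRNA carry
binding sites for the same miRNA. When the circRNA is abundant it
sequesters ("sponges") the miRNA, so less miRNA is available to repress
the mRNA. The observable signature in a two-group expression study is
direction consistency: if the miRNA goes up, its sponged targets should
go down, and vice versa. `spongenet` operationalises the model as three
layers — differential screening, interaction prediction, and network
assembly with direction filters — each testable in isolation.

## Differential screening

`screening_rule()` defaults to `min_abs_log2fc = 1` and `max_p = 0.05`:
a feature passes when |log2 fold change| ≥ 1 **and** p < 0.05. Two
boundary conventions are fixed and tested: the fold-change comparison is
inclusive (a feature at exactly one log2 unit, i.e. a doubling or
halving, passes) while the p-value comparison is strict. Fold-change
thresholds in this literature are quoted on the log2 scale, so the
threshold of 1 means a two-fold change. P-values are raw by default
because small-cohort screens are typically reported unadjusted;
`adjust = "BH"` switches to Benjamini–Hochberg within the screened
table.

When only count matrices are available, `de_from_counts()` supplies a
transparent stand-in for a full count-model fit: the fold change is
`log2((mean(case) + c)/(mean(control) + c))` with pseudocount
`c = 0.5`, and the p-value is a pooled-variance Student's t-test on
`log2(count + c)`. Pooling is deliberate: the generator (and the
balanced designs this package targets) draws both groups under a shared
dispersion model, and at `n = 3` per group the pooled test keeps its
`2n − 2` degrees of freedom where Welch's approximation becomes
unstable and loses power. A dedicated count-model package is the right
tool for production differential expression; this test exists so the
pipeline is self-contained, explainable, and exactly reproducible.

circRNA abundance is quantified on back-splice-junction (BSJ) reads,
the only reads unique to the circular form:
`rpkm_bsj(bsj, len, total) = bsj * 1e9 / (len * total)`.

## Seed-match target prediction

`find_seed_sites()` implements canonical seed pairing on a 0-based,
antiparallel geometry: the 6mer core is the reverse complement of miRNA
positions 2–7; a 7mer-m8 adds Watson–Crick pairing of miRNA position 8
immediately upstream of the core on the target; a 7mer-A1 adds an
adenosine opposite miRNA position 1; an 8mer has both. Site scores
weight these classes 1/2/3/4 (6mer/7mer-A1/7mer-m8/8mer) — the ordering
follows the well-established site-efficacy hierarchy — plus one point
per Watson–Crick pair of miRNA positions 13–16 against the
3′-supplementary region. For circRNA targets, `circular = TRUE` scans
the sequence extended by its own first six bases so junction-spanning
sites are found, with coordinates wrapped modulo the length.

`predict_interactions()` emulates the common practice of intersecting
or unioning several prediction tools by running two *internally
independent* criteria — a site-count source (`min_sites`, default 1)
and a score source (`min_score`, default 3, the 7mer-m8 weight) — and
combining them. The default policy is **intersection for miRNA→mRNA**
edges (targeting claims should be conservative, mirroring the
overlap-of-databases convention) and **union for circRNA→miRNA** edges
(sponge discovery favours sensitivity). Both are parameters; neither
threshold has an external calibration, which is stated rather than
hidden.

## Sponge network and hub selection

Networks are undirected igraph graphs with `rna_class` and `direction`
vertex attributes. `restrict_to_de()` keeps only differentially
expressed miRNAs (the intersection step of a DE-restricted network);
circRNA nodes are retained even if isolated, and the count of newly
isolated circRNAs is reported.

`add_centralities()` computes degree, betweenness with the
`2/((n−1)(n−2))` pair normalisation, and Wasserman–Faust closeness:
for a node reaching `r` others at total distance `d`,
`closeness = (r/(n−1)) · (r/d)`, with isolated nodes scoring 0. The
Wasserman–Faust form is chosen because sponge networks are routinely
disconnected, and it degrades gracefully on fragments instead of being
undefined. Both measures are verified in the test suite against a
brute-force oracle that counts shortest paths via adjacency-matrix
powers.

`select_key_mirnas()` implements the median-multiple rule: a miRNA is
"key" when its degree is **strictly greater than** `multiplier` (default
3) times the **median degree of the miRNA nodes**. The median is taken
over miRNA nodes only because in a bipartite sponge graph the circRNA
degree distribution would otherwise dominate the reference point;
`scope = "all"` restores the all-node median for sensitivity analyses.

`rank_hub_circrnas()` ranks circRNA nodes by the mean of their
betweenness rank and closeness rank (ascending), breaking ties by
higher degree and then lexicographic id so results are total-ordered
and reproducible; the default `k = 5` reflects the typical size of a
reported hub panel.

## ceRNA triads

`assemble_triads()` forms all (circRNA, miRNA, mRNA) combinations along
hub sponge edges and the miRNA→mRNA map, and annotates two flags:
`circ_mirna_opposite` and `mirna_mrna_opposite`. By default only the
mRNA flag is **required** — the sponge hypothesis predicts
miRNA-opposite movement of the mRNA — while circRNA–miRNA opposition is
recorded but not enforced, because published sponge tables legitimately
retain same-direction circRNA–miRNA pairs (competing regulation can
mask the transcriptional response of the circRNA itself).
`require_opposite_circ = TRUE` applies the stricter filter.

## Enrichment and qPCR

`run_ora()` is the upper-tail hypergeometric test
`P(X ≥ k)` for `k` annotated genes among `n` query genes, `K` term
members, universe `N`, with BH adjustment **within each namespace**
(BP, MF, CC and pathway collections are separate testing families). The
universe defaults to the union of annotation members, the most
conservative choice that needs no external gene catalogue.

`delta_delta_ct()` computes `dCT = CT_gene − CT_ref` per sample,
calibrates against the mean control dCT, and reports `2^−ddCT`. With
this calibrator the control group's ddCT average is identically zero,
so the geometric mean of control folds is exactly 1 — an invariant the
tests check exactly, not approximately. Group comparison uses an
equal-variance t-test on folds (or on dCT), matching how validation
panels are usually analysed.

## The synthetic generator

`sim_config()` defaults encode the study conditions the package
emulates: 3 animals per group; 40 circRNAs, 60 miRNAs, 150 mRNAs;
negative-binomial counts with mean 500, dispersion 0.1
(`var = μ + φμ²`; `φ = 0` gives the Poisson limit) and log-normal
per-feature baseline jitter of 1 on the log2 scale; 8/10/16 planted
differential features per class at |log2FC| = 2; and 4 planted triads
whose directions are (circRNA down, miRNA up, mRNA down) or the mirror
image with equal probability. One seed drives a single RNG stream
through counts, sequences and CT values, so a whole dataset is
reproducible from one integer.

`simulate_sequences()` plants, for each triad, the exact reverse
complement of miRNA positions 2–8 (a site of at least 7mer-m8 class,
which both prediction sources detect at the default thresholds) into
the triad's circRNA and mRNA. Background realism is bounded
deliberately: miRNA seed windows (positions 2–7 and 3–8) are drawn
globally unique — otherwise one miRNA's planted site would be an
unremovable chance match for another — and remaining chance seed-core
matches of non-planted pairs are resampled until none are left, so the
planted interactions are provably the only ones present. The generator
therefore supports exact recovery statements (sensitivity, precision,
triad recall in `benchmark_recovery()`) but does **not** model GC
content, conservation, expression-sequence coupling, or secondary
structure; conclusions about those do not transfer.

`simulate_ct_table()` offsets target CTs from each sample's reference
CT so the expected `2^−ddCT` equals the planted fold; with
`noise_sd = 0` the planted fold is recovered exactly.

## Numerical and reproducibility choices

- All screening and triad operations are order-preserving and
  permutation-invariant; hub ranking is a total order.
- `run_pipeline()` writes a manifest containing the package version,
  seed and a configuration hash but no timestamp, so identical runs are
  byte-identical — a property the tests assert file by file.
- Problem sizes (tens to hundreds of features, networks of a few
  hundred nodes) are this package's own envelope, chosen so every
  property test and the 50-seed recovery benchmark run on one CPU in
  minutes; nothing in the implementation limits larger inputs, but
  performance beyond that envelope is untested.
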