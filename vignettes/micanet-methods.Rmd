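---
title: "Inferring small-sample gene regulatory networks with chromatin-accessibility refinement"
author: "micanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring small-sample gene regulatory networks with chromatin-accessibility refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micanet)
```

## The problem

Cell-type-specific gene regulatory networks (GRNs) — directed graphs of
transcription factor (TF) to target-gene regulations — are usually inferred
from co-expression across many cells. In systems such as the human
preimplantation blastocyst only a few tens of cells per lineage (epiblast,
primitive endoderm, trophectoderm) are available, so inference operates far
below the sample sizes where co-expression methods are reliable, and a large
fraction of predicted edges are indirect or unstable. `micanet` implements a
pipeline built for exactly this regime: pairwise or regression-based
co-expression inference whose edge universe is *refined by a
chromatin-accessibility (CA) prior* — the set of TF-to-gene pairs supported
by a TF-binding motif inside open chromatin near the gene's transcription
start site (TSS). The flagship combination, mutual information refined by
chromatin accessibility, is the MICA method (`grn_infer(..., method = "mi",
prior = ...)`).

Everything the package claims is exercised on synthetic data with known
ground truth; no restricted-access embryo data are required or shipped.

## The inference engines

All five engines share one contract: given a genes-by-samples matrix and a
regulator list, emit a score for every ordered (TF, gene) pair with the
source in the regulator list (self-pairs excluded). Because all methods emit
this same universe before any thresholding, their outputs can be
intersected, differenced and compared on a single denominator.

**Spearman** — score is the absolute Spearman rank correlation; two-sided
p-values by the t approximation. Rank-based, hence invariant to monotone
per-gene transforms.

**Mutual information with an empirical-CDF null (the MICA core)** — each
gene is discretized into `ceiling(sqrt(n))` equal-frequency bins and the
maximum-likelihood plug-in MI (bits) is computed for every pair. For a pair
(x, y) with MI value M, the statistic

z² = Φ⁻¹(F̂(M | x))² + Φ⁻¹(F̂(M | y))²

combines the smoothed ranks (rank − ½)/(G − 1) of M within all MI values
involving x and within all involving y. Pairs that dominate both of their
partners' MI distributions get large z². p-values use the upper χ²₂ tail
(the only distribution consistent with a *sum of two squared probits*; a
one-sided normal reading of z = √(z²/2) is available behind
`null = "normal"`), q-values are Benjamini–Hochberg, and the retained set is
q < 0.05. The edge score is −log₁₀ p.

*Calibration caveat (important, and deliberately documented rather than
patched):* on fully independent data the two probit terms are not
independent — both are ranks of the *same* M value in ensembles that share
one null distribution (equal-frequency binning gives every gene identical
margins), so they correlate near +1 and z² behaves like 2·χ²₁ rather than
χ²₂. Consequences: (i) the z²-ranking of edges is unaffected, which is what
selection uses; (ii) tail p-values are mis-calibrated in absolute terms, and
a Kolmogorov–Smirnov test of z² against χ²₂ on null data rejects by design
of the statistic; (iii) because smoothed ranks are bounded, the smallest
attainable p on a G-gene universe is P(χ²₂ > 2·Φ⁻¹(1 − ½/(G−1))²), so on
small universes the BH gate at 5% can retain nothing — evaluation metrics
therefore rank by score over the full universe rather than relying on the
retained set.

**GENIE3-style random forests** — per target gene, a random-forest
regression of the target on all other regulators (response scaled to unit
variance); a regulator's importance is its forest-averaged total variance
reduction. The pooled, genome-wide importance distribution is thresholded at
its 10th percentile ("pooled" rather than per-target is the package's
reading; a per-target variant would be a trivial wrapper). The forest is
compiled code using R's RNG, so runs are reproducible under a seed. Tree
count trades accuracy for time; benchmark runs here use 100–1000 trees and
scale the count down, never the grid, when a time budget applies.

**L0L2 best-subset regression** — per target, minimise

½‖y − a − Xb‖² + γ·#{j : bⱼ ≠ 0} + λ‖b‖²

over the candidate regulators, which the CA prior restricts *before* fitting
(this is where regression differs from the pairwise methods: the prior
shapes the model, not just the output). The solver is cyclic coordinate
descent with hard thresholding: coordinate j enters at value c/(s + 2λ) iff
its objective gain c²/(2(s + 2λ)) exceeds γ. Because each exact coordinate
update is non-increasing in the objective, the stopping rule is a relative
objective stall (coefficient-wise stopping can cycle under a hard
threshold). The γ path runs geometrically down from just above the first
entry point, so the empty model is always on the path; (γ, λ) are chosen by
K-fold cross-validated MSE with ties resolved toward the sparser, more
ridge-penalised model. The edge score is |b| of the selected support;
non-converged targets are skipped and reported, and only a fully failed run
errors.

**Random baseline** — a uniformly random strict ranking of the universe; the
null reference every Δ metric subtracts.

## The chromatin-accessibility prior

`build_prior()` turns a motif-hit table (BED-style, 0-based half-open, TF in
the name column) and a TSS table into the network of all *possible*
regulations. Each hit is represented by its interval midpoint (footprints
are short; the midpoint is symmetric and deterministic), assigned to the
nearest same-chromosome TSS (absolute distance, ties to the
lexicographically smaller gene), and kept iff its strand-aware signed
distance — negative upstream of the TSS in the gene's reading direction —
lies within [−5 kb, +10 kb] by default, the promoter-proximal band seen in
blastocyst accessibility data. The bounds are configurable; the source data
motivating them describe *most* distances in that range, so a hard window is
an approximation the package makes explicit. A region carrying motifs of
several TFs yields one pair per TF. Mirror-image coordinates with flipped
strands produce the identical prior (tested), and enlarging the window never
removes pairs.

Refinement is exact set intersection for the pairwise methods
(`refine_with_prior()`, the "+CA" suffix) and candidate restriction for
L0L2. The final network keeps the top 100,000 edges by score
(`select_top_edges()`), ties broken lexicographically so reruns are
identical.

## The synthetic world

The generator states one world and the tests live in it:

* **Ground truths** are DAGs over p genes at ordered-pair edge density
  ρ = 0.07 (the density estimated from accessibility data in the motivating
  study). A uniformly random topological order is fixed and each
  order-respecting pair enters with probability 2ρ, making the expected
  density over *all* ordered pairs equal ρ (attainable for ρ ≤ 0.5).
* **Expression** follows the linear structural-equation model: in
  topological order, xⱼ = Σ b·x_parent + e. The weight and noise laws are
  unstated in the source, so the package fixes |b| ~ Uniform(0.5, 1.5) with
  random sign and e ~ N(0, 1), intercept 0 — unit-scale, sign-balanced
  signal against unit noise — and does not revisit them.
* **Priors** for benchmarking include each true edge with probability
  `sensitivity` and each non-edge with probability `false_edge_rate`.
* **Gene sets** are either uniform draws or hub neighbourhoods (hub plus its
  targets), the latter enrichable by construction.

`run_simulation_study()` sweeps p × n × method with AUROC against the ground
truth over all ordered pairs (Mann–Whitney with tie correction; an
`undirected` flag gives credit for reversed edges, off by default so that
correlation and regression methods share one denominator). Within a
replicate the n grid uses *nested subsamples* of one simulated matrix: the
across-n comparison is paired, which sharply reduces the Monte-Carlo
variance of sample-size contrasts; marginal distributions are unchanged.
Replicate counts (100 in the reference world) are scaled down for desk runs
— stated wherever done.

What the generator does **not** emulate: count noise, dropout, library-size
variation, batch structure, nonlinear regulation, feedback loops (the
ground truth is acyclic by construction). A green simulation test therefore
establishes correctness of the machinery and qualitative ordering of
methods under linear-Gaussian data, not performance on real single-cell
counts. Two known consequences of the linear-SEM world are visible in the
results: regression and forest methods select Markov-blanket neighbours
(including a target's own children), capping directed AUROC well below 1,
and pairwise methods saturate with n once population rankings stabilise —
accuracy beyond n ≈ 100 improves only marginally.

## Evaluation metrics

* **Bootstrap reproducibility R** — the bootstrap estimate of the posterior
  probability of an edge given the data is operationalised as selection
  frequency: B cell-resamples (with replacement), the full
  inference + refinement + top-k pipeline on each, R(edge) = fraction of
  resample networks containing the edge, reported for the full-data top-k.
  ΔR subtracts the random predictor's median. The random baseline's median R
  is k/N by construction — a tested anchor.
* **Split-half cross-validation** — repeated random halving; the top 1% of
  all possible interactions from one half is the reference set, the other
  half's scores over the same universe are the predictions, agreement is
  average precision (step-wise AP); both fold orders averaged. A random
  ranking scores at the prevalence (= top fraction).
* **Normalised L2 loss** — ‖s_A − s_B‖₂ divided by the product of the square
  roots of the two L2 norms, with the squared-numerator reading behind a
  flag. As implemented, the default statistic is scale-invariant (the scale
  cancels between numerator and denominator); the squared variant scales
  linearly. The inverse is floored at a configurable ε.
* **Lineage set algebra** — EPI-specific = (EPI∖PE)∖TE and cyclically, the
  common network the three-way intersection; the four derived sets plus
  pairwise-only intersections tile each lineage network exactly (tested).
* **Marker activity** — a marker TF's out-degree divided by the gene count
  of the network, flagged active when at least the median over the pooled
  (marker × network) cells. One deliberate deviation from the printed rule:
  a marker with zero out-degree is never active, because "no detectable
  network" cannot satisfy an activity criterion even when the pooled median
  is itself 0. Median pooling across the run is the default; per-marker
  pooling is a flag, since the source is ambiguous about the pooling scope.
* **V-statistic** — among the 25 most-connected TFs (out-degree, ties by
  summed score then label) keep the 500 best-scoring regulations; the query
  is the union of their sources and targets (targets-only behind a flag);
  V counts gene sets with one-sided hypergeometric p < 0.1 against the
  declared universe. No multiplicity correction, by design: the aggregate
  count at a permissive α is the statistic. V is normalised by the maximum
  across the compared methods per cell type.

## Numerical choices and degenerate inputs

Natural log for normalization transforms (base only rescales; ranks are
unaffected — note that Spearman results *do* differ between TPM and
FPKM/log-counts on the same counts, because TPM's per-sample factor is not
the library size; FPKM and log-counts are rank-identical). Zero-variance
genes: score 0 / p 1 for Spearman, zero MI, zero forest importance, empty
L0L2 support. Equal-frequency binning uses first-occurrence rank ties, so
seeded runs are bit-reproducible. Edge ordering everywhere is score
descending, then TF, then gene. Bootstrap resamples that fail inference are
dropped and counted; more than half failing aborts. All randomness flows
through R's RNG (including compiled code), so a single seed reproduces any
run end to end.

## A worked miniature

```{r example, eval = FALSE}
dag <- random_dag(50, 0.07, seed = 1)
g <- sem_grn(dag, seed = 1)
x <- simulate(g, n = 200, seed = 2)
prior <- synth_prior(dag, sensitivity = 1, false_edge_rate = 0.05, seed = 3)

mica <- grn_infer(x, rownames(x), method = "mi", prior = prior)
net <- select_top_edges(mica, k = 200)
auroc(mica, dag)

cv <- split_half_cv(x, rownames(x), "mi", prior = prior, seed = 4)
rnd <- split_half_cv(x, rownames(x), "random", seed = 4)
delta_auprc(cv, rnd)
```

## Known limitations

The hard TSS window ignores long-range enhancers; the accessibility prior is
not cell-type-resolved when the underlying assay pools lineages; the MI
p-values are rank-faithful but not tail-calibrated (see above); L0L2
inherits the Markov-blanket ambiguity of all regression-on-expression
methods; and the simulator's linear-Gaussian world understates the
difficulty of real single-cell data. These are properties of the method
family, surfaced here so that green tests are read for what they establish.
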