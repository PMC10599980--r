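# micanet

Gene regulatory network (GRN) inference for *small* single-cell expression
datasets, refined by chromatin accessibility. The package exists for the
regime where only tens of cells per cell type are available — the situation
in human preimplantation embryos, where the three blastocyst lineages
(epiblast, primitive endoderm, trophectoderm) contribute 26–45 cells each —
and co-expression inference alone is barely better than random. Restricting
predicted transcription-factor (TF) → gene edges to pairs supported by a
TF-binding motif in open chromatin near the gene's transcription start site
(TSS) makes the surviving network markedly more reproducible. The flagship
method, **MICA**, is mutual-information inference with an empirical-CDF null,
intersected with that chromatin-accessibility (CA) prior.

## What is inside

* **One fitting interface.** `grn_infer(expr, regulators, method, prior)`
  returns a classed `grn_fit` (with `print`, `summary`, `coef`, `plot`
  methods) for five engines that all score the same TF × gene edge universe:

  | method | score | notes |
  |---|---|---|
  | `mi` | −log₁₀ p | plug-in MI, equal-frequency bins; z² = Φ⁻¹(F̂(M\|x))² + Φ⁻¹(F̂(M\|y))², χ²₂ p-values, BH FDR 5% gate |
  | `spearman` | \|ρ\| | rank correlation, t-approximation p |
  | `genie3` | importance | random-forest variance reduction, pooled 10th-percentile threshold (compiled, seeded) |
  | `l0l2` | \|b\| | best-subset regression, ψ = γ·Σ I(\|bⱼ\|>0) + λ·Σ bⱼ², CV-selected (γ, λ); the prior restricts candidates before fitting |
  | `random` | rank | the null baseline every Δ metric subtracts |

* **CA prior construction.** `build_prior()` assigns accessible motif hits to
  the nearest TSS with strand-aware signed distances and a hard
  [−5 kb, +10 kb] window; `refine_with_prior()` intersects an edge list with
  the prior ("+CA"); `select_top_edges()` cuts the final network at the
  top 100,000 edges.
* **A ground-truth simulator.** `random_dag()` (edge density ρ = 0.07 over
  ordered pairs), `sem_grn()` + `simulate()` (linear structural-equation
  expression, x_j = Σ b·x_parent + e), `synth_prior()`, `synth_genesets()`,
  and `run_simulation_study()` for the AUROC-vs-sample-size benchmark grid.
* **Evaluation.** Bootstrap edge reproducibility R and ΔR,
  repeated split-half cross-validation with top-1% reference sets and
  AUPRC, the normalised L2 loss, lineage set algebra
  ((EPI∖PE)∖TE etc.), marker out-degree activity, hypergeometric gene-set
  enrichment and the V-statistic, and hub-centred TF subnetworks with
  Spearman correlation classes (`build_hub_network()`, GraphML/TSV export).
* **Orchestration.** `run_pipeline()` drives
  load → normalize → restrict → infer → refine → select → evaluate from an R
  list or JSON config and writes a provenance manifest.

## A worked example

Fifty genes, ground-truth density 0.07, 200 cells, a perfect-sensitivity
prior with a 5% false-edge rate:

```r
library(micanet)
dag   <- random_dag(50, 0.07, seed = 1)
x     <- simulate(sem_grn(dag, seed = 1), n = 200, seed = 2)
prior <- synth_prior(dag, sensitivity = 1, false_edge_rate = 0.05, seed = 3)

mica <- grn_infer(x, rownames(x), method = "mi", prior = prior)
mica
#> GRN fit (mi+CA): 50 TFs x 50 genes, 281 scored edges, 0 retained
#>   expression units: sem-raw

select_top_edges(mica, k = 200)
#> GRN (mi+CA, CA-refined): 200 edges (k = 200)

cv  <- split_half_cv(x, rownames(x), "mi", prior = prior, seed = 4)
rnd <- split_half_cv(x, rownames(x), "random", seed = 4)
cv
#> Split-half CV (mi): median AUPRC = 0.4753, median 1/L2 = 1.419 over 10 repeats (0 failed)
rnd
#> Split-half CV (random): median AUPRC = 0.0114, median 1/L2 = 1.403 over 10 repeats (0 failed)
delta_auprc(cv, rnd)
#> [1] 0.4639
```

Read: the 281 scored edges are the CA-supported pairs (171 true edges plus
the prior's false positives); half-split networks inferred by MI+CA agree
with each other's top 1% at AUPRC ≈ 0.48 versus ≈ 0.01 — the top-fraction
prevalence — for a random ranking, so the ΔAUPRC of ≈ 0.46 is the
reproducibility gain over chance. The `0 retained` flag is expected at this
scale: with 50 genes the bounded smoothed ranks floor the attainable MI
p-value above the BH 5% gate, so selection is score-driven (see the methods
vignette for why, and for the tail-calibration caveat of the z² statistic).
Unrefined MI scores the full 2,450-pair universe at AUROC ≈ 0.62 against the
ground truth on this dataset.

## The acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's benchmark computation from scratch against the
installed package: a scaled simulation study (AUROC of all five methods
across n = 10/100/1000 and p = 10/50), a full MICA pipeline run on a
synthetic 50-gene, 500-cell dataset with an oracle-sensitivity prior, and
the ΔAUPRC / ΔR comparison of MICA against the random predictor, then
writes the machine-readable report to `--out`.

## Layout

```
R/            implementation (simulator, I/O, prior, engines, evaluation,
              hubs, pipeline)
src/          Rcpp kernels: random-forest importance, L0L2 coordinate descent
tests/        testthat suite incl. test-acceptance.R
scripts/      acceptance.R
vignettes/    methods vignette (model, assumptions, choices, limitations)
```
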