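---
title: "Models and methods behind coexmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coexmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coexmod` analyzes a three-condition proteomics experiment — normoxia
(19% O₂), hypoxia (1% O₂), and hypoxia with cyclosporine A — from a
summed-reporter protein abundance table to differential proteins,
treatment-restored proteins, a permutation-thresholded co-expression
network, edge-betweenness modules with a reversal test, and a comparison
with a curated knowledge network. This vignette records the models, the
defaults and why they are set where they are, and the numerical decisions
a reader would otherwise have to reverse-engineer from the code.

## The abundance model and preprocessing

The pipeline starts at a proteins × samples table of non-negative raw
abundances (for TMT data, summed reporter-ion intensities). Two filters
define the analysis universe:

* **Low-abundance filter** (`min_count = 1`): a protein is kept only if
  every sample reaches one count. We read "per experiment/replicate" as
  per sample; a mean-based alternative is available via `per_sample =
  FALSE`. This guarantees strictly positive values, so `log2` is safe.
* **Coefficient-of-variation filter** (`min_cv = 0.01`), applied before
  network construction only: CV = population sd / mean across **all**
  samples, computed on **raw** abundances. CV on the log scale is not
  scale-free, and the filter's purpose is to remove proteins whose
  near-constant profiles make correlations meaningless; a flag switches
  the scale for sensitivity analysis. The population (denominator *n*) sd
  is immaterial at a 0.01 threshold but is fixed for reproducibility.

All inference happens on `log2` abundances; per-sample Shapiro–Wilk
statistics and QQ plots (`qq_normality_check()`) are advisory diagnostics
and never filter anything.

## Moderated t-statistics

Each protein is fit as a one-way layout: the coefficient for condition
*c* is the mean log2 abundance of its replicates, and the residual
variance `s²_g` is pooled across conditions with `d_g = N − k` degrees of
freedom. With three replicates per condition, `d_g = 6` — too few for
stable per-protein variances — so variances are shrunk toward an ensemble
prior with the standard empirical-Bayes machinery: assuming
`s²_g | σ²_g ~ σ²_g χ²_{d_g}/d_g` with a scaled inverse-χ² prior
`σ²_g ~ d₀ s₀² / χ²_{d₀}`, the marginal distribution of `log s²_g` is a
log scaled-F whose mean and variance are matched via digamma/trigamma
functions. The trigamma equation is inverted by Newton iteration
(tolerance 1e-8, ≤ 100 iterations). When the observed variances are no
more dispersed than χ² sampling noise the equation has no positive
solution; then `d₀ = ∞` and the posterior variance is the ensemble mean
`mean(s²_g)` for every protein. Posterior variances are

```
s̃²_g = (d₀ s₀² + d_g s²_g) / (d₀ + d_g),
```

always between `s²_g` and `s₀²`. The contrast statistic is
`t̃ = log2FC / sqrt(s̃²_g (1/n_A + 1/n_B))` on `d₀ + d_g` df (normal when
`d₀ = ∞`). The test suite verifies this machinery against `limma` to
1e-10 and, with moderation disabled (`skip = TRUE`, `d₀ = 0`), against the
classical pooled-variance t-test.

Orientation: contrast "A_vs_B" is `mean(A) − mean(B)`, so positive
`O19_vs_O1` values mean higher abundance at 19% O₂.

**Differential rule**: `p ≤ 0.01` and `|log2FC| ≥ 0.5`, on **raw**
p-values. No multiplicity adjustment gates the call — the operating point
is a fixed dual threshold — but BH-adjusted p-values are reported in every
output table. **Restored** proteins are differential in `O19_vs_O1` and in
`O1_vs_O1CyA` but not in `O19_vs_O1CyA`: the drug returns the hypoxic
abundance to its normoxic level.

## The co-expression network

Edges are weighted by the absolute Pearson correlation `w = |r|` between
log2 profiles of CV-passing proteins. Each edge receives a z-score from a
permutation null: in each of `n_perm = 50` iterations, every protein's
values are permuted across samples **independently**, and all pairwise
`|r|` are recomputed; `z = (w_obs − mean_perm)/sd_perm` with the sample
(n−1) sd. A single shared permutation of the sample labels would leave
every correlation unchanged, so independent per-row permutation — which
breaks inter-protein association while preserving each marginal — is the
only operative reading. The permutation stream is seeded from the
mandatory pipeline seed; an unseeded run is an error.

Edges survive iff `|z| ≥ 1.5` **and** `w > 0.5` (strict: a weight of
exactly 0.5 is removed). Network nodes are the endpoints of surviving
edges; isolated proteins drop out.

**A calibration caveat worth stating plainly.** With nine samples the
null distribution of `|r|` is wide (`sd(r) ≈ 0.35`), and a per-edge
z-score compares an observation against the same null the permutations
sample — so under independence roughly 13% of pairs have `|z| ≥ 1.5` and
about 10% survive the joint filter. These thresholds therefore do *not*
control the false-edge rate at the percent level; they are the analysis's
operating point, kept as given. Consequences: synthetic networks at these
settings carry a substantial background of spurious edges, and module
recovery (below) must work against that background. The dense pair
computation is done with full matrices: at ~4000 proteins the three
accumulator matrices occupy ≈ 370 MB, well within a desktop budget at the
scales the package targets.

## Community detection and the reversal test

Girvan–Newman: repeatedly delete the edge with maximal betweenness,
recomputed after every deletion (restricted, for speed, to the component
the last deletion touched — betweenness elsewhere is unchanged). Ties
break by canonical (lexicographic) edge order, making the procedure fully
deterministic. Across the deletion sequence the connected-component
partition maximizing Newman–Girvan modularity *Q* on the **original,
unweighted** graph is returned; the first maximum wins ties. The graph is
treated as unweighted because weights-as-distances and
weights-as-strengths conventions pull in opposite directions and neither
is clearly the right reading; the compiled Brandes implementation is
tested against exhaustive path enumeration (≤ 8 nodes) and against
`igraph` on larger graphs. Modules with ≥ 10 members (ids assigned by
decreasing size) proceed to enrichment and the reversal test.

**Reversal test**: per protein, the replicate-paired log2 fold change
(replicate *i* of A minus replicate *i* of B, median over replicates) is
computed for `O19_vs_O1` and `O19_vs_O1CyA`; within a module the two
profiles are compared by a two-tailed **paired** t-test across proteins
(the same proteins appear in both contrasts), flagging at `p ≤ 0.05`. An
unpaired Welch alternative is exposed via `paired = FALSE`, which is also
the escape hatch when paired differences are exactly constant. Note the
test treats module members as exchangeable; proteins sharing a latent
factor violate independence, which inflates the flag rate on modules with
strong shared structure — visible in the synthetic benchmarks, where
unshifted high-loading modules are sometimes flagged alongside the
planted one.

## Enrichment

Over-representation uses the inclusive upper hypergeometric tail
`P(X ≥ k)` (the one-sided Fisher convention; verified against
`fisher.test` over all 2×2 tables with `N ≤ 30`). The default universe is
the quantified proteins intersected with the union of collection members;
sets are size-filtered to 3–500 members within the universe (standard
guard rails — the analysis defines none). Gene symbols are uppercased on
both sides; protein identifiers stay case-sensitive elsewhere.

## The synthetic generator

`generate_synthetic()` draws, on the log2 scale,

```
x_gs = μ_g + effect(g, condition(s)) + ρ_m f_m(s) + ε_gs
```

with `μ_g ~ N(μ₀ = 20, τ = 2)` (typical of log2 summed TMT intensities),
noise `ε ~ N(0, σ = 0.25)`, and a per-sample standard-normal latent
factor `f_m` shared within module *m*, giving expected within-module
correlation `ρ²/(ρ² + σ²)` (≈ 0.93 at the default `ρ = 0.9`). Differential
proteins carry `±δ = ±1.2` at both 1% O₂ conditions; restored proteins at
1% O₂ only; one module may carry an O1-only shift (default 1.2 on the
first module) so the reversal test has a planted positive. Low-abundance
proteins are shifted so their minimum sample falls below one count;
low-CV proteins get noise sd 0.003 (raw CV ≈ 0.002). Defaults — 5000
proteins, 3 × 3 design, 40 DE, 10 restored, three modules of 30 —
describe the emulated study's scale and effect regime. A named-stream RNG
(separate sub-seeds for baselines, effects, factors, noise) derives from
the single mandatory seed.

What the generator does **not** emulate: peptide-level roll-up, missing
values, TMT ratio compression, channel/batch effects, and
abundance-dependent variance. Passing benchmarks therefore demonstrate
the statistical machinery under the stated model, not robustness to those
real-data features.

Members of a module with a planted shift are labelled `module_restored`
rather than `restored`: their shared latent factor inflates per-protein
residual variance (σ² + ρ² ≈ 0.87), so individual restored classification
is not expected for them, and they are excluded from both the null set of
the false-positive accounting and the individually-restored recall.

## Benchmark problem sizes

The acceptance script and test suite run the differential/restored
benchmarks at the full default scale (5000 proteins) and null calibration
on 5000 independent proteins. Module recovery runs on a reduced-background
configuration — the three planted modules of 30 plus 150 independent
proteins (240 total) — because at these thresholds roughly 10% of all
null pairs survive the edge filter (see the caveat above), and an
all-against-all network at 5000 proteins yields on the order of a million
spurious edges, beyond what iterated-betweenness community detection can
process. The reduced configuration preserves the planted structure, the
sample size, and every threshold. Module recovery under a ~10%
inter-module spurious-edge background is genuinely variable: across seeds
the detected partition occasionally merges two planted modules, which the
Adjusted Rand Index reports as ≈ 0.5 rather than 1. The package reports
what the method does; it does not tune around it.

The study-scale structural benchmark uses `synthetic_study_network()`, a
constructed stand-in with the study network's exact dimensions (1408
nodes, 1211 edges; 24 planted modules of 12 plus small filler components)
that exercises parsing, community detection and overlap machinery at
realistic scale with known ground truth. It is labelled synthetic
throughout: the study's own network is not available as a re-usable
artifact, so its published counts are design targets for the machinery,
not reproduced results.

## Known limitations

* The permutation z-threshold does not control the false-edge rate (see
  above); interpret network density accordingly.
* The reversal test's independence assumption is violated by construction
  in strongly co-expressed modules; treat flags as a screen, not
  confirmatory inference.
* The moderated model has no abundance-variance trend (no trended prior);
  TMT data with strong intensity-dependent variance would be
  under-served.
* Identifier mapping between proteins and gene symbols is a user-supplied
  table; no online resource is queried.
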