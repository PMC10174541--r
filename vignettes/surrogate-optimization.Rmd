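---
title: "Surrogate models and NSGA-II for seed-sterilization optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate models and NSGA-II for seed-sterilization optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling decisions behind `sterilopt`: the
data model, the three surrogate regressors, the sensitivity and
optimization procedures, the synthetic replicate generator, and the known
limits of what this replication can and cannot show.

## The experiment and its data model

The underlying experiment sterilized petunia seeds with six disinfectants
— NaOCl, Ca(ClO)₂, HgCl₂, H₂O₂ (dosed as % solutions) and the carbon
nanotube materials NWCN-Fe and MWCNT (mg/L) — each at 4–5 concentration
levels crossed with 3 immersion times, plus untreated controls, and
recorded two antagonistic responses per treatment: contamination rate (%)
and seed germination (%). Only treatment means and standard errors were
published; they ship with the package as six CSV fixtures (90 rows; the
controls repeat per table as printed, so each disinfectant's subset is
self-contained).

Inputs are encoded as a 7-vector: one concentration slot per disinfectant
plus immersion time. The design never mixes disinfectants, so at most one
slot is nonzero; an all-zero concentration row is an untreated control.
Inputs are min–max scaled to [0, 1] (constant columns map to 0);
responses stay on the raw percent scale, which is what makes RMSE values
directly interpretable in percent points.

The published design summary ("76 treatments", "608 datapoints") cannot
be reconciled exactly with the 90 printed rows; the package treats the
90 printed rows as canonical and does not enforce the 608 arithmetic.

## The replicate generator

The raw replicate-level data are unavailable, so `expand_replicates()`
reconstructs them: for each treatment it draws `replicates` (default 8,
the sub-set count of the original design) values per response from a
normal law centred on the printed mean with per-datapoint
sd = SE·√8, truncated to [0, 100]. Truncation is exact (inverse-CDF
sampling), not clipping, so the bounds carry no point mass. The √8 factor
assumes the printed SE is the standard error of the mean over the 8
sub-set datapoints; whether the SEs were instead computed over 12 seeds
is not stated in the source and is recorded as an assumption. The noise
scale is deliberately decoupled from the number of simulated replicates:
simulating more datapoints must not inflate the reconstructed noise, or
mean preservation would fail in the large-sample limit.

What the generator emulates: the location and dispersion summaries of
the published tables, and the design structure (balanced replication,
shared controls). What it does **not** emulate: the real experiment's
unexplained biological variation. The printed SEs are small (typically
0.2–1.7 points), so the reconstructed replicate noise is far below the
between-treatment signal. Consequences are discussed under *Limitations*.

A second generator, `make_benchmark_surface()`, produces fully synthetic
bi-objective response surfaces (a unimodal germination peak and a
monotone-decreasing contamination curve) with a known, grid-computed
optimum, used for parameter-recovery testing of the optimizer.

## The three surrogates

One model is fitted per response rather than a single two-output network:
the source describes single-output RBF/GRNN architectures and reports
per-response metrics.

**GRNN.** Nadaraya–Watson kernel regression over the stored training
patterns: the S-summation Σᵢ K(x, xᵢ) and D-summation Σᵢ wᵢ K(x, xᵢ) with
Gaussian kernel K = exp(−‖x−xᵢ‖²/2σ²); the prediction is their ratio, a
convex combination of stored targets (hence always inside the target
range, tending to nearest-neighbour regression as σ→0 and to the grand
mean as σ→∞). Predictions subtract the per-query nearest distance inside
the exponential — a normalization-invariant shift that keeps the σ→0
limit finite.

The only free parameter, σ, is chosen by leave-one-out grid search (25
log-spaced widths over 10⁻²–10¹ on the scaled-input metric). One subtlety
matters a great deal here: under replicated designs many training rows
share an identical feature vector, and *row-level* LOO is degenerate —
the held-out replicate is predicted by its identical siblings at any
small-to-moderate width, so the LOO profile sits flat at the
replicate-noise floor and its argmin is decided by numerically tiny
fluctuations. The default (`loo = "design"`) therefore holds out all rows
sharing the held-out row's feature vector, which measures
between-treatment generalization and reduces to ordinary LOO when rows
are distinct. Both schemes are exposed, and the degeneracy is verified by
a test.

**RBF network.** Gaussian bases φₖ(x) = exp(−‖x−cₖ‖²/2σ²) around centers
chosen by seeded k-means (default 120, capped at the number of distinct
training rows), a shared width from the d_max/√(2p) heuristic, and
output weights solved by linear least squares (QR; ridge fallback with
λ = 10⁻⁸ only if the basis is numerically rank-deficient). With every
distinct training point as a center the network interpolates, which the
tests exploit as an oracle.

**MLP.** A 7→128→64→1 network, tanh hidden activations, linear output,
trained to minimize mean squared error by Levenberg–Marquardt: damped
Gauss–Newton steps δ = (JᵀJ + λI)⁻¹Jᵀr with the Jacobian computed
analytically and the system solved in the dual (n × n) space via
Jᵀ(JJᵀ + λI)⁻¹r — algebraically identical but cheap when parameters
(~9,500) far outnumber rows (~600). Damping decreases tenfold on
accepted steps and increases tenfold on rejections; exceeding λ = 10¹⁰
returns the best parameters so far with a warning. Because the
architecture is deliberately overparameterized for this data scale, an
inner 10% validation split provides early stopping (patience 5). The
default cap of 30 accepted iterations is ample for convergence of the
early-stopped fit at this problem size.

All three trainers are deterministic given (data, config, seed).

## Evaluation and sensitivity

Models are compared on a stratified 80/20 split (stratified by
disinfectant so no disinfectant vanishes from either subset at this n;
the global train size is ⌊0.8 n⌋ by largest-remainder apportionment, and
the stratum order is fixed by first appearance so the seeded partition is
locale-independent). Metrics are the conventional R², RMSE, and
MBE = mean(predicted − observed) (negative = under-prediction); the
printed formulas in the source swap observed/predicted in places, and the
conventional orientations are used. The best family is the one with the
highest test R² averaged over the two responses.

Input importance follows the variable-removal scheme: VSE_j is the test
RMSE after *retraining* the surrogate without input j (same split and
seed), and VSR_j = VSE_j / full-model test RMSE; inputs are ranked by
descending VSR. Retraining (rather than zeroing the column at prediction
time) is the only coherent reading in this encoding, because a zeroed
concentration column is indistinguishable from an untreated control.

## The optimizer

`nsga2()` is a from-scratch NSGA-II over box-bounded real vectors:
fast non-dominated sorting (verified against a brute-force dominance
oracle), crowding distance with infinite distance at per-objective
extremes, binary tournament on (rank, crowding), two-point crossover at
rate 0.70, per-gene Gaussian mutation (probability 0.01, sd = 10% of the
gene's range, clipped to bounds), and (μ+λ) elitist environmental
selection. The study's calibration — population 85, 800 generations — is
the default. The odd population is kept as published; offspring are
generated in pairs and truncated. Germination is negated internally so
all sorting minimizes.

Each disinfectant defines a scenario: its concentration varies over
[0, max tested level] and time over the tested range, while the other
five concentration genes are frozen at zero (equal bounds, plus an
explicit re-mask after variation). Crossover operates on the full 7-gene
chromosome, matching the published operator, with the frozen genes
carrying no information. From the final first front the **ideal point**
is selected: the member minimizing the Euclidean distance to
(m, n) = (minimum observed contamination, maximum observed germination)
of that disinfectant's own printed subset; exact ties break toward lower
contamination.

On the synthetic benchmark surfaces, the search recovers the known
optimum within a few percent of each input's range (test-verified at
pop 60 × 150 generations, well below the defaults).

One deviation from a literal reading of the elitism folklore is worth
recording: with crossover and mutation disabled, standard NSGA-II is
*not* a strict population fixed point, because tournament selection
duplicates members and crowding truncation may then swap copies for
dominated originals. What is guaranteed — and tested — is that no new
decision values appear, the per-objective optima are preserved exactly,
and the population's utopia-distance trace is non-increasing.

## Problem sizes and reproducibility

The shipped analysis uses the full study conditions: 90 treatments × 8
replicates = 720 rows, 576/144 split, all three families, six scenarios
at 85 × 800 GA settings — about two minutes end-to-end per seed on one
CPU, the MLP dominating. Replication summaries average 10 seeds (model
accuracy) and 5 seeds (optimization); these sizes give seed-to-seed
standard errors well below the tolerances of interest. A single master
seed fans out to per-stage seeds through a fixed affine derivation
(`stage_seed()`), so any stage can be rerun independently.

## Limitations

- **The synthetic replication is cleaner than the real data.** With
  replicate noise reconstructed from the tiny printed SEs, held-out
  replicates of *seen* treatments are almost exactly predictable, so
  test-set R² values run higher than the published ones (contamination
  ~0.99 vs 0.886; germination lands close at ~0.84–0.89), and
  interpolating models are flattered: the RBF network, which nearly
  interpolates the 90 design points, edges out the GRNN on mean test R²
  under these conditions, whereas the original study found the GRNN best.
  The published figures are only reproducible to the extent that the
  real, unpublished replicate scatter mattered.
- **Optimization headlines depend on surrogate smoothness.** Four of the
  six scenario optima land close to the published ones (NaOCl, HgCl₂,
  NWCN-Fe, MWCNT). For Ca(ClO)₂ and H₂O₂ the published ideal points imply
  a smoother response surface than the design-point-LOO GRNN produces
  (the published run plausibly used a fixed, wider kernel), so the
  replicated ideal points trade a few points of germination or
  contamination against the published row.
- **The sensitivity mechanism is underdetermined.** Under
  retrain-without-column removal, deleting a concentration column merges
  that disinfectant with the controls and dominates the error, so
  concentration inputs outrank immersion time; the published ranking
  (immersion time first) evidently arose from a different, unstated
  removal mechanism. VSR magnitudes are not comparable; rank agreement is
  partial.
- No seed-level binomial granularity is modelled; replicate values are
  continuous percentages.
- Constraint handling is box-bounds only; no many-objective extensions.
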