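---
title: "Calibrating virtual populations on mechanistic axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating virtual populations on mechanistic axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A cohort of N virtual patients (VPs) carries, per VP, M mechanistic-axis
coefficients `C[i, j]` and simulated continuous ACR-N responses (percent
improvement) to each therapy at each sample time. The calibration estimates
one upper-bin probability per axis rather than one weight per VP. Each axis
is split at its empirical median — the two bins therefore each hold about
half the cohort, and since the two bin probabilities sum to one, `p_j` (the
upper-bin probability) is the single free variable per axis. The prevalence
weight of VP i is the normalized product over axes of the probability of
the bin the VP occupies:

    w_i ∝ ∏_j [(1 − p_j) if C[i,j] ≤ median_j else p_j]

Two modeling assumptions are implicit and worth stating. First, axes act
independently on prevalence unless a correlation is declared; the weight
factorizes over axes. Second, the two-bin marginal is deliberately coarse:
it asks only whether a patient type is in the lower or upper half of each
biological axis, which keeps the optimization M-dimensional and
well-conditioned at the cost of within-bin resolution.

### Pairwise dependence through a Gaussian copula

A declared pair of axes (k, l) is coupled by a latent standard bivariate
normal with correlation ρ. Each axis is cut at `z_j = Φ⁻¹(1 − p_j)`, so the
upper half-line carries exactly mass `p_j`; the pair's two independent
factors are replaced by the probability of the rectangle formed by the VP's
two half-lines. This preserves both binned marginals for every ρ and
reduces exactly to the independent product at ρ = 0. Only bivariate
couplings are supported, and an axis can appear in at most one pair;
higher-dimensional couplings are out of scope. The rectangle probability is
evaluated by inclusion–exclusion over four bivariate-normal CDF terms
(deterministic TVPACK evaluation, absolute error below 1e−8); tests
cross-check it against the arcsin orthant closed form and a 10⁶-draw Monte
Carlo oracle.

The cohort mean and SD per axis are recorded on the solution object for
completeness, but the rectangle limits depend only on the bin
probabilities: bin membership already fixes which side of the cut each VP
occupies.

### Scoring against trial targets

For each therapy × timepoint target the package computes the weighted mean
`x̄ = Σ w_i x_i`, the weighted SD `s = sqrt(N Σ w_i (x_i − x̄)² / (N − 1))`
(the printed population form, which reduces to the classical sample SD at
uniform weights), and the weighted mass in each ACR response bin. Targets
reported only as bin counts get a mean and SD reconstructed by placing
every patient at their bin midpoint, with the conventional 35 for the
ACR 20–50 bin; the edge-bin midpoints (10 and 85 by default) are not fixed
by convention and are configurable. Matching the reconstructed mean and SD
in addition to the bins prevents solutions that game the bin distribution
by piling weight at bin edges.

Agreement is scored with three p-values per target — Welch t-test on the
mean, two-sided variance-ratio F-test on the SD (doubling the smaller
tail), chi-squared on the binned distribution with B − 1 degrees of
freedom — combined across all targets by Fisher's method. The Welch form
is used because the F-test already scores variance agreement separately;
pooling variances in the t-test would double-count it. The acceptance rule
is composite p > 0.05.

The weighted cohort is not N independent patients, and no sample size for
it is canonical. The default surrogate is the Kish effective sample size
`(Σw)²/Σw²` in both the t and F tests; setting `vpop_n = "trial"` uses the
trial's own N on both sides instead. The choice matters in one visible
place: at a perfect SD match (F = 1) the two-sided p-value is exactly 1
only when the two degrees of freedom agree, so the trial-N configuration
scores an exactly-matching solution at p = 1 while the Kish default scores
it slightly below (the two-sided tail split is asymmetric at unequal
dof). Both behaviors are pinned by tests.

## Optimization

Bin probabilities are re-parameterized as `p = sin²θ` (the two-bin
hyperspherical case) and correlations as `ρ = tanh z`, so Nelder–Mead runs
over an unconstrained space with no edge complications: any real vector
maps to a valid solution, and the transform round-trips to 1e−12. The
objective is `Σ log p` over all included statistics — a strictly monotone
transform of the Fisher composite at fixed statistic count, so maximizing
one maximizes the other. p-values are floored at 1e−300 before logs; a
structurally impossible solution (every VP annihilated by a 0/1
probability pattern) scores a finite sentinel worst value rather than
erroring inside the simplex.

Defaults: standard Nelder–Mead coefficients as implemented in
`stats::optim`, relative objective tolerance 1e−6, 2,000 iterations per
start, 5 random starts (`p_j ~ U(0, 1)` independently, ρ initialized in
(−0.5, 0.5)), all seeded and recorded. The iteration trace stores the
best-so-far objective and is monotone by construction.

### Ensembles

Alternate valid VPops are built by repeated calibration: the first start is
random; once any member is accepted, every subsequent attempt starts from a
Gaussian perturbation (SD `sigma_seed`, default 0.25 in the unconstrained
space) of a uniformly chosen accepted solution — accepted solutions seed
the search for neighbors, which is what makes the ensemble explore the
valid set rather than re-derive it from scratch. Acceptance requires
composite p above the threshold; the attempt budget is 20 × the requested
ensemble size, and an optional minimum L∞ distance on the probabilities can
enforce member distinctness (off by default — overlapping solutions are
legitimate members of the valid set). Member randomness derives only from
recorded per-attempt seeds, so ensembles are reproducible.

## Downstream analyses

*Responder contrast.* Ensemble members are split by their weighted mean
response to a chosen therapy (defaults 48 for strong responders and 44.75 —
the observed clinical mean — for weak); per axis, the median and IQR of the
fitted `p_j` within each group are reported with axes ordered by absolute
median difference. An empty group warns and flags rather than errors.

*Scenario re-statting.* `predict()` on a fitted VPop applies the fixed
weights to new response columns (e.g. pathway on/off variants simulated for
the same VPs) with no re-optimization — the weight-application half of a
sensitivity analysis. Rows align by VP id, not position.

*Multianalyte biomarkers.* Analytes correlated above |ρ| = 0.8 are grouped
into connected components of the thresholded correlation graph; each
component keeps the analyte with the lowest mean absolute correlation
against *all* other analytes (ties broken by column order), constants are
retained but flagged. Best subsets are then found by exhaustive
enumeration of size-k prevalence-weighted least-squares fits. The
regression is weighted because alternate VPops differ *only* by their
weights — unweighted fits could not differ between members. Model quality
uses the Kish effective sample size: adjusted
R² = 1 − (1 − R²)(n_eff − 1)/(n_eff − k − 1) and
BIC = n_eff·log(RSS_w/n_eff) + (k + 1)·log(n_eff). The default model size
is k = 5, the size at which explained variance and overfitting risk
balance for panels of this collinearity; the default response for biomarker
fitting is the VPop's 6-month biologic-therapy ACR-N. Selection stability
across an ensemble is summarized by per-analyte selection frequencies.

## The synthetic generator

The generator emulates the statistical shape the calibration consumes, and
nothing else: axis coefficients i.i.d. U(0, 1) (median-splittable by
construction; Beta alternatives exist for asymmetric splits), responses
`clip(a_t + Σ_j b_tj C_ij + ε, −21, 100)` with Gaussian noise — the clip
range is the observed envelope of simulated ACR-N responses (21% worsening
to 100% improvement) — and a mediator panel that is a linear map of the
axes plus noise, with near-duplicate columns (noise SD 0.05 × the column
SD) injected specifically to exercise the ρ > 0.8 pruning path. Defaults:
200 VPs, 10 axes, three therapy arms at 6 months with intercepts
(20, 5, 35), loadings U(−10, 15), residual SD 10, trial size N_T = 300,
ground truth `p* ~ U(0.2, 0.8)`. Every stochastic ingredient is drawn once
from the master seed inside `synthetic_spec()`, so the spec object is the
complete study description.

Targets are generated from the truth in two modes. *Exact* mode apportions
`N_T × f_b` into integer counts by largest remainder (counts always sum to
N_T) and stores the weighted population mean/SD directly, so the truth
scores a near-perfect composite and recovery is a well-posed feasibility
check. *Sampled* mode draws multinomial counts and reconstructs mean/SD
from the sampled bins, emulating what a real published trial table gives
you.

What passing recovery tests do **not** show: real cohorts are not uniform
on their axes, responses are not linear in the axes, and the true
data-generating process is not inside the model family. The recovery task
certifies the estimation machinery (identifiability at M = 1, feasibility
at M = 10), not biological fidelity. For M > 3 the assertable contract is
the achieved composite, not per-axis error — many axis-weight solutions
can induce nearly identical weighted response distributions.

One structural feature deserves emphasis: the binned-midpoint
reconstruction of a trial *mean* is biased relative to the continuous
weighted mean whenever the within-bin mass is asymmetric, and at realistic
trial sizes this bias exceeds the sampling standard error. Consequently,
evaluating the truth against sampled-mode targets yields t-test p-values
that run systematically low, and the full composite at the truth is *not*
uniform-dominant — while the composite restricted to the SD and bin
statistics, which are free of this bias, is (both facts are asserted by the
property tests). This is a property of midpoint reconstruction itself, the
same reconstruction applied to real published tables; in actual calibration
the optimizer simply absorbs the bias into the weights.

## Numerical choices and degenerate inputs

- Median ties go to LOWER: bins are `(−∞, med]` / `(med, ∞)`. A constant
  axis (empty upper bin) is a named error — such an axis carries no
  weighting information.
- Response bins are half-open `[lo, hi)`, lowest open below, highest closed
  above; out-of-range responses clip into the edge bins by default
  (`clip = FALSE` makes them a named coverage error).
- Expected chi-squared counts are floored at `1e−6 × N_T` and renormalized
  so an empty weighted bin yields a finite statistic.
- Weight normalization happens once, at the end of the product — for a
  global normalization the result is identical wherever it is applied.
- All randomness (starts, perturbations, sampled targets) flows through
  per-step seeds derived from one recorded master seed.

Problem sizes used by the shipped tests and the acceptance script — chosen
as the smallest sizes at which each property is cleanly identified: the
default recovery task (200 VPs × 10 axes × 3 targets, 5 restarts),
one-axis recovery at 400 VPs with a grid-search cross-check, ensembles of
3 members on an 80 VP × 3 axis task, 200 replicate seeds for the
sampled-mode calibration check, and 10⁶ draws for the Monte-Carlo copula
oracle.

## Known limitations

- Two bins per axis; no finer marginals and no multivariate (>2) copulas.
- No global optimizer: Nelder–Mead with random restarts finds local optima
  of a multimodal objective; the ensemble machinery is the intended answer
  to solution multiplicity, not a guarantee of global optimality.
- The Kish surrogate for the VPop sample size is a modeling choice, not a
  derived quantity; both it and the trial-N alternative are defensible and
  the package exposes the switch.
- Calibration is on ACR-N summaries only — no longitudinal or structural
  endpoints.
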