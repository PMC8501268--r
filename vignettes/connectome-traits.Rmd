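---
title: "Discovering structural connectome traits: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering structural connectome traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Structural connectomes — one symmetric matrix per subject, with a
white-matter integrity measure (e.g. fractional anisotropy, FA) per
pair of brain regions — vary across people in correlated, whole-brain
patterns. When the expected group differences are subtle (for example
between cognitively healthy first-degree relatives of Alzheimer's
disease patients and controls), edge-by-edge comparisons have little
power. `conntrait` instead models the cohort as a *linear mixture of
latent connectivity traits*:

$$X \;=\; A\,T \;+\; \text{baseline} \;+\; \varepsilon,$$

where $X$ is the $S \times m$ cohort matrix ($S$ subjects, $m =
n(n-1)/2$ vectorized upper-triangle edges), the rows of $T$ ($K \times
m$) are statistically independent edge-space patterns ("SC-traits"),
and $A$ ($S \times K$) holds per-subject *weights* quantifying how
strongly each trait is expressed in each subject. Group structure, if
any, lives in the weights, not in the decomposition: traits are
estimated on the whole population with no stratification, and group
association is tested afterwards on the weights.

The estimation pipeline has four stages:

1. **Denoising.** Each edge is centered across subjects and the matrix
   is reconstructed from the smallest number of principal components
   whose cumulative explained variance reaches `var_explained`
   (default 0.95), with the edge means added back.
2. **Decomposition.** FastICA (symmetric/parallel decorrelation,
   logcosh contrast) factors the reconstructed matrix into
   `n_components` (default 20) unit-variance edge patterns and their
   subject weights. Because FastICA solutions depend on the random
   initialization, the decomposition is repeated `n_runs` times
   (default 500) with seeds `base_seed + r`.
3. **Consensus.** Components are clustered greedily across runs: a
   component is *present* in another run when some component there
   matches it at $|r| \ge$ `match_rho` (default 0.7, absolute Pearson
   over edges — ICA signs are arbitrary, so sign-blind matching is the
   only meaningful reading of a correlation criterion). A cluster is
   a *robust trait* when it recurs in at least `presence_min`
   (default 75%) of the runs. The consensus trait is the
   sign-aligned mean of its members, re-standardized, with the
   canonical sign convention that the entry of maximal magnitude is
   positive; weights are averaged under the same alignment.
4. **Association.** Robust-trait weights are compared between groups
   (pooled-variance t-tests by default, Welch optional) under a single
   Benjamini–Hochberg family spanning every trait of every
   (measure, parcellation) combination at $q < 0.05$; significant
   traits go on to the balanced regression and network localization
   described below.

## Matching correlations and orientation conventions

Two conventions are deliberately fixed rather than estimated. First,
component matching across runs uses the trait vectors (edge space),
not the weight vectors: the trait patterns are the high-dimensional,
identifiable part of the factorization, and matching on them follows
the original connICA formulation. Second, PCA centering is per edge
(across subjects): edges are the variables whose covariance the PCA
summarizes, subjects are the observations.

## Convergence of repeated FastICA runs

The symmetric FastICA fixed point is degenerate on any whitened
direction whose distribution is Gaussian: the update contracts such
directions to zero length before renormalization, so the rotation
within a Gaussian subspace performs a random walk and never meets a
tolerance criterion, no matter how many iterations are allowed —
even while the informative (non-Gaussian) components have long since
stabilized. Realistic connectome cohorts, and this package's
synthetic cohorts by construction, contain such subspaces once the
PCA keeps more dimensions than there are latent traits. For that
reason runs that exhaust `max_iter` (default 200) are *not* discarded:
they enter the consensus flagged, strict-convergence counts are
reported, and the robustness filter — which exists precisely because
single runs are unstable — decides what survives. Setting
`drop_nonconverged = TRUE` in `extraction_params()` restores strict
dropping for data where full convergence is expected (e.g. noiseless
mixtures). `tol` stays at $10^{-4}$.

## The balanced sampling-without-replacement regression

The reference cohort is unbalanced: 123 relatives vs 61 controls, and
the groups may differ on nuisance covariates. The multiple linear
regression of trait weights on nine predictors (age, APOE-ε4 carriage,
sex, years of education, MoCA, TPA, average cortical thickness,
hippocampal volume, and family history — family history deliberately
*last*) is therefore estimated on repeated balanced subsamples:

- each draw selects `target_n` (default: the control group size, 61)
  relatives without replacement;
- the draw is accepted only if the selection shows no significant
  difference from the controls on any of the 8 nuisance predictors
  (pooled-variance t-tests with Cohen's d for continuous predictors;
  Pearson chi-square without continuity correction with the phi
  coefficient for sex and APOE, falling back to Fisher's exact test
  when a level is absent in a group — a regime the tests record);
- rejection sampling continues until `n_runs` (default 100) draws are
  accepted, with a `max_attempts` cap (default 100 000) that fails
  loudly with the acceptance rate and the worst predictor, because a
  heavily confounded cohort can make acceptance arbitrarily rare.

Within each accepted sampling the response and all predictors are
z-scored (hence standardized coefficients β) and fitted by ordinary
least squares with intercept; residual degrees of freedom are
$n_{\text{sub}} - 9 - 1$ (112 when 61+61 subjects enter). Statistics
are averaged across samplings — $R^2$, β (mean and SD), t — and each
predictor's p-value is the two-tailed tail probability of the
*averaged* t at the common df. Sequential (incremental) $R^2$
contributions add the predictors in specification order; they
telescope, so they sum to the full-model $R^2$ exactly, and with
family history last its contribution is the variance explained on top
of all nuisance predictors. Averaged predicted values and standardized
residuals are reported per subject: controls average over all
samplings, each relative over the samplings that selected them — a
reporting convention recorded in the output rather than a modelling
assumption. Balance-test choices (Student t, chi-square, α = 0.05) are
themselves conventions: they reproduce demographic-table-style
"bootstrap p-value" envelopes whose minima sit just above 0.05.

## Subtraits and network-block localization

A significant trait is *oriented* so that positive entries mean
greater integrity in the higher-weight group (the sign of the group
difference of weights supplies the orientation), z-scored over edges,
and split at `z_thresh` (default 2.0): entries above $+z$ form the
*enhanced* subtrait, entries below $-z$ the *diminished* one; the
threshold is a deterministic, scale-free stand-in for "excluding
spurious connections" and is always reported with the output. Each
subtrait is reduced to its giant connected component, discarding
stray edges touching only one or a few regions (ties broken by edge
count, then smallest node index). Block presence over the $G(G+1)/2$
unordered network pairs (7 cortical resting-state networks + a
subcortical group, $G = 8$) is the sum of retained edge magnitudes
divided by a size-correcting denominator. Two denominators are
available because "total number of edges" is genuinely ambiguous:
`retained_edges` (default; presence = mean magnitude per retained
edge) and `possible_edges` (presence diluted by block size); both are
reported when they disagree materially. Under the working hypothesis
that the at-risk group gains no true integrity, the *maximal enhanced
presence* serves as the noise ceiling: any diminished block exceeding
it is flagged as over-represented, and the output records whether the
hypothesis check (all enhanced values below the maximal diminished
presence) held.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` draws data exactly from the linear-mixture model:
planted unit-variance trait patterns with named network blocks
(block entries Normal(±amplitude, 0.3·amplitude), background
Normal(0, 0.1·amplitude) — never exactly sparse, since ICA on
exactly-sparse sources can be degenerate), Gaussian loadings with
unit SD (so a configured group effect is exactly Cohen's d), a fixed
random baseline, and i.i.d. Gaussian edge noise. FA cohorts are
affinely mapped into [0.05, 0.95] — an affine map, not clipping, so
the mixture stays exactly linear. Covariate distributions mirror a
two-group cohort of healthy older adults (age 57.9 ± 6.9 y, 64%
female, 32% APOE-ε4 carriers, education 15.5 ± 3.8 y, MoCA
26.1 ± 2.8, TPA 1.44 ± 1.19, cortical thickness 2.37 ± 0.072 mm,
hippocampal volume 3821 ± 377 mm³); group offsets default to zero so
the balanced sampler runs in its easy regime, and the `confounded`
preset shifts the controls' age by d = 0.6 to exercise its hard
regime.

The default planted structure (the package's reference conditions,
used by the tests and the acceptance script) is 123 + 61 subjects,
100 nodes with network sizes scaled from the Schaefer-100/Yeo-7
proportions, K = 3 traits — trait 1 with a strong negative
visual–visual block (amplitude 4) and a weaker positive default-mode
block (amplitude 2) and a group effect d = 1, plus a somatomotor and
a limbic–subcortical trait with no group effect — and noise SD 0.5.
The asymmetric trait-1 structure mirrors the empirical situation the
over-representation statistic was designed for: a concentrated
diminished pattern against widespread weaker enhancement, which is
what makes the max-enhanced threshold a meaningful noise ceiling.

What the generator does **not** emulate: spatial embedding and
distance-dependent connectivity, measure-specific noise (streamline
count dispersion, diffusivity units), subject-level motion artifacts,
non-Gaussian weight distributions (Gaussian loadings are an
assumption), and correlated covariates. Passing tests therefore show
that the pipeline recovers what its own model class generates — a
necessary check, not a demonstration about any particular empirical
dataset.

## Numerical choices and degenerate inputs

- Symmetry violations beyond 1e−8 are hard errors, never silently
  repaired; an asymmetric input signals an upstream fault.
- Edge ordering is fixed package-wide (row-major upper triangle,
  i < j) and written into every output sidecar.
- If the PCA rank is below the requested component count, the count
  is reduced to the rank with a warning (small cohorts would
  otherwise be untestable); requesting more components than the data
  rank within a single run is an error.
- Robustness at `presence_min` uses an inclusive threshold with a
  1e−12 guard against floating-point run-count artifacts (2 of 2 runs
  is robust at 0.75; 74 of 100 is not).
- A perfectly fitted regression (zero residual variance) reports
  zero standardized residuals rather than 0/0.
- Collinear predictors (design condition number above 1e10) abort
  with the most correlated pair named.
- An empty enhanced subtrait makes the over-representation threshold
  0 with a warning — every nonzero diminished block is then flagged,
  which is the honest reading of "no noise ceiling available".
- Raising `presence_min` can only remove robust traits (exactly
  monotone). No such guarantee holds for `match_rho`: the greedy
  best-match clustering can, at lower rho, let a strong cluster poach
  a weaker one's members. This is a property of the greedy scheme,
  not a bug, and the tests assert only the exact half.

## Problem sizes used by the tests and the acceptance script

The shipped checks run the reference conditions at full cohort size
(184 subjects, 100 nodes, 4950 edges) with 100 FastICA runs — enough
for presence fractions in steps of 1% — and the replicated
calibration studies at 40–50 nodes with 12–20 runs and 10–20
replicate seeds, sizes at which the type-I and power properties are
already stable. The extraction default stays at the 500 runs of the
published setting; nothing in the implementation depends on the run
count beyond the presence denominator.

## Known limitations

- No alternative decompositions (NMF, dictionary learning) and no
  automatic selection of the number of components.
- No permutation or nonparametric group tests (an extension point).
- No propensity-score or optimal matching; the balanced sampler is
  rejection sampling, by design transparent but potentially slow
  under heavy confounding.
- The subcortical group is treated as an eighth network throughout;
  the partition file is authoritative about how many subcortical
  regions it contains.
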