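---
title: "Double-pass analysis: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-pass analysis: models, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublepass)
```

This vignette is the package's account of the science it implements: the
generative model of the decision variable, the estimators built on it, the
conventions adopted where the methodology leaves choices open, and the
numerical machinery underneath. It states no empirical result that the test
suite does not itself compute.

## The decision-variable model

A 2IFC disparity-discrimination trial presents a standard stimulus at
pedestal disparity $\delta_{std}$ (signed, arcmin; negative = uncrossed) and
a comparison at $\delta_{cmp}$. The observer's response is the sign of a
scalar decision variable

$$D = \Delta\delta + V + W, \qquad
  V \sim \mathcal N(0, \sigma_E^2), \quad W \sim \mathcal N(0, \sigma_I^2),$$

with $\Delta\delta = \delta_{cmp}-\delta_{std}$. $V$ is the stimulus-driven
perturbation: it is a property of the particular pair of images shown on
that unique trial, so it repeats exactly when the trial is repeated in a
second pass. $W$ is internal noise, fresh on every pass. The assumptions
inherited from signal detection theory are: normality of both components,
their independence, a fixed criterion at zero, and decision variance that is
constant across the comparison levels of a condition.

Across the two passes the joint decision variable is bivariate normal with
correlation $\rho = \sigma_E^2/(\sigma_E^2+\sigma_I^2)$ — the fraction of
decision variance that is repeatable. In the paired-experiment design the
stimulus-driven component further splits into a luminance-driven part $L$
(identical for the natural and flattened version of a scene location, hence
shared by all four passes) and a depth-driven part $B$ (present only with
natural depth profiles, shared by that experiment's two passes):

$$D^\dagger = \Delta\delta + L + W^\dagger, \qquad
  D^{*} = \Delta\delta + L + B + W^{*} .$$

The three pass-pair correlations
$(\rho^{\dagger\dagger},\rho^{**},\rho^{\dagger*})$, together with the two
total variances $\sigma_{T\dagger}^2,\sigma_{T*}^2$, identify the five
unknowns $(\sigma_L^2, \sigma_B^2, \mathrm{cov}[L,B],
\sigma_{I\dagger}^2, \sigma_{I*}^2)$ in closed form
(`solve_components()`, exactly invertible by
`correlations_from_components()`; the package tests the round-trip at
1e-12).

## Psychometric scale and the two d′ conventions

`fit_thresholds()` fits every pedestal of one (experiment, bin) data set
jointly, with the psychometric mean fixed at the pedestal and the SD
constrained to a log-linear law $\sigma_T = \exp(m\,\delta_{std} + b)$ — the
classic exponential rise of disparity thresholds. The fitted $\sigma_T$ *is*
the decision-variable SD, so percent-comparison-chosen follows
$PC = \Phi(\Delta\delta/\sigma_T)$, and the normalised orthant means used by
every correlation estimator are $d' = \Delta\delta/\sigma_T$.

Two d′ conventions coexist in the 2IFC literature and differ by $\sqrt 2$:
the *per-interval* convention (each interval's estimate has SD $\sigma$;
the difference has SD $\sqrt2\sigma$; $PC = \Phi(d'/\sqrt2)$ and threshold
performance at $d'_{crit}=1$ is the 76% point) and the *decision-variable*
convention used internally here ($PC = \Phi(d')$). `pc_from_dprime()`
implements the classical per-interval conversion; the estimation chain uses
the decision-variable convention throughout, which is the one under which
threshold (at $d'_{crit}=1$), fitted psychometric SD, and the likelihood
normalisation are a single consistent quantity with
$\sigma_T^2 = T^2$. Mixing the conventions changes nothing downstream —
only the scalar reading of "d′" attached to a given $PC$.

## Estimating decision-variable correlation

Responses are tallied per condition and comparison level into joint
patterns (4 for two passes, 16 for four; canonical order
`pattern_labels()`: binary counting, `-`=0, `+`=1, pass 1 most
significant). The log-likelihood is $\sum_j N_j \log \mathcal L_j(\theta)$
with $\mathcal L_j$ a normal orthant probability at mean
$(d'_1,\dots)$ and the structured correlation matrix
(`build_quad_corr()`); criteria are zero (nonzero criteria are supported and
simply shift the orthant). Level-wise likelihoods are summed with a shared
$\rho$ per condition — the pooling the agreement-versus-PC curve implies.
The decision-variable SDs entering the normalisation are frozen at the
constrained threshold fits, not re-estimated jointly.

Numerical choices:

* $\rho$ is profiled through $\tanh$-reparameterised unconstrained
  optimisation (double pass: golden-section on $(-1+10^{-6},1-10^{-6})$,
  tolerance $10^{-9}$; quadruple pass: Nelder–Mead from multi-starts at
  correlations $\{0, \pm0.3, \pm0.6\}$-scale, relative tolerance $10^{-8}$).
* the PSD cone of the structured matrix is closed form,
  $4\rho_{\dagger*}^2 \le (1+\rho_{\dagger\dagger})(1+\rho_{**})$; points
  outside receive a smooth penalty so derivative-free search recovers.
* with equal means within a pass pair, the two orderings of a disagreement
  are equiprobable, so only 9 of the 16 orthants are integrated.
* boundary estimates ($|\hat\rho| > 1-10^{-4}$) are flagged; degenerate
  data (perfect agreement at $d'=0$) legitimately produce them.
* the `cov_zero` mode of `fit_quadpass()` re-fits with the interaction
  constrained to zero by tying
  $\rho^{\dagger*} = \rho^{\dagger\dagger}\,\sigma_{T\dagger}/\sigma_{T*}$,
  the sanctioned remedy when raw components come out slightly negative
  (they are reported raw and flagged, never clipped).

## The orthant engine

Bivariate orthants use the trigonometric (Drezner–Wesolowsky-type) form of
the bivariate normal CDF, $\Phi(h)\Phi(k) + \frac1{2\pi}\int_0^{\arcsin\rho}
\exp\!\big({-\tfrac{h^2+k^2-2hk\sin\theta}{2\cos^2\theta}}\big)\,d\theta$,
integrated by 48-node Gauss–Legendre: deterministic and accurate to
~1e-12 over the whole correlation range (the test suite checks the
zero-mean quadrant against $\tfrac14 + \arcsin(\rho)/2\pi$ at 1e-6).

Three- and four-dimensional orthants use Genz's sequential transformation
integrated over a Kronecker (Richtmyer) point set with a baker transform.
Inside likelihood optimisation the point set is *fixed* (no randomisation),
which makes the objective smooth and deterministic — the property the
optimisers need; `orthant_prob()` adds randomised shifts and doubles the
sample size until its error estimate meets the tolerance (default 1e-5,
checked against a $10^6$-sample Monte-Carlo oracle in the tests). Point
counts: 256 for point estimates, 32 for warm-started bootstrap refits,
where quadrature error is far below binomial resampling noise.

## The synthetic-observer generator

`build_design()` + `simulate_observer()` emulate the full study design: 2
experiments × 2 passes × 5 pedestals ([−11.25, −9.38, −7.5, −5.63, −3.75]
arcmin) × 2 disparity-contrast bins × 5 comparison levels × 100 repeats —
5000 unique trials per experiment, 20,000 presentations per observer.
Comparison levels are symmetric around and include the standard (the
$PC=0.5$ point is the most informative one for correlation estimation); the
default spacing tracks the log-linear threshold law (`step_m = -0.15`,
`step_b = -1.05`, giving noiseless $PC$ spans of roughly 10–90%). Stimulus
perturbations attach to the unique trial — the modelling level at which the
likelihood operates — with $(L,B)$ drawn jointly (conditional construction
gives the requested covariance exactly) and separate seeded streams for
stimulus versus noise, so observers can share a stimulus stream, as real
observers viewing the same stimuli do.

Default generative SDs scale with the same log-linear law;
$\sigma_L = \sqrt{0.45}\,\mathrm{base}$ and
$\sigma_I = \sqrt{0.55}\,\mathrm{base}$ make external and internal
variance roughly equal in the flattened experiment
($\rho^{\dagger\dagger} \approx 0.45$), while
$\sigma_B = 0.35\,\mathrm{base}$ (low bin) and $0.9\,\mathrm{base}$ (high
bin) make the depth-driven component bin-dependent and the natural
experiment's correlation larger — the qualitative fingerprint of the
natural-stimulus findings. $\sigma_B$ in the low bin is small but nonzero:
with exactly zero, the orderings of the two experiments' correlations would
be undetermined rather than reproducible.

What the generator does *not* emulate: real luminance content (synthetic
patches are smoothed noise), criterion drift between passes, serial
dependencies, lapses, and any non-Gaussian tail behaviour of real decision
variables. Green tests therefore certify the estimators against the model's
own assumptions — exactly the guarantee a parameter-recovery study can
give — not the assumptions themselves.

## Stimulus metrics

`disparity_contrast()` is the windowed RMS deviation of the vergence-demand
map from the central corresponding point (arcmin), half-occluded pixels
excluded with the window renormalised; `rms_contrast()` pools the two eyes'
Weber-contrast images under the window. Conventions the methodology leaves
open, fixed here: the window is the separable 2-D Hann profile peaking at
the centre pixel (a radial variant, `hann_window_radial()`, is provided and
accepted anywhere a window matrix is); Weber contrast is normalised by that
eye's windowed mean luminance; the centre pixel is included in the
disparity-contrast sum (it contributes zero). The patch convention is
32 px/°; vetting requires central (4 px, 1/8°) disparity-contrast ≤ 20
arcsec and no central half-occlusions, and bins whole-patch
disparity-contrast into the low (0.025–0.117) and high (0.393–1.375 arcmin)
ranges. `fix_contrast()` rescales both eyes' contrast images by a common
factor — the statistic is linear in that factor, so the target (0.3, the
natural-scene median convention) is hit exactly. `flatten()` duplicates one
half-image, which by construction zeroes the disparity variation.

## Bootstrap

`bootstrap_ci()` resamples *unique trials* with replacement within each
(pedestal, bin, comparison) cell, carrying every pass — across experiments
and observers — of a resampled trial along. The trial is the correct
exchangeable unit because every estimator conditions on between-pass
pairing; session/block structure is not part of the record schema, so block
bootstrap is out of scope. Percentile intervals at 68% are the conventional
single-observer band; 95% is used for between-observer analyses and the
recovery study. Coverage of the 68% interval for $\hat\rho$ is verified by
simulation (200 replicate datasets at 500 trials/condition, acceptance
band 60–76%).

## Spatial integration

`windowed_dv()` and `heuristic_dv()` compute alternative trial-level
decision variables from per-pixel disparity maps (pillbox means over
diameters 4–32 px, or nearest / farthest / maximally-deviant disparity;
pillbox membership: pixel centre within the radius, ties included; the
upper diameter bound is the patch diagonal so the largest window equals the
unweighted patch mean). `compare_models()` regresses binary responses on
each candidate by logistic regression with group-specific intercepts and
slopes (the reading adopted for "a single random-effects model conditioned
on pedestal, disparity-contrast and observer"; an intercept-only switch is
provided), and reports McFadden's pseudo-$R^2$ — both absolute and as an
increment over the central-pixel model — plus AIC and the ΔAIC against the
central-pixel model. Complete-separation fits are penalised-by-flag rather
than hidden.

## Problem sizes in the test suite

The suite exercises the full study scale where the check requires it and
smaller sizes where it does not: design arithmetic at the full 20,000-trial
layout; estimator recovery at 500 trials/condition (the study's own cell
size), with 20 replicates × 3 observers and 200-resample bootstrap
intervals, analysing one rotating pedestal per observer — the conditions
are statistically identical under the constant generative SDs, so this
loses no information while keeping the recovery study at roughly ten
minutes; convergence checks (agreement at chance, psychometric SD
recovery) at $10^4$–$10^5$ trials; the orthant oracle at $10^6$ Monte-Carlo
samples. Coverage in the recovery study is pooled across quantities,
observers and replicates and required to reach 0.90 for nominal-0.95
intervals.

## Known limitations

* Criteria are assumed at zero and stable across passes; the package
  provides a sign-rate symmetry diagnostic through the tabulated margins
  but no criterion-drift model.
* The quasi-quadruple-pass likelihood treats the flattened/natural pairing
  as exact at the trial level; misregistered pairings would bias
  $\rho^{\dagger*}$ downward.
* ML boundary behaviour: degenerate inputs (duplicated observers, perfect
  agreement) push estimates to the PSD cone's edge, where coupled
  parameters are only approximately separable.
* The generator and estimators share the Gaussian decision-variable family;
  recovery tests cannot detect misspecification of that family.
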