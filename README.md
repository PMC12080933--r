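# doublepass

Partitioning what limits perceptual performance: external stimulus
variability versus internal noise, estimated from double-pass
forced-choice experiments.

## The problem

In a two-interval forced-choice (2IFC) discrimination task with natural
stimuli, every trial shows a different stimulus, so the observer's internal
decision variable varies from trial to trial for two reasons: the stimuli
themselves differ (*external*, stimulus-driven variability) and the nervous
system is noisy (*internal* noise). Thresholds alone cannot tell these
apart. In a **double-pass** experiment the observer runs the exact same set
of unique trials twice; how often the two passes *agree* reveals how much of
the decision variance is repeatable.

The signal-detection model is

```
D = Δδ + V + W,     V ~ N(0, σ_E²),  W ~ N(0, σ_I²),
```

where `Δδ = δ_cmp − δ_std` is the disparity difference between comparison
and standard, `V` is fixed per unique trial (shared across passes) and `W`
is drawn fresh on every pass. The total decision variance is
`σ_T² = σ_E² + σ_I²`, measurable from the psychometric function (at a
criterion d′ of 1 the threshold satisfies `T² = σ_T²`). The **decision-
variable correlation** across passes,

```
ρ = σ_E² / (σ_E² + σ_I²),
```

is estimated by maximum likelihood from the four joint response patterns
(−−, −+, +−, ++), whose probabilities are orthants of a bivariate normal
with normalized means `d′ = Δδ/σ_T` and correlation ρ. Then
`σ_E² = ρ σ_T²` and `σ_I² = σ_T² − σ_E²`.

Running *two* double-pass experiments on the same scene locations — one with
natural depth profiles, one with "flattened" stimuli (one eye's image
duplicated, removing all disparity variation) — and analysing all four
passes jointly (the **quasi-quadruple-pass** analysis, a 16-pattern
likelihood over 4-D normal orthants with correlation parameters ρ††, ρ**,
ρ†\*) further splits the stimulus-driven variance into a luminance-driven
component `σ_L²`, a depth-driven component `σ_B²` and their interaction
`cov[L,B]`:

```
σ_L²   = ρ†† σ_T†²
cov    = ρ†* σ_T† σ_T* − σ_L²
σ_B²   = ρ** σ_T*² − σ_L² − 2 cov
```

The same 4-D machinery applied to two *observers* yields between-observer
correlations and the noise-corrected partial correlation
`ρ12·W = ρ12 / √(ρ11 ρ22)`, the shared stimulus-driven computation.

The package implements the full chain — synthetic observers from the
generative model, constrained psychometric fits (`σ_T = exp(m δ_std + b)`
across pedestals), the orthant-probability engine (deterministic bivariate
CDF plus Genz-style quasi-Monte-Carlo for 4-D), the correlation estimators,
the variance partition, trial-level bootstrap CIs, stimulus metrics for
stereo patches (disparity-contrast, RMS contrast, flattening, vetting), and
a spatial-integration model comparison.

## Worked example

Simulate one observer at half the study scale (250 trials per condition),
fit thresholds, and run the quasi-quadruple-pass partition for the high
disparity-contrast bin:

```r
library(doublepass)

cfg    <- design_config(repeats_per_comparison = 50L, seed = 7L)
params <- generative_params()   # study-like defaults
trials <- simulate_observer(build_design(cfg, "obs1"), params, seed = 7L)

high     <- trials[trials$contrast_bin == "high", ]
thr_flat <- fit_thresholds(high[high$experiment == "flattened", ])
thr_nat  <- fit_thresholds(high[high$experiment == "natural", ])
print(thr_nat)
#> Constrained log-linear threshold fit (natural, high bin)
#>   sigma_t = exp(-0.1382 * pedestal + -0.6837)
#>   log-likelihood: -1367.31
#>  pedestal sigma_t threshold
#>    -11.25  2.3898    2.3898
#>     -9.38  1.8455    1.8455
#>     -7.50  1.4232    1.4232
#>     -5.63  1.0990    1.0990
#>     -3.75  0.8476    0.8476

quad <- fit_quadpass(tabulate_agreement(high), thr_flat, thr_nat)
print(quad)
#> Quasi-quadruple-pass decision-variable correlations
#>  pedestal  bin rho_flat rho_nat rho_cross sigma_t_flat sigma_t_nat  loglik
#>    -11.25 high   0.4634  0.7036    0.3173       1.8810      2.3898 -473.96
#>     -9.38 high   0.6363  0.7190    0.3752       1.4370      1.8455 -419.42
#>     -7.50 high   0.5780  0.6803    0.3180       1.0963      1.4232 -498.76
#>     -5.63 high   0.4948  0.6630    0.3141       0.8375      1.0990 -495.55
#>     -3.75 high   0.4163  0.7182    0.2616       0.6389      0.8476 -463.64
```

Thresholds rise exponentially with pedestal disparity (log-linear fit), and
the natural experiment's between-pass correlation `rho_nat` exceeds the
flattened experiment's `rho_flat` in every condition: natural depth
variation makes responses *more repeatable*, not noisier. Solving the
correlations for the variance components:

```r
print(summary(quad), digits = 3)
#>   pedestal  bin sigmaL2 sigmaB2   covLB sigmaI2_flat sigmaI2_nat ...
#> 1   -11.25 high   1.639   2.805 -0.2131        1.899       1.693
#> 2    -9.38 high   1.314   1.773 -0.3189        0.751       0.957
#> 3    -7.50 high   0.695   1.080 -0.1985        0.507       0.647
#> 4    -5.63 high   0.347   0.570 -0.0579        0.354       0.407
#> 5    -3.75 high   0.170   0.403 -0.0283        0.238       0.202
```

Both stimulus-driven components grow with pedestal; the interaction
covariance stays near zero. `bootstrap_ci()` wraps any of these estimators
in trial-level percentile intervals, and `run_pipeline()` executes the whole
staged analysis (simulate → thresholds → correlations → partition) with
on-disk artifacts and a provenance manifest.

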