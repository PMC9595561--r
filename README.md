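# distractnorm

Simulation and analysis toolkit for studying how task-irrelevant
**distracters** shape perceptual choices about a **target** in
two-alternative orientation discrimination.

An observer reports whether a probed noisy grating is tilted clockwise
(CW) or counterclockwise (CCW) of a decision boundary while a second,
irrelevant grating is visible. The package implements the full analysis
pipeline for such experiments, driven entirely by synthetic data:

* **Stimulus and trial generation** — noisy Gabor patches (cosine carrier
  × Gaussian envelope, plus smoothed Gaussian pixel noise with signal and
  noise contrasts summing to 1) and trial designs with boundary-relative
  orientations θ_T, θ_D ~ U(−10°, 10°), including orthogonal-boundary and
  spatially-cued (70% validity) layouts.
* **Simulated observers** — a parametric normalization observer, an
  energy-template observer with a recoverable decision rule, and an
  accelerated stochastic-approximation **staircase** that titrates noise
  contrast to 75% accuracy.
* **Energy profiles & reverse correlation** — a 181 × 5 Gabor filter bank
  (orientations −45°…45° in 0.5° steps, 5 phases), closed-form cosine
  phase fits E·cos(φ_n − φ_max), per-bin probit **decision kernels** with
  a competitive distracter variant, and an uncentered **SVD** of the
  energy-profile matrix with automatic selection of the tilt-informative
  component.
* **Choice regressions** — the consistency-bias family

      y = β₀ + β₁ θ_T + β₂ θ_D + β₃ (θ_T · |θ_T − θ_D|)   (+ attention interactions)

  with stepwise predictor selection, distracter-binned sensitivity
  curves, stratified cross-validated likelihoods, and random-effects
  Bayesian model selection (exceedance probabilities).
* **Normalization model** — the three-parameter contextual transducer

      y = (x − ρ·μ) / (r + τ·σ),   μ = (θ_T + θ_D)/2,   σ = |θ_T − θ_D|

  fitted by seeded multistart maximum likelihood, with a reduced
  (τ = ρ = 0) variant and an attention variant in which r varies by cue
  condition, compared via cross-validated Bayesian model selection.

The methods vignette (`vignettes/distractor-normalization.Rmd`) documents
the models, the parameter choices and the recovery-experiment design.

## Worked example

```r
library(distractnorm)

cfg <- pipeline_config(design = "exp1", n_subjects = 6, n_trials = 900,
                       observer = list(r_mean = 1.5, r_sd = 0.2,
                                       tau_mean = 0.2, tau_sd = 0.05,
                                       rho_mean = 0.4, rho_sd = 0.1),
                       fit_norm = TRUE, seed = 1)
man <- run_pipeline(cfg)
round(colMeans(man$coefficients), 4)
#>   intercept     theta_T     theta_D consistency
#>     -0.0701      0.3867     -0.0382     -0.1412
```

The cohort-mean coefficients show the two distracter signatures the
pipeline is built to detect: a positive target weight (β₁ = 0.39), a
small repulsive distracter effect (β₂ = −0.04), and a negative
consistency interaction (β₃ = −0.14 on the reported /10 scale) — the
target influences choices more when target and distracter agree.
Refitting the generating transducer to the first simulated subject:

```r
fit_norm_model(man$trials[[1]], "full", seed = 1)
#> norm_fit (full), nll = 414.43
#>      r    tau    rho
#> 1.8348 0.1410 0.2870
```

recovers that subject's parameters (drawn around r = 1.5, τ = 0.2,
ρ = 0.4) to within sampling error of 900 trials. The staircase converges
to the noise contrast holding a simulated observer at the target
accuracy:

```r
run_staircase(contrast_observer(sigma_int = 3), seed = 1)
#> staircase_trace: 800 trials, 314 reversals, converged noise contrast 0.551 (target accuracy 0.75)
```

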