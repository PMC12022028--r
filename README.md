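# hiermotion

Hierarchical Bayesian causal inference for motion perception.

When several elements move in a scene, what we perceive depends on which
elements the brain groups into common reference frames: a dot that is
stationary inside a moving group is seen as carried along; a dot moving
relative to its group is seen in the group's frame, not the retina's.
`hiermotion` implements an ideal-observer model of this process for
psychophysicists and computational neuroscientists who want to fit
direction-report data or generate quantitative predictions for grouped
motion displays.

## The model in brief

A scene of *n* moving elements is explained by a **causal structure**: a
grouping tree (elements → groups → supergroups → world) plus a binary flag
per node saying whether its velocity relative to its parent frame is exactly
zero. Relative velocities have a mixture prior
`α·δ(0) + (1−α)·N(0, σ²_prior I)` — a delta at zero (stationarity from
friction) plus a slow-speed Gaussian. Velocities compose down the tree with
noise `σ_Δ`, and each element is observed with isotropic Gaussian noise.
For two elements there are 12 causal structures; for three, 264.

Because everything is linear-Gaussian given a structure, the posterior over
an element's perceived velocity is an exact mixture of Gaussians (one
component per structure). Its direction image is a von Mises mixture
(concentrations via the calibrated map `κ = T₂(σ²/‖μ‖²)`, plus a lapse
component), and reports add motor bias `b` and von Mises motor noise `κ_m`.
Four readout strategies map the posterior to a single-trial report: model
averaging, model selection, structure sampling, posterior sampling.
Response distributions marginalise observation noise by Gauss–Hermite
quadrature, which keeps the trial likelihood deterministic for fitting.

## Worked example

```r
library(hiermotion)

# 12 causal structures for a center/surround scene
length(enumerate_causal_structures(2))
#> [1] 12

# a synthetic observer on the two-element design, then a fit
truth <- cim_params(alpha_center = 0.9, alpha_surround = 0.9)
grid  <- exp1_grid(center_directions = c(0, 2.5, 5, 10, 20, 45),
                   n_patches = 10, control = FALSE)
dat   <- simulate_observer(truth, grid, trials_per_condition = 150,
                           strategy = "posterior_sampling", seed = 21)
fit   <- cim_fit(dat, "posterior_sampling", free = c("alpha", "sigma_obs"),
                 order = 3)
print(fit)
#> Causal-inference observer fit (posterior_sampling readout, MLE)
#>   900 trials, 2 free parameter group(s)
#>     alpha sigma_obs
#>    0.9425    0.2786
#>   logLik -4150.69 | AIC 8305.39

post <- sample_posterior(dat, free = "alpha", start = truth, n_chains = 2,
                         n_samples = 200, burn_in = 50, order = 3, seed = 4)
round(c(mean = unname(coef(post)["alpha"]),
        lo = unname(post$ci95[1, "alpha"]), hi = unname(post$ci95[2, "alpha"]),
        rhat = unname(post$rhat["alpha"])), 3)
#>  mean    lo    hi  rhat
#> 0.912 0.872 0.943 0.996
```

The fitted `alpha` is the recovered mass of the delta (exactly-stationary)
component of the relative-velocity prior — the MLE lands within 0.05 and the
posterior mean within 0.02 of the generating value 0.9, with the generating
value inside the 95% credible interval; `sigma_obs` is a shared observation
noise s.d. in deg/s (truth 0.3 for the center). `sample_posterior()` reports
split-R̂ and effective sample sizes alongside the draws, `aic_compare()`
ranks strategy/prior variants, and `variance_explained()` gives an absolute
goodness-of-fit.

Stimulus-side helpers cover the two standard designs (`exp1_velocities()`,
`exp2_velocities()`), the modulation index summarising surround influence
(`modulation_percept()`, `invert_modulation_index()`, and the noise-aware
`infer_modulation_index()`), report preprocessing and observer QC.

A command-line interface wraps the same functions:

```sh
inst/cli/hiermotion structures --n 3 --count      # 264
inst/cli/hiermotion simulate --seed 7 --out trials.csv
inst/cli/hiermotion fit --trials trials.csv --out fit.json
```

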