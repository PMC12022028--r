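---
title: "Hierarchical causal inference for motion perception: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical causal inference for motion perception: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiermotion)
```

## The model

When several elements move in a visual scene, the brain must decide which of
them share a reference frame before it can decide how each one moves. This
package implements an ideal-observer account of that problem: motion
perception as joint Bayesian inference over *causal structures* — which
elements group together, which groups nest inside supergroups — and over the
velocities expressed within those structures.

A **grouping tree** has the scene's elements as leaves, inferred groups as
internal nodes, and the stationary world as the implicit root. A **causal
structure** adds one binary flag per node stating whether that node's
velocity *relative to its parent frame* is exactly zero or not. Relative
velocities carry a mixture prior

\[
\vec v_{\mathrm{rel}} \sim \alpha\,\delta(0) + (1-\alpha)\,
\mathcal N(0, \sigma_{\mathrm{prior}}^2 \mathbb I),
\]

a delta component at zero (in the world, touching things are mostly *exactly*
stationary relative to each other, because of friction) plus a zero-mean
Gaussian slow-speed component. Each node's absolute velocity is its parent's
velocity plus its own relative velocity plus isotropic composition noise
$\sigma_\Delta$; element velocities are observed with role-specific isotropic
Gaussian noise ($\sigma_{\mathrm{center}}$, $\sigma_{\mathrm{surround}}$).
The prior probability that elements share a structure is $\beta$.

An element's *percept* is the relative velocity at the lowest flagged-moving
node on its path to the world (or zero velocity if there is none). Because
every conditional is linear-Gaussian, the posterior over the percept given
the stacked observations is an **exact mixture of isotropic Gaussians**, one
component per causal structure, with weights equal to the structure
posterior. The direction image of that mixture is a von Mises mixture: mean
directions from the two-argument arctangent of the component means,
concentrations from a calibrated map $\kappa = T_2(\sigma^2/\lVert\mu\rVert^2)$,
plus a lapse component (weight $\lambda$). Reports add a motor bias $b$ and
von Mises motor noise $\kappa_m$.

## The tree grammar

The enumeration grammar is the one design choice the printed structure counts
can falsify, so it is implemented as a configurable rule-set
(`grammar_rules()`) and frozen at the variant that reproduces the known
counts — 2 structures for one element, 12 for two, 264 for three:

* a group node normally has at least two children;
* a singleton group (an element promoted to its own reference frame) is
  admitted only directly under the world, and only in scenes that already
  contain at least one multi-element group;
* chain groups (a group whose only child is a group) are never admitted.

```{r counts}
sapply(1:3, function(n) length(enumerate_causal_structures(n)))
```

Under this rule-set the three-element scene has 11 grouping trees. The
maximum node count is 5, which stays below the loose bound $n(n+1)/2 = 6$
used in the combinatorial cap $T(n)\,2^{n(n+1)/2}$; the enumeration count is
always checked against that cap. Alternative rule-sets (e.g. admitting
nested singleton groups) are one constructor argument away, and the unit
tests pin the default to the published counts.

For three-level scenes the full 264-structure posterior is expensive inside
nested fitting loops, which motivates the **pure structure** filter
(`is_pure()`): structures in which every group has at least one stationary
member. These anchor the interpretable extremes; the remaining structures
produce percepts in between.

## Inference implementation

Per structure, the stacked per-axis observations are jointly zero-mean
Gaussian with covariance assembled from shared ancestor paths (each common
ancestor contributes its flag times $\sigma_{\mathrm{prior}}^2$ plus one
$\sigma_\Delta^2$ composition term; observation noise on the diagonal). The
x and y axes are independent scalar chains sharing one covariance, so
marginal likelihoods multiply across axes and percept conditionals follow
from conjugate conditioning. We deliberately use dense per-structure
covariance algebra rather than message passing: for the supported scene
sizes (up to four elements) the matrices are at most $4\times4$, the dense
form is exact, easier to audit, and vectorises over thousands of quadrature
nodes or simulated trials in single matrix products. Structure weights are
kept in the log domain and normalised by log-sum-exp (the weight sum is
checked to $10^{-10}$).

The tree prior generalises $\beta$ beyond two elements as
$p(\mathrm{tree}) \propto \beta^{g}(1-\beta)^{g_{\max}-g}$ with $g$ the
number of group nodes; for two elements this reduces exactly to
$\beta$ vs $1-\beta$ for the grouped and independent trees. This is a
package design choice — any normalised tree prior could be substituted — and
it only matters for scenes with more than two elements, which are outside
the quantitative fitting surface.

## The $T_2$ calibration

The direction distribution implied by an isotropic Gaussian velocity is not
von Mises; it is approximated by one whose concentration depends only on the
ratio $r = \sigma^2/\lVert\mu\rVert^2$. `calibrate_t2()` tabulates the map by
Monte Carlo (default: 71 log-spaced ratios from $10^{-4}$ to $10^{3}$,
$2\times10^4$ samples each, fixed seed), fitting each ratio by matching the
mean resultant length through the inverse of $A(\kappa)=I_1(\kappa)/I_0(\kappa)$.
Numerical guards, all documented on the object: ratios floored at $10^{-8}$,
concentrations capped at $10^4$ (Bessel stability), the tabulated curve made
strictly decreasing before interpolation, and log–log linear interpolation
with tail extrapolation (the analytic tail is $\kappa \propto r^{-1/2}$).
Stationary percepts have $\lVert\mu\rVert = 0$: their direction is undefined,
and rather than dropping that posterior mass we assign $\kappa = 0$ (uniform
on the circle), the $r \to \infty$ limit of $T_2$.

## Readout strategies and response distributions

Four linking hypotheses map the direction mixture to a single-trial
estimate: **model averaging** (mean of the joint posterior), **model
selection** (mean direction of the highest-weight component; ties broken by
lowest component index — a measure-zero event), **structure sampling** (a
component drawn by weight), and **posterior sampling** (a draw from the full
mixture). Averaging is implemented as the *circular* mean — the argument of
the resultant $\sum_i w_i A(\kappa_i) e^{i\theta_i}$ — which is the
well-defined circular version of the posterior-mean readout and agrees with
a literal weighted sum of mean directions away from wrap-around.

The lapse lives inside the direction mixture as component 0, so lapses arise
naturally under the sampling readouts and no separate lapse stage is applied
at simulation time (no double counting). With a uniform lapse
($\kappa_{\mathrm{lapse}} = 0$, the default) the lapse contributes nothing to
the circular mean, so the averaging readout is unaffected by it.

Predicted response distributions marginalise over sensory observations with
product Gauss–Hermite quadrature (default 7 nodes per scalar dimension, four
dimensions for two elements; a unit test checks that order 7 agrees with
order 9 to better than $10^{-3}$ log-likelihood per trial on the two-element
geometry). For the point-estimate readouts each node contributes one motor
von Mises; for the sampling readouts the node's estimate is itself a
distribution, convolved with the motor von Mises analytically by composing
concentrations through resultant-length multiplication
($A(\kappa_{12}) = A(\kappa_1)A(\kappa_2)$). A test measures this
approximation against numeric circular convolution (sup-CDF error below
0.015 across representative concentration pairs); the convolution keeps the
likelihood deterministic, so optimisation is well-posed for every strategy.
Beyond three elements the product rule would exceed six dimensions and the
code raises, pointing to the Monte-Carlo path (`simulate_responses()`).

## What the synthetic observer emulates

`simulate_observer()` is the package's study-condition generator: the
two-element design with the surround moving rightwards at 1 deg/s, center
directions from $\{0, \pm2.5, \pm5, \pm10, \pm20, \pm45\}^\circ$ with the
horizontal velocity component matched to the surround (so the relative
velocity is exactly vertical), surround patch counts from
$\{1, 2, 3, 5, 10\}$, and a stationary-surround control. Surround
observation noise is scaled by $1/\sqrt{k}$ with $k$ the patch count,
encoding that more patches give a more reliable surround signal.

Default observer parameters were chosen once as plausible values for this
task and are not tuned: $\alpha = 0.9$ for all roles (most prior mass in the
delta component), $\sigma_{\mathrm{prior}} = 1$ deg/s (matching the stimulus
speed scale), $\sigma_\Delta = 0.1$ deg/s, $\sigma_{\mathrm{center}} = 0.3$
and $\sigma_{\mathrm{surround}} = 0.1$ deg/s (the surround is the more
reliable signal), $\beta = 0.5$, $\lambda = 0.02$ with a uniform lapse,
$b = 0$, and $\kappa_m = 67$ (about $7^\circ$ of circular motor scatter).

The generator reproduces the model's own assumptions — Gaussian observation
noise, structure-conditional percepts, von Mises motor noise, lapses — and
nothing else. Real observers bring eye movements, color and spatial
segmentation cues, report biases that depend on the dial, and sequential
effects, none of which are modelled. Passing recovery and self-consistency
tests therefore certifies the inference/fitting machinery, not the model's
adequacy for any particular human dataset.

## Fitting

`cim_fit()` maximises the likelihood (or posterior, `method = "map"`) by
BFGS on transformed parameters: log standard deviations and concentrations,
logit probabilities, untransformed angles. Tie aliases fit one shared value
for all delta masses (`"alpha"`) or both observation noises
(`"sigma_obs"`). Non-convergence and boundary solutions (transformed values
beyond $\pm12$) are flagged on the result, never raised — degenerate inputs
such as zero-variance reports give a flagged, finite-AIC fit.

`sample_posterior()` uses slice-sampling-within-Gibbs on the same
transformed scale. Any correct sampler satisfies the contract here;
slice sampling was chosen because it is tuning-free and robust for the low
dimensionalities involved. Convergence is summarised by split-$\hat R$
(warning flag above 1.1) and an effective-sample-size estimate from
Geyer-truncated autocorrelations. Default priors are weakly informative and
overridable: Beta(1,1) on probabilities, half-normal (scale 5 deg/s) on
standard deviations, uniform on circular means, log-normal (meanlog 3,
sdlog 2) on concentrations.

Because the delta masses, $\beta$ and the lapse rate enter the likelihood
only through mixture *weights*, a cached likelihood path precomputes the
quadrature, per-structure Gaussian marginals and the report-by-component von
Mises density matrix once, reducing each evaluation to a reweighting and one
matrix–vector product. This is what makes desk-scale MCMC over $\alpha$
cheap; fits that free noise parameters use the general path.

Model comparison uses AIC ($2k - 2\log L$ at the MLE) via `aic_compare()`,
which refuses to compare fits on non-identical data. Absolute goodness of
fit is summarised as variance explained: per condition, the model response
CDF evaluated at the sorted reports against the empirical CDF levels, pooled
as $100(1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}})$. Bootstrap p-values follow
the conservative $(t+1)/(N+2)$ convention (the posterior mean under a
uniform prior given $t$ exceedances in $N$ resamples).

## Problem sizes used in the checks

The test-suite and reproduction scripts run at desk scale, chosen as the
smallest sizes at which each check is statistically meaningful: the
importance-sampling oracle uses $10^6$ particles on two-element scenes;
distributional self-consistency uses $10^4$ simulated trials per
strategy/condition (KS threshold 0.02); parameter recovery uses 20 synthetic
observers of 2000 trials each on the 11-direction grid with a reduced MCMC
budget (2 chains, 150 kept samples after 50 burn-in — the $\alpha$ posterior
is one-dimensional and mixes essentially instantly under slice sampling);
the factorial strategy-by-prior AIC comparison uses 3 replicates of 720
trials. The full published-scale budgets (e.g. 144 chains of 25000 samples)
remain available through the same function arguments.

## Known limitations

* Enumeration is exact only up to four elements; larger scenes need a
  structure-search strategy that is out of scope here.
* The Gaussian slow-speed component implies a Rayleigh speed prior; data at
  high speeds may prefer heavier tails.
* The von Mises approximations ($T_2$ and the convolution rule) are
  excellent at the concentrations this task produces but are approximations;
  both are bounded by tests rather than assumed.
* The world node is fixed at zero velocity (stationary observer); self-motion
  extensions would free that level.
* Quantitative fitting of the full 264-structure, three-element model is
  supported in the likelihood machinery but computationally heavy; the pure
  structure filter is the intended approximation there.
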