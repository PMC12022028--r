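#' Stimulus condition
#'
#' Experimenter-defined retinal velocities per element, plus element roles
#' and an optional per-element observation-noise scale (e.g. to model the
#' higher reliability of a surround made of many patches).
#'
#' @param nu n x 2 matrix (or length-2 vector for one element) of retinal
#'   velocities (deg/s).
#' @param label condition label (string) used to match trials to conditions.
#' @param roles element roles; element 1 is the report target.
#' @param sigma_scale per-element multiplier on the role observation noise.
#' @return object of class `"stimulus_condition"`.
#' @export
stimulus_condition <- function(nu, label = NULL,
                               roles = default_roles(nrow(rbind(nu))),
                               sigma_scale = 1) {
  nu <- rbind(nu)
  stopifnot(is.numeric(nu), ncol(nu) == 2L, all(is.finite(nu)),
            length(roles) == nrow(nu))
  if (is.null(label))
    label <- paste(apply(round(nu, 6), 1, paste, collapse = ","), collapse = ";")
  structure(list(nu = nu, label = label, roles = roles,
                 sigma_scale = rep_len(sigma_scale, nrow(nu))),
            class = "stimulus_condition")
}

cond_sigma_obs <- function(cond, params) {
  sigma_for_role(params, cond$roles) * cond$sigma_scale
}

.strategies <- c("averaging", "selection", "structure_sampling",
                 "posterior_sampling")

#' Single-trial perceptual point estimate
#'
#' Converts a direction mixture into a single perceived direction under one
#' of four readout strategies: `averaging` (circular mean of the mixture),
#' `selection` (mean direction of the highest-weight component; ties broken
#' by lowest component index), `structure_sampling` (mean direction of a
#' component drawn proportionally to its weight) and `posterior_sampling`
#' (a draw from the full mixture density).
#'
#' @param dm a [direction_mixture()].
#' @param strategy one of `"averaging"`, `"selection"`,
#'   `"structure_sampling"`, `"posterior_sampling"`.
#' @param seed optional seed (sampling strategies).
#' @return direction estimate in degrees.
#' @export
point_estimate <- function(dm, strategy = .strategies, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  switch(strategy,
    averaging = vm_mixture_circular_mean(dm$w, dm$theta, dm$kappa),
    selection = dm$theta[which.max(dm$w)],
    structure_sampling = dm$theta[sample.int(length(dm$w), 1L, prob = dm$w)],
    posterior_sampling = {
      i <- sample.int(length(dm$w), 1L, prob = dm$w)
      rvonmises_deg(1, dm$theta[i], dm$kappa[i])
    })
}

## Gauss-Hermite product quadrature over the observation noise around nu.
## Returns Ox, Oy (N x n) and normalised weights w (length N).
gh_observation_nodes <- function(nu, sigma_obs, order) {
  n <- nrow(nu)
  ndim <- 2L * n
  if (ndim > 6L)
    stop("product quadrature unsupported beyond 6 dimensions (3 elements); ",
         "use the Monte-Carlo fallback via simulate_responses()")
  gh <- pracma::gaussHermite(order)
  grids <- rep(list(seq_len(order)), ndim)
  idx <- as.matrix(do.call(expand.grid, grids))
  W <- matrix(gh$w[idx], nrow(idx), ndim)
  w <- apply(W, 1L, prod) / pi^(ndim / 2)
  X <- matrix(gh$x[idx], nrow(idx), ndim)
  Ox <- sweep(X[, seq_len(n), drop = FALSE] * sqrt(2), 2, sigma_obs, "*")
  Oy <- sweep(X[, n + seq_len(n), drop = FALSE] * sqrt(2), 2, sigma_obs, "*")
  Ox <- sweep(Ox, 2, nu[, 1], "+")
  Oy <- sweep(Oy, 2, nu[, 2], "+")
  list(Ox = Ox, Oy = Oy, w = w / sum(w))
}

## per-observation direction-mixture arrays (lapse prepended as column 1)
## from batched inference output
batch_direction_arrays <- function(mb, t2, params) {
  W <- normalise_logw(mb$logW)
  TH <- wrap_deg(rad2deg(atan2(mb$My, mb$Mx)))
  speed2 <- mb$Mx^2 + mb$My^2
  ratio <- sweep(1 / pmax(speed2, .Machine$double.xmin), 2, mb$sigma2, "*")
  ratio[speed2 == 0] <- Inf
  KP <- matrix(t2_kappa(t2, ratio), nrow(ratio), ncol(ratio))
  lam <- params$lambda_lapse
  list(W = cbind(lam, (1 - lam) * W),
       TH = cbind(wrap_deg(params$theta_lapse), TH),
       KP = cbind(params$kappa_lapse, KP))
}

## strategy-specific per-observation estimate machinery, vectorised over rows
batch_point_estimates <- function(arr, strategy) {
  N <- nrow(arr$W)
  switch(strategy,
    averaging = {
      A <- matrix(vm_A(arr$KP), N, ncol(arr$KP))
      rx <- rowSums(arr$W * A * cos(deg2rad(arr$TH)))
      ry <- rowSums(arr$W * A * sin(deg2rad(arr$TH)))
      wrap_deg(rad2deg(atan2(ry, rx)))
    },
    selection = {
      imax <- max.col(arr$W, ties.method = "first")
      arr$TH[cbind(seq_len(N), imax)]
    },
    structure_sampling = {
      i <- .rowwise_categorical(arr$W)
      arr$TH[cbind(seq_len(N), i)]
    },
    posterior_sampling = {
      i <- .rowwise_categorical(arr$W)
      rvonmises_deg(N, arr$TH[cbind(seq_len(N), i)],
                    arr$KP[cbind(seq_len(N), i)])
    })
}

## one categorical draw per row of a weight matrix (inverse-CDF, vectorised)
.rowwise_categorical <- function(W) {
  C <- t(apply(W, 1L, cumsum))
  u <- stats::runif(nrow(W)) * C[, ncol(C)]
  rowSums(C < u) + 1L
}

#' Predicted response distribution for a stimulus condition
#'
#' Marginalises the full inference-to-report pipeline over sensory
#' observations with product Gauss-Hermite quadrature: at each quadrature
#' node the posterior percept mixture, its von Mises direction image, and the
#' readout strategy produce a motor-noise von Mises contribution centred at
#' the estimate plus the motor bias. For point-estimate strategies
#' (averaging, selection) each node contributes a single von Mises; for the
#' sampling strategies the node's estimate is itself a distribution, which is
#' convolved with the motor von Mises analytically (concentrations composed
#' by resultant-length multiplication), keeping the likelihood deterministic.
#'
#' @param cond a [stimulus_condition()].
#' @param params [cim_params()].
#' @param strategy readout strategy, see [point_estimate()].
#' @param order Gauss-Hermite nodes per scalar dimension (>= 3, default 7).
#' @param t2 T2 calibration table.
#' @param rules grammar rule-set.
#' @return object of class `"cim_response"`: a von Mises mixture over reports
#'   with fields `w`, `theta`, `kappa` and quadrature metadata.
#' @export
response_distribution <- function(cond, params, strategy = .strategies,
                                  order = 7, t2 = default_t2(),
                                  rules = grammar_rules()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cond, "stimulus_condition"), order >= 3)
  n <- nrow(cond$nu)
  sig <- cond_sigma_obs(cond, params)
  q <- gh_observation_nodes(cond$nu, sig, order)
  structures <- scene_structures(n, rules)
  pre <- structure_precompute(structures, params, sig, 1L, cond$roles)
  mb <- mixture_batch(q$Ox, q$Oy, pre)
  arr <- batch_direction_arrays(mb, t2, params)
  b <- params$motor_bias; km <- params$kappa_motor
  if (strategy %in% c("averaging", "selection")) {
    est <- batch_point_estimates(arr, strategy)
    comps <- list(w = q$w, theta = wrap_deg(est + b), kappa = rep(km, length(est)))
  } else {
    wfull <- sweep(arr$W, 1, q$w, "*")
    kap <- if (strategy == "posterior_sampling") {
      matrix(vm_conv_kappa(arr$KP, km), nrow(arr$KP), ncol(arr$KP))
    } else matrix(km, nrow(arr$KP), ncol(arr$KP))
    comps <- list(w = as.vector(wfull),
                  theta = wrap_deg(as.vector(arr$TH) + b),
                  kappa = as.vector(kap))
  }
  keep <- comps$w > 0
  structure(list(w = comps$w[keep], theta = comps$theta[keep],
                 kappa = comps$kappa[keep],
                 condition = cond, strategy = strategy, order = order,
                 n_nodes = length(q$w)),
            class = "cim_response")
}

#' Log density of a predicted response distribution
#' @param rd a `cim_response`.
#' @param theta reported directions (deg), vectorised.
#' @return log density per degree.
#' @export
response_log_density <- function(rd, theta) {
  log(vm_mixture_density(theta, rd$w, rd$theta, rd$kappa))
}

## chunked von Mises mixture density (per degree); linear-space accumulation
vm_mixture_density <- function(theta, w, mu, kappa, chunk = 4000L) {
  dens <- numeric(length(theta))
  th <- deg2rad(theta)
  coef <- w / (360 * besselI(kappa, 0, expon.scaled = TRUE))
  for (s in seq(1L, length(w), by = chunk)) {
    j <- s:min(s + chunk - 1L, length(w))
    D <- outer(th, deg2rad(mu[j]), "-")
    dens <- dens + drop(exp(sweep(cos(D) - 1, 2, kappa[j], "*")) %*% coef[j])
  }
  dens
}

#' CDF of a predicted response distribution
#'
#' Circular CDF on `[0, 360)` anchored at 0 degrees, computed once on a fine
#' grid (trapezoid rule) and linearly interpolated.
#'
#' @param rd a `cim_response`.
#' @param theta report values (deg).
#' @param grid_step grid resolution in degrees.
#' @return CDF values in `[0, 1]`.
#' @export
response_cdf <- function(rd, theta, grid_step = 0.25) {
  grid <- seq(0, 360, by = grid_step)
  dens <- vm_mixture_density(grid, rd$w, rd$theta, rd$kappa)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * grid_step))
  cum <- cum / cum[length(cum)]
  stats::approx(grid, cum, xout = wrap_deg(theta), rule = 2)$y
}

#' @export
print.cim_response <- function(x, ...) {
  cat(sprintf(
    "Predicted response distribution (%s readout)\n  condition: %s\n  %d von Mises components from %d quadrature nodes (order %d)\n",
    x$strategy, x$condition$label, length(x$w), x$n_nodes, x$order))
  cm <- vm_mixture_circular_mean(x$w, x$theta, x$kappa)
  cat(sprintf("  circular mean: %.2f deg\n", cm))
  invisible(x)
}

#' @export
plot.cim_response <- function(x, n = 721, ...) {
  grid <- seq(0, 360, length.out = n)
  graphics::plot(grid, vm_mixture_density(grid, x$w, x$theta, x$kappa),
                 type = "l", xlab = "reported direction (deg)",
                 ylab = "density (per deg)",
                 main = sprintf("%s | %s", x$condition$label, x$strategy), ...)
  invisible(x)
}

#' Simulate trial-level responses (synthetic observer)
#'
#' Full forward pass per trial: observations are sampled around the condition
#' velocities, the posterior percept mixture and its direction image are
#' computed, a point estimate is read out under the chosen strategy (lapses
#' arise through the lapse component of the mixture), and motor bias plus von
#' Mises motor noise are added. Seeded and reproducible.
#'
#' @inheritParams response_distribution
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed.
#' @return numeric vector of reported directions in `[0, 360)`.
#' @export
simulate_responses <- function(cond, params, strategy = .strategies,
                               n_trials, seed = NULL, t2 = default_t2(),
                               rules = grammar_rules()) {
  strategy <- match.arg(strategy)
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cond$nu)
  sig <- cond_sigma_obs(cond, params)
  Ox <- matrix(stats::rnorm(n_trials * n, rep(cond$nu[, 1], each = n_trials),
                            rep(sig, each = n_trials)), n_trials, n)
  Oy <- matrix(stats::rnorm(n_trials * n, rep(cond$nu[, 2], each = n_trials),
                            rep(sig, each = n_trials)), n_trials, n)
  structures <- scene_structures(n, rules)
  pre <- structure_precompute(structures, params, sig, 1L, cond$roles)
  mb <- mixture_batch(Ox, Oy, pre)
  arr <- batch_direction_arrays(mb, t2, params)
  est <- batch_point_estimates(arr, strategy)
  wrap_deg(est + params$motor_bias +
             rvonmises_deg(n_trials, 0, params$kappa_motor))
}
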