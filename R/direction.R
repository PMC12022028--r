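## Circular helpers. Degrees at every external boundary (0 deg = rightward,
## counter-clockwise positive), radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

wrap_deg <- function(x) x %% 360

## log I0 via exponentially scaled Bessel, stable for kappa up to ~1e4+
log_bessel_i0 <- function(kappa) log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa

## mean resultant length A(kappa) = I1(kappa) / I0(kappa)
vm_A <- function(kappa) {
  r <- ifelse(kappa <= 0, 0,
              besselI(kappa, 1, expon.scaled = TRUE) /
                besselI(kappa, 0, expon.scaled = TRUE))
  r[kappa > 1e7] <- 1 - 1 / (2 * kappa[kappa > 1e7])
  r
}

## invert A(kappa) = R: Fisher (1993) starting approximation polished by
## Newton steps on A(kappa) - R
vm_A_inv <- function(R, kappa_max = 1e4) {
  R <- pmin(pmax(R, 0), 1 - 1e-12)
  k <- ifelse(R < 0.53, 2 * R + R^3 + 5 * R^5 / 6,
       ifelse(R < 0.85, -0.4 + 1.39 * R + 0.43 / (1 - R),
              1 / (R^3 - 4 * R^2 + 3 * R)))
  k <- pmin(pmax(k, 1e-8), kappa_max)
  for (it in 1:4) {
    A <- vm_A(k)
    dA <- pmax(1 - A^2 - A / pmax(k, 1e-12), 1e-12)  # A'(k)
    k <- k - (A - R) / dA
    k <- pmin(pmax(k, 1e-8), kappa_max)
  }
  k
}

#' Von Mises log density over degrees
#'
#' Density per degree (integrates to 1 over `[0, 360)`), numerically stable
#' for concentrations up to the package cap of 1e4.
#'
#' @param theta,mu angles in degrees.
#' @param kappa concentration (>= 0; 0 gives the uniform circle, 1/360 per
#'   degree).
#' @param log return log density?
#' @return density values (recycled over inputs).
#' @export
dvonmises_deg <- function(theta, mu, kappa, log = FALSE) {
  d <- deg2rad(theta - mu)
  ld <- kappa * (cos(d) - 1) - log(besselI(kappa, 0, expon.scaled = TRUE)) -
    base::log(360)
  if (log) ld else exp(ld)
}

#' Von Mises random draws (degrees)
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` draws uniformly.
#' @param n number of draws.
#' @param mu mean direction (deg).
#' @param kappa concentration (scalar or length-n).
#' @return angles in `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu, kappa) {
  mu <- rep_len(mu, n); kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-8
  out[unif] <- stats::runif(sum(unif), 0, 360)
  idx <- which(!unif)
  if (length(idx)) {
    k <- kappa[idx]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(length(idx)); todo <- seq_along(idx)
    while (length(todo)) {
      m <- length(todo)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[todo] * z) / (r[todo] + z)
      cc <- k[todo] * (r[todo] - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      th[todo[ok]] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      todo <- todo[!ok]
    }
    out[idx] <- rad2deg(th)
  }
  wrap_deg(out + mu)
}

#' Calibrate the variance-ratio to concentration map T2
#'
#' The direction of a 2-D velocity with isotropic Gaussian uncertainty is
#' approximated by a von Mises distribution whose concentration depends only
#' on the ratio `r = sigma^2 / ||mu||^2`. The map is calibrated by Monte
#' Carlo: for each grid ratio, 2-D Gaussian samples around `(1, 0)` with
#' variance `r` per axis are converted to angles and a von Mises fit is
#' obtained by matching the mean resultant length (inverting
#' `A(kappa) = I1/I0`). Ratios are floored at 1e-8 and concentrations capped
#' at 1e4 for numerical safety; the tabulated curve is made strictly
#' decreasing before building the (log-log linear) interpolator.
#'
#' @param ratios grid of variance-to-squared-speed ratios (> 0); default a
#'   log-spaced grid from 1e-4 to 1e3.
#' @param n_mc Monte Carlo samples per ratio (>= 1e4).
#' @param seed integer seed recorded in the table.
#' @return object of class `"t2_table"`.
#' @export
calibrate_t2 <- function(ratios = 10^seq(-4, 3, length.out = 71),
                         n_mc = 2e4, seed = 1L) {
  stopifnot(all(ratios > 0), n_mc >= 1e4)
  ratios <- sort(pmax(ratios, 1e-8))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  kappa <- vapply(ratios, function(r) {
    x <- stats::rnorm(n_mc, 1, sqrt(r))
    y <- stats::rnorm(n_mc, 0, sqrt(r))
    Rbar <- sqrt(mean(cos(atan2(y, x)))^2 + mean(sin(atan2(y, x)))^2)
    vm_A_inv(Rbar)
  }, numeric(1))
  kappa <- pmin(kappa, 1e4)
  # drop the noise-dominated far tail: the mean resultant length has an
  # upward bias of order 1/sqrt(n_mc) even for uniform angles, which flattens
  # the tabulated curve there; the analytic tail (kappa ~ r^(-1/2)) takes
  # over in t2_kappa() beyond the last reliable grid point
  kfloor <- 20 / sqrt(n_mc)
  last_ok <- match(TRUE, kappa <= kfloor, nomatch = length(kappa) + 1L) - 1L
  last_ok <- max(last_ok, 2L)
  ratios <- ratios[seq_len(last_ok)]
  kappa <- kappa[seq_len(last_ok)]
  # enforce strict monotone decrease against residual MC jitter
  kappa <- cummin(kappa)
  for (i in seq_along(kappa)[-1])
    if (kappa[i] >= kappa[i - 1]) kappa[i] <- kappa[i - 1] * (1 - 1e-9)
  structure(list(ratio = ratios, kappa = kappa,
                 log_ratio = log(ratios), log_kappa = log(kappa),
                 n_mc = n_mc, seed = seed, kappa_cap = 1e4),
            class = "t2_table")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate a T2 table
#'
#' Log-log linear interpolation of the calibrated concentration curve;
#' log-log linear extrapolation beyond the grid (the tail is kappa ~
#' r^(-1/2)), with the documented cap `kappa <= 1e4` and ratio floor 1e-8.
#'
#' @param t2 a `t2_table`.
#' @param ratio variance-to-squared-speed ratios (vectorised). Infinite or
#'   `NaN` ratios (zero-mean components) map to `kappa = 0`.
#' @return concentrations (same length as `ratio`).
#' @export
t2_kappa <- function(t2, ratio) {
  stopifnot(inherits(t2, "t2_table"))
  out <- numeric(length(ratio))
  zero_mean <- !is.finite(ratio)
  r <- pmax(ratio[!zero_mean], 1e-8)
  lr <- log(r)
  n <- length(t2$log_ratio)
  # linear interp with linear extrapolation in log-log space
  lk <- stats::approx(t2$log_ratio, t2$log_kappa, xout = lr, rule = 2)$y
  lo <- lr < t2$log_ratio[1]
  if (any(lo)) {
    sl <- (t2$log_kappa[2] - t2$log_kappa[1]) / (t2$log_ratio[2] - t2$log_ratio[1])
    lk[lo] <- t2$log_kappa[1] + sl * (lr[lo] - t2$log_ratio[1])
  }
  hi <- lr > t2$log_ratio[n]
  if (any(hi)) {
    # analytic tail: kappa ~ 2 Rbar and Rbar ~ (pi / (4 r))^(1/2), so the
    # log-log slope is exactly -1/2 beyond the calibrated range
    lk[hi] <- t2$log_kappa[n] - 0.5 * (lr[hi] - t2$log_ratio[n])
  }
  out[!zero_mean] <- pmin(exp(lk), t2$kappa_cap)
  out[zero_mean] <- 0
  out
}

#' @export
print.t2_table <- function(x, ...) {
  cat(sprintf(
    "T2 calibration table: %d ratios in [%.2g, %.2g], %d MC samples each (seed %d)\n",
    length(x$ratio), min(x$ratio), max(x$ratio), x$n_mc, x$seed))
  invisible(x)
}

.t2_default_cache <- new.env(parent = emptyenv())

#' Package-default T2 table (cached)
#' @return a `t2_table` calibrated with the default grid and seed.
#' @export
default_t2 <- function() {
  if (is.null(.t2_default_cache$t2)) .t2_default_cache$t2 <- calibrate_t2()
  .t2_default_cache$t2
}

#' Map a percept mixture to a von Mises direction mixture
#'
#' Each velocity-space Gaussian component maps to a von Mises component:
#' mean direction from the two-argument arctangent of the component mean,
#' concentration from the T2 calibration of the variance-to-squared-speed
#' ratio. Stationary (zero-mean) components get concentration 0 (uniform on
#' the circle), preserving their mass. The lapse component is prepended at
#' index 1 with weight `lambda_lapse`, all other weights scaled by
#' `1 - lambda_lapse`.
#'
#' @param pm a [percept_mixture()].
#' @param t2 a `t2_table` (default: [default_t2()]).
#' @param params [cim_params()] (lapse parameters).
#' @return object of class `"direction_mixture"`: list with `w`, `theta`
#'   (deg), `kappa`; component 1 is the lapse.
#' @export
direction_mixture <- function(pm, t2 = default_t2(), params) {
  stopifnot(inherits(pm, "percept_mixture"))
  speed2 <- pm$mu[, 1]^2 + pm$mu[, 2]^2
  ratio <- ifelse(speed2 > 0, pm$sigma2 / speed2, Inf)
  kap <- t2_kappa(t2, ratio)
  th <- wrap_deg(rad2deg(atan2(pm$mu[, 2], pm$mu[, 1])))
  lam <- params$lambda_lapse
  structure(list(w = c(lam, (1 - lam) * pm$w),
                 theta = c(wrap_deg(params$theta_lapse), th),
                 kappa = c(params$kappa_lapse, kap)),
            class = "direction_mixture")
}

#' Log density of a direction mixture
#'
#' Von Mises mixture density per degree; integrates to 1 over the circle.
#'
#' @param dm a `direction_mixture`.
#' @param theta angles in degrees (vectorised).
#' @return log densities.
#' @export
mixture_log_density <- function(dm, theta) {
  vm_mixture_log_density(theta, dm$w, dm$theta, dm$kappa)
}

## shared mixture evaluator: components (w, mu, kappa), query angles theta
vm_mixture_log_density <- function(theta, w, mu, kappa) {
  keep <- w > 0
  w <- w[keep]; mu <- mu[keep]; kappa <- kappa[keep]
  D <- deg2rad(outer(theta, mu, "-"))
  lbi <- log(besselI(kappa, 0, expon.scaled = TRUE))
  L <- sweep(cos(D) - 1, 2, kappa, "*")
  L <- sweep(L, 2, log(w) - lbi, "+") - base::log(360)
  m <- apply(L, 1L, max)
  m + log(rowSums(exp(L - m)))
}

#' @export
print.direction_mixture <- function(x, top = 5, ...) {
  cat(sprintf("Direction mixture: %d components (component 1 = lapse)\n",
              length(x$w)))
  ord <- order(x$w, decreasing = TRUE)[seq_len(min(top, length(x$w)))]
  print(data.frame(w = x$w[ord], theta = x$theta[ord], kappa = x$kappa[ord]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

## circular mean (deg) of a von Mises mixture; resultant of each component
## is A(kappa) e^{i theta}
vm_mixture_circular_mean <- function(w, theta, kappa) {
  A <- vm_A(kappa)
  cx <- sum(w * A * cos(deg2rad(theta)))
  cy <- sum(w * A * sin(deg2rad(theta)))
  if (cx == 0 && cy == 0) return(0)
  wrap_deg(rad2deg(atan2(cy, cx)))
}

## approximate concentration of the circular convolution of two von Mises
## densities: A(k) = A(k1) A(k2)
vm_conv_kappa <- function(k1, k2) {
  vm_A_inv(vm_A(k1) * vm_A(k2))
}
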