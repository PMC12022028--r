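test_that("T2 calibration is monotone with the documented limits", {
  t2 <- test_t2()
  expect_true(all(diff(t2$kappa) < 0))
  expect_true(all(t2_kappa(t2, c(1e-7, 0.1, 10, 1e6)) >= 0))
  expect_equal(t2_kappa(t2, 1e-8), 1e4)           # cap at the ratio floor
  expect_lt(t2_kappa(t2, 1e6), 0.01)              # directions become uniform
  # interpolation is monotone between grid points
  r <- 10^seq(-3.9, 2.9, length.out = 200)
  expect_true(all(diff(t2_kappa(t2, r)) <= 0))
})

test_that("T2 agrees with an independent brute-force fit at r = 0.25", {
  t2 <- test_t2()
  set.seed(99)
  x <- rnorm(1e6, 1, 0.5); y <- rnorm(1e6, 0, 0.5)
  th <- atan2(y, x)
  Rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  kappa_bf <- hiermotion:::vm_A_inv(Rbar)
  expect_equal(t2_kappa(t2, 0.25), kappa_bf, tolerance = 0.02)
})

test_that("direction mixtures map means, lapses and stationary mass correctly", {
  p <- cim_params(lambda_lapse = 0.1, theta_lapse = 180, kappa_lapse = 2)
  pm <- structure(list(w = c(0.6, 0.4), mu = rbind(c(1, 1), c(0, 0)),
                       sigma2 = c(0.05, 0), structure_id = 1:2, element = 1L),
                  class = "percept_mixture")
  dm <- direction_mixture(pm, test_t2(), p)
  expect_equal(dm$w, c(0.1, 0.9 * 0.6, 0.9 * 0.4))
  expect_equal(dm$theta[1], 180)
  expect_equal(dm$kappa[1], 2)
  expect_equal(dm$theta[2], 45)
  expect_equal(dm$kappa[3], 0)     # stationary percept is uniform on the circle
  # lambda = 1 collapses onto the lapse component
  dm1 <- direction_mixture(pm, test_t2(), update_params(p, lambda_lapse = 1))
  expect_equal(dm1$w[1], 1)
  grid <- seq(0.5, 359.5, by = 1)
  dens <- exp(mixture_log_density(dm1, grid))
  expect_equal(dens, dvonmises_deg(grid, 180, 2), tolerance = 1e-12)
})

test_that("mixture density normalises, is uniform at kappa 0, and has the
           closed-form mode/antimode ratio", {
  dm <- structure(list(w = c(0.3, 0.7), theta = c(0, 120), kappa = c(3, 8)),
                  class = "direction_mixture")
  grid <- seq(0.5, 359.5, by = 1)
  expect_equal(sum(exp(mixture_log_density(dm, grid))), 1, tolerance = 1e-6)
  dm0 <- structure(list(w = 1, theta = 90, kappa = 0),
                   class = "direction_mixture")
  expect_equal(exp(mixture_log_density(dm0, c(0, 45, 300))),
               rep(1 / 360, 3), tolerance = 1e-12)
  k <- 4.2
  single <- structure(list(w = 1, theta = 50, kappa = k),
                      class = "direction_mixture")
  ratio <- exp(mixture_log_density(single, 50) -
                 mixture_log_density(single, 230))
  expect_equal(ratio, exp(2 * k), tolerance = 1e-9)
})

test_that("the von Mises image matches directions of sampled velocities", {
  p <- cim_params(lambda_lapse = 0)
  o <- rbind(c(1, tan(20 * pi / 180)), c(1, 0))
  pm <- percept_mixture(o, p)
  dm <- direction_mixture(pm, test_t2(), p)
  set.seed(123)
  n <- 1e5
  comp <- sample.int(length(pm$w), n, replace = TRUE, prob = pm$w)
  vx <- rnorm(n, pm$mu[comp, 1], sqrt(pm$sigma2[comp]))
  vy <- rnorm(n, pm$mu[comp, 2], sqrt(pm$sigma2[comp]))
  # stationary percepts are exactly (0,0): their direction is undefined and
  # the mixture assigns them uniform mass by convention (checked in the unit
  # test above), so the distributional comparison covers the components with
  # a defined direction
  defined <- !(vx == 0 & vy == 0)
  ang <- sort(hiermotion:::wrap_deg(atan2(vy[defined], vx[defined]) * 180 / pi))
  stationary <- pm$sigma2 == 0 & rowSums(pm$mu^2) == 0
  w_def <- pm$w; w_def[stationary] <- 0
  dm <- structure(list(w = w_def / sum(w_def),
                       theta = dm$theta[-1], kappa = dm$kappa[-1]),
                  class = "direction_mixture")
  grid <- seq(0, 360, by = 0.25)
  dens <- exp(mixture_log_density(dm, grid))
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * 0.25))
  cdf <- cdf / cdf[length(cdf)]
  Fm <- approx(grid, cdf, xout = ang, rule = 2)$y
  expect_lt(ks_to_model(ang, Fm), 0.02)
})

test_that("rotating the percept mixture rotates only the mean directions", {
  p <- cim_params()
  o <- rbind(c(1, 0.3), c(1, 0))
  rot <- function(m, deg) {
    a <- deg * pi / 180
    m %*% t(rbind(c(cos(a), -sin(a)), c(sin(a), cos(a))))
  }
  dm <- direction_mixture(percept_mixture(o, p), test_t2(), p)
  dm_r <- direction_mixture(percept_mixture(rot(o, 40), p), test_t2(), p)
  expect_equal(dm_r$w, dm$w, tolerance = 1e-9)
  expect_equal(dm_r$kappa, dm$kappa, tolerance = 1e-6)
  moving <- dm$kappa > 0 & dm$w > 0
  dth <- (dm_r$theta[moving] - dm$theta[moving] - 40) %% 360
  expect_true(all(pmin(dth, 360 - dth) < 1e-6))
})

test_that("the analytic von Mises convolution is close to the numeric one", {
  grid <- seq(0.5, 359.5, by = 1)
  for (ks in list(c(2, 67), c(0.5, 20), c(10, 67))) {
    k12 <- hiermotion:::vm_conv_kappa(ks[1], ks[2])
    approx_d <- dvonmises_deg(grid, 0, k12)
    # numeric circular convolution of the two densities
    f <- dvonmises_deg(grid, 0, ks[1])
    g <- dvonmises_deg(grid, 0, ks[2])
    num <- vapply(seq_along(grid), function(i) {
      sum(f * g[((seq_along(grid) - i) %% 360) + 1])
    }, numeric(1))
    num <- num / sum(num)
    capprox <- cumsum(approx_d) / sum(approx_d)
    cnum <- cumsum(num)
    expect_lt(max(abs(capprox - cnum)), 0.015)
  }
})
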