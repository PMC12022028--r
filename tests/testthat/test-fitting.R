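test_that("the dataset likelihood is additive and peaks at the mode", {
  p <- cim_params()
  cond <- exp1_condition(10, TRUE, 5)
  rd <- response_distribution(cond, p, "posterior_sampling", order = 5,
                              t2 = test_t2())
  grid <- seq(0, 359.5, by = 0.5)
  dens <- hiermotion:::vm_mixture_density(grid, rd$w, rd$theta, rd$kappa)
  mode <- grid[which.max(dens)]; antimode <- grid[which.min(dens)]
  d_mode <- make_trials(cond, mode, 10, TRUE, 5)
  d_anti <- make_trials(cond, antimode, 10, TRUE, 5)
  ll_mode <- dataset_log_likelihood(p, d_mode, "posterior_sampling", 5,
                                    test_t2())
  ll_anti <- dataset_log_likelihood(p, d_anti, "posterior_sampling", 5,
                                    test_t2())
  expect_gt(ll_mode, ll_anti)
  dat <- make_trials(cond, simulate_responses(cond, p, "posterior_sampling",
                                              40, seed = 2, t2 = test_t2()),
                     10, TRUE, 5)
  ll1 <- dataset_log_likelihood(p, dat, "posterior_sampling", 3, test_t2())
  ll2 <- dataset_log_likelihood(p, rbind(dat, dat), "posterior_sampling", 3,
                                test_t2())
  expect_equal(ll2, 2 * ll1, tolerance = 1e-8)
})

test_that("generating parameters beat inflated-noise parameters", {
  p <- cim_params()
  p_bad <- update_params(p, sigma_center = 2 * p$sigma_center,
                         sigma_surround = 2 * p$sigma_surround)
  grid <- exp1_grid(center_directions = c(0, 5, 20, 45), n_patches = 10,
                    control = FALSE)
  wins <- 0
  for (r in 1:8) {
    dat <- simulate_observer(p, grid, trials_per_condition = 40,
                             strategy = "posterior_sampling", seed = 100 + r,
                             t2 = test_t2())
    llg <- dataset_log_likelihood(p, dat, "posterior_sampling", 3, test_t2())
    llb <- dataset_log_likelihood(p_bad, dat, "posterior_sampling", 3,
                                  test_t2())
    wins <- wins + (llg > llb)
  }
  expect_gte(wins, 8)
})

test_that("maximum likelihood recovers the generating observer", {
  truth <- cim_params()
  grid <- exp1_grid(center_directions = c(0, 2.5, 5, 10, 20, 45),
                    n_patches = 10, control = FALSE)
  dat <- simulate_observer(truth, grid, trials_per_condition = 150,
                           strategy = "posterior_sampling", seed = 21,
                           t2 = test_t2())
  fit <- cim_fit(dat, "posterior_sampling",
                 free = c("alpha", "sigma_obs", "kappa_motor"),
                 start = update_params(truth, alpha_center = 0.7,
                                       alpha_surround = 0.7,
                                       alpha_group = 0.7,
                                       sigma_center = 0.2,
                                       sigma_surround = 0.2),
                 order = 3, t2 = test_t2())
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)["alpha"] - 0.9), 0.1)
  expect_lt(abs(coef(fit)["sigma_obs"] / truth$sigma_center - 1), 0.5)
  expect_equal(fit$AIC, 2 * fit$df - 2 * fit$logLik)
  expect_equal(as.numeric(AIC(fit)), fit$AIC)  # stats::AIC via logLik method
})

test_that("degenerate data give a flagged but finite fit", {
  cond <- exp1_condition(10, TRUE, 5)
  dat <- make_trials(cond, rep(42, 30), 10, TRUE, 5)
  fit <- cim_fit(dat, "averaging", free = c("kappa_motor", "motor_bias"),
                 order = 3, t2 = test_t2())
  expect_true(is.finite(fit$AIC))
  expect_false(fit$converged)   # boundary solution is flagged, not an error
})

test_that("AIC comparison is anchored at the best model", {
  f <- structure(list(logLik = -100, df = 3, AIC = 206, data_hash = "h",
                      n_trials = 10), class = "cim_fit")
  g <- structure(list(logLik = -100, df = 4, AIC = 208, data_hash = "h",
                      n_trials = 10), class = "cim_fit")
  tab <- aic_compare(list(base = f, extra = g))
  expect_equal(tab$dAIC, c(0, 2))
  expect_equal(aic_compare(list(a = f, b = f))$dAIC, c(0, 0))
  h <- structure(list(logLik = -100, df = 3, AIC = 206, data_hash = "other",
                      n_trials = 10), class = "cim_fit")
  expect_error(aic_compare(list(a = f, b = h)), "identical data")
})

test_that("a prior-only MCMC run reproduces the prior", {
  empty <- data.frame(observer = character(0), session = integer(0),
                      condition = character(0), center_dir_deg = numeric(0),
                      surround_moving = logical(0),
                      n_surround_patches = numeric(0),
                      report_deg = numeric(0))
  post <- sample_posterior(empty, free = "alpha", n_chains = 2,
                           n_samples = 400, burn_in = 50, seed = 3,
                           t2 = test_t2())
  # Beta(1, 1): mean 1/2, sd 1/sqrt(12)
  expect_equal(mean(post$samples[, "alpha"]), 0.5, tolerance = 0.05)
  expect_equal(sd(post$samples[, "alpha"]), 1 / sqrt(12), tolerance = 0.05)
  expect_true(all(is.finite(post$rhat)))
})

test_that("MCMC on synthetic data covers the generating delta mass", {
  truth <- cim_params()
  grid <- exp1_grid(center_directions = c(0, 5, 20, 45), n_patches = 10,
                    control = FALSE)
  dat <- simulate_observer(truth, grid, trials_per_condition = 80,
                           strategy = "posterior_sampling", seed = 33,
                           t2 = test_t2())
  post <- sample_posterior(dat, free = "alpha", start = truth, n_chains = 2,
                           n_samples = 200, burn_in = 50, order = 3,
                           t2 = test_t2(), seed = 9)
  expect_lt(post$rhat["alpha"], 1.1)
  expect_gt(post$ess["alpha"], 50)
  expect_lte(post$ci95[1, "alpha"], 0.9)
  expect_gte(post$ci95[2, "alpha"], 0.9 - 0.08)
  ac <- acf(post$samples[post$chain == 1, "alpha"], lag.max = 1,
            plot = FALSE)$acf[2]
  expect_lt(ac, 0.5)
})

test_that("variance explained separates matched and mismatched models", {
  truth <- cim_params()
  grid <- exp1_grid(center_directions = c(0, 5, 20, 45), n_patches = 10,
                    control = FALSE)
  dat <- simulate_observer(truth, grid, trials_per_condition = 120,
                           strategy = "posterior_sampling", seed = 41,
                           t2 = test_t2())
  self_fit <- structure(list(params = truth, strategy = "posterior_sampling",
                             order = 5, t2 = test_t2(),
                             conditions = resolve_conditions(dat)),
                        class = "cim_fit")
  ve <- variance_explained(self_fit, dat)
  expect_gt(ve, 85)
  uniform_fit <- structure(list(params = update_params(truth,
                                                       lambda_lapse = 1,
                                                       kappa_lapse = 0),
                                strategy = "posterior_sampling", order = 5,
                                t2 = test_t2(),
                                conditions = resolve_conditions(dat)),
                           class = "cim_fit")
  expect_lt(variance_explained(uniform_fit, dat), 40)
})

test_that("the bootstrap p-value follows the conservative convention", {
  expect_equal(bootstrap_pvalue(rep(-1, 5000), 0, "greater"), 1 / 5002)
  expect_equal(bootstrap_pvalue(rep(1, 5000), 0, "greater"), 5001 / 5002)
  set.seed(4)
  x <- rnorm(20000)
  expect_equal(bootstrap_pvalue(x, 0, "greater"), 0.5, tolerance = 0.02)
  expect_equal(bootstrap_pvalue(x, 0, "less"), 0.5, tolerance = 0.02)
})

test_that("fit methods expose the standard modelling interface", {
  truth <- cim_params()
  grid <- exp1_grid(center_directions = c(5, 20), n_patches = 10,
                    control = FALSE)
  dat <- simulate_observer(truth, grid, trials_per_condition = 40,
                           strategy = "posterior_sampling", seed = 55,
                           t2 = test_t2())
  fit <- cim_fit(dat, "posterior_sampling", free = "alpha", start = truth,
                 order = 3, t2 = test_t2())
  expect_named(coef(fit), "alpha")
  expect_s3_class(summary(fit), "summary.cim_fit")
  expect_output(print(fit), "observer fit")
  mu <- predict(fit, type = "mean")
  expect_length(mu, 2)
  sim <- simulate(fit, seed = 1)
  expect_equal(nrow(sim), nrow(dat))
  expect_true(all(sim$report_deg >= 0 & sim$report_deg < 360))
  res <- residuals(fit, data = dat)
  expect_true(all(abs(res) <= 180))
})
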