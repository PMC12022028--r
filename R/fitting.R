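## Likelihood of trial data, MLE/MAP optimisation, MCMC posterior, AIC
## comparison, variance explained and the bootstrap p-value convention.

.par_types <- c(alpha_center = "prob", alpha_surround = "prob",
                alpha_group = "prob", sigma_prior = "sigma",
                sigma_delta = "sigma", sigma_center = "sigma",
                sigma_surround = "sigma", beta = "prob",
                lambda_lapse = "prob", theta_lapse = "angle",
                kappa_lapse = "kappa", motor_bias = "angle",
                kappa_motor = "kappa")

.to_t <- function(x, type) switch(type,
  prob = stats::qlogis(pmin(pmax(x, 1e-9), 1 - 1e-9)),
  sigma = log(pmax(x, 1e-9)), kappa = log(pmax(x, 1e-9)), angle = x)

.from_t <- function(t, type) switch(type,
  prob = stats::plogis(t), sigma = exp(t), kappa = exp(t), angle = t)

## expand tie aliases: "alpha" ties all delta masses, "sigma_obs" both
## observation noises; anything else must be a parameter name
.expand_free <- function(free) {
  out <- lapply(free, function(f) switch(f,
    alpha = c("alpha_center", "alpha_surround", "alpha_group"),
    sigma_obs = c("sigma_center", "sigma_surround"),
    {
      if (!f %in% names(.par_types)) stop("unknown free parameter: ", f)
      f
    }))
  names(out) <- free
  out
}

.group_type <- function(members) unname(.par_types[members[1]])

.params_from_t <- function(tvec, groups, base) {
  for (i in seq_along(groups)) {
    nat <- .from_t(tvec[i], .group_type(groups[[i]]))
    for (nm in groups[[i]]) base[[nm]] <- nat
  }
  base
}

#' Dataset log-likelihood
#'
#' Sum over trials of the log predicted response density at the reported
#' direction, with per-condition response distributions computed once and
#' shared across that condition's trials.
#'
#' @param params [cim_params()].
#' @param data trial table (see [read_trials()]).
#' @param strategy readout strategy.
#' @param order quadrature order per scalar dimension (fitting default 5).
#' @param t2 T2 calibration table.
#' @param conditions optional pre-resolved condition list.
#' @return log-likelihood (scalar).
#' @export
dataset_log_likelihood <- function(params, data, strategy = "posterior_sampling",
                                   order = 5, t2 = default_t2(),
                                   conditions = NULL) {
  if (is.null(conditions)) conditions <- resolve_conditions(data)
  ll <- 0
  for (lab in names(conditions)) {
    idx <- which(data$condition == lab)
    if (!length(idx)) next
    rd <- response_distribution(conditions[[lab]], params, strategy,
                                order = order, t2 = t2)
    li <- response_log_density(rd, data$report_deg[idx])
    if (any(!is.finite(li))) {
      bad <- idx[which(!is.finite(li))[1]]
      stop(sprintf("non-finite response density for trial %d (condition %s, report %.2f deg)",
                   bad, lab, data$report_deg[bad]))
    }
    ll <- ll + sum(li)
  }
  ll
}

## ---- cached likelihood ----------------------------------------------------
##
## The delta masses (alpha), the structure prior (beta) and the lapse rate
## only enter the likelihood through mixture *weights*: component means,
## variances and hence all von Mises parameters are unchanged. When every
## free parameter is weight-only, per-condition quadrature, per-structure
## Gaussian marginals and the full report-by-component von Mises density
## matrix can be precomputed once, reducing each likelihood evaluation to a
## reweighting plus one matrix-vector product.

.weight_only <- c("alpha_center", "alpha_surround", "alpha_group", "beta",
                  "lambda_lapse")

loglik_factory <- function(data, strategy, start, groups, order, t2,
                           conditions = resolve_conditions(data)) {
  fast <- length(groups) > 0 &&
    all(unlist(groups) %in% .weight_only) &&
    strategy %in% c("posterior_sampling", "structure_sampling")
  if (!fast) {
    return(list(fast = FALSE, fn = function(tvec) {
      p <- .params_from_t(tvec, groups, start)
      dataset_log_likelihood(p, data, strategy, order, t2, conditions)
    }))
  }
  km <- start$kappa_motor; b <- start$motor_bias
  cache <- lapply(names(conditions), function(lab) {
    cond <- conditions[[lab]]
    reports <- data$report_deg[data$condition == lab]
    if (!length(reports)) return(NULL)
    n <- nrow(cond$nu)
    sig <- cond_sigma_obs(cond, start)
    q <- gh_observation_nodes(cond$nu, sig, order)
    structures <- scene_structures(n)
    pre <- structure_precompute(structures, start, sig, 1L, cond$roles)
    mb <- mixture_batch(q$Ox, q$Oy, pre)
    lpriors <- vapply(pre, function(p) p$lprior, numeric(1))
    llik <- sweep(mb$logW, 2, lpriors)   # likelihood part only
    arr <- batch_direction_arrays(mb, t2, start)
    kap <- if (strategy == "posterior_sampling")
      matrix(vm_conv_kappa(arr$KP, km), nrow(arr$KP), ncol(arr$KP))
    else matrix(km, nrow(arr$KP), ncol(arr$KP))
    theta <- wrap_deg(arr$TH + b)
    # report x component von Mises density matrix (components flattened)
    mu <- as.vector(theta); kv <- as.vector(kap)
    D <- exp(sweep(cos(deg2rad(outer(reports, mu, "-"))) - 1, 2, kv, "*"))
    D <- sweep(D, 2, 360 * besselI(kv, 0, expon.scaled = TRUE), "/")
    # per-structure flag-prior sufficient statistics by node role
    roles <- cond$roles
    stats_s <- t(vapply(structures, function(s) {
      role_of <- ifelse(s$tree$kind == "group", "group",
                        ifelse(roles[pmin(seq_along(s$tree$kind),
                                          length(roles))] == "center" &
                                 s$tree$kind == "element", "center", "surround"))
      c(c0 = sum(role_of == "center" & s$moving == 0L),
        c1 = sum(role_of == "center" & s$moving == 1L),
        s0 = sum(role_of == "surround" & s$moving == 0L),
        s1 = sum(role_of == "surround" & s$moving == 1L),
        g0 = sum(role_of == "group" & s$moving == 0L),
        g1 = sum(role_of == "group" & s$moving == 1L),
        ng = s$tree$n_groups)
    }, numeric(7)))
    list(llik = llik, D = D, w_quad = q$w, stats_s = stats_s,
         n_comp = ncol(arr$W))
  })
  cache <- Filter(Negate(is.null), cache)
  fn <- function(tvec) {
    p <- .params_from_t(tvec, groups, start)
    la0 <- log(c(p$alpha_center, p$alpha_surround, p$alpha_group))
    la1 <- log1p(-c(p$alpha_center, p$alpha_surround, p$alpha_group))
    ll <- 0
    for (cc in cache) {
      st <- cc$stats_s
      gmax <- max(st[, "ng"])
      ltree <- st[, "ng"] * log(p$beta) + (gmax - st[, "ng"]) * log1p(-p$beta)
      ltree[is.nan(ltree)] <- 0
      # the tree-prior normaliser is structure-independent and cancels in the
      # row-wise softmax below, so unnormalised tree log priors suffice
      lp_flags <- st[, "c0"] * la0[1] + st[, "c1"] * la1[1] +
        st[, "s0"] * la0[2] + st[, "s1"] * la1[2] +
        st[, "g0"] * la0[3] + st[, "g1"] * la1[3]
      lw <- sweep(cc$llik, 2, ltree + lp_flags, "+")
      m <- apply(lw, 1L, max)
      if (any(!is.finite(m))) return(-Inf)
      W <- exp(lw - m); W <- W / rowSums(W)
      lam <- p$lambda_lapse
      wcomp <- as.vector(cbind(lam, (1 - lam) * W) * cc$w_quad)
      dens <- drop(cc$D %*% wcomp)
      if (any(dens <= 0)) return(-Inf)
      ll <- ll + sum(log(dens))
    }
    ll
  }
  list(fast = TRUE, fn = fn)
}

## cheap dataset fingerprint used to tie fits to data for aic_compare
data_fingerprint <- function(data) {
  paste(nrow(data),
        format(sum(data$report_deg), digits = 15),
        format(sum(data$center_dir_deg), digits = 15),
        length(unique(data$condition)), sep = "|")
}

#' Weakly informative default priors
#'
#' Beta(1, 1) for probabilities, half-normal (scale 5 deg/s) for standard
#' deviations, uniform circular for angle parameters, log-normal
#' (meanlog 3, sdlog 2) for concentrations. Each prior is a function of the
#' natural-scale value returning a log density; all overridable.
#'
#' @return named list of log-prior functions keyed by parameter name.
#' @export
default_priors <- function() {
  pr <- list(
    prob = function(x) stats::dbeta(x, 1, 1, log = TRUE),
    sigma = function(x) log(2) + stats::dnorm(x, 0, 5, log = TRUE),
    angle = function(x) -log(360),
    kappa = function(x) stats::dlnorm(x, 3, 2, log = TRUE))
  out <- lapply(names(.par_types), function(nm) pr[[.par_types[[nm]]]])
  names(out) <- names(.par_types)
  out
}

## log prior on the transformed scale (includes the Jacobian)
.log_prior_t <- function(tvec, groups, priors) {
  lp <- 0
  for (i in seq_along(groups)) {
    nm <- groups[[i]][1]
    type <- .group_type(groups[[i]])
    nat <- .from_t(tvec[i], type)
    jac <- switch(type, prob = log(nat) + log1p(-nat),
                  sigma = log(nat), kappa = log(nat), angle = 0)
    lp <- lp + priors[[nm]](nat) + jac
  }
  lp
}

#' Fit the causal-inference observer model to trial data
#'
#' Maximum-likelihood (or maximum a posteriori) fit by quasi-Newton BFGS on
#' unconstrained transformed parameters (log sigmas and concentrations,
#' logit probabilities, angles untransformed). Tie aliases `"alpha"` (all
#' delta masses equal) and `"sigma_obs"` (shared observation noise) are
#' supported in `free`. Non-convergence or a boundary solution is flagged on
#' the result, never raised as an error.
#'
#' @param data trial table.
#' @param strategy readout strategy generating the likelihood.
#' @param free character vector of parameters (or tie aliases) to optimise.
#' @param start starting / fixed parameter values ([cim_params()]).
#' @param method `"mle"` or `"map"` (adds the priors to the objective).
#' @param priors log-prior list (for `"map"`), see [default_priors()].
#' @param order quadrature order used in the likelihood.
#' @param t2 T2 calibration table.
#' @param multistart number of jittered starts (best kept).
#' @param seed seed for the multistart jitter.
#' @return object of class `"cim_fit"`.
#' @export
cim_fit <- function(data, strategy = "posterior_sampling",
                    free = c("alpha", "sigma_obs", "kappa_motor"),
                    start = cim_params(), method = c("mle", "map"),
                    priors = default_priors(), order = 5, t2 = default_t2(),
                    multistart = 1, seed = 1L) {
  method <- match.arg(method)
  stopifnot(nrow(data) >= 1)
  groups <- .expand_free(free)
  conditions <- resolve_conditions(data)
  lf <- loglik_factory(data, strategy, start, groups, order, t2, conditions)
  negobj <- function(tvec) {
    ll <- tryCatch(lf$fn(tvec), error = function(e) -Inf)
    if (method == "map" && is.finite(ll))
      ll <- ll + .log_prior_t(tvec, groups, priors)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  t0 <- vapply(groups, function(g) .to_t(start[[g[1]]], .group_type(g)),
               numeric(1))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(multistart)) {
    ts <- if (s == 1) t0 else t0 + stats::rnorm(length(t0), 0, 0.5)
    o <- stats::optim(ts, negobj, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-9))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p_hat <- .params_from_t(best$par, groups, start)
  ll_hat <- dataset_log_likelihood(p_hat, data, strategy, order, t2, conditions)
  k <- length(groups)
  coefs <- vapply(groups, function(g) p_hat[[g[1]]], numeric(1))
  names(coefs) <- names(groups)
  boundary <- any(abs(best$par) > 12)
  structure(list(coefficients = coefs, params = p_hat, free = groups,
                 logLik = ll_hat, df = k, AIC = 2 * k - 2 * ll_hat,
                 strategy = strategy, method = method, order = order,
                 convergence = best$convergence, boundary = boundary,
                 converged = best$convergence == 0 && !boundary,
                 data_hash = data_fingerprint(data), n_trials = nrow(data),
                 conditions = conditions, condition_key = condition_key(data),
                 t2 = t2, call = match.call()),
            class = "cim_fit")
}

#' @export
print.cim_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Causal-inference observer fit (%s readout, %s)\n",
              x$strategy, toupper(x$method)))
  cat(sprintf("  %d trials, %d free parameter group(s)\n", x$n_trials, x$df))
  print(round(x$coefficients, digits))
  cat(sprintf("  logLik %.2f | AIC %.2f%s\n", x$logLik, x$AIC,
              if (!x$converged) " | WARNING: not converged or boundary" else ""))
  invisible(x)
}

#' @export
summary.cim_fit <- function(object, ...) {
  out <- list(fit = object,
              table = data.frame(parameter = names(object$coefficients),
                                 estimate = unname(object$coefficients)),
              AIC = object$AIC, logLik = object$logLik,
              converged = object$converged)
  if (!is.null(object$samples)) {
    qs <- t(apply(object$samples, 2, stats::quantile,
                  probs = c(0.025, 0.5, 0.975)))
    out$table <- cbind(out$table, qs, rhat = object$rhat, ess = object$ess)
  }
  class(out) <- "summary.cim_fit"
  out
}

#' @export
print.summary.cim_fit <- function(x, ...) {
  print(x$fit)
  if (ncol(x$table) > 2) print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cim_fit <- function(object, ...) object$coefficients

#' @export
logLik.cim_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_trials,
            class = "logLik")
}

#' @export
predict.cim_fit <- function(object, newdata = NULL,
                            type = c("distribution", "mean"), ...) {
  conds <- if (is.null(newdata)) object$conditions
           else resolve_conditions(newdata)
  rds <- lapply(conds, function(cond)
    response_distribution(cond, object$params, object$strategy,
                          order = max(object$order, 7), t2 = object$t2))
  if (match.arg(type) == "distribution") return(rds)
  vapply(rds, function(rd)
    vm_mixture_circular_mean(rd$w, rd$theta, rd$kappa), numeric(1))
}

#' @export
simulate.cim_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  key <- object$condition_key
  tabs <- lapply(seq_len(nsim), function(rep) {
    rows <- lapply(seq_len(nrow(key)), function(i) {
      lab <- key$condition[i]
      r <- simulate_responses(object$conditions[[lab]], object$params,
                              object$strategy, n_trials = key$n_trials[i],
                              t2 = object$t2)
      data.frame(observer = "sim", session = rep, condition = lab,
                 center_dir_deg = key$center_dir_deg[i],
                 surround_moving = key$surround_moving[i],
                 n_surround_patches = key$n_surround_patches[i],
                 report_deg = r)
    })
    do.call(rbind, rows)
  })
  if (nsim == 1) tabs[[1]] else tabs
}

## per-condition trial counts and design columns, stored on fits
condition_key <- function(data) {
  key <- unique(data[, c("condition", "center_dir_deg", "surround_moving",
                         "n_surround_patches")])
  key$n_trials <- vapply(key$condition,
                         function(lab) sum(data$condition == lab), integer(1))
  rownames(key) <- NULL
  key
}

#' @export
residuals.cim_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) stop("supply the trial data used for the fit")
  mu <- predict(object, type = "mean")
  r <- data$report_deg - mu[data$condition]
  ((r + 180) %% 360) - 180
}

#' @export
plot.cim_fit <- function(x, data = NULL, conditions = NULL, ...) {
  conds <- x$conditions
  if (!is.null(conditions)) conds <- conds[conditions]
  grid <- seq(0, 360, length.out = 361)
  old <- graphics::par(mfrow = c(min(length(conds), 3), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (lab in names(conds)[seq_len(min(length(conds), 3))] ) {
    rd <- response_distribution(conds[[lab]], x$params, x$strategy,
                                order = max(x$order, 7), t2 = x$t2)
    d <- vm_mixture_density(grid, rd$w, rd$theta, rd$kappa)
    graphics::plot(grid, d, type = "l", xlab = "report (deg)",
                   ylab = "density", main = lab)
    if (!is.null(data)) {
      r <- data$report_deg[data$condition == lab]
      if (length(r)) graphics::rug(wrap_deg(r))
    }
  }
  invisible(x)
}

## ---- MCMC -----------------------------------------------------------------

## univariate slice sampler (Neal 2003, stepping out + shrinkage)
.slice1 <- function(x0, logf, f0, w = 1, m = 50) {
  y <- f0 - stats::rexp(1)
  L <- x0 - stats::runif(1) * w; R <- L + w
  j <- floor(stats::runif(1) * m); k <- m - 1 - j
  while (j > 0 && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    f1 <- logf(x1)
    if (f1 >= y) return(list(x = x1, f = f1))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Posterior sampling over model parameters
#'
#' Slice-sampling-within-Gibbs MCMC on the transformed parameter scale under
#' the weakly informative [default_priors()] (overridable). Chains are run
#' with burn-in discarded and optional thinning; split-Rhat and effective
#' sample size are reported per parameter. `Rhat > 1.1` produces a warning
#' flag on the result, not a failure.
#'
#' @inheritParams cim_fit
#' @param n_chains number of chains.
#' @param n_samples post-burn-in samples per chain (before thinning).
#' @param burn_in burn-in iterations per chain.
#' @param thin keep every `thin`-th sample.
#' @param seed integer seed.
#' @return a `cim_fit` with elements `samples` (matrix), `chain` (index),
#'   `rhat`, `ess`, `ci95`.
#' @export
sample_posterior <- function(data, strategy = "posterior_sampling",
                             free = c("alpha"), start = cim_params(),
                             priors = default_priors(), n_chains = 4,
                             n_samples = 1000, burn_in = 200, thin = 1,
                             order = 3, t2 = default_t2(), seed = 1L) {
  groups <- .expand_free(free)
  conditions <- if (nrow(data)) resolve_conditions(data) else list()
  d <- length(groups)
  lf <- if (nrow(data)) loglik_factory(data, strategy, start, groups, order,
                                       t2, conditions) else NULL
  logpost <- function(tvec) {
    ll <- if (is.null(lf)) 0 else
      tryCatch(lf$fn(tvec), error = function(e) -Inf)
    if (!is.finite(ll)) return(-Inf)
    ll + .log_prior_t(tvec, groups, priors)
  }
  t0 <- vapply(groups, function(g) .to_t(start[[g[1]]], .group_type(g)),
               numeric(1))
  set.seed(seed)
  keep <- floor(n_samples / thin)
  samples <- matrix(NA_real_, n_chains * keep, d,
                    dimnames = list(NULL, names(groups)))
  chain_id <- rep(seq_len(n_chains), each = keep)
  for (ch in seq_len(n_chains)) {
    x <- t0 + stats::rnorm(d, 0, 0.5)
    f <- logpost(x)
    if (!is.finite(f)) { x <- t0; f <- logpost(x) }
    row <- 0L
    for (it in seq_len(burn_in + n_samples)) {
      for (j in seq_len(d)) {
        coord_fn <- local({
          jj <- j
          function(v) { xx <- x; xx[jj] <- v; logpost(xx) }
        })
        s <- .slice1(x[j], coord_fn, f)
        x[j] <- s$x; f <- s$f
      }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        row <- row + 1L
        samples[(ch - 1L) * keep + row, ] <- x
      }
    }
  }
  nat <- samples
  for (i in seq_len(d))
    nat[, i] <- .from_t(samples[, i], .group_type(groups[[i]]))
  rhat <- vapply(seq_len(d), function(i) split_rhat(nat[, i], chain_id),
                 numeric(1))
  ess <- vapply(seq_len(d), function(i) ess_basic(nat[, i], chain_id),
                numeric(1))
  names(rhat) <- names(ess) <- names(groups)
  post_mean <- colMeans(nat)
  p_hat <- .params_from_t(
    vapply(seq_len(d), function(i) .to_t(post_mean[i], .group_type(groups[[i]])),
           numeric(1)), groups, start)
  ll <- if (nrow(data)) dataset_log_likelihood(p_hat, data, strategy, order,
                                               t2, conditions) else NA_real_
  structure(list(coefficients = post_mean, params = p_hat, free = groups,
                 samples = nat, chain = chain_id, rhat = rhat, ess = ess,
                 rhat_warning = any(rhat > 1.1, na.rm = TRUE),
                 ci95 = apply(nat, 2, stats::quantile, c(0.025, 0.975)),
                 logLik = ll, df = d, AIC = 2 * d - 2 * ll,
                 strategy = strategy, method = "mcmc", order = order,
                 converged = !any(rhat > 1.1, na.rm = TRUE), boundary = FALSE,
                 data_hash = data_fingerprint(data), n_trials = nrow(data),
                 conditions = conditions,
                 condition_key = if (nrow(data)) condition_key(data) else NULL,
                 t2 = t2, call = match.call()),
            class = "cim_fit")
}

## split-Rhat (halved chains, classic between/within variance ratio)
split_rhat <- function(x, chain_id) {
  halves <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    h <- floor(length(v) / 2)
    if (h < 2) return(NA_real_)
    halves <- c(halves, list(v[seq_len(h)]), list(v[(h + 1):(2 * h)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## effective sample size via pairwise (Geyer) truncated autocorrelation
ess_basic <- function(x, chain_id) {
  chains <- split(x, chain_id)
  n <- min(lengths(chains)); m <- length(chains)
  if (n < 4) return(NA_real_)
  rho_sum <- 0; lag <- 1
  acfs <- lapply(chains, function(v)
    stats::acf(v[seq_len(n)], lag.max = min(n - 2, 200), plot = FALSE)$acf[, 1, 1])
  rho <- Reduce(`+`, acfs) / m
  t <- 2
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    rho_sum <- rho_sum + pair
    t <- t + 2
  }
  m * n / (1 + 2 * rho_sum)
}

#' AIC comparison table
#'
#' Delta-AIC of each fit relative to the best, sorted. All fits must be on
#' the identical dataset (fingerprint-checked).
#'
#' @param fits named list of `cim_fit` objects.
#' @return data frame with `model`, `logLik`, `k`, `AIC`, `dAIC`.
#' @export
aic_compare <- function(fits) {
  stopifnot(length(fits) >= 1)
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  if (length(unique(hashes)) != 1L)
    stop("fits were not computed on identical data")
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  tab <- data.frame(model = names(fits),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    k = vapply(fits, function(f) f$df, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)))
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab[order(tab$dAIC), , drop = FALSE]
}

#' Variance explained by a fitted model
#'
#' For every condition with at least `min_trials` trials the model response
#' CDF is evaluated at the sorted reports and compared with the empirical
#' CDF levels; VE = 100 (1 - SS_res / SS_tot) pooled over conditions.
#'
#' @param fit a `cim_fit`.
#' @param data trial table.
#' @param min_trials minimum trials per included condition.
#' @return variance explained in percent.
#' @export
variance_explained <- function(fit, data, min_trials = 2) {
  ss_res <- 0; ss_tot <- 0
  for (lab in names(fit$conditions)) {
    r <- sort(data$report_deg[data$condition == lab])
    m <- length(r)
    if (m < min_trials) next
    rd <- response_distribution(fit$conditions[[lab]], fit$params,
                                fit$strategy, order = max(fit$order, 5),
                                t2 = fit$t2)
    Fm <- response_cdf(rd, r)
    Fe <- (seq_len(m) - 0.5) / m
    ss_res <- ss_res + sum((Fm - Fe)^2)
    ss_tot <- ss_tot + sum((Fe - mean(Fe))^2)
  }
  if (ss_tot == 0) return(NA_real_)
  100 * (1 - ss_res / ss_tot)
}

#' Conservative bootstrap p-value
#'
#' Counts bootstrap samples beyond the boundary on the stated side (`t`) and
#' reports `(t + 1) / (N + 2)`, the posterior-mean estimate under a uniform
#' prior that accounts for the finite number of bootstrap samples.
#'
#' @param samples bootstrap statistic samples.
#' @param boundary decision boundary.
#' @param side `"greater"` counts samples > boundary, `"less"` samples <
#'   boundary.
#' @return p-value in (0, 1).
#' @export
bootstrap_pvalue <- function(samples, boundary, side = c("greater", "less")) {
  side <- match.arg(side)
  N <- length(samples)
  stopifnot(N >= 1)
  t <- if (side == "greater") sum(samples > boundary) else sum(samples < boundary)
  (t + 1) / (N + 2)
}
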