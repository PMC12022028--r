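# Independent oracles and small utilities shared across tests. These
# deliberately avoid the package's linear-Gaussian algebra: the importance
# sampler works on raw latent draws from the generative model, so agreement
# is a genuine cross-check.

# importance-sampling oracle for the structure posterior and percept
# conditionals of a scene: sample latents from the prior conditioned on each
# structure's flags, weight by the Gaussian observation likelihood
is_oracle <- function(obs, params, roles, n_particles = 2e5, seed = 1,
                      element = 1L) {
  set.seed(seed)
  structs <- enumerate_causal_structures(nrow(obs))
  sigs <- vapply(structs, function(s) hiermotion:::.tree_signature(s$tree),
                 character(1))
  utrees <- lapply(structs[!duplicated(sigs)], function(s) s$tree)
  tree_lp <- hiermotion:::tree_log_priors(utrees, params$beta)
  names(tree_lp) <- sigs[!duplicated(sigs)]
  sig_obs <- hiermotion:::sigma_for_role(params, roles)

  per <- lapply(structs, function(s) {
    tree <- s$tree; m <- length(tree$parent); n <- tree$n_elements
    rel <- array(0, c(n_particles, m, 2))
    for (nd in seq_len(m)) if (s$moving[nd] == 1L)
      rel[, nd, ] <- rnorm(2 * n_particles, 0, params$sigma_prior)
    vab <- array(0, c(n_particles, m, 2))
    depth <- vapply(seq_len(m), function(i) {
      d <- 0L; node <- i
      while (tree$parent[node] != 0L) { node <- tree$parent[node]; d <- d + 1L }
      d
    }, integer(1))
    for (i in order(depth)) {
      parv <- if (tree$parent[i] == 0L) 0 else vab[, tree$parent[i], ]
      vab[, i, ] <- parv + rel[, i, ] +
        rnorm(2 * n_particles, 0, params$sigma_delta)
    }
    lw <- 0
    for (e in seq_len(n)) for (ax in 1:2)
      lw <- lw + dnorm(obs[e, ax], vab[, e, ax], sig_obs[e], log = TRUE)
    w <- exp(lw - max(lw))
    a <- hiermotion:::alpha_for_node(params, tree, roles)
    lp <- hiermotion:::flags_log_prior(s$moving, a) +
      tree_lp[[hiermotion:::.tree_signature(tree)]]
    q <- percept_node(s, element)
    mean_q <- if (q > 0) c(sum(w * rel[, q, 1]) / sum(w),
                           sum(w * rel[, q, 2]) / sum(w)) else c(0, 0)
    # batch split for Monte-Carlo standard errors of the marginal likelihood
    nb <- 10L
    batch <- rep(seq_len(nb), each = n_particles / nb)
    bm <- tapply(w, batch, mean)
    list(lml = lp + log(mean(w)) + max(lw), mean = mean_q,
         lml_se = sd(log(bm)) / sqrt(nb))
  })
  lml <- vapply(per, function(p) p$lml, numeric(1))
  w <- exp(lml - max(lml)); w <- w / sum(w)
  list(w = w,
       mu = t(vapply(per, function(p) p$mean, numeric(2))),
       lml_se = vapply(per, function(p) p$lml_se, numeric(1)))
}

# two-sample-free KS distance between an empirical sample and a model CDF
ks_to_model <- function(samples, cdf_values_at_sorted) {
  n <- length(samples)
  Fe_hi <- seq_len(n) / n
  Fe_lo <- (seq_len(n) - 1) / n
  max(pmax(abs(cdf_values_at_sorted - Fe_hi),
           abs(cdf_values_at_sorted - Fe_lo)))
}

make_trials <- function(cond, reports, center_dir, moving, patches,
                        observer = "sim1") {
  data.frame(observer = observer, session = 1L, condition = cond$label,
             center_dir_deg = center_dir, surround_moving = moving,
             n_surround_patches = patches, report_deg = reports)
}

# shared calibration table so the suite pays the Monte-Carlo cost once
test_t2 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- default_t2()
    tab
  }
})
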