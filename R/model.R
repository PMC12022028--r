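#' Log prior of a relative velocity under the delta + Gaussian mixture
#'
#' The prior over a node's relative velocity is a mixture of a delta function
#' at zero (probability `alpha`; exact stationarity, e.g. from friction) and a
#' zero-mean isotropic Gaussian (slow-speed component). Atoms and densities
#' are kept explicitly separate: the return value carries an `atom` indicator
#' so callers never mix a probability mass with a density value.
#'
#' @param v numeric length-2 velocity (deg/s). The delta component is hit
#'   only by the exact-zero encoding `c(0, 0)`.
#' @param alpha delta mass in `[0, 1]`.
#' @param sigma_prior slow-speed prior s.d. (deg/s).
#' @return list with `log_value` (log mass if `atom`, else log density) and
#'   `atom` (logical).
#' @export
relative_velocity_log_prior <- function(v, alpha, sigma_prior) {
  stopifnot(is.numeric(v), length(v) == 2L, all(is.finite(v)),
            alpha >= 0, alpha <= 1, sigma_prior > 0)
  if (identical(as.numeric(v), c(0, 0)) && alpha > 0) {
    return(list(log_value = log(alpha), atom = TRUE))
  }
  ld <- sum(stats::dnorm(v, 0, sigma_prior, log = TRUE))
  list(log_value = log1p(-alpha) + ld, atom = FALSE)
}

## log prior over the grouping tree: beta-weighted by number of group nodes,
## p(tree) proportional to beta^g (1-beta)^(gmax-g); reduces to
## beta / (1-beta) over the two 2-element trees
tree_log_priors <- function(trees, beta) {
  g <- vapply(trees, function(t) t$n_groups, numeric(1))
  gmax <- max(g)
  lw <- g * log(beta) + (gmax - g) * log1p(-beta)
  lw[g == 0 & beta == 1] <- -Inf
  lw[g > 0 & beta == 0] <- -Inf
  lw[is.nan(lw)] <- 0  # beta in {0,1} with exponent 0
  if (!any(is.finite(lw))) return(lw)  # all trees excluded by the prior
  lw - logsumexp(lw)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log prior of a structure's flag assignment given per-node alpha
flags_log_prior <- function(moving, alpha_node) {
  lp <- ifelse(moving == 1L, log1p(-alpha_node), log(alpha_node))
  sum(lp)
}

#' Sample a causal structure and its latent velocities
#'
#' Forward pass of the generative model: a grouping tree is drawn with prior
#' weight controlled by `beta`, each node's stationarity flag by the
#' role-specific `alpha`; relative velocities are exactly `(0,0)` for flag-0
#' nodes and zero-mean Gaussian (`sigma_prior`) otherwise; absolute
#' velocities are composed parent-to-child with isotropic composition noise
#' `sigma_delta`, starting from a stationary world.
#'
#' @param params [cim_params()].
#' @param n_elements number of elements.
#' @param seed optional integer seed.
#' @param roles element roles (default [default_roles()]).
#' @param rules grammar rule-set.
#' @return list with `structure`, `v_relative` (nodes x 2), `v_absolute`
#'   (nodes x 2).
#' @export
sample_structure_and_latents <- function(params, n_elements, seed = NULL,
                                         roles = default_roles(n_elements),
                                         rules = grammar_rules()) {
  if (!is.null(seed)) set.seed(seed)
  trees <- enumerate_grouping_trees(n_elements, rules)
  lw <- tree_log_priors(trees, params$beta)
  tree <- trees[[sample.int(length(trees), 1L, prob = exp(lw))]]
  a <- alpha_for_node(params, tree, roles)
  moving <- as.integer(stats::runif(length(a)) > a)
  s <- structure(list(tree = tree, moving = moving), class = "causal_structure")
  m <- length(tree$parent)
  v_rel <- matrix(0, m, 2)
  mv <- moving == 1L
  v_rel[mv, ] <- stats::rnorm(2 * sum(mv), 0, params$sigma_prior)
  v_abs <- matrix(0, m, 2)
  ord <- order(vapply(seq_len(m), function(i) {
    d <- 0L; node <- i
    while (tree$parent[node] != 0L) { node <- tree$parent[node]; d <- d + 1L }
    d
  }, integer(1)))  # parents before children
  for (i in ord) {
    par_v <- if (tree$parent[i] == 0L) c(0, 0) else v_abs[tree$parent[i], ]
    v_abs[i, ] <- par_v + v_rel[i, ] + stats::rnorm(2, 0, params$sigma_delta)
  }
  list(structure = s, v_relative = v_rel, v_absolute = v_abs)
}

#' Sample observations given latent element velocities
#'
#' Independent isotropic Gaussian corruption of each element's absolute
#' velocity by its role-specific observation noise.
#'
#' @param v_elements numeric matrix (n_elements x 2) of latent absolute
#'   velocities (deg/s).
#' @param sigma_obs per-element observation noise s.d. (recycled).
#' @param seed optional integer seed.
#' @return an observation set: list with `o` (n x 2 matrix) and `sigma_obs`.
#' @export
sample_observations <- function(v_elements, sigma_obs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- rbind(v_elements)
  stopifnot(ncol(v) == 2L, all(sigma_obs > 0))
  sig <- rep_len(sigma_obs, nrow(v))
  o <- v + matrix(stats::rnorm(length(v), 0, rep(sig, 2)), nrow(v), 2)
  list(o = o, sigma_obs = sig)
}
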