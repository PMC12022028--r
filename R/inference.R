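## Exact posterior over causal structures and perceived velocities.
##
## For a fixed structure, each element's observation per axis is a linear
## combination of the Gaussian relative velocities of its ancestors (flag-1
## nodes), composition noise at every ancestor edge, and observation noise.
## The stacked observations per axis are therefore jointly zero-mean Gaussian
## with covariance built from shared ancestor paths; x and y are independent
## scalar chains sharing the same covariance (all covariances isotropic).

.structure_cache <- new.env(parent = emptyenv())

scene_structures <- function(n_elements, rules = grammar_rules()) {
  key <- paste(n_elements, paste(unlist(rules), collapse = ""), sep = "_")
  if (is.null(.structure_cache[[key]]))
    .structure_cache[[key]] <- enumerate_causal_structures(n_elements, rules)
  .structure_cache[[key]]
}

## per-structure Gaussian precomputation for a fixed parameter setting
## sigma_obs: per-element observation sd; element: the report target
structure_precompute <- function(structures, params, sigma_obs,
                                 element = 1L,
                                 roles = default_roles(structures[[1]]$tree$n_elements)) {
  n <- structures[[1]]$tree$n_elements
  stopifnot(length(sigma_obs) == n)
  sigs <- vapply(structures, function(s) .tree_signature(s$tree), character(1))
  utrees <- lapply(structures[!duplicated(sigs)], function(s) s$tree)
  tree_lp <- tree_log_priors(utrees, params$beta)
  names(tree_lp) <- sigs[!duplicated(sigs)]
  sp2 <- params$sigma_prior^2; sd2 <- params$sigma_delta^2

  lapply(structures, function(s) {
    tree <- s$tree
    a <- alpha_for_node(params, tree, roles)
    lprior <- tree_lp[[.tree_signature(tree)]] + flags_log_prior(s$moving, a)
    Sigma <- diag(sigma_obs^2, n)
    for (node in seq_along(tree$parent)) {
      ind <- rep(0, n)
      ind[tree$members[[node]]] <- 1
      Sigma <- Sigma + (s$moving[node] * sp2 + sd2) * tcrossprod(ind)
    }
    ch <- chol(Sigma)
    Ainv <- chol2inv(ch)
    cst <- -2 * sum(log(diag(ch))) - n * log(2 * pi)  # per-axis log-normaliser x2 applied later
    q <- percept_node(s, element)
    if (q > 0L) {
      cvec <- rep(0, n)
      cvec[tree$members[[q]]] <- sp2
      k <- drop(Ainv %*% cvec)
      pvar <- sp2 - sum(cvec * k)
      stationary <- FALSE
    } else {
      k <- rep(0, n); pvar <- 0; stationary <- TRUE
    }
    list(lprior = lprior, cst = cst, Ainv = Ainv, k = k,
         pvar = max(pvar, 0), stationary = stationary, id = s$id)
  })
}

## vectorised mixture over many stacked observations.
## Ox, Oy: N x n matrices of per-axis observations.
## Returns unnormalised logW (N x S), component means Mx, My (N x S) and
## per-structure isotropic variances sigma2 (length S).
mixture_batch <- function(Ox, Oy, pre) {
  N <- nrow(Ox); S <- length(pre)
  logW <- matrix(0, N, S); Mx <- matrix(0, N, S); My <- matrix(0, N, S)
  sigma2 <- numeric(S)
  for (j in seq_len(S)) {
    p <- pre[[j]]
    Qx <- rowSums((Ox %*% p$Ainv) * Ox)
    Qy <- rowSums((Oy %*% p$Ainv) * Oy)
    logW[, j] <- p$lprior + p$cst - 0.5 * (Qx + Qy)
    if (!p$stationary) {
      Mx[, j] <- Ox %*% p$k
      My[, j] <- Oy %*% p$k
    }
    sigma2[j] <- p$pvar
  }
  list(logW = logW, Mx = Mx, My = My, sigma2 = sigma2)
}

normalise_logw <- function(logW) {
  m <- apply(logW, 1L, max)
  if (any(!is.finite(m)))
    stop("degenerate model: all structure weights are zero for some observation")
  W <- exp(logW - m)
  W / rowSums(W)
}

.obs_matrix <- function(obs) {
  if (is.list(obs) && !is.null(obs$o)) obs <- obs$o
  o <- rbind(obs)
  stopifnot(is.numeric(o), ncol(o) == 2L, all(is.finite(o)))
  o
}

.obs_sigma <- function(obs, params, n, roles) {
  if (is.list(obs) && !is.null(obs$sigma_obs)) return(rep_len(obs$sigma_obs, n))
  sigma_for_role(params, roles)
}

#' Unnormalised log posterior weight of a causal structure
#'
#' Log prior of the structure (tree prior from `beta`, flag priors from the
#' role-specific `alpha`) plus the closed-form Gaussian log marginal
#' likelihood of the observations with all flag-0 relative velocities pinned
#' to zero and flag-1 velocities marginalised analytically.
#'
#' @param structure a `causal_structure`.
#' @param obs observation set (list with `o` an n x 2 matrix and optionally
#'   `sigma_obs`), or a bare n x 2 matrix.
#' @param params [cim_params()].
#' @param roles element roles.
#' @return log weight (scalar; `-Inf` allowed).
#' @export
structure_log_weight <- function(structure, obs, params,
                                 roles = default_roles(structure$tree$n_elements)) {
  n <- structure$tree$n_elements
  o <- .obs_matrix(obs)
  if (nrow(o) != n) stop("observation count does not match structure elements")
  sig <- .obs_sigma(obs, params, n, roles)
  pre <- structure_precompute(list(structure), params, sig, 1L, roles)
  mb <- mixture_batch(matrix(o[, 1], 1), matrix(o[, 2], 1), pre)
  drop(mb$logW)
}

#' Gaussian posterior of an element's percept under one structure
#'
#' Conjugate linear-Gaussian conditioning of the relative velocity at the
#' element's percept-defining node on the stacked observations. Returns the
#' exact zero-velocity percept (`mean = (0,0)`, `var = 0`) when the percept
#' is stationary.
#'
#' @inheritParams structure_log_weight
#' @param element report-target element id.
#' @return list with `mean` (length-2) and `var` (scalar, isotropic).
#' @export
percept_conditional <- function(structure, obs, params, element = 1L,
                                roles = default_roles(structure$tree$n_elements)) {
  n <- structure$tree$n_elements
  o <- .obs_matrix(obs)
  if (nrow(o) != n) stop("observation count does not match structure elements")
  sig <- .obs_sigma(obs, params, n, roles)
  pre <- structure_precompute(list(structure), params, sig, element, roles)[[1]]
  list(mean = c(sum(o[, 1] * pre$k), sum(o[, 2] * pre$k)), var = pre$pvar)
}

#' Posterior percept mixture over all causal structures
#'
#' The exact posterior over an element's perceived velocity is a mixture of
#' isotropic Gaussians, one component per causal structure, with weights
#' equal to the structure posterior (normalised in log domain by
#' log-sum-exp) and component means/variances from conjugate conditioning.
#'
#' @inheritParams percept_conditional
#' @param structures optional list of `causal_structure` (default: full
#'   enumeration for the scene's element count).
#' @param rules grammar rule-set used when `structures` is `NULL`.
#' @return object of class `"percept_mixture"`: list with `w`, `mu`
#'   (S x 2), `sigma2`, `structure_id`, `element`.
#' @export
percept_mixture <- function(obs, params, element = 1L, structures = NULL,
                            roles = NULL, rules = grammar_rules()) {
  o <- .obs_matrix(obs)
  n <- nrow(o)
  if (is.null(roles)) roles <- default_roles(n)
  if (is.null(structures)) structures <- scene_structures(n, rules)
  if (!length(structures)) stop("`structures` must be nonempty")
  sig <- .obs_sigma(obs, params, n, roles)
  pre <- structure_precompute(structures, params, sig, element, roles)
  mb <- mixture_batch(matrix(o[, 1], 1), matrix(o[, 2], 1), pre)
  w <- drop(normalise_logw(mb$logW))
  structure(list(w = w, mu = cbind(drop(mb$Mx), drop(mb$My)),
                 sigma2 = mb$sigma2,
                 structure_id = vapply(pre, function(p)
                   if (is.null(p$id)) NA_integer_ else p$id, integer(1)),
                 element = element),
            class = "percept_mixture")
}

#' @export
print.percept_mixture <- function(x, top = 5, ...) {
  cat(sprintf("Percept mixture for element %d: %d components (sum w = %.6f)\n",
              x$element, length(x$w), sum(x$w)))
  ord <- order(x$w, decreasing = TRUE)[seq_len(min(top, length(x$w)))]
  df <- data.frame(structure = x$structure_id[ord], w = x$w[ord],
                   mu_x = x$mu[ord, 1], mu_y = x$mu[ord, 2],
                   sigma2 = x$sigma2[ord])
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
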