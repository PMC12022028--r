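#' Model parameters
#'
#' Container for all generative and readout parameters of the hierarchical
#' causal-inference observer. Velocities are in deg/s, angles in degrees
#' (0 deg = rightward, counter-clockwise positive).
#'
#' @param alpha_center,alpha_surround prior mass on the delta (exactly
#'   stationary) component of the relative-velocity prior, for center and
#'   surround element nodes. `alpha` close to 1 encodes a strong expectation
#'   that relative motion in a reference frame is exactly zero.
#' @param alpha_group delta mass for group nodes; defaults to
#'   `alpha_surround` (roles may be tied via [cim_fit()]).
#' @param sigma_prior s.d. (deg/s) of the zero-mean Gaussian slow-speed
#'   component of the relative-velocity prior.
#' @param sigma_delta s.d. (deg/s) of the composition noise added when a
#'   node's velocity is composed from its reference-frame velocity plus its
#'   relative velocity.
#' @param sigma_center,sigma_surround observation noise s.d. (deg/s) per
#'   element role; isotropic in x/y.
#' @param beta prior probability that elements share a causal structure
#'   (for two elements, the prior on the grouped tree).
#' @param lambda_lapse lapse probability; on a lapse the reported direction is
#'   drawn from a stimulus-independent von Mises component.
#' @param theta_lapse,kappa_lapse mean direction (deg) and concentration of
#'   the lapse component (`kappa_lapse = 0` gives a uniform lapse).
#' @param motor_bias constant report bias b (deg).
#' @param kappa_motor concentration of the von Mises motor noise on reports.
#' @return object of class `"cim_params"` (a validated named list).
#' @examples
#' p <- cim_params(alpha_center = 0.9)
#' p$alpha_center
#' @export
cim_params <- function(alpha_center = 0.9, alpha_surround = 0.9,
                       alpha_group = alpha_surround,
                       sigma_prior = 1, sigma_delta = 0.1,
                       sigma_center = 0.3, sigma_surround = 0.1,
                       beta = 0.5,
                       lambda_lapse = 0.02, theta_lapse = 0, kappa_lapse = 0,
                       motor_bias = 0, kappa_motor = 67) {
  p <- list(alpha_center = alpha_center, alpha_surround = alpha_surround,
            alpha_group = alpha_group,
            sigma_prior = sigma_prior, sigma_delta = sigma_delta,
            sigma_center = sigma_center, sigma_surround = sigma_surround,
            beta = beta, lambda_lapse = lambda_lapse,
            theta_lapse = theta_lapse, kappa_lapse = kappa_lapse,
            motor_bias = motor_bias, kappa_motor = kappa_motor)
  validate_cim_params(p)
  structure(p, class = "cim_params")
}

validate_cim_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop(sprintf("parameter `%s` must be a finite number", nm))
  probs <- c("alpha_center", "alpha_surround", "alpha_group", "beta",
             "lambda_lapse")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("parameter `%s` must lie in [0, 1]", nm))
  sds <- c("sigma_prior", "sigma_delta", "sigma_center", "sigma_surround")
  for (nm in sds)
    if (p[[nm]] <= 0) stop(sprintf("parameter `%s` must be > 0", nm))
  for (nm in c("kappa_lapse", "kappa_motor"))
    if (p[[nm]] < 0) stop(sprintf("parameter `%s` must be >= 0", nm))
  invisible(p)
}

#' Update parameters
#' @param object a `cim_params` object.
#' @param ... named replacements, e.g. `alpha_center = 0.5`.
#' @return updated, re-validated `cim_params`.
#' @export
update_params <- function(object, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), names(object))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(repl)) object[[nm]] <- repl[[nm]]
  validate_cim_params(object)
  structure(object, class = "cim_params")
}

#' @export
print.cim_params <- function(x, digits = 4, ...) {
  cat("Hierarchical causal-inference model parameters:\n")
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}

## role of each element node given the element roles of the scene; group
## nodes take alpha_group
alpha_for_node <- function(params, tree, roles) {
  a <- numeric(length(tree$parent))
  for (i in seq_along(tree$parent)) {
    if (tree$kind[i] == "group") a[i] <- params$alpha_group
    else a[i] <- if (roles[i] == "center") params$alpha_center else
                   params$alpha_surround
  }
  a
}

sigma_for_role <- function(params, roles) {
  ifelse(roles == "center", params$sigma_center, params$sigma_surround)
}

#' Default element roles for a scene
#' @param n_elements number of elements.
#' @return character vector; element 1 is the report target ("center").
#' @export
default_roles <- function(n_elements) {
  if (n_elements == 1L) "center"
  else if (n_elements == 2L) c("center", "surround")
  else c("center", paste0("surround", seq_len(n_elements - 1L)))
}
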