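## Stimulus geometry for the two behavioural designs, the modulation index,
## trial preprocessing, observer QC and the synthetic observer.

#' Center/surround velocities for the two-element design
#'
#' The surround moves horizontally rightwards at 1 deg/s (or is stationary);
#' the center's horizontal velocity component is matched to the surround so
#' that the center-surround relative velocity is exactly vertical (+/-90 deg)
#' for any nonzero center direction.
#'
#' @param center_direction center retinal direction in degrees, |dir| < 90.
#' @param surround_moving logical; stationary surround is the control.
#' @return list with `center` and `surround` length-2 velocities (deg/s).
#' @examples
#' exp1_velocities(45, TRUE)  # center (1,1), surround (1,0)
#' @export
exp1_velocities <- function(center_direction, surround_moving = TRUE) {
  if (!is.finite(center_direction) || abs(center_direction) >= 90)
    stop("|center_direction| must be < 90 degrees for this geometry")
  center <- c(1, tan(deg2rad(center_direction)))
  surround <- if (surround_moving) c(1, 0) else c(0, 0)
  list(center = center, surround = surround)
}

#' Center/inner/outer velocities for the three-element design
#'
#' Canonical frame with the center moving at 0 deg at 0.5 deg/s. The inner
#' ring's direction is offset clockwise (negative degrees) from the center
#' with its speed solved so the inner-center relative velocity is
#' perpendicular to the center direction; the outer ring is anchored 60 deg
#' counter-clockwise from the center at zero inner offset, and its velocity
#' is solved to keep the outer-inner relative velocity constant across inner
#' offsets while staying perpendicular to the center.
#'
#' @param inner_offset inner-ring direction offset in degrees, in [-45, 0].
#' @return 3 x 2 matrix with rows center, inner, outer (deg/s).
#' @export
exp2_velocities <- function(inner_offset) {
  if (!is.finite(inner_offset) || inner_offset < -45 || inner_offset > 0)
    stop("inner_offset must lie in [-45, 0] degrees")
  speed <- 0.5
  center <- c(speed, 0)
  # perpendicular relative velocity forces the x-component to match the center
  inner <- c(speed, speed * tan(deg2rad(inner_offset)))
  rel0 <- c(0, speed * tan(deg2rad(60)))  # outer - inner at zero offset
  outer <- inner + rel0
  if (abs((outer - center)[1]) > 1e-12)
    stop("infeasible geometry: outer-center relative velocity not perpendicular")
  rbind(center = center, inner = inner, outer = outer)
}

#' Predicted percept under a modulation index
#'
#' Piecewise linear map summarising the surround's effect on the perceived
#' center velocity: `w = +1` gives the center-minus-surround relative
#' velocity (complete segmentation), `w = 0` the retinal center velocity (no
#' effect), `w = -1` the surround velocity (complete integration).
#'
#' @param w modulation index in [-1, 1].
#' @param o_center,o_surround observed velocities (length-2, deg/s).
#' @return length-2 percept velocity.
#' @export
modulation_percept <- function(w, o_center, o_surround) {
  stopifnot(length(w) == 1L, w >= -1, w <= 1)
  if (w >= 0) o_center - w * o_surround
  else (1 + w) * o_center - w * o_surround
}

#' Noiseless algebraic inversion of the modulation index
#'
#' Finds the `w` in [-1, 1] whose predicted percept direction equals the
#' given direction. The map from `w` to percept direction is monotone for
#' the two-element geometry; inversion uses a fine grid plus root polishing.
#' Directions unreachable under any `w` return the nearest endpoint with
#' attribute `clipped = TRUE` (the noise-aware [infer_modulation_index()] is
#' the unbiased tool for real reports).
#'
#' @param direction target percept direction (deg).
#' @param o_center,o_surround observed velocities (length-2, deg/s).
#' @return modulation index in [-1, 1].
#' @export
invert_modulation_index <- function(direction, o_center, o_surround) {
  ang <- function(w) {
    p <- modulation_percept(w, o_center, o_surround)
    rad2deg(atan2(p[2], p[1]))
  }
  ad <- function(w) {
    d <- (ang(w) - direction) %% 360
    if (d > 180) d <- d - 360
    d
  }
  grid <- seq(-1, 1, length.out = 4001)
  dv <- vapply(grid, ad, numeric(1))
  i <- which.min(abs(dv))
  if (abs(dv[i]) < 1e-9) return(grid[i])
  # bracket a sign change around the best grid point
  lo <- max(i - 1L, 1L); hi <- min(i + 1L, length(grid))
  if (sign(dv[lo]) != sign(dv[hi])) {
    r <- stats::uniroot(ad, c(grid[lo], grid[hi]), tol = 1e-12)
    return(r$root)
  }
  structure(grid[i], clipped = TRUE)
}

#' Noise-aware posterior over the modulation index
#'
#' Grid posterior over `w` in [-1, 1] under a forward model with explicit
#' observation noise (marginalised by Gauss-Hermite quadrature), motor bias
#' and von Mises motor noise, and the lapse mixture. A uniform prior over
#' `w` is used; the likelihood is never zero, so no clipping of the grid is
#' needed. The naive per-trial algebraic inversion is also returned, flagged
#' as biased.
#'
#' @param reports reported directions (deg), nonempty.
#' @param cond a two-element [stimulus_condition()].
#' @param params [cim_params()] supplying the noise/motor/lapse terms.
#' @param grid_n number of grid points over [-1, 1].
#' @param order quadrature order per scalar dimension.
#' @param ci credible-interval mass.
#' @return list with `mean`, `sd`, `ci` (quantile interval), `mode`, `grid`,
#'   `posterior`, and `naive` (per-trial inversions, biased).
#' @export
infer_modulation_index <- function(reports, cond, params, grid_n = 201,
                                   order = 7, ci = 0.95) {
  stopifnot(length(reports) >= 1, inherits(cond, "stimulus_condition"),
            nrow(cond$nu) == 2L)
  sig <- cond_sigma_obs(cond, params)
  q <- gh_observation_nodes(cond$nu, sig, order)
  grid <- seq(-1, 1, length.out = grid_n)
  lam <- params$lambda_lapse
  loglik <- vapply(grid, function(w) {
    cc <- if (w >= 0) 1 else 1 + w
    px <- cc * q$Ox[, 1] - w * q$Ox[, 2]
    py <- cc * q$Oy[, 1] - w * q$Oy[, 2]
    thw <- wrap_deg(rad2deg(atan2(py, px)) + params$motor_bias)
    dens <- vm_mixture_density(reports, q$w, thw,
                               rep(params$kappa_motor, length(thw)))
    dens <- lam / 360 + (1 - lam) * dens
    sum(log(dens))
  }, numeric(1))
  post <- exp(loglik - logsumexp(loglik))
  m <- sum(post * grid)
  s <- sqrt(max(sum(post * grid^2) - m^2, 0))
  cum <- cumsum(post)
  qfun <- function(p) grid[which.max(cum >= p)]
  naive <- vapply(reports, function(r)
    as.numeric(invert_modulation_index(r, cond$nu[1, ], cond$nu[2, ])),
    numeric(1))
  list(mean = m, sd = s,
       ci = c(qfun((1 - ci) / 2), qfun(1 - (1 - ci) / 2)),
       mode = grid[which.max(post)], grid = grid, posterior = post,
       naive = structure(naive, biased = TRUE))
}

## ---- condition grids and trial tables -------------------------------------

exp1_label <- function(center_dir, surround_moving, n_patches) {
  sprintf("c%+05.1f_%s_k%d", center_dir,
          ifelse(surround_moving, "mov", "sta"), n_patches)
}

#' Build one two-element stimulus condition
#'
#' Observation noise for the surround is scaled by `1/sqrt(n_patches)`:
#' a surround made of more patches yields a more reliable velocity signal.
#'
#' @param center_dir center direction (deg).
#' @param surround_moving logical.
#' @param n_patches number of surround patches.
#' @return a [stimulus_condition()].
#' @export
exp1_condition <- function(center_dir, surround_moving = TRUE, n_patches = 5) {
  v <- exp1_velocities(center_dir, surround_moving)
  stimulus_condition(rbind(v$center, v$surround),
                     label = exp1_label(center_dir, surround_moving, n_patches),
                     roles = c("center", "surround"),
                     sigma_scale = c(1, 1 / sqrt(n_patches)))
}

#' Condition grid for the two-element design
#'
#' Full factor set: center directions crossed with surround patch counts for
#' the moving surround, plus the stationary-surround control (always 5
#' patches). Complete and duplicate-free.
#'
#' @param center_directions center directions (deg).
#' @param n_patches surround patch counts for the moving-surround conditions.
#' @param control include the stationary-surround control conditions?
#' @return data frame with columns `condition`, `center_dir_deg`,
#'   `surround_moving`, `n_surround_patches`.
#' @export
exp1_grid <- function(center_directions = c(0, 2.5, 5, 10, 20, 45,
                                            -2.5, -5, -10, -20, -45),
                      n_patches = c(1, 2, 3, 5, 10),
                      control = TRUE) {
  g <- expand.grid(center_dir_deg = center_directions,
                   n_surround_patches = n_patches,
                   KEEP.OUT.ATTRS = FALSE)
  g$surround_moving <- TRUE
  if (control) {
    gc <- data.frame(center_dir_deg = center_directions,
                     n_surround_patches = 5, surround_moving = FALSE)
    g <- rbind(g, gc)
  }
  g$condition <- exp1_label(g$center_dir_deg, g$surround_moving,
                            g$n_surround_patches)
  stopifnot(!anyDuplicated(g$condition))
  g[, c("condition", "center_dir_deg", "surround_moving",
        "n_surround_patches")]
}

#' Build one three-element (center / inner ring / outer ring) condition
#'
#' Canonical frame (center at 0 deg); inner and outer ring velocities from
#' [exp2_velocities()]. Observation noise scales encode the increasing dot
#' counts from center to inner to outer ring (10, 50, 250 dots), so each
#' ring is a more reliable signal than the one inside it.
#'
#' @param inner_offset inner-ring offset (deg) in [-45, 0].
#' @param report_target which element is reported (`"center"` or `"inner"`).
#' @return a [stimulus_condition()]; the report target is element 1.
#' @export
exp2_condition <- function(inner_offset, report_target = c("center", "inner")) {
  report_target <- match.arg(report_target)
  v <- exp2_velocities(inner_offset)
  ord <- if (report_target == "center") c(1L, 2L, 3L) else c(2L, 1L, 3L)
  # dot counts 10 / 50 / 250 from center outwards -> noise scales 1/sqrt(k/10)
  scales <- c(center = 1, inner = 1 / sqrt(5), outer = 1 / sqrt(25))
  part <- c("center", "inner", "outer")[ord]
  # element 1 is the report target (role "center"); the others act as
  # surround-type elements whose reliability differences live in sigma_scale
  roles <- c("center", paste0("surround_", part[-1]))
  stimulus_condition(v[ord, , drop = FALSE],
                     label = sprintf("e2_off%+05.1f_%s", inner_offset,
                                     report_target),
                     roles = roles,
                     sigma_scale = unname(scales[part]))
}

#' Condition grid for the three-element design
#'
#' Inner-ring offsets crossed with the report-target factor; complete and
#' duplicate-free.
#'
#' @param inner_offsets inner-ring offsets (deg).
#' @param report_targets report-target levels.
#' @return data frame with `condition`, `inner_offset_deg`, `report_target`.
#' @export
exp2_grid <- function(inner_offsets = c(0, -3, -10, -30, -45),
                      report_targets = c("center", "inner")) {
  g <- expand.grid(inner_offset_deg = inner_offsets,
                   report_target = report_targets,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$condition <- sprintf("e2_off%+05.1f_%s", g$inner_offset_deg,
                         g$report_target)
  stopifnot(!anyDuplicated(g$condition))
  g
}

#' Resolve trial rows to stimulus conditions
#' @param data a trial table (see [read_trials()]).
#' @return named list of [stimulus_condition()] keyed by condition label.
#' @export
resolve_conditions <- function(data) {
  key <- unique(data[, c("condition", "center_dir_deg", "surround_moving",
                         "n_surround_patches")])
  out <- lapply(seq_len(nrow(key)), function(i)
    exp1_condition(key$center_dir_deg[i], key$surround_moving[i],
                   key$n_surround_patches[i]))
  names(out) <- key$condition
  out
}

#' Reflect reports for negative center directions
#'
#' Reports (and conditions) for negative center directions are mirrored
#' about the horizontal axis so that all conditions have positive center
#' directions; applying the operation twice is the identity on the already
#' positive rows. A symmetry summary (circular mean of flipped vs unflipped
#' reports per |direction|) is attached as attribute `"symmetry"`.
#'
#' @param data a trial table with two-element condition columns.
#' @return trial table with nonnegative center directions.
#' @export
preprocess_reports <- function(data) {
  neg <- data$center_dir_deg < 0
  out <- data
  out$center_dir_deg[neg] <- -data$center_dir_deg[neg]
  out$report_deg[neg] <- wrap_deg(-data$report_deg[neg])
  out$condition <- exp1_label(out$center_dir_deg, out$surround_moving,
                              out$n_surround_patches)
  sym <- stats::aggregate(report_deg ~ center_dir_deg + surround_moving + flipped,
                          data = transform(out, flipped = neg),
                          FUN = function(x) circular_mean_deg(x))
  attr(out, "symmetry") <- sym
  out
}

#' Circular mean (deg)
#' @param x angles in degrees.
#' @return mean direction in `[0, 360)`.
#' @export
circular_mean_deg <- function(x) {
  wrap_deg(rad2deg(atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x))))))
}

#' Circular standard deviation (deg)
#'
#' Defined through the mean resultant length as `sqrt(-2 log Rbar)`,
#' converted to degrees.
#' @param x angles in degrees.
#' @return circular s.d. in degrees.
#' @export
circular_sd_deg <- function(x) {
  Rbar <- sqrt(mean(cos(deg2rad(x)))^2 + mean(sin(deg2rad(x)))^2)
  rad2deg(sqrt(-2 * log(max(Rbar, .Machine$double.xmin))))
}

#' Observer quality control
#'
#' Computes the circular standard deviation of control-condition reports
#' relative to the identity prediction (report minus center direction) and
#' excludes the observer iff it exceeds 30 degrees (strict inequality; a
#' value of exactly 30 is kept).
#'
#' @param data a trial table.
#' @param control_conditions condition labels of the control trials
#'   (default: all stationary-surround rows).
#' @param threshold exclusion threshold in degrees.
#' @return list with `keep` (logical), `circular_sd` (deg), `n_control`.
#' @export
observer_qc <- function(data, control_conditions = NULL, threshold = 30) {
  ctrl <- if (is.null(control_conditions)) !data$surround_moving
          else data$condition %in% control_conditions
  if (!any(ctrl)) stop("no control trials found for observer QC")
  resid <- data$report_deg[ctrl] - data$center_dir_deg[ctrl]
  s <- circular_sd_deg(resid)
  list(keep = !(s > threshold), circular_sd = s, n_control = sum(ctrl))
}

#' Simulate a synthetic observer on a condition grid
#'
#' Runs [simulate_responses()] for every condition of the grid and returns a
#' trial table in the standard schema.
#'
#' @param params [cim_params()] of the synthetic observer.
#' @param grid condition grid as from [exp1_grid()].
#' @param trials_per_condition trials per condition.
#' @param strategy readout strategy.
#' @param seed integer seed (one stream for the whole table).
#' @param observer,session identifiers written to the table.
#' @param t2 T2 calibration table.
#' @return data frame (trial table).
#' @export
simulate_observer <- function(params, grid = exp1_grid(),
                              trials_per_condition = 22,
                              strategy = "posterior_sampling", seed = 1L,
                              observer = "sim1", session = 1L,
                              t2 = default_t2()) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cond <- exp1_condition(grid$center_dir_deg[i], grid$surround_moving[i],
                           grid$n_surround_patches[i])
    r <- simulate_responses(cond, params, strategy, trials_per_condition,
                            seed = NULL, t2 = t2)
    data.frame(observer = observer, session = session,
               condition = cond$label,
               center_dir_deg = grid$center_dir_deg[i],
               surround_moving = grid$surround_moving[i],
               n_surround_patches = grid$n_surround_patches[i],
               report_deg = r)
  })
  do.call(rbind, rows)
}
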