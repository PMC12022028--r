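test_that("two-element geometry keeps the relative velocity vertical", {
  v0 <- exp1_velocities(0, TRUE)
  expect_equal(v0$center, c(1, 0))
  expect_equal(v0$surround, c(1, 0))
  v45 <- exp1_velocities(45, TRUE)
  expect_equal(v45$center, c(1, 1))
  rel <- v45$center - v45$surround
  expect_equal(atan2(rel[2], rel[1]) * 180 / pi, 90)
  vs <- exp1_velocities(45, FALSE)
  expect_equal(vs$surround, c(0, 0))
  expect_equal(vs$center, c(1, 1))
  for (d in c(-45, -20, -5, 2.5, 10, 20, 45)) {
    v <- exp1_velocities(d, TRUE)
    rel <- v$center - v$surround
    expect_equal(abs(atan2(rel[2], rel[1])) * 180 / pi, 90, tolerance = 1e-10)
  }
  expect_error(exp1_velocities(90, TRUE), "< 90")
})

test_that("three-element geometry satisfies the ring constraints", {
  v0 <- exp2_velocities(0)
  expect_equal(v0["inner", ], v0["center", ])
  outer_dir <- unname(atan2(v0["outer", 2], v0["outer", 1]) * 180 / pi)
  expect_equal(outer_dir, 60, tolerance = 1e-10)
  v45 <- exp2_velocities(-45)
  expect_equal(sqrt(sum(v45["inner", ]^2)), 0.5 * sqrt(2), tolerance = 1e-12)
  rel_ref <- exp2_velocities(0)["outer", ] - exp2_velocities(0)["inner", ]
  for (off in c(0, -3, -10, -30, -45)) {
    v <- exp2_velocities(off)
    for (ring in c("inner", "outer")) {
      rel <- v[ring, ] - v["center", ]
      expect_lt(abs(sum(rel * v["center", ])), 1e-12)  # perpendicularity
    }
    expect_equal(v["outer", ] - v["inner", ], rel_ref, tolerance = 1e-10)
  }
  expect_error(exp2_velocities(5), "\\[-45, 0\\]")
})

test_that("three-element conditions wire geometry, roles and reliability", {
  g <- exp2_grid()
  expect_equal(nrow(g), 10)
  expect_false(anyDuplicated(g$condition) > 0)
  cond <- exp2_condition(-10)
  expect_equal(cond$roles[1], "center")
  expect_equal(cond$nu, exp2_velocities(-10), ignore_attr = TRUE)
  # rings with more dots are more reliable signals
  expect_true(all(diff(cond$sigma_scale) < 0))
  # reporting the inner ring puts it first with the center demoted to surround
  ci <- exp2_condition(-10, report_target = "inner")
  expect_equal(ci$nu[1, ], exp2_velocities(-10)["inner", ],
               ignore_attr = TRUE)
  expect_equal(ci$roles[1], "center")
  expect_false("center" %in% ci$roles[-1])
  # the full 264-structure posterior runs on a three-element condition
  p <- cim_params()
  pm <- percept_mixture(list(o = cond$nu,
                             sigma_obs = hiermotion:::cond_sigma_obs(cond, p)),
                        p, roles = cond$roles)
  expect_length(pm$w, 264)
  expect_equal(sum(pm$w), 1, tolerance = 1e-10)
  # pure-structure restriction is a valid sub-model
  pure <- Filter(is_pure, hiermotion:::scene_structures(3))
  pm_pure <- percept_mixture(list(o = cond$nu,
                                  sigma_obs = hiermotion:::cond_sigma_obs(cond, p)),
                             p, structures = pure, roles = cond$roles)
  expect_equal(sum(pm_pure$w), 1, tolerance = 1e-10)
})

test_that("the modulation index maps its anchor percepts exactly", {
  oc <- c(1, 1); os <- c(1, 0)
  expect_equal(modulation_percept(1, oc, os), oc - os)
  expect_equal(modulation_percept(-1, oc, os), os)
  expect_equal(modulation_percept(0, oc, os), oc)
  # inversion returns the anchors from the anchor directions
  expect_equal(as.numeric(invert_modulation_index(90, oc, os)), 1,
               tolerance = 1e-6)
  expect_equal(as.numeric(invert_modulation_index(45, oc, os)), 0,
               tolerance = 1e-6)
  expect_equal(as.numeric(invert_modulation_index(0, oc, os)), -1,
               tolerance = 1e-6)
  # interior consistency: forward then invert recovers w
  for (w in c(-0.6, 0.3, 0.5)) {
    pv <- modulation_percept(w, oc, os)
    d <- atan2(pv[2], pv[1]) * 180 / pi
    expect_equal(as.numeric(invert_modulation_index(d, oc, os)), w,
                 tolerance = 1e-6)
  }
})

test_that("noise-aware modulation inference recovers the generating index", {
  p <- cim_params(sigma_center = 0.15, sigma_surround = 0.08,
                  kappa_motor = 67, lambda_lapse = 0.02)
  cond <- exp1_condition(20, TRUE, 5)
  w_true <- 0.3
  pv <- modulation_percept(w_true, cond$nu[1, ], cond$nu[2, ])
  d_true <- atan2(pv[2], pv[1]) * 180 / pi
  # near-noiseless reports pin the posterior at the generating index
  mi0 <- infer_modulation_index(rep(d_true, 30), cond,
                                update_params(p, kappa_motor = 1e4,
                                              sigma_center = 1e-3,
                                              sigma_surround = 1e-3,
                                              lambda_lapse = 0),
                                order = 5)
  expect_equal(mi0$mode, w_true, tolerance = 0.02)
  # reports at the surround direction indicate full integration
  mi_int <- infer_modulation_index(rep(0, 30), cond,
                                   update_params(p, kappa_motor = 1e4,
                                                 sigma_center = 1e-3,
                                                 sigma_surround = 1e-3,
                                                 lambda_lapse = 0),
                                   order = 5)
  expect_lt(mi_int$mode, -0.9)
  # recovery with motor noise: CI covers in most replicates
  set.seed(77)
  cover <- 0
  for (r in 1:10) {
    reps <- hiermotion:::wrap_deg(d_true +
      rvonmises_deg(40, 0, p$kappa_motor))
    mi <- infer_modulation_index(reps, cond, p, order = 5)
    if (mi$ci[1] <= w_true && w_true <= mi$ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 8)
  expect_true(isTRUE(attr(mi0$naive, "biased")))
})

test_that("report preprocessing reflects negative center directions", {
  dat <- data.frame(observer = "o1", session = 1,
                    condition = hiermotion:::exp1_label(c(-20, 20, -5), TRUE, 5),
                    center_dir_deg = c(-20, 20, -5), surround_moving = TRUE,
                    n_surround_patches = 5, report_deg = c(350, 10, 100))
  out <- preprocess_reports(dat)
  expect_equal(out$center_dir_deg, c(20, 20, 5))
  expect_equal(out$report_deg, c(10, 10, 260))
  expect_equal(out$report_deg[2], dat$report_deg[2])  # positives unchanged
  twice <- preprocess_reports(out)
  expect_equal(twice$report_deg, out$report_deg)      # involution
  expect_equal(twice$condition, out$condition)
})

test_that("observer QC applies the strict 30-degree rule", {
  sd_to_a <- function(s) acos(exp(-(s * pi / 180)^2 / 2)) * 180 / pi
  build <- function(s) {
    a <- sd_to_a(s)
    data.frame(observer = "o", session = 1,
               condition = hiermotion:::exp1_label(10, FALSE, 5),
               center_dir_deg = 10, surround_moving = FALSE,
               n_surround_patches = 5,
               report_deg = hiermotion:::wrap_deg(10 + c(a, -a)))
  }
  expect_true(observer_qc(build(12))$keep)
  expect_false(observer_qc(build(31))$keep)
  # boundary convention is strict: a dispersion exactly at the threshold is
  # kept (compare the measured value against itself)
  qc30 <- observer_qc(build(30))
  expect_true(observer_qc(build(30), threshold = qc30$circular_sd)$keep)
  expect_equal(observer_qc(build(12))$circular_sd, 12, tolerance = 1e-6)
  moving_only <- build(12); moving_only$surround_moving <- TRUE
  expect_error(observer_qc(moving_only), "no control trials")
})
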