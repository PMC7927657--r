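test_that("sphere-based initial guess matches the independent bisection oracle", {
  geom <- foram_geom()
  guess <- initial_operating_guess(geom, seawater(), calcite())
  re_oracle <- oracle_terminal_re(morrison_cd, geom, calcite(), seawater())
  expect_equal(guess$Re_O, re_oracle, tolerance = 1e-3)
  expect_equal(guess$U_O, speed_from_reynolds(re_oracle, geom$L, seawater()),
               tolerance = 1e-3)
  expect_false(guess$extrapolated)
  expect_identical(guess$iteration, 0L)
})

test_that("initial guess recovers the Stokes terminal velocity for tiny spheres", {
  d <- 1e-4
  geom <- sphere_geom(d)
  oil <- mineral_oil()
  mat <- material_spec(1500)
  guess <- initial_operating_guess(geom, oil, mat)
  expect_lt(guess$Re_O, 0.1)
  U_stokes <- standard_gravity() * d^2 * (mat$density - oil$density) / (18 * oil$viscosity)
  expect_equal(guess$U_O, U_stokes, tolerance = 0.02)
})

test_that("first-scale planning honours the no-wall limit and the S2 < S1 < S3 ordering", {
  geom <- foram_geom()
  guess <- initial_operating_guess(geom, seawater(), calcite())
  # enormous tank: S1 solves the scaled force balance with no wall correction,
  # computed here in closed form (constraint ~ S^3 with V = S^3 V^O)
  scales0 <- plan_first_scales(guess, geom, 1e6, mineral_oil(), printing_resin())
  s1_closed <- (guess$C_D_O * guess$Re_O^2 * geom$A * mineral_oil()$viscosity^2 /
                  (2 * standard_gravity() * geom$V *
                     (printing_resin()$density - mineral_oil()$density) *
                     geom$L^2 * mineral_oil()$density))^(1 / 3)
  expect_equal(unname(scales0[["S1"]]), s1_closed, tolerance = 1e-6)
  # real tank: ordering holds, and the wall-amplified drag target demands a
  # slightly larger model to reach the same Re
  scales <- plan_first_scales(guess, geom, 0.9, mineral_oil(), printing_resin())
  expect_lt(scales[["S2"]], scales[["S1"]])
  expect_lt(scales[["S1"]], scales[["S3"]])
  expect_gt(scales[["S1"]], scales0[["S1"]])
})

test_that("the S1 model lands near the guessed Re in a noiseless virtual tank", {
  geom <- foram_geom()
  guess <- initial_operating_guess(geom, seawater(), calcite())
  scales <- plan_first_scales(guess, geom, 0.9, mineral_oil(), printing_resin())
  truth <- virtual_particle_truth(geom, morrison_correlation(), calcite())
  rec <- sink_model(truth, scales[["S1"]], 0.9, mineral_oil(), printing_resin(),
                    noise_model(velocity_cv = 0, volume_bias_c = 0))
  re_meas <- reynolds(scales[["S1"]] * geom$L, mean(rec$speeds), mineral_oil())
  expect_equal(re_meas, guess$Re_O, tolerance = 0.1)
})

test_that("volume prediction: cubic scaling below 4 pairs, interpolation above", {
  # single pair: pure cubic scaling
  vp1 <- volume_predictor(10, 5e-8)
  expect_equal(predict_volume(vp1, 20), 8 * 5e-8)
  # prediction at a measured S returns the measured V exactly
  S <- c(8, 10, 12, 14, 16)
  V <- 2e-10 * S^3 * (1 + 0.5 / S)
  vp <- volume_predictor(S, V)
  expect_equal(predict_volume(vp, S), V)
  # interior predictions track the generating rule within 1%
  Sq <- seq(8.5, 15.5, by = 0.5)
  Vtrue <- 2e-10 * Sq^3 * (1 + 0.5 / Sq)
  expect_lt(max(abs(predict_volume(vp, Sq) - Vtrue) / Vtrue), 0.01)
  # outside the measured range: cubic scaling from the nearest pair
  expect_equal(predict_volume(vp, 32), V[5] * (32 / 16)^3)
  expect_error(volume_predictor(numeric(0), numeric(0)), "insufficient")
})

test_that("operating point solved on an exact sphere-curve fit matches the oracle", {
  geom <- foram_geom()
  re <- c(12, 20, 32, 48, 70, 100)
  crv <- fit_drag_spline(data.frame(Re = re, C_D = morrison_cd(re)))
  op <- solve_operating_point(crv, geom, seawater(), calcite())
  U_oracle <- oracle_terminal_u(morrison_cd, geom, calcite(), seawater())
  expect_equal(op$U_O, U_oracle, tolerance = 0.01)
  expect_false(op$extrapolated)
  # the root is a true intersection
  expect_lt(op$residual, 1e-6)
  expect_equal(cd_force_balance(op$Re_O, geom, calcite(), seawater()),
               as.numeric(predict(crv, op$Re_O)), tolerance = 1e-6)
})

test_that("raising the drag curve lowers the operating Re", {
  geom <- foram_geom()
  re <- c(12, 20, 32, 48, 70, 100)
  base <- fit_drag_spline(data.frame(Re = re, C_D = morrison_cd(re)))
  doubled <- fit_drag_spline(data.frame(Re = re, C_D = 2 * morrison_cd(re)))
  op1 <- solve_operating_point(base, geom, seawater(), calcite())
  op2 <- solve_operating_point(doubled, geom, seawater(), calcite())
  expect_lt(op2$Re_O, op1$Re_O)
})

test_that("an operating point outside the fitted range is flagged as extrapolated", {
  geom <- foram_geom() # operates near Re ~ 42
  re <- c(80, 120, 180)
  crv <- fit_drag_spline(data.frame(Re = re, C_D = morrison_cd(re)))
  op <- solve_operating_point(crv, geom, seawater(), calcite())
  expect_true(op$extrapolated)
})

test_that("next_scale is deterministic and closes the loop in a noiseless tank", {
  geom <- foram_geom()
  truth <- virtual_particle_truth(geom, morrison_correlation(), calcite())
  src <- virtual_experiment_source(truth, 0.9, mineral_oil(), printing_resin(),
                                   noise_model(velocity_cv = 0))
  guess <- initial_operating_guess(geom, seawater(), calcite())
  scales <- plan_first_scales(guess, geom, 0.9, mineral_oil(), printing_resin())
  recs <- lapply(scales, src)
  pts <- suppressWarnings(
    drag_points_from_records(recs, geom, 0.9, mineral_oil(), printing_resin()))
  op <- solve_operating_point(fit_drag_spline(pts[, c("Re", "C_D")]),
                              geom, seawater(), calcite())
  vp <- volume_predictor(pts$S, vapply(recs, `[[`, numeric(1), "V_model"))
  s_next <- next_scale(op, vp, geom, 0.9, mineral_oil(), printing_resin())
  expect_identical(s_next, next_scale(op, vp, geom, 0.9, mineral_oil(), printing_resin()))
  # the planned model should land within 5% of the predicted operating Re
  rec <- src(s_next)
  re_meas <- reynolds(s_next * geom$L, mean(rec$speeds), mineral_oil())
  expect_equal(re_meas, op$Re_O, tolerance = 0.05)
  # a much wider tank changes the plan by well under 1% at small lambda
  s_wide <- next_scale(op, vp, geom, 1.8, mineral_oil(), printing_resin())
  expect_lt(abs(s_wide - s_next) / s_next, 0.01)
})

test_that("convergence report applies the three criteria exactly", {
  pts <- data.frame(Re = c(20, 40, 60))
  op_in <- operating_point(41, 1.6, 0.05, extrapolated = FALSE, iteration = 3L)
  op_out <- operating_point(41, 1.6, 0.05, extrapolated = TRUE, iteration = 3L)
  # all criteria pass
  rep1 <- check_convergence(op_in, pts, U_cubic = 0.05, U_linear = 0.05)
  expect_true(rep1$converged)
  expect_equal(rep1$criterion3_re_gap, 1 / 41)
  # criterion 2 boundary: 5% is still convergent, 6% is not
  expect_true(check_convergence(op_in, pts, 100, 105)$converged)
  expect_false(check_convergence(op_in, pts, 100, 106)$converged)
  # criterion 1: extrapolated operating point blocks convergence
  expect_false(check_convergence(op_out, pts, 0.05, 0.05)$converged)
  # criterion 3: nearest measured Re must be within 15% (strict)
  far <- data.frame(Re = c(10, 100, 200))
  op_far <- operating_point(50, 1.3, 0.06, FALSE, 3L)
  rep3 <- check_convergence(op_far, far, 0.06, 0.06)
  expect_false(rep3$converged)
  expect_equal(rep3$criterion3_re_gap, 40 / 50)
  expect_error(check_convergence(op_in, data.frame(Re = c(20, 40)), 1, 1), ">= 3")
})

test_that("noiseless closed-loop runs recover the truth for a family of drag curves", {
  cases <- list(list(factor = 1, shift = 0),
                list(factor = 0.7, shift = 0),
                list(factor = 1.5, shift = 0),
                list(factor = 1, shift = -0.1),
                list(factor = 1, shift = 0.1))
  for (cs in cases) {
    res <- run_virtual(factor = cs$factor, shift = cs$shift, cv = 0)
    expect_lt(res$rel_err, 0.01)
    expect_true(res$run$converged)
    expect_gte(res$run$n_models, 3L)
    expect_lt(res$run$operating_point$residual, 1e-6)
  }
})

test_that("estimation histories are reproducible under a fixed seed", {
  r1 <- run_virtual(factor = 1.2, cv = 0.02, seed = 77)
  r2 <- run_virtual(factor = 1.2, cv = 0.02, seed = 77)
  expect_identical(r1$run$history, r2$run$history)
  expect_identical(r1$run$operating_point$U_O, r2$run$operating_point$U_O)
})

test_that("hitting max_iter returns the best estimate flagged, never silently", {
  geom <- foram_geom()
  truth <- virtual_particle_truth(geom, morrison_correlation(), calcite())
  base <- virtual_experiment_source(truth, 0.9, mineral_oil(), printing_resin(),
                                    noise_model(velocity_cv = 0, seed = 5))
  # an adversarial tank whose measured speeds swing by +/-25% defeats the
  # convergence criteria within the allotted models
  k <- 0
  wild <- function(S) {
    k <<- k + 1
    rec <- base(S)
    rec$speeds <- rec$speeds * (1 + 0.25 * (-1)^k)
    rec
  }
  w <- capture_warnings(run <- run_estimation(geom, seawater(), calcite(), 0.9,
                                              mineral_oil(), printing_resin(), wild,
                                              max_iter = 4L))
  expect_true(any(grepl("did not converge", w)))
  expect_false(run$converged)
  expect_identical(run$n_models, 4L)
  expect_s3_class(run$operating_point, "operating_point")
})
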