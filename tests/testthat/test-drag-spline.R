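morrison_points <- function(re) data.frame(Re = re, C_D = morrison_cd(re))

test_that("cubic fit to exact sphere-curve samples reproduces the curve off-sample", {
  crv <- fit_drag_spline(morrison_points(c(10, 20, 40, 70, 100)))
  test_re <- seq(10, 100, length.out = 41)
  err <- abs(as.numeric(predict(crv, test_re)) - morrison_cd(test_re)) / morrison_cd(test_re)
  expect_lt(max(err), 0.02)
  expect_equal(as.numeric(predict(crv, 50)), morrison_cd(50), tolerance = 0.02)
})

test_that("three collinear log-log points are interpolated exactly by the linear fit", {
  re <- c(10, 30, 90)
  cd <- 5 * re^-0.8
  crv <- fit_drag_spline(data.frame(Re = re, C_D = cd), order = "linear")
  expect_equal(as.numeric(predict(crv, re)), cd, tolerance = 1e-6)
  expect_equal(as.numeric(predict(crv, 17)), 5 * 17^-0.8, tolerance = 1e-6)
})

test_that("fitted curves obey the monotone-decreasing and concave-up constraints", {
  re <- c(5, 12, 30, 60, 120)
  crv <- fit_drag_spline(data.frame(Re = re, C_D = 0.8 + 24 / re))
  dense <- exp(seq(log(5), log(120), length.out = 300))
  vals <- as.numeric(predict(crv, dense))
  expect_true(all(diff(vals) < 0))
  # concave-up in linear (Re, C_D) coordinates, checked by finite differences
  d2 <- diff(diff(vals) / diff(dense)) / diff(dense[-1])
  expect_true(all(d2 > -1e-8 * max(vals)))
  # three-point cubic fit honours the same constraints
  crv3 <- fit_drag_spline(morrison_points(c(15, 35, 80)))
  v3 <- as.numeric(predict(crv3, exp(seq(log(15), log(80), length.out = 250))))
  expect_true(all(diff(v3) < 0))
})

test_that("evaluations outside the data range are linear in fit space and flagged", {
  crv <- fit_drag_spline(morrison_points(c(10, 20, 40, 70, 100)))
  p <- predict(crv, c(50, 150, 5))
  expect_equal(attr(p, "extrapolated"), c(FALSE, TRUE, TRUE))
  expect_equal(drag_curve_extrapolated(crv, c(50, 150, 5)), c(FALSE, TRUE, TRUE))
  # linear continuation in log-log space: constant log-slope beyond the range
  hi <- c(110, 121, 133.1)
  lp <- log10(as.numeric(predict(crv, hi)))
  expect_equal(diff(lp)[1], diff(lp)[2], tolerance = 1e-10)
})

test_that("refitting after adding an on-curve point barely changes the curve", {
  crv <- fit_drag_spline(morrison_points(c(10, 20, 40, 70, 100)))
  new_re <- 55
  new_cd <- as.numeric(predict(crv, new_re))
  crv2 <- fit_drag_spline(rbind(morrison_points(c(10, 20, 40, 70, 100)),
                                data.frame(Re = new_re, C_D = new_cd)))
  test_re <- seq(10, 100, length.out = 31)
  rel <- abs(as.numeric(predict(crv2, test_re)) - as.numeric(predict(crv, test_re))) /
    as.numeric(predict(crv, test_re))
  expect_lt(max(rel), 0.01)
})

test_that("cubic and linear fits to ample exact data give closely matching operating points", {
  geom <- foram_geom()
  pts <- morrison_points(c(12, 20, 32, 48, 70, 100))
  op_c <- solve_operating_point(fit_drag_spline(pts, "cubic"), geom, seawater(), calcite())
  op_l <- solve_operating_point(fit_drag_spline(pts, "linear"), geom, seawater(), calcite())
  expect_lt(abs(op_l$U_O - op_c$U_O) / op_c$U_O, 0.05)
})

test_that("degenerate or insufficient drag data is rejected", {
  expect_error(fit_drag_spline(morrison_points(c(10, 20))), "insufficient")
  expect_error(fit_drag_spline(data.frame(Re = c(10, 10, 20), C_D = c(4, 4.1, 2))),
               "duplicate")
  expect_error(fit_drag_spline(data.frame(Re = c(10, 20, 30), C_D = c(1, -2, 3))),
               "positive")
})

test_that("strongly non-monotone data triggers the best-feasible-fit warning", {
  bad <- data.frame(Re = c(10, 20, 40, 80), C_D = c(1, 4, 0.7, 3.5))
  expect_warning(crv <- fit_drag_spline(bad), "best feasible")
  dense <- exp(seq(log(10), log(80), length.out = 200))
  expect_true(all(diff(as.numeric(predict(crv, dense))) <= 1e-8))
})

test_that("drag curves survive a JSON round trip", {
  crv <- fit_drag_spline(morrison_points(c(10, 25, 60, 100)))
  js <- drag_curve_to_json(crv)
  crv2 <- drag_curve_from_json(js)
  test_re <- c(12, 30, 55, 95, 140)
  expect_equal(as.numeric(predict(crv2, test_re)), as.numeric(predict(crv, test_re)),
               tolerance = 1e-12)
  expect_equal(crv2$data_range, crv$data_range)
  f <- tempfile(fileext = ".json")
  drag_curve_to_json(crv, f)
  expect_equal(as.numeric(predict(drag_curve_from_json(f), 30)),
               as.numeric(predict(crv, 30)), tolerance = 1e-12)
})
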