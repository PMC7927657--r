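#' Operating point of a sinking particle
#'
#' The (Re, C_D, U) at which the life-size particle settles in its natural
#' fluid: the intersection of the force-balance constraint curve with the
#' shape's drag curve. Constructed by [initial_operating_guess()] and
#' [solve_operating_point()].
#'
#' @param Re_O,C_D_O,U_O The operating Reynolds number, drag coefficient and
#'   speed (m s^-1).
#' @param extrapolated Was the drag curve extrapolated beyond its data range
#'   to locate the intersection?
#' @param iteration Number of experimental data points behind the estimate
#'   (0 for the sphere-based initial guess).
#' @param residual Relative intersection residual |C_D^F - C_D^E| / C_D.
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(Re_O, C_D_O, U_O, extrapolated = FALSE,
                            iteration = 0L, residual = NA_real_) {
  structure(list(Re_O = Re_O, C_D_O = C_D_O, U_O = U_O,
                 extrapolated = isTRUE(extrapolated),
                 iteration = as.integer(iteration), residual = residual),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> Re = %.4g, C_D = %.4g, U = %.4g m s^-1%s (n data = %d)\n",
              x$Re_O, x$C_D_O, x$U_O,
              if (x$extrapolated) " [extrapolated]" else "", x$iteration))
  invisible(x)
}

# Intersection of the force-balance constraint (a Re^-2 power law) with a
# drag curve that decreases more slowly: the log-log difference is strictly
# decreasing, so the crossing is unique. Root-found on log10(Re).
solve_intersection <- function(cd_curve_fn, original, material, fluid,
                               g = standard_gravity(),
                               bracket = c(1e-6, 1e6), extend = TRUE) {
  h <- function(lre) {
    re <- 10^lre
    log10(cd_force_balance(re, original, material, fluid, g)) -
      log10(cd_curve_fn(re))
  }
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  flo <- h(lo); fhi <- h(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    if (extend) {
      stop(sprintf("no intersection of force balance and drag curve in Re = (%g, %g)",
                   bracket[1], bracket[2]), call. = FALSE)
    }
    stop(sprintf(paste0("no intersection: force balance and drag curve do not cross in ",
                        "Re = (%g, %g) [h(lo)=%.3g, h(hi)=%.3g]"),
                 bracket[1], bracket[2], flo, fhi), call. = FALSE)
  }
  root <- stats::uniroot(h, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-12)
  10^root$root
}

#' First guess of the operating point using the sphere drag curve
#'
#' Before any shape-specific data exist, the particle is treated as if it
#' obeyed the Morrison sphere drag correlation: the operating Re solves
#' `C_D^F(Re) = C_D^M(Re)` for the life-size particle in its natural fluid.
#' The force-balance side falls as `Re^-2` while the sphere curve falls more
#' slowly, so the root is unique.
#'
#' @param original The original particle's [particle_geometry()].
#' @param natural_fluid Natural fluid (e.g. seawater), a [fluid_spec()].
#' @param particle_material Particle material (e.g. calcite), a [material_spec()].
#' @param g Gravitational acceleration, m s^-2.
#' @return An `operating_point` with `iteration = 0`.
#' @examples
#' geom <- particle_geometry(1e-3, pi / 4 * 1e-6, 1e-10, "virtual foram")
#' initial_operating_guess(geom, seawater(), calcite())
#' @export
initial_operating_guess <- function(original, natural_fluid, particle_material,
                                    g = standard_gravity()) {
  check_sinks(particle_material, natural_fluid)
  Re <- solve_intersection(morrison_cd, original, particle_material, natural_fluid, g,
                           bracket = c(1e-6, 1e6 * (1 - 1e-9)))
  C_D <- cd_force_balance(Re, original, particle_material, natural_fluid, g)
  operating_point(Re, C_D, speed_from_reynolds(Re, original$L, natural_fluid),
                  extrapolated = FALSE, iteration = 0L,
                  residual = abs(C_D - morrison_cd(Re)) / C_D)
}

#' Predictor of model volume from scale factor
#'
#' Printed models deviate from the ideal `V = S^3 V^O` scaling, so model
#' volumes are measured by weighing and predicted for new scale factors from
#' the accumulated (S, V) data: with at least 4 pairs and a target S inside
#' their range, by cubic spline interpolation; otherwise by cubic scaling from
#' the nearest measured pair, `V(S_near) (S / S_near)^3`.
#'
#' @param S Measured scale factors (positive; duplicates are averaged).
#' @param V Measured volumes, m^3.
#' @return An object of class `volume_predictor`.
#' @export
volume_predictor <- function(S, V) {
  if (length(S) < 1L || length(S) != length(V)) {
    stop("insufficient data: need at least one measured (S, V) pair", call. = FALSE)
  }
  if (any(S <= 0) || any(V <= 0)) stop("S and V must be positive", call. = FALSE)
  agg <- stats::aggregate(list(V = V), by = list(S = S), FUN = mean)
  agg <- agg[order(agg$S), ]
  structure(list(S = agg$S, V = agg$V), class = "volume_predictor")
}

#' @rdname volume_predictor
#' @param predictor A `volume_predictor`.
#' @param S_new Scale factor(s) to predict at.
#' @return `predict_volume()`: predicted volume(s), m^3.
#' @export
predict_volume <- function(predictor, S_new) {
  stopifnot(inherits(predictor, "volume_predictor"))
  if (any(S_new <= 0)) stop("S must be positive", call. = FALSE)
  n <- length(predictor$S)
  vapply(S_new, function(s) {
    inside <- n >= 4L && s >= min(predictor$S) && s <= max(predictor$S)
    if (inside) {
      H <- stats::splinefun(predictor$S, predictor$V, method = "fmm")
      H(s)
    } else {
      i <- which.min(abs(predictor$S - s))
      predictor$V[i] * (s / predictor$S[i])^3
    }
  }, numeric(1))
}

# Accept a wall_geometry, a settling-tank diameter, or a list with $D
tank_diameter <- function(tank) {
  if (inherits(tank, "wall_geometry")) return(tank$D)
  if (is.numeric(tank) && length(tank) == 1L && tank > 0) return(tank)
  if (is.list(tank) && !is.null(tank$D)) return(tank$D)
  stop("tank must be a wall_geometry, a positive tank diameter (m), or a list with $D",
       call. = FALSE)
}

# Solve the model scale S that should land at a target (Re, C_D^inf) in the
# tank: model force balance at Re equals the wall-amplified target drag.
# The left side grows ~S^3 through the predicted volume while the right side
# grows only weakly through lambda(S), so the crossing is unique.
solve_scale_for_target <- function(Re_t, Cd_t, original, D, working_fluid,
                                   model_material, vol_fn, g) {
  h <- function(ls) {
    s <- 10^ls
    lam <- s * original$L / D
    if (lam > 0.1) return(Inf) # beyond wall-correction validity: too big
    log10(cd_constraint_at_scale(Re_t, s, original, vol_fn(s),
                                 model_material, working_fluid, g)) -
      log10(Cd_t * wall_factor_K(lam))
  }
  root <- stats::uniroot(h, c(-3, log10(0.1 * D / original$L) - 1e-9),
                         tol = 1e-12, extendInt = "no")
  10^root$root
}

#' Plan the first three model scale factors
#'
#' The first scale `S1` is chosen so that a model with the ideal volume
#' `S^3 V^O` sinking in the tank (wall effects included) is expected to land
#' at the sphere-based initial guess of the operating point. `S2 < S1 < S3`
#' are then chosen so the three models' expected tank Reynolds numbers span
#' the literature range for the taxon (default Re 18-55) together with the
#' guess, bracketing the true operating point.
#'
#' @param guess The initial `operating_point` (from [initial_operating_guess()]).
#' @param original The original particle's [particle_geometry()].
#' @param tank Settling tank: a [wall_geometry()], a tank diameter in m, or a
#'   list with `$D`.
#' @param working_fluid Tank fluid, a [fluid_spec()].
#' @param model_material Model material, a [material_spec()].
#' @param re_bracket Length-2 Re interval the first experiments should span.
#' @param g Gravitational acceleration, m s^-2.
#' @return Numeric `c(S2, S1, S3)` sorted ascending (named `S2`, `S1`, `S3`).
#' @export
plan_first_scales <- function(guess, original, tank, working_fluid, model_material,
                              re_bracket = c(18, 55), g = standard_gravity()) {
  stopifnot(inherits(guess, "operating_point"))
  D <- tank_diameter(tank)
  vol_fn <- function(s) s^3 * original$V
  targets <- c(S2 = min(re_bracket[1], 0.8 * guess$Re_O),
               S1 = guess$Re_O,
               S3 = max(re_bracket[2], 1.25 * guess$Re_O))
  cds <- c(morrison_cd(targets[["S2"]]), guess$C_D_O, morrison_cd(targets[["S3"]]))
  out <- vapply(seq_along(targets), function(i) {
    solve_scale_for_target(targets[i], cds[i], original, D, working_fluid,
                           model_material, vol_fn, g)
  }, numeric(1))
  names(out) <- names(targets)
  if (!(out[["S2"]] < out[["S1"]] && out[["S1"]] < out[["S3"]])) {
    stop(sprintf("scale planning failed to order S2 < S1 < S3 (got %.4g, %.4g, %.4g)",
                 out[["S2"]], out[["S1"]], out[["S3"]]), call. = FALSE)
  }
  out[c("S2", "S1", "S3")]
}

#' Locate the operating point on a fitted empirical drag curve
#'
#' Solves `C_D^F(Re) = C_D^E(Re)` for the life-size particle in its natural
#' fluid, where `C_D^E` is the fitted empirical drag curve. The root is sought
#' in `(Re_min/10, Re_max*10)` around the curve's data range; if the crossing
#' falls outside the data range the curve's flagged linear (log-log)
#' extrapolation is used and the operating point is marked extrapolated.
#' `C_D^O` is obtained by substituting the root back into the force balance,
#' and `U^O` follows from the definition of Re.
#'
#' @param curve A fitted `drag_curve` (see [fit_drag_spline()]).
#' @inheritParams initial_operating_guess
#' @return An `operating_point`.
#' @export
solve_operating_point <- function(curve, original, natural_fluid, particle_material,
                                  g = standard_gravity()) {
  stopifnot(inherits(curve, "drag_curve"))
  bracket <- c(curve$data_range[1] / 10, curve$data_range[2] * 10)
  Re <- solve_intersection(function(re) as.numeric(predict(curve, re)),
                           original, particle_material, natural_fluid, g,
                           bracket = bracket, extend = FALSE)
  C_D <- cd_force_balance(Re, original, particle_material, natural_fluid, g)
  operating_point(Re, C_D, speed_from_reynolds(Re, original$L, natural_fluid),
                  extrapolated = drag_curve_extrapolated(curve, Re),
                  iteration = nrow(curve$points),
                  residual = abs(C_D - as.numeric(predict(curve, Re))) / C_D)
}

#' Scale factor for the next experiment
#'
#' Given the current operating-point estimate, chooses the model scale whose
#' predicted volume, sinking in the tank with wall effects included, should
#' land at `(Re^O, C_D^O)` — tightly bracketing the operating point with data.
#'
#' @param op Current `operating_point`.
#' @param predictor A [volume_predictor()] built from the measured models.
#' @inheritParams plan_first_scales
#' @return The next scale factor (deterministic in its inputs).
#' @export
next_scale <- function(op, predictor, original, tank, working_fluid, model_material,
                       g = standard_gravity()) {
  stopifnot(inherits(op, "operating_point"), inherits(predictor, "volume_predictor"))
  D <- tank_diameter(tank)
  solve_scale_for_target(op$Re_O, op$C_D_O, original, D, working_fluid,
                         model_material, function(s) predict_volume(predictor, s), g)
}

#' Convergence check for the iterative loop
#'
#' The loop stops when three criteria hold simultaneously: (1) the predicted
#' operating point is not extrapolated beyond the existing data; (2) the
#' variation in `U^O` between linear- and cubic-spline fits is no greater
#' than 5%; (3) the variation between the predicted `Re^O` and the closest
#' experimentally measured Re is less than 15%.
#'
#' @param op The current (cubic-fit) `operating_point`.
#' @param points data.frame of measured drag points (column `Re`).
#' @param U_cubic,U_linear Operating speeds from the cubic and linear fits.
#' @return An object of class `convergence_report` with fields
#'   `criterion1_no_extrapolation`, `criterion2_spline_variation`,
#'   `criterion3_re_gap`, `converged`.
#' @export
check_convergence <- function(op, points, U_cubic, U_linear) {
  stopifnot(inherits(op, "operating_point"))
  if (nrow(points) < 3L) stop("convergence is only assessed with >= 3 data points", call. = FALSE)
  c1 <- !op$extrapolated
  c2 <- abs(U_linear - U_cubic) / U_cubic
  c3 <- min(abs(points$Re - op$Re_O)) / op$Re_O
  structure(list(criterion1_no_extrapolation = c1,
                 criterion2_spline_variation = c2,
                 criterion3_re_gap = c3,
                 converged = c1 && c2 <= 0.05 && c3 < 0.15),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(paste0("<convergence_report> %s\n",
                     "  1. operating point within data range: %s\n",
                     "  2. linear vs cubic U^O variation:      %.2f%% (<= 5%%)\n",
                     "  3. gap to closest measured Re:         %.2f%% (< 15%%)\n"),
              if (x$converged) "CONVERGED" else "not converged",
              if (x$criterion1_no_extrapolation) "yes" else "no",
              100 * x$criterion2_spline_variation, 100 * x$criterion3_re_gap))
  invisible(x)
}

#' Run the full iterative sinking-velocity estimation
#'
#' Orchestrates the whole method: a sphere-based initial guess, planning of
#' the first three model scale factors, "sinking" each model through
#' `experiment_source`, converting measured speeds to wall-corrected
#' (Re, C_D) data, fitting cubic and linear shape-constrained drag curves,
#' solving for the operating point, and iterating with new scales until the
#' three convergence criteria hold or `max_iter` models have been sunk.
#'
#' Scale factors are rounded to 1 decimal place before being sent to the
#' experiment source, mirroring the precision used when scaling models for
#' printing. Wall-correction validity warnings raised during the loop (for
#' measurements above Re = 50) are collected into the result rather than
#' emitted one by one.
#'
#' @inheritParams plan_first_scales
#' @param natural_fluid,particle_material The original system ([fluid_spec()],
#'   [material_spec()]).
#' @param experiment_source Function of a scale factor `S` returning an
#'   experiment: a list with `V_model` (m^3), `speeds` (replicate speeds,
#'   m s^-1) and optionally `mass` (kg). Use [virtual_experiment_source()]
#'   for the simulated tank, or wrap measured data.
#' @param max_iter Maximum number of models to sink (default 10).
#' @return An object of class `sink_run`: the final `operating_point`,
#'   `report` (a `convergence_report`), `history` (one row per model sunk),
#'   `op_history` (operating points per iteration), the final cubic and
#'   linear `drag_curve`s, `converged`, `n_models`, and the initial `guess`.
#'   If the loop does not converge within `max_iter` models the best estimate
#'   is returned flagged (`converged = FALSE`) with a warning, never silently.
#' @examples
#' geom <- particle_geometry(1e-3, pi / 4 * 1e-6, 1e-10, "virtual foram")
#' truth <- virtual_particle_truth(geom, morrison_correlation(), calcite())
#' src <- virtual_experiment_source(truth, 0.9, mineral_oil(), printing_resin(),
#'                                  noise_model(velocity_cv = 0, seed = 1))
#' run <- run_estimation(geom, seawater(), calcite(), 0.9, mineral_oil(),
#'                       printing_resin(), src)
#' run$operating_point
#' @export
run_estimation <- function(original, natural_fluid, particle_material,
                           tank, working_fluid, model_material,
                           experiment_source, max_iter = 10L,
                           re_bracket = c(18, 55), g = standard_gravity()) {
  D <- tank_diameter(tank)
  wall_notes <- 0L
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("wall correction applied at Re > 50", conditionMessage(w))) {
        wall_notes <<- wall_notes + 1L
        invokeRestart("muffleWarning")
      }
    })
  }

  guess <- initial_operating_guess(original, natural_fluid, particle_material, g)
  scales <- collect(plan_first_scales(guess, original, D, working_fluid,
                                      model_material, re_bracket, g))

  history <- NULL
  points <- NULL
  op_history <- list()
  sunk_scales <- numeric(0)

  round_scale <- function(s) {
    s1 <- max(round(s, 1), 0.1)
    while (any(abs(sunk_scales - s1) < 0.05)) s1 <- s1 + 0.1
    s1
  }

  sink_one <- function(S_planned, iteration) {
    S <- round_scale(S_planned)
    rec <- experiment_source(S)
    reps <- aggregate_replicates(rec$speeds)
    lam <- S * original$L / D
    Re <- reynolds(S * original$L, reps$mean_U, working_fluid)
    Cd_walls <- cd_constraint_at_scale(Re, S, original, rec$V_model,
                                       model_material, working_fluid, g)
    Cd_inf <- collect(cd_unbounded(Cd_walls, lam, Re))
    row <- data.frame(iteration = iteration, S_planned = S_planned, S = S,
                      V_model = rec$V_model, U_mean = reps$mean_U,
                      n_replicates = length(reps$speeds), n_kept = sum(reps$kept),
                      Re = Re, lambda = lam, K = wall_factor_K(lam),
                      C_D_walls = Cd_walls, C_D_inf = Cd_inf)
    history <<- rbind(history, row)
    points <<- rbind(points, data.frame(Re = Re, C_D = Cd_inf))
    sunk_scales <<- c(sunk_scales, S)
    invisible(row)
  }

  for (i in seq_along(scales)) sink_one(scales[i], i)

  op <- NULL; report <- NULL; cubic <- NULL; linear <- NULL
  repeat {
    n <- nrow(points)
    cubic <- fit_drag_spline(points, "cubic")
    linear <- fit_drag_spline(points, "linear")
    op <- solve_operating_point(cubic, original, natural_fluid, particle_material, g)
    op_lin <- solve_operating_point(linear, original, natural_fluid, particle_material, g)
    op_history[[length(op_history) + 1L]] <- op
    report <- check_convergence(op, points, op$U_O, op_lin$U_O)
    if (report$converged || n >= max_iter) break
    predictor <- volume_predictor(history$S, history$V_model)
    S_next <- collect(next_scale(op, predictor, original, D, working_fluid,
                                 model_material, g))
    sink_one(S_next, n + 1L)
  }

  if (!report$converged) {
    warning(sprintf("estimation did not converge after %d models; returning best estimate flagged",
                    nrow(points)), call. = FALSE)
  }
  structure(list(operating_point = op, report = report, history = history,
                 op_history = op_history, curve = cubic, curve_linear = linear,
                 converged = report$converged, n_models = nrow(points),
                 guess = guess, wall_validity_notes = wall_notes),
            class = "sink_run")
}

#' @export
print.sink_run <- function(x, ...) {
  cat(sprintf("<sink_run> %d models sunk, %s\n",
              x$n_models, if (x$converged) "converged" else "NOT converged"))
  print(x$operating_point)
  print(x$report)
  invisible(x)
}
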