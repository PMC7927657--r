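#' Ground truth for a virtual particle
#'
#' Defines a synthetic particle completely: its life-size geometry, the true
#' (but, to the estimator, unknown) drag curve of its shape, and its material.
#' The virtual tank sinks scaled models of this particle so the entire
#' estimation loop can be exercised without hardware; the estimator never sees
#' the drag curve, only simulated measurements.
#'
#' @param original Life-size [particle_geometry()].
#' @param drag True shape drag curve, a [drag_correlation()].
#' @param material Particle material, a [material_spec()].
#' @return An object of class `virtual_particle_truth`.
#' @export
virtual_particle_truth <- function(original, drag, material) {
  stopifnot(inherits(original, "particle_geometry"),
            inherits(drag, "drag_correlation"),
            inherits(material, "material_spec"))
  structure(list(original = original, drag = drag, material = material),
            class = "virtual_particle_truth")
}

#' Measurement noise and printing bias model
#'
#' Controls the imperfections the virtual tank adds on top of the ideal
#' physics: replicate-to-replicate speed variation (i.i.d. multiplicative
#' lognormal noise with unit mean), the printing-volume bias by which real
#' printed models exceed the ideal `S^3 V^O` volume (excess resin is harder
#' to remove from small models, so the relative bias shrinks with scale:
#' `V = S^3 V^O (1 + c / S)`), and the number of drops per model.
#'
#' @param velocity_cv Coefficient of variation of replicate speeds (default
#'   0.01, i.e. 1%). Zero gives noiseless replicates.
#' @param volume_bias_c Bias constant `c >= 0` in `V = S^3 V^O (1 + c/S)`
#'   (default 0.3).
#' @param replicates Drops per model (default 5).
#' @param seed Optional integer; fixing it makes every simulated experiment
#'   reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(velocity_cv = 0.01, volume_bias_c = 0.3,
                        replicates = 5L, seed = NULL) {
  stopifnot(velocity_cv >= 0, volume_bias_c >= 0, replicates >= 1)
  structure(list(velocity_cv = velocity_cv, volume_bias_c = volume_bias_c,
                 replicates = as.integer(replicates),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

# Run expr under a deterministic seed without disturbing the caller's RNG
# state; seed = NULL leaves the global RNG stream alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sink one virtual model in the tank
#'
#' Simulates a complete experiment on a model at scale `S`: applies the
#' printing-volume bias, solves the model's terminal force balance in the
#' tank — with the in-tank apparent drag equal to the true drag amplified by
#' the wall factor `K(lambda)` at the model's Re — and emits replicate speeds
#' with multiplicative lognormal noise plus the model's measured mass.
#' Deterministic for a fixed `noise$seed` (the per-call stream is derived
#' from the seed and the scale factor, so each model gets independent noise
#' but repeat calls reproduce exactly).
#'
#' @param truth A [virtual_particle_truth()].
#' @param S Model scale factor.
#' @param tank A [wall_geometry()], tank diameter (m), or list with `$D`.
#' @param working_fluid Tank fluid, a [fluid_spec()].
#' @param model_material Model material, a [material_spec()] (must be denser
#'   than the working fluid).
#' @param noise A [noise_model()].
#' @param g Gravitational acceleration, m s^-2.
#' @return An `experiment_record`: list with `S`, `V_model` (true volume,
#'   m^3), `mass` (kg), `speeds` (replicate speeds, m s^-1), `lambda`, and a
#'   `truth` sublist (`U`, `Re` in-tank) for diagnostics only.
#' @export
sink_model <- function(truth, S, tank, working_fluid, model_material,
                       noise = noise_model(), g = standard_gravity()) {
  stopifnot(inherits(truth, "virtual_particle_truth"), inherits(noise, "noise_model"))
  check_positive_scalar(S, "S")
  check_sinks(model_material, working_fluid)
  D <- tank_diameter(tank)
  orig <- truth$original
  V_true <- S^3 * orig$V * (1 + noise$volume_bias_c / S)
  lam <- S * orig$L / D
  if (lam > 0.1) {
    stop(sprintf("model too large for the tank: lambda = %.3g > 0.1", lam), call. = FALSE)
  }
  K <- wall_factor_K(lam)
  h <- function(lre) {
    re <- 10^lre
    log10(cd_constraint_at_scale(re, S, orig, V_true, model_material, working_fluid, g)) -
      log10(K * eval_drag(truth$drag, re))
  }
  hi_re <- min(truth$drag$validity[2] * (1 - 1e-9), 1e6)
  root <- stats::uniroot(h, log10(c(1e-6, hi_re)), tol = 1e-12)
  Re_tank <- 10^root$root
  U_true <- speed_from_reynolds(Re_tank, S * orig$L, working_fluid)

  call_seed <- if (is.null(noise$seed)) NULL else
    (noise$seed + 97L * (round(10 * S) %% 20000L)) %% .Machine$integer.max
  speeds <- with_local_seed(call_seed, {
    if (noise$velocity_cv > 0) {
      sdlog <- sqrt(log(1 + noise$velocity_cv^2))
      U_true * stats::rlnorm(noise$replicates, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      rep(U_true, noise$replicates)
    }
  })
  structure(list(S = S, V_model = V_true, mass = V_true * model_material$density,
                 speeds = speeds, lambda = lam,
                 truth = list(U = U_true, Re = Re_tank)),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("<experiment_record> S = %.4g: V = %.4g m^3, mass = %.4g kg, %d drops, mean U = %.4g m s^-1\n",
              x$S, x$V_model, x$mass, length(x$speeds), mean(x$speeds)))
  invisible(x)
}

#' Experiment source backed by the virtual tank
#'
#' Wraps [sink_model()] into the `experiment_source` protocol expected by
#' [run_estimation()]: a function of `S` returning the simulated experiment.
#'
#' @inheritParams sink_model
#' @return A function `function(S) -> experiment_record`.
#' @export
virtual_experiment_source <- function(truth, tank, working_fluid, model_material,
                                      noise = noise_model(), g = standard_gravity()) {
  force(truth); force(tank); force(working_fluid); force(model_material)
  force(noise); force(g)
  function(S) sink_model(truth, S, tank, working_fluid, model_material, noise, g)
}

#' Synthesize two-camera centroid tracks for a recorded drop
#'
#' Generates the straight-line descent a camera pair would have recorded for
#' one replicate of an experiment: depth increases at the replicate's speed,
#' an optional lateral drift adds a horizontal component seen by camera 1,
#' frame intervals vary around the nominal frame rate, and recorded
#' timestamps carry jitter (a fraction of the frame interval), emulating
#' consumer webcams' variable frame-rate clocks. With zero jitter,
#' [track_velocity()] recovers the replicate speed exactly.
#'
#' @param record An `experiment_record` from [sink_model()] (or any list with
#'   a `speeds` field).
#' @param replicate Which replicate's speed to use (default 1).
#' @param frame_rate Nominal frame rate, Hz (default 30).
#' @param jitter Timestamp jitter as a fraction of the frame interval
#'   (default 0).
#' @param depth_range Total depth to record, m (default 1.1).
#' @param depth_window Depth window (m) stored on the tracks for velocity
#'   calculation (default the central `c(0.19, 0.99)`).
#' @param drift Horizontal drift speed seen by camera 1, m s^-1 (default 0).
#' @param seed Optional integer for reproducible jitter.
#' @return List of two [centroid_track()]s.
#' @export
make_tracks <- function(record, replicate = 1L, frame_rate = 30, jitter = 0,
                        depth_range = 1.1, depth_window = c(0.19, 0.99),
                        drift = 0, seed = NULL) {
  U <- record$speeds[[replicate]]
  check_positive_scalar(U, "replicate speed")
  dt <- 1 / frame_rate
  n <- ceiling(depth_range / U / dt) + 1L
  with_local_seed(seed, {
    t_true <- cumsum(c(0, dt * (1 + 0.2 * stats::runif(n - 1L, -0.5, 0.5))))
    z <- U * t_true
    x <- drift * t_true
    t_rec <- t_true + if (jitter > 0) jitter * dt * stats::runif(n, -0.5, 0.5) else 0
    # jittered clocks can locally reorder stamps; keep them strictly increasing
    t_rec <- cummax(t_rec) + seq_len(n) * 1e-12
    list(centroid_track(1, t_rec, x, z, depth_window),
         centroid_track(2, t_rec, rep(0, n), z, depth_window))
  })
}
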