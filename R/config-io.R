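#' Load a run configuration from YAML
#'
#' Reads fluids, materials, particle geometry, tank geometry and constants
#' from a YAML file. Quantities are SI internally; the geometry block may be
#' given in micrometres or millimetres via `length_unit` (areas and volumes
#' use the square and cube of that unit).
#'
#' Recognized structure (all blocks optional; missing entries fall back to
#' package defaults — seawater / mineral oil / calcite / printing resin,
#' 0.9 m tank, standard gravity):
#' \preformatted{
#' fluids:
#'   natural:  {name: seawater, density: 1025, viscosity: 1.22e-3}
#'   working:  {name: mineral oil, density: 830, viscosity: 0.022}
#' materials:
#'   particle: {name: calcite, density: 2710}
#'   model:    {name: resin, density: 1121.43}
#' geometry:  {L: 1000, A: 785400, V: 1.0e8, length_unit: um, shape: "..."}
#' tank:      {diameter: 0.9}
#' constants: {g: 9.80665}
#' }
#'
#' @param path Path to a YAML file.
#' @return A list with elements `natural_fluid`, `working_fluid`,
#'   `particle_material`, `model_material`, `geometry` (a
#'   [particle_geometry()] or `NULL`), `tank_diameter`, `g`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML parsers keep exponent forms like 1.0e8 as strings; coerce explicitly
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  get_fluid <- function(block, default) {
    if (is.null(block)) return(default)
    fluid_spec(num(block$density), num(block$viscosity),
               if (is.null(block$name)) "fluid" else block$name)
  }
  get_material <- function(block, default) {
    if (is.null(block)) return(default)
    material_spec(num(block$density), if (is.null(block$name)) "material" else block$name)
  }
  geom <- NULL
  if (!is.null(raw$geometry)) {
    gb <- raw$geometry
    scale <- length_unit_m(if (is.null(gb$length_unit)) "m" else gb$length_unit)
    geom <- particle_geometry(L = num(gb$L) * scale, A = num(gb$A) * scale^2,
                              V = num(gb$V) * scale^3,
                              shape_label = if (is.null(gb$shape)) "config" else gb$shape)
  }
  list(natural_fluid = get_fluid(raw$fluids$natural, seawater()),
       working_fluid = get_fluid(raw$fluids$working, mineral_oil()),
       particle_material = get_material(raw$materials$particle, calcite()),
       model_material = get_material(raw$materials$model, printing_resin()),
       geometry = geom,
       tank_diameter = if (is.null(raw$tank$diameter)) 0.9 else num(raw$tank$diameter),
       g = if (is.null(raw$constants$g)) standard_gravity() else num(raw$constants$g))
}

length_unit_m <- function(unit) {
  switch(tolower(unit),
         "um" = 1e-6, "µm" = 1e-6, "micron" = 1e-6,
         "mm" = 1e-3, "cm" = 1e-2, "m" = 1,
         stop(sprintf("unknown length unit '%s' (use um, mm, cm or m)", unit),
              call. = FALSE))
}

#' Read an experiments table
#'
#' Reads per-model experiment records from CSV with columns `experiment_id`,
#' `S`, `mass_g`, and replicate speeds in columns whose names start with
#' `speed` (m s^-1; empty cells allowed for unequal replicate counts).
#'
#' @param path CSV file path.
#' @param model_material The model [material_spec()], used to convert mass
#'   (grams) to volume.
#' @return A list of records, each a list with `experiment_id`, `S`, `mass`
#'   (kg), `V_model` (m^3) and `speeds`.
#' @export
read_experiments <- function(path, model_material = printing_resin()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "S", "mass_g")
  if (!all(need %in% names(df))) {
    stop("experiments CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  speed_cols <- grep("^speed", names(df), value = TRUE)
  if (length(speed_cols) == 0L) {
    stop("experiments CSV must have at least one replicate speed column (speed1, speed2, ...)",
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    speeds <- as.numeric(df[i, speed_cols])
    speeds <- speeds[is.finite(speeds)]
    mass <- df$mass_g[i] / 1000
    list(experiment_id = df$experiment_id[i], S = df$S[i], mass = mass,
         V_model = mass / model_material$density, speeds = speeds)
  })
}

#' Convert experiment records into wall-corrected drag data
#'
#' For each record: replicate speeds are aggregated with the median +/- 5%
#' filter, the model Reynolds number and the apparent in-tank drag
#' coefficient follow from the force balance at the measured volume, and the
#' wall correction converts the latter to its unbounded-domain value.
#'
#' @param records List of records as returned by [read_experiments()] (or
#'   `experiment_record`s from [sink_model()], each carrying `S`, `V_model`,
#'   `speeds`).
#' @param original Life-size [particle_geometry()].
#' @param tank A [wall_geometry()], tank diameter (m), or list with `$D`.
#' @param working_fluid,model_material The working system.
#' @param g Gravitational acceleration, m s^-2.
#' @return data.frame with one row per record: `experiment_id`, `S`,
#'   `U_mean`, `n_kept`, `Re`, `lambda`, `K`, `C_D_walls`, `C_D` (unbounded).
#' @export
drag_points_from_records <- function(records, original, tank, working_fluid,
                                     model_material, g = standard_gravity()) {
  D <- tank_diameter(tank)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    reps <- aggregate_replicates(r$speeds)
    lam <- r$S * original$L / D
    Re <- reynolds(r$S * original$L, reps$mean_U, working_fluid)
    cdw <- cd_constraint_at_scale(Re, r$S, original, r$V_model,
                                  model_material, working_fluid, g)
    cdi <- cd_unbounded(cdw, lam, Re)
    data.frame(experiment_id = if (is.null(r$experiment_id)) paste0("exp", i)
                               else r$experiment_id,
               S = r$S, U_mean = reps$mean_U, n_kept = sum(reps$kept),
               Re = Re, lambda = lam, K = wall_factor_K(lam),
               C_D_walls = cdw, C_D = cdi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-shot analysis of a set of measured experiments
#'
#' The non-interactive counterpart of [run_estimation()] for real (manual)
#' experiments: given the records measured so far, fits cubic and linear
#' drag curves, solves for the operating point, evaluates the three
#' convergence criteria, and suggests the scale factor for the next model.
#'
#' @inheritParams drag_points_from_records
#' @param natural_fluid,particle_material The original system.
#' @return A list: `points` (the wall-corrected drag data),
#'   `operating_point`, `operating_point_linear`, `report`
#'   (a `convergence_report`), `next_S` (suggested next scale, `NA` if the
#'   loop already converged), and the fitted `curve`.
#' @export
analyze_experiments <- function(records, original, natural_fluid, particle_material,
                                tank, working_fluid, model_material,
                                g = standard_gravity()) {
  pts <- drag_points_from_records(records, original, tank, working_fluid,
                                  model_material, g)
  cubic <- fit_drag_spline(pts[, c("Re", "C_D")], "cubic")
  linear <- fit_drag_spline(pts[, c("Re", "C_D")], "linear")
  op <- solve_operating_point(cubic, original, natural_fluid, particle_material, g)
  op_lin <- solve_operating_point(linear, original, natural_fluid, particle_material, g)
  report <- check_convergence(op, pts, op$U_O, op_lin$U_O)
  next_S <- NA_real_
  if (!report$converged) {
    predictor <- volume_predictor(vapply(records, `[[`, numeric(1), "S"),
                                  vapply(records, `[[`, numeric(1), "V_model"))
    next_S <- next_scale(op, predictor, original, tank, working_fluid,
                         model_material, g)
  }
  list(points = pts, operating_point = op, operating_point_linear = op_lin,
       report = report, next_S = next_S, curve = cubic)
}

#' Write a result summary as JSON
#'
#' Serializes an estimation result (a `sink_run` from [run_estimation()] or
#' the list returned by [analyze_experiments()]) — operating point,
#' convergence report and per-model history — for audit trails.
#'
#' @param result A `sink_run` or `analyze_experiments()` result.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_result_json <- function(result, path = NULL) {
  op <- result$operating_point
  payload <- list(
    operating_point = list(Re_O = op$Re_O, C_D_O = op$C_D_O, U_O = op$U_O,
                           extrapolated = op$extrapolated, n_data = op$iteration),
    convergence = unclass(result$report),
    history = if (!is.null(result$history)) result$history else result$points)
  if (!is.null(result$converged)) payload$converged <- result$converged
  if (!is.null(result$next_S) && is.finite(result$next_S)) payload$next_S <- result$next_S
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
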