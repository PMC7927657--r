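#' Particle geometry
#'
#' Bundle of the three size descriptors of a sinking particle: `L`, the maximum
#' extent parallel to the sinking direction (m); `A`, the projected frontal
#' area perpendicular to the sinking direction (m^2); and `V`, the solid
#' material volume excluding fluid-filled cavities (m^3). Shape enters the
#' physics only through the empirical drag curve, so it is carried as a free
#' text label.
#'
#' @param L Maximum length parallel to flow, m. Positive scalar.
#' @param A Projected frontal area, m^2. Positive scalar.
#' @param V Solid volume, m^3. Positive scalar, at most `A * L`.
#' @param shape_label Free-text shape descriptor.
#' @return An object of class `particle_geometry`.
#' @examples
#' particle_geometry(L = 1e-3, A = pi / 4 * 1e-6, V = 1e-10, "virtual foram")
#' @export
particle_geometry <- function(L, A, V, shape_label = "unspecified") {
  check_positive_scalar(L, "L")
  check_positive_scalar(A, "A")
  check_positive_scalar(V, "V")
  if (V > A * L * (1 + 1e-12)) {
    stop("invalid particle geometry: V exceeds A*L (solid must fit in its bounding prism)",
         call. = FALSE)
  }
  structure(list(L = L, A = A, V = V, shape_label = as.character(shape_label)),
            class = "particle_geometry")
}

#' @export
print.particle_geometry <- function(x, ...) {
  cat(sprintf("<particle_geometry> %s\n  L = %.6g m, A = %.6g m^2, V = %.6g m^3 (solidity V/AL = %.3f)\n",
              x$shape_label, x$L, x$A, x$V, x$V / (x$A * x$L)))
  invisible(x)
}

#' Fluid properties
#'
#' @param density Fluid density, kg m^-3.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param name Fluid name.
#' @return An object of class `fluid_spec`.
#' @examples
#' mineral_oil <- fluid_spec(830, 0.022, "mineral oil")
#' @export
fluid_spec <- function(density, viscosity, name = "fluid") {
  check_positive_scalar(density, "density")
  check_positive_scalar(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity, name = as.character(name)),
            class = "fluid_spec")
}

#' @export
print.fluid_spec <- function(x, ...) {
  cat(sprintf("<fluid_spec> %s: rho = %g kg m^-3, mu = %g Pa s\n",
              x$name, x$density, x$viscosity))
  invisible(x)
}

#' Solid material properties
#'
#' @param density Material density, kg m^-3 (of the solid itself; for a shelled
#'   particle whose `V` excludes internal cavities this is the wall-material
#'   density, e.g. calcite for foraminifera tests).
#' @param name Material name.
#' @return An object of class `material_spec`.
#' @examples
#' resin <- material_spec(1121.43, "clear resin")
#' @export
material_spec <- function(density, name = "material") {
  check_positive_scalar(density, "density")
  structure(list(density = density, name = as.character(name)),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s: rho = %g kg m^-3\n", x$name, x$density))
  invisible(x)
}

#' Default fluids, materials and constants
#'
#' Package defaults for the natural system (seawater at about 15 degC and 35
#' PSU; calcite for the test wall material), the working system used in the
#' tank experiments (Carnation white mineral oil; clear printing resin), and
#' standard gravity. All are plain constructors so they can be overridden from
#' a config file; no operation hard-codes them.
#'
#' @return The corresponding `fluid_spec` / `material_spec` object (or numeric
#'   for [standard_gravity()]).
#' @examples
#' seawater()
#' standard_gravity()
#' @export
seawater <- function() fluid_spec(1025, 1.22e-3, "seawater")

#' @rdname seawater
#' @export
mineral_oil <- function() fluid_spec(830, 0.022, "mineral oil")

#' @rdname seawater
#' @export
calcite <- function() material_spec(2710, "calcite")

#' @rdname seawater
#' @export
printing_resin <- function() material_spec(1121.43, "clear printing resin")

#' @rdname seawater
#' @export
standard_gravity <- function() 9.80665

#' Reynolds number of a sinking particle
#'
#' `Re = L U rho_fluid / mu`, the ratio of inertial to viscous forces for a
#' particle of characteristic length `L` moving at speed `U` through the fluid.
#'
#' @param L Characteristic length (maximum extent parallel to flow), m.
#' @param U Speed, m s^-1.
#' @param fluid A [fluid_spec()].
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds(0.01, 0.05, mineral_oil()) # ~18.9
#' @export
reynolds <- function(L, U, fluid) {
  check_positive_scalar(L, "L")
  check_positive_scalar(U, "U")
  stopifnot(inherits(fluid, "fluid_spec"))
  L * U * fluid$density / fluid$viscosity
}

#' Speed implied by a Reynolds number
#'
#' Inverts the definition of the Reynolds number: `U = Re mu / (L rho_fluid)`.
#' Exact inverse of [reynolds()].
#'
#' @param Re Reynolds number, dimensionless.
#' @param L Characteristic length, m.
#' @param fluid A [fluid_spec()].
#' @return Speed, m s^-1.
#' @export
speed_from_reynolds <- function(Re, L, fluid) {
  check_positive_scalar(Re, "Re")
  check_positive_scalar(L, "L")
  stopifnot(inherits(fluid, "fluid_spec"))
  Re * fluid$viscosity / (L * fluid$density)
}

#' Internally consistent (Re, C_D, U) triple
#'
#' @param Re Reynolds number.
#' @param C_D Drag coefficient.
#' @param L Characteristic length used to form `Re`, m.
#' @param fluid The fluid the triple refers to.
#' @return An object of class `sinking_state` with fields `Re`, `C_D`, `U`.
#' @export
sinking_state <- function(Re, C_D, L, fluid) {
  check_positive_scalar(Re, "Re")
  check_positive_scalar(C_D, "C_D")
  structure(list(Re = Re, C_D = C_D, U = speed_from_reynolds(Re, L, fluid)),
            class = "sinking_state")
}

#' Drag coefficient required by the terminal force balance
#'
#' At terminal velocity, drag plus buoyancy balances weight. Eliminating the
#' (unknown) speed through the Reynolds number turns the balance into a
#' constraint curve in the (Re, C_D) plane:
#' \deqn{C_D^F(Re) = \frac{2 g V (\rho_p - \rho_f)\, L^2 \rho_f}{A \mu^2 Re^2},}
#' a pure `Re^-2` power law whose prefactor is twice the Archimedes number
#' (see [archimedes()]). The particle's operating point is where this curve
#' crosses the shape's actual drag curve.
#'
#' @param Re Reynolds number(s), dimensionless, positive.
#' @param geom A [particle_geometry()].
#' @param material A [material_spec()] for the particle; must be denser than
#'   the fluid, otherwise there is no terminal sinking solution.
#' @param fluid A [fluid_spec()].
#' @param g Gravitational acceleration, m s^-2.
#' @return Drag coefficient(s) demanded by the force balance at `Re`.
#' @examples
#' geom <- particle_geometry(1e-3, pi / 4 * 1e-6, 1e-10)
#' cd_force_balance(42, geom, calcite(), seawater())
#' @export
cd_force_balance <- function(Re, geom, material, fluid, g = standard_gravity()) {
  stopifnot(inherits(geom, "particle_geometry"),
            inherits(material, "material_spec"),
            inherits(fluid, "fluid_spec"))
  if (any(!is.finite(Re)) || any(Re <= 0)) {
    stop("Re must be positive and finite", call. = FALSE)
  }
  check_sinks(material, fluid)
  2 * g * geom$V * (material$density - fluid$density) * geom$L^2 * fluid$density /
    (geom$A * fluid$viscosity^2 * Re^2)
}

#' Force-balance constraint for a scaled model
#'
#' Rewrites the force-balance drag constraint for a geometrically similar
#' model at scale factor `S`, in terms of the original particle's size
#' descriptors: `L = S L^O`, `A = S^2 A^O` (the explicit `S` in `L^2/A`
#' cancels) and the model's actual measured volume `V_model` (printed models
#' rarely satisfy `V = S^3 V^O` exactly, so the measured volume is used).
#'
#' @param Re Reynolds number(s) at which to evaluate the constraint.
#' @param S Model scale factor (model length / original length), positive.
#' @param original The original particle's [particle_geometry()].
#' @param V_model Measured model volume, m^3.
#' @param material Model material ([material_spec()]).
#' @param fluid Working fluid ([fluid_spec()]).
#' @param g Gravitational acceleration, m s^-2.
#' @return Drag coefficient(s) demanded by the model's force balance.
#' @export
cd_constraint_at_scale <- function(Re, S, original, V_model, material, fluid,
                                   g = standard_gravity()) {
  check_positive_scalar(S, "S")
  check_positive_scalar(V_model, "V_model")
  stopifnot(inherits(original, "particle_geometry"))
  model_geom <- particle_geometry(S * original$L, S^2 * original$A, V_model,
                                  paste0(original$shape_label, " (S=", signif(S, 6), ")"))
  cd_force_balance(Re, model_geom, material, fluid, g)
}

#' Archimedes number
#'
#' `Ar = g L_Ar^3 rho_f (rho_p - rho_f) / mu^2` with the cubed length scale
#' `L_Ar^3 = V L^2 / A`. The force-balance constraint is then simply
#' `C_D^F = 2 Ar / Re^2`.
#'
#' @inheritParams cd_force_balance
#' @return Dimensionless Archimedes number.
#' @export
archimedes <- function(geom, material, fluid, g = standard_gravity()) {
  stopifnot(inherits(geom, "particle_geometry"),
            inherits(material, "material_spec"),
            inherits(fluid, "fluid_spec"))
  check_sinks(material, fluid)
  L_ar3 <- geom$V * geom$L^2 / geom$A
  g * L_ar3 * fluid$density * (material$density - fluid$density) / fluid$viscosity^2
}

# ---- internal validation helpers ----

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("%s must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

check_sinks <- function(material, fluid) {
  if (material$density <= fluid$density) {
    stop(sprintf(paste0("buoyant particle: material density (%g kg m^-3) does not exceed ",
                        "fluid density (%g kg m^-3); no terminal sinking solution"),
                 material$density, fluid$density), call. = FALSE)
  }
  invisible(TRUE)
}
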