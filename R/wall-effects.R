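#' Tank/particle wall geometry
#'
#' Holds the particle-to-tank diameter ratio `lambda = d / D` governing wall
#' effects; the particle "diameter" is taken to be its maximum length `L`.
#' The default tank is the 0.9 m diameter cylindrical settling tank.
#'
#' @param particle_diameter Sinking particle (model) diameter `d`, m.
#' @param tank_diameter Tank inner diameter `D`, m.
#' @return An object of class `wall_geometry` with fields `d`, `D`, `lambda`.
#' @examples
#' wall_geometry(0.013, 0.9)
#' @export
wall_geometry <- function(particle_diameter, tank_diameter = 0.9) {
  check_positive_scalar(particle_diameter, "particle_diameter")
  check_positive_scalar(tank_diameter, "tank_diameter")
  lambda <- particle_diameter / tank_diameter
  if (lambda >= 0.5) {
    stop("wall_geometry: particle diameter must be well below the tank diameter (lambda < 0.5)",
         call. = FALSE)
  }
  structure(list(d = particle_diameter, D = tank_diameter, lambda = lambda),
            class = "wall_geometry")
}

#' @export
print.wall_geometry <- function(x, ...) {
  cat(sprintf("<wall_geometry> d = %g m in D = %g m tank (lambda = %.4g, K = %.4f)\n",
              x$d, x$D, x$lambda, wall_factor_K(x$lambda)))
  invisible(x)
}

#' Wall-effect correction factor K
#'
#' Low-Reynolds correction for a particle settling on the axis of a cylindrical
#' container: the walls act as an extra source of drag, multiplying the drag
#' force at a given speed by
#' \deqn{K(\lambda) = \frac{1}{1 - 2.1\,\lambda}, \qquad \lambda = d / D.}
#' `K(0) = 1` (no walls) and K increases with lambda. The correction is
#' intended for small ratios; beyond `lambda = 0.1` an error is raised since
#' different (stronger) corrections should be used there.
#'
#' @param lambda Particle-to-tank diameter ratio(s), in `[0, 0.1]`.
#' @return Correction factor(s) `K >= 1`.
#' @examples
#' wall_factor_K(0.0027) # 1.0057
#' wall_factor_K(0.0173) # 1.0377
#' @export
wall_factor_K <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("lambda must be non-negative and finite", call. = FALSE)
  }
  if (any(lambda > 0.1)) {
    stop(paste0("lambda > 0.1: this small-ratio wall correction does not apply; ",
                "use a correction suited to larger particle/tank ratios"),
         call. = FALSE)
  }
  1 / (1 - 2.1 * lambda)
}

#' Convert an in-tank drag coefficient to its unbounded-domain value
#'
#' An experimentally determined drag coefficient in the tank is the apparent
#' `C_D^walls`; the quantity needed for predictions in the open ocean is the
#' unbounded `C_D^inf` at the same Reynolds number. Since the walls multiply
#' the drag force at a given speed by `K(lambda)`,
#' `C_D^inf = C_D^walls / K(lambda)`, which is at most `C_D^walls` and tends
#' to it as `lambda -> 0`. The correction is derived for `Re` up to about 50;
#' above that it is applied unchanged with a warning.
#'
#' @param C_D_walls Apparent drag coefficient(s) measured with walls present.
#' @param lambda Particle-to-tank diameter ratio.
#' @param Re Reynolds number of the measurement (validity check only).
#' @return Unbounded-domain drag coefficient(s).
#' @export
cd_unbounded <- function(C_D_walls, lambda, Re) {
  if (any(!is.finite(C_D_walls)) || any(C_D_walls <= 0)) {
    stop("C_D_walls must be positive and finite", call. = FALSE)
  }
  warn_wall_re(Re)
  C_D_walls / wall_factor_K(lambda)
}

#' Convert an unbounded drag coefficient to its expected in-tank value
#'
#' Exact inverse of [cd_unbounded()]: `C_D^walls = K(lambda) * C_D^inf`.
#' Used when planning experiments, to predict the apparent drag coefficient a
#' model will exhibit inside the tank.
#'
#' @param C_D_inf Unbounded-domain drag coefficient(s).
#' @param lambda Particle-to-tank diameter ratio.
#' @param Re Reynolds number (validity check only).
#' @return Apparent in-tank drag coefficient(s).
#' @export
cd_bounded <- function(C_D_inf, lambda, Re) {
  if (any(!is.finite(C_D_inf)) || any(C_D_inf <= 0)) {
    stop("C_D_inf must be positive and finite", call. = FALSE)
  }
  warn_wall_re(Re)
  C_D_inf * wall_factor_K(lambda)
}

warn_wall_re <- function(Re) {
  if (any(!is.finite(Re)) || any(Re < 0)) {
    stop("Re must be non-negative and finite", call. = FALSE)
  }
  if (any(Re > 50)) {
    warning("wall correction applied at Re > 50, beyond its stated validity; ",
            "treat the corrected value as approximate", call. = FALSE)
  }
  invisible(TRUE)
}
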