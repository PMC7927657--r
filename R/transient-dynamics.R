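#' Unsteady sinking from rest
#'
#' Integrates the transient momentum balance for a particle released from
#' rest: `M dU/dt = V g (rho_p - rho_f) - F_drag(U)`, `dZ/dt = U`, with
#' `M = V rho_p`, `U(0) = Z(0) = 0`. The drag force is written directly as a
#' function of speed,
#' `F_drag(U) = 12 mu A U / L + (1/2) rho_f A U^2 [C_D(Re) - 24/Re]`,
#' which equals `(1/2) rho_f A U^2 C_D(Re)` for any `U > 0` but remains
#' regular at `U = 0` where the drag coefficient itself diverges: the first
#' term is the analytically continued Stokes limit (for a sphere it reduces
#' to `3 pi mu d U` exactly), and the bracketed correction vanishes as
#' `Re -> 0`. Integration uses an adaptive Runge-Kutta (rtol 1e-8 by
#' default); added-mass and history forces are neglected.
#'
#' @param geom [particle_geometry()] of the sinking body.
#' @param material Its [material_spec()] (must be denser than the fluid).
#' @param fluid The surrounding [fluid_spec()].
#' @param drag A [drag_correlation()] valid from vanishing Re up to the
#'   terminal Re (default the Morrison sphere curve).
#' @param g Gravitational acceleration, m s^-2.
#' @param t_end Integration end time, s. `NULL` (default) integrates until
#'   the speed reaches 99.99% of terminal, extending automatically.
#' @param rtol Relative tolerance of the integrator.
#' @return An object of class `transient_solution`: data.frame `trajectory`
#'   with columns `t`, `U`, `Z`; `U_terminal` (the steady force-balance
#'   root); and `reached_terminal` (TRUE when the solution attains 99.9% of
#'   terminal; otherwise the solution is flagged incomplete).
#' @examples
#' sphere <- particle_geometry(0.01, pi / 4 * 1e-4, pi / 6 * 1e-6, "sphere d=1cm")
#' sol <- solve_transient(sphere, printing_resin(), mineral_oil())
#' depth_to_fraction(sol, 0.999)
#' @export
solve_transient <- function(geom, material, fluid, drag = morrison_correlation(),
                            g = standard_gravity(), t_end = NULL, rtol = 1e-8) {
  stopifnot(inherits(geom, "particle_geometry"), inherits(drag, "drag_correlation"))
  check_sinks(material, fluid)

  U_term <- speed_from_reynolds(
    solve_intersection(function(re) eval_drag(drag, re), geom, material, fluid, g,
                       bracket = c(1e-8, min(1e6, drag$validity[2]) * (1 - 1e-9))),
    geom$L, fluid)

  M <- geom$V * material$density
  W_eff <- geom$V * g * (material$density - fluid$density)
  k_stokes <- 12 * fluid$viscosity * geom$A / geom$L
  f_drag <- function(U) {
    if (U <= 0) return(0)
    Re <- reynolds(geom$L, U, fluid)
    k_stokes * U + 0.5 * fluid$density * geom$A * U^2 *
      (eval_drag(drag, Re) - 24 / Re)
  }
  deriv <- function(t, y, parms) {
    list(c((W_eff - f_drag(y[1])) / M, max(y[1], 0)))
  }

  tau <- M / k_stokes # linear-drag time scale; inertial runs extend adaptively
  span <- if (is.null(t_end)) 15 * max(tau, U_term / (W_eff / M)) else t_end
  traj <- NULL
  y0 <- c(U = 0, Z = 0)
  t0 <- 0
  for (chunk in 1:6) {
    times <- seq(t0, t0 + span, length.out = 1500L)
    sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = "ode45",
                        rtol = rtol, atol = rtol * max(U_term, 1e-12))
    block <- as.data.frame(sol)
    names(block) <- c("t", "U", "Z")
    traj <- if (is.null(traj)) block else rbind(traj, block[-1, ])
    if (!is.null(t_end)) break
    if (max(traj$U) >= 0.9999 * U_term) break
    y0 <- c(U = block$U[nrow(block)], Z = block$Z[nrow(block)])
    t0 <- block$t[nrow(block)]
    span <- span * 2
  }

  reached <- max(traj$U) >= 0.999 * U_term
  if (!reached) {
    warning("transient solution did not reach 99.9% of terminal velocity; flagged incomplete",
            call. = FALSE)
  }
  structure(list(trajectory = traj, U_terminal = U_term,
                 reached_terminal = reached, geom = geom, drag_name = drag$name),
            class = "transient_solution")
}

#' @export
print.transient_solution <- function(x, ...) {
  cat(sprintf("<transient_solution> U_terminal = %.4g m s^-1 (%s), %d steps%s\n",
              x$U_terminal, x$drag_name, nrow(x$trajectory),
              if (x$reached_terminal) "" else " [incomplete]"))
  invisible(x)
}

#' Depth at which a fraction of terminal velocity is reached
#'
#' Returns `Z` at the first time the transient speed attains
#' `fraction * U_terminal`, interpolating linearly between integration steps.
#' Used to check that the tracking window of a settling experiment lies
#' entirely in the terminal regime.
#'
#' @param sol A `transient_solution` from [solve_transient()].
#' @param fraction Fraction of terminal velocity in `[0, 1)` (default 0.999).
#' @return Depth, m.
#' @export
depth_to_fraction <- function(sol, fraction = 0.999) {
  stopifnot(inherits(sol, "transient_solution"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)", call. = FALSE)
  if (fraction == 0) return(0)
  target <- fraction * sol$U_terminal
  tr <- sol$trajectory
  i <- which(tr$U >= target)[1]
  if (is.na(i)) {
    stop(sprintf("incomplete solution: speed never reached %.3g of terminal", fraction),
         call. = FALSE)
  }
  if (i == 1L) return(tr$Z[1])
  w <- (target - tr$U[i - 1]) / (tr$U[i] - tr$U[i - 1])
  tr$Z[i - 1] + w * (tr$Z[i] - tr$Z[i - 1])
}
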