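# Shared fixtures and independent oracles for the test suite.

# A realistic life-size virtual particle: 1 mm maximum length, circular
# frontal area of the same diameter, ~13% solidity (hollow multi-chambered
# shell whose V counts only wall material). In seawater with calcite walls it
# operates near Re ~ 42, inside the literature range for the taxon.
foram_geom <- function() {
  particle_geometry(L = 1e-3, A = pi / 4 * 1e-6, V = 1e-10, "virtual foram test")
}

sphere_geom <- function(d) {
  particle_geometry(L = d, A = pi / 4 * d^2, V = pi / 6 * d^3,
                    shape_label = sprintf("sphere d=%g", d))
}

# Independent terminal-settling oracle: plain bisection on the raw force
# balance (re-derived here from first principles, not calling the package's
# solver or cd_force_balance). Returns the terminal Re.
oracle_terminal_re <- function(cd_fn, geom, material, fluid, g = 9.80665,
                               lo = 1e-6, hi = 9.9e5) {
  f <- function(Re) {
    lhs <- 2 * g * geom$V * (material$density - fluid$density) * geom$L^2 *
      fluid$density / (geom$A * fluid$viscosity^2 * Re^2)
    lhs - cd_fn(Re)
  }
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

oracle_terminal_u <- function(cd_fn, geom, material, fluid, g = 9.80665) {
  Re <- oracle_terminal_re(cd_fn, geom, material, fluid, g)
  Re * fluid$viscosity / (geom$L * fluid$density)
}

# One closed-loop virtual-tank estimation run against a perturbed Morrison
# ground truth; returns the run plus the oracle truth and the relative error.
run_virtual <- function(factor = 1, shift = 0, cv = 0, seed = NULL,
                        bias = 0.3, max_iter = 10L) {
  geom <- foram_geom()
  truth_curve <- if (factor == 1 && shift == 0) morrison_correlation() else
    perturbed_cd(morrison_correlation(), factor, shift)
  truth <- virtual_particle_truth(geom, truth_curve, calcite())
  src <- virtual_experiment_source(truth, 0.9, mineral_oil(), printing_resin(),
                                   noise_model(velocity_cv = cv,
                                               volume_bias_c = bias, seed = seed))
  run <- suppressWarnings(
    run_estimation(geom, seawater(), calcite(), 0.9, mineral_oil(),
                   printing_resin(), src, max_iter = max_iter))
  U_truth <- oracle_terminal_u(truth_curve$evaluator, geom, calcite(), seawater())
  list(run = run, U_truth = U_truth,
       rel_err = abs(run$operating_point$U_O - U_truth) / U_truth)
}

# Expensive benchmark mesh, built once per test session.
get_icosphere4 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mesh_icosphere(1, 4)
    cache
  }
})
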