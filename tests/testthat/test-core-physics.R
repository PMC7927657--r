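test_that("reynolds number matches direct arithmetic and is linear in speed", {
  expect_equal(reynolds(1, 1, fluid_spec(1, 1)), 1)
  expect_equal(reynolds(0.01, 0.05, mineral_oil()), 0.01 * 0.05 * 830 / 0.022)
  expect_equal(reynolds(0.01, 0.05, mineral_oil()), 18.8636, tolerance = 1e-4)
  f <- fluid_spec(912, 0.031)
  expect_equal(reynolds(0.02, 0.08, f), 2 * reynolds(0.02, 0.04, f))
})

test_that("speed_from_reynolds is the exact inverse of reynolds", {
  expect_equal(speed_from_reynolds(1, 1, fluid_spec(1, 1)), 1)
  f <- mineral_oil()
  for (L in c(1e-4, 0.013, 0.5)) {
    for (U in c(1e-3, 0.05, 2)) {
      expect_equal(speed_from_reynolds(reynolds(L, U, f), L, f), U)
    }
  }
  expect_equal(speed_from_reynolds(18.8636, 0.01, f), 0.05, tolerance = 1e-4)
})

test_that("inputs to dimensionless-number operations are validated", {
  expect_error(reynolds(-1, 1, mineral_oil()), "positive")
  expect_error(reynolds(0.1, 0, mineral_oil()), "positive")
  expect_error(speed_from_reynolds(0, 1, mineral_oil()), "positive")
  expect_error(fluid_spec(-1, 0.02), "positive")
  expect_error(material_spec(0), "positive")
  expect_error(particle_geometry(1, 1, 1.01), "bounding prism")
})

test_that("force-balance drag constraint scales exactly as Re^-2", {
  geom <- foram_geom()
  re <- c(0.5, 7, 42, 300)
  v1 <- cd_force_balance(re, geom, calcite(), seawater())
  v2 <- cd_force_balance(2 * re, geom, calcite(), seawater())
  expect_equal(v2, v1 / 4)
  expect_true(all(diff(cd_force_balance(seq(1, 100, by = 1), geom, calcite(),
                                        seawater())) < 0))
})

test_that("force balance reproduces Stokes law for spheres at low Re", {
  d <- 1e-4
  rho_p <- 1500
  oil <- mineral_oil()
  g <- standard_gravity()
  U_stokes <- g * d^2 * (rho_p - oil$density) / (18 * oil$viscosity)
  Re_stokes <- reynolds(d, U_stokes, oil)
  expect_lt(Re_stokes, 0.1)
  geom <- sphere_geom(d)
  # at the Stokes terminal Re the constraint equals the Stokes drag 24/Re
  expect_equal(cd_force_balance(Re_stokes, geom, material_spec(rho_p), oil),
               24 / Re_stokes, tolerance = 1e-12)
  # and the Re solving cd_force_balance = 24/Re reproduces U_stokes to <0.1%
  Re_solved <- oracle_terminal_re(function(Re) 24 / Re, geom,
                                  material_spec(rho_p), oil)
  expect_equal(Re_solved * oil$viscosity / (d * oil$density), U_stokes,
               tolerance = 1e-3)
})

test_that("buoyant particles are rejected with a clear error", {
  geom <- foram_geom()
  light <- material_spec(800)
  expect_error(cd_force_balance(10, geom, light, mineral_oil()), "buoyant")
  expect_error(archimedes(geom, light, mineral_oil()), "buoyant")
})

test_that("Archimedes number: unit-sphere value and identity with the force balance", {
  # unit sphere, unit densities/viscosity/g: L_Ar^3 = V L^2 / A = 2/3
  geom <- sphere_geom(1)
  expect_equal(archimedes(geom, material_spec(2), fluid_spec(1, 1), g = 1), 2 / 3)
  # property: cd_force_balance == 2 Ar / Re^2 over random valid inputs
  set.seed(11)
  for (i in 1:20) {
    L <- runif(1, 1e-4, 1e-2)
    A <- runif(1, 1e-8, 1e-4)
    geom <- particle_geometry(L, A, runif(1, 0.05, 0.9) * A * L)
    mat <- material_spec(runif(1, 900, 3000))
    fl <- fluid_spec(runif(1, 700, 890), runif(1, 1e-3, 0.1))
    if (mat$density <= fl$density) next
    re <- 10^runif(1, -2, 3)
    expect_equal(cd_force_balance(re, geom, mat, fl),
                 2 * archimedes(geom, mat, fl) / re^2,
                 tolerance = 1e-12)
  }
  # mu^-2 scaling
  geom <- foram_geom()
  f1 <- fluid_spec(1025, 1.22e-3)
  f2 <- fluid_spec(1025, 2.44e-3)
  expect_equal(archimedes(geom, calcite(), f2),
               archimedes(geom, calcite(), f1) / 4)
})

test_that("scaled-model constraint reduces, cancels S in L^2/A, and is linear in V", {
  geom <- foram_geom()
  # S = 1 with the original volume and system reduces to cd_force_balance
  expect_equal(cd_constraint_at_scale(42, 1, geom, geom$V, calcite(), seawater()),
               cd_force_balance(42, geom, calcite(), seawater()))
  # at fixed measured V the explicit S cancels (L^2/A): changing S alone
  # leaves the constraint unchanged
  v <- 2.2e-7
  expect_equal(cd_constraint_at_scale(30, 10, geom, v, printing_resin(), mineral_oil()),
               cd_constraint_at_scale(30, 16, geom, v, printing_resin(), mineral_oil()))
  # with the ideal V = S^3 V^O the constraint grows as S^3
  c10 <- cd_constraint_at_scale(30, 10, geom, 10^3 * geom$V, printing_resin(), mineral_oil())
  c20 <- cd_constraint_at_scale(30, 20, geom, 20^3 * geom$V, printing_resin(), mineral_oil())
  expect_equal(c20 / c10, 8)
  # linear in measured volume: 10% volume inflation scales the result by 1.10
  base <- cd_constraint_at_scale(30, 12, geom, v, printing_resin(), mineral_oil())
  infl <- cd_constraint_at_scale(30, 12, geom, 1.1 * v, printing_resin(), mineral_oil())
  expect_equal(infl / base, 1.1)
})
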