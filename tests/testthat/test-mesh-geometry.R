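cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

test_that("cube morphometrics are exact along an axis", {
  cu <- mesh_cube(1)
  expect_equal(mesh_volume(cu), 1)
  expect_equal(max_length_along(cu), 1)
  expect_equal(projected_area(cu, grid_n = 256), 1, tolerance = 1e-6)
})

test_that("cube along its body diagonal: length sqrt(3), hexagonal shadow sqrt(3)", {
  cu <- mesh_cube(1, sink_direction = c(1, 1, 1))
  expect_equal(max_length_along(cu), sqrt(3), tolerance = 1e-12)
  expect_equal(projected_area(cu, grid_n = 512), sqrt(3), tolerance = 0.01)
})

test_that("icosphere morphometrics match the analytic sphere", {
  ic <- get_icosphere4()
  expect_equal(mesh_volume(ic), 4 / 3 * pi, tolerance = 0.005)
  expect_equal(projected_area(ic, grid_n = 1024, refine = FALSE), pi,
               tolerance = 0.005)
  expect_equal(max_length_along(ic), 2, tolerance = 0.005)
  # any direction: same diameter
  ic2 <- mesh_icosphere(0.5, 2, sink_direction = c(1, 2, -0.5))
  expect_equal(max_length_along(ic2), 1, tolerance = 0.01)
})

test_that("volume is additive over disjoint closed components", {
  two <- mesh_union_disjoint(mesh_cube(1), mesh_cube(1, center = c(5, 0, 0)))
  expect_equal(mesh_volume(two), 2)
})

test_that("morphometrics scale as (k, k^2, k^3) under uniform scaling", {
  m <- mesh_icosphere(1, 2, sink_direction = c(0.3, -1, 0.2))
  for (k in c(0.25, 3)) {
    ms <- oriented_mesh(m$vertices * k, m$faces, m$sink_direction)
    expect_equal(max_length_along(ms), k * max_length_along(m), tolerance = 1e-10)
    expect_equal(mesh_volume(ms), k^3 * mesh_volume(m), tolerance = 1e-10)
    expect_equal(projected_area(ms, grid_n = 256, refine = FALSE),
                 k^2 * projected_area(m, grid_n = 256, refine = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("V <= A * L and the convex projection bound hold across directions", {
  set.seed(21)
  m <- mesh_icosphere(1, 2)
  cu <- mesh_cube(1)
  for (i in 1:5) {
    dir <- rnorm(3)
    for (mesh0 in list(m, cu)) {
      mm <- oriented_mesh(mesh0$vertices, mesh0$faces, dir)
      L <- max_length_along(mm)
      A <- projected_area(mm, grid_n = 256, refine = FALSE)
      V <- mesh_volume(mm)
      expect_lte(V, A * L * 1.01)
      # Cauchy bound for convex bodies: mean shadow = surface / 4 <= surface / 2
      area_faces <- sum(sqrt(rowSums((
        cross3(mm$vertices[mm$faces[, 2], ] - mm$vertices[mm$faces[, 1], ],
               mm$vertices[mm$faces[, 3], ] - mm$vertices[mm$faces[, 1], ]))^2)) / 2)
      expect_lte(A, area_faces / 2)
    }
  }
})

test_that("non-watertight meshes are rejected with the open-edge count", {
  cu <- mesh_cube(1)
  holed <- oriented_mesh(cu$vertices, cu$faces[-1, ], cu$sink_direction)
  expect_error(mesh_volume(holed), "3 open")
  # projected area still works on open surfaces
  expect_equal(projected_area(holed, grid_n = 128, refine = FALSE), 1,
               tolerance = 1e-4)
})

test_that("a flat mesh parallel to the flow has a degenerate shadow", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  flat <- oriented_mesh(v, f, sink_direction = c(0, 0, -1))
  expect_warning(a <- projected_area(flat, grid_n = 64), "degenerate")
  expect_equal(a, 0)
})

test_that("mesh construction validates faces and directions", {
  v <- diag(3)
  expect_error(oriented_mesh(v, rbind(c(1, 1, 2))), "degenerate faces")
  expect_error(oriented_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(oriented_mesh(v, rbind(c(1, 2, 3)), c(0, 0, 0)), "non-zero")
})

test_that("measure_mesh assembles a consistent particle geometry", {
  geom <- measure_mesh(get_icosphere4(), "benchmark sphere", grid_n = 512,
                       refine = FALSE)
  expect_s3_class(geom, "particle_geometry")
  expect_equal(geom$L, 2, tolerance = 0.005)
  expect_equal(geom$A, pi, tolerance = 0.01)
  expect_equal(geom$V, 4 / 3 * pi, tolerance = 0.01)
})

test_that("STL files round-trip in ASCII and binary", {
  m <- mesh_icosphere(0.01, 2)
  fa <- tempfile(fileext = ".stl")
  fb <- tempfile(fileext = ".stl")
  write_stl(m, fa)
  write_stl(m, fb, binary = TRUE)
  ma <- read_stl(fa)
  mb <- read_stl(fb)
  expect_equal(nrow(ma$faces), nrow(m$faces))
  expect_equal(nrow(mb$faces), nrow(m$faces))
  expect_equal(mesh_volume(ma), mesh_volume(m), tolerance = 1e-8)
  # binary STL stores 32-bit floats
  expect_equal(mesh_volume(mb), mesh_volume(m), tolerance = 1e-6)
  expect_equal(max_length_along(ma), max_length_along(m), tolerance = 1e-8)
})
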