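test_that("icosphere node counts, Euler characteristic and face counts", {
  for (lev in 0:3) {
    m <- build_icosphere(1e-5, lev)
    expect_identical(nrow(m$V), as.integer(10 * 4^lev + 2))
    expect_identical(nrow(m$Tri), as.integer(20 * 4^lev))
    expect_identical(nrow(m$V) - nrow(m$edges) + nrow(m$Tri), 2L)
  }
  m <- build_icosphere(3.5e-6, 2, center = c(1, 2, 3) * 1e-6)
  r <- row_norm(sweep(m$V, 2, c(1, 2, 3) * 1e-6))
  expect_equal(r, rep(3.5e-6, 162), tolerance = 1e-12)
  expect_error(build_icosphere(-1, 2), "radius")
  expect_error(build_icosphere(1, -1), "level")
})

test_that("enclosed volume: cube, sphere convergence, translation invariance", {
  cube <- make_cube_mesh()
  expect_equal(enclosed_volume(cube), 1, tolerance = 1e-14)
  vfrac <- sapply(1:4, function(l)
    enclosed_volume(build_icosphere(1, l)) / (4 * pi / 3))
  expect_gt(vfrac[3], 0.95)
  expect_true(all(vfrac < 1))
  expect_true(all(diff(vfrac) > 0))                 # monotone refinement
  m <- build_icosphere(1, 3)
  v0 <- enclosed_volume(m)
  expect_gt(v0 / (4 * pi / 3), 0.95)
  vt <- enclosed_volume(m, sweep(m$V, 2, c(17.3, -4.1, 256), "+"))
  expect_equal(vt, v0, tolerance = 1e-12)
})

test_that("surface area: cube, sphere approximation, quadratic scaling", {
  cube <- make_cube_mesh()
  expect_equal(surface_area(cube), 6, tolerance = 1e-14)
  m <- build_icosphere(1, 3)
  expect_equal(surface_area(m), 4 * pi, tolerance = 0.02)
  s <- 2.7
  expect_equal(surface_area(m, m$V * s), s^2 * surface_area(m),
               tolerance = 1e-12)
  expect_equal(enclosed_volume(m, m$V * s), s^3 * enclosed_volume(m),
               tolerance = 1e-12)
})

test_that("Voronoi areas partition the surface exactly and are near-uniform", {
  for (lev in 1:3) {
    m <- build_icosphere(1e-5, lev)
    S <- node_voronoi_areas(m)
    expect_true(all(S > 0))
    expect_equal(sum(S), surface_area(m), tolerance = 1e-10)
    if (lev == 3) expect_lt(max(S) / min(S), 2)
  }
  cube <- make_cube_mesh()
  expect_equal(sum(node_voronoi_areas(cube)), 6, tolerance = 1e-10)
})

test_that("flat equilateral fan gives the center one third of the fan area", {
  fan <- make_flat_fan(1)
  S <- node_voronoi_areas(fan)
  fan_area <- 6 * sqrt(3) / 4
  expect_equal(S[1], fan_area / 3, tolerance = 1e-10)
})

test_that("curvature radii recover the sphere radius and scale linearly", {
  m <- build_icosphere(10e-6, 3)
  cr <- curvature_radii(m)
  expect_true(all(abs(cr$radius - 10e-6) / 10e-6 < 0.05))
  # outward convention
  u <- m$V / row_norm(m$V)
  expect_true(all(rowSums(cr$normal * u) > 0.99))
  # uniform scaling scales the radii
  cr2 <- curvature_radii(m, m$V * 2, r_max = 1)
  expect_equal(cr2$radius, 2 * cr$radius, tolerance = 1e-6)
  # clamping engages when the band excludes the true radius
  cr3 <- curvature_radii(m, r_max = 5e-6)
  expect_true(all(cr3$radius <= 5e-6 + 1e-18))
  expect_true(all(cr3$clamped))
})

test_that("malformed meshes are rejected", {
  cube <- make_cube_mesh()
  expect_error(build_trimesh(cube$V, cube$Tri[-1, ]), "closed")
  flipped <- cube$Tri
  flipped[, 2:3] <- flipped[, 3:2]
  expect_error(build_trimesh(cube$V, flipped), "volume|orientation")
})
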