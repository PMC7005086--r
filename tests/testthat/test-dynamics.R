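test_that("Stokes node friction", {
  g <- stokes_node_friction(1e-3, 8.8e-6, 642)
  expect_equal(g, 2.583e-10, tolerance = 1e-3)
  expect_equal(g * 642, 6 * pi * 1e-3 * 8.8e-6, tolerance = 1e-12)
  expect_equal(stokes_node_friction(2e-3, 8.8e-6, 642), 2 * g)
})

test_that("an isolated center-based cell moves with v = F/gamma", {
  sc <- new_scene(dt = 10, seed = 1, gamma_cbm_sub = 5e8)
  sc <- scene_add(sc, cbm_cell(c(0, 0, 0)))
  Fapp <- c(2e-10, 0, 0)
  sc$f_ext <- function(scene) list(cbm = matrix(Fapp, 1, 3))
  x0 <- sc$cbm[[1]]$center
  sc <- scene_step(sc)
  gam <- 5e8 * pi * (12e-6)^2
  expect_equal(sc$cbm[[1]]$center - x0, Fapp / gam * 10, tolerance = 1e-9)
  # zero force, zero velocity
  sc$f_ext <- NULL
  sc <- scene_step(sc)
  expect_equal(max(abs(sc$last$vel)), 0)
})

test_that("internal equal-and-opposite forces leave the center of mass at rest", {
  sc <- new_scene(dt = 10, seed = 1)
  sc <- scene_add(sc, cbm_cell(c(0, 0, 0)))
  sc <- scene_add(sc, cbm_cell(c(23e-6, 0, 0)))   # overlapping: JKR couple
  com0 <- (sc$cbm[[1]]$center + sc$cbm[[2]]$center) / 2
  sc <- simulate_scene(sc, 30)
  com1 <- (sc$cbm[[1]]$center + sc$cbm[[2]]$center) / 2
  expect_lt(max(abs(com1 - com0)), 1e-12)
})

test_that("missing grounding friction is rejected", {
  sc <- new_scene(dt = 10, seed = 1, gamma_cbm_sub = 0)
  sc <- scene_add(sc, cbm_cell(c(0, 0, 0)))
  expect_error(scene_step(sc), "grounding friction")
})

test_that("directed migration force splits exactly and validates direction", {
  Fm <- directed_migration_force(162, 0.3e-9, c(0, 0, 2))
  expect_equal(colSums(Fm), c(0, 0, 0.3e-9), tolerance = 1e-20)
  expect_equal(Fm[1, 3], 0.3e-9 / 162, tolerance = 1e-20)  # 1.85e-12 N
  expect_error(directed_migration_force(10, 1e-9, c(0, 0, 0)), "zero")
  expect_equal(max(abs(random_migration_force(10, 0, 1, 1))), 0)
})

test_that("random migration reproduces the configured diffusion constant", {
  D <- 1e-16
  dt <- 20
  nrep <- 24
  nstep <- 300
  msd <- numeric(nrep)
  for (r in seq_len(nrep)) {
    sc <- new_scene(dt = dt, seed = 100 + r,
                    migration = list(D = D, F_mor = 0, leader_only = TRUE,
                                     dir_fun = NULL))
    sc <- scene_add(sc, cbm_cell(c(0, 0, 0)))
    x0 <- sc$cbm[[1]]$center
    sc <- simulate_scene(sc, nstep)
    msd[r] <- sum((sc$cbm[[1]]$center - x0)^2)
  }
  Dfit <- mean(msd) / (6 * nstep * dt)
  expect_gt(Dfit, 0.7 * D)
  expect_lt(Dfit, 1.3 * D)
})

test_that("halving the time step changes a relaxation endpoint by < 1 %", {
  run <- function(dt, n) {
    cell <- dcm_cell(build_icosphere(10e-6, 1))
    cell$mesh$V <- cell$mesh$V * 0.96    # compressed start
    sc <- new_scene(dt = dt, seed = 1, medium = "area",
                    gamma_medium_area = 1e8)
    sc <- scene_add(sc, cell)
    sc <- simulate_scene(sc, n)
    sc$dcm[[1]]$mesh$V
  }
  V1 <- run(0.02, 300)
  V2 <- run(0.01, 600)
  expect_lt(max(row_norm(V1 - V2)), 0.01 * 10e-6)
})

test_that("scene stepping is deterministic given (config, seed)", {
  mk <- function() {
    sc <- new_scene(dt = 20, seed = 42,
                    migration = list(D = 1e-16, F_mor = 0, leader_only = TRUE,
                                     dir_fun = NULL))
    sc <- scene_add(sc, cbm_cell(c(0, 0, 0)))
    sc <- scene_add(sc, cbm_cell(c(23.5e-6, 0, 0)))
    simulate_scene(sc, 50)
  }
  a <- mk(); b <- mk()
  expect_identical(a$cbm[[1]]$center, b$cbm[[1]]$center)
  expect_identical(a$cbm[[2]]$center, b$cbm[[2]]$center)
})

test_that("named RNG substreams are independent and reproducible", {
  r1 <- cellmech:::make_rng(7)
  r2 <- cellmech:::make_rng(7)
  a <- cellmech:::rng_draw(r1, "division", function() rnorm(3))
  # drawing from another stream does not shift the first
  cellmech:::rng_draw(r2, "migration", function() rnorm(50))
  b <- cellmech:::rng_draw(r2, "division", function() rnorm(3))
  expect_identical(a, b)
})
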