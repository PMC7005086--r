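test_that("linear growth doubles the reference volume in one cycle time", {
  cell <- dcm_cell(build_icosphere(10e-6, 1), tau = 24 * 3600)
  V0 <- cell$mesh$V0
  l0 <- cell$mesh$l0
  A0 <- cell$mesh$A0
  grown <- grow_step(cell, dt = cell$tau)          # alpha = V0/tau
  expect_equal(grown$mesh$V0 / V0, 2, tolerance = 1e-12)
  expect_equal(grown$mesh$l0 / l0, rep(2^(1 / 3), length(l0)), tolerance = 1e-12)
  expect_equal(grown$mesh$A0 / A0, 2^(2 / 3), tolerance = 1e-12)
  # alpha = 0 leaves everything unchanged
  same <- grow_step(cell, alpha = 0, dt = 1000)
  expect_identical(same$mesh$l0, cell$mesh$l0)
  # growth in many small steps introduces no spurious mismatch
  c2 <- cell
  for (i in 1:100) c2 <- grow_step(c2, dt = cell$tau / 100)
  expect_equal(c2$mesh$V0 / V0, 2, tolerance = 1e-9)
})

test_that("a quasi-statically grown free cell tracks its reference volume", {
  # cycle time chosen far above the mechanical relaxation time (~0.2 s),
  # so growth remains quasi-static at this reduced problem size
  tau <- 120
  cell <- dcm_cell(build_icosphere(8e-6, 1), tau = tau)
  sc <- new_scene(dt = 0.04, seed = 1, medium = "area",
                  gamma_medium_area = 1e8)
  sc <- scene_add(sc, cell)
  n <- round(tau / sc$dt / 2)        # half a cycle: V0 x 1.5
  for (s in seq_len(n)) {
    sc <- scene_step(sc)
    sc$dcm[[1]] <- grow_step(sc$dcm[[1]], dt = sc$dt)
  }
  v <- enclosed_volume(sc$dcm[[1]]$mesh)
  expect_equal(v / sc$dcm[[1]]$mesh$V0, 1, tolerance = 0.02)
})

test_that("lysis is the inverse of growth and removes cells at the floor", {
  cell <- dcm_cell(build_icosphere(10e-6, 1), tau = 24 * 3600)
  V0 <- cell$mesh$V0
  rate <- cell$alpha
  shr <- lysis_step(cell, rate, dt = cell$tau / 2, floor_volume = 0.1 * V0)
  expect_equal(shr$mesh$V0 / V0, 0.5, tolerance = 1e-12)
  expect_gt(enclosed_volume(shr$mesh), 0)   # mesh still closed and oriented
  gone <- lysis_step(shr, rate, dt = cell$tau / 2, floor_volume = 0.1 * V0)
  expect_null(gone)
})

test_that("CBM division: half volumes, stiffness ramp, center of mass", {
  mother <- cbm_cell(c(1, 2, 3) * 1e-6, R = 12e-6, tau = 24 * 3600)
  mother$V0 <- 2 * mother$V0     # grown to V_crit
  ds <- divide_cbm(mother, direction = c(0, 0, 1), time = 500,
                   V_crit = mother$V0)
  expect_equal(ds[[1]]$V0 / mother$V0, 0.5, tolerance = 1e-12)
  expect_equal(ds[[2]]$V0 / mother$V0, 0.5, tolerance = 1e-12)
  expect_equal(ds[[1]]$ramp_T, 24 * 3600 / 10)   # 2.4 h for a 24 h cycle
  expect_equal(ds[[1]]$t_div, 500)
  com <- (ds[[1]]$center + ds[[2]]$center) / 2
  expect_equal(com, mother$center, tolerance = 1e-18)
  # daughters fit inside the mother footprint
  expect_lt(max(row_norm(rbind(ds[[1]]$center, ds[[2]]$center) -
                           matrix(mother$center, 2, 3, byrow = TRUE))) +
              ds[[1]]$R, mother$R * 1.0 + 1e-12)
})

test_that("random division-plane normals are uniform on the sphere", {
  set.seed(11)
  n <- 1000
  normals <- t(replicate(n, division_plane_normal("random")))
  expect_equal(row_norm(normals), rep(1, n), tolerance = 1e-12)
  # Rayleigh statistic 3 n |mean|^2 ~ chi^2_3 under uniformity
  stat <- 3 * n * sum(colMeans(normals)^2)
  expect_lt(stat, qchisq(0.999, df = 3))
})

test_that("division plane aligns with the nearest sinusoid segment under HSA", {
  segs <- rbind(c(0, 0, 0, 1e-5, 0, 0),           # x-aligned, near
                c(0, 1e-3, 0, 0, 1e-3, 1e-5))     # far
  n <- division_plane_normal("hsa", center = c(2e-6, 1e-6, 0),
                             sinusoid_segments = segs)
  expect_equal(abs(sum(n * c(1, 0, 0))), 1, tolerance = 1e-12)
})

test_that("DCM division produces two valid, non-interpenetrating daughters", {
  # structural check at the standard 162-node discretization with a
  # truncated protocol; strict volume bookkeeping is asserted in the
  # end-to-end suite
  sc <- new_scene(dt = 0.02, seed = 5, medium = "area",
                  gamma_medium_area = 1e8)
  mother <- dcm_cell(build_icosphere(8e-6, 2), tau = 3600)
  s <- 2
  mother$mesh$V0 <- mother$mesh$V0 * s
  mother$mesh$A0_tri <- mother$mesh$A0_tri * s^(2 / 3)
  mother$mesh$A0 <- mother$mesh$A0 * s^(2 / 3)
  mother$mesh$l0 <- mother$mesh$l0 * s^(1 / 3)
  sc <- scene_add(sc, mother)
  sc <- simulate_scene(sc, 200)
  Vm <- enclosed_volume(sc$dcm[[1]]$mesh)
  sc2 <- divide_dcm(sc, 1, max_sub_steps = 100L)
  expect_length(sc2$dcm, 2)
  expect_false(is.null(sc2$last_division$normal))
  sc2 <- simulate_scene(sc2, 200)
  v1 <- enclosed_volume(sc2$dcm[[1]]$mesh)
  v2 <- enclosed_volume(sc2$dcm[[2]]$mesh)
  expect_gt(v1, 0); expect_gt(v2, 0)
  expect_equal((v1 + v2) / Vm, 1, tolerance = 0.15)
  # daughters adhere without deep interpenetration
  pt <- sc2$last$patches
  if (length(pt) > 0) {
    h0 <- sc2$dcm[[1]]$contact$h0
    expect_gt(min(pt[[1]][, "gmin"]), -0.5 * h0)
  }
})

test_that("an uninhibited CBM population doubles every cycle time", {
  res <- run_growth_assay("spheroid", "CBM", n_target = 28, tau = 24 * 3600,
                          D = 0, seed = 2)
  s <- res$series
  fit <- lm(log(N) ~ time, data = s[s$N > 1, ])
  rate <- unname(coef(fit)[2])
  expect_equal(rate, log(2) / (24 * 3600), tolerance = 0.1)
  expect_equal(s$R_gyr[1], 0, tolerance = 1e-12)   # single cell
})
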