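test_that("JKR reduces to Hertz without adhesion", {
  Ehat <- 300; Rhat <- 6e-6
  for (delta in c(1e-7, 5e-7, 2e-6)) {
    jf <- jkr_force(delta, 450, 0.47, 12e-6, 450, 0.47, 12e-6, W = 0)
    red <- reduced_pair(450, 0.47, 450, 0.47, 12e-6, 12e-6)
    expect_equal(jf$a, sqrt(delta * red$Rhat), tolerance = 1e-10)
    expect_equal(jf$F, 4 / 3 * red$Ehat * sqrt(red$Rhat) * delta^1.5,
                 tolerance = 1e-8)
  }
  expect_equal(jkr_force(0, 450, 0.47, 12e-6, W = 0)$F, 0)
})

test_that("JKR radius solve is consistent and flags detachment", {
  red <- reduced_pair(450, 0.47, 450, 0.47, 12e-6, 12e-6)
  W <- 1e-5
  a <- jkr_contact_radius(2e-7, red$Ehat, red$Rhat, W)
  # plugging a back into the overlap relation returns delta
  expect_equal(a^2 / red$Rhat - sqrt(2 * pi * W * a / red$Ehat), 2e-7,
               tolerance = 1e-13)
  dmin <- jkr_detachment_overlap(red$Ehat, red$Rhat, W)
  expect_lt(dmin, 0)
  jf <- jkr_force(dmin * 1.5, 450, 0.47, 12e-6, 450, 0.47, 12e-6, W = W)
  expect_true(jf$detached)
  expect_equal(jf$F, 0)
})

test_that("vectorized JKR matches the scalar root solve (dual route)", {
  red <- reduced_pair(450, 0.47, 450, 0.47, 12e-6, 12e-6)
  W <- 1e-5
  deltas <- seq(-2e-7, 2e-6, length.out = 25)
  fast <- jkr_force_vec(deltas, red$Ehat, red$Rhat, W, TRUE)
  for (q in seq_along(deltas)) {
    a <- jkr_contact_radius(deltas[q], red$Ehat, red$Rhat, W)
    if (is.na(a)) {
      expect_equal(fast$F[q], 0)
    } else {
      Fq <- 4 * red$Ehat / (3 * red$Rhat) * a^3 -
        sqrt(8 * pi * W * red$Ehat * a^3)
      expect_equal(fast$F[q], Fq, tolerance = 1e-5)
    }
  }
})

test_that("JKR equilibrium overlap is positive and matches the force zero", {
  red <- reduced_pair(450, 0.47, 450, 0.47, 12e-6, 12e-6)
  W <- 1e-5
  f <- function(d) jkr_force_vec(d, red$Ehat, red$Rhat, W, TRUE)$F
  deq <- uniroot(f, c(1e-8, 2e-6))$root
  expect_gt(deq, 0)
  # closed form: a_eq^3 = 9 pi W Rhat^2 / (2 Ehat)
  aeq <- (4.5 * pi * W * red$Rhat^2 / red$Ehat)^(1 / 3)
  deq_th <- aeq^2 / red$Rhat - sqrt(2 * pi * W * aeq / red$Ehat)
  expect_equal(deq, deq_th, tolerance = 1e-5)
})

test_that("packing measure and corrected modulus", {
  expect_equal(packing_measure(24e-6, 12e-6, 12e-6), 0)
  expect_equal(mean(c(0.1, 0.3)), packing_measure(c(0.9, 0.7) * 24e-6,
                                                  12e-6, c(12e-6, 12e-6)))
  expect_equal(packing_measure(numeric(0), 12e-6, numeric(0)), 0)
  # compression of a fixed neighborhood increases the measure
  dists <- seq(24e-6, 18e-6, by = -1e-6)
  vals <- sapply(dists, function(d) packing_measure(rep(d, 6), 12e-6, 12e-6))
  expect_true(all(diff(vals) > 0))
  expect_equal(corrected_modulus(450, 0), 450)
  expect_equal(corrected_modulus(450, 0.1, a1 = 4e6), 850)
  expect_equal(corrected_modulus(450, 0.1, a1 = 4e6, ramp = 0.5), 650)
  d <- seq(0, 0.3, by = 0.05)
  expect_true(all(diff(corrected_modulus(450, d)) > 0))
})

test_that("CBM elastic parameters tie to the DCM bulk modulus", {
  cl <- cbm_cell(c(0, 0, 0), K_V = 2500, nu = 0.47)
  expect_equal(cl$E, 2500 / (3 * (1 - 2 * 0.47)), tolerance = 1e-12)
  cl2 <- cbm_cell(c(0, 0, 0), E = 450, nu = 0.47)
  expect_equal(cl2$E, 450)
  expect_equal(cl2$V0, 4 / 3 * pi * (12e-6)^3, tolerance = 1e-12)
})

test_that("hybrid DCM-CBM pair obeys Newton's third law and forms a contact disk", {
  R <- 10e-6
  dcm <- dcm_cell(build_icosphere(R, 2), contact = contact_params(W = 1e-5))
  cbm <- cbm_cell(c(2 * R - 0.4e-6 + 2e-6, 0, 0), R = 12e-6, W = 1e-5)
  hp <- hybrid_pair(dcm, cbm)
  expect_equal(hp$F_cbm, -colSums(hp$F_dcm), tolerance = 1e-12)
  expect_gt(sum(hp$area), 0)
  # W = 0 and no overlap: nothing
  cbm_far <- cbm_cell(c(2 * R + 13e-6, 0, 0), R = 12e-6, W = 0)
  hp0 <- hybrid_pair(dcm, cbm_far, W = 0)
  expect_equal(sum(abs(hp0$F_dcm)), 0)
})
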