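test_that("Tabor coefficient: value, linearity in sigma0, guards", {
  # own evaluation: 500 * (9*5e-6 / (2*pi*1e-5*3.6e5))^(1/3) = 6.2885
  Ehat <- sqrt(3.6e5)
  lam <- tabor_coefficient(500, 5e-6, 1e-5, Ehat)
  expect_equal(lam, 500 * (9 * 5e-6 / (2 * pi * 1e-5 * 3.6e5))^(1 / 3),
               tolerance = 1e-12)
  expect_equal(lam, 6.2885, tolerance = 1e-4)
  expect_equal(tabor_coefficient(1000, 5e-6, 1e-5, Ehat), 2 * lam,
               tolerance = 1e-12)
  expect_error(tabor_coefficient(500, 5e-6, 1e-5, 0), "Ehat")
  # W = h0 * sigma0 decomposition
  expect_equal(contact_params(W = 1e-5, h0 = 2e-8)$sigma0, 500)
})

test_that("Maugis m: root residual, JKR limit, monotone in lambda", {
  a <- 1e-6; W <- 1e-5; Ehat <- 600; Rhat <- 5e-6
  for (lam in c(0.5, 1, 2, 5)) {
    m <- solve_maugis_m(lam, a, W, Ehat, Rhat)
    expect_lt(abs(maugis_lhs(m, lam, a, W, Ehat, Rhat) - 1), 1e-8)
    expect_gte(m, 1)
  }
  expect_lt(solve_maugis_m(20, a, W, Ehat, Rhat), 1.01)  # JKR limit
  ms <- sapply(c(0.5, 1, 2, 5, 10), solve_maugis_m, a = a, W = W,
               Ehat = Ehat, Rhat = Rhat)
  expect_true(all(diff(ms) < 0))
})

test_that("Maugis-Dugdale traction profile", {
  sigma0 <- 500; Ehat <- 1e-12; Rhat <- 1  # negligible Hertz part
  expect_equal(md_traction(3, 1, 2, sigma0, Ehat, Rhat), 0)
  expect_equal(md_traction(0, 1, 2, sigma0, Ehat, Rhat),
               -sigma0 / pi * acos(-1 / 2), tolerance = 1e-9)
  expect_equal(md_traction(0, 1, 2, sigma0, Ehat, Rhat) / sigma0, -2 / 3,
               tolerance = 1e-9)
  expect_equal(md_traction(1.999, 1, 2, sigma0, Ehat, Rhat), -sigma0,
               tolerance = 1e-9)
  # Hertz part integrates to the Eq. 20 repulsive term
  Ehat <- 300; Rhat <- 5e-6; a <- 1e-6
  f <- function(r) 2 * Ehat / (pi * Rhat) * sqrt(a^2 - r^2) * 2 * pi * r
  tot <- integrate(f, 0, a)$value
  expect_equal(tot, 4 * Ehat * a^3 / (3 * Rhat), tolerance = 1e-6)
})

test_that("cell-pair contact conserves momentum and respects the adhesive range", {
  R <- 10e-6
  cA <- dcm_cell(build_icosphere(R, 2), contact = contact_params(W = 1e-5))
  cB <- dcm_cell(build_icosphere(R, 2, center = c(2 * R - 0.3e-6, 0, 0)),
                 contact = contact_params(W = 1e-5))
  res <- cell_pair_contact(cA, cB)
  expect_gt(nrow(res$patches), 0)
  expect_lt(max(abs(colSums(res$F1) + colSums(res$F2))),
            1e-12 * sum(abs(res$F1)))
  expect_equal(colSums(res$F1), res$total1, tolerance = 1e-12)
  # attraction grows with W near touching
  Fx <- sapply(c(1e-6, 1e-5, 5e-5), function(W)
    cell_pair_contact(cA, cB, W = W)$total1[1])
  expect_true(all(diff(Fx) > 0))
  # out of range: no force
  cC <- dcm_cell(build_icosphere(R, 2, center = c(2 * R + 5e-6, 0, 0)))
  expect_equal(cell_pair_contact(cA, cC)$total1, c(0, 0, 0))
})

test_that("tractions are gated by the actual surface separation", {
  V1 <- rbind(c(0, 0, 0), c(2e-6, 0, 0), c(0, 2e-6, 0))
  T1 <- matrix(c(1L, 2L, 3L), 1)
  mk2 <- function(z) rbind(c(0, 0, z), c(0, 2e-6, z), c(2e-6, 0, z))
  # 50 nm separation (> h0 = 20 nm): zero force
  r50 <- cpp_pair_contact(V1, T1, 1e-4, mk2(5e-8), T1, 1e-4,
                          cbind(1L, 1L), 500, 2e-8, 1e-5, 300, 20)
  expect_equal(r50$total1, c(0, 0, 0))
  # 10 nm: cohesive traction sigma0 over the 2e-12 m^2 overlap
  r10 <- cpp_pair_contact(V1, T1, 1e-4, mk2(1e-8), T1, 1e-4,
                          cbind(1L, 1L), 500, 2e-8, 1e-5, 300, 20)
  expect_equal(r10$total1[3], 500 * 2e-12, tolerance = 1e-12)
  # overlap: the penalty pushes back
  rneg <- cpp_pair_contact(V1, T1, 1e-4, mk2(-1e-8), T1, 1e-4,
                           cbind(1L, 1L), 500, 2e-8, 1e-5, 300, 20)
  expect_lt(rneg$total1[3], 0)
})

test_that("integrated repulsion approaches the Hertz force with refinement", {
  R <- 10e-6; delta <- 1e-6
  red <- reduced_pair(450, 0.47, 450, 0.47)
  hertz <- 4 / 3 * red$Ehat * sqrt(R / 2) * delta^1.5
  ratios <- sapply(2:3, function(lev) {
    cA <- dcm_cell(build_icosphere(R, lev),
                   contact = contact_params(W = 0, pen_stiff = 0))
    cB <- dcm_cell(build_icosphere(R, lev, center = c(2 * R - delta, 0, 0)),
                   contact = contact_params(W = 0, pen_stiff = 0))
    -cell_pair_contact(cA, cB, W = 0)$total1[1] / hertz
  })
  expect_gt(ratios[2], ratios[1])      # converging from below
  expect_gt(ratios[2], 0.75)
  expect_lt(ratios[2], 1.1)
})

test_that("smooth-body contact: plane equals the large-sphere limit; W=0 sinusoid repels", {
  R <- 10e-6
  cell <- dcm_cell(build_icosphere(R, 2, center = c(0, 0, R - 0.2e-6)),
                   contact = contact_params(W = 0))
  pl <- cell_body_contact(cell, list(type = "plane", point = c(0, 0, 0),
                                     normal = c(0, 0, 1), W = 0))
  bigR <- 1e6 * R
  sp <- cell_body_contact(cell, list(type = "sphere",
                                     center = c(0, 0, -bigR), R = bigR, W = 0))
  expect_gt(pl$total[3], 0)  # pushed away from the plane
  expect_equal(sp$total[3], pl$total[3], tolerance = 0.01)
  # rigid sinusoid sphere, W = 0: purely repulsive
  sin_b <- list(type = "sphere", center = c(2 * R * 0.72, 0, R - 0.2e-6),
                R = 4.7e-6, E = 600, nu = 0.4, W = 0)
  rs <- cell_body_contact(cell, sin_b)
  if (sum(abs(rs$total)) > 0) {
    u <- sin_b$center - colMeans(cell$mesh$V)
    expect_lt(sum(rs$total * u), 0)   # net force away from the obstacle
  }
  # Newton's third law bookkeeping
  expect_equal(rs$body_force, -rs$total)
})

test_that("anisotropic friction tensor", {
  e <- c(1, 0, 0)
  expect_equal(friction_tensor(e, 2, 2), 2 * diag(3))
  G <- friction_tensor(c(1, 1, 0) / sqrt(2), 3, 1)
  ev <- eigen(G, symmetric = TRUE)
  expect_equal(sort(ev$values), c(1, 1, 3), tolerance = 1e-12)
  expect_equal(as.vector(G %*% (c(1, 1, 0) / sqrt(2))),
               3 * c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  expect_error(friction_tensor(c(0, 0, 0), 1, 1), "zero")
})
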