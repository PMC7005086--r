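# Virtual experiments: optical stretcher, pull-off, compression calibration,
# growth assays, and liver-lobule regeneration.

#' Nominal physical parameter set
#'
#' The reference parameter values for both model types and the lobule
#' network geometry, as used throughout the experiments. Starred parameters
#' (cycle time, adhesion energy, Young modulus) support +/-10 % per-cell
#' Gaussian variability via [sample_cell_parameters()].
#'
#' @return nested list with components `dcm`, `cbm`, `lobule`.
#' @export
default_parameters <- function() {
  list(
    dcm = list(R_c = 8.8e-6, tau = 24 * 3600, E_cor = 1000, h_cor = 500e-9,
               nu_cor = 0.5, K_A = 0.8e-3, K_V = 2500, W = 1e-5,
               gamma_int = 1e-4, gamma_cc_area = 5e10, gamma_ecm_area = 1e8,
               gamma_liq_area = 500, D = 1e-16, h0 = 2e-8),
    cbm = list(R_c = 12e-6, tau = 24 * 3600, E = 450, nu = 0.47, W = 1e-5,
               gamma_cc_area = 1e10, gamma_ecm_area = 5e8, D = 1e-16),
    lobule = list(R_lob = 280e-6, R_pv = 15e-6, R_cv = 10e-6, R_sin = 4.7e-6,
                  E_sin = 600, nu_sin = 0.4, W_sin = 0, R_nec = 150e-6,
                  slab = 72e-6, R_c = 12e-6)
  )
}

# ---- optical stretcher -------------------------------------------------------

#' Simulate an optical stretcher experiment
#'
#' A single deformable cell in suspension (Stokes node friction) is loaded
#' with the standard optical-stretcher surface-stress profile
#' `sigma(theta) = sigma_peak cos^2(theta)` about the beam (Z) axis, applied
#' outward on the node Voronoi areas, for `t_stretch` seconds, then released
#' for `t_release` seconds. While the laser is on, all cortical friction
#' coefficients are multiplied by the thermal ratio of the corresponding
#' laser power; at release they are restored instantly.
#'
#' @param power_mW laser power (mW); `sigma_peak = sigma_per_mW * power_mW`.
#' @param element_model `"KVE"` or `"MME"`; defaults to the stretcher-fitted
#'   element constants (`k_s` 1e-4 / 5e-4 N/m, `k_b` 2e-17 N m, nominal
#'   damping 2.3e-4 / 3e-5 Ns/m, Maxwell dashpot 3e-3 Ns/m).
#' @param K_V cell bulk modulus (Pa).
#' @param level icosphere subdivision (2 = 162 nodes, 3 = 642 nodes).
#' @param R cell radius (m).
#' @param dt time step (s).
#' @param t_stretch,t_release stretch / monitoring durations (s).
#' @param sigma_per_mW peak-stress calibration constant (Pa/mW).
#' @param thermal_ratios named vector: friction multiplier per laser power.
#' @param seed RNG seed (the run itself is deterministic).
#' @return data.frame with `time`, `strain_long` (Z), `strain_short` (Y);
#'   attributes `peak_strain_long`, `residual_strain_long`.
#' @export
run_optical_stretcher <- function(power_mW = 1100,
                                  element_model = c("MME", "KVE"),
                                  K_V = 2500, level = 2, R = 8.8e-6,
                                  dt = NULL, t_stretch = 2, t_release = 2,
                                  sigma_per_mW = 1e-3,
                                  thermal_ratios = c("900" = 0.29, "1100" = 0.11),
                                  seed = 1L) {
  element_model <- match.arg(element_model)
  par <- if (element_model == "KVE") {
    cortex_params(E_cor = 1000, h_cor = 5e-7, K_V = K_V,
                  element_model = "KVE", gamma_int = 2.3e-4)
  } else {
    cortex_params(E_cor = 1000, h_cor = 5e-7, K_V = K_V,
                  element_model = "MME", gamma_int = 3e-5, gamma_ME = 3e-3)
  }
  cell <- dcm_cell(build_icosphere(R, level), params = par)
  # stretcher-fitted discrete constants
  cell$params$k_s <- if (element_model == "KVE") 1e-4 else 5e-4
  cell$params$k_b <- 2e-17
  ratio <- if (power_mW <= 0) 1 else {
    key <- names(thermal_ratios)[which.min(abs(as.numeric(names(thermal_ratios)) - power_mW))]
    unname(thermal_ratios[key])
  }
  if (is.null(dt)) {
    # volume pressure is integrated semi-implicitly, so the limit is the
    # explicit in-plane stiffness against the thermally reduced damping
    g_edge <- 2 * ratio * cell$params$gamma_int
    K_edge <- 8 * (if (element_model == "KVE") 1e-4 else 0)
    dt <- if (K_edge > 0) min(0.01, 0.25 * g_edge / K_edge) else 0.01
  }
  sc <- new_scene(dt = dt, seed = seed, medium = "stokes")
  sc <- scene_add(sc, cell)
  sigma_peak <- sigma_per_mW * power_mW
  laser_force <- function(scene, state) {
    cl <- scene$dcm[[1]]
    V <- cl$mesh$V
    ctr <- colMeans(V)
    rel <- sweep(V, 2, ctr)
    rn <- row_norm(rel)
    u <- rel / rn
    S <- state$Svor[[1]]
    cth2 <- (u[, 3])^2
    list(dcm = list(u * (sigma_peak * cth2 * S)))
  }
  ext0 <- function(V) {
    ctr <- colMeans(V)
    c(long = max(V[, 3]) - min(V[, 3]), short = max(V[, 2]) - min(V[, 2]))
  }
  e0 <- ext0(cell$mesh$V)
  n_on <- round(t_stretch / dt); n_off <- round(t_release / dt)
  out <- matrix(NA_real_, n_on + n_off, 3)
  sc$f_ext <- laser_force
  sc$thermal_scale <- ratio
  for (s in seq_len(n_on)) {
    sc <- scene_step(sc)
    e <- ext0(sc$dcm[[1]]$mesh$V)
    out[s, ] <- c(sc$time, (e - e0) / e0)
  }
  sc$f_ext <- NULL
  sc$thermal_scale <- 1
  for (s in seq_len(n_off)) {
    sc <- scene_step(sc)
    e <- ext0(sc$dcm[[1]]$mesh$V)
    out[n_on + s, ] <- c(sc$time, (e - e0) / e0)
  }
  df <- data.frame(time = out[, 1], strain_long = out[, 2],
                   strain_short = out[, 3])
  attr(df, "peak_strain_long") <- max(df$strain_long)
  attr(df, "residual_strain_long") <- df$strain_long[nrow(df)]
  attr(df, "power_mW") <- power_mW
  attr(df, "element_model") <- element_model
  df
}

# ---- pull-off ----------------------------------------------------------------

min_surface_gap <- function(VA, VB) {
  d2 <- -2 * tcrossprod(VA, VB)
  d2 <- d2 + rowSums(VA^2)
  d2 <- sweep(d2, 2, rowSums(VB^2), "+")
  sqrt(max(min(d2), 0))
}

#' Two-cell pull-off experiment with binary force search
#'
#' Two equal deformable cells are relaxed into adhesive equilibrium, then
#' equal and opposite nodal forces perpendicular to the contact are applied;
#' a bisection on the force magnitude between a held bound and a separating
#' bound estimates the pull-off force, which JKR theory predicts as
#' `(3/2) pi W Rhat`.
#'
#' @param W specific adhesion energy (J/m^2).
#' @param R cell radius (m), equal for both cells.
#' @param level icosphere subdivision (2 = 162 nodes).
#' @param dt time step (s); by default scaled with `1e-5/W` because the
#'   cohesive-zone stiffness grows with `sigma0 = W/h0`.
#' @param overlap0 initial center overlap used to seed the contact (m).
#' @param relax_time relaxation duration to adhesive equilibrium (s).
#' @param pull_time duration of each quasi-static pulling trial (s).
#' @param n_bisect bisection iterations.
#' @param seed RNG seed.
#' @param gamma_cc_pull cell-cell contact friction per area during the
#'   trials (Ns/m^3); reduced relative to the nominal value because the
#'   quasi-static threshold does not depend on it while the time to reach a
#'   verdict does.
#' @return list with `F_pulloff` (N), `F_ref` (JKR reference, N), `ratio`,
#'   `trials` (data.frame of force, separated).
#' @export
run_pulloff <- function(W = 1e-5, R = 10e-6, level = 2, dt = NULL,
                        overlap0 = 0.4e-6, relax_time = 14, pull_time = 50,
                        n_bisect = 6, seed = 1L, gamma_cc_pull = 5e7) {
  # the cohesive-zone stiffness grows with sigma0 = W/h0, so the stable
  # step shrinks proportionally; relaxation and trials have fixed
  # quasi-static durations
  if (is.null(dt)) dt <- min(0.02, 0.02 * 1e-5 / max(W, 1e-6))
  n_pull <- round(pull_time / dt)
  n_relax <- round(relax_time / dt)
  sc <- new_scene(dt = dt, seed = seed, medium = "area",
                  gamma_medium_area = 1e8)
  c1 <- dcm_cell(build_icosphere(R, level), contact = contact_params(W = W))
  c2 <- dcm_cell(build_icosphere(R, level, center = c(2 * R - overlap0, 0, 0)),
                 contact = contact_params(W = W))
  sc <- scene_add(sc, c1); sc <- scene_add(sc, c2)
  sc <- simulate_scene(sc, n_relax)
  if (W > 0 && length(sc$last$patches) == 0)
    stop("cells failed to adhere during relaxation")
  base <- sc
  # quasi-static threshold is friction-independent; reduced contact friction
  # lets each trial reach its verdict in fewer steps
  base$gamma_cc_area <- gamma_cc_pull
  base$fcache <- NULL
  F_ref <- abs(jkr_pulloff_force(W, R / 2))
  F_scale <- abs(jkr_pulloff_force(max(W, 1e-5), R / 2))
  n1 <- nrow(base$dcm[[1]]$mesh$V)
  np0 <- if (length(base$last$patches)) nrow(base$last$patches[[1]]) else 0L
  trial <- function(Fmag) {
    s <- base
    s$f_ext <- function(scene) {
      list(dcm = list(
        matrix(rep(c(-Fmag / n1, 0, 0), each = n1), n1, 3),
        matrix(rep(c(Fmag / n1, 0, 0), each = n1), n1, 3)
      ))
    }
    clear <- 0L
    for (k in seq_len(n_pull)) {
      s <- scene_step(s)
      np <- if (length(s$last$patches)) nrow(s$last$patches[[1]]) else 0L
      clear <- if (np == 0L) clear + 1L else 0L
      if (clear >= 10L) return(TRUE)   # contact fully peeled
      # early verdict only for clear-cut holds: the bonded area is still
      # essentially intact late in the quasi-static window
      if (k == round(0.6 * n_pull) && np0 > 0 && np >= 0.85 * np0)
        return(FALSE)
    }
    FALSE
  }
  hi <- 2 * F_scale
  tr <- list()
  for (g in 1:5) {
    sep <- trial(hi)
    tr[[length(tr) + 1]] <- c(hi, sep)
    if (sep) break
    hi <- hi * 2
  }
  lo <- 0
  for (b in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    sep <- trial(mid)
    tr[[length(tr) + 1]] <- c(mid, sep)
    if (sep) hi <- mid else lo <- mid
  }
  trials <- as.data.frame(do.call(rbind, tr))
  names(trials) <- c("force", "separated")
  est <- (lo + hi) / 2
  list(F_pulloff = est, F_ref = F_ref, ratio = if (F_ref > 0) est / F_ref else NA,
       trials = trials)
}

# ---- compression calibration -------------------------------------------------

#' Quasi-static compression of a DCM doublet and CBM stiffness calibration
#'
#' Two adhered deformable cells inside a snug rigid cage (standing in for
#' the neighbors of a spheroid interior) are compressed quasi-statically by
#' equal and opposite center forces applied in increasing steps; at
#' mechanical equilibrium the interface transmits exactly the applied load,
#' so the cell-cell contact force is recorded as a function of the center
#' distance without any dynamic measurement noise. The packing-corrected
#' JKR law (`Etilde = E + a1 dtilde^4`) is then least-squares fitted to the
#' curve, yielding the correction coefficient `a1`.
#'
#' @param W cell-cell adhesion energy (J/m^2); cage walls are non-adhesive.
#' @param R cell radius (m).
#' @param level icosphere subdivision.
#' @param dt time step (s).
#' @param n_relax initial relaxation steps.
#' @param forces_nN applied compression levels (nN), increasing.
#' @param n_eq equilibration steps per force level.
#' @param n_avg steps over which the center distance is averaged.
#' @param E_cbm,nu_cbm CBM elastic parameters for the comparison.
#' @param seed RNG seed.
#' @return list with `curve` (data.frame: distance, delta, F_dcm, dtilde,
#'   F_jkr, F_fit), `a1` (fitted, Pa), `max_rel_dev` (of the corrected fit
#'   over the strong-force range), `underestimate_ratio` (uncorrected JKR
#'   force over DCM force at the highest compression).
#' @export
run_compression_calibration <- function(W = 1e-5, R = 10e-6, level = 2,
                                        dt = 0.02, n_relax = 500,
                                        forces_nN = c(0, 0.3, 0.6, 1, 1.5,
                                                      2.2, 3, 4, 5.2, 6.6, 8),
                                        n_eq = 300, n_avg = 60, E_cbm = 450,
                                        nu_cbm = 0.47, seed = 1L) {
  # Two cells in adhesive equilibrium inside a snug rigid cage (which plays
  # the role of the neighbors of a spheroid interior); equal and opposite
  # compressive center forces are then applied in increasing steps. At
  # mechanical equilibrium the interface transmits exactly the applied
  # load, so the contact force-distance curve is read off statically.
  x0 <- R - 0.2e-6
  box <- R + 0.1e-6
  sc <- new_scene(dt = dt, seed = seed, medium = "area",
                  gamma_medium_area = 1e8)
  sc <- scene_add(sc, dcm_cell(build_icosphere(R, level, center = c(-x0, 0, 0)),
                               contact = contact_params(W = W)))
  sc <- scene_add(sc, dcm_cell(build_icosphere(R, level, center = c(x0, 0, 0)),
                               contact = contact_params(W = W)))
  for (pl in list(
    list(type = "plane", point = c(0, -box, 0), normal = c(0, 1, 0), W = 0),
    list(type = "plane", point = c(0, box, 0), normal = c(0, -1, 0), W = 0),
    list(type = "plane", point = c(0, 0, -box), normal = c(0, 0, 1), W = 0),
    list(type = "plane", point = c(0, 0, box), normal = c(0, 0, -1), W = 0)))
    sc <- scene_add(sc, pl)
  sc <- simulate_scene(sc, n_relax)
  n1 <- nrow(sc$dcm[[1]]$mesh$V)
  rec <- list()
  for (FnN in forces_nN) {
    Fap <- FnN * 1e-9
    sc$f_ext <- function(scene) list(dcm = list(
      matrix(rep(c(Fap / n1, 0, 0), each = n1), n1, 3),
      matrix(rep(c(-Fap / n1, 0, 0), each = n1), n1, 3)))
    sc <- simulate_scene(sc, n_eq)
    ds <- numeric(n_avg)
    for (j in seq_len(n_avg)) {
      sc <- scene_step(sc)
      ctr1 <- colMeans(sc$dcm[[1]]$mesh$V)
      ctr2 <- colMeans(sc$dcm[[2]]$mesh$V)
      ds[j] <- sqrt(sum((ctr2 - ctr1)^2))
    }
    d <- mean(ds)
    rec[[length(rec) + 1]] <- c(d = d, F_dcm = Fap,
                                dtil = max(1 - d / (2 * R), 0))
  }
  curve <- as.data.frame(do.call(rbind, rec))
  curve$delta <- 2 * R - curve$d
  cbm_force <- function(a1) {
    Et <- E_cbm + a1 * curve$dtil^4
    Ehat <- Et / (2 * (1 - nu_cbm^2))
    jkr_force_vec(curve$delta, Ehat, R / 2, W, TRUE)$F
  }
  sel <- curve$delta > 0 & curve$F_dcm > 0
  obj <- function(la1) sum((cbm_force(10^la1)[sel] - curve$F_dcm[sel])^2)
  la1 <- optimize(obj, c(3, 9))$minimum
  a1 <- 10^la1
  curve$F_jkr <- cbm_force(0)
  curve$F_fit <- cbm_force(a1)
  big <- sel & curve$F_dcm > 0.2 * max(curve$F_dcm)
  list(curve = curve, a1 = a1,
       max_rel_dev = max(abs(curve$F_fit[big] - curve$F_dcm[big]) /
                           curve$F_dcm[big]),
       underestimate_ratio = curve$F_jkr[which.max(curve$delta)] /
         curve$F_dcm[which.max(curve$delta)])
}

# ---- growth assays -----------------------------------------------------------

cbm_grow_divide <- function(scene, policy = list(), time = scene$time) {
  nc <- length(scene$cbm)
  for (q in seq_len(nc)) {
    cl <- scene$cbm[[q]]
    if (!isTRUE(cl$growing)) next
    cl <- grow_step(cl, dt = scene$dt)
    if (cl$V0 >= cl$V_crit) {
      dirn <- if (identical(policy$axis, "hsa")) {
        division_plane_normal("hsa", cl$center, policy$segments)
      } else {
        division_plane_normal("random",
                              z3 = rng_draw(scene$rng, "division", function() rnorm(3)))
      }
      ds <- divide_cbm(cl, dirn, time = time, V_crit = cl$V_crit)
      ds[[1]]$growing <- isTRUE(policy$keep_growing)
      ds[[2]]$growing <- isTRUE(policy$keep_growing)
      ds[[2]]$id <- scene$next_id
      scene$next_id <- scene$next_id + 1L
      scene$cbm[[q]] <- ds[[1]]
      scene$cbm[[length(scene$cbm) + 1L]] <- ds[[2]]
    } else {
      scene$cbm[[q]] <- cl
    }
  }
  scene
}

#' Growth assay: multicellular spheroid or monolayer from a single cell
#'
#' Uninhibited growth and division from one seeded cell; in monolayer mode
#' the cells sit on a flat adhesive substrate. Reports population size,
#' radius of gyration of the cell centers and, at the end, the radial area
#' density profile and per-cell pressure proxies.
#'
#' @param mode `"spheroid"` or `"monolayer"`.
#' @param engine `"CBM"` (default) or `"DCM"` (small populations).
#' @param n_target stop once the population reaches this size.
#' @param tau cell-cycle time (s).
#' @param R0 initial cell radius (m).
#' @param W cell-cell adhesion energy (J/m^2).
#' @param W_sub cell-substrate adhesion energy (monolayer).
#' @param D diffusion constant (m^2/s).
#' @param dt time step (s); default `tau / 200`.
#' @param level DCM icosphere subdivision.
#' @param stride record metrics every `stride` steps.
#' @param seed RNG seed.
#' @param max_steps hard step cap.
#' @return list with `series` (data.frame: time, N, R_gyr), `density`
#'   (data.frame r, rho; monolayer), `pressure` (per cell, Pa), `scene`.
#' @export
run_growth_assay <- function(mode = c("spheroid", "monolayer"),
                             engine = c("CBM", "DCM"), n_target = 30,
                             tau = 24 * 3600, R0 = 12e-6, W = 1e-5,
                             W_sub = 1e-5, D = 1e-16, dt = tau / 200,
                             level = 2, stride = 10, seed = 1L,
                             max_steps = 20000L) {
  mode <- match.arg(mode); engine <- match.arg(engine)
  sc <- new_scene(dt = dt, seed = seed, medium = "area",
                  gamma_medium_area = 1e8,
                  migration = list(D = D, F_mor = 0, leader_only = TRUE,
                                   dir_fun = NULL))
  if (mode == "monolayer") {
    sc <- scene_add(sc, list(type = "plane", point = c(0, 0, 0),
                             normal = c(0, 0, 1), W = W_sub))
  }
  z0 <- if (mode == "monolayer") R0 * 0.98 else 0
  if (engine == "CBM") {
    cell <- cbm_cell(c(0, 0, z0), R = R0, W = W, tau = tau)
    cell$growing <- TRUE
    sc <- scene_add(sc, cell)
  } else {
    cell <- dcm_cell(build_icosphere(R0, level, center = c(0, 0, z0)),
                     contact = contact_params(W = W), tau = tau)
    cell$growing <- TRUE
    sc <- scene_add(sc, cell)
  }
  centers <- function(s) {
    if (engine == "CBM") do.call(rbind, lapply(s$cbm, `[[`, "center"))
    else do.call(rbind, lapply(s$dcm, function(cl) colMeans(cl$mesh$V)))
  }
  series <- list()
  nsteps <- 0L
  repeat {
    sc <- scene_step(sc)
    nsteps <- nsteps + 1L
    if (engine == "CBM") {
      sc <- cbm_grow_divide(sc, policy = list(keep_growing = TRUE))
    } else {
      for (q in seq_along(sc$dcm)) {
        if (!isTRUE(sc$dcm[[q]]$growing)) next
        sc$dcm[[q]] <- grow_step(sc$dcm[[q]], dt = sc$dt)
      }
      for (q in seq_along(sc$dcm)) {
        if (enclosed_volume(sc$dcm[[q]]$mesh) >= 0 &&
            sc$dcm[[q]]$mesh$V0 >= sc$dcm[[q]]$V_crit) {
          sc <- divide_dcm(sc, q, max_sub_steps = 150L)
          sc$dcm[[q]]$growing <- TRUE
          sc$dcm[[length(sc$dcm)]]$growing <- TRUE
        }
      }
    }
    N <- if (engine == "CBM") length(sc$cbm) else length(sc$dcm)
    if (nsteps %% stride == 0 || N >= n_target) {
      ctr <- centers(sc)
      com <- colMeans(ctr)
      rg <- sqrt(mean(rowSums(sweep(ctr, 2, com)^2)))
      series[[length(series) + 1]] <- c(time = sc$time, N = N, R_gyr = rg)
    }
    if (N >= n_target || nsteps >= max_steps) break
  }
  series <- as.data.frame(do.call(rbind, series))
  # density profile (monolayer) and pressure proxies
  ctr <- centers(sc)
  density <- NULL
  if (mode == "monolayer") {
    com <- colMeans(ctr)
    r <- sqrt((ctr[, 1] - com[1])^2 + (ctr[, 2] - com[2])^2)
    br <- seq(0, max(r) + 2 * R0, by = 2 * R0)
    cnt <- tabulate(findInterval(r, br), nbins = length(br) - 1)
    area <- pi * diff(br^2)
    density <- data.frame(r = br[-1] - R0, rho = cnt / area)
  }
  pressure <- if (engine == "DCM") {
    vapply(sc$dcm, function(cl)
      -cl$params$K_V * log(enclosed_volume(cl$mesh) / cl$mesh$V0), 1)
  } else {
    cbm_pressure_proxy(sc)
  }
  list(series = series, density = density, pressure = pressure, scene = sc)
}

# repulsive contact load per surface area for each CBM cell
cbm_pressure_proxy <- function(scene) {
  nc <- length(scene$cbm)
  ctrs <- do.call(rbind, lapply(scene$cbm, `[[`, "center"))
  Rs <- vapply(scene$cbm, `[[`, 1, "R")
  Es <- vapply(scene$cbm, `[[`, 1, "E")
  nus <- vapply(scene$cbm, `[[`, 1, "nu")
  out <- numeric(nc)
  if (nc < 2) return(out)
  D2 <- as.matrix(stats::dist(ctrs))
  for (q in seq_len(nc)) {
    js <- which(D2[q, ] < Rs[q] + Rs + 1e-9 & seq_len(nc) != q)
    if (!length(js)) next
    del <- Rs[q] + Rs[js] - D2[q, js]
    Ehat <- 1 / ((1 - nus[q]^2) / Es[q] + (1 - nus[js]^2) / Es[js])
    Rhat <- Rs[q] * Rs[js] / (Rs[q] + Rs[js])
    f <- jkr_force_vec(del, Ehat, Rhat, 0, FALSE)$F
    out[q] <- sum(pmax(f, 0)) / (4 * pi * Rs[q]^2)
  }
  out
}
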