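# Liver-lobule regeneration: wedge geometry, synthetic sinusoid network,
# lesion metric and the three regeneration model variants.

#' Lobule network geometry
#'
#' The statistically representative hexagonal lobule: radius 280 um, portal
#' vein radius 15 um, central vein radius 10 um, sinusoid radius 4.7 um,
#' lesion radius 150 um, slab of three 24-um cell layers, sinusoid modulus
#' 600 Pa with zero cell-sinusoid adhesion.
#'
#' @param ... overrides of the listed fields.
#' @return list of geometry parameters (m, Pa).
#' @export
lobule_geometry <- function(...) {
  modifyList(default_parameters()$lobule, list(...))
}

# uncovered fraction of the pericentral disk of radius R_nec in the XY
# mid-plane, rasterized at `res`; `sector_half_angle` restricts the mask to
# the simulated wedge (the disk sector around the +x axis)
lesion_area_fraction <- function(centers, radii, R_nec, res = 1e-6,
                                 sector_half_angle = NULL) {
  g <- seq(-R_nec, R_nec, by = res)
  nx <- length(g)
  X <- matrix(g, nx, nx)
  Y <- matrix(g, nx, nx, byrow = TRUE)
  inside <- X^2 + Y^2 <= R_nec^2
  if (!is.null(sector_half_angle))
    inside <- inside & abs(atan2(Y, X)) <= sector_half_angle
  covered <- matrix(FALSE, nx, nx)
  if (length(radii) > 0) {
    for (q in seq_along(radii)) {
      zc <- centers[q, 3]
      if (abs(zc) >= radii[q]) next
      rq <- sqrt(radii[q]^2 - zc^2)
      covered <- covered | ((X - centers[q, 1])^2 + (Y - centers[q, 2])^2 <= rq^2)
    }
  }
  sum(inside & !covered) / sum(inside)
}

#' Relative pericentral lesion area of a scene
#'
#' Rasterizes the XY mid-plane disk of radius `R_nec` at `res` resolution;
#' the uncovered fraction (area not overlain by any cell cross-section),
#' normalized by `norm` (the value at t = 0 in a regeneration run).
#'
#' @param scene a `scene` with CBM and/or DCM cells.
#' @param R_nec lesion radius (m).
#' @param res raster resolution (m).
#' @param norm normalization constant.
#' @return relative lesion area (1 at regeneration start by construction).
#' @export
lesion_area <- function(scene, R_nec = 150e-6, res = 1e-6, norm = 1,
                        sector_half_angle = pi / 6) {
  ctr <- NULL; rad <- numeric(0)
  if (length(scene$cbm) > 0) {
    ctr <- rbind(ctr, do.call(rbind, lapply(scene$cbm, `[[`, "center")))
    rad <- c(rad, vapply(scene$cbm, `[[`, 1, "R"))
  }
  if (length(scene$dcm) > 0) {
    ctr <- rbind(ctr, do.call(rbind, lapply(scene$dcm, function(cl) colMeans(cl$mesh$V))))
    rad <- c(rad, vapply(scene$dcm, function(cl)
      (3 * enclosed_volume(cl$mesh) / (4 * pi))^(1 / 3), 1))
  }
  if (is.null(ctr)) return(1 / norm)
  lesion_area_fraction(ctr, rad, R_nec, res, sector_half_angle) / norm
}

# jittered radial polyline chains of overlapping spheres from the lobule
# periphery to the central vein
make_sinusoid_chains <- function(geom, n_chains, rng, spacing_factor = 0.5) {
  spheres <- NULL
  segments <- NULL
  half <- pi / 6
  for (k in seq_len(n_chains)) {
    u <- rng_draw(rng, "sinusoids", function() runif(7))
    z <- rng_draw(rng, "sinusoids", function() rnorm(3))
    phi0 <- (u[1] * 2 - 1) * (half * 0.93)
    r0 <- geom$R_lob * (0.92 + 0.08 * u[2])
    z0 <- (u[3] - 0.5) * 0.8 * geom$slab
    phi1 <- phi0 + (u[4] - 0.5) * 0.35
    r1 <- geom$R_cv + geom$R_sin
    z1 <- z0 * (0.3 + 0.5 * u[5])
    p0 <- c(r0 * cos(phi0), r0 * sin(phi0), z0)
    p1 <- c(r1 * cos(phi1), r1 * sin(phi1), z1)
    # mild lateral jitter at the midpoint
    mid <- (p0 + p1) / 2 + z * 4e-6
    len <- sqrt(sum((mid - p0)^2)) + sqrt(sum((p1 - mid)^2))
    npt <- max(3, ceiling(len / (spacing_factor * geom$R_sin)))
    t1n <- floor(npt / 2); t2n <- npt - t1n
    pts <- rbind(
      t(sapply(seq(0, 1, length.out = t1n), function(s) p0 + s * (mid - p0))),
      t(sapply(seq(0, 1, length.out = t2n + 1)[-1], function(s) mid + s * (p1 - mid)))
    )
    spheres <- rbind(spheres, pts)
    idx <- seq(1, nrow(pts) - 4, by = 4)
    segments <- rbind(segments, cbind(pts[idx, , drop = FALSE],
                                      pts[idx + 4, , drop = FALSE]))
  }
  list(spheres = spheres, segments = segments)
}

wedge_planes <- function(geom) {
  half <- pi / 6
  list(
    list(type = "plane", point = c(0, 0, 0),
         normal = c(sin(half), -cos(half), 0), W = 0),
    list(type = "plane", point = c(0, 0, 0),
         normal = c(sin(half), cos(half), 0), W = 0),
    list(type = "plane", point = c(geom$R_lob, 0, 0), normal = c(-1, 0, 0), W = 0),
    list(type = "plane", point = c(0, 0, -geom$slab / 2), normal = c(0, 0, 1), W = 0),
    list(type = "plane", point = c(0, 0, geom$slab / 2), normal = c(0, 0, -1), W = 0)
  )
}

#' Build a one-sixth liver-lobule wedge scene
#'
#' A 60-degree pie of the hexagonal lobule: bounding planes that push cells
#' back (mimicking the neighboring lobule parts), a static central-vein
#' sphere column on the axis, portal-vein columns at the outer corners, a
#' synthetic network of jittered radial sinusoid chains built from dense
#' overlapping static spheres (radius 4.7 um, zero adhesion), and cells
#' seeded in the inter-sinusoid voids, inflated quasi-statically to their
#' physiological radius, relaxed, and finally ablated within the pericentral
#' lesion radius.
#'
#' @param geom a [lobule_geometry()].
#' @param engine `"CBM"` (default) or `"DCM"` (small property-check wedges).
#' @param n_cells number of cells to seed before ablation.
#' @param n_chains number of sinusoid chains.
#' @param dt time step (s).
#' @param seed RNG seed.
#' @param W cell-cell adhesion energy (J/m^2).
#' @param tau cell-cycle time (s).
#' @param level DCM icosphere subdivision (DCM engine).
#' @param inflate_steps relaxation steps per inflation increment.
#' @param spacing_factor sinusoid sphere spacing in units of `R_sin`.
#' @return a `scene` with `scene$lobule` holding the geometry, the sinusoid
#'   segment table (for division alignment), and the lesion normalization.
#' @export
build_lobule <- function(geom = lobule_geometry(), engine = c("CBM", "DCM"),
                         n_cells = 90, n_chains = 20, dt = 60, seed = 1L,
                         W = 1e-5, tau = 24 * 3600, level = 1,
                         inflate_steps = 25, spacing_factor = 0.5) {
  engine <- match.arg(engine)
  sc <- new_scene(dt = dt, seed = seed, medium = "area",
                  gamma_medium_area = 1e8, gamma_cbm_sub = 5e8)
  for (pl in wedge_planes(geom)) sc <- scene_add(sc, pl)
  half <- pi / 6
  # central vein column
  for (z in seq(-geom$slab / 2, geom$slab / 2, by = geom$R_cv / 2))
    sc <- scene_add(sc, list(type = "sphere", center = c(0, 0, z),
                             R = geom$R_cv, E = geom$E_sin, nu = geom$nu_sin,
                             W = geom$W_sin))
  # portal vein columns at the two outer wedge corners
  for (sgn in c(-1, 1)) for (z in seq(-geom$slab / 2, geom$slab / 2,
                                      by = geom$R_pv / 2))
    sc <- scene_add(sc, list(type = "sphere",
                             center = c(geom$R_lob * cos(half),
                                        sgn * geom$R_lob * sin(half), z),
                             R = geom$R_pv, E = geom$E_sin, nu = geom$nu_sin,
                             W = geom$W_sin))
  sin_net <- make_sinusoid_chains(geom, n_chains, sc$rng, spacing_factor)
  for (q in seq_len(nrow(sin_net$spheres)))
    sc <- scene_add(sc, list(type = "sphere", center = sin_net$spheres[q, ],
                             R = geom$R_sin, E = geom$E_sin, nu = geom$nu_sin,
                             W = geom$W_sin))
  # seed cells in the voids at half radius
  r_seed <- geom$R_c / 2
  obc <- sin_net$spheres
  placed <- NULL
  tries <- 0L
  while ((is.null(placed) || nrow(placed) < n_cells) && tries < 30000L) {
    tries <- tries + 1L
    u <- rng_draw(sc$rng, "seeding", function() runif(3))
    rr <- sqrt(u[1]) * (geom$R_lob - geom$R_c) + geom$R_cv + geom$R_sin + r_seed
    if (rr > geom$R_lob - r_seed) next
    phi <- (u[2] * 2 - 1) * (half - asin(min(1, r_seed / rr)))
    z <- (u[3] - 0.5) * (geom$slab - 2 * r_seed)
    p <- c(rr * cos(phi), rr * sin(phi), z)
    if (!is.null(placed) &&
        min(rowSums(sweep(placed, 2, p)^2)) < (1.9 * r_seed)^2) next
    dsin <- min(rowSums(sweep(obc, 2, p)^2))
    if (dsin < (0.85 * r_seed + geom$R_sin)^2) next
    placed <- rbind(placed, p)
  }
  if (is.null(placed) || nrow(placed) < n_cells)
    warning(sprintf("seeded %d of %d requested cells", NROW(placed), n_cells))
  if (engine == "CBM") {
    for (q in seq_len(nrow(placed)))
      sc <- scene_add(sc, cbm_cell(placed[q, ], R = r_seed, W = W, tau = tau))
    # quasi-static inflation to the physiological radius
    fr <- seq(r_seed / geom$R_c, 1, length.out = 8)[-1]
    for (f in fr) {
      for (q in seq_along(sc$cbm)) {
        sc$cbm[[q]]$R <- f * geom$R_c
        sc$cbm[[q]]$V0 <- 4 / 3 * pi * sc$cbm[[q]]$R^3
        sc$cbm[[q]]$alpha <- sc$cbm[[q]]$V0 / tau
        sc$cbm[[q]]$V_crit <- 2 * sc$cbm[[q]]$V0
      }
      sc <- simulate_scene(sc, inflate_steps)
    }
    sc <- simulate_scene(sc, 4 * inflate_steps)
    keep <- vapply(sc$cbm, function(cl)
      sqrt(sum(cl$center[1:2]^2)) >= geom$R_nec, TRUE)
    sc$cbm <- sc$cbm[keep]
  } else {
    n_dcm <- min(nrow(placed), n_cells)
    for (q in seq_len(n_dcm))
      sc <- scene_add(sc, dcm_cell(build_icosphere(r_seed, level,
                                                   center = placed[q, ]),
                                   contact = contact_params(W = W), tau = tau))
    sc <- simulate_scene(sc, inflate_steps)
    keep <- vapply(sc$dcm, function(cl)
      sqrt(sum(colMeans(cl$mesh$V)[1:2]^2)) >= geom$R_nec, TRUE)
    sc$dcm <- sc$dcm[keep]
  }
  sc$obcache <- NULL
  area0 <- lesion_area(sc, geom$R_nec, res = 2e-6)
  sc$lobule <- list(geom = geom, segments = sin_net$segments,
                    area0 = area0, engine = engine)
  sc
}

# leader detection: cells at the lesion front with an unobstructed corridor
# toward the central-vein axis; `rfront` is the effective lesion radius
update_leaders <- function(scene, rfront) {
  geom <- scene$lobule$geom
  nc <- length(scene$cbm)
  if (nc == 0) return(scene)
  ctrs <- do.call(rbind, lapply(scene$cbm, `[[`, "center"))
  r <- sqrt(ctrs[, 1]^2 + ctrs[, 2]^2)
  cand <- which(r < rfront + 2 * geom$R_c)
  lead <- rep(FALSE, nc)
  for (q in cand) {
    blocked <- FALSE
    for (p in seq_len(nc)) {
      if (p == q || r[p] >= r[q]) next
      # distance from cell p to the segment (cell q -> axis at same z)
      a <- ctrs[q, ]; b <- c(0, 0, ctrs[q, 3])
      ab <- b - a
      t <- sum((ctrs[p, ] - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      dd <- sqrt(sum((a + t * ab - ctrs[p, ])^2))
      if (dd < geom$R_c / 2) { blocked <- TRUE; break }
    }
    lead[q] <- !blocked
  }
  for (q in seq_len(nc)) scene$cbm[[q]]$leader <- lead[q]
  scene
}

#' Run a lobule regeneration simulation
#'
#' Three model variants: Model I (random division axes, unbiased random
#' micro-motility), Model II (division axes aligned with the nearest
#' sinusoid segment, HSA), Model III (Model I plus a directed migration
#' force on leader cells toward the central vein). Proliferation is
#' restricted to a band of cell layers closest to the lesion and to a time
#' window. Outputs the relative pericentral lesion area (normalized to 1 at
#' t = 0) and the cell count over time.
#'
#' @param scene a [build_lobule()] scene (CBM engine).
#' @param model `"I"`, `"II"` or `"III"`.
#' @param days simulated duration (days).
#' @param F_mor directed migration force (N), Model III.
#' @param D diffusion constant (m^2/s).
#' @param band proliferation band in cell layers from the lesion front.
#' @param window_days proliferation time window (days, length 2).
#' @param corrected apply the packing-dependent stiffness correction with
#'   this `a1` (Pa); `NULL` for the uncorrected JKR forces.
#' @param stride_h metric recording interval (hours).
#' @return data.frame with `time_d`, `N`, `lesion_rel`, `r_front_um`.
#' @export
run_regeneration <- function(scene, model = c("I", "II", "III"), days = 4,
                             F_mor = 1e-9, D = 1e-16, band = 4,
                             window_days = c(0, days), corrected = NULL,
                             stride_h = 2) {
  model <- match.arg(model)
  geom <- scene$lobule$geom
  scene$migration$D <- D
  if (model == "III") {
    scene$migration$F_mor <- F_mor
    scene$migration$leader_only <- TRUE
    scene$migration$dir_fun <- function(ctr) {
      v <- -c(ctr[1], ctr[2], 0)
      n <- sqrt(sum(v * v))
      if (n == 0) c(0, 0, 0) else v / n
    }
  }
  if (!is.null(corrected)) {
    scene$correction <- list(enabled = TRUE, a1 = corrected)
  }
  policy <- if (model == "II")
    list(axis = "hsa", segments = scene$lobule$segments) else list()
  n_steps <- ceiling(days * 86400 / scene$dt)
  stride <- max(1L, round(stride_h * 3600 / scene$dt))
  out <- list()
  for (s in seq_len(n_steps)) {
    if (s %% stride == 1L || stride == 1L) {
      la <- lesion_area(scene, geom$R_nec, res = 2e-6, norm = scene$lobule$area0)
      # effective lesion radius from the uncovered sector area; robust
      # against single cells running ahead of the regeneration front
      rfront <- geom$R_nec * sqrt(min(la * scene$lobule$area0, 1))
      ctrs <- do.call(rbind, lapply(scene$cbm, `[[`, "center"))
      r <- sqrt(ctrs[, 1]^2 + ctrs[, 2]^2)
      tday <- scene$time / 86400
      in_window <- tday >= window_days[1] && tday <= window_days[2]
      for (q in seq_along(scene$cbm)) {
        if (in_window && r[q] < rfront + band * 2 * geom$R_c)
          scene$cbm[[q]]$growing <- TRUE
        else if (!in_window) scene$cbm[[q]]$growing <- FALSE
      }
      scene <- update_leaders(scene, rfront)
      out[[length(out) + 1]] <- c(time_d = tday, N = length(scene$cbm),
                                  lesion_rel = la, r_front_um = rfront * 1e6)
      if (la < 0.02) break
    }
    scene <- scene_step(scene)
    scene <- cbm_grow_divide(scene, policy)
  }
  df <- as.data.frame(do.call(rbind, out))
  attr(df, "model") <- model
  attr(df, "corrected") <- !is.null(corrected)
  df
}
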