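# Scene container and overdamped dynamics: friction assembly and the
# per-step linear solve Gamma v = F over all DCM nodes and CBM centers.

#' Per-node Stokes friction coefficient
#'
#' Splitting the Stokes drag of a sphere of radius R over its N surface
#' nodes: `gamma_ns = 6 pi mu R / N`, so the summed coefficient equals the
#' Stokes prediction exactly.
#'
#' @param mu medium viscosity (Pa s).
#' @param R cell radius (m).
#' @param N number of surface nodes (>= 1).
#' @return friction coefficient per node (Ns/m).
#' @export
stokes_node_friction <- function(mu, R, N) {
  stopifnot(N >= 1)
  6 * pi * mu * R / N
}

# ---- named RNG substreams ----------------------------------------------------
# One integer master seed; each named stream draws from its own deterministic
# sequence so enabling one stochastic feature does not shift another's draws.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$counter <- list()
  env
}

rng_draw <- function(rng, name, fun) {
  cnt <- rng$counter[[name]]
  if (is.null(cnt)) cnt <- 0L
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  sub <- (as.double(rng$seed) * 48271 + h * 16807 + cnt * 69621) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(sub))
  out <- fun()
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  rng$counter[[name]] <- cnt + 1L
  out
}

#' Create a simulation scene
#'
#' Holds all cells (deformable and center-based), rigid obstacles, boundary
#' planes, the time step and the seeded random-number state.
#'
#' @param dt time step (s), > 0.
#' @param seed integer RNG seed (mandatory for stochastic runs).
#' @param mu medium viscosity (Pa s).
#' @param medium node-medium friction model for DCM nodes: `"stokes"`
#'   (6 pi mu R / N per node, suspension experiments) or `"area"`
#'   (`gamma_medium_area` times the node Voronoi area, tissue/ECM).
#' @param gamma_medium_area medium friction per area (Ns/m^3), used by the
#'   `"area"` medium (cell-ECM default 1e8).
#' @param gamma_cc_area cell-cell contact friction per area (Ns/m^3).
#' @param gamma_cbm_sub substrate/ECM friction coefficient for CBM cells per
#'   area (Ns/m^3); multiplied by `pi R^2`.
#' @param solver `"direct"` (sparse solve of the coupled friction system) or
#'   `"lumped"` (diagonal-only fast mode).
#' @param migration list: `D` (diffusion constant, m^2/s), `F_mor` (directed
#'   force, N), `leader_only`, `dir_fun(center)` returning the unit target
#'   direction.
#' @param max_disp_frac displacement limiter per step, as a fraction of the
#'   smallest edge rest length (numerical safety under strong transients).
#' @return object of class `scene`.
#' @export
new_scene <- function(dt, seed = 1L, mu = 1e-3,
                      medium = c("area", "stokes"),
                      gamma_medium_area = 1e8, gamma_cc_area = 5e10,
                      gamma_cbm_sub = 5e8,
                      solver = c("direct", "lumped"),
                      migration = list(D = 0, F_mor = 0, leader_only = TRUE,
                                       dir_fun = NULL),
                      max_disp_frac = 0.25) {
  stopifnot(dt > 0)
  structure(list(
    dcm = list(), cbm = list(), obstacles = list(),
    dt = dt, time = 0, mu = mu, medium = match.arg(medium),
    gamma_medium_area = gamma_medium_area, gamma_cc_area = gamma_cc_area,
    gamma_cbm_sub = gamma_cbm_sub,
    solver = match.arg(solver), thermal_scale = 1,
    migration = modifyList(list(D = 0, F_mor = 0, leader_only = TRUE,
                                dir_fun = NULL), migration),
    correction = list(enabled = FALSE, a1 = 4e6),
    engaged = new.env(parent = emptyenv()),
    f_ext = NULL, rng = make_rng(seed), seed = as.integer(seed),
    max_disp_frac = max_disp_frac, next_id = 1L
  ), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d DCM cells, %d CBM cells, %d obstacles, t=%.3g s (dt=%.3g)\n",
              length(x$dcm), length(x$cbm), length(x$obstacles), x$time, x$dt))
  invisible(x)
}

#' Add a cell or obstacle to a scene
#'
#' @param scene a `scene`.
#' @param x a `dcm_cell`, `cbm_cell`, or obstacle body list
#'   (`type = "sphere"` with `center`, `R` or `type = "plane"` with `point`,
#'   `normal`; optional `W`, `E`, `nu`, `gamma_area`).
#' @return the updated scene.
#' @export
scene_add <- function(scene, x) {
  if (inherits(x, "dcm_cell")) {
    x$id <- scene$next_id
    scene$dcm[[length(scene$dcm) + 1L]] <- x
    scene$next_id <- scene$next_id + 1L
  } else if (inherits(x, "cbm_cell")) {
    x$id <- scene$next_id
    scene$cbm[[length(scene$cbm) + 1L]] <- x
    scene$next_id <- scene$next_id + 1L
  } else if (is.list(x) && !is.null(x$type)) {
    if (identical(x$type, "mesh")) {
      if (is.null(x$mesh)) stop("mesh obstacle needs a trimesh in $mesh")
      x$tri_radius <- curvature_radii(x$mesh)$tri_radius
      x$bs <- dcm_bounding_sphere(x$mesh$V)
    }
    scene$obstacles[[length(scene$obstacles) + 1L]] <- x
  } else stop("cannot add object of class ", paste(class(x), collapse = "/"))
  scene
}

# ---- migration forces --------------------------------------------------------

#' Random migration force for one cell
#'
#' A single cell-level force sampled per step and distributed homogeneously
#' over the nodes. The amplitude is calibrated against the overdamped limit
#' so that a free cell with total ground friction `gamma_cell` has
#' `MSD(tau) = 6 D tau`: each component is Normal with standard deviation
#' `gamma_cell sqrt(2 D / dt)`.
#'
#' @param n_nodes number of surface nodes (1 for a CBM cell).
#' @param D diffusion constant (m^2/s).
#' @param dt time step (s).
#' @param gamma_cell total cell-medium friction (Ns/m).
#' @param rnorm3 optional pre-drawn standard normal triple (for seeded
#'   substreams).
#' @return n_nodes x 3 matrix of nodal forces (N).
#' @export
random_migration_force <- function(n_nodes, D, dt, gamma_cell,
                                   rnorm3 = rnorm(3)) {
  stopifnot(D >= 0)
  if (D == 0) return(matrix(0, n_nodes, 3))
  Fcell <- gamma_cell * sqrt(2 * D / dt) * rnorm3
  matrix(rep(Fcell / n_nodes, each = n_nodes), n_nodes, 3)
}

#' Directed (morphogen-gradient) migration force
#'
#' Total magnitude `F_mor` along a unit direction, split homogeneously over
#' the nodes; applied only to leader cells in leader-only mode.
#'
#' @param n_nodes number of surface nodes.
#' @param F_mor force magnitude (N), >= 0.
#' @param direction target direction (length 3, nonzero).
#' @return n_nodes x 3 matrix summing exactly to `F_mor * direction`.
#' @export
directed_migration_force <- function(n_nodes, F_mor, direction) {
  stopifnot(F_mor >= 0)
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("zero-length direction")
  u <- direction / n
  matrix(rep(F_mor * u / n_nodes, each = n_nodes), n_nodes, 3)
}

# ---- helpers -----------------------------------------------------------------

dcm_bounding_sphere <- function(V) {
  ctr <- colMeans(V)
  list(center = ctr, r = max(row_norm(sweep(V, 2, ctr))))
}

cell_radius_from_volume <- function(V0) (3 * V0 / (4 * pi))^(1 / 3)

pair_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))

# ---- the integrator ----------------------------------------------------------

#' Advance a scene by one time step
#'
#' Computes all internal DCM forces (in-plane elements, bending, volume,
#' membrane area), all contact forces (DCM-DCM, DCM-obstacle, DCM-CBM,
#' CBM-CBM, CBM-obstacle), migration and external forces, assembles the
#' friction matrix (node-medium on the diagonal; node-node, cell-cell and
#' contact couplings off-diagonal) and solves the overdamped system
#' `Gamma v = F` for all velocities simultaneously. Positions are advanced
#' by `v dt`; there is no inertia.
#'
#' @param scene a `scene`.
#' @return the updated scene. Diagnostics of the step (pressures, contact
#'   patch tables, max displacement) are stored in `scene$last`.
#' @export
scene_step <- function(scene) {
  dt <- scene$dt
  nd <- length(scene$dcm)
  nc <- length(scene$cbm)
  sizes <- vapply(scene$dcm, function(cl) nrow(cl$mesh$V), 1L)
  offs <- c(0L, cumsum(sizes))
  ndof <- sum(sizes) + nc
  coff <- sum(sizes)            # CBM DOFs come after all DCM nodes
  if (ndof == 0) stop("empty scene")

  Fm <- matrix(0, ndof, 3)
  diag_g <- numeric(ndof)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)  # off-diagonal couplings
  add_coupling <- function(a, b, g) {
    # indices may repeat: accumulate via rowsum, not plain [<-
    acc <- rowsum(c(g, g), c(a, b))
    idx <- as.integer(rownames(acc))
    diag_g[idx] <<- diag_g[idx] + acc[, 1]
    if (scene$solver != "lumped") {
      ti <<- c(ti, a, b); tj <<- c(tj, b, a); tx <<- c(tx, -g, -g)
    }
  }

  curv <- vector("list", nd)
  Svor <- vector("list", nd)
  press <- numeric(nd)
  patch_tables <- list()
  pair_totals <- list()
  Uvol <- vector("list", nd)   # volume-mode vectors for the implicit update
  cvol <- numeric(nd)

  # internal DCM forces and ground friction
  for (ci in seq_len(nd)) {
    cell <- scene$dcm[[ci]]
    V <- cell$mesh$V
    n <- sizes[ci]
    idx <- offs[ci] + seq_len(n)
    cell$.dt <- dt
    gME <- cell$params$gamma_ME * scene$thermal_scale
    cell$params$gamma_ME <- gME
    rr <- cell_radius_from_volume(cell$mesh$V0)
    fr <- cpp_dcm_forces(V, cell$mesh$Tri, cell$mesh$edges, cell$mesh$l0,
                         cell$mesh$hinges, cell$mesh$theta0, cell$mesh$A0,
                         cell$mesh$V0, cell$params$k_s, cell$params$k_b,
                         cell$params$k_mem, cell$params$K_V,
                         if (cell$params$element_model == "MME") 1L else 0L,
                         cell$mme_F, dt, gME, 0.1 * rr, 10 * rr)
    Svor[[ci]] <- fr$S
    curv[[ci]] <- list(radius = fr$node_radius, normal = fr$normal,
                       tri_radius = fr$tri_radius, S = fr$S)
    press[ci] <- fr$p
    Fm[idx, ] <- Fm[idx, ] + fr$F
    # semi-implicit volume pressure: the weakly damped breathing mode is
    # rank-one per cell (dV = sum_i S_i n_i . v_i dt), handled by a Woodbury
    # correction in the solve so it never limits the stable time step
    Uvol[[ci]] <- fr$S * fr$normal
    cvol[ci] <- cell$params$K_V * dt / fr$vol
    if (!is.null(cell$f_node)) Fm[idx, ] <- Fm[idx, ] + cell$f_node
    # ground friction
    if (scene$medium == "stokes") {
      Rc <- cell_radius_from_volume(cell$mesh$V0)
      diag_g[idx] <- diag_g[idx] + stokes_node_friction(scene$mu, Rc, n)
    } else {
      gmed <- if (!is.null(cell$gamma_medium_area)) cell$gamma_medium_area else scene$gamma_medium_area
      diag_g[idx] <- diag_g[idx] + gmed * Svor[[ci]]
    }
    # intra-cell node-node friction along edges (+ implicit MME damping)
    g_int <- cell$params$gamma_int * scene$thermal_scale
    if (!is.null(cell$friction_scale)) g_int <- g_int * cell$friction_scale
    ge <- rep(g_int, nrow(cell$mesh$edges))
    if (cell$params$element_model == "MME") {
      kap <- cell$params$k_s * dt / gME
      ge <- ge + cell$params$k_s * dt / (1 + kap)
    }
    e <- cell$mesh$edges
    add_coupling(offs[ci] + e[, 1], offs[ci] + e[, 2], ge)
    # migration
    mig <- scene$migration
    if (mig$D > 0 && !isTRUE(cell$frozen)) {
      gcell <- sum(diag_g[idx])
      z <- rng_draw(scene$rng, paste0("mig_dcm_", cell$id), function() rnorm(3))
      Fm[idx, ] <- Fm[idx, ] + random_migration_force(n, mig$D, dt, gcell, z)
    }
    if (mig$F_mor > 0 && !is.null(mig$dir_fun) &&
        (cell$leader || !mig$leader_only)) {
      ctr <- colMeans(V)
      Fm[idx, ] <- Fm[idx, ] + directed_migration_force(n, mig$F_mor, mig$dir_fun(ctr))
    }
    scene$dcm[[ci]] <- cell
  }

  # DCM-DCM contacts
  if (nd >= 2) {
    bs <- lapply(scene$dcm, function(cl) dcm_bounding_sphere(cl$mesh$V))
    for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
      margin <- scene$dcm[[a]]$contact$h0 + 1e-6
      if (sqrt(sum((bs[[a]]$center - bs[[b]]$center)^2)) >
          bs[[a]]$r + bs[[b]]$r + margin) next
      ca <- scene$dcm[[a]]; cb <- scene$dcm[[b]]
      W <- (ca$contact$W + cb$contact$W) / 2
      # broad-phase cache: candidate triangle pairs stay valid until the
      # accumulated motion approaches the broad-phase slack
      key <- paste0(a, "_", b, "_", sizes[a], "_", sizes[b])
      pc <- scene$ppcache[[key]]
      drift <- if (is.null(scene$last)) 0 else scene$last$max_disp
      if (!is.null(pc)) pc$accum <- pc$accum + drift
      if (is.null(pc) || pc$accum > 0.06e-6) {
        slack <- ca$contact$h0 + 0.1 * mean(ca$mesh$l0) + 0.08e-6
        pc <- list(prs = candidate_tri_pairs(ca$mesh$V, ca$mesh$Tri,
                                             cb$mesh$V, cb$mesh$Tri, slack),
                   accum = 0)
      }
      scene$ppcache[[key]] <- pc
      if (nrow(pc$prs) == 0) next
      res <- dcm_pair_contact_cached(ca, cb, curv[[a]], curv[[b]], W, pc$prs)
      if (is.null(res$patches) || nrow(res$patches) == 0) next
      ia <- offs[a] + seq_len(sizes[a]); ib <- offs[b] + seq_len(sizes[b])
      Fm[ia, ] <- Fm[ia, ] + res$F1
      Fm[ib, ] <- Fm[ib, ] + res$F2
      patch_tables[[length(patch_tables) + 1L]] <-
        cbind(cell_a = ca$id, cell_b = cb$id, res$patches)
      pair_totals[[length(pair_totals) + 1L]] <- res$total1
      # contact friction: couple the triangle node triples of each patch
      pt <- res$patches
      ga <- scene$gamma_cc_area * pt[, "area"] / 9
      n1 <- matrix(ca$mesh$Tri[pt[, "t1"], ], ncol = 3)
      n2 <- matrix(cb$mesh$Tri[pt[, "t2"], ], ncol = 3)
      for (k1 in 1:3) for (k2 in 1:3)
        add_coupling(offs[a] + n1[, k1], offs[b] + n2[, k2], ga)
    }
  }

  # DCM-obstacle and DCM-CBM contacts
  for (ci in seq_len(nd)) {
    cell <- scene$dcm[[ci]]
    idx <- offs[ci] + seq_len(sizes[ci])
    bsc <- dcm_bounding_sphere(cell$mesh$V)
    for (ob in scene$obstacles) {
      near <- if (ob$type == "sphere") {
        sqrt(sum((bsc$center - ob$center)^2)) < bsc$r + ob$R + 2e-6
      } else if (ob$type == "plane") {
        abs(sum((bsc$center - ob$point) * ob$normal)) < bsc$r + 2e-6
      } else {
        sqrt(sum((bsc$center - ob$bs$center)^2)) < bsc$r + ob$bs$r + 2e-6
      }
      if (!near) next
      if (identical(ob$type, "mesh")) {
        # static triangulated body: pair narrow phase, body forces discarded
        Wob <- if (is.null(ob$W)) 0 else ob$W
        red <- reduced_pair(cell$contact$E, cell$contact$nu,
                            if (is.null(ob$E)) Inf else ob$E,
                            if (is.null(ob$nu)) 0 else ob$nu)
        prs <- candidate_tri_pairs(cell$mesh$V, cell$mesh$Tri,
                                   ob$mesh$V, ob$mesh$Tri,
                                   cell$contact$h0 + 0.1 * mean(cell$mesh$l0))
        if (nrow(prs) == 0) next
        res0 <- cpp_pair_contact(cell$mesh$V, cell$mesh$Tri,
                                 curv[[ci]]$tri_radius,
                                 ob$mesh$V, ob$mesh$Tri, ob$tri_radius, prs,
                                 Wob / cell$contact$h0, cell$contact$h0, Wob,
                                 red$Ehat, cell$contact$pen_stiff)
        res <- list(F = res0$F1, area = res0$area1)
      } else {
        res <- cell_body_contact(cell, ob, curv = curv[[ci]])
      }
      Fm[idx, ] <- Fm[idx, ] + res$F
      gob <- if (!is.null(ob$gamma_area)) ob$gamma_area else scene$gamma_medium_area
      diag_g[idx] <- diag_g[idx] + gob * res$area
    }
    if (nc > 0) {
      for (q in seq_len(nc)) {
        cb <- scene$cbm[[q]]
        if (sqrt(sum((bsc$center - cb$center)^2)) > bsc$r + cb$R + 2e-6) next
        body <- list(type = "sphere", center = cb$center, R = cb$R,
                     E = cb$E, nu = cb$nu,
                     W = (cell$contact$W + cb$W) / 2)
        res <- cell_body_contact(cell, body, curv = curv[[ci]])
        Fm[idx, ] <- Fm[idx, ] + res$F
        Fm[coff + q, ] <- Fm[coff + q, ] + res$body_force
        touching <- res$area > 0
        if (any(touching))
          add_coupling(idx[touching], rep(coff + q, sum(touching)),
                       scene$gamma_cc_area * res$area[touching])
      }
    }
  }

  # CBM cells: ground friction, pairwise JKR, obstacles, migration
  if (nc > 0) {
    ctrs <- do.call(rbind, lapply(scene$cbm, `[[`, "center"))
    Rs <- vapply(scene$cbm, `[[`, 1, "R")
    Es <- vapply(scene$cbm, `[[`, 1, "E")
    nus <- vapply(scene$cbm, `[[`, 1, "nu")
    Ws <- vapply(scene$cbm, `[[`, 1, "W")
    ids <- vapply(scene$cbm, `[[`, 1L, "id")
    diag_g[coff + seq_len(nc)] <- diag_g[coff + seq_len(nc)] +
      scene$gamma_cbm_sub * pi * Rs^2
    mig <- scene$migration
    dtil_num <- numeric(nc)
    dtil_den <- integer(nc)
    # cell-cell candidates, cached until cells move or the population changes
    prs <- NULL
    if (nc >= 2) {
      cc <- scene$cbmcache
      margin <- 2.5e-6
      stale <- is.null(cc) || nrow(cc$snapshot) != nc ||
        max(abs(ctrs - cc$snapshot)) > margin / 3
      if (stale) {
        D2 <- as.matrix(stats::dist(ctrs))
        sumR <- outer(Rs, Rs, "+")
        cand <- which(upper.tri(D2) & D2 < sumR + margin, arr.ind = TRUE)
        keys <- if (nrow(cand)) pair_key(ids[cand[, 1]], ids[cand[, 2]])
          else character(0)
        cc <- list(snapshot = ctrs, i = cand[, 1], j = cand[, 2], keys = keys,
                   eng = vapply(mget(keys, envir = scene$engaged,
                                     ifnotfound = list(FALSE)), isTRUE, TRUE))
        scene$cbmcache <- cc
      }
      if (length(cc$i) > 0) {
        dv <- ctrs[cc$j, , drop = FALSE] - ctrs[cc$i, , drop = FALSE]
        dd <- sqrt(rowSums(dv * dv))
        sumRp <- Rs[cc$i] + Rs[cc$j]
        keep <- which(dd < sumRp + 2e-6)
        prs <- list(i = cc$i[keep], j = cc$j[keep], d = dd[keep],
                    sumR = sumRp[keep], keys = cc$keys[keep],
                    cache_idx = keep)
        prs$delta <- prs$sumR - prs$d
        pos <- prs$delta > 0
        if (any(pos)) {
          contrib <- 1 - prs$d[pos] / prs$sumR[pos]
          acc <- rowsum(c(contrib, contrib), c(prs$i[pos], prs$j[pos]))
          dtil_num[as.integer(rownames(acc))] <-
            dtil_num[as.integer(rownames(acc))] + acc
          cnt <- rowsum(rep(1L, 2 * sum(pos)), c(prs$i[pos], prs$j[pos]))
          dtil_den[as.integer(rownames(cnt))] <-
            dtil_den[as.integer(rownames(cnt))] + cnt
        }
      }
    }
    # static obstacle tables (rebuilt only when the obstacle list changes)
    os <- scene$obstatic
    if (is.null(os) || os$n_obstacles != length(scene$obstacles)) {
      ob_spheres <- Filter(function(o) o$type == "sphere", scene$obstacles)
      os <- list(
        n_obstacles = length(scene$obstacles),
        n_spheres = length(ob_spheres),
        obc = if (length(ob_spheres)) do.call(rbind, lapply(ob_spheres, `[[`, "center")) else NULL,
        obR = vapply(ob_spheres, `[[`, 1, "R"),
        obE = vapply(ob_spheres, function(o) if (is.null(o$E)) Inf else o$E, 1),
        obnu = vapply(ob_spheres, function(o) if (is.null(o$nu)) 0 else o$nu, 1),
        obW = vapply(ob_spheres, function(o) if (is.null(o$W)) 0 else o$W, 1),
        planes = Filter(function(o) o$type == "plane", scene$obstacles))
      scene$obstatic <- os
      scene$obcache <- NULL
    }
    # obstacle-sphere neighbor cache (rebuilt when cells move or change)
    ob_pairs <- NULL
    if (os$n_spheres > 0) {
      oc <- scene$obcache
      margin <- 3e-6
      stale <- is.null(oc) || nrow(oc$snapshot) != nc ||
        max(abs(ctrs - oc$snapshot)) > margin / 3
      if (stale) {
        obc <- os$obc; obR <- os$obR
        qi <- oi <- integer(0)
        for (q in seq_len(nc)) {
          dd2 <- (obc[, 1] - ctrs[q, 1])^2 + (obc[, 2] - ctrs[q, 2])^2 +
            (obc[, 3] - ctrs[q, 3])^2
          hit <- which(dd2 < (Rs[q] + obR + margin)^2)
          qi <- c(qi, rep.int(q, length(hit))); oi <- c(oi, hit)
        }
        scene$obcache <- oc <- list(snapshot = ctrs, q = qi, o = oi,
                                    obc = obc, obR = obR, obE = os$obE,
                                    obnu = os$obnu, obW = os$obW)
      }
      if (length(oc$q) > 0) {
        dv <- oc$obc[oc$o, , drop = FALSE] - ctrs[oc$q, , drop = FALSE]
        dd <- sqrt(rowSums(dv * dv))
        del <- Rs[oc$q] + oc$obR[oc$o] - dd
        keep <- del > -1e-9 & dd > 0
        if (any(keep)) {
          ob_pairs <- list(q = oc$q[keep], o = oc$o[keep], d = dd[keep],
                           delta = del[keep],
                           u = dv[keep, , drop = FALSE] / dd[keep])
          pos <- ob_pairs$delta > 0
          if (any(pos)) {
            contrib <- ob_pairs$delta[pos] /
              (Rs[ob_pairs$q[pos]] + oc$obR[ob_pairs$o[pos]])
            acc <- rowsum(contrib, ob_pairs$q[pos])
            dtil_num[as.integer(rownames(acc))] <-
              dtil_num[as.integer(rownames(acc))] + acc
            cnt <- rowsum(rep(1L, sum(pos)), ob_pairs$q[pos])
            dtil_den[as.integer(rownames(cnt))] <-
              dtil_den[as.integer(rownames(cnt))] + cnt
          }
        }
      }
    }
    dtil <- ifelse(dtil_den > 0, dtil_num / pmax(dtil_den, 1L), 0)
    ramp <- vapply(scene$cbm, function(cl) {
      if (is.na(cl$t_div)) 1 else
        min(1, max(0, (scene$time - cl$t_div) / cl$ramp_T))
    }, 1)
    Eeff <- if (scene$correction$enabled) {
      corrected_modulus(Es, dtil, scene$correction$a1, ramp)
    } else Es
    # cell-cell JKR, vectorized, with engagement hysteresis
    if (!is.null(prs) && length(prs$i) > 0) {
      keys <- prs$keys
      eng_old <- scene$cbmcache$eng[prs$cache_idx]
      eng <- eng_old | prs$delta > 0
      ce1 <- (1 - nus[prs$i]^2) / Eeff[prs$i]
      ce2 <- (1 - nus[prs$j]^2) / Eeff[prs$j]
      Ehat <- 1 / (ce1 + ce2)
      Rhat <- Rs[prs$i] * Rs[prs$j] / prs$sumR
      Wij <- (Ws[prs$i] + Ws[prs$j]) / 2
      jf <- jkr_force_vec(prs$delta, Ehat, Rhat, Wij, eng)
      detach <- eng & jf$a == 0 & prs$delta <= 0
      eng_new <- eng & !detach
      changed <- which(eng_new != eng_old)
      for (r in changed) assign(keys[r], eng_new[r], envir = scene$engaged)
      scene$cbmcache$eng[prs$cache_idx] <- eng_new
      act <- which(jf$F != 0)
      if (length(act)) {
        u <- (ctrs[prs$j[act], , drop = FALSE] -
                ctrs[prs$i[act], , drop = FALSE]) / prs$d[act]
        Fi <- -jf$F[act] * u
        accF <- rowsum(rbind(Fi, -Fi), c(prs$i[act], prs$j[act]))
        rows <- as.integer(rownames(accF))
        Fm[coff + rows, ] <- Fm[coff + rows, ] + accF
        add_coupling(coff + prs$i[act], coff + prs$j[act],
                     scene$gamma_cc_area * pi * jf$a[act]^2)
      }
    }
    # CBM-obstacle sphere JKR (static partners, v = 0)
    if (!is.null(ob_pairs)) {
      oc <- scene$obcache
      ce1 <- (1 - nus[ob_pairs$q]^2) / Eeff[ob_pairs$q]
      ce2 <- ifelse(is.finite(oc$obE[ob_pairs$o]),
                    (1 - oc$obnu[ob_pairs$o]^2) / oc$obE[ob_pairs$o], 0)
      Ehat <- 1 / (ce1 + ce2)
      Rhat <- Rs[ob_pairs$q] * oc$obR[ob_pairs$o] /
        (Rs[ob_pairs$q] + oc$obR[ob_pairs$o])
      jf <- jkr_force_vec(ob_pairs$delta, Ehat, Rhat, oc$obW[ob_pairs$o],
                          ob_pairs$delta > 0)
      act <- which(jf$F != 0)
      if (length(act)) {
        Fi <- -jf$F[act] * ob_pairs$u[act, , drop = FALSE]
        accF <- rowsum(Fi, ob_pairs$q[act])
        rows <- as.integer(rownames(accF))
        Fm[coff + rows, ] <- Fm[coff + rows, ] + accF
        gacc <- rowsum(scene$gamma_cc_area * pi * jf$a[act]^2, ob_pairs$q[act])
        diag_g[coff + as.integer(rownames(gacc))] <-
          diag_g[coff + as.integer(rownames(gacc))] + gacc
      }
    }
    # CBM-plane contacts (boundaries / substrate)
    for (ob in os$planes) {
      s <- as.vector(sweep(ctrs, 2, ob$point) %*% ob$normal)
      del <- Rs - s
      hit <- which(del > 0)
      if (!length(hit)) next
      Wp <- if (is.null(ob$W)) 0 else ob$W
      Ehat <- Eeff[hit] / (1 - nus[hit]^2)
      jf <- jkr_force_vec(del[hit], Ehat, Rs[hit], Wp, TRUE)
      Fm[coff + hit, ] <- Fm[coff + hit, ] + outer(jf$F, ob$normal)
      diag_g[coff + hit] <- diag_g[coff + hit] +
        scene$gamma_cbm_sub * pi * jf$a^2
    }
    # migration
    for (q in seq_len(nc)) {
      cl <- scene$cbm[[q]]
      if (mig$D > 0) {
        z <- rng_draw(scene$rng, paste0("mig_cbm_", cl$id), function() rnorm(3))
        Fm[coff + q, ] <- Fm[coff + q, ] +
          random_migration_force(1, mig$D, dt, diag_g[coff + q], z)
      }
      if (mig$F_mor > 0 && !is.null(mig$dir_fun) &&
          (cl$leader || !mig$leader_only)) {
        Fm[coff + q, ] <- Fm[coff + q, ] +
          directed_migration_force(1, mig$F_mor, mig$dir_fun(cl$center))
      }
    }
  }

  # external experiment forces
  if (!is.null(scene$f_ext)) {
    ex <- if (length(formals(scene$f_ext)) >= 2)
      scene$f_ext(scene, list(curv = curv, Svor = Svor)) else scene$f_ext(scene)
    if (!is.null(ex$dcm)) for (ci in seq_along(ex$dcm)) {
      if (is.null(ex$dcm[[ci]])) next
      idx <- offs[ci] + seq_len(sizes[ci])
      Fm[idx, ] <- Fm[idx, ] + ex$dcm[[ci]]
    }
    if (!is.null(ex$cbm) && nc > 0)
      Fm[coff + seq_len(nc), ] <- Fm[coff + seq_len(nc), ] + ex$cbm
  }

  # frozen cells (division cocoon): zero velocity via huge ground friction
  for (ci in seq_len(nd)) if (isTRUE(scene$dcm[[ci]]$frozen)) {
    idx <- offs[ci] + seq_len(sizes[ci])
    Fm[idx, ] <- 0
    diag_g[idx] <- 1e6
  }

  if (any(diag_g <= 0))
    stop("singular friction matrix: some degrees of freedom have no grounding friction")

  # solve Gamma v = F; the factorization is reused while the friction
  # pattern and values are unchanged (no contact changes)
  if (scene$solver == "lumped" || length(ti) == 0) {
    sol <- function(X) X / diag_g
  } else {
    hash <- c(ndof, length(tx), sum(diag_g), sum(tx), sum(ti), sum(tj))
    fc <- scene$fcache
    if (is.null(fc) || !identical(fc$hash, hash)) {
      A <- Matrix::sparseMatrix(i = c(seq_len(ndof), ti), j = c(seq_len(ndof), tj),
                                x = c(diag_g, tx), dims = c(ndof, ndof),
                                symmetric = FALSE)
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
      scene$fcache <- fc <- list(hash = hash, ch = ch)
    }
    sol <- function(X) as.matrix(Matrix::solve(fc$ch, X, system = "A"))
  }
  v <- sol(Fm)
  # Woodbury correction for the implicit volume modes:
  # (Gamma + sum_k c_k u_k u_k^T) v = F with u_k supported on cell k's nodes
  act <- which(cvol > 0)
  if (length(act) > 0) {
    m <- length(act)
    Wl <- vector("list", m)
    Ul <- vector("list", m)
    for (q in seq_len(m)) {
      ci <- act[q]
      U <- matrix(0, ndof, 3)
      U[offs[ci] + seq_len(sizes[ci]), ] <- Uvol[[ci]]
      Ul[[q]] <- U
      Wl[[q]] <- sol(U)
    }
    C <- matrix(0, m, m)
    b <- numeric(m)
    for (q in seq_len(m)) {
      b[q] <- sum(Ul[[q]] * v)
      for (r in seq_len(m)) C[q, r] <- sum(Ul[[q]] * Wl[[r]])
      C[q, q] <- C[q, q] + 1 / cvol[act[q]]
    }
    z <- solve(C, b)
    for (q in seq_len(m)) v <- v - Wl[[q]] * z[q]
  }

  # displacement limiter (numerical safety, quasi-static runs); tightened
  # while any freshly divided cell is still relaxing to its reference shape
  lmin <- if (nd > 0) min(vapply(scene$dcm, function(cl) min(cl$mesh$l0), 1)) else
    min(vapply(scene$cbm, `[[`, 1, "R"))
  guard <- nd > 0 && any(vapply(scene$dcm, function(cl)
    isTRUE(cl$guard > 0L), TRUE))
  cap <- min(scene$max_disp_frac, if (guard) 0.05 else Inf) * lmin
  vmax <- max(row_norm(v)) * dt
  sc <- if (vmax > cap) cap / vmax else 1
  dX <- v * (dt * sc)

  for (ci in seq_len(nd)) {
    cell <- scene$dcm[[ci]]
    idx <- offs[ci] + seq_len(sizes[ci])
    cell$mesh$V <- cell$mesh$V + dX[idx, , drop = FALSE]
    if (isTRUE(cell$guard > 0L)) cell$guard <- cell$guard - 1L
    if (cell$params$element_model == "MME") {
      e <- cell$mesh$edges
      vrel <- (dX[offs[ci] + e[, 1], , drop = FALSE] -
                 dX[offs[ci] + e[, 2], , drop = FALSE]) / dt
      kap <- cell$params$k_s * dt / cell$params$gamma_ME
      cell$mme_F <- (cell$mme_F + cell$params$k_s * dt * vrel) / (1 + kap)
    }
    cell$params$gamma_ME <- cell$params$gamma_ME / scene$thermal_scale
    scene$dcm[[ci]] <- cell
  }
  if (nc > 0) for (q in seq_len(nc)) {
    scene$cbm[[q]]$center <- scene$cbm[[q]]$center + dX[coff + q, ]
  }
  scene$time <- scene$time + dt
  scene$last <- list(pressure = press, patches = patch_tables,
                     pair_totals = pair_totals,
                     max_disp = vmax * sc, limited = sc < 1,
                     vel = v)
  scene
}

# contact between two DCM cells reusing per-step curvature caches and a
# precomputed candidate pair list
dcm_pair_contact_cached <- function(ca, cb, curva, curvb, W, prs) {
  pa <- ca$contact
  h0 <- pa$h0
  sigma0 <- W / h0
  red <- reduced_pair(pa$E, pa$nu, cb$contact$E, cb$contact$nu)
  cpp_pair_contact(ca$mesh$V, ca$mesh$Tri, curva$tri_radius,
                   cb$mesh$V, cb$mesh$Tri, curvb$tri_radius,
                   prs, sigma0, h0, W, red$Ehat, pa$pen_stiff)
}

#' Run a scene for a number of steps
#'
#' @param scene a `scene`.
#' @param n_steps number of steps.
#' @param callback optional `function(scene, step)` called after each step;
#'   a non-NULL return value replaces the scene (allowing growth/division
#'   drivers).
#' @return the final scene.
#' @export
simulate_scene <- function(scene, n_steps, callback = NULL) {
  for (s in seq_len(n_steps)) {
    scene <- scene_step(scene)
    if (!is.null(callback)) {
      out <- callback(scene, s)
      if (!is.null(out)) scene <- out
    }
  }
  scene
}
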