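# Cell growth with coordinated reference-geometry updates, the
# envelope-constrained DCM division algorithm, CBM division with the
# post-division stiffness ramp, and lysis.

#' Grow a cell by one time step
#'
#' Linear reference-volume growth `V0 <- V0 + alpha dt`. For a deformable
#' cell every triangle rest area is scaled by `(V0'/V0)^(2/3)` and every
#' rest length by `(V0'/V0)^(1/3)` in the same update, so the growth itself
#' introduces no penalty forces. For a center-based cell the intrinsic
#' radius follows the intrinsic volume.
#'
#' @param cell a `dcm_cell` or `cbm_cell`.
#' @param alpha volume growth rate (m^3/s), >= 0 (negative only via
#'   [lysis_step()]).
#' @param dt time step (s).
#' @return the updated cell.
#' @export
grow_step <- function(cell, alpha = cell$alpha, dt) UseMethod("grow_step")

#' @export
grow_step.dcm_cell <- function(cell, alpha = cell$alpha, dt) {
  if (alpha == 0) return(cell)
  V0new <- cell$mesh$V0 + alpha * dt
  if (V0new <= 0) stop("reference volume must stay positive")
  s <- V0new / cell$mesh$V0
  cell$mesh$V0 <- V0new
  cell$mesh$A0_tri <- cell$mesh$A0_tri * s^(2 / 3)
  cell$mesh$A0 <- cell$mesh$A0 * s^(2 / 3)
  cell$mesh$l0 <- cell$mesh$l0 * s^(1 / 3)
  cell
}

#' @export
grow_step.cbm_cell <- function(cell, alpha = NULL, dt) {
  if (is.null(alpha)) alpha <- cell$alpha
  if (alpha == 0) return(cell)
  cell$V0 <- cell$V0 + alpha * dt
  if (cell$V0 <= 0) stop("intrinsic volume must stay positive")
  cell$R <- (3 * cell$V0 / (4 * pi))^(1 / 3)
  cell
}

#' Lysis: inverse of growth
#'
#' Shrinks the reference volume at `rate` with the same coordinated
#' reference updates as [grow_step()]; below `floor_volume` the cell is
#' marked for removal.
#'
#' @param cell a `dcm_cell` or `cbm_cell` flagged dead.
#' @param rate volume shrink rate (m^3/s), > 0.
#' @param dt time step (s).
#' @param floor_volume removal threshold (m^3).
#' @return the updated cell, or `NULL` once the floor is reached.
#' @export
lysis_step <- function(cell, rate, dt, floor_volume) {
  V0 <- if (inherits(cell, "dcm_cell")) cell$mesh$V0 else cell$V0
  if (V0 - rate * dt <= floor_volume) return(NULL)
  grow_step(cell, -rate, dt)
}

#' Sample a division-plane normal
#'
#' `"random"`: uniform on the unit sphere. `"hsa"`: the axis of the nearest
#' sinusoid chain segment (hepatocyte-sinusoid alignment) - daughters are
#' placed *along* this axis, i.e. the plane normal is the segment direction.
#'
#' @param policy `"random"` or `"hsa"`.
#' @param center cell center (for `"hsa"`).
#' @param sinusoid_segments optional matrix with columns x1,y1,z1,x2,y2,z2 of
#'   chain segments (for `"hsa"`).
#' @param z3 optional pre-drawn standard normal triple (seeded substream).
#' @return unit length-3 normal.
#' @export
division_plane_normal <- function(policy = c("random", "hsa"), center = NULL,
                                  sinusoid_segments = NULL, z3 = rnorm(3)) {
  policy <- match.arg(policy)
  if (policy == "random" || is.null(sinusoid_segments) ||
      nrow(sinusoid_segments) == 0) {
    n <- sqrt(sum(z3^2))
    if (n == 0) z3 <- c(0, 0, 1)
    return(z3 / max(n, 1e-300))
  }
  mid <- (sinusoid_segments[, 1:3] + sinusoid_segments[, 4:6]) / 2
  d <- row_norm(sweep(mid, 2, center))
  seg <- sinusoid_segments[which.min(d), ]
  u <- seg[4:6] - seg[1:3]
  u / sqrt(sum(u^2))
}

#' Divide a center-based cell
#'
#' Two daughters of volume `V_crit/2` are placed symmetrically inside the
#' mother's footprint along the division direction (pair center of mass =
#' mother center); each daughter's contact-stiffness correction ramps from
#' zero to full over one tenth of the cycle time (`ramp_T = tau/10`).
#'
#' @param cell a `cbm_cell` with intrinsic volume >= `V_crit`.
#' @param direction unit division axis.
#' @param time current simulation time (s), stored as the ramp start.
#' @param V_crit division-trigger volume (m^3); default `2 V0` of a fresh
#'   cell, i.e. the current intrinsic volume.
#' @return list of two `cbm_cell`s.
#' @export
divide_cbm <- function(cell, direction = c(1, 0, 0), time = 0,
                       V_crit = cell$V0) {
  u <- direction / sqrt(sum(direction^2))
  Vd <- V_crit / 2
  Rd <- (3 * Vd / (4 * pi))^(1 / 3)
  off <- (cell$R - Rd) * u
  mk <- function(sgn, id) {
    d <- cell
    d$center <- cell$center + sgn * off
    d$V0 <- Vd
    d$R <- Rd
    d$alpha <- Vd / cell$tau
    d$V_crit <- 2 * Vd
    d$t_div <- time
    d$ramp_T <- cell$tau / 10
    d$growing <- FALSE
    d$id <- id
    d
  }
  list(mk(-1, cell$id), mk(1, -1L))  # second id assigned by the scene
}

# mother mesh level inferred from node count (10 * 4^level + 2)
mesh_level <- function(n_nodes) round(log((n_nodes - 2) / 10, 4))

#' Divide a deformable cell inside its mother envelope
#'
#' Implements the one-step division algorithm: a division plane through the
#' center of mass splits the nodes into two sides; two icosphere daughters
#' are seeded at the side-wise centers of mass with radii 0.95 times the
#' largest inscribed sphere, nodes beyond the plane are projected onto it,
#' and a sub-simulation with frozen mother envelope, repulsive division
#' plane and strongly reduced daughter friction inflates each daughter to
#' half the mother's enclosed volume. The mother envelope is then removed
#' and the daughters (which adhere) are returned in the scene for normal
#' relaxation over the mitosis phase.
#'
#' @param scene the `scene` containing the cell.
#' @param index position of the mother in `scene$dcm`.
#' @param normal optional division-plane normal (unit); drawn from the
#'   `"division"` RNG substream per the random policy when NULL.
#' @param friction_scale sub-simulation friction multiplier (<< 1).
#' @param max_sub_steps cap on sub-simulation steps.
#' @param vol_tol daughters stop inflating when within this relative
#'   tolerance of half the mother volume.
#' @return the scene with the mother replaced by two relaxed daughters;
#'   attributes of the division (plane normal, sub-steps used) in
#'   `scene$last_division`.
#' @export
divide_dcm <- function(scene, index, normal = NULL, friction_scale = 1e-2,
                       max_sub_steps = 400L, vol_tol = 0.02) {
  mother <- scene$dcm[[index]]
  Vm <- enclosed_volume(mother$mesh)
  ctr <- colMeans(mother$mesh$V)
  lev <- mesh_level(nrow(mother$mesh$V))
  for (attempt in 1:20) {
    if (is.null(normal) || attempt > 1) {
      z <- rng_draw(scene$rng, "division", function() rnorm(3))
      n <- z / sqrt(sum(z^2))
    } else n <- normal
    side <- as.vector(sweep(mother$mesh$V, 2, ctr) %*% n)
    if (any(side > 0) && any(side < 0)) break
    if (attempt == 20) stop("degenerate node partition in division")
  }
  daughters <- list()
  for (sgn in c(-1, 1)) {
    sel <- if (sgn < 0) side <= 0 else side > 0
    com <- colMeans(mother$mesh$V[sel, , drop = FALSE])
    dist_surf <- min(row_norm(sweep(mother$mesh$V, 2, com)))
    # the seed must fit inside the mother AND its own half-space, else the
    # projection step flattens the mesh into a near-degenerate shape
    dist_plane <- abs(sum((com - ctr) * n))
    r_seed <- 0.95 * min(dist_surf, max(dist_plane, 0.25 * dist_surf))
    d <- dcm_cell(build_icosphere(r_seed, lev, center = com),
                  params = mother$params, contact = mother$contact,
                  tau = mother$tau)
    # reference geometry of a half-volume cell: the sub-simulation inflates
    # the seed toward it
    s <- (Vm / 2) / d$mesh$V0
    d$mesh$V0 <- Vm / 2
    d$mesh$A0_tri <- d$mesh$A0_tri * s^(2 / 3)
    d$mesh$A0 <- d$mesh$A0 * s^(2 / 3)
    d$mesh$l0 <- d$mesh$l0 * s^(1 / 3)
    d$alpha <- d$mesh$V0 / d$tau
    d$V_crit <- 2 * d$mesh$V0
    # project nodes beyond the division plane back onto it
    h <- as.vector(sweep(d$mesh$V, 2, ctr) %*% n) * sgn  # >0 = own side
    bad <- h < 0
    if (any(bad))
      d$mesh$V[bad, ] <- d$mesh$V[bad, , drop = FALSE] -
        (h[bad] * sgn - sgn * 1e-9) %o% n
    d$friction_scale <- friction_scale
    d$gamma_medium_area <- scene$gamma_medium_area * friction_scale
    daughters[[length(daughters) + 1L]] <- d
  }
  # sub-simulation: frozen mother + two inflating daughters + division plane
  sub <- scene
  mother$frozen <- TRUE
  sub$dcm <- list(mother, daughters[[1]], daughters[[2]])
  sub$migration$D <- 0; sub$migration$F_mor <- 0
  sub$max_disp_frac <- 0.08   # gentle inflation steps
  sub$ppcache <- NULL; sub$fcache <- NULL
  sub$obstacles <- c(scene$obstacles, list(
    list(type = "plane", point = ctr, normal = -n, W = 0),
    list(type = "plane", point = ctr, normal = n, W = 0)
  ))
  used <- max_sub_steps
  for (s in seq_len(max_sub_steps)) {
    sub <- scene_step(sub)
    v2 <- enclosed_volume(sub$dcm[[2]]$mesh)
    v3 <- enclosed_volume(sub$dcm[[3]]$mesh)
    if (abs(v2 - Vm / 2) < vol_tol * Vm / 2 &&
        abs(v3 - Vm / 2) < vol_tol * Vm / 2) { used <- s; break }
  }
  d1 <- sub$dcm[[2]]; d2 <- sub$dcm[[3]]
  d1$friction_scale <- NULL; d1$gamma_medium_area <- NULL
  d2$friction_scale <- NULL; d2$gamma_medium_area <- NULL
  # mitosis-phase guard: the freshly released daughters are far from their
  # reference geometry, so the integrator uses a small displacement cap
  # while this counts down
  d1$guard <- 250L
  d2$guard <- 250L
  d1$id <- mother$id
  d2$id <- scene$next_id
  scene$next_id <- scene$next_id + 1L
  scene$dcm[[index]] <- d1
  scene$dcm[[length(scene$dcm) + 1L]] <- d2
  scene$rng <- sub$rng
  scene$ppcache <- NULL
  scene$fcache <- NULL
  scene$last_division <- list(normal = n, sub_steps = used,
                              mother_volume = Vm,
                              daughter_volumes = c(enclosed_volume(d1$mesh),
                                                   enclosed_volume(d2$mesh)))
  scene
}
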