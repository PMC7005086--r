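# Cell-cell and cell-obstacle adhesive contact (Maugis-Dugdale), plus
# friction tensors. The narrow phase (projection, clipping, quadrature) is
# compiled; this file holds the theory-level functions and the broad phase.

#' Tabor coefficient
#'
#' `lambda = sigma0 (9 Rhat / (2 pi W Ehat^2))^(1/3)`; large values are the
#' JKR regime (short interaction range, soft bodies), small values the DMT
#' regime.
#'
#' @param sigma0 peak adhesive tension (Pa), `W / h0`.
#' @param Rhat reduced radius (m).
#' @param W specific adhesion energy (J/m^2).
#' @param Ehat reduced elastic modulus (Pa).
#' @return dimensionless Tabor coefficient.
#' @export
tabor_coefficient <- function(sigma0, Rhat, W, Ehat) {
  stopifnot(sigma0 > 0, Rhat > 0, W > 0)
  if (Ehat <= 0) stop("Ehat must be > 0")
  sigma0 * (9 * Rhat / (2 * pi * W * Ehat^2))^(1 / 3)
}

#' Reduced modulus and radius of a contacting pair
#'
#' `Ehat = ((1-nu1^2)/E1 + (1-nu2^2)/E2)^-1`, `Rhat = (1/R1 + 1/R2)^-1`.
#' Use `E = Inf` for a rigid partner and `R = Inf` for a plane.
#'
#' @param E1,nu1,E2,nu2 Young moduli (Pa) and Poisson ratios.
#' @param R1,R2 radii (m).
#' @return list with `Ehat`, `Rhat`.
#' @export
reduced_pair <- function(E1, nu1, E2 = Inf, nu2 = 0, R1 = Inf, R2 = Inf) {
  c1 <- if (is.finite(E1)) (1 - nu1^2) / E1 else 0
  c2 <- if (is.finite(E2)) (1 - nu2^2) / E2 else 0
  r1 <- if (is.finite(R1)) 1 / R1 else 0
  r2 <- if (is.finite(R2)) 1 / R2 else 0
  list(Ehat = 1 / (c1 + c2), Rhat = if (r1 + r2 > 0) 1 / (r1 + r2) else Inf)
}

#' Solve the Maugis relation for m = c/a
#'
#' Root of the Maugis-Dugdale self-consistency relation linking the adhesive
#' annulus radius c to the Hertz contact radius a, found by bracketed
#' bisection with m >= 1. In the large-lambda (JKR) limit m tends to 1; if no
#' bracket exists the JKR limit is returned with a warning.
#'
#' @param lambda Tabor coefficient (> 0).
#' @param a contact radius (m), > 0.
#' @param W,Ehat,Rhat adhesion energy, reduced modulus, reduced radius.
#' @return m = c/a (>= 1).
#' @export
solve_maugis_m <- function(lambda, a, W, Ehat, Rhat) {
  stopifnot(lambda > 0, a > 0)
  A <- 4 * a^3 * Ehat / (3 * pi * W * Rhat^2)
  m <- cpp_maugis_m(lambda, A)
  if (is.na(m)) {
    warning("no bracket for Maugis m; returning JKR limit m -> 1")
    m <- 1
  }
  m
}

# left-hand side of the Maugis relation; exposed for residual checks
maugis_lhs <- function(m, lambda, a, W, Ehat, Rhat) {
  A <- 4 * a^3 * Ehat / (3 * pi * W * Rhat^2)
  s <- sqrt(pmax(m^2 - 1, 0))
  as <- atan(s)
  0.5 * lambda * A^(2 / 3) * ((m^2 - 2) * as + s) +
    (4 / 3) * lambda^2 * A^(1 / 3) * (s * as - m + 1)
}

#' Maugis-Dugdale traction at radial distance r from the contact point
#'
#' Total normal traction `p_a + p_r`: the adhesive component is
#' `-sigma0/pi * acos((2a^2 - c^2 - r^2)/(c^2 - r^2))` inside the Hertz zone
#' (r < a), the constant `-sigma0` on the Dugdale annulus (a <= r <= c) and
#' zero beyond c; the repulsive component is the Hertz pressure
#' `2 Ehat/(pi Rhat) sqrt(a^2 - r^2)` for r < a. Positive values are
#' repulsive.
#'
#' @param r radial distance(s) from the contact point (m), >= 0.
#' @param a Hertz contact radius (m).
#' @param c adhesive zone radius (m), c >= a.
#' @param sigma0 peak adhesive tension (Pa).
#' @param Ehat,Rhat reduced modulus and radius.
#' @return traction (Pa), vectorized over `r`.
#' @export
md_traction <- function(r, a, c, sigma0, Ehat, Rhat) {
  if (any(r < 0)) stop("r must be >= 0")
  stopifnot(a >= 0, c >= a)
  cpp_md_traction(as.numeric(r), a, c, sigma0, Ehat, Rhat, sigma0 > 0)
}

# ---- broad phase -------------------------------------------------------------

tri_circumradius <- function(V, Tri, bary) {
  r <- row_norm(V[Tri[, 1], , drop = FALSE] - bary)
  r <- pmax(r, row_norm(V[Tri[, 2], , drop = FALSE] - bary))
  pmax(r, row_norm(V[Tri[, 3], , drop = FALSE] - bary))
}

candidate_tri_pairs <- function(VA, TriA, VB, TriB, slack) {
  gA <- triangle_geometry(VA, TriA)
  gB <- triangle_geometry(VB, TriB)
  cA <- tri_circumradius(VA, TriA, gA$bary)
  cB <- tri_circumradius(VB, TriB, gB$bary)
  d2 <- -2 * tcrossprod(gA$bary, gB$bary)
  d2 <- d2 + rowSums(gA$bary^2)                 # recycles down columns
  d2 <- sweep(d2, 2, rowSums(gB$bary^2), "+")
  cut <- sweep(matrix(cA + slack, length(cA), length(cB)), 2, cB, "+")
  which(d2 < cut * cut, arr.ind = TRUE)
}

#' Contact forces between two deformable cells
#'
#' Broad phase (triangle barycenter distance against summed circumradii) then
#' compiled narrow phase: every candidate triangle pair is projected onto the
#' common contact plane (perpendicular to the line joining the local
#' curvature spheres, at the mid-gap point), the projections are clipped
#' against each other (Sutherland-Hodgman) and the Maugis-Dugdale traction is
#' integrated with a degree-2 Gauss rule over the overlap. Forces are
#' distributed equally to the three nodes of each triangle with
#' equal-and-opposite pair totals; each node also accumulates overlap-area/3
#' as contact area for friction.
#'
#' @param cellA,cellB `dcm_cell` objects.
#' @param VA,VB optional vertex overrides.
#' @param W specific adhesion energy for this pair (J/m^2); defaults to the
#'   mean of the two cells' contact parameters.
#' @param slack extra broad-phase margin (m).
#' @return list with nodal force matrices `F1`, `F2`, per-node contact areas
#'   `area1`, `area2`, `total1` (momentum check) and a per-patch diagnostics
#'   matrix `patches` (a, c, lambda, force, area, approach).
#' @export
cell_pair_contact <- function(cellA, cellB, VA = cellA$mesh$V, VB = cellB$mesh$V,
                              W = NULL, slack = NULL) {
  pa <- cellA$contact; pb <- cellB$contact
  if (is.null(W)) W <- (pa$W + pb$W) / 2
  h0 <- pa$h0
  sigma0 <- W / h0
  red <- reduced_pair(pa$E, pa$nu, pb$E, pb$nu)
  if (is.null(slack)) slack <- h0 + 0.1 * mean(cellA$mesh$l0)
  prs <- candidate_tri_pairs(VA, cellA$mesh$Tri, VB, cellB$mesh$Tri, slack)
  if (nrow(prs) == 0) {
    return(list(F1 = matrix(0, nrow(VA), 3), F2 = matrix(0, nrow(VB), 3),
                area1 = numeric(nrow(VA)), area2 = numeric(nrow(VB)),
                total1 = c(0, 0, 0), patches = NULL))
  }
  ctA <- curvature_radii(cellA$mesh, VA)
  ctB <- curvature_radii(cellB$mesh, VB)
  res <- cpp_pair_contact(VA, cellA$mesh$Tri, ctA$tri_radius,
                          VB, cellB$mesh$Tri, ctB$tri_radius,
                          prs, sigma0, h0, W, red$Ehat, pa$pen_stiff)
  res
}

#' Contact of one triangle pair (diagnostic wrapper)
#'
#' Runs the narrow phase for a single candidate triangle pair of two cells.
#'
#' @inheritParams cell_pair_contact
#' @param t1,t2 triangle indices into the two meshes.
#' @return as [cell_pair_contact()]; `patches` has zero or one row.
#' @export
triangle_pair_contact <- function(cellA, cellB, t1, t2,
                                  VA = cellA$mesh$V, VB = cellB$mesh$V, W = NULL) {
  pa <- cellA$contact; pb <- cellB$contact
  if (is.null(W)) W <- (pa$W + pb$W) / 2
  red <- reduced_pair(pa$E, pa$nu, pb$E, pb$nu)
  ctA <- curvature_radii(cellA$mesh, VA)
  ctB <- curvature_radii(cellB$mesh, VB)
  cpp_pair_contact(VA, cellA$mesh$Tri, ctA$tri_radius,
                   VB, cellB$mesh$Tri, ctB$tri_radius,
                   cbind(as.integer(t1), as.integer(t2)),
                   W / pa$h0, pa$h0, W, red$Ehat, pa$pen_stiff)
}

#' Contact between a deformable cell and a smooth body (sphere or plane)
#'
#' The contact establishes between each triangle's local curvature sphere and
#' the sphere that represents the body as a whole (a plane is the
#' infinite-radius limit). The reaction force is returned for application at
#' a center-based cell's center, or discarded for static obstacles.
#'
#' @param cell a `dcm_cell`.
#' @param body list: `type = "sphere"` with `center`, `R`, or `type = "plane"`
#'   with `point`, `normal` (unit, pointing toward the cell); optional `E`,
#'   `nu` (defaults: rigid), `W` adhesion override.
#' @param V optional vertex override.
#' @param curv optional precomputed [curvature_radii()].
#' @return list with `F` (nodal forces), `area` (per-node contact areas),
#'   `total`, `body_force`, `patches`.
#' @export
cell_body_contact <- function(cell, body, V = cell$mesh$V, curv = NULL) {
  pa <- cell$contact
  W <- if (!is.null(body$W)) body$W else pa$W
  bE <- if (!is.null(body$E)) body$E else Inf
  bnu <- if (!is.null(body$nu)) body$nu else 0
  red <- reduced_pair(pa$E, pa$nu, bE, bnu)
  if (is.null(curv)) curv <- curvature_radii(cell$mesh, V)
  g <- triangle_geometry(V, cell$mesh$Tri)
  circ <- tri_circumradius(V, cell$mesh$Tri, g$bary)
  slack <- pa$h0 + 0.1 * mean(cell$mesh$l0)
  if (body$type == "sphere") {
    d <- row_norm(sweep(g$bary, 2, body$center))
    cand <- which(d < body$R + circ + slack & d > body$R - 4 * circ - slack)
    res <- cpp_body_contact(V, cell$mesh$Tri, curv$tri_radius, as.integer(cand),
                            0L, body$center[1], body$center[2], body$center[3],
                            body$R, 0, 0, 0, W / pa$h0, pa$h0, W, red$Ehat,
                            pa$pen_stiff)
  } else if (body$type == "plane") {
    s <- as.vector(sweep(g$bary, 2, body$point) %*% body$normal)
    cand <- which(s < circ + slack & s > -4 * circ)
    res <- cpp_body_contact(V, cell$mesh$Tri, curv$tri_radius, as.integer(cand),
                            1L, body$point[1], body$point[2], body$point[3], 0,
                            body$normal[1], body$normal[2], body$normal[3],
                            W / pa$h0, pa$h0, W, red$Ehat, pa$pen_stiff)
  } else stop("unknown body type: ", body$type)
  res
}

#' Anisotropic friction tensor for a contact direction
#'
#' `Gamma = gamma_perp (e x e) + gamma_par (I - e x e)` (dyadic products);
#' symmetric positive semi-definite with eigenvalues `gamma_perp` (along `e`)
#' and `gamma_par` (twice, across).
#'
#' @param e unit direction vector (length 3).
#' @param gamma_perp,gamma_par friction coefficients normal/parallel to the
#'   relative motion (Ns/m).
#' @return 3 x 3 matrix.
#' @export
friction_tensor <- function(e, gamma_perp, gamma_par) {
  n <- sqrt(sum(e^2))
  if (n == 0) stop("zero direction vector")
  if (abs(n - 1) > 1e-8) e <- e / n
  P <- tcrossprod(e)
  gamma_perp * P + gamma_par * (diag(3) - P)
}
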