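# Internal DCM surface mechanics: in-plane viscoelastic elements, bending,
# volume pressure, membrane-area conservation, virial stress, thermal scaling.

#' Derive discrete cortex stiffness constants from continuum moduli
#'
#' For a sixfold-symmetric triangulated lattice the edge spring constant is
#' `k_s = (2/sqrt(3)) E_cor h_cor`, the hinge bending constant
#' `k_b = E_cor h_cor^3 / (12 (1 - nu^2))` (units N m) and the discrete
#' membrane-area stiffness `k_mem = K_A l0` with `l0` the vertex resolution.
#'
#' @param E_cor cortex Young modulus (Pa).
#' @param h_cor cortex thickness (m).
#' @param nu_cor cortex Poisson ratio, in (-1, 0.5].
#' @param l0 typical edge rest length (m).
#' @param K_A membrane area-compression modulus (N/m).
#' @return list with `k_s` (N/m), `k_b` (N m), `k_mem` (N).
#' @export
derive_cortex_constants <- function(E_cor, h_cor, nu_cor = 0.5, l0, K_A = 0.8e-3) {
  stopifnot(E_cor > 0, h_cor > 0, l0 > 0, K_A > 0)
  if (abs(abs(nu_cor) - 1) < 1e-12) stop("nu_cor = +/-1 not allowed")
  list(k_s = 2 / sqrt(3) * E_cor * h_cor,
       k_b = E_cor * h_cor^3 / (12 * (1 - nu_cor^2)),
       k_mem = K_A * l0)
}

#' Cortex/volume/membrane parameter set for a deformable cell
#'
#' Bundles the continuum inputs and derived discrete constants. Defaults are
#' the nominal values for a parenchymal cell: cortex modulus 1 kPa, thickness
#' 500 nm, bulk modulus 2500 Pa, membrane area compression 0.8 mN/m.
#'
#' @param E_cor,h_cor,nu_cor,K_A see [derive_cortex_constants()].
#' @param K_V cell bulk modulus (Pa).
#' @param element_model `"KVE"` (Kelvin-Voigt: spring parallel to the nodal
#'   damping) or `"MME"` (modified Maxwell: spring in series with a dashpot
#'   `gamma_ME`, in parallel with the nodal damping).
#' @param gamma_int node-node friction within a cell (Ns/m).
#' @param gamma_ME Maxwell dashpot coefficient (Ns/m), used when
#'   `element_model = "MME"`.
#' @param l0 vertex resolution (m) used for `k_mem`; taken from the mesh when
#'   a cell is built.
#' @return list of class `cortex_params`.
#' @export
cortex_params <- function(E_cor = 1000, h_cor = 5e-7, nu_cor = 0.5,
                          K_A = 0.8e-3, K_V = 2500,
                          element_model = c("KVE", "MME"),
                          gamma_int = 1e-4, gamma_ME = 3e-3, l0 = 2e-6) {
  element_model <- match.arg(element_model)
  stopifnot(K_V > 0, gamma_int > 0)
  if (element_model == "MME" && gamma_ME <= 0) stop("gamma_ME must be > 0 for MME")
  k <- derive_cortex_constants(E_cor, h_cor, nu_cor, l0, K_A)
  structure(c(list(E_cor = E_cor, h_cor = h_cor, nu_cor = nu_cor, K_A = K_A,
                   K_V = K_V, element_model = element_model,
                   gamma_int = gamma_int, gamma_ME = gamma_ME, l0 = l0), k),
            class = "cortex_params")
}

#' Contact parameter set (Maugis-Dugdale / JKR)
#'
#' @param E,nu apparent elastic modulus (Pa) and Poisson ratio of the body
#'   entering the reduced modulus of a contact.
#' @param W specific adhesion energy (J/m^2); may be decomposed as bond
#'   density x bond energy by the caller.
#' @param h0 adhesive interaction range (m); the peak adhesive tension is
#'   `sigma0 = W / h0`.
#' @param gamma_cc,gamma_ecm,gamma_liq contact-class friction coefficients
#'   per area (Ns/m^3): cell-cell, cell-ECM/substrate, cell-liquid. They are
#'   multiplied by the respective contact (or Voronoi) areas.
#' @param pen_stiff dimensionless conformal-contact penalty: flattened
#'   contact regions transmit an extra pressure `pen_stiff * Ehat / h0`
#'   per unit of local overlap, extending the sphere-pair Hertz pressure
#'   where the surfaces conform.
#' @return list of class `contact_params` with `sigma0` precomputed.
#' @export
contact_params <- function(E = 450, nu = 0.47, W = 1e-5, h0 = 2e-8,
                           gamma_cc = 5e10, gamma_ecm = 1e8, gamma_liq = 500,
                           pen_stiff = 20) {
  stopifnot(E > 0, W >= 0, h0 > 0)
  structure(list(E = E, nu = nu, W = W, h0 = h0, sigma0 = W / h0,
                 gamma_cc = gamma_cc, gamma_ecm = gamma_ecm,
                 gamma_liq = gamma_liq, pen_stiff = pen_stiff),
            class = "contact_params")
}

#' Construct a deformable (DCM) cell
#'
#' @param mesh a `trimesh`, usually from [build_icosphere()].
#' @param params a [cortex_params()] set; `l0` is replaced by the mesh mean
#'   edge length and the derived constants recomputed.
#' @param contact a [contact_params()] set.
#' @param tau cell-cycle time (s); the growth rate is `alpha = V0 / tau`.
#' @param id integer identity.
#' @return object of class `dcm_cell` holding the mesh, parameters, Maxwell
#'   force memory (zero-initialized) and growth state.
#' @export
dcm_cell <- function(mesh, params = cortex_params(), contact = contact_params(),
                     tau = 24 * 3600, id = 1L) {
  l0m <- mean(mesh$l0)
  params$l0 <- l0m
  params[c("k_s", "k_b", "k_mem")] <-
    derive_cortex_constants(params$E_cor, params$h_cor, params$nu_cor, l0m, params$K_A)
  structure(list(
    mesh = mesh, params = params, contact = contact,
    mme_F = matrix(0, nrow(mesh$edges), 3),
    tau = tau, alpha = mesh$V0 / tau, V_crit = 2 * mesh$V0,
    growing = FALSE, dead = FALSE, leader = FALSE, id = as.integer(id)
  ), class = "dcm_cell")
}

#' @export
print.dcm_cell <- function(x, ...) {
  cat(sprintf("dcm_cell #%d: %d nodes, %s elements, V=%.3g um^3 (V0=%.3g)\n",
              x$id, nrow(x$mesh$V), x$params$element_model,
              enclosed_volume(x$mesh) * 1e18, x$mesh$V0 * 1e18))
  invisible(x)
}

# ---- viscoelastic elements ---------------------------------------------------

#' Kelvin-Voigt edge force on a node pair
#'
#' `F_i = -k_s (l - l0) e_ji - gamma v_ij` with `e_ji = (r_i - r_j)/l`;
#' the force on j is the negative. The damping part is usually handled
#' implicitly through the friction matrix; pass `gamma = 0` to get the
#' elastic part alone.
#'
#' @param xi,xj node positions (length 3, m).
#' @param l0 rest length (m), > 0.
#' @param k_s spring constant (N/m).
#' @param gamma damping coefficient (Ns/m).
#' @param vi,vj node velocities (m/s).
#' @return list with `Fi`, `Fj` (N).
#' @export
kve_edge_force <- function(xi, xj, l0, k_s, gamma = 0,
                           vi = c(0, 0, 0), vj = c(0, 0, 0)) {
  stopifnot(l0 > 0)
  d <- xj - xi
  l <- sqrt(sum(d * d))
  if (l == 0) stop("coincident nodes: edge direction undefined")
  e_ij <- d / l
  Fi <- k_s * (l - l0) * e_ij - gamma * (vi - vj)
  list(Fi = Fi, Fj = -Fi)
}

#' Maxwell-branch edge force update (modified Maxwell element)
#'
#' Backward-difference discretization of the serial spring-dashpot branch
#' `Fdot/k_s + F/gamma_ME = v_ij`:
#' `F(t) = (F(t - dt) + k_s dt v_ij) / (1 + k_s dt / gamma_ME)`.
#' At constant extension rate the branch force tends to `gamma_ME v`; on a
#' hold it decays as `exp(-k_s t / gamma_ME)`. In the full element this
#' branch acts in parallel with the overall nodal damping `gamma(T0)`.
#'
#' @param memory previous internal branch force (vector, N).
#' @param v_rel relative velocity `v_i - v_j` over the step (m/s).
#' @param dt time step (s), > 0.
#' @param k_s spring constant (N/m).
#' @param gamma_ME serial dashpot coefficient (Ns/m), > 0.
#' @return list with `F` (force the branch exerts resisting `v_rel`, to be
#'   applied as `-F` on node i and `+F` on node j) and `memory` (the updated
#'   internal force, equal to `F`).
#' @export
mme_edge_force <- function(memory, v_rel, dt, k_s, gamma_ME) {
  if (dt <= 0) stop("dt must be > 0")
  if (gamma_ME <= 0) stop("gamma_ME must be > 0")
  Fnew <- (memory + k_s * dt * v_rel) / (1 + k_s * dt / gamma_ME)
  list(F = Fnew, memory = Fnew)
}

# vectorized elastic edge forces for a cell; returns nodal forces and the
# scalar edge tensions (positive = tensile) used by the virial stress
elastic_edge_forces <- function(cell, V = cell$mesh$V) {
  mesh <- cell$mesh
  e <- mesh$edges
  d <- V[e[, 2], , drop = FALSE] - V[e[, 1], , drop = FALSE]
  l <- row_norm(d)
  u <- d / l
  n <- nrow(V)
  if (cell$params$element_model == "KVE") {
    t_s <- cell$params$k_s * (l - mesh$l0)    # tension > 0 when stretched
    Fi <- u * t_s                              # pulls i toward j when stretched
    F <- accumulate_nodes_mat(e[, 1], Fi, n) + accumulate_nodes_mat(e[, 2], -Fi, n)
    list(F = F, tension = t_s, length = l, unit = u)
  } else {
    # MME: the memory part of the Maxwell branch is a force on the RHS; the
    # velocity part becomes an implicit per-edge friction handled by the
    # integrator (see scene_step). Branch force Fb resists v_ij: node i
    # receives -Fb/(1+kappa).
    kappa <- cell$params$k_s * cell$.dt / cell$params$gamma_ME
    Fb <- cell$mme_F / (1 + kappa)
    F <- accumulate_nodes_mat(e[, 1], -Fb, n) + accumulate_nodes_mat(e[, 2], Fb, n)
    t_s <- -rowSums(Fb * u)  # tension: branch force opposing extension
    list(F = F, tension = t_s, length = l, unit = u)
  }
}

# ---- bending -----------------------------------------------------------------

#' Hinge bending forces
#'
#' Each hinge (edge shared by triangles T1, T2 with apex nodes k, l) carries
#' a moment `M = k_b sin(theta - theta0)`. The apex nodes receive
#' `-/+ M / h` along their triangle normals (h = apex distance to the hinge
#' line) and the two edge nodes receive the balancing forces, so every hinge
#' force quadruple sums to zero exactly.
#'
#' @param mesh a `trimesh` (provides hinges and `theta0`).
#' @param k_b bending constant (N m).
#' @param V optional deformed vertex positions.
#' @return n x 3 matrix of nodal forces (N).
#' @export
bending_forces <- function(mesh, k_b, V = mesh$V, geom = NULL) {
  h <- mesh$hinges
  g <- if (is.null(geom)) triangle_geometry(V, mesh$Tri) else geom
  theta <- hinge_angles(mesh, V, g)
  M <- k_b * sin(theta - mesh$theta0)
  le <- row_norm(V[h[, "j"], , drop = FALSE] - V[h[, "i"], , drop = FALSE])
  h1 <- 2 * g$area[h[, "t1"]] / le
  h2 <- 2 * g$area[h[, "t2"]] / le
  n1 <- g$normal[h[, "t1"], , drop = FALSE]
  n2 <- g$normal[h[, "t2"], , drop = FALSE]
  # restoring: for theta > theta0 the apexes are pushed along the triangle
  # normals (unfolds the hinge under this sign convention)
  Fk <- n1 * (M / h1)
  Fl <- n2 * (M / h2)
  Fe <- -(Fk + Fl) / 2
  n <- nrow(V)
  accumulate_nodes_mat(h[, "k"], Fk, n) +
    accumulate_nodes_mat(h[, "l"], Fl, n) +
    accumulate_nodes_mat(h[, "i"], Fe, n) +
    accumulate_nodes_mat(h[, "j"], Fe, n)
}

# ---- volume and membrane area ------------------------------------------------

#' Volume (pressure) forces
#'
#' Internal pressure from the logarithmic volume strain,
#' `p = -K_V log(V / V0)`, applied to each node over its Voronoi area along
#' the outward curvature normal: `F_i = p S_i R^n_i`.
#'
#' @param cell a `dcm_cell`.
#' @param V optional deformed vertex positions.
#' @param curv optional precomputed [curvature_radii()] result.
#' @return list with `F` (n x 3, N) and `p` (Pa).
#' @export
volume_pressure_forces <- function(cell, V = cell$mesh$V, curv = NULL) {
  vol <- enclosed_volume(cell$mesh, V)
  if (vol <= 0) stop("enclosed volume must be positive")
  p <- -cell$params$K_V * log(vol / cell$mesh$V0)
  if (is.null(curv)) curv <- curvature_radii(cell$mesh, V)
  S <- if (!is.null(curv$S)) curv$S else node_voronoi_areas(cell$mesh, V)
  list(F = curv$normal * (p * S), p = p)
}

#' Membrane area-conservation forces
#'
#' Resists isotropic expansion of the membrane: per-triangle force magnitude
#' `F_T = k_mem (A - A0) / A0` directed along the triangle normal (inward
#' when the surface is dilated, outward when compressed), split equally to
#' the triangle's three nodes.
#'
#' @inheritParams volume_pressure_forces
#' @return list with `F` (n x 3, N) and `F_T` (signed per-triangle magnitude, N).
#' @export
membrane_area_forces <- function(cell, V = cell$mesh$V, geom = NULL) {
  mesh <- cell$mesh
  g <- if (is.null(geom)) triangle_geometry(V, mesh$Tri) else geom
  A <- sum(g$area)
  F_T <- cell$params$k_mem * (A - mesh$A0) / mesh$A0
  Ftri <- -g$normal * F_T / 3
  n <- nrow(V)
  F <- accumulate_nodes_mat(mesh$Tri[, 1], Ftri, n) +
    accumulate_nodes_mat(mesh$Tri[, 2], Ftri, n) +
    accumulate_nodes_mat(mesh$Tri[, 3], Ftri, n)
  list(F = F, F_T = F_T)
}

# ---- diagnostics -------------------------------------------------------------

#' Virial in-plane stress per node
#'
#' `sigma_i = (sqrt(3)/N_i) sum_j F_int,ij / l_ij` over the `N_i` edges
#' incident on node i, with tensile edge forces positive. Used to color
#' membrane tension fields; compressed zones (e.g. the common adhesive plane
#' of a doublet) come out negative.
#'
#' @param cell a `dcm_cell`.
#' @param V optional deformed vertex positions.
#' @return numeric vector (Pa-like surface stress, N/m), one per node.
#' @export
virial_stress <- function(cell, V = cell$mesh$V) {
  ef <- elastic_edge_forces(cell, V)
  e <- cell$mesh$edges
  n <- nrow(V)
  ratio <- ef$tension / ef$length
  cnt <- tabulate(e[, 1], n) + tabulate(e[, 2], n)
  if (any(cnt == 0)) stop("isolated node: virial stress undefined")
  s <- accumulate_nodes(e[, 1], ratio, n) + accumulate_nodes(e[, 2], ratio, n)
  sqrt(3) * s / cnt
}

#' Arrhenius friction scaling with temperature
#'
#' `gamma(T)/gamma(T0) = exp((E_a/R) (1/T - 1/T0))`; applied multiplicatively
#' to the cortical friction coefficients while a laser heats the sample, and
#' restored instantly when it is off.
#'
#' @param T_now,T0 temperatures (K), > 0.
#' @param E_a activation energy (J/mol).
#' @param R_gas gas constant, J/(mol K).
#' @return dimensionless multiplier.
#' @export
arrhenius_scale <- function(T_now, T0 = 290, E_a = 55e3, R_gas = 8.314) {
  stopifnot(T_now > 0, T0 > 0)
  exp(E_a / R_gas * (1 / T_now - 1 / T0))
}
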