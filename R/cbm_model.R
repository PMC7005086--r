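# Center-based model: JKR pairwise forces, packing-dependent stiffness
# correction, and the CBM cell record.

#' JKR contact radius for a given overlap
#'
#' Solves `delta = a^2/Rhat - sqrt(2 pi W a / Ehat)` for the contact radius
#' `a` (largest, stable branch) by bracketed root finding. For `W = 0` this
#' reduces to the Hertz radius `sqrt(delta Rhat)`.
#'
#' @param delta geometric overlap `R_i + R_j - d_ij` (m); may be negative
#'   down to the detachment overlap when `W > 0`.
#' @param Ehat,Rhat reduced modulus (Pa) and radius (m).
#' @param W specific adhesion energy (J/m^2).
#' @return contact radius (m); `NA` below the detachment point.
#' @export
jkr_contact_radius <- function(delta, Ehat, Rhat, W = 0) {
  if (W <= 0) return(if (delta > 0) sqrt(delta * Rhat) else if (delta == 0) 0 else NA_real_)
  k <- sqrt(2 * pi * W / Ehat)
  f <- function(a) a^2 / Rhat - k * sqrt(a) - delta
  # stationary point of f: the turning point of the delta(a) relation
  a_c <- (Rhat * k / 4)^(2 / 3)
  delta_c <- f(a_c) + delta           # minimum attainable overlap
  if (delta < delta_c) return(NA_real_)
  a_w <- (k * Rhat)^(2 / 3)           # zero-overlap radius upper-bound seed
  hi <- 2 * sqrt(abs(delta) * Rhat) + 2 * a_w
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(a_c, hi), tol = 1e-3 * .Machine$double.eps^0.5 * a_w)$root
}

#' JKR detachment overlap
#'
#' The most negative overlap at which a JKR contact can exist; beyond it the
#' bond is broken.
#' @inheritParams jkr_contact_radius
#' @return overlap (m), negative for `W > 0`.
#' @export
jkr_detachment_overlap <- function(Ehat, Rhat, W) {
  if (W <= 0) return(0)
  k <- sqrt(2 * pi * W / Ehat)
  a_c <- (Rhat * k / 4)^(2 / 3)
  a_c^2 / Rhat - k * sqrt(a_c)
}

#' JKR interaction force between two adhesive elastic spheres
#'
#' `F = (4 Ehat / 3 Rhat) a^3 - sqrt(8 pi W Ehat a^3)` with the contact
#' radius from [jkr_contact_radius()]. Positive values are repulsive; the
#' most negative value over the adhesive branch is the pull-off force
#' `-(3/2) pi W Rhat`. Below the detachment overlap the force is zero
#' (broken bond).
#'
#' @param delta overlap `R_i + R_j - d_ij` (m).
#' @param E_i,nu_i,R_i,E_j,nu_j,R_j elastic moduli (Pa), Poisson ratios and
#'   radii (m) of the two bodies.
#' @param W specific adhesion energy (J/m^2).
#' @return list with `F` (N), `a` (contact radius, m), `detached` (logical).
#' @export
jkr_force <- function(delta, E_i, nu_i, R_i, E_j = Inf, nu_j = 0, R_j = Inf,
                      W = 0) {
  red <- reduced_pair(E_i, nu_i, E_j, nu_j, R_i, R_j)
  a <- jkr_contact_radius(delta, red$Ehat, red$Rhat, W)
  if (is.na(a)) return(list(F = 0, a = NA_real_, detached = TRUE))
  F <- 4 * red$Ehat / (3 * red$Rhat) * a^3 - sqrt(8 * pi * W * red$Ehat * a^3)
  list(F = F, a = a, detached = FALSE)
}

# Universal dimensionless JKR curve. With a = (pi W Rhat^2 / Ehat)^(1/3) ahat
# and delta = (pi^2 W^2 Rhat / Ehat^2)^(1/3) dhat, the radius relation
# becomes dhat = ahat^2 - sqrt(2 ahat) independently of all parameters; the
# stable branch is tabulated once and inverted by interpolation.
.jkr_env <- new.env(parent = emptyenv())

jkr_universal <- function() {
  if (is.null(.jkr_env$inv)) {
    a_c <- (sqrt(2) / 4)^(2 / 3)                 # turning point of the branch
    ah <- exp(seq(log(a_c), log(200), length.out = 4000))
    dh <- ah^2 - sqrt(2 * ah)
    .jkr_env$inv <- stats::approxfun(dh, ah, rule = 2)
    .jkr_env$dhat_min <- dh[1]
  }
  .jkr_env
}

# vectorized JKR force over overlaps; adhesive branch where engaged, else
# repulsion-only Hertz. Positive force = repulsive.
jkr_force_vec <- function(delta, Ehat, Rhat, W, engaged = NULL) {
  n <- length(delta)
  if (length(Ehat) == 1) Ehat <- rep(Ehat, n)
  if (length(Rhat) == 1) Rhat <- rep(Rhat, n)
  if (length(W) == 1) W <- rep(W, n)
  if (is.null(engaged)) engaged <- rep(TRUE, n)
  Weff <- ifelse(engaged, W, 0)
  Fout <- numeric(n)
  aout <- numeric(n)
  # Hertz part (no adhesion)
  hz <- Weff <= 0 & delta > 0
  if (any(hz)) {
    aout[hz] <- sqrt(delta[hz] * Rhat[hz])
    Fout[hz] <- 4 / 3 * Ehat[hz] * sqrt(Rhat[hz]) * delta[hz]^1.5
  }
  ad <- Weff > 0
  if (any(ad)) {
    u <- jkr_universal()
    A0 <- (pi * Weff[ad] * Rhat[ad]^2 / Ehat[ad])^(1 / 3)
    D0 <- (pi^2 * Weff[ad]^2 * Rhat[ad] / Ehat[ad]^2)^(1 / 3)
    dhat <- delta[ad] / D0
    live <- dhat >= u$dhat_min
    a <- ifelse(live, A0 * u$inv(dhat), NA_real_)
    Fa <- ifelse(live,
                 4 * Ehat[ad] / (3 * Rhat[ad]) * a^3 -
                   sqrt(8 * pi * Weff[ad] * Ehat[ad] * a^3), 0)
    aout[ad] <- ifelse(live, a, 0)
    Fout[ad] <- Fa
  }
  list(F = Fout, a = aout)
}

#' Theoretical JKR pull-off force
#'
#' `F_p = -(3/2) pi W Rhat`.
#' @inheritParams jkr_contact_radius
#' @return force (N), negative (tensile).
#' @export
jkr_pulloff_force <- function(W, Rhat) -1.5 * pi * W * Rhat

#' Local packing measure of a center-based cell
#'
#' `dtilde_ij = 1 - d_ij / (R_i + R_j)` for each of the N contacting
#' neighbors (cells and obstacles alike), averaged: `dtilde_i = sum/N`.
#' Zero without contacts.
#'
#' @param d_ij center distances to contacting neighbors (m).
#' @param R_i cell radius (m).
#' @param R_j neighbor radii (m).
#' @return scalar packing measure.
#' @export
packing_measure <- function(d_ij, R_i, R_j) {
  if (length(d_ij) == 0) return(0)
  mean(1 - d_ij / (R_i + R_j))
}

#' Packing-corrected apparent modulus
#'
#' `Etilde_i = a0 + a1 dtilde_i^4` with `a0 = E_i`; during the post-division
#' stiffness ramp `a1` is scaled linearly from 0 to its full value over
#' one tenth of the cell-cycle time.
#'
#' @param E_i baseline Young modulus (Pa).
#' @param dtilde packing measure (>= 0).
#' @param a1 quartic coefficient (Pa), default 4e6.
#' @param ramp fraction in `[0, 1]` of the post-division ramp completed
#'   (1 = full stiffness).
#' @return corrected modulus (Pa).
#' @export
corrected_modulus <- function(E_i, dtilde, a1 = 4e6, ramp = 1) {
  stopifnot(dtilde >= 0, a1 >= 0)
  E_i + ramp * a1 * dtilde^4
}

#' Construct a center-based (CBM) cell record
#'
#' The CBM Young modulus and Poisson ratio are tied to the DCM bulk modulus
#' through `E = K_V / (3 (1 - 2 nu))`; when `K_V` is supplied, `E` is derived
#' from it, otherwise the pair (`E`, `nu`) is used as given.
#'
#' @param center position (m).
#' @param R intrinsic radius (m).
#' @param E,nu elastic modulus (Pa) and Poisson ratio.
#' @param K_V optional DCM bulk modulus (Pa) from which to derive `E`.
#' @param W specific cell-cell adhesion energy (J/m^2).
#' @param tau cell-cycle time (s).
#' @param id integer identity.
#' @return list of class `cbm_cell` with intrinsic volume `V0`, division
#'   ramp timer `t_div` (NA until a division) and motility state.
#' @export
cbm_cell <- function(center, R = 12e-6, E = 450, nu = 0.47, K_V = NULL,
                     W = 1e-5, tau = 24 * 3600, id = 1L) {
  stopifnot(R > 0)
  if (!is.null(K_V)) E <- K_V / (3 * (1 - 2 * nu))
  V0 <- 4 / 3 * pi * R^3
  structure(list(center = as.numeric(center), R = R, E = E, nu = nu, W = W,
                 V0 = V0, alpha = V0 / tau, V_crit = 2 * V0,
                 tau = tau, t_div = NA_real_, ramp_T = tau / 10,
                 growing = FALSE, leader = FALSE, id = as.integer(id)),
            class = "cbm_cell")
}

#' Contact handshake between a deformable and a center-based cell
#'
#' Every triangle of the DCM surface interacts with the CBM sphere through
#' the triangle-smooth-body Maugis-Dugdale contact; the net reaction is
#' applied at the CBM center, so the pair totals obey Newton's third law
#' exactly.
#'
#' @param dcm a `dcm_cell`.
#' @param cbm a `cbm_cell`.
#' @param W pair adhesion energy (default: mean of the two).
#' @return list with `F_dcm` (nodal forces), `F_cbm` (length-3 center
#'   force), `area` (per-node contact areas), `patches`.
#' @export
hybrid_pair <- function(dcm, cbm, W = NULL) {
  if (is.null(W)) W <- (dcm$contact$W + cbm$W) / 2
  res <- cell_body_contact(dcm, list(type = "sphere", center = cbm$center,
                                     R = cbm$R, E = cbm$E, nu = cbm$nu, W = W))
  list(F_dcm = res$F, F_cbm = res$body_force, area = res$area,
       patches = res$patches)
}

#' @export
print.cbm_cell <- function(x, ...) {
  cat(sprintf("cbm_cell #%d: R=%.2f um, E=%.0f Pa, V0=%.3g um^3\n",
              x$id, x$R * 1e6, x$E, x$V0 * 1e18))
  invisible(x)
}
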