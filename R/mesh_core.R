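#' @useDynLib cellmech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif optimize uniroot setNames
#' @importFrom utils modifyList write.csv read.csv
NULL

# ---- basic triangle geometry -------------------------------------------------

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(m) sqrt(rowSums(m * m))

#' Per-triangle normals, areas and barycenters
#'
#' @param V numeric matrix of vertex positions (n x 3, metres).
#' @param Tri integer matrix of triangle vertex indices (f x 3, 1-based,
#'   consistently outward-oriented).
#' @return list with `normal` (unit outward normals, f x 3), `area` (f),
#'   `bary` (f x 3). Degenerate (zero-area) triangles get a zero normal.
#' @keywords internal
triangle_geometry <- function(V, Tri) {
  p1 <- V[Tri[, 1], , drop = FALSE]
  p2 <- V[Tri[, 2], , drop = FALSE]
  p3 <- V[Tri[, 3], , drop = FALSE]
  cr <- vec_cross(p2 - p1, p3 - p1)
  a2 <- row_norm(cr)
  n <- cr
  ok <- a2 > 0
  n[ok, ] <- cr[ok, , drop = FALSE] / a2[ok]
  n[!ok, ] <- 0
  list(normal = n, area = a2 / 2, bary = (p1 + p2 + p3) / 3)
}

# ---- TriMesh construction ----------------------------------------------------

#' Build a closed triangulated surface with topology and reference geometry
#'
#' Computes the unique edge list, hinge (adjacent-triangle) list with
#' spontaneous angles, rest lengths, rest triangle areas, reference area and
#' reference volume from a vertex/triangle representation. The mesh must be a
#' closed, consistently outward-oriented 2-manifold.
#'
#' @param V vertex positions, n x 3 matrix (m).
#' @param Tri triangle indices, f x 3 integer matrix (1-based).
#' @return an object of class `trimesh`: a list with fields `V`, `Tri`,
#'   `edges` (e x 2, i < j), `l0` (rest lengths), `hinges` (e x 6 matrix with
#'   columns `i, j, k, l, t1, t2`: edge nodes, the two apex nodes, the two
#'   adjacent triangles), `theta0` (spontaneous hinge angles, rad),
#'   `A0_tri` (rest triangle areas), `A0` (reference area), `V0` (reference
#'   volume).
#' @export
build_trimesh <- function(V, Tri) {
  V <- as.matrix(V)
  storage.mode(Tri) <- "integer"
  if (ncol(V) != 3L || ncol(Tri) != 3L) stop("V must be n x 3 and Tri f x 3")
  nf <- nrow(Tri)
  # directed half-edges (a -> b) per triangle corner
  ha <- c(Tri[, 1], Tri[, 2], Tri[, 3])
  hb <- c(Tri[, 2], Tri[, 3], Tri[, 1])
  hop <- c(Tri[, 3], Tri[, 1], Tri[, 2])  # opposite (apex) vertex
  htri <- rep.int(seq_len(nf), 3L)
  lo <- pmin(ha, hb)
  hi <- pmax(ha, hb)
  key <- paste(lo, hi)
  dup <- duplicated(key)
  ekey <- key[!dup]
  edges <- cbind(lo[!dup], hi[!dup])
  eid <- match(key, ekey)
  cnt <- tabulate(eid, nbins = nrow(edges))
  if (any(cnt != 2L)) {
    stop("mesh is not a closed 2-manifold: every edge must be shared by exactly two triangles")
  }
  fwd <- ha < hb  # directed half-edge runs from the smaller to the larger index
  if (any(tabulate(eid[fwd], nbins = nrow(edges)) != 1L)) {
    stop("inconsistent triangle orientation")
  }
  ne <- nrow(edges)
  t1 <- k1 <- t2 <- k2 <- integer(ne)
  t1[eid[fwd]] <- htri[fwd]; k1[eid[fwd]] <- hop[fwd]
  t2[eid[!fwd]] <- htri[!fwd]; k2[eid[!fwd]] <- hop[!fwd]
  hinges <- cbind(i = edges[, 1], j = edges[, 2], k = k1, l = k2, t1 = t1, t2 = t2)
  geo <- triangle_geometry(V, Tri)
  vol <- enclosed_volume_vt(V, Tri)
  if (vol <= 0) stop("signed enclosed volume must be positive (outward orientation)")
  l0 <- row_norm(V[edges[, 2], , drop = FALSE] - V[edges[, 1], , drop = FALSE])
  if (any(l0 <= 0)) stop("rest lengths must be strictly positive")
  m <- structure(list(
    V = V, Tri = Tri, edges = edges, l0 = l0,
    hinges = hinges, theta0 = numeric(ne),
    A0_tri = geo$area, A0 = sum(geo$area), V0 = vol
  ), class = "trimesh")
  m$theta0 <- hinge_angles(m)
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d edges, %d triangles\n",
              nrow(x$V), nrow(x$edges), nrow(x$Tri)))
  cat(sprintf("  area %.4g m^2, volume %.4g m^3 (reference %.4g / %.4g)\n",
              surface_area(x), enclosed_volume(x), x$A0, x$V0))
  invisible(x)
}

#' Signed hinge (dihedral) angles
#'
#' The angle between the unit normals of the two triangles adjacent to each
#' edge, signed by the orientation of `n1 x n2` relative to the edge
#' direction. Zero for coplanar triangles, positive on a convex outward mesh.
#'
#' @param mesh a `trimesh`.
#' @param V optional vertex matrix overriding `mesh$V` (same topology).
#' @return numeric vector of angles (rad), one per hinge/edge.
#' @export
hinge_angles <- function(mesh, V = mesh$V, geom = NULL) {
  g <- if (is.null(geom)) triangle_geometry(V, mesh$Tri) else geom
  h <- mesh$hinges
  n1 <- g$normal[h[, "t1"], , drop = FALSE]
  n2 <- g$normal[h[, "t2"], , drop = FALSE]
  e <- V[h[, "j"], , drop = FALSE] - V[h[, "i"], , drop = FALSE]
  e <- e / row_norm(e)
  s <- rowSums(vec_cross(n1, n2) * e)
  c_ <- rowSums(n1 * n2)
  atan2(s, c_)
}

# ---- icosphere ---------------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  V <- V / sqrt(1 + phi^2)
  Tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(V = V, Tri = Tri)
}

#' Build an icosphere cell surface
#'
#' Subdivide-then-project construction: each subdivision level splits every
#' triangle into four (midpoint insertion with vertex de-duplication) and
#' projects new vertices onto the sphere. Level 2 gives the 162-node and
#' level 3 the 642-node discretizations used for cell surfaces.
#'
#' @param radius sphere radius (m), > 0.
#' @param level subdivision count (integer >= 0); vertex count is
#'   `10 * 4^level + 2`.
#' @param center sphere center, length-3 (m).
#' @return a [build_trimesh()] `trimesh` with reference geometry taken from
#'   the built sphere.
#' @export
build_icosphere <- function(radius, level = 2L, center = c(0, 0, 0)) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  level <- as.integer(level)
  if (is.na(level) || level < 0L) stop("level must be a non-negative integer")
  ic <- icosahedron()
  V <- ic$V; Tri <- ic$Tri
  for (s in seq_len(level)) {
    nf <- nrow(Tri)
    a <- Tri[, 1]; b <- Tri[, 2]; c3 <- Tri[, 3]
    ep <- rbind(cbind(a, b), cbind(b, c3), cbind(c3, a))
    key <- paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2]))
    ukey <- unique(key)
    mididx <- nrow(V) + match(key, ukey)
    firsts <- match(ukey, key)
    mids <- (V[ep[firsts, 1], , drop = FALSE] + V[ep[firsts, 2], , drop = FALSE]) / 2
    mids <- mids / row_norm(mids)
    V <- rbind(V, mids)
    mab <- mididx[seq_len(nf)]
    mbc <- mididx[nf + seq_len(nf)]
    mca <- mididx[2 * nf + seq_len(nf)]
    Tri <- rbind(cbind(a, mab, mca), cbind(mab, b, mbc),
                 cbind(mca, mbc, c3), cbind(mab, mbc, mca))
  }
  V <- V * radius
  V <- sweep(V, 2, center, "+")
  build_trimesh(V, Tri)
}

# ---- integral quantities -----------------------------------------------------

enclosed_volume_vt <- function(V, Tri) {
  orig <- colMeans(V)
  p1 <- sweep(V[Tri[, 1], , drop = FALSE], 2, orig)
  p2 <- sweep(V[Tri[, 2], , drop = FALSE], 2, orig)
  p3 <- sweep(V[Tri[, 3], , drop = FALSE], 2, orig)
  sum(rowSums(vec_cross(p1, p2) * p3)) / 6
}

#' Enclosed volume of a closed oriented mesh
#'
#' Signed sum of tetrahedra spanned by each triangle and a fixed origin
#' (taken at the vertex centroid, which makes the sum translation-invariant
#' to round-off). Positive for outward orientation.
#'
#' @param mesh a `trimesh`.
#' @param V optional vertex matrix overriding `mesh$V`.
#' @return volume (m^3).
#' @export
enclosed_volume <- function(mesh, V = mesh$V) enclosed_volume_vt(V, mesh$Tri)

#' Total surface area of a mesh
#'
#' @inheritParams enclosed_volume
#' @return area (m^2); zero-area triangles contribute 0 with a warning.
#' @export
surface_area <- function(mesh, V = mesh$V) {
  g <- triangle_geometry(V, mesh$Tri)
  if (any(g$area == 0)) warning("degenerate zero-area triangle(s) contribute 0")
  sum(g$area)
}

# ---- node areas and curvature ------------------------------------------------

accumulate_nodes <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s
  out
}

accumulate_nodes_mat <- function(idx, vals, n) {
  out <- matrix(0, n, 3)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s)), ] <- s
  out
}

corner_cotangents <- function(V, Tri) {
  p1 <- V[Tri[, 1], , drop = FALSE]
  p2 <- V[Tri[, 2], , drop = FALSE]
  p3 <- V[Tri[, 3], , drop = FALSE]
  cot_at <- function(a, b, c) {
    u <- b - a; v <- c - a
    rowSums(u * v) / pmax(row_norm(vec_cross(u, v)), .Machine$double.xmin)
  }
  cbind(cot_at(p1, p2, p3), cot_at(p2, p3, p1), cot_at(p3, p1, p2))
}

#' Node Voronoi region areas (mixed Voronoi scheme)
#'
#' Cotangent (circumcentric) Voronoi areas with the standard barycentric
#' fallback for obtuse triangles: an obtuse triangle assigns half its area to
#' the obtuse corner and a quarter to each of the others. The areas always
#' partition the total surface area exactly.
#'
#' @inheritParams enclosed_volume
#' @return numeric vector `S_i` (m^2), one per node; `sum(S) == surface_area`.
#' @export
node_voronoi_areas <- function(mesh, V = mesh$V) {
  Tri <- mesh$Tri
  n <- nrow(V)
  cot <- corner_cotangents(V, Tri)
  p <- list(V[Tri[, 1], , drop = FALSE], V[Tri[, 2], , drop = FALSE],
            V[Tri[, 3], , drop = FALSE])
  l2 <- cbind(rowSums((p[[2]] - p[[3]])^2),   # edge opposite corner 1
              rowSums((p[[3]] - p[[1]])^2),
              rowSums((p[[1]] - p[[2]])^2))
  area <- triangle_geometry(V, Tri)$area
  obtuse <- cot < 0                       # corner angle > pi/2
  anyobt <- rowSums(obtuse) > 0
  # circumcentric contribution of triangle t to corner c:
  #   (l_b^2 cot_b + l_c^2 cot_c) / 8 over the two edges incident to c
  w <- matrix(0, nrow(Tri), 3)
  w[, 1] <- (l2[, 2] * cot[, 2] + l2[, 3] * cot[, 3]) / 8
  w[, 2] <- (l2[, 3] * cot[, 3] + l2[, 1] * cot[, 1]) / 8
  w[, 3] <- (l2[, 1] * cot[, 1] + l2[, 2] * cot[, 2]) / 8
  # exact partition per triangle: rescale tiny numerical drift, then replace
  # obtuse triangles by the barycentric 1/2, 1/4, 1/4 split
  tw <- w[, 1] + w[, 2] + w[, 3]
  ok <- !anyobt & tw > 0
  w[ok, ] <- w[ok, , drop = FALSE] * (area[ok] / tw[ok])
  if (any(anyobt)) {
    idx <- which(anyobt)
    wa <- matrix(area[idx] / 4, length(idx), 3)
    om <- obtuse[idx, , drop = FALSE]
    wa[om] <- matrix(area[idx] / 2, length(idx), 3)[om]
    w[idx, ] <- wa
  }
  accumulate_nodes(as.vector(Tri), as.vector(w), n)
}

#' Per-node curvature radii and curvature normals
#'
#' Discrete mean-curvature normal from the cotangent Laplace-Beltrami
#' operator; the radius is `R_i = 2 / |K_i|` so that a sphere of radius R
#' returns R at every node. Radii are clamped to `[r_min, r_max]` (defaults
#' 0.1 and 10 times the radius of the volume-equivalent sphere), keeping
#' contact radii finite on flat or degenerate patches.
#'
#' @inheritParams enclosed_volume
#' @param r_min,r_max clamp bounds (m); `NULL` for the defaults.
#' @return list with `radius` (per node, m), `normal` (unit outward curvature
#'   normals, n x 3), `tri_radius` (per triangle: mean of its three node
#'   radii), `clamped` (logical per node).
#' @export
curvature_radii <- function(mesh, V = mesh$V, r_min = NULL, r_max = NULL,
                            S = NULL) {
  Tri <- mesh$Tri
  n <- nrow(V)
  r_ref <- (3 * mesh$V0 / (4 * pi))^(1 / 3)
  if (is.null(r_min)) r_min <- 0.1 * r_ref
  if (is.null(r_max)) r_max <- 10 * r_ref
  if (is.null(S)) S <- node_voronoi_areas(mesh, V)
  cot <- corner_cotangents(V, Tri)
  # cotangent Laplacian: K_i = (1/(2 S_i)) sum_j (cot a + cot b) (x_i - x_j)
  # assembled per triangle corner pair; edge opposite corner c gets cot[, c]
  K <- matrix(0, n, 3)
  pair <- function(a, b, copp) {
    d <- V[Tri[, a], , drop = FALSE] - V[Tri[, b], , drop = FALSE]
    w <- cot[, copp]
    K <<- K + accumulate_nodes_mat(Tri[, a], d * w, n)
    K <<- K + accumulate_nodes_mat(Tri[, b], -d * w, n)
  }
  pair(1, 2, 3); pair(2, 3, 1); pair(3, 1, 2)
  K <- K / (2 * pmax(S, .Machine$double.xmin))
  # for an outward-oriented sphere this K points inward; flip to outward
  K <- -K
  kn <- row_norm(K)
  geo <- triangle_geometry(V, Tri)
  nrm_node <- accumulate_nodes_mat(as.vector(Tri), geo$normal[rep(seq_len(nrow(Tri)), 3), ], n)
  nn <- row_norm(nrm_node)
  nrm_node <- nrm_node / pmax(nn, .Machine$double.xmin)
  normal <- K
  ok <- kn > 0
  normal[ok, ] <- K[ok, , drop = FALSE] / kn[ok]
  normal[!ok, ] <- nrm_node[!ok, , drop = FALSE]
  # fall back to the angle-averaged face normal where the curvature normal
  # is unreliable (flips sign on saddle/flat regions)
  flip <- rowSums(normal * nrm_node) < 0
  normal[flip, ] <- nrm_node[flip, , drop = FALSE]
  radius <- ifelse(kn > 0, 2 / kn, Inf)
  clamped <- radius < r_min | radius > r_max | !is.finite(radius)
  radius <- pmin(pmax(radius, r_min), r_max)
  tri_radius <- (radius[Tri[, 1]] + radius[Tri[, 2]] + radius[Tri[, 3]]) / 3
  list(radius = radius, normal = normal, tri_radius = tri_radius,
       clamped = clamped, S = S)
}
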