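# Programmatic fixtures: small closed meshes and helper assertions.

# internal helpers exercised directly by the tests
row_norm <- cellmech:::row_norm
maugis_lhs <- cellmech:::maugis_lhs
jkr_force_vec <- cellmech:::jkr_force_vec
elastic_edge_forces <- cellmech:::elastic_edge_forces
lesion_area_fraction <- cellmech:::lesion_area_fraction
min_surface_gap <- cellmech:::min_surface_gap
triangle_geometry <- cellmech:::triangle_geometry
cpp_pair_contact <- cellmech:::cpp_pair_contact
cpp_dcm_forces <- cellmech:::cpp_dcm_forces

# unit cube as 12 outward-oriented triangles
make_cube_mesh <- function(side = 1) {
  V <- side * rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  Tri <- rbind(
    c(1, 3, 2), c(1, 4, 3),      # bottom (z = 0), outward -z
    c(5, 6, 7), c(5, 7, 8),      # top
    c(1, 2, 6), c(1, 6, 5),      # front (y = 0)
    c(2, 3, 7), c(2, 7, 6),      # right
    c(3, 4, 8), c(3, 8, 7),      # back
    c(4, 1, 5), c(4, 5, 8))      # left
  build_trimesh(V, Tri)
}

# flat fan of 6 equilateral triangles around a central node (open surface;
# only used for the area-partition scheme, wrapped in a bare trimesh shell)
make_flat_fan <- function(s = 1) {
  ang <- (0:5) * pi / 3
  V <- rbind(c(0, 0, 0), cbind(s * cos(ang), s * sin(ang), 0))
  Tri <- cbind(1L, 2:7, c(3:7, 2L))
  structure(list(V = V, Tri = Tri), class = "trimesh")
}

# relaxed adhering DCM doublet used by several contact tests (cached per run)
.doublet_env <- new.env(parent = emptyenv())
relaxed_doublet <- function(W = 1e-5, R = 10e-6, level = 2, steps = 800) {
  key <- paste(W, R, level, steps)
  if (!is.null(.doublet_env[[key]])) return(.doublet_env[[key]])
  sc <- new_scene(dt = 0.02, seed = 1, medium = "area",
                  gamma_medium_area = 1e8)
  sc <- scene_add(sc, dcm_cell(build_icosphere(R, level),
                               contact = contact_params(W = W)))
  sc <- scene_add(sc, dcm_cell(build_icosphere(R, level,
                                               center = c(2 * R - 0.4e-6, 0, 0)),
                               contact = contact_params(W = W)))
  sc <- simulate_scene(sc, steps)
  .doublet_env[[key]] <- sc
  sc
}
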