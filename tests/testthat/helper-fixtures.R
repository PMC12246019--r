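# Shared fixtures, all generated in code at test time.

# two bone slabs separated by a suture of `wvox` voxels along the
# anteroposterior axis (axis 3)
slab_model_ap <- function(wvox = 4L, vs = 50, side = 20L) {
  d <- c(side, side, 10L + wvox + 10L)
  lab <- array(0L, d)
  lab[, , 1:10] <- 1L
  lab[, , (10 + wvox + 1):(10 + wvox + 10)] <- 2L
  lab[, , (10 + 1):(10 + wvox)] <- 3L
  labeled_volume(lab, vs, c(`1` = "bone", `2` = "bone", `3` = "suture"))
}

# hollow voxelised sphere (labels: 1 = shell), optional polar opening
hollow_sphere <- function(r_in, t, vs = 1000, hole_deg = 0,
                          second_hole = FALSE) {
  R <- r_in + t
  d <- as.integer(2 * (R + 3))
  cc <- (seq_len(d) - 0.5) - d / 2
  x <- array(cc, c(d, d, d))
  y <- array(rep(cc, each = d), c(d, d, d))
  z <- array(rep(cc, each = d * d), c(d, d, d))
  r <- sqrt(x^2 + y^2 + z^2)
  lab <- array(0L, c(d, d, d))
  lab[r >= r_in & r <= R] <- 1L
  if (hole_deg > 0) {
    lab[z / pmax(r, 1e-9) > cos(hole_deg * pi / 180)] <- 0L
    if (second_hole)
      lab[-z / pmax(r, 1e-9) > cos(hole_deg * pi / 180)] <- 0L
  }
  labeled_volume(lab, vs, c(`1` = "bone"))
}

make_alignment <- function(R = diag(3), t = c(0, 0, 0), label = NULL) {
  structure(list(R = R, t = t, rms = 0, iterations = 0, label = label),
            class = "bone_alignment")
}

# uniform bar/beam voxel mesh: nx x ny x nz cells of pitch h_mm
bar_mesh <- function(nx, ny, nz, h_mm) {
  v <- labeled_volume(array(1L, c(nx, ny, nz)), h_mm * 1000,
                      c(`1` = "bone"))
  tetrahedralize(v, max_size = Inf)
}

uniform_mats <- function(E, nu = 0.3) {
  material_set(young = c(bone = E, suture = E, brain = E), poisson = nu)
}

# FE-scale phantom shared by the heavier tests; memoised per session
fe_phantom_cache <- new.env(parent = emptyenv())
fe_phantom <- function() {
  if (is.null(fe_phantom_cache$model)) {
    sp <- phantom_spec(outer_radius = 1500, shell_thickness = 300,
                       gap_width = 225, n_plates = 4, voxel_size = 75)
    model <- build_phantom_model(sp, morph = morph_params(2, 2, 3, 1, 3))
    mesh <- phantom_mesh(model, coarsen = 2L)
    fe_phantom_cache$model <- model
    fe_phantom_cache$mesh <- mesh
  }
  list(model = fe_phantom_cache$model, mesh = fe_phantom_cache$mesh)
}

# node index lookup on the tet-mesh corner lattice
lattice_match <- function(points, mesh) {
  h <- mesh$h
  key <- function(M) paste(round(M[, 1] / h), round(M[, 2] / h),
                           round(M[, 3] / h))
  match(key(points), key(mesh$nodes))
}
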