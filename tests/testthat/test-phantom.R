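test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(outer_radius = 100, shell_thickness = 200),
               "outer_radius")
  expect_error(phantom_spec(gap_width = -1), "gap_width")
  expect_error(phantom_spec(n_plates = 1), "n_plates")
  expect_error(generate_phantom(
    phantom_spec(outer_radius = 300, shell_thickness = 250, gap_width = 200,
                 n_plates = 16, voxel_size = 25)),
    "degenerate plate")
})

test_that("plates are present, 26-disconnected across gaps, and deterministic", {
  sp <- phantom_spec(outer_radius = 1000, shell_thickness = 200,
                     gap_width = 100, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  expect_setequal(bone_labels(v), 1:4)
  expect_true(all(1:4 %in% v$labels))
  bl <- v$labels
  bl[!(bl %in% 1:4)] <- 0L
  comp <- suturemech:::cpp_label_components(array(bl > 0, dim(bl)),
                                            dim(bl), 26L)
  expect_identical(max(comp), 4L)
  # determinism
  v2 <- generate_phantom(sp)
  expect_identical(v$labels, v2$labels)
})

test_that("zero gap leaves plates in face contact", {
  sp <- phantom_spec(outer_radius = 800, shell_thickness = 200,
                     gap_width = 0, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  lab <- v$labels
  touching <- FALSE
  for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    sh <- suturemech:::shift3(lab, o[1], o[2], o[3])
    touching <- touching ||
      any(lab %in% 1:4 & sh %in% 1:4 & sh > 0L & lab != sh)
  }
  expect_true(touching)
})

test_that("physical extent equals voxel count times voxel size", {
  sp <- phantom_spec(outer_radius = 500, shell_thickness = 150,
                     gap_width = 50, n_plates = 2, voxel_size = 9.5)
  v <- generate_phantom(sp)
  extent <- dim(v$labels) * v$voxel_size
  # the volume contains the whole phantom with its margin, at 9.5 um pitch
  expect_true(all(extent >= 2 * sp$outer_radius))
  expect_true(all(extent <= 2 * (sp$outer_radius + 4 * 9.5)))
  expect_identical(v$voxel_size, 9.5)
})

test_that("loaded pair: identity transforms give bit-identical surfaces and
           stored transforms reproduce the loaded state exactly", {
  sp <- phantom_spec(outer_radius = 1000, shell_thickness = 250,
                     gap_width = 100, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  ctr <- attr(v, "centre")
  tr <- list(`1` = rigid_transform(0),
             `2` = rigid_transform(0, translation = c(50, 0, 20)),
             `3` = rigid_transform(10, axis = c(1, 0, 0), centre = ctr),
             `4` = rigid_transform(0))
  pair <- generate_loaded_pair(v, ground_truth_deformation(tr))
  i1 <- which(pair$unloaded$vertex_region == 1)
  expect_identical(pair$unloaded$vertices[i1, ], pair$loaded$vertices[i1, ])
  # ground-truth closure < 1e-9 um
  for (b in 2:3) {
    ib <- which(pair$unloaded$vertex_region == b)
    tb <- tr[[as.character(b)]]
    x <- pair$unloaded$vertices[ib, ] * 1000
    y <- sweep(x %*% t(tb$R), 2, tb$t, `+`) / 1000
    expect_lt(max(abs(y - pair$loaded$vertices[ib, ])) * 1000, 1e-9)
  }
  # missing transform errors
  expect_error(generate_loaded_pair(v, ground_truth_deformation(tr[1:3])),
               "missing transform")
})

test_that("translating a plate along the suture normal opens the gap by
           exactly the prescribed amount", {
  sp <- phantom_spec(outer_radius = 1000, shell_thickness = 250,
                     gap_width = 100, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  # plate boundary at angle phi: translate plate 2 (centred at theta = 0)
  # outward along +ml; measure min distance between plate 1 and plate 2
  # vertices before/after
  delta_um <- 120
  tr <- list(`1` = rigid_transform(0),
             `2` = rigid_transform(0, translation = c(0, 0, 0)),
             `3` = rigid_transform(0), `4` = rigid_transform(0))
  pair0 <- generate_loaded_pair(v, ground_truth_deformation(tr))
  # plate 2 sits around theta = 0 (+ml); its boundaries are diagonal, so
  # translate along the boundary-plane normal (-sin(phi), 0, cos(phi)) with
  # phi = -pi/4
  phi <- -pi / 4
  nvec <- c(-sin(phi), 0, cos(phi))
  tr$`2` <- rigid_transform(0, translation = delta_um * nvec)
  pair1 <- generate_loaded_pair(v, ground_truth_deformation(tr))
  d_of <- function(p) {
    a <- p$loaded$vertices[p$loaded$vertex_region == 1, ]
    b <- p$loaded$vertices[p$loaded$vertex_region == 2, ]
    # distance along the gap normal between the facing vertex sets
    sa <- a %*% nvec
    sb <- b %*% nvec
    min(sb) - max(sa)
  }
  expect_equal(d_of(pair1) - d_of(pair0), delta_um / 1000, tolerance = 1e-12)
})

test_that("gap stack realises the requested per-slice profile", {
  v <- generate_gap_stack(95, 9.5, 200)
  gt <- attr(v, "gap_truth")
  expect_true(all(gt$distance_um == 95))
  expect_error(generate_gap_stack(c(10, -5)), "must be >= 0")
  # zeros give fused (touching) slices
  vf <- generate_gap_stack(0, 9.5, 20)
  sl <- vf$labels[1, , ]
  expect_true(any(sl == 1L & cbind(sl[, -1], 0L) == 2L))
  # ramp: realised truth is monotone and within a voxel of the request
  ramp <- seq(9.5, 190, length.out = 200)
  vr <- generate_gap_stack(ramp, 9.5, 200)
  gtr <- attr(vr, "gap_truth")
  expect_true(all(diff(gtr$distance_um) >= 0))
  expect_lt(max(abs(gtr$distance_um - ramp)), 9.5 + 1e-9)
})
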