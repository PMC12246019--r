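test_that("ICP on identical surfaces returns the identity at machine
           precision", {
  sp <- phantom_spec(outer_radius = 1000, shell_thickness = 250,
                     gap_width = 100, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  surf <- extract_surface(v, region_labels = 1L)
  al <- align_bone(surf$vertices, surf$vertices)
  expect_lt(al$rms, 1e-9)
  expect_lt(max(abs(al$R - diag(3))), 1e-9)
  expect_lt(max(abs(al$t)), 1e-9)
})

test_that("ICP recovers known per-bone translations and rotations", {
  sp <- phantom_spec(outer_radius = 1200, shell_thickness = 250,
                     gap_width = 150, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  ctr <- attr(v, "centre")
  tr <- list(`1` = rigid_transform(0),
             `2` = rigid_transform(0, translation = c(50, 0, 20)),
             `3` = rigid_transform(10, axis = c(1, 0, 0), centre = ctr),
             `4` = rigid_transform(0))
  pair <- generate_loaded_pair(v, ground_truth_deformation(tr))
  # translation within 1e-4 mm
  i2 <- which(pair$unloaded$vertex_region == 2)
  a2 <- align_bone(pair$unloaded$vertices[i2, ], pair$loaded$vertices[i2, ])
  expect_lt(max(abs(a2$t - c(0.05, 0, 0.02))), 1e-4)
  # 10-degree rotation within 0.1 degree
  i3 <- which(pair$unloaded$vertex_region == 3)
  a3 <- align_bone(pair$unloaded$vertices[i3, ], pair$loaded$vertices[i3, ])
  tr3 <- tr[["3"]]
  ang_err <- acos(pmin(1, (sum(diag(t(a3$R) %*% tr3$R)) - 1) / 2)) * 180 / pi
  expect_lt(ang_err, 0.1)
})

test_that("non-overlapping surfaces are rejected", {
  set.seed(1)
  P <- matrix(runif(600), ncol = 3)
  Q <- P + 100
  expect_error(align_bone(P, Q), "do not overlap")
  expect_error(align_bone(P[1:10, ], Q), "at least 100 vertices")
})

test_that("prescribed normal opening is recovered as e1 ~ delta/width over
           strain magnitudes 0.3 to 4, and identity gives zero", {
  m <- slab_model_ap(4, vs = 50)
  w_mm <- 4 * 50 / 1000
  for (ratio in c(0.3, 1, 4)) {
    al <- list(`1` = make_alignment(label = 1),
               `2` = make_alignment(t = c(0, 0, ratio * w_mm), label = 2))
    rep <- estimate_suture_strain(m, al)
    expect_gt(rep$e1, 0.9 * ratio)
    expect_lt(rep$e1, 1.1 * ratio)
    expect_lt(rep$e3, 0)            # lateral contraction, sign-consistent
    expect_gt(rep$von_mises, 0)
  }
  al0 <- list(`1` = make_alignment(label = 1),
              `2` = make_alignment(label = 2))
  rep0 <- estimate_suture_strain(m, al0)
  expect_lt(max(abs(c(rep0$von_mises, rep0$e1, rep0$e3))), 1e-9)
})

test_that("pure tangential slide behaves as simple shear: e1 ~ gamma/2 and
           e1 ~ -e3", {
  m <- slab_model_ap(4, vs = 50)
  w_mm <- 0.2
  al <- list(`1` = make_alignment(label = 1),
             `2` = make_alignment(t = c(w_mm, 0, 0), label = 2))
  rep <- estimate_suture_strain(m, al)
  expect_gt(rep$von_mises, 0)
  expect_lt(abs(rep$e1 - 0.5), 0.05)
  expect_lt(abs(rep$e1 + rep$e3), 0.1 * rep$e1)
})

test_that("the report is invariant to a rigid motion shared by all bones", {
  m <- slab_model_ap(4, vs = 50)
  al <- list(`1` = make_alignment(label = 1),
             `2` = make_alignment(t = c(0, 0, 0.2), label = 2))
  rep1 <- estimate_suture_strain(m, al)
  Q <- rigid_transform(25, axis = c(1, 2, 0.5))$R
  tq <- c(0.3, -0.1, 0.2)
  al2 <- lapply(al, function(a)
    make_alignment(Q %*% a$R, as.numeric(Q %*% a$t) + tq, a$label))
  rep2 <- estimate_suture_strain(m, al2)
  expect_lt(max(abs(c(rep1$von_mises - rep2$von_mises,
                      rep1$e1 - rep2$e1, rep1$e3 - rep2$e3))), 1e-6)
})

test_that("a suture with fewer than two aligned bones is rejected", {
  m <- slab_model_ap(4)
  expect_error(estimate_suture_strain(m, list(`1` = make_alignment(label = 1))),
               "fewer than 2 aligned bones")
})

test_that("Green-Lagrange mode reports finite-strain values above the
           infinitesimal ones for a large opening", {
  m <- slab_model_ap(4, vs = 50)
  al <- list(`1` = make_alignment(label = 1),
             `2` = make_alignment(t = c(0, 0, 0.8), label = 2))  # ratio 4
  inf <- estimate_suture_strain(m, al, measure = "infinitesimal")
  gl <- estimate_suture_strain(m, al, measure = "green")
  expect_gt(gl$e1, inf$e1)   # lambda + lambda^2/2 > lambda
})

test_that("strains estimated from FE-deformed surfaces with near-rigid bones
           match the FE per-suture averages", {
  vs <- 50
  d <- c(16, 24, 16)
  lab <- array(0L, d)
  lab[, 1:10, ] <- 1L
  lab[, 15:24, ] <- 2L
  lab[, 11:14, ] <- 3L
  m <- labeled_volume(lab, vs, c(`1` = "bone", `2` = "bone", `3` = "suture"))
  mesh <- tetrahedralize(m, max_size = Inf)
  E_s <- 0.03
  sys <- fem_assemble(mesh, material_set(
    young = c(bone = 1e4 * E_s, suture = E_s, brain = 1)))
  n <- mesh$nodes
  sys <- fix_dofs(sys, which(n[, 2] < 1e-9), dofs = 1:3)
  bf <- tet_boundary_faces(mesh)
  topf <- bf[apply(matrix(n[bf, 2], nrow(bf)), 1, min) > 1.2 - 1e-9, ]
  sys <- apply_traction(sys, topf, c(0, 0.001, 0))
  res <- fem_solve(sys)
  fe <- suture_average(res, mesh, 3L)
  surf <- extract_surface(m, region_labels = c(1L, 2L))
  vi <- lattice_match(surf$vertices, mesh)
  loaded <- surf
  loaded$vertices <- surf$vertices + res$u[vi, ]
  als <- lapply(c(`1` = 1L, `2` = 2L), function(b) {
    ib <- which(surf$vertex_region == b)
    align_bone(surf$vertices[ib, ], loaded$vertices[ib, ], label = b)
  })
  est <- estimate_suture_strain(m, als)
  expect_lt(abs(est$von_mises - fe["von_mises"]) / fe["von_mises"], 0.2)
  expect_lt(abs(est$e1 - fe["e1"]) / abs(fe["e1"]), 0.2)
  expect_lt(abs(est$e3 - fe["e3"]) / abs(fe["e3"]), 0.2)
})
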