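test_that("unit cases of label dilation", {
  lab <- array(0L, c(9, 9, 9))
  lab[4:6, 4:6, 4:6] <- 1L
  v <- labeled_volume(lab, 10, c(`1` = "bone"))
  expect_identical(dilate_labels(v, 0)$labels, lab)      # n = 0 identity
  expect_identical(sum(dilate_labels(v, 1)$labels == 1L), 125L)
})

test_that("two bones 4 voxels apart meet under 5 rounds with a single
           contact sheet and no double assignment", {
  lab <- array(0L, c(30, 10, 10))
  lab[1:10, , ] <- 1L
  lab[15:24, , ] <- 2L
  v <- labeled_volume(lab, 50, c(`1` = "bone", `2` = "bone"))
  ex <- dilate_labels(v, 5)
  # each voxel carries one label; originals unchanged
  expect_true(all(ex$labels[lab > 0L] == lab[lab > 0L]))
  ct <- detect_contacts(ex)
  expect_true(any(ct))
  comp <- suturemech:::cpp_label_components(ct, dim(ct), 26L)
  expect_identical(max(comp), 1L)  # a single sheet spans the former gap
})

test_that("dilation and majority smoothing match the brute-force per-voxel
           oracles on random volumes", {
  set.seed(20260915)
  for (rep in 1:20) {
    d <- sample(12:28, 3, replace = TRUE)
    lab <- array(0L, d)
    nseed <- sample(5:40, 1)
    lab[sample(prod(d), nseed)] <- sample(1:5, nseed, replace = TRUE)
    roles <- structure(rep("bone", 5), names = as.character(1:5))
    v <- labeled_volume(lab, 10, roles)
    n <- sample(1:3, 1)
    out <- dilate_labels(v, n)
    ref <- suturemech:::cpp_dilate_brute(lab, d, n)
    expect_identical(out$labels, ref$labels)
    expect_identical(attr(out, "ties"), ref$ties)
    # majority filter on a random mask
    m <- array(stats::runif(prod(d)) > 0.5, d)
    r <- sample(1:2, 1)
    mine <- 2 * suturemech:::boxsum3(m, r) > suturemech:::boxwin3(d, r)
    expect_identical(mine, suturemech:::cpp_majority_brute(m, d, r))
  }
})

test_that("contact detection needs bones and is empty for a single label", {
  lab <- array(0L, c(8, 8, 8)); lab[3:5, 3:5, 3:5] <- 1L
  v <- labeled_volume(lab, 10, c(`1` = "bone"))
  expect_false(any(detect_contacts(dilate_labels(v, 1))))
  v2 <- labeled_volume(lab, 10, c(`1` = "suture"))
  expect_error(detect_contacts(v2), "no bone labels")
})

test_that("three plates meeting at a line produce a triple-junction contact", {
  d <- c(21, 21, 6)
  lab <- array(0L, d)
  cc <- seq_len(21) - 11
  x <- array(cc, d); y <- array(rep(cc, each = 21), d)
  th <- atan2(y, x)
  sector <- (floor((th + pi) / (2 * pi / 3)) %% 3) + 1L
  keep <- sqrt(x^2 + y^2) > 2.2   # leave a gap column at the junction
  lab[keep] <- sector[keep]
  v <- labeled_volume(lab, 10, c(`1` = "bone", `2` = "bone", `3` = "bone"))
  ct <- detect_contacts(dilate_labels(v, 3))
  # contact mask reaches the junction axis
  expect_true(any(ct[10:12, 10:12, ]))
})

test_that("majority smoothing: identity at radius 0, half-space fixed point,
           protrusion removal, bone protection", {
  lab <- array(0L, c(11, 11, 11))
  lab[, , 1:5] <- 2L
  lab[6, 6, 7] <- 2L       # isolated protruding voxel
  lab[1, 1, 11] <- 1L      # a bone voxel elsewhere
  v <- labeled_volume(lab, 10, c(`1` = "bone", `2` = "suture"))
  expect_identical(smooth_label(v, 2, 0)$labels, lab)
  s <- smooth_label(v, 2, 1)
  expect_identical(s$labels[6, 6, 7], 0L)             # protrusion gone
  expect_true(all(s$labels[, , 1:5] == 2L))           # plane unchanged
  expect_identical(s$labels[1, 1, 11], 1L)            # bone preserved
  expect_error(smooth_label(v, 9, 1), "unknown label")
})

test_that("suture synthesis bridges gaps, preserves bones, and respects the
           original background", {
  sp <- phantom_spec(outer_radius = 1000, shell_thickness = 250,
                     gap_width = 150, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  m <- synthesize_sutures(v, morph_params(2, 2, 3, 1, 3))
  sl <- labels_of_role(m, "suture")
  expect_length(sl, 1)
  expect_true(all(m$labels[v$labels > 0L] == v$labels[v$labels > 0L]))
  expect_true(all(v$labels[m$labels == sl] == 0L))
  # every adjacent plate pair is connected through {boneA, suture, boneB}
  lab <- m$labels
  for (pr in list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))) {
    keep <- array(lab %in% c(pr, sl), dim(lab))
    reach <- suturemech:::cpp_flood_fill(keep, dim(lab),
                                         which(lab == pr[1])[1], 6L)
    expect_true(any(reach[lab == pr[2]]))
  }
})

test_that("suture voxel count is monotone in suture_expand and grow", {
  sp <- phantom_spec(outer_radius = 800, shell_thickness = 200,
                     gap_width = 100, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  count <- function(p) {
    m <- synthesize_sutures(v, p)
    sum(m$labels == labels_of_role(m, "suture"))
  }
  c_base <- count(morph_params(2, 1, 2, 0, 2))
  expect_gte(count(morph_params(2, 2, 2, 0, 2)), c_base)
  expect_gte(count(morph_params(2, 1, 2, 1, 2)), c_base)
})

test_that("bones far beyond the expansion reach raise a disjoint-model error
           naming the separation", {
  lab <- array(0L, c(40, 12, 12))
  lab[1:10, , ] <- 1L
  lab[26:40, , ] <- 2L   # 15 voxels apart, 2 x 5 < 15
  v <- labeled_volume(lab, 50, c(`1` = "bone", `2` = "bone"))
  expect_error(synthesize_sutures(v, morph_params()), "disjoint model")
})

test_that("plates in direct contact yield a thin carved suture sheet when
           requested", {
  sp <- phantom_spec(outer_radius = 800, shell_thickness = 200,
                     gap_width = 0, n_plates = 4, voxel_size = 50)
  v <- generate_phantom(sp)
  m <- synthesize_sutures(v, morph_params(2, 2, 3, 1, 3),
                          carve_contact = TRUE)
  sl <- labels_of_role(m, "suture")
  expect_gt(sum(m$labels %in% sl), 0)
})

test_that("suture splitting attributes voxels to bone pairs and merges
           junction slivers", {
  m <- split_sutures(slab_model_ap(4))
  pairs <- attr(m, "suture_pairs")
  expect_identical(nrow(pairs), 1L)
  expect_identical(c(pairs$bone_a, pairs$bone_b), c(1L, 2L))
  sp <- phantom_spec(outer_radius = 1000, shell_thickness = 250,
                     gap_width = 150, n_plates = 4, voxel_size = 50)
  mp <- split_sutures(synthesize_sutures(generate_phantom(sp),
                                         morph_params(2, 2, 3, 1, 3)))
  pp <- attr(mp, "suture_pairs")
  adj <- paste(pp$bone_a, pp$bone_b)
  # all four adjacent plate-plate sutures are recovered, with no
  # opposite-plate (junction sliver) pairs left
  expect_true(all(c("1 2", "2 3", "3 4", "1 4") %in% adj))
  expect_false(any(c("1 3", "2 4") %in% adj))
})
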