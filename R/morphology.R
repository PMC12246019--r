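#' Morphological parameters of the suture-synthesis recipe
#'
#' Defaults are tuned for 9.5 um micro-CT segmentations of neonatal mouse
#' skulls:
#' bones expanded 5 voxels, contact voxels assigned to sutures and expanded
#' 5 voxels, then one smooth (9) / grow (1) / smooth (9) pass applied to the
#' suture segment only. All counts are in voxels; "expansion of n voxels"
#' means n iterations of unit dilation with a 3x3x3 (Chebyshev) structuring
#' element, and "smoothing of r voxels" means a strict-majority filter over
#' the (2r+1)^3 window.
#'
#' Smoothing counts are kernel \emph{sizes} (window edge lengths in
#' voxels, as in interactive segmentation tools), so a smoothing of 9
#' voxels majority-filters over the 9x9x9 window (radius 4).
#'
#' @param bone_expand,suture_expand,smooth_a,grow,smooth_b voxel counts
#' @export
morph_params <- function(bone_expand = 5L, suture_expand = 5L,
                         smooth_a = 9L, grow = 1L, smooth_b = 9L) {
  p <- list(bone_expand = as.integer(bone_expand),
            suture_expand = as.integer(suture_expand),
            smooth_a = as.integer(smooth_a), grow = as.integer(grow),
            smooth_b = as.integer(smooth_b))
  if (any(unlist(p) < 0)) stop("all morphological parameters must be >= 0")
  structure(p, class = "morph_params")
}

#' Grow labels into background with contact (tie) detection
#'
#' Performs \code{n} synchronous rounds of unit Chebyshev dilation of the
#' selected labels into background. A background voxel reachable in one
#' round from exactly one distinct label takes that label; a voxel reachable
#' from two or more distinct labels is assigned to neither and becomes a
#' permanent \emph{tie} voxel (these are the contact voxels later assigned
#' to sutures). Original label voxels are never modified.
#'
#' @param vol a \code{labeled_volume}
#' @param n number of dilation rounds
#' @param labels labels allowed to grow (default: all nonzero labels);
#'   other labels act as fixed obstacles
#' @return the dilated \code{labeled_volume}, with the logical tie-voxel
#'   array attached as attribute \code{"ties"}
#' @export
dilate_labels <- function(vol, n, labels = NULL) {
  stopifnot(inherits(vol, "labeled_volume"), n >= 0)
  cur <- vol$labels
  d <- dim(cur)
  ties <- array(FALSE, d)
  if (n > 0) {
    if (is.null(labels)) labels <- as.integer(names(vol$roles))
    offs <- neighbour_offsets_26()
    for (round in seq_len(n)) {
      gl <- cur
      gl[!(gl %in% labels)] <- 0L
      if (!any(gl > 0L)) break
      bg <- cur == 0L & !ties
      claim <- array(0L, d)
      conflict <- array(FALSE, d)
      for (o in seq_len(nrow(offs))) {
        sh <- shift3(gl, offs[o, 1], offs[o, 2], offs[o, 3])
        upd <- bg & sh > 0L
        conflict <- conflict | (upd & claim > 0L & claim != sh)
        take <- upd & claim == 0L
        claim[take] <- sh[take]
      }
      ties <- ties | conflict
      assign <- claim > 0L & !conflict
      cur[assign] <- claim[assign]
    }
  }
  out <- labeled_volume(cur, vol$voxel_size, vol$roles)
  attr(out, "ties") <- ties
  out
}

neighbour_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

#' Contact voxels between expanded bones
#'
#' The contact mask is the union of the tie voxels recorded during
#' dilation (claimed simultaneously by two or more bones) and all voxels
#' sitting on a face between two distinct bone labels (these arise when two
#' fronts meet exactly across an even-width gap, leaving no tie voxel).
#'
#' @param vol_expanded output of \code{\link{dilate_labels}}
#' @param labels labels participating in contact detection (default: the
#'   bone labels)
#' @return logical 3-D contact mask
#' @export
detect_contacts <- function(vol_expanded, labels = NULL) {
  stopifnot(inherits(vol_expanded, "labeled_volume"))
  if (is.null(labels)) labels <- bone_labels(vol_expanded)
  bones <- labels
  if (length(bones) == 0) stop("no bone labels present")
  lab <- vol_expanded$labels
  bl <- lab
  bl[!(bl %in% bones)] <- 0L
  mask <- attr(vol_expanded, "ties")
  if (is.null(mask)) mask <- array(FALSE, dim(lab))
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    sh <- shift3(bl, o[1], o[2], o[3])
    mask <- mask | (bl > 0L & sh > 0L & bl != sh)
  }
  mask
}

#' Majority-filter smoothing of one label
#'
#' Replaces the label's binary mask with its strict-majority filter over the
#' clipped \code{(2*radius+1)^3} window. The filter only ever modifies
#' voxels that currently carry the label or are background, so bone (and
#' every other label) is preserved; additions are clipped to background.
#' A flat half-space is a fixed point of the filter.
#'
#' @param vol a \code{labeled_volume}
#' @param label the label to smooth
#' @param radius window radius in voxels
#' @export
smooth_label <- function(vol, label, radius) {
  stopifnot(inherits(vol, "labeled_volume"), radius >= 0)
  lab <- vol$labels
  if (!(label %in% lab)) stop("unknown label: ", label)
  if (radius == 0) return(vol)
  mask <- lab == label
  maj <- 2 * boxsum3(mask, radius) > boxwin3(dim(lab), radius)
  lab[mask & !maj] <- 0L
  add <- maj & lab == 0L
  lab[add] <- as.integer(label)
  out <- labeled_volume(lab, vol$voxel_size, vol$roles)
  attributes(out) <- c(attributes(out),
                       attributes(vol)[setdiff(names(attributes(vol)),
                                               names(attributes(out)))])
  out
}

#' Synthesise sutures between disarticulated bones
#'
#' Implements the morphological recipe that turns a fully disarticulated
#' bone segmentation into a bone-plus-suture model: (1) expand the bones by
#' \code{bone_expand} voxels, (2) take the contact voxels between expanded
#' bones as the initial suture, (3) expand the suture by
#' \code{suture_expand} voxels, clipped to the original background so the
#' suture never extrudes over bone, (4) smooth / grow / smooth the suture
#' segment only with radii \code{smooth_a}, \code{grow}, \code{smooth_b}.
#' The bone expansion is scaffolding: bones are restored to their original
#' extent afterwards (set \code{restore_bones = FALSE} to keep them).
#'
#' Bones that start in direct contact leave no background to host a suture;
#' with \code{carve_contact = TRUE} the facing voxel layers of such contacts
#' are reassigned to the suture (a thin interface sheet), at the price of
#' modifying those bone voxels.
#'
#' Sutures are confined to the skull hull — the morphological closing of
#' the bone mask with radius \code{bone_expand + suture_expand + grow} —
#' so that they follow the shape of the skull instead of flaring into the
#' cranial cavity or the exterior along the open ends of a gap.
#'
#' @param vol a \code{labeled_volume} with >= 2 bone labels
#' @param p a \code{\link{morph_params}}
#' @param restore_bones restore bones to their pre-expansion extent?
#' @param carve_contact carve a suture sheet where bones touch directly?
#' @return a \code{labeled_volume} with one added suture label (role
#'   \code{"suture"}); the contact mask is attached as attribute
#'   \code{"contacts"}
#' @export
synthesize_sutures <- function(vol, p = morph_params(),
                               restore_bones = TRUE, carve_contact = FALSE) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(p, "morph_params"))
  bones <- bone_labels(vol)
  if (length(bones) < 2) stop("need at least 2 bone labels")
  # constraint patches are bone tissue reserved for fixation: they expand
  # and detect contacts like any other plate
  hard <- c(bones, labels_of_role(vol, "constraint"))
  orig_bg <- vol$labels == 0L
  ex <- dilate_labels(vol, p$bone_expand, labels = hard)
  contacts <- detect_contacts(ex, labels = hard)
  if (!any(contacts)) {
    extra <- 0L
    probe <- ex
    while (!any(contacts) && extra < 4L * p$bone_expand + 10L) {
      probe <- dilate_labels(probe, 1L, labels = hard)
      contacts <- detect_contacts(probe, labels = hard)
      extra <- extra + 1L
    }
    stop("disjoint model: no bone contacts after ", p$bone_expand,
         " expansion rounds; nearest bone pair is about ",
         2L * (p$bone_expand + extra),
         " voxels apart")
  }
  bonemask <- array(vol$labels %in% hard, dim(vol$labels))
  hull_r <- p$bone_expand + p$suture_expand + p$grow
  hull <- erode_mask(dilate_mask(bonemask, hull_r), hull_r)
  allowed <- orig_bg & hull
  suture <- contacts & allowed
  if (p$suture_expand > 0)
    suture <- dilate_mask(suture, p$suture_expand) & allowed
  # smoothing votes the solid phase (suture + bone) against open
  # background, so a suture pinned between bone faces is never carved out
  # while flares protruding into free space are trimmed; counts are kernel
  # sizes (window edge lengths), as in interactive segmentation tools
  smooth_mask <- function(m, size) {
    r <- size %/% 2
    if (r == 0) return(m)
    solid <- m | bonemask
    (2 * boxsum3(solid, r) > boxwin3(dim(m), r)) & allowed
  }
  suture <- smooth_mask(suture, p$smooth_a)
  if (p$grow > 0) suture <- dilate_mask(suture, p$grow) & allowed
  suture <- smooth_mask(suture, p$smooth_b)

  lab <- if (restore_bones) vol$labels else ex$labels
  sl <- max(as.integer(names(vol$roles))) + 1L
  lab[suture & lab == 0L] <- sl
  if (carve_contact) {
    bl <- vol$labels
    bl[!(bl %in% bones)] <- 0L
    touch <- array(FALSE, dim(bl))
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      sh <- shift3(bl, o[1], o[2], o[3])
      touch <- touch | (bl > 0L & sh > 0L & bl != sh)
    }
    lab[touch] <- sl
  }
  roles <- c(vol$roles, structure("suture", names = as.character(sl)))
  out <- labeled_volume(lab, vol$voxel_size, roles)
  attributes(out) <- c(attributes(out),
                       attributes(vol)[setdiff(names(attributes(vol)),
                                               names(attributes(out)))])
  attr(out, "contacts") <- contacts
  out
}

#' Split the suture label into one label per flanking bone pair
#'
#' Attributes every suture voxel to the pair of bones whose fronts reach it
#' first (multi-source breadth-first search seeded at the bone voxels and
#' restricted to the suture region), then relabels the suture into one
#' label per observed bone pair. Per-suture labels make the FE per-suture
#' strain averages and the strain-estimation report line up by suture.
#'
#' Junction slivers — voxels where three or more plates meet and whose
#' nominal pair covers only a tiny fraction of the suture volume — are
#' merged into the neighbouring suture whose front reaches them first.
#'
#' @param vol a \code{labeled_volume} containing a suture label
#' @param min_fraction pairs smaller than this fraction of the total
#'   suture volume are merged into a neighbouring pair
#' @return a \code{labeled_volume} whose suture labels are named by bone
#'   pair; the pair table is attached as attribute \code{"suture_pairs"}
#'   (columns label, bone_a, bone_b)
#' @export
split_sutures <- function(vol, min_fraction = 0.01) {
  stopifnot(inherits(vol, "labeled_volume"))
  sut <- labels_of_role(vol, "suture")
  if (length(sut) == 0) stop("no suture label present")
  lab <- vol$labels
  smask <- array(lab %in% sut, dim(lab))
  hard <- c(bone_labels(vol), labels_of_role(vol, "constraint"))
  bl <- lab
  bl[!(bl %in% hard)] <- 0L
  two <- cpp_first_two_ids(bl, smask, dim(lab), 26L)
  a <- pmin(two$id1, two$id2)[smask]
  b <- pmax(two$id1, two$id2)[smask]
  # voxels reached by a single front inherit that bone on both slots
  single <- a == 0L
  a[single] <- b[single]
  pair_key <- as.numeric(a) * 100000 + as.numeric(b)
  counts <- table(pair_key)
  small <- as.numeric(names(counts))[counts < min_fraction * length(pair_key)]
  # a self-pair (one flanking bone) is a sliver whatever its size
  selfkeys <- as.numeric(names(counts))
  selfkeys <- selfkeys[selfkeys %/% 100000 == selfkeys %% 100000]
  small <- union(small, selfkeys)
  if (length(small) && length(small) < length(counts)) {
    seeds <- array(0L, dim(lab))
    sidx <- which(smask)
    big <- !(pair_key %in% small)
    seeds[sidx[big]] <- match(pair_key[big], sort(unique(pair_key[big])))
    near <- cpp_nearest_seed(seeds, smask, dim(lab), 26L)
    bigkeys <- sort(unique(pair_key[big]))
    nr <- near[sidx[!big]]
    pair_key[!big] <- ifelse(nr > 0, bigkeys[pmax(nr, 1L)], pair_key[!big])
  }
  keys <- sort(unique(pair_key))
  base <- max(as.integer(names(vol$roles)))
  new_lab <- base + match(pair_key, keys)
  lab[smask] <- as.integer(new_lab)
  pairs <- data.frame(label = base + seq_along(keys),
                      bone_a = as.integer(keys %/% 100000),
                      bone_b = as.integer(keys %% 100000))
  roles <- vol$roles[!(names(vol$roles) %in% as.character(sut))]
  roles <- c(roles, structure(rep("suture", nrow(pairs)),
                              names = as.character(pairs$label)))
  out <- labeled_volume(lab, vol$voxel_size, roles)
  attributes(out) <- c(attributes(out),
                       attributes(vol)[setdiff(names(attributes(vol)),
                                               names(attributes(out)))])
  attr(out, "suture_pairs") <- pairs
  out
}
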