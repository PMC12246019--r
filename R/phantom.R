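#' Phantom specification
#'
#' Parameters of the synthetic calvaria phantom: a thin spherical shell of
#' bone plates separated by micrometre-scale planar gaps (sutures), with an
#' enclosed cavity standing in for the intracranial volume and two reserved
#' constraint patches standing in for the anterior (incisor-contact) and
#' posterior-ventral (basioccipital) fixation sites. All lengths are in
#' micrometres.
#'
#' The default geometry is a ~4 mm dome with a 250 um shell and 120 um
#' suture gaps voxelised at 30 um (4 voxels per gap), a desk-scale stand-in
#' for a neonatal mouse calvaria.
#'
#' @param outer_radius outer shell radius, um
#' @param shell_thickness shell thickness, um (< outer_radius)
#' @param gap_width inter-plate (suture) gap width, um
#' @param n_plates number of bone plates (>= 2)
#' @param voxel_size voxel edge length, um
#' @param cavity keep the interior empty (endocast cavity)?
#' @param seed integer seed carried for reproducibility bookkeeping (the
#'   construction itself is deterministic)
#' @return object of class \code{phantom_spec}
#' @export
phantom_spec <- function(outer_radius = 2000, shell_thickness = 250,
                         gap_width = 120, n_plates = 4, voxel_size = 30,
                         cavity = TRUE, seed = 1L) {
  if (!(outer_radius > shell_thickness && shell_thickness > 0))
    stop("need outer_radius > shell_thickness > 0")
  if (gap_width < 0) stop("gap_width must be >= 0")
  if (n_plates < 2) stop("n_plates must be >= 2")
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  structure(list(outer_radius = outer_radius,
                 shell_thickness = shell_thickness,
                 gap_width = gap_width, n_plates = as.integer(n_plates),
                 voxel_size = voxel_size, cavity = isTRUE(cavity),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic disarticulated calvaria volume
#'
#' Voxelises a spherical shell partitioned into \code{n_plates} wedge-shaped
#' bone plates by half-planes containing the dorsoventral axis; the plates
#' are separated by planar gaps of width \code{gap_width}. Two constraint
#' patches (anterior and posterior-ventral) are carved out of the shell as
#' reserved labels with role \code{"constraint"}. Labels 1..n_plates are the
#' bones; labels n_plates+1 and n_plates+2 are the anterior and
#' posterior-ventral patches.
#'
#' The construction guarantees that for \code{gap_width >= 2 * voxel_size}
#' no two plates are 26-connected across a gap, and that the gap width is
#' analytically known, which is what makes the downstream suture-synthesis
#' and strain tests exact.
#'
#' @param spec a \code{phantom_spec}
#' @return a \code{labeled_volume}; the spec, the physical centre (um) and
#'   the gap-plane angles are attached as attributes
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size
  R <- spec$outer_radius; th <- spec$shell_thickness
  n <- spec$n_plates; gap <- spec$gap_width
  delta <- 2 * pi / n
  if (gap >= 2 * (R - th) * sin(delta / 2))
    stop("degenerate plate: gap_width (", gap,
         " um) is not smaller than the plate angular extent")
  half <- R + 3 * vs
  d <- as.integer(ceiling(2 * half / vs))
  dims <- c(d, d, d)
  centre <- d / 2 * vs
  cc <- (seq_len(d) - 0.5) * vs - centre    # voxel-centre coordinate
  ml <- array(cc, dims)
  dv <- array(rep(cc, each = d), dims)
  ap <- array(rep(cc, each = d * d), dims)
  r2 <- ml^2 + dv^2 + ap^2
  shell <- if (spec$cavity) r2 <= R^2 & r2 >= (R - th)^2 else r2 <= R^2
  # wedge index from azimuth in the mediolateral-anteroposterior plane;
  # boundaries are offset half a wedge so the +/- anteroposterior poles fall
  # mid-plate (keeps the constraint patches inside single plates for n = 4)
  theta <- atan2(ap, ml)
  plate <- (floor((theta + pi - delta / 2) / delta) %% n) + 1L
  gapmask <- array(FALSE, dims)
  bound <- -pi + (seq_len(n) - 0.5) * delta
  if (gap > 0) {
    for (phi in bound) {
      dperp <- abs(-sin(phi) * ml + cos(phi) * ap)
      s <- cos(phi) * ml + sin(phi) * ap
      gapmask <- gapmask | (dperp < gap / 2 & s > 0)
    }
  }
  labels <- array(0L, dims)
  keep <- shell & !gapmask
  labels[keep] <- plate[keep]
  # constraint patches carved out of the shell: an anterior (+AP) cap for
  # the incisor-contact analogue, and a ventral polar cap for the
  # cranial-base (basioccipital) fixation — the ventral cap grounds every
  # plate, so that bones deform under load the way base-anchored calvarial
  # bones do instead of floating on their sutures
  # patches are solid bone: the suture gaps do not cut through them (the
  # cranial base is one continuous ossification)
  r <- sqrt(pmax(r2, .Machine$double.eps))
  alpha_a <- min(15, 90 / n) * pi / 180
  ant <- shell & (ap / r > cos(alpha_a))
  pv <- shell & (-dv / r > cos(25 * pi / 180))
  labels[ant] <- n + 1L
  labels[pv] <- n + 2L
  roles <- c(rep("bone", n), "constraint", "constraint")
  names(roles) <- as.character(seq_len(n + 2L))
  present <- sort(unique(as.vector(labels)))
  roles <- roles[names(roles) %in% as.character(setdiff(present, 0L))]
  vol <- labeled_volume(labels, vs, roles)
  attr(vol, "spec") <- spec
  attr(vol, "centre") <- rep(centre, 3)
  attr(vol, "gap_planes") <- bound
  vol
}

#' Ground-truth rigid deformation of a phantom
#'
#' A proper rigid transform (rotation + translation, micrometres, acting on
#' physical voxel coordinates) per bone label. Used to manufacture
#' loaded/unloaded surface pairs with exactly known relative motion.
#'
#' @param transforms named list (names = bone labels); each element a list
#'   with \code{R} (3x3 rotation) and \code{t} (length-3 translation, um)
#' @param opening optional named nominal per-suture opening, um
#' @param width optional named nominal per-suture width, um
#' @export
ground_truth_deformation <- function(transforms, opening = NULL, width = NULL) {
  if (is.null(names(transforms)) || any(names(transforms) == ""))
    stop("transforms must be named by bone label")
  for (nm in names(transforms)) {
    tr <- transforms[[nm]]
    if (!is.matrix(tr$R) || any(dim(tr$R) != 3) || length(tr$t) != 3)
      stop("transform for label ", nm, " must have a 3x3 R and length-3 t")
    if (max(abs(crossprod(tr$R) - diag(3))) > 1e-8 || det(tr$R) < 0)
      stop("transform for label ", nm,
           " is not a proper rigid rotation (orthonormal, det +1)")
  }
  if (!is.null(width) && any(width <= 0)) stop("nominal width must be > 0")
  structure(list(transforms = transforms, opening = opening, width = width),
            class = "ground_truth_deformation")
}

#' Build a rigid transform from an axis-angle rotation about a point
#'
#' @param angle_deg rotation angle in degrees
#' @param axis rotation axis (length 3; need not be unit)
#' @param centre point the rotation pivots about (um); defaults to origin
#' @param translation additional translation (um)
#' @return list with components \code{R} and \code{t} suitable for
#'   \code{\link{ground_truth_deformation}}
#' @export
rigid_transform <- function(angle_deg = 0, axis = c(1, 0, 0),
                            centre = c(0, 0, 0), translation = c(0, 0, 0)) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  t <- as.numeric(centre - R %*% centre + translation)
  list(R = R, t = t)
}

#' Unloaded/loaded surface pair with known per-bone rigid motion
#'
#' Extracts the boundary surface of every bone plate and applies the stored
#' per-bone rigid transform to produce the loaded state. Per-bone vertex
#' correspondence between the two surfaces is retained (identical vertex
#' ordering), so the ground-truth motion can be recovered exactly.
#'
#' @param vol a \code{labeled_volume} (phantom)
#' @param gt a \code{ground_truth_deformation} covering every bone label
#' @return list with \code{unloaded} and \code{loaded} (both
#'   \code{surface_mesh}, region id = bone label, coordinates mm)
#' @export
generate_loaded_pair <- function(vol, gt) {
  stopifnot(inherits(vol, "labeled_volume"),
            inherits(gt, "ground_truth_deformation"))
  bones <- bone_labels(vol)
  missing <- setdiff(as.character(bones), names(gt$transforms))
  if (length(missing))
    stop("missing transform for bone label(s): ",
         paste(missing, collapse = ", "))
  unloaded <- extract_surface(vol, region_labels = bones)
  loaded <- unloaded
  for (b in bones) {
    tr <- gt$transforms[[as.character(b)]]
    idx <- which(loaded$vertex_region == b)
    x_um <- loaded$vertices[idx, , drop = FALSE] * 1000
    y_um <- sweep(x_um %*% t(tr$R), 2, tr$t, "+")
    loaded$vertices[idx, ] <- y_um / 1000
  }
  list(unloaded = unloaded, loaded = loaded, gt = gt)
}

#' Two-plate stack with a prescribed per-slice gap profile
#'
#' Builds a fixture for the slice-wise suture-gap measurement: two flat bone
#' slabs whose dorsal edges face each other across the anteroposterior axis,
#' with the centre-to-centre dorsal-edge separation in each mediolateral
#' slice following \code{gap_profile} (um). A profile value of zero makes
#' the slabs touch (fused slice). The realised per-slice ground truth is
#' attached as attribute \code{"gap_truth"}.
#'
#' @param gap_profile per-slice gap, um; recycled to \code{n_slices}
#' @param voxel_size voxel edge, um
#' @param n_slices number of mediolateral slices
#' @export
generate_gap_stack <- function(gap_profile, voxel_size = 9.5,
                               n_slices = 200L) {
  if (any(gap_profile < 0)) stop("gap profile values must be >= 0")
  g <- rep_len(gap_profile, n_slices)
  # centre-to-centre separation in voxels; >= 2 needed for a measurable gap,
  # 1 means face-adjacent (fused)
  sep <- ifelse(g == 0, 1L, pmax(2L, as.integer(round(g / voxel_size))))
  a_end <- 12L
  d3 <- a_end + max(sep) + 10L + 3L
  d2 <- 22L
  labels <- array(0L, c(n_slices, d2, d3))
  dvr <- 3:18  # flat slabs, common dorsal edge at dv = 18
  for (k in seq_len(n_slices)) {
    labels[k, dvr, 3:a_end] <- 1L
    labels[k, dvr, (a_end + sep[k]):(a_end + sep[k] + 9L)] <- 2L
  }
  vol <- labeled_volume(labels, voxel_size,
                        c(`1` = "bone", `2` = "bone"))
  attr(vol, "gap_truth") <- data.frame(
    slice = seq_len(n_slices),
    distance_um = ifelse(g == 0, 0, sep * voxel_size),
    fused = g == 0)
  vol
}
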