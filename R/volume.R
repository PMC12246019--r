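#' Labeled voxel volume
#'
#' The central container of the pipeline: a 3-D integer label grid with a
#' physical voxel size and a role for every nonzero label. Background is
#' always label 0. Roles classify labels as \code{"bone"}, \code{"suture"},
#' \code{"endocast"}, \code{"cover"} or \code{"constraint"}; downstream
#' stages (suture synthesis, endocast extraction, meshing, FE material
#' assignment) key off the role, never the raw label value.
#'
#' Axis convention, used everywhere in the package: axis 1 is mediolateral,
#' axis 2 is dorsoventral (larger index = more dorsal), axis 3 is
#' anteroposterior (larger index = more anterior). Physical coordinates are
#' \code{index * voxel_size} in micrometres, with the voxel-corner origin.
#'
#' @param labels 3-D integer array of label values, background 0.
#' @param voxel_size voxel edge length in micrometres (scalar > 0).
#' @param roles named character vector mapping each nonzero label (names are
#'   label values) to its role.
#' @return An object of class \code{labeled_volume}.
#' @export
labeled_volume <- function(labels, voxel_size, roles) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a positive scalar (micrometres)")
  storage.mode(labels) <- "integer"
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  role_names <- names(roles)
  roles <- as.character(roles)
  names(roles) <- role_names
  if (is.null(names(roles))) {
    if (length(roles) != length(present))
      stop("roles must be named by label when they do not match the ",
           "present labels one-to-one")
    names(roles) <- as.character(present)
  }
  known <- c("bone", "suture", "endocast", "cover", "constraint")
  if (!all(roles %in% known))
    stop("unknown role(s): ", paste(setdiff(roles, known), collapse = ", "))
  missing <- setdiff(as.character(present), names(roles))
  if (length(missing))
    stop("labels without a role: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 roles = roles),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("Labeled volume: ", paste(d, collapse = " x "),
      " voxels at ", x$voxel_size, " um\n", sep = "")
  tab <- table(factor(x$roles, levels = unique(x$roles)))
  for (r in names(tab))
    cat("  ", r, ": ", tab[[r]], " label(s)\n", sep = "")
  invisible(x)
}

#' Labels carrying a given role
#' @param vol a \code{labeled_volume}
#' @param role role name, e.g. \code{"bone"}
#' @return integer vector of label values (possibly empty)
#' @export
labels_of_role <- function(vol, role) {
  as.integer(names(vol$roles)[vol$roles == role])
}

#' @rdname labels_of_role
#' @export
bone_labels <- function(vol) labels_of_role(vol, "bone")

role_of_label <- function(vol, label) {
  r <- vol$roles[as.character(label)]
  ifelse(is.na(r), "background", r)
}

#' Write / read a labeled volume as NIfTI
#'
#' The voxel size is carried in the NIfTI header (pixdim, millimetres).
#' Roles are not representable in NIfTI and must be supplied on read.
#' @param vol a \code{labeled_volume}
#' @param path output file (.nii or .nii.gz)
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- rep(vol$voxel_size / 1000, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param roles role map for the labels found in the file
#' @export
read_volume <- function(path, roles) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1] * 1000
  labeled_volume(array(as.integer(img), dim = dim(img)), vs, roles)
}

# ---- internal array utilities ----

# Shift a 3-D array by (dx, dy, dz), filling vacated voxels with `fill`.
shift3 <- function(a, dx, dy, dz, fill = 0L) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src1 <- seq_len(d[1]) - dx; src2 <- seq_len(d[2]) - dy; src3 <- seq_len(d[3]) - dz
  k1 <- src1 >= 1 & src1 <= d[1]
  k2 <- src2 >= 1 & src2 <= d[2]
  k3 <- src3 >= 1 & src3 <= d[3]
  out[which(k1), which(k2), which(k3)] <- a[src1[k1], src2[k2], src3[k3]]
  out
}

# Column-wise cumulative sums of a matrix in O(n) without apply().
col_cumsum <- function(m) {
  full <- cumsum(as.numeric(m))
  nr <- nrow(m); nc <- ncol(m)
  if (nc > 1L) {
    offs <- c(0, full[nr * seq_len(nc - 1L)])
    full <- full - rep(offs, each = nr)
  }
  matrix(full, nr, nc)
}

# Sliding-window sum along the first axis with window [i-r, i+r], clipped.
axis1_boxsum <- function(a, r) {
  d <- dim(a)
  m <- matrix(as.numeric(a), d[1], d[2] * d[3])
  cs <- rbind(0, col_cumsum(m))
  hi <- pmin(seq_len(d[1]) + r, d[1]) + 1L
  lo <- pmax(seq_len(d[1]) - r, 1L)
  out <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  array(out, dim = d)
}

# Box (Chebyshev-ball) sum over the clipped (2r+1)^3 window, separably.
boxsum3 <- function(a, r) {
  if (r == 0L) return(array(as.numeric(a), dim = dim(a)))
  out <- axis1_boxsum(a, r)
  out <- aperm(axis1_boxsum(aperm(out, c(2, 1, 3)), r), c(2, 1, 3))
  aperm(axis1_boxsum(aperm(out, c(3, 2, 1)), r), c(3, 2, 1))
}

# Clipped window volume at every voxel (denominator for border-aware filters).
boxwin3 <- function(d, r) {
  w <- function(n) pmin(seq_len(n) + r, n) - pmax(seq_len(n) - r, 1L) + 1
  outer(outer(w(d[1]), w(d[2])), w(d[3]))
}

# Binary Chebyshev dilation / erosion by radius r via box sums.
dilate_mask <- function(mask, r) {
  if (r == 0L) return(mask)
  boxsum3(mask, r) > 0.5
}

erode_mask <- function(mask, r) {
  if (r == 0L) return(mask)
  boxsum3(mask, r) > boxwin3(dim(mask), r) - 0.5
}

# Border voxel linear indices of a grid (flood-fill seeds for the exterior).
border_indices <- function(d) {
  a <- array(FALSE, dim = d)
  a[c(1, d[1]), , ] <- TRUE
  a[, c(1, d[2]), ] <- TRUE
  a[, , c(1, d[3])] <- TRUE
  which(a)
}
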