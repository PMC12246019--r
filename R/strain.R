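#' Rigid alignment of an unloaded bone surface to its loaded counterpart
#'
#' Point-to-point iterative closest point (ICP): nearest-neighbour
#' correspondences (k-d tree) followed by the closed-form rigid fit
#' (SVD/Kabsch), iterated until the RMS point distance changes by less
#' than \code{tol} mm or \code{max_iter} iterations. The recovered
#' transform maps unloaded coordinates to loaded coordinates (mm).
#'
#' @param unloaded,loaded \code{surface_mesh} objects (or n x 3 vertex
#'   matrices) of the same bone
#' @param max_iter iteration cap
#' @param tol RMS-change convergence tolerance, mm
#' @param sample maximum number of source vertices used (deterministic
#'   stride subsample)
#' @param label optional bone label carried into the result
#' @return object of class \code{bone_alignment} with rotation \code{R},
#'   translation \code{t} (mm), final \code{rms} and iteration count
#' @export
align_bone <- function(unloaded, loaded, max_iter = 200L, tol = 1e-6,
                       sample = 5000L, label = NULL) {
  P <- if (inherits(unloaded, "surface_mesh")) unloaded$vertices else unloaded
  Q <- if (inherits(loaded, "surface_mesh")) loaded$vertices else loaded
  if (nrow(P) < 100 || nrow(Q) < 100)
    stop("need at least 100 vertices per surface")
  Pfull <- P
  if (nrow(P) > sample)
    P <- P[seq(1, nrow(P), length.out = sample), , drop = FALSE]
  bbox <- apply(rbind(P, Q), 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  idx0 <- cpp_nn_index(P, Q)
  rms0 <- sqrt(mean(rowSums((Q[idx0, , drop = FALSE] - P)^2)))
  if (rms0 > diag_len / 2)
    stop("surfaces do not overlap (initial RMS ", signif(rms0, 4),
         " mm exceeds half the bounding-box diagonal)")
  init <- principal_axes_init(Pfull, Q, P)
  R <- init$R; tvec <- init$t
  rms_prev <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Pc <- sweep(P %*% t(R), 2, tvec, `+`)
    idx <- cpp_nn_index(Pc, Q)
    M <- Q[idx, , drop = FALSE]
    rms <- sqrt(mean(rowSums((M - Pc)^2)))
    fit <- kabsch(P, M)
    R <- fit$R; tvec <- fit$t
    if (abs(rms_prev - rms) < tol || iter >= max_iter) break
    rms_prev <- rms
  }
  Pc <- sweep(P %*% t(R), 2, tvec, `+`)
  rms <- sqrt(mean(rowSums((Q[cpp_nn_index(Pc, Q), , drop = FALSE] - Pc)^2)))
  structure(list(R = R, t = tvec, rms = rms, iterations = iter,
                 label = label),
            class = "bone_alignment")
}

#' @export
print.bone_alignment <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat("Bone alignment", if (!is.null(x$label)) paste0(" (label ", x$label, ")"),
      ": rotation ", signif(ang, 4), " deg, |t| = ",
      signif(sqrt(sum(x$t^2)), 4), " mm, RMS ", signif(x$rms, 4),
      " mm in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

# coarse initial alignment from centroids and covariance principal axes;
# the eigenvector sign ambiguity is resolved by nearest-neighbour RMS.
# Protects the ICP iteration from the lattice-offset local minima of
# staircase (voxel) surfaces.
principal_axes_init <- function(P, Q, Psub = P) {
  cp <- colMeans(P); cq <- colMeans(Q)
  ep <- eigen(stats::cov(P), symmetric = TRUE)$vectors
  eq <- eigen(stats::cov(Q), symmetric = TRUE)$vectors
  best <- list(R = diag(3), t = c(0, 0, 0))
  Pc <- Psub
  best_rms <- sqrt(mean(rowSums((Q[cpp_nn_index(Pc, Q), , drop = FALSE] -
                                   Pc)^2)))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  for (r in seq_len(nrow(signs))) {
    s <- as.numeric(signs[r, ])
    R0 <- eq %*% diag(s) %*% t(ep)
    if (det(R0) < 0) next
    t0 <- as.numeric(cq - R0 %*% cp)
    Pc <- sweep(Psub %*% t(R0), 2, t0, `+`)
    rms <- sqrt(mean(rowSums((Q[cpp_nn_index(Pc, Q), , drop = FALSE] -
                                Pc)^2)))
    if (rms < best_rms) { best_rms <- rms; best <- list(R = R0, t = t0) }
  }
  best
}

# closed-form least-squares rigid fit P -> Q (proper rotation enforced)
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

#' Estimate suture strain from per-bone rigid alignments
#'
#' Reconstructs the strain field inside each suture from the rigid motions
#' of its flanking bones: the suture region of the unloaded model is
#' tetrahedralized on its voxel lattice; every suture-mesh node adjacent to
#' a bone inherits that bone's displacement; interior nodes follow from a
#' linear-elastic solve with those Dirichlet boundaries (unit modulus —
#' the strain field is modulus-independent for pure Dirichlet data). Each
#' suture (bone pair) is solved in the frame of its first bone, i.e. with
#' the relative transforms A_a^{-1} A_c, which makes the report exactly
#' invariant to a rigid motion shared by all bones.
#'
#' @param model a \code{labeled_volume} with bone and suture labels
#' @param alignments list of \code{bone_alignment} objects (named by bone
#'   label, or carrying their label field)
#' @param measure \code{"infinitesimal"} (default) or \code{"green"}
#'   (Green-Lagrange) strain
#' @param poisson Poisson's ratio of the suture fill
#' @return object of class \code{suture_strain_report}: a data frame with
#'   one row per suture (bone pair) and volume-weighted average von Mises,
#'   1st and 3rd principal strains
#' @export
estimate_suture_strain <- function(model, alignments,
                                   measure = c("infinitesimal", "green"),
                                   poisson = 0.3) {
  measure <- match.arg(measure)
  stopifnot(inherits(model, "labeled_volume"))
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, function(a)
      as.character(a$label), character(1))
  sut <- labels_of_role(model, "suture")
  if (!length(sut)) stop("model has no suture label")
  pairs <- attr(model, "suture_pairs")
  if (is.null(pairs) || !all(pairs$label %in% sut)) {
    model <- split_sutures(model)
    pairs <- attr(model, "suture_pairs")
  }
  # only bone-to-bone sutures have two aligned surfaces; joints flanking a
  # constraint patch are not part of the strain report
  bones_all <- bone_labels(model)
  pairs <- pairs[pairs$bone_a %in% bones_all & pairs$bone_b %in% bones_all, ,
                 drop = FALSE]
  if (!nrow(pairs)) stop("no bone-to-bone suture present")
  lab <- model$labels
  d <- dim(lab)
  mesh <- tetrahedralize(model, max_size = Inf,
                         region_labels = pairs$label)
  node_bone <- node_adjacent_bone(model, mesh)
  rows <- list()
  for (pi in seq_len(nrow(pairs))) {
    pl <- pairs$label[pi]
    a <- pairs$bone_a[pi]; b <- pairs$bone_b[pi]
    have <- intersect(as.character(c(a, b)), names(alignments))
    if (length(have) < 2)
      stop("suture between bones ", a, " and ", b,
           " has fewer than 2 aligned bones")
    sel <- mesh$region == pl
    nodes_used <- sort(unique(as.vector(mesh$tets[sel, , drop = FALSE])))
    sub <- list(nodes = mesh$nodes[nodes_used, , drop = FALSE],
                tets = matrix(match(mesh$tets[sel, , drop = FALSE],
                                    nodes_used), ncol = 4),
                region = mesh$region[sel], h = mesh$h,
                roles = structure("suture", names = as.character(pl)))
    class(sub) <- "tet_mesh"
    nb <- node_bone[nodes_used]
    Aa <- alignments[[as.character(a)]]
    sys <- fem_assemble(sub, material_set(
      young = c(bone = 1, suture = 1, brain = 1), poisson = poisson))
    bnodes <- which(nb > 0 & as.character(nb) %in% names(alignments))
    uvals <- matrix(0, length(bnodes), 3)
    for (ii in seq_along(bnodes)) {
      Ac <- alignments[[as.character(nb[bnodes[ii]])]]
      Rrel <- t(Aa$R) %*% Ac$R
      trel <- as.numeric(t(Aa$R) %*% (Ac$t - Aa$t))
      xx <- sub$nodes[bnodes[ii], ]
      uvals[ii, ] <- as.numeric(Rrel %*% xx + trel) - xx
    }
    for (i in 1:3)
      sys <- fix_dofs(sys, bnodes, dofs = i, values = uvals[, i])
    res <- fem_solve(sys)
    eps <- if (measure == "green") green_strain(res$H) else res$strain
    m <- strain_measures_m(eps)
    w <- res$volume
    rows[[pi]] <- data.frame(
      suture = sprintf("suture_%d_%d", a, b), bone_a = a, bone_b = b,
      von_mises = sum(m$vm * w) / sum(w),
      e1 = sum(m$e1 * w) / sum(w),
      e3 = sum(m$e3 * w) / sum(w),
      n_elements = sum(sel), volume_mm3 = sum(w))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("suture_strain_report", "data.frame")
  attr(out, "measure") <- measure
  out
}

# Green-Lagrange strain tensors (m x 6) from displacement gradients
green_strain <- function(H) {
  # H columns: (11,21,31,12,22,32,13,23,33); E = (H + H^T + H^T H)/2
  hp <- function(p, q) H[, p + 3 * (q - 1)]
  EE <- matrix(0, nrow(H), 6)
  idx <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(2, 3), c(3, 1))
  for (k in seq_along(idx)) {
    p <- idx[[k]][1]; q <- idx[[k]][2]
    quad <- hp(1, p) * hp(1, q) + hp(2, p) * hp(2, q) + hp(3, p) * hp(3, q)
    EE[, k] <- (hp(p, q) + hp(q, p) + quad) / 2
  }
  colnames(EE) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  EE
}

# bone label adjacent to each mesh node (0 if none): a node is adjacent to
# a bone if any of its up-to-8 incident voxels carries a bone label
node_adjacent_bone <- function(model, mesh) {
  lab <- model$labels
  d <- dim(lab)
  bones <- bone_labels(model)
  h <- mesh$h
  g <- round(mesh$nodes / h)  # 0-based corner-grid coordinates
  out <- integer(nrow(g))
  for (off in list(c(0, 0, 0), c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1),
                   c(-1, -1, 0), c(-1, 0, -1), c(0, -1, -1), c(-1, -1, -1))) {
    i <- g[, 1] + off[1] + 1L; j <- g[, 2] + off[2] + 1L
    k <- g[, 3] + off[3] + 1L
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3] &
      out == 0L
    if (!any(ok)) next
    v <- lab[cbind(i[ok], j[ok], k[ok])]
    isb <- v %in% bones
    idx <- which(ok)[isb]
    out[idx] <- v[isb]
  }
  out
}
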