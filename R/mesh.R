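#' Surface mesh container
#'
#' Triangulated boundary surface in millimetres with a region id per
#' triangle (and per vertex where unambiguous). Produced by
#' \code{\link{extract_surface}}; interfaces between regions share corner
#' vertices, so multi-region surfaces are conforming.
#'
#' @param vertices n x 3 numeric matrix, mm
#' @param triangles m x 3 integer matrix of vertex indices
#' @param region integer region id per triangle
#' @param vertex_region optional integer region id per vertex
#' @export
surface_mesh <- function(vertices, triangles, region,
                         vertex_region = NULL) {
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            length(region) == nrow(triangles))
  structure(list(vertices = vertices,
                 triangles = matrix(as.integer(triangles), ncol = 3),
                 region = as.integer(region),
                 vertex_region = vertex_region),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("Surface mesh: ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ",
      length(unique(x$region)), " region(s)\n", sep = "")
  invisible(x)
}

#' Triangle areas of a surface mesh (mm^2)
#' @param mesh a \code{surface_mesh}
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2) / 2)
}

#' Extract per-region boundary surfaces from a labeled volume
#'
#' Builds the exact boundary surface of each region's voxel mask: every
#' exposed voxel face becomes two triangles with outward orientation, with
#' vertices on the shared corner lattice so that surfaces of adjacent
#' regions conform. Masks can be pre-smoothed with a majority filter of
#' radius \code{presmooth} before extraction, and the result can be
#' decimated by vertex clustering to at most \code{target_triangles}.
#' Coordinates are converted from micrometres to millimetres.
#'
#' @param vol a \code{labeled_volume}
#' @param presmooth majority-filter radius (voxels) applied to each region
#'   mask before extraction; 0 disables smoothing
#' @param target_triangles decimation budget over all regions
#'   (\code{Inf} keeps the raw surface)
#' @param region_labels labels to extract (default: all nonzero labels)
#' @return a \code{surface_mesh}
#' @export
extract_surface <- function(vol, presmooth = 0L, target_triangles = Inf,
                            region_labels = NULL) {
  stopifnot(inherits(vol, "labeled_volume"))
  lab <- vol$labels
  d <- dim(lab)
  if (is.null(region_labels))
    region_labels <- as.integer(names(vol$roles))
  region_labels <- intersect(region_labels, unique(as.vector(lab)))
  h <- vol$voxel_size / 1000  # mm
  cid <- function(i, j, k) i + (d[1] + 1) * (j + (d[2] + 1) * k) + 1
  tri_acc <- list(); reg_acc <- list(); face_acc <- list()
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (lb in region_labels) {
    mask <- lab == lb
    if (presmooth > 0) {
      mask <- 2 * boxsum3(mask, presmooth) > boxwin3(d, presmooth)
      if (!any(mask))
        stop("region ", lb, " vanished under presmoothing radius ", presmooth)
    }
    for (dir in dirs) {
      sh <- shift3(mask, dir[1], dir[2], dir[3], fill = FALSE)
      face_vox <- which(mask & !sh)
      if (!length(face_vox)) next
      ijk <- arrayInd(face_vox, d) - 1L  # 0-based cell index
      corners <- face_corners(ijk, dir)
      q <- cbind(cid(corners$c1[, 1], corners$c1[, 2], corners$c1[, 3]),
                 cid(corners$c2[, 1], corners$c2[, 2], corners$c2[, 3]),
                 cid(corners$c3[, 1], corners$c3[, 2], corners$c3[, 3]),
                 cid(corners$c4[, 1], corners$c4[, 2], corners$c4[, 3]))
      tri_acc[[length(tri_acc) + 1L]] <- rbind(q[, c(1, 2, 3), drop = FALSE],
                                               q[, c(1, 3, 4), drop = FALSE])
      reg_acc[[length(reg_acc) + 1L]] <- rep(lb, 2 * nrow(q))
      face_acc[[length(face_acc) + 1L]] <-
        data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                   dir = which(vapply(dirs, identical, logical(1), dir)),
                   region = lb)
    }
  }
  if (!length(tri_acc)) stop("no surface found for requested regions")
  tri_corner <- do.call(rbind, tri_acc)
  tri_region <- unlist(reg_acc)
  used <- sort(unique(as.vector(tri_corner)))
  tri <- matrix(match(as.vector(tri_corner), used), ncol = 3)
  g0 <- used - 1
  i <- g0 %% (d[1] + 1)
  j <- (g0 %/% (d[1] + 1)) %% (d[2] + 1)
  k <- g0 %/% ((d[1] + 1) * (d[2] + 1))
  verts <- cbind(i, j, k) * h
  # vertex region: assign from the first triangle touching the vertex
  vreg <- rep(NA_integer_, nrow(verts))
  first <- !duplicated(as.vector(tri))
  vreg[as.vector(tri)[first]] <- rep(tri_region, 3)[first]
  mesh <- surface_mesh(verts, tri, tri_region, vreg)
  attr(mesh, "volume") <- vol
  attr(mesh, "faces") <- do.call(rbind, face_acc)
  if (is.finite(target_triangles) && nrow(mesh$triangles) > target_triangles)
    mesh <- decimate_surface(mesh, target_triangles)
  mesh
}

# corner quadruple (0-based corner-grid coordinates) of the exposed face of
# cell ijk in direction dir, ordered so the normal points along dir
face_corners <- function(ijk, dir) {
  x <- ijk[, 1]; y <- ijk[, 2]; z <- ijk[, 3]
  o <- function(a, b, c) cbind(x + a, y + b, z + c)
  if (all(dir == c(1, 0, 0)))
    list(c1 = o(1, 0, 0), c2 = o(1, 1, 0), c3 = o(1, 1, 1), c4 = o(1, 0, 1))
  else if (all(dir == c(-1, 0, 0)))
    list(c1 = o(0, 0, 0), c2 = o(0, 0, 1), c3 = o(0, 1, 1), c4 = o(0, 1, 0))
  else if (all(dir == c(0, 1, 0)))
    list(c1 = o(0, 1, 0), c2 = o(0, 1, 1), c3 = o(1, 1, 1), c4 = o(1, 1, 0))
  else if (all(dir == c(0, -1, 0)))
    list(c1 = o(0, 0, 0), c2 = o(1, 0, 0), c3 = o(1, 0, 1), c4 = o(0, 0, 1))
  else if (all(dir == c(0, 0, 1)))
    list(c1 = o(0, 0, 1), c2 = o(1, 0, 1), c3 = o(1, 1, 1), c4 = o(0, 1, 1))
  else
    list(c1 = o(0, 0, 0), c2 = o(0, 1, 0), c3 = o(1, 1, 0), c4 = o(1, 0, 0))
}

#' Coarsen a labeled volume by an integer factor
#'
#' Aggregates \code{factor^3} voxel blocks into single cells for meshing at
#' a coarser pitch. Each cell takes the label of the highest-priority role
#' present in the block (cover and suture outrank bone, bone outranks
#' endocast), with ties within a role broken by voxel count; this
#' preserves thin sutures and covers that plain majority voting would
#' erase. Trailing partial blocks are padded with background.
#'
#' @param vol a \code{labeled_volume}
#' @param factor integer coarsening factor >= 1
#' @param priority role priority, highest first
#' @export
coarsen_volume <- function(vol, factor,
                           priority = c("cover", "suture", "constraint",
                                        "bone", "endocast")) {
  stopifnot(inherits(vol, "labeled_volume"), factor >= 1)
  f <- as.integer(factor)
  if (f == 1L) return(vol)
  lab <- vol$labels
  d <- dim(lab)
  dp <- ceiling(d / f) * f
  if (any(dp > d)) {
    tmp <- array(0L, dp)
    tmp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- lab
    lab <- tmp
  }
  dc <- dp / f
  cell_counts <- function(mask) {
    a <- array(mask, c(f, dc[1], f, dc[2], f, dc[3]))
    colSums(aperm(a, c(1, 3, 5, 2, 4, 6)), dims = 3)
  }
  out <- array(0L, dc)
  for (role in priority) {
    rl <- labels_of_role(vol, role)
    if (!length(rl)) next
    role_lab <- array(0L, dc)
    role_cnt <- array(0L, dc)
    for (l in rl) {
      cnt <- cell_counts(lab == l)
      better <- cnt > role_cnt
      role_lab[better] <- l
      role_cnt[better] <- cnt[better]
    }
    take <- out == 0L & role_lab > 0L
    out[take] <- role_lab[take]
  }
  res <- labeled_volume(out, vol$voxel_size * f, vol$roles)
  attributes(res) <- c(attributes(res),
                       attributes(vol)[setdiff(names(attributes(vol)),
                                               names(attributes(res)))])
  res
}

#' Decimate a surface mesh
#'
#' Two-stage decimation tuned to voxel surfaces. First, coplanar exposed
#' faces are merged into maximal rectangles (greedy meshing): this stage is
#' exact — the decimated surface occupies the same geometry and area as the
#' raw one. If the budget is still exceeded, vertices are clustered on a
#' uniform grid of increasing cell size and collapsed triangles dropped,
#' which is approximate. Region ids are preserved per surviving triangle;
#' conformity of shared region interfaces is not guaranteed after
#' decimation.
#'
#' @param mesh a \code{surface_mesh}
#' @param target_triangles triangle budget
#' @export
decimate_surface <- function(mesh, target_triangles) {
  stopifnot(target_triangles >= 4)
  faces <- attr(mesh, "faces")
  vol <- attr(mesh, "volume")
  out <- mesh
  if (!is.null(faces) && !is.null(vol)) {
    out <- merge_coplanar_faces(faces, vol$voxel_size / 1000)
    attr(out, "volume") <- vol
  }
  h <- if (!is.null(vol)) vol$voxel_size / 1000 else
    min(stats::dist(mesh$vertices[seq_len(min(50, nrow(mesh$vertices))), ]))
  base <- out
  while (nrow(out$triangles) > target_triangles) {
    h <- h * 2
    cell <- floor(sweep(base$vertices, 2, apply(base$vertices, 2, min)) / h)
    key <- cell[, 1] + 1e5 * (cell[, 2] + 1e5 * cell[, 3])
    cl <- match(key, unique(key))
    nv <- rowsum(base$vertices, cl, reorder = TRUE) /
      as.vector(tabulate(cl))
    tri <- matrix(cl[base$triangles], ncol = 3)
    keep <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
    tri <- tri[keep, , drop = FALSE]
    lo <- pmin(tri[, 1], tri[, 2], tri[, 3])
    hi <- pmax(tri[, 1], tri[, 2], tri[, 3])
    keep2 <- !duplicated(paste(lo, rowSums(tri) - lo - hi, hi))
    out <- surface_mesh(nv, tri[keep2, , drop = FALSE],
                        base$region[keep][keep2])
    attr(out, "volume") <- vol
    if (h > 1e4) break
  }
  out
}

# exact lossless merge of coplanar voxel faces into maximal rectangles
merge_coplanar_faces <- function(faces, h) {
  # per direction: plane coordinate and in-plane (u, v) cell coordinates
  plane_uv <- function(f) {
    switch(f$dir[1],
           list(p = f$i + 1L, u = f$j, v = f$k),   # +x
           list(p = f$i,      u = f$j, v = f$k),   # -x
           list(p = f$j + 1L, u = f$i, v = f$k),   # +y
           list(p = f$j,      u = f$i, v = f$k),   # -y
           list(p = f$k + 1L, u = f$i, v = f$j),   # +z
           list(p = f$k,      u = f$i, v = f$j))   # -z
  }
  # corner order (outward orientation) for a rectangle [u0,u1] x [v0,v1]
  rect_corners <- function(dir, p, u0, u1, v0, v1) {
    cor2 <- switch(dir,
      cbind(u = c(u0, u1, u1, u0), v = c(v0, v0, v1, v1)),  # +x
      cbind(u = c(u0, u0, u1, u1), v = c(v0, v1, v1, v0)),  # -x
      cbind(u = c(u0, u0, u1, u1), v = c(v0, v1, v1, v0)),  # +y
      cbind(u = c(u0, u1, u1, u0), v = c(v0, v0, v1, v1)),  # -y
      cbind(u = c(u0, u1, u1, u0), v = c(v0, v0, v1, v1)),  # +z
      cbind(u = c(u0, u0, u1, u1), v = c(v0, v1, v1, v0)))  # -z
    if (dir %in% 1:2) cbind(p, cor2[, 1], cor2[, 2])
    else if (dir %in% 3:4) cbind(cor2[, 1], p, cor2[, 2])
    else cbind(cor2[, 1], cor2[, 2], p)
  }
  verts <- list(); tris <- list(); regs <- integer(0)
  vkey <- new.env(parent = emptyenv())
  nv <- 0L
  vid <- function(corner) {
    k <- paste(corner, collapse = " ")
    id <- vkey[[k]]
    if (is.null(id)) {
      nv <<- nv + 1L
      vkey[[k]] <- nv
      verts[[nv]] <<- corner
      id <- nv
    }
    id
  }
  groups <- split(faces, list(faces$region, faces$dir), drop = TRUE)
  for (g in groups) {
    uv0 <- plane_uv(g)
    for (p in unique(uv0$p)) {
      sel <- uv0$p == p
      u <- uv0$u[sel]; v <- uv0$v[sel]
      umin <- min(u); vmin <- min(v)
      M <- matrix(FALSE, max(u) - umin + 1L, max(v) - vmin + 1L)
      M[cbind(u - umin + 1L, v - vmin + 1L)] <- TRUE
      for (vv in seq_len(ncol(M))) {
        uu <- 1L
        while (uu <= nrow(M)) {
          if (!M[uu, vv]) { uu <- uu + 1L; next }
          w <- 1L
          while (uu + w <= nrow(M) && M[uu + w, vv]) w <- w + 1L
          hh <- 1L
          while (vv + hh <= ncol(M) &&
                 all(M[uu:(uu + w - 1L), vv + hh])) hh <- hh + 1L
          M[uu:(uu + w - 1L), vv:(vv + hh - 1L)] <- FALSE
          cr <- rect_corners(g$dir[1], p,
                             uu - 1L + umin, uu + w - 1L + umin,
                             vv - 1L + vmin, vv + hh - 1L + vmin)
          ids <- c(vid(cr[1, ]), vid(cr[2, ]), vid(cr[3, ]), vid(cr[4, ]))
          tris[[length(tris) + 1L]] <- rbind(ids[c(1, 2, 3)],
                                             ids[c(1, 3, 4)])
          regs <- c(regs, g$region[1], g$region[1])
          uu <- uu + w
        }
      }
    }
  }
  V <- do.call(rbind, verts) * h
  TT <- do.call(rbind, tris)
  vreg <- rep(NA_integer_, nrow(V))
  first <- !duplicated(as.vector(TT))
  vreg[as.vector(TT)[first]] <- rep(regs, 3)[first]
  surface_mesh(V, TT, regs, vreg)
}

#' Tetrahedral mesh container
#'
#' Conforming multi-region tetrahedral mesh: nodes in mm, 4-node tets with
#' positive signed volume, and an integer region id (the source voxel
#' label) per tet.
#' @export
#' @rdname tetrahedralize
print.tet_mesh <- function(x, ...) {
  cat("Tet mesh: ", nrow(x$nodes), " nodes, ", nrow(x$tets),
      " tets (cell ", signif(x$h, 3), " mm), regions: ",
      paste(sort(unique(x$region)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Tetrahedralize a labeled volume (or its extracted surface)
#'
#' Generates a conforming multi-region tetrahedral mesh by Freudenthal/Kuhn
#' subdivision of the voxel lattice: every labeled voxel is split into six
#' tetrahedra around its main diagonal, which conforms across neighbouring
#' voxels and across region interfaces (shared faces, shared nodes). The
#' lattice can be resampled by an integer factor so that the longest tet
#' edge (the cell diagonal) does not exceed \code{max_size}; per-region
#' adaptive sizing is not supported — the smallest requested size wins.
#'
#' @param x a \code{labeled_volume}, or a \code{surface_mesh} produced by
#'   \code{\link{extract_surface}} (its source volume is used)
#' @param max_size maximum element edge length, mm
#' @param region_sizes optional named per-region target cell sizes, mm; the
#'   minimum is used for the whole lattice
#' @param region_labels labels to mesh (default: all nonzero)
#' @return a \code{tet_mesh}
#' @export
tetrahedralize <- function(x, max_size = 0.2, region_sizes = NULL,
                           region_labels = NULL) {
  vol <- if (inherits(x, "surface_mesh")) attr(x, "volume") else x
  if (!inherits(vol, "labeled_volume"))
    stop("x must be a labeled_volume or a surface mesh extracted from one")
  h <- vol$voxel_size / 1000
  target <- max_size / sqrt(3)
  if (!is.null(region_sizes)) target <- min(target, min(region_sizes))
  lab <- vol$labels
  if (h > target) {             # refine by integer factor
    f <- as.integer(ceiling(h / target))
    d <- dim(lab)
    lab <- lab[rep(seq_len(d[1]), each = f),
               rep(seq_len(d[2]), each = f),
               rep(seq_len(d[3]), each = f)]
    h <- h / f
  }
  if (is.null(region_labels)) region_labels <- as.integer(names(vol$roles))
  d <- dim(lab)
  vox <- which(array(lab %in% region_labels, d))
  if (!length(vox)) stop("no voxels to mesh")
  ijk <- arrayInd(vox, d) - 1L
  region_per_cell <- lab[vox]
  cid <- function(di, dj, dk)
    (ijk[, 1] + di) + (d[1] + 1) * ((ijk[, 2] + dj) +
                                      (d[2] + 1) * (ijk[, 3] + dk)) + 1
  corner <- cbind(c000 = cid(0, 0, 0), c100 = cid(1, 0, 0),
                  c010 = cid(0, 1, 0), c110 = cid(1, 1, 0),
                  c001 = cid(0, 0, 1), c101 = cid(1, 0, 1),
                  c011 = cid(0, 1, 1), c111 = cid(1, 1, 1))
  # Kuhn subdivision: one tet per permutation of the axes, each walking
  # 000 -> e_p1 -> e_p1+e_p2 -> 111
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cname <- function(v) paste0("c", v[1], v[2], v[3])
  e <- diag(3)
  tets <- NULL; treg <- NULL
  for (p in perms) {
    a <- e[p[1], ]; b <- e[p[1], ] + e[p[2], ]
    cols <- c("c000", cname(a), cname(b), "c111")
    tt <- corner[, cols, drop = FALSE]
    tets <- rbind(tets, tt)
    treg <- c(treg, region_per_cell)
  }
  used <- sort(unique(as.vector(tets)))
  tt <- matrix(match(as.vector(tets), used), ncol = 4)
  g0 <- used - 1
  nodes <- cbind(g0 %% (d[1] + 1),
                 (g0 %/% (d[1] + 1)) %% (d[2] + 1),
                 g0 %/% ((d[1] + 1) * (d[2] + 1))) * h
  # enforce positive signed volume
  v6 <- tet_signed_volume6(nodes, tt)
  flip <- v6 < 0
  if (any(flip)) tt[flip, c(3, 4)] <- tt[flip, c(4, 3)]
  mesh <- structure(list(nodes = nodes, tets = tt, region = as.integer(treg),
                         h = h, roles = vol$roles),
                    class = "tet_mesh")
  mesh
}

# 6 times the signed volume of each tet
tet_signed_volume6 <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c_ <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
}

#' Tet volumes in mm^3
#' @param mesh a \code{tet_mesh}
#' @export
tet_volumes <- function(mesh) tet_signed_volume6(mesh$nodes, mesh$tets) / 6

#' Boundary triangles of a tet mesh (faces used by exactly one tet)
#' @param mesh a \code{tet_mesh}
#' @return integer matrix of node triples
#' @export
tet_boundary_faces <- function(mesh) {
  tt <- mesh$tets
  faces <- rbind(tt[, c(1, 2, 3)], tt[, c(1, 2, 4)],
                 tt[, c(1, 3, 4)], tt[, c(2, 3, 4)])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  counts <- table(key)
  single <- counts[key] == 1
  faces[single, , drop = FALSE]
}

#' Mesh quality and sizing summary
#'
#' Reports per-region element counts, mean element size (cube-root of mean
#' tet volume and mean edge length) and the minimum dihedral angle.
#' @param mesh a \code{tet_mesh}
#' @export
mesh_summary <- function(mesh) {
  v <- tet_volumes(mesh)
  regs <- sort(unique(mesh$region))
  per <- data.frame(
    region = regs,
    n_tets = vapply(regs, function(r) sum(mesh$region == r), integer(1)),
    volume_mm3 = vapply(regs, function(r) sum(v[mesh$region == r]),
                        numeric(1)),
    mean_edge_mm = mesh$h * mean(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(3))))
  list(per_region = per, min_dihedral_deg = min_dihedral(mesh),
       total_volume_mm3 = sum(v))
}

min_dihedral <- function(mesh) {
  # all Kuhn tets are congruent; measure the first one
  n <- mesh$nodes[mesh$tets[1, ], ]
  combs <- utils::combn(4, 3)
  normals <- apply(combs, 2, function(f) {
    a <- n[f[2], ] - n[f[1], ]; b <- n[f[3], ] - n[f[1], ]
    nv <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    nv / sqrt(sum(nv^2))
  })
  ang <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    cosd <- abs(sum(normals[, i] * normals[, j]))
    ang <- c(ang, 180 - acos(pmin(1, cosd)) * 180 / pi)
  }
  min(ang)
}
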