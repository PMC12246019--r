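#' Elastic material set
#'
#' Isotropic linear-elastic constants per model region, in the package's
#' consistent mm-N-MPa unit system (displacements mm, strains
#' dimensionless). A single Poisson's ratio is shared by all regions. The
#' defaults are the calibrated neonatal-mouse set: bone 20 MPa, suture
#' 30 kPa (0.03 MPa) and a vanishing brain modulus of 3 Pa (3e-6 MPa) that
#' keeps the endocast meshed while discounting its load share; cover
#' material inherits the suture modulus unless given explicitly.
#'
#' @param young named vector of Young's moduli in MPa; recognised names are
#'   \code{bone}, \code{suture}, \code{brain} and optionally \code{cover}
#' @param poisson Poisson's ratio, shared by all regions (0 <= nu < 0.5)
#' @export
material_set <- function(young = c(bone = 20, suture = 0.03, brain = 3e-6),
                         poisson = 0.3) {
  if (is.na(young["cover"])) young["cover"] <- young["suture"]
  young <- young[!is.na(young)]
  if (any(young <= 0)) stop("all Young's moduli must be > 0")
  if (poisson < 0 || poisson >= 0.5) stop("need 0 <= poisson < 0.5")
  structure(list(young = young, poisson = poisson), class = "material_set")
}

# material name for a region role
material_of_role <- function(role) {
  switch(role,
         bone = "bone", constraint = "bone", suture = "suture",
         cover = "cover", endocast = "brain",
         stop("no material mapping for role ", role))
}

#' Point-load case
#'
#' A force applied over a disc of surface nodes in a given direction, with
#' the model fixed at its two constraint patches: the posterior-ventral
#' patch in all degrees of freedom and the anterior patch, by default, in
#' the load direction only (set \code{anterior_fix = "all"} for full
#' fixation).
#'
#' @param load_point point on (or above) the loaded surface, mm
#' @param disc_diameter diameter of the loaded node disc, mm
#' @param force total applied force, N, split equally over the disc nodes
#' @param direction unit load direction (default: ventral, i.e. pressing
#'   down the dorsoventral axis)
#' @param anterior_fix \code{"direction"} or \code{"all"}
#' @param name optional label for reports
#' @export
load_case <- function(load_point, disc_diameter = 1, force = 0.1,
                      direction = c(0, -1, 0),
                      anterior_fix = c("direction", "all"), name = NULL) {
  if (force <= 0) stop("force must be > 0")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) direction <- direction / nrm
  structure(list(load_point = as.numeric(load_point),
                 disc_diameter = disc_diameter, force = force,
                 direction = as.numeric(direction),
                 anterior_fix = match.arg(anterior_fix), name = name),
            class = "load_case")
}

#' Assemble the linear-elastic stiffness system
#'
#' Standard 4-node (constant-strain) tetrahedral elasticity. The element
#' stiffness is built from the shape-function gradients g_a as
#' K[(a,i),(b,j)] = V (lambda g_ai g_bj + mu g_aj g_bi +
#' mu delta_ij g_a.g_b); per-material unit-modulus stiffness blocks are
#' retained so that modulus sweeps can re-form the system without
#' re-assembly. Before constraints the assembled matrix annihilates the
#' six-dimensional rigid-body space.
#'
#' @param mesh a \code{tet_mesh}
#' @param mats a \code{material_set} covering every region role in the mesh
#' @return an object of class \code{fem_system}
#' @export
fem_assemble <- function(mesh, mats = material_set()) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(mats, "material_set"))
  v6 <- tet_signed_volume6(mesh$nodes, mesh$tets)
  if (any(v6 <= 0))
    stop("inverted element(s): ", paste(utils::head(which(v6 <= 0), 5),
                                        collapse = ", "))
  V <- v6 / 6
  G <- shape_gradients(mesh$nodes, mesh$tets, v6)
  roles <- mesh$roles[as.character(mesh$region)]
  matname <- vapply(roles, material_of_role, character(1))
  missing <- setdiff(unique(matname), names(mats$young))
  if (length(missing))
    stop("no modulus for material(s): ", paste(missing, collapse = ", "))
  nu <- mats$poisson
  lam1 <- nu / ((1 + nu) * (1 - 2 * nu))
  mu1 <- 1 / (2 * (1 + nu))
  nd <- 3L * nrow(mesh$nodes)
  Kr <- list()
  for (m in unique(matname)) {
    idx <- which(matname == m)
    Tm <- mesh$tets[idx, , drop = FALSE]
    Vm <- V[idx]
    nE <- length(idx)
    rows <- integer(144 * nE); cols <- integer(144 * nE)
    vals <- numeric(144 * nE)
    pos <- 0L
    for (a in 1:4) for (b in 1:4) {
      gab <- G[idx, a, 1] * G[idx, b, 1] + G[idx, a, 2] * G[idx, b, 2] +
        G[idx, a, 3] * G[idx, b, 3]
      for (i in 1:3) for (j in 1:3) {
        val <- Vm * (lam1 * G[idx, a, i] * G[idx, b, j] +
                       mu1 * G[idx, a, j] * G[idx, b, i] +
                       (if (i == j) mu1 * gab else 0))
        rng <- pos + seq_len(nE)
        rows[rng] <- 3L * (Tm[, a] - 1L) + i
        cols[rng] <- 3L * (Tm[, b] - 1L) + j
        vals[rng] <- val
        pos <- pos + nE
      }
    }
    Kr[[m]] <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                    dims = c(nd, nd))
  }
  K <- Reduce(`+`, Map(function(m) mats$young[[m]] * Kr[[m]], names(Kr)))
  structure(list(K = K, Kr = Kr, mesh = mesh, mats = mats, G = G, V = V,
                 f = numeric(nd), fixed = logical(nd),
                 u_fixed = numeric(nd), lc = NULL),
            class = "fem_system")
}

# shape-function gradients (m x 4 x 3): columns of the inverse edge matrix
shape_gradients <- function(nodes, tets, v6) {
  e1 <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  e2 <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  e3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  m <- nrow(e1)
  G <- array(0, c(m, 4, 3))
  # inverse of A = rbind(e1, e2, e3) per element via cofactors; columns of
  # A^-1 are the gradients of nodes 2..4
  cf <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c1 <- cf(e2, e3); c2 <- cf(e3, e1); c3 <- cf(e1, e2)
  # A^-1 = [c1 c2 c3]^T... columns of A^-1: A^-1 e_k
  G[, 2, ] <- c1 / v6
  G[, 3, ] <- c2 / v6
  G[, 4, ] <- c3 / v6
  G[, 1, ] <- -(G[, 2, ] + G[, 3, ] + G[, 4, ])
  G
}

#' Constrain and load a system from a load case
#'
#' Locates the disc of surface nodes within \code{disc_diameter/2} of the
#' load axis, splits the total force equally over them, and fixes the
#' constraint-patch node sets (posterior-ventral patch: all dofs; anterior
#' patch: the load-direction dof, or all dofs per the load case).
#'
#' @param system a \code{fem_system}
#' @param mesh the system's mesh (defaults to \code{system$mesh})
#' @param lc a \code{load_case}
#' @return the constrained, loaded \code{fem_system}
#' @export
apply_load_case <- function(system, mesh = system$mesh, lc) {
  stopifnot(inherits(system, "fem_system"), inherits(lc, "load_case"))
  sn <- surface_nodes(mesh)
  # the disc loads the bone (the experiments load bone surfaces, never the
  # soft tissue): restrict candidates to nodes incident to bone/constraint
  hard <- as.integer(names(mesh$roles)[mesh$roles %in%
                                         c("bone", "constraint")])
  if (length(hard)) {
    hard_nodes <- unique(as.vector(
      mesh$tets[mesh$region %in% hard, , drop = FALSE]))
    sn <- intersect(sn, hard_nodes)
  }
  x <- mesh$nodes[sn, , drop = FALSE]
  u <- lc$direction
  rel <- sweep(x, 2, lc$load_point)
  s <- rel %*% u
  perp2 <- rowSums(rel^2) - s^2
  r <- lc$disc_diameter / 2
  cand <- perp2 <= r^2
  if (!any(cand))
    stop("empty load disc: nearest surface node is ",
         signif(sqrt(min(rowSums(rel^2))), 4), " mm from the load point")
  smin <- min(s[cand])
  band <- cand & s <= smin + 2 * mesh$h * sqrt(3)
  disc <- sn[band]
  nd <- length(system$f)
  f <- numeric(nd)
  per_node <- lc$force / length(disc)
  for (i in 1:3)
    f[3L * (disc - 1L) + i] <- per_node * u[i]
  fixed <- logical(nd)
  cons <- constraint_node_sets(mesh)
  if (!is.null(cons$posterior))
    fixed[rep(3L * (cons$posterior - 1L), each = 3) + 1:3] <- TRUE
  if (!is.null(cons$anterior)) {
    if (lc$anterior_fix == "all") {
      fixed[rep(3L * (cons$anterior - 1L), each = 3) + 1:3] <- TRUE
    } else {
      dof <- which.max(abs(u))
      fixed[3L * (cons$anterior - 1L) + dof] <- TRUE
    }
  }
  if (any(fixed & f != 0))
    stop("fixed node sets overlap the load disc")
  system$f <- f
  system$fixed <- fixed
  system$u_fixed <- numeric(nd)
  system$lc <- lc
  system$disc_nodes <- disc
  system
}

# nodes on the mesh boundary (cached on the mesh by attribute)
surface_nodes <- function(mesh) {
  sn <- attr(mesh, "surface_nodes")
  if (is.null(sn)) sn <- sort(unique(as.vector(tet_boundary_faces(mesh))))
  sn
}

# anterior / posterior-ventral constraint node sets from constraint regions
constraint_node_sets <- function(mesh) {
  cl <- as.integer(names(mesh$roles)[mesh$roles == "constraint"])
  if (!length(cl)) return(list(anterior = NULL, posterior = NULL))
  sets <- lapply(cl, function(l) {
    sort(unique(as.vector(mesh$tets[mesh$region == l, , drop = FALSE])))
  })
  if (length(cl) == 1) return(list(anterior = NULL, posterior = sets[[1]]))
  # anterior patch = larger mean anteroposterior (axis 3) coordinate
  ap <- vapply(sets, function(s) mean(mesh$nodes[s, 3]), numeric(1))
  list(anterior = sets[[which.max(ap)]], posterior = sets[[which.min(ap)]])
}

#' Fix degrees of freedom explicitly
#'
#' Low-level constraint interface used for patch tests, bar problems and
#' Dirichlet strain estimation: prescribes (possibly nonzero) displacement
#' values at node/dof pairs.
#'
#' @param system a \code{fem_system}
#' @param nodes node indices
#' @param dofs dof indices (1 = x, 2 = y, 3 = z) applied to every node
#' @param values prescribed displacement, recycled
#' @export
fix_dofs <- function(system, nodes, dofs = 1:3, values = 0) {
  idx <- as.vector(outer(dofs, 3L * (nodes - 1L), `+`))
  vals <- rep_len(values, length(idx))
  system$fixed[idx] <- TRUE
  system$u_fixed[idx] <- vals
  system
}

#' Apply a uniform traction to boundary faces
#'
#' Consistent nodal forces: each face contributes traction x area / 3 to
#' its three nodes.
#'
#' @param system a \code{fem_system}
#' @param faces integer matrix of boundary node triples
#' @param traction traction vector, N/mm^2 (MPa)
#' @export
apply_traction <- function(system, faces, traction) {
  n <- system$mesh$nodes
  a <- n[faces[, 2], , drop = FALSE] - n[faces[, 1], , drop = FALSE]
  b <- n[faces[, 3], , drop = FALSE] - n[faces[, 1], , drop = FALSE]
  area <- sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
                 (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
                 (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2) / 2
  for (v in 1:3) {
    nodes <- faces[, v]
    for (i in 1:3) {
      contrib <- traction[i] * area / 3
      agg <- rowsum(contrib, nodes)
      ids <- as.integer(rownames(agg))
      system$f[3L * (ids - 1L) + i] <- system$f[3L * (ids - 1L) + i] + agg[, 1]
    }
  }
  system
}

#' Solve the constrained system
#'
#' Direct sparse Cholesky solve of the free dofs with prescribed-value
#' elimination; verifies the relative residual and recovers constant
#' element strain tensors from the shape-function gradients.
#'
#' @param system a constrained \code{fem_system}
#' @return an object of class \code{fem_result}: nodal displacements (mm),
#'   per-element infinitesimal strain tensors (xx, yy, zz, xy, yz, zx),
#'   displacement gradients, reaction forces (N) and the solve residual
#' @export
fem_solve <- function(system) {
  stopifnot(inherits(system, "fem_system"))
  free <- !system$fixed
  if (!any(free)) {
    u <- system$u_fixed
  } else {
    Kff <- system$K[free, free, drop = FALSE]
    rhs <- system$f[free]
    if (any(system$fixed & system$u_fixed != 0))
      rhs <- rhs - as.vector(system$K[free, !free, drop = FALSE] %*%
                               system$u_fixed[!free])
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff),
                                    super = TRUE),
                   error = function(e)
                     stop("singular system: unconstrained rigid-body ",
                          "component(s) remain (", conditionMessage(e), ")"))
    uf <- as.vector(Matrix::solve(ch, rhs))
    res <- sqrt(sum((as.vector(Kff %*% uf) - rhs)^2))
    nrm <- sqrt(sum(rhs^2))
    rel <- if (nrm > 0) res / nrm else res
    if (is.finite(rel) && rel > 1e-8)
      warning("large solve residual: ", signif(rel, 3))
    u <- system$u_fixed
    u[free] <- uf
  }
  reactions <- as.vector(system$K %*% u) - system$f
  U <- matrix(u, ncol = 3, byrow = TRUE)
  H <- displacement_gradients(system, U)
  eps <- cbind(xx = H[, 1], yy = H[, 5], zz = H[, 9],
               xy = (H[, 2] + H[, 4]) / 2,
               yz = (H[, 6] + H[, 8]) / 2,
               zx = (H[, 3] + H[, 7]) / 2)
  structure(list(u = U, strain = eps, H = H,
                 region = system$mesh$region, volume = system$V,
                 reactions = reactions, residual = if (any(free)) rel else 0,
                 mesh = system$mesh),
            class = "fem_result")
}

# per-element displacement gradient H (m x 9, column-major 3x3: H[p,q] =
# du_p/dx_q stored as (11,21,31,12,22,32,13,23,33))
displacement_gradients <- function(system, U) {
  G <- system$G; tets <- system$mesh$tets
  m <- nrow(tets)
  H <- matrix(0, m, 9)
  for (p in 1:3) for (q in 1:3) {
    acc <- numeric(m)
    for (a in 1:4) acc <- acc + U[tets[, a], p] * G[, a, q]
    H[, p + 3 * (q - 1)] <- acc
  }
  H
}

#' @export
print.fem_result <- function(x, ...) {
  cat("FE result: ", nrow(x$u), " nodes, ", nrow(x$strain), " elements; ",
      "max |u| = ", signif(max(abs(x$u)), 4), " mm; residual ",
      signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

#' Scalar strain measures of a strain tensor
#'
#' Computes the von Mises equivalent strain
#' \eqn{\sqrt{(2/3)\,\epsilon^{dev}:\epsilon^{dev}}} and the first and
#' third principal strains (largest/smallest eigenvalues).
#'
#' @param tensor symmetric 3x3 strain tensor
#' @return named vector \code{c(von_mises, e1, e3)}
#' @export
strain_measures <- function(tensor) {
  if (!is.matrix(tensor) || any(dim(tensor) != 3) ||
      max(abs(tensor - t(tensor))) > 1e-12 * max(1, max(abs(tensor))))
    stop("tensor must be a symmetric 3x3 matrix")
  eps <- cbind(tensor[1, 1], tensor[2, 2], tensor[3, 3],
               tensor[1, 2], tensor[2, 3], tensor[3, 1])
  m <- strain_measures_m(eps)
  c(von_mises = m$vm, e1 = m$e1, e3 = m$e3)
}

# vectorised measures from m x 6 tensors (xx, yy, zz, xy, yz, zx)
strain_measures_m <- function(eps) {
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  d1 <- eps[, 1] - tr / 3; d2 <- eps[, 2] - tr / 3; d3 <- eps[, 3] - tr / 3
  dev2 <- d1^2 + d2^2 + d3^2 + 2 * (eps[, 4]^2 + eps[, 5]^2 + eps[, 6]^2)
  vm <- sqrt(pmax(0, 2 / 3 * dev2))
  ev <- sym3_eigenvalues(eps)
  list(vm = vm, e1 = ev$e1, e2 = ev$e2, e3 = ev$e3)
}

# analytic eigenvalues of symmetric 3x3 tensors (trigonometric method)
sym3_eigenvalues <- function(eps) {
  a11 <- eps[, 1]; a22 <- eps[, 2]; a33 <- eps[, 3]
  a12 <- eps[, 4]; a23 <- eps[, 5]; a13 <- eps[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a23^2 + a13^2)
  p <- sqrt(pmax(p2 / 6, 0))
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / 2 / p^3, 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  list(e1 = e1, e2 = e2, e3 = e3)
}

#' Volume-weighted average strain measures over a region
#'
#' Tet-volume-weighted means of von Mises, 1st and 3rd principal strain
#' over the elements of one region (a label, a vector of labels, or a role
#' name such as \code{"suture"}).
#'
#' @param result a \code{fem_result}
#' @param mesh the mesh (defaults to the result's mesh)
#' @param region label(s) or role name
#' @export
suture_average <- function(result, mesh = result$mesh, region) {
  if (is.character(region))
    region <- as.integer(names(mesh$roles)[mesh$roles == region])
  sel <- result$region %in% region
  if (!any(sel)) stop("empty region: ", paste(region, collapse = " "))
  m <- strain_measures_m(result$strain[sel, , drop = FALSE])
  w <- result$volume[sel]
  c(von_mises = sum(m$vm * w) / sum(w),
    e1 = sum(m$e1 * w) / sum(w),
    e3 = sum(m$e3 * w) / sum(w))
}
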