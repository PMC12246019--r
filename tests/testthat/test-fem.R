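test_that("single-tet element stiffness matches the explicit B-matrix oracle
           and is linear in the modulus", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- structure(list(nodes = nodes, tets = matrix(1:4, 1), region = 1L,
                         h = 1, roles = c(`1` = "bone")),
                    class = "tet_mesh")
  sys <- fem_assemble(mesh, uniform_mats(1, 0.3))
  K <- as.matrix(sys$K)
  # oracle: V * B' D B with the standard engineering-strain B matrix
  nu <- 0.3
  Dm <- 1 / ((1 + nu) * (1 - 2 * nu)) *
    rbind(c(1 - nu, nu, nu, 0, 0, 0), c(nu, 1 - nu, nu, 0, 0, 0),
          c(nu, nu, 1 - nu, 0, 0, 0),
          cbind(matrix(0, 3, 3), diag(3) * (1 - 2 * nu) / 2))
  grads <- rbind(c(-1, -1, -1), diag(3))
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- grads[a, ]; c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[1]; B[2, c0 + 2] <- g[2]; B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
    B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
  }
  expect_lt(max(abs(K - t(B) %*% Dm %*% B / 6)), 1e-12)
  # rigid-body space annihilated
  for (u in list(rep(c(1, 0, 0), 4), rep(c(0, 0, 1), 4))) {
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
  # doubling E doubles K exactly
  K2 <- as.matrix(fem_assemble(mesh, uniform_mats(2, 0.3))$K)
  expect_identical(max(abs(K2 - 2 * K)), 0)
  # inverted element flagged
  mesh_bad <- mesh
  mesh_bad$tets <- matrix(c(1, 3, 2, 4), 1)
  expect_error(fem_assemble(mesh_bad, uniform_mats(1)), "inverted")
})

test_that("uniaxial bar reproduces sigma/E axial and -nu sigma/E lateral
           strain to 1e-10, with exact reaction equilibrium", {
  mesh <- bar_mesh(10, 4, 4, 0.25)
  sys <- fem_assemble(mesh, uniform_mats(1000, 0.3))
  n <- mesh$nodes
  sys <- fix_dofs(sys, which(n[, 1] < 1e-9), dofs = 1)
  sys <- fix_dofs(sys, which(n[, 2] < 1e-9), dofs = 2)
  sys <- fix_dofs(sys, which(n[, 3] < 1e-9), dofs = 3)
  bf <- tet_boundary_faces(mesh)
  endf <- bf[apply(matrix(n[bf, 1], nrow(bf)), 1, min) > 2.5 - 1e-9, ]
  sys <- apply_traction(sys, endf, c(1, 0, 0))  # 1 MPa over 1 mm^2
  res <- fem_solve(sys)
  expect_lt(max(abs(res$strain[, 1] - 1e-3)), 1e-13)
  expect_lt(max(abs(res$strain[, 2] + 3e-4)), 1e-13)
  expect_lt(max(abs(res$strain[, 3] + 3e-4)), 1e-13)
  expect_lt(max(abs(res$strain[, 4:6])), 1e-13)
  # total x reactions balance the 1 N load to 1e-8
  rx <- sum(res$reactions[seq(1, length(res$reactions), 3)])
  expect_lt(abs(rx + 1), 1e-8)
  # fixed nodes stay put
  expect_identical(max(abs(res$u[n[, 1] < 1e-9, 1])), 0)
})

test_that("patch test: affine boundary displacement reproduces the constant
           strain field to 1e-10", {
  mesh <- bar_mesh(4, 3, 3, 0.3)
  sys <- fem_assemble(mesh, uniform_mats(123, 0.25))
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                3e-4, -5e-4, 2.5e-4,
                1e-4, 2e-4, 8e-4), 3, 3, byrow = TRUE)
  bn <- sort(unique(as.vector(tet_boundary_faces(mesh))))
  ub <- mesh$nodes[bn, ] %*% t(A)
  for (i in 1:3) sys <- fix_dofs(sys, bn, dofs = i, values = ub[, i])
  res <- fem_solve(sys)
  S <- (A + t(A)) / 2
  expc <- c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[2, 3], S[3, 1])
  expect_lt(max(abs(sweep(res$strain, 2, expc))), 1e-10)
})

test_that("slender cantilever tip deflection is within 15% of the
           Euler-Bernoulli closed form and converges under refinement", {
  bend <- function(nt) {
    h <- 1 / nt
    mesh <- bar_mesh(round(10 / h), nt, nt, h)
    sys <- fem_assemble(mesh, uniform_mats(1000, 0.3))
    n <- mesh$nodes
    sys <- fix_dofs(sys, which(n[, 1] < 1e-9), dofs = 1:3)
    bf <- tet_boundary_faces(mesh)
    L <- round(10 / h) * h
    endf <- bf[apply(matrix(n[bf, 1], nrow(bf)), 1, min) > L - 1e-9, ,
               drop = FALSE]
    P <- 0.01
    sys <- apply_traction(sys, endf, c(0, -P, 0))
    res <- fem_solve(sys)
    tip <- mean(res$u[n[, 1] > L - 1e-9, 2])
    abs(tip - (-P * L^3 / (3 * 1000 / 12))) / (P * L^3 / (3 * 1000 / 12))
  }
  e4 <- bend(4)
  e6 <- bend(6)
  expect_lt(e6, 0.15)
  expect_lt(e6, e4)   # error decreases under uniform refinement
})

test_that("load disc splits the force equally over its nodes and excludes
           fixed sets; empty discs are reported with the nearest distance", {
  f <- fe_phantom()
  sys <- fem_assemble(f$mesh, material_set())
  lc <- phantom_load_cases(f$model)$frontal
  sysl <- apply_load_case(sys, lc = lc)
  k <- length(sysl$disc_nodes)
  expect_gt(k, 0)
  nz <- sysl$f[sysl$f != 0]
  expect_equal(unname(sum(sysl$f[seq(2, length(sysl$f), 3)])), -0.1,
               tolerance = 1e-12)
  expect_true(all(abs(abs(nz) - 0.1 / k) < 1e-12))
  expect_false(any(sysl$fixed & sysl$f != 0))
  lc_far <- load_case(load_point = c(50, 50, 50))
  expect_error(apply_load_case(sys, lc = lc_far), "empty load disc")
})

test_that("strain measures follow the deviatoric von Mises convention and
           ordered principal values", {
  expect_identical(unname(strain_measures(matrix(0, 3, 3))), c(0, 0, 0))
  hyd <- strain_measures(diag(rep(0.01, 3)))
  expect_equal(unname(hyd), c(0, 0.01, 0.01), tolerance = 1e-14)
  uni <- strain_measures(diag(c(0.01, 0, 0)))
  expect_equal(unname(uni), c(2 * 0.01 / 3, 0.01, 0), tolerance = 1e-14)
  expect_error(strain_measures(matrix(1:9, 3, 3)), "symmetric")
  # e1 >= e2 >= e3 and vm >= 0 on random symmetric tensors
  set.seed(4)
  eps <- matrix(rnorm(600, sd = 0.01), ncol = 6)
  m <- suturemech:::strain_measures_m(eps)
  expect_true(all(m$e1 >= m$e2 - 1e-12 & m$e2 >= m$e3 - 1e-12))
  expect_true(all(m$vm >= 0))
})

test_that("region averages are volume-weighted means", {
  # two tets with volumes v and 2v built by splitting scaled cells
  res <- list(region = c(1L, 1L), volume = c(2, 1),
              strain = rbind(c(0.02, 0, 0, 0, 0, 0),
                             c(0.05, 0, 0, 0, 0, 0)))
  class(res) <- "fem_result"
  mesh <- list(roles = c(`1` = "suture"))
  avg <- suture_average(res, mesh, 1L)
  expect_equal(unname(avg["e1"]), (2 * 0.02 + 1 * 0.05) / 3,
               tolerance = 1e-14)
  expect_error(suture_average(res, mesh, 99L), "empty region")
})

test_that("softer sutures experience larger average strain, all else equal", {
  f <- fe_phantom()
  lc <- phantom_load_cases(f$model)$frontal
  soft <- fem_assemble(f$mesh,
                       material_set(young = c(bone = 3500, suture = 0.03,
                                              brain = 3e-6)))
  stiff <- fem_assemble(f$mesh,
                        material_set(young = c(bone = 3500, suture = 30,
                                               brain = 3e-6)))
  r_soft <- fem_suture_report(soft, lc)
  r_stiff <- fem_suture_report(stiff, lc)
  expect_true(all(r_soft$von_mises > r_stiff$von_mises))
})
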