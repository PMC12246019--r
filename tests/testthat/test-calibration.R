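test_that("percentage difference follows its definition and flags zero
           experimental strain", {
  expect_identical(percent_difference(1, 1), 0)
  expect_identical(percent_difference(0.5, 1), 50)
  expect_equal(percent_difference(2.45, 1), 145, tolerance = 1e-12)
  expect_warning(pd <- percent_difference(c(1, 1), c(1, 0)), "flagged")
  expect_true(is.na(pd[2]))
})

test_that("Lin's CCC: perfect concordance, perfect anticoncordance,
           degenerate constant, and the location-shift closed form", {
  x <- c(1, 2, 3, 4, 5.5)
  expect_identical(lin_ccc(x, x), 1)
  x0 <- x - mean(x)
  expect_equal(lin_ccc(x0, -x0), -1, tolerance = 1e-14)
  expect_identical(lin_ccc(x, rep(2, 5)), 0)
  n <- length(x)
  sx2 <- sum((x - mean(x))^2) / n
  expect_equal(lin_ccc(x, x + 3), 2 * sx2 / (2 * sx2 + 9),
               tolerance = 1e-14)
  expect_error(lin_ccc(x, x[1:3]), "equal length")
  expect_error(lin_ccc(1, 1), "at least 2")
})

test_that("CCC never exceeds |Pearson r| (Lin's inequality)", {
  set.seed(123)
  for (i in 1:200) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(length(a)) * runif(1, 0.2, 3) + rnorm(1, 0, 2)
    expect_lte(lin_ccc(a, b), abs(stats::cor(a, b)) + 1e-12)
  }
})

test_that("best-fit line: exact line, orthogonalised noise, anticorrelation
           sign, and the degenerate-x error", {
  x <- c(0, 1, 2, 3, 4)
  expect_equal(unname(fit_line(x, 2 * x + 1)), c(2, 1, 1),
               tolerance = 1e-12)
  set.seed(6)
  y <- rnorm(5)
  y_orth <- stats::residuals(stats::lm(y ~ x))  # uncorrelated with x
  f <- fit_line(x, y_orth)
  expect_lt(abs(f["slope"]), 1e-10)
  expect_lt(f["r_squared"], 1e-10)
  expect_lt(fit_line(x, -3 * x + rnorm(5, 0, 0.1))["slope"], 0)
  expect_error(fit_line(rep(1, 4), 1:4), "var\\(x\\)")
})

test_that("strain comparison reports CCC/fit and recomputes after
           exclusion exactly as a direct recomputation", {
  comp <- c(s1 = 1.0, s2 = 2.1, s3 = 0.4, s4 = 3.2, s5 = 1.4, s6 = 8.7)
  expc <- c(s1 = 1.1, s2 = 2.0, s3 = 0.5, s4 = 3.4, s5 = 1.2, s6 = 2.0)
  sc <- compare_strains(comp, expc, exclude = "s6")
  keep <- setdiff(names(comp), "s6")
  expect_equal(sc$excluded$ccc, lin_ccc(expc[keep], comp[keep]),
               tolerance = 1e-14)
  expect_false(isTRUE(all.equal(sc$all$ccc, sc$excluded$ccc)))
  # identical vectors: perfect agreement
  ident <- compare_strains(comp, comp)
  expect_equal(ident$all$ccc, 1, tolerance = 1e-14)
  expect_equal(unname(ident$all$fit[c("slope", "intercept", "r_squared")]),
               c(1, 0, 1), tolerance = 1e-12)
  # constant offset: CCC < 1 while Pearson r = 1
  off <- compare_strains(comp + 0.5, comp)
  expect_lt(off$all$ccc, 1)
  expect_equal(unname(off$all$fit["slope"]), 1, tolerance = 1e-12)
  expect_error(compare_strains(comp[1:2], comp[1:2], exclude = "s1"),
               "fewer than 2")
})

test_that("the sweep objective decomposes: the mean curve equals the
           unweighted mean of per-suture curves", {
  grid <- modulus_grid(8, 10, 1000)
  fake <- function(E) c(a = 1 / E, b = 2 / E + 0.001, c = 5 / sqrt(E))
  expv <- fake(100)
  cal <- calibrate_modulus(fake, expv, grid)
  expect_lt(max(abs(cal$mean_percent_diff -
                      colMeans(cal$percent_diff))), 1e-12)
  # 100 MPa falls between two grid points; the optimum is one of them
  neigh <- order(abs(log(grid) - log(100)))[1:2]
  expect_true(cal$best_index %in% neigh)
})

test_that("self-consistency: experiments generated by the same pipeline at a
           grid modulus are recovered exactly; off-grid moduli land on a
           neighbouring grid point", {
  fake <- function(E) c(a = 1 / E, b = 2 / E)
  grid <- modulus_grid(12, 10, 7000)
  gi <- 5L
  cal <- calibrate_modulus(fake, fake(grid[gi]), grid)
  expect_identical(cal$best_index, gi)
  # off-grid E* between grid points gi and gi+1
  E_off <- sqrt(grid[gi] * grid[gi + 1])
  cal2 <- calibrate_modulus(fake, fake(E_off), grid)
  expect_true(cal2$best_index %in% c(gi, gi + 1))
})

test_that("failed grid points are skipped and flagged", {
  fake <- function(E) {
    if (E > 100 && E < 1000) stop("solver blew up")
    c(a = 1 / E)
  }
  grid <- modulus_grid(10, 10, 7000)
  w <- testthat::capture_warnings(
    cal <- calibrate_modulus(fake, fake(20), grid))
  expect_true(any(grepl("failed", w)))
  expect_true(any(cal$failed))
  expect_false(cal$failed[cal$best_index])
})
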