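#' Percentage difference of computational to experimental strain
#'
#' \code{100 * |comp - exp| / exp}, the magnitude of the percentage
#' difference relative to the experimental value. Pairs with a zero
#' experimental strain are undefined and returned as \code{NA} with a
#' warning (flagged, not computed).
#'
#' @param comp,exp numeric vectors (recycled)
#' @export
percent_difference <- function(comp, exp) {
  out <- 100 * abs(comp - exp) / exp
  if (any(exp == 0)) {
    warning("percentage difference undefined for zero experimental strain; ",
            "flagged as NA")
    out[exp == 0] <- NA_real_
  }
  out
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2) with population (1/n)
#' moments, measuring agreement with the identity line: it penalises both
#' scatter and location/scale shift, so CCC <= |Pearson r| always.
#'
#' @param x,y numeric vectors of equal length >= 2
#' @param population use 1/n moments (default, Lin's original definition);
#'   \code{FALSE} uses 1/(n-1) sample moments
#' @export
lin_ccc <- function(x, y, population = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  denom_n <- if (population) n else n - 1
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / denom_n
  sx2 <- sum((x - mx)^2) / denom_n
  sy2 <- sum((y - my)^2) / denom_n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Ordinary least-squares best-fit line
#'
#' @param x,y numeric vectors
#' @return named vector \code{c(slope, intercept, r_squared)}
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need equal-length vectors with at least 2 points")
  if (stats::var(x) == 0) stop("var(x) = 0: best-fit line undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  c(slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Agreement statistics between computational and experimental strains
#'
#' CCC, best-fit line and R-squared over aligned per-suture strain pairs,
#' optionally recomputed with named sutures excluded (sensitivity to
#' extreme-strain sutures).
#'
#' @param comp,exp named numeric vectors aligned by suture id
#' @param exclude optional suture names to drop in a second pass
#' @export
compare_strains <- function(comp, exp, exclude = NULL) {
  if (!is.null(names(comp)) && !is.null(names(exp)))
    exp <- exp[names(comp)]
  if (length(comp) != length(exp) || anyNA(exp))
    stop("comp and exp must align by suture id")
  base <- list(ccc = lin_ccc(exp, comp),
               fit = fit_line(exp, comp),
               n = length(comp))
  out <- list(all = base)
  if (!is.null(exclude)) {
    keep <- !(names(comp) %in% exclude)
    if (sum(keep) < 2) stop("fewer than 2 pairs remain after exclusion")
    out$excluded <- list(ccc = lin_ccc(exp[keep], comp[keep]),
                         fit = fit_line(exp[keep], comp[keep]),
                         n = sum(keep), dropped = exclude)
  }
  structure(out, class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat("Strain agreement (n = ", x$all$n, "): CCC = ",
      signif(x$all$ccc, 4), ", Y = ", signif(x$all$fit["slope"], 5), "x + ",
      signif(x$all$fit["intercept"], 5), ", R^2 = ",
      signif(x$all$fit["r_squared"], 4), "\n", sep = "")
  if (!is.null(x$excluded))
    cat("  excluding ", paste(x$excluded$dropped, collapse = ", "),
        ": CCC = ", signif(x$excluded$ccc, 4), ", R^2 = ",
        signif(x$excluded$fit["r_squared"], 4), "\n", sep = "")
  invisible(x)
}

#' Default log-spaced modulus grid
#'
#' 25 points spanning 10 to 7000 MPa, matching the orders-of-magnitude
#' behaviour of the strain-versus-modulus response.
#' @param n number of grid points
#' @param from,to grid range, MPa
#' @export
modulus_grid <- function(n = 25L, from = 10, to = 7000) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Calibrate the bone Young's modulus against experimental suture strains
#'
#' Sweeps the bone modulus over a grid, computes per-suture von Mises
#' strain predictions with suture and brain moduli held fixed, records the
#' magnitude of the percentage difference to the experimental strains for
#' every suture individually and their unweighted mean, and selects the
#' modulus minimising the mean. This is the classic one-parameter inverse
#' calibration: the estimator interface returns a fitted-model object with
#' \code{coef}, \code{print}, \code{summary} and \code{plot} methods.
#'
#' @param strain_fn function(E_bone_MPa) returning a named vector of
#'   per-suture von Mises strains (see \code{\link{fem_strain_fn}})
#' @param exp named vector of experimental per-suture von Mises strains
#' @param grid modulus grid, MPa
#' @return object of class \code{modulus_calibration}
#' @export
calibrate_modulus <- function(strain_fn, exp, grid = modulus_grid()) {
  if (!length(grid)) stop("modulus grid is empty")
  curves <- matrix(NA_real_, length(exp), length(grid),
                   dimnames = list(names(exp), NULL))
  failed <- logical(length(grid))
  for (g in seq_along(grid)) {
    pred <- tryCatch(strain_fn(grid[g]), error = function(e) {
      warning("FE evaluation failed at ", signif(grid[g], 4), " MPa: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(pred)) { failed[g] <- TRUE; next }
    curves[, g] <- pred[names(exp)]
  }
  if (all(failed)) stop("every grid point failed")
  pd <- 100 * abs(sweep(curves, 1, exp, `-`)) / exp
  mean_pd <- colMeans(pd)
  ok <- !failed
  best <- which(ok)[which.min(mean_pd[ok])]
  structure(list(grid = grid, curves = curves, percent_diff = pd,
                 mean_percent_diff = mean_pd, best_index = best,
                 E_hat = grid[best], exp = exp, failed = failed),
            class = "modulus_calibration")
}

#' @export
coef.modulus_calibration <- function(object, ...) {
  c(E_bone = object$E_hat)
}

#' @export
print.modulus_calibration <- function(x, ...) {
  cat("Bone modulus calibration over ", length(x$grid), " grid points (",
      signif(min(x$grid), 3), "-", signif(max(x$grid), 4), " MPa)\n",
      "  best-fit E_bone = ", signif(x$E_hat, 4), " MPa (mean |%diff| = ",
      signif(x$mean_percent_diff[x$best_index], 4), "%)\n", sep = "")
  if (any(x$failed))
    cat("  ", sum(x$failed), " grid point(s) failed and were skipped\n",
        sep = "")
  invisible(x)
}

#' @export
summary.modulus_calibration <- function(object, ...) {
  comp <- object$curves[, object$best_index]
  agr <- compare_strains(comp, object$exp)
  cat("Calibrated bone Young's modulus: ", signif(object$E_hat, 4),
      " MPa\n", sep = "")
  cat("Per-suture |% difference| at the optimum:\n")
  print(round(object$percent_diff[, object$best_index], 2))
  print(agr)
  invisible(list(E_hat = object$E_hat, agreement = agr))
}

#' @export
plot.modulus_calibration <- function(x, ...) {
  graphics::matplot(x$grid, t(x$percent_diff), type = "l", lty = 1, log = "x",
          xlab = "bone Young's modulus (MPa)",
          ylab = "|% difference| to experimental strain",
          col = grDevices::hcl.colors(nrow(x$percent_diff), "Dark 3"), ...)
  graphics::lines(x$grid, x$mean_percent_diff, lwd = 3)
  graphics::abline(v = x$E_hat, lty = 2)
  graphics::legend("topright", bty = "n", lwd = c(1, 3),
                   legend = c("per suture", "mean"))
  invisible(x)
}

#' FE strain predictor for the modulus sweep
#'
#' Builds a closure \code{function(E_bone)} that re-forms the stiffness
#' matrix from the cached per-material unit blocks, re-uses the symbolic
#' Cholesky factorisation across moduli, and returns the per-suture
#' volume-weighted average von Mises strains for the given load case.
#'
#' @param system an assembled \code{fem_system}
#' @param lc a \code{load_case}
#' @return function(E_bone_MPa) -> named per-suture von Mises strains
#' @export
fem_strain_fn <- function(system, lc) {
  system <- apply_load_case(system, lc = lc)
  free <- !system$fixed
  Kr_ff <- lapply(system$Kr, function(K) K[free, free, drop = FALSE])
  young <- system$mats$young
  fixed_part <- Reduce(`+`, Map(function(m) young[[m]] * Kr_ff[[m]],
                                setdiff(names(Kr_ff), "bone")))
  if (is.null(fixed_part)) fixed_part <- 0 * Kr_ff[["bone"]]
  rhs <- system$f[free]
  mesh <- system$mesh
  sut <- as.integer(names(mesh$roles)[mesh$roles == "suture"])
  pairs0 <- attr(mesh, "suture_pairs")
  if (!is.null(pairs0)) {
    bones <- as.integer(names(mesh$roles)[mesh$roles == "bone"])
    keep <- pairs0$bone_a %in% bones & pairs0$bone_b %in% bones
    sut <- intersect(sut, pairs0$label[keep])
  }
  chol_cache <- NULL
  function(E_bone) {
    Kff <- Matrix::forceSymmetric(fixed_part + E_bone * Kr_ff[["bone"]])
    if (is.null(chol_cache)) {
      chol_cache <<- Matrix::Cholesky(Kff, super = TRUE)
    } else {
      chol_cache <<- Matrix::update(chol_cache, Kff)
    }
    uf <- as.vector(Matrix::solve(chol_cache, rhs))
    u <- numeric(length(system$f))
    u[free] <- uf
    U <- matrix(u, ncol = 3, byrow = TRUE)
    H <- displacement_gradients(system, U)
    eps <- cbind(H[, 1], H[, 5], H[, 9],
                 (H[, 2] + H[, 4]) / 2, (H[, 6] + H[, 8]) / 2,
                 (H[, 3] + H[, 7]) / 2)
    out <- numeric(length(sut))
    names(out) <- sprintf("suture_%d", sut)
    pairs <- attr(mesh, "suture_pairs")
    for (si in seq_along(sut)) {
      sel <- mesh$region == sut[si]
      m <- strain_measures_m(eps[sel, , drop = FALSE])
      w <- system$V[sel]
      out[si] <- sum(m$vm * w) / sum(w)
      if (!is.null(pairs)) {
        row <- pairs[pairs$label == sut[si], ]
        if (nrow(row) == 1)
          names(out)[si] <- sprintf("suture_%d_%d", row$bone_a, row$bone_b)
      }
    }
    out
  }
}
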