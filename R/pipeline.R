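#' Build the complete bone + suture + endocast + cover phantom model
#'
#' Runs the model-construction pipeline on a synthetic phantom: generate
#' the disarticulated plates, synthesise sutures from their contacts,
#' extract the endocast, seal residual openings with covers, and split the
#' suture label per bone pair.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param morph a \code{\link{morph_params}}; the defaults are tuned to
#'   9.5-25 um voxel pitches — for coarse lattices pass scaled counts
#' @param closing_radius endocast closing radius (voxels); default twice
#'   the suture gap
#' @param split split sutures per bone pair?
#' @return a \code{labeled_volume} carrying all model labels
#' @export
build_phantom_model <- function(spec = phantom_spec(),
                                morph = morph_params(),
                                closing_radius = NULL, split = TRUE) {
  vol <- generate_phantom(spec)
  model <- synthesize_sutures(vol, morph)
  if (is.null(closing_radius))
    closing_radius <- max(2L, 2L * round(spec$gap_width / spec$voxel_size))
  model <- extract_endocast(model, closing_radius)
  model <- generate_covers(model)
  if (split) model <- split_sutures(model)
  model
}

#' Tetrahedral mesh of a phantom model
#'
#' @param model output of \code{\link{build_phantom_model}}
#' @param max_size maximum element edge, mm
#' @param coarsen integer lattice coarsening factor applied before meshing
#'   (see \code{\link{coarsen_volume}})
#' @return a \code{tet_mesh} with the suture pair table attached
#' @export
phantom_mesh <- function(model, max_size = Inf, coarsen = 1L) {
  if (coarsen > 1L) model <- coarsen_volume(model, coarsen)
  mesh <- tetrahedralize(model, max_size = max_size)
  attr(mesh, "suture_pairs") <- attr(model, "suture_pairs")
  mesh
}

#' The four calvarial loading locations of a phantom
#'
#' Places point loads analogous to the experimental frontal, anterior
#' parietal, posterior parietal and interparietal loading sites: each load
#' point sits on the dorsal surface (45 degrees elevation) near a plate
#' boundary, pressing ventrally. Each load case carries the identity of
#' the suture it targets (the nearest plate boundary) and of the sutures
#' flanking the loaded plate, as attributes \code{"target"} and
#' \code{"side_sutures"}.
#'
#' @param model phantom model (needs the phantom spec attributes)
#' @param force total force, N
#' @param disc_diameter loaded disc diameter, mm
#' @return named list of \code{load_case} objects
#' @export
phantom_load_cases <- function(model, force = 0.1, disc_diameter = 1) {
  spec <- attr(model, "spec")
  centre <- attr(model, "centre")
  if (is.null(spec) || is.null(centre))
    stop("model does not carry phantom spec attributes")
  n <- spec$n_plates
  delta <- 2 * pi / n
  plate_at <- function(theta)
    (floor((atan2(sin(theta), cos(theta)) + pi - delta / 2) / delta) %% n) + 1
  pair_at <- function(phi) {
    p <- sort(c(plate_at(phi - 0.05), plate_at(phi + 0.05)))
    sprintf("suture_%d_%d", p[1], p[2])
  }
  # boundary angles nearest the anterior (+AP) and posterior (-AP) poles on
  # the "left" (positive mediolateral... negative ml) side of the dome
  bound <- -pi + (seq_len(n) - 0.5) * delta
  ant_left <- bound[which.min(abs(bound - 3 * pi / 4))]
  post_left <- bound[which.min(abs(bound + 3 * pi / 4))]
  off <- 0.2 * delta
  angles <- c(frontal = ant_left - off,
              anterior_parietal = ant_left + off,
              posterior_parietal = post_left - off,
              interparietal = post_left + off)
  targets <- c(pair_at(ant_left), pair_at(ant_left),
               pair_at(post_left), pair_at(post_left))
  elev <- pi / 4
  out <- list()
  for (i in seq_along(angles)) {
    th <- angles[i]
    p_um <- centre + spec$outer_radius *
      c(cos(elev) * cos(th), sin(elev), cos(elev) * sin(th))
    lc <- load_case(load_point = p_um / 1000, disc_diameter = disc_diameter,
                    force = force, direction = c(0, -1, 0),
                    name = names(angles)[i])
    loaded_plate <- plate_at(th)
    flank <- bound[order(pmin(abs(bound - th),
                              abs(bound - th + 2 * pi),
                              abs(bound - th - 2 * pi)))[1:2]]
    attr(lc, "target") <- targets[i]
    attr(lc, "side_sutures") <- unique(vapply(flank, pair_at, character(1)))
    attr(lc, "loaded_plate") <- loaded_plate
    out[[names(angles)[i]]] <- lc
  }
  out
}

#' Per-suture FE strain report
#'
#' Solves the loaded system and tabulates volume-weighted average von
#' Mises, 1st and 3rd principal strains for every suture region.
#'
#' @param system an assembled \code{fem_system}
#' @param lc a \code{load_case}
#' @return data frame with one row per suture
#' @export
fem_suture_report <- function(system, lc) {
  system <- apply_load_case(system, lc = lc)
  res <- fem_solve(system)
  mesh <- system$mesh
  sut <- as.integer(names(mesh$roles)[mesh$roles == "suture"])
  pairs <- attr(mesh, "suture_pairs")
  # investigated sutures are the bone-to-bone joints; sutures flanking a
  # constraint patch carry suture material but are not reported
  if (!is.null(pairs)) {
    bones <- as.integer(names(mesh$roles)[mesh$roles == "bone"])
    keep <- pairs$bone_a %in% bones & pairs$bone_b %in% bones
    sut <- intersect(sut, pairs$label[keep])
  }
  rows <- lapply(sut, function(s) {
    avg <- suture_average(res, mesh, s)
    nm <- if (!is.null(pairs) && s %in% pairs$label) {
      r <- pairs[pairs$label == s, ]
      sprintf("suture_%d_%d", r$bone_a, r$bone_b)
    } else sprintf("suture_%d", s)
    data.frame(suture = nm, label = s, von_mises = avg["von_mises"],
               e1 = avg["e1"], e3 = avg["e3"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "load_case") <- lc$name
  out
}
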