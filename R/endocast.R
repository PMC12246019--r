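#' Extract the intracranial volume (endocast)
#'
#' Morphologically closes the non-background mask with a Chebyshev ball of
#' radius \code{closing_radius} (sealing openings narrower than twice the
#' radius), then classifies as endocast every original-background voxel
#' that the closed mask encloses, i.e. that an exterior flood fill started
#' at the volume border cannot reach. Only the largest enclosed component
#' is kept. The endocast is disjoint from bone and suture by construction.
#'
#' @param model a \code{labeled_volume} with an enclosed or nearly enclosed
#'   cavity
#' @param closing_radius closing radius in voxels; a good default is twice
#'   the suture gap in voxels
#' @return the model with one added label of role \code{"endocast"}
#' @export
extract_endocast <- function(model, closing_radius = 4L) {
  stopifnot(inherits(model, "labeled_volume"), closing_radius >= 0)
  lab <- model$labels
  d <- dim(lab)
  solid <- lab > 0L
  closed <- erode_mask(dilate_mask(solid, closing_radius), closing_radius)
  open_space <- !closed
  exterior <- cpp_flood_fill(open_space, d, border_indices(d), 6L)
  cavity <- open_space & !exterior & lab == 0L
  if (!any(cavity))
    stop("cavity not closable at this radius (", closing_radius,
         " voxels): interior flood fill escapes to the volume boundary")
  comp <- cpp_label_components(cavity, d, 6L)
  main <- which.max(tabulate(comp[comp > 0L]))
  endo <- comp == main
  el <- max(as.integer(names(model$roles))) + 1L
  lab[endo] <- el
  roles <- c(model$roles, structure("endocast", names = as.character(el)))
  out <- labeled_volume(lab, model$voxel_size, roles)
  attributes(out) <- c(attributes(out),
                       attributes(model)[setdiff(names(attributes(model)),
                                                 names(attributes(out)))])
  out
}

#' Seal exposed endocast surface with cover material
#'
#' Wherever the endocast surface is exposed to the exterior (an exterior
#' flood fill through background can reach a voxel face-adjacent to the
#' endocast), those exterior voxels are labelled \code{"cover"} — at least
#' a one-voxel shell — and the flood fill is repeated until the exterior
#' can no longer touch the endocast. Cover material is assigned suture
#' elastic properties downstream. A fully shielded endocast yields zero
#' cover voxels.
#'
#' @param model a \code{labeled_volume} containing an endocast label
#' @return the model with a cover label added when any opening exists
#' @export
generate_covers <- function(model) {
  stopifnot(inherits(model, "labeled_volume"))
  endo <- labels_of_role(model, "endocast")
  if (length(endo) == 0) stop("endocast label required; run extract_endocast")
  lab <- model$labels
  d <- dim(lab)
  emask <- array(lab %in% endo, d)
  near_endo <- dilate_face(emask)
  cover <- array(FALSE, d)
  repeat {
    bg <- lab == 0L & !cover
    exterior <- cpp_flood_fill(bg, d, border_indices(d), 6L)
    exposed <- exterior & near_endo
    if (!any(exposed)) break
    cover <- cover | exposed
  }
  if (any(cover)) {
    cl <- max(as.integer(names(model$roles))) + 1L
    lab[cover] <- cl
    roles <- c(model$roles, structure("cover", names = as.character(cl)))
  } else {
    roles <- model$roles
  }
  out <- labeled_volume(lab, model$voxel_size, roles)
  attributes(out) <- c(attributes(out),
                       attributes(model)[setdiff(names(attributes(model)),
                                                 names(attributes(out)))])
  attr(out, "n_cover_voxels") <- sum(cover)
  out
}

# one face-adjacency (6-neighbourhood) dilation of a logical mask
dilate_face <- function(mask) {
  out <- mask
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out | shift3(mask, o[1], o[2], o[3], fill = FALSE)
  out
}
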