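#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between two points after per-axis minimum-image
#' wrapping.  Symmetric, and never larger than half the box diagonal.
#'
#' @param p,q numeric length-3 positions (nm).
#' @param box orthorhombic box lengths (nm), all > 0.
#' @return distance in nm.
#' @export
min_image_distance <- function(p, q, box) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0))
    stop("box lengths must be three positive numbers")
  d <- as.numeric(p) - as.numeric(q)
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# minimum-image wrap of an n x 3 displacement matrix
mic_displacements <- function(d, box) {
  for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
  d
}

#' Shortest cross-group atom-pair distance in a frame
#'
#' The distance between a molecule and a membrane surface is taken as the
#' shortest minimum-image distance between any atom of one group and any
#' atom of the other.
#'
#' @param fr a [frame()].
#' @param group_a,group_b non-empty integer vectors of atom indices.
#' @return minimum distance in nm.
#' @export
min_distance_to_selection <- function(fr, group_a, group_b) {
  if (!length(group_a)) stop("group_a is empty")
  if (!length(group_b)) stop("group_b is empty")
  pa <- fr$positions[group_a, , drop = FALSE]
  pb <- fr$positions[group_b, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(pa))) {
    d <- mic_displacements(sweep(pb, 2, pa[i, ]), fr$box)
    best <- min(best, min(rowSums(d * d)))
  }
  sqrt(best)
}

# vectorized over frames: min cross-group distance per frame
min_distance_series <- function(traj, group_a, group_b, idx) {
  if (!length(group_a)) stop("group_a is empty")
  if (!length(group_b)) stop("group_b is empty")
  vapply(idx, function(i)
    min_distance_to_selection(get_frame(traj, i), group_a, group_b), 0)
}

#' Bilayer mid-plane position
#'
#' The mid-plane is the mass-weighted mean z-coordinate of the lipid atoms;
#' all reported z-locations are measured relative to it.  The membrane
#' normal is z by convention, with the upper leaflet at z greater than the
#' mid-plane.
#'
#' @param fr a [frame()].
#' @param top the matching [topology()] (source of masses).
#' @param atoms lipid atom indices; defaults to all atoms with a leaflet
#'   label.
#' @return mid-plane z in nm.
#' @export
assign_midplane <- function(fr, top, atoms = lipid_atoms(top)) {
  if (!length(atoms)) stop("lipid atom set is empty")
  weighted.mean(fr$positions[atoms, 3], top$mass[atoms])
}

# mid-plane per frame; if the system has no lipid atoms fall back to the
# geometric box centre (bulk simulations)
midplane_series <- function(traj, idx = seq_along(traj$times)) {
  lip <- lipid_atoms(traj$topology)
  if (!length(lip)) return(traj$boxes[idx, 3] / 2)
  m <- traj$topology$mass[lip]
  vapply(idx, function(i) weighted.mean(traj$coords[lip, 3, i], m), 0)
}
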