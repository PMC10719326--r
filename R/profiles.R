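#' One-dimensional mass density profile along the membrane normal
#'
#' Time-averaged mass density (kg/m^3) per z-bin for each named atom group,
#' with z measured from the per-frame mid-plane.  Densities are mass per
#' bin divided by the bin volume (box x-y area times bin width), converted
#' from amu/nm^3 with the factor 1.66053906660.
#'
#' @param traj a [trajectory()].
#' @param groups named list of atom index vectors.
#' @param bin_width bin width in nm (> 0).
#' @param window analyzed time range (ps); \code{NULL} for all frames.
#' @return object of class \code{"density_profile"}: list with
#'   \code{bin_edges}, \code{z} (bin centres, nm relative to the mid-plane),
#'   and \code{values} (bins x groups matrix, kg/m^3).
#' @export
density_profile <- function(traj, groups, bin_width = 0.1, window = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  idx <- window_frames(traj, window)
  z0 <- midplane_series(traj, idx)
  all_atoms <- unique(unlist(groups))
  if (length(all_atoms)) {
    zr <- sweep(matrix(traj$coords[all_atoms, 3, idx],
                       nrow = length(all_atoms)), 2, z0)
    lo <- floor(min(zr) / bin_width) * bin_width
    hi <- ceiling(max(zr) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
  } else {
    lo <- -bin_width
    hi <- bin_width
  }
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1
  vals <- matrix(0, nb, length(groups),
                 dimnames = list(NULL, names(groups)))
  area <- traj$boxes[idx, 1] * traj$boxes[idx, 2]
  for (g in seq_along(groups)) {
    atoms <- groups[[g]]
    if (!length(atoms)) next
    m <- traj$topology$mass[atoms]
    acc <- numeric(nb)
    for (k in seq_along(idx)) {
      z <- traj$coords[atoms, 3, idx[k]] - z0[k]
      bin <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE),
                       1L), nb)
      mass_in <- vapply(split(m, factor(bin, levels = seq_len(nb))),
                        sum, 0)
      acc <- acc + mass_in / (area[k] * bin_width)
    }
    vals[, g] <- acc / length(idx) * .amu_nm3_to_kg_m3
  }
  structure(list(bin_edges = edges, z = (edges[-1] + edges[-nb - 1]) / 2,
                 values = vals, bin_width = bin_width,
                 mean_area = mean(area), n_frames = length(idx)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf(
    "density profile: %d bins of %.3g nm, groups: %s (%d frames)\n",
    length(x$z), x$bin_width, paste(colnames(x$values), collapse = ", "),
    x$n_frames))
  invisible(x)
}

#' Occupancy histogram of the drug along the membrane normal
#'
#' Frame counts of the drug centre-of-mass z-coordinate (relative to the
#' per-frame mid-plane, or to the box centre when the system has no
#' lipids), on bins aligned to multiples of \code{bin_width}.
#'
#' @param traj a [trajectory()].
#' @param drug drug atom indices.
#' @param bin_width bin width in nm.
#' @param window analyzed time range (ps); \code{NULL} for all frames.
#' @return object of class \code{"occupancy_histogram"}: list with
#'   \code{bin_edges}, \code{z} (bin centres) and \code{counts}.
#' @export
occupancy_histogram <- function(traj, drug, bin_width = 0.1, window = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  idx <- window_frames(traj, window)
  z <- com_series(traj, drug)[idx, 3] - midplane_series(traj, idx)
  lo <- floor(min(z) / bin_width) * bin_width
  hi <- ceiling(max(z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1
  bin <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L), nb)
  structure(list(bin_edges = edges, z = (edges[-1] + edges[-nb - 1]) / 2,
                 counts = tabulate(bin, nb), n_frames = length(idx)),
            class = "occupancy_histogram")
}

#' Free-energy profile by Boltzmann inversion
#'
#' Converts an equilibrium occupancy histogram into a free-energy profile
#' \code{F(z) = -ln(p(z) / max p(z))} in kT units, anchored so the most
#' occupied bin sits at zero.  Empty bins yield \code{NA}, never infinities.
#'
#' @param hist an [occupancy_histogram()] (or any list with \code{z} and
#'   \code{counts}).
#' @param temperature K; metadata only, since the profile is expressed in
#'   kT.
#' @return data frame of class \code{"free_energy_profile"} with columns
#'   \code{z} (nm) and \code{F_kT}.
#' @export
free_energy_profile <- function(hist, temperature = 310) {
  counts <- hist$counts
  if (all(counts == 0)) stop("all-zero occupancy histogram")
  p <- counts / sum(counts)
  F <- -log(p / max(p))
  F[counts == 0] <- NA_real_
  out <- data.frame(z = hist$z, F_kT = F)
  attr(out, "temperature") <- temperature
  class(out) <- c("free_energy_profile", "data.frame")
  out
}

#' Average drug location relative to the bilayer mid-plane
#'
#' Frames are partitioned by the sign of the drug centre-of-mass
#' z-coordinate relative to the per-frame mid-plane, and the mean absolute
#' distance from the mid-plane is reported separately for the
#' above-upper-layer (z > 0) and below-lower-layer (z < 0) subsets.  Frames
#' with the drug between the head-group planes still partition by z-sign —
#' there is no third category.  A side with no frames reports an absent
#' (\code{NA}) value flagged \code{"absent"}.
#'
#' @param traj a [trajectory()].
#' @param drug drug atom indices.
#' @param window analyzed time range (ps); \code{NULL} for all frames.
#' @param n_blocks blocks for the uncertainty estimate.
#' @return list with [metric_result()] elements \code{upper_side} and
#'   \code{lower_side} (nm).
#' @export
midplane_location <- function(traj, drug, window = NULL, n_blocks = 4) {
  idx <- window_frames(traj, window)
  z <- com_series(traj, drug)[idx, 3] - midplane_series(traj, idx)
  win <- range(traj$times[idx])
  one_side <- function(sel, label) {
    zz <- abs(z[sel])
    if (!length(zz))
      return(metric_result(NA_real_, selection = label, window = win,
                           units = "nm", n_frames = 0L, note = "absent"))
    metric_result(
      value = mean(zz),
      block_std = block_std_or_na(zz, n_blocks),
      n_blocks = if (length(zz) >= n_blocks) n_blocks else NA_integer_,
      selection = label, window = win, units = "nm",
      n_frames = length(zz))
  }
  list(upper_side = one_side(z >= 0, "above upper layer"),
       lower_side = one_side(z < 0, "below lower layer"))
}

#' Molecular dipole moment from point charges
#'
#' \code{mu = |sum q_i r_i|}, converted at 1 e nm = 48.0321 Debye.  For a
#' net-neutral site set the moment is origin-independent; for charged
#' species it is reported about the centre of mass with a neutrality
#' warning.
#'
#' @param atoms data frame (e.g. topology rows) with \code{charge} and
#'   \code{mass} columns.
#' @param positions matrix of site positions (nm), one row per atom.
#' @return list with \code{debye}, the vector \code{mu_e_nm} (e nm) and
#'   \code{net_charge} (e).
#' @export
dipole_moment <- function(atoms, positions) {
  positions <- as.matrix(positions)
  q <- atoms$charge
  if (length(q) != nrow(positions))
    stop("atoms and positions disagree on the number of sites")
  net <- sum(q)
  if (abs(net) > 1e-8) {
    warning(sprintf(
      "net charge %.3f e: dipole reported about the centre of mass", net))
    w <- if (!is.null(atoms$mass)) atoms$mass else rep(1, length(q))
    origin <- colSums(positions * (w / sum(w)))
    positions <- sweep(positions, 2, origin)
  }
  mu <- colSums(positions * q)
  list(debye = sqrt(sum(mu * mu)) * .e_nm_to_debye, mu_e_nm = mu,
       net_charge = net)
}
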