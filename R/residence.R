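#' Residence time near a membrane surface
#'
#' The percentage of analyzed frames in which the shortest minimum-image
#' distance between any drug atom and any atom of the leaflet selection is
#' at or below the cutoff.  The default cutoff of 0.3 nm is the average
#' length of a biological salt bridge; the boundary is inclusive
#' ("0.3 nm or less").  Computed independently per leaflet by passing the
#' corresponding atom selection.
#'
#' @param traj a [trajectory()].
#' @param drug drug atom indices.
#' @param leaflet_atoms atom indices of the leaflet surface ("surface atom"
#'   means any atom of a lipid assigned to that leaflet; narrower selections
#'   may be passed).
#' @param cutoff contact distance in nm (> 0).
#' @param window analyzed time range \code{c(t0, t1)} in ps; \code{NULL}
#'   analyzes the full trajectory.
#' @param n_blocks blocks for the uncertainty estimate.
#' @param selection label stored in the result.
#' @return a [metric_result()] in percent.
#' @export
residence_time <- function(traj, drug, leaflet_atoms, cutoff = 0.3,
                           window = NULL, n_blocks = 4, selection = "") {
  if (cutoff <= 0) stop("cutoff must be > 0")
  idx <- window_frames(traj, window)
  d <- min_distance_series(traj, drug, leaflet_atoms, idx)
  within <- d <= cutoff
  metric_result(
    value = 100 * mean(within),
    block_std = block_std_or_na(within, n_blocks,
                                stat = function(b) 100 * mean(b)),
    n_blocks = if (length(within) >= n_blocks) n_blocks else NA_integer_,
    selection = selection,
    window = range(traj$times[idx]), units = "%",
    n_frames = length(idx))
}
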