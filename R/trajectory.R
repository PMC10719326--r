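#' A single trajectory frame
#'
#' @param time frame time in ps.
#' @param box orthorhombic box lengths (nm), length-3 positive numeric.
#' @param positions numeric matrix, one row per atom, columns x/y/z in nm.
#' @return object of class \code{"md_frame"}.
#' @export
frame <- function(time, box, positions) {
  box <- as.numeric(box)
  if (length(box) != 3 || anyNA(box) || any(box <= 0))
    stop("box must be three positive lengths (nm)")
  positions <- as.matrix(positions)
  if (ncol(positions) != 3)
    stop("positions must be an n x 3 matrix")
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  structure(list(time = as.numeric(time), box = box, positions = positions),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("frame: t = %g ps, %d atoms, box %.3f x %.3f x %.3f nm\n",
              x$time, nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Build a trajectory from a topology and frames
#'
#' A trajectory holds time-ordered coordinates with per-frame orthorhombic
#' box dimensions.  Frame times must be strictly increasing and the atom
#' count constant and equal to the topology.
#'
#' @param topology a [topology()].
#' @param frames list of [frame()] objects, or \code{NULL} when
#'   \code{times}/\code{boxes}/\code{coords} are given directly.
#' @param times numeric vector of frame times (ps).
#' @param boxes numeric matrix (n_frames x 3) of box lengths.
#' @param coords numeric array \code{[n_atoms, 3, n_frames]}.
#' @return object of class \code{"trajectory"}.
#' @export
trajectory <- function(topology, frames = NULL, times = NULL, boxes = NULL,
                       coords = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (!is.null(frames)) {
    times <- vapply(frames, function(f) f$time, 0)
    boxes <- do.call(rbind, lapply(frames, function(f) f$box))
    na <- nrow(frames[[1]]$positions)
    coords <- array(NA_real_, c(na, 3, length(frames)))
    for (i in seq_along(frames)) {
      if (nrow(frames[[i]]$positions) != na)
        stop("atom count varies across frames")
      coords[, , i] <- frames[[i]]$positions
    }
  }
  if (dim(coords)[1] != nrow(topology))
    stop(sprintf("frame has %d positions but topology has %d atoms",
                 dim(coords)[1], nrow(topology)))
  if (length(times) != dim(coords)[3])
    stop("times and coords disagree on the number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  boxes <- matrix(as.numeric(boxes), ncol = 3)
  if (any(boxes <= 0)) stop("box lengths must be > 0")
  structure(list(topology = topology, times = as.numeric(times),
                 boxes = boxes, coords = coords,
                 frame_interval = if (length(times) > 1)
                   stats::median(diff(times)) else NA_real_),
            class = "trajectory")
}

#' @rdname trajectory
#' @param traj a trajectory.
#' @export
n_frames <- function(traj) length(traj$times)

#' @rdname trajectory
#' @param i frame index.
#' @export
get_frame <- function(traj, i) {
  frame(traj$times[i], traj$boxes[i, ], traj$coords[, , i])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames x %d atoms, t = %g..%g ps (interval %g ps)\n",
    n_frames(x), dim(x$coords)[1], x$times[1], x$times[n_frames(x)],
    x$frame_interval))
  invisible(x)
}

# Restrict a trajectory to a [t0, t1] time window (ps); NULL keeps all.
# Returns integer frame indices.
window_frames <- function(traj, window = NULL) {
  if (is.null(window)) return(seq_along(traj$times))
  stopifnot(length(window) == 2)
  idx <- which(traj$times >= window[1] & traj$times <= window[2])
  if (!length(idx))
    stop("empty trajectory window [", window[1], ", ", window[2], "] ps")
  idx
}

#' Default equilibration-discarding analysis window
#'
#' The production-analysis convention used by the pipeline: drop the first
#' third of the trajectory and analyze the remainder (which the uncertainty
#' protocol then splits into blocks).
#'
#' @param traj a trajectory.
#' @param discard_fraction fraction of the time span dropped from the start.
#' @return numeric \code{c(t0, t1)} time window in ps.
#' @export
analysis_window <- function(traj, discard_fraction = 1 / 3) {
  t0 <- traj$times[1]
  t1 <- traj$times[n_frames(traj)]
  c(t0 + discard_fraction * (t1 - t0), t1)
}

# mass-weighted center of mass of a set of atoms, one frame
com_position <- function(positions, masses) {
  w <- masses / sum(masses)
  colSums(positions * w)
}

# COM time series of an atom selection: n_frames x 3 matrix
com_series <- function(traj, atoms) {
  m <- traj$topology$mass[atoms]
  w <- m / sum(m)
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, 3)
  for (j in 1:3) {
    sub <- matrix(traj$coords[atoms, j, ], nrow = length(atoms), ncol = nf)
    out[, j] <- colSums(sub * w)
  }
  out
}
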