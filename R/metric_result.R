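#' Scalar metric with block-averaged uncertainty
#'
#' Container for a trajectory-derived scalar: its value, the block standard
#' deviation (the spread of the metric recomputed on consecutive blocks of
#' the analysis window), the selection it describes, and the time window it
#' was measured on.
#'
#' @param value metric value.
#' @param block_std block standard deviation, same units (\code{NA} when the
#'   window cannot support >= 2 blocks).
#' @param n_blocks number of blocks used.
#' @param selection free-text description of the leaflet/group analyzed.
#' @param window analyzed time range \code{c(t0, t1)} in ps.
#' @param units unit label.
#' @param n_frames number of frames analyzed.
#' @param note optional flag, e.g. \code{"absent"} for an empty side.
#' @return object of class \code{"metric_result"}.
#' @export
metric_result <- function(value, block_std = NA_real_, n_blocks = NA_integer_,
                          selection = "", window = c(NA_real_, NA_real_),
                          units = "", n_frames = NA_integer_, note = NULL) {
  if (!is.na(block_std)) {
    if (block_std < 0) stop("block_std must be >= 0")
    if (is.na(n_blocks) || n_blocks < 2)
      stop("a reported block_std requires n_blocks >= 2")
  }
  structure(list(value = value, block_std = block_std,
                 n_blocks = n_blocks, selection = selection,
                 window = window, units = units, n_frames = n_frames,
                 note = note),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s%s: %s", x$selection,
              if (nzchar(x$selection)) " " else "",
              if (is.na(x$value)) "absent" else format(x$value)))
  if (!is.na(x$block_std))
    cat(sprintf(" +/- %s (block sd, %d blocks)", format(x$block_std),
                x$n_blocks))
  if (nzchar(x$units)) cat(" ", x$units, sep = "")
  if (!is.null(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.metric_result <- function(x, ...) {
  data.frame(value = x$value, block_std = x$block_std,
             n_blocks = x$n_blocks, selection = x$selection,
             window_start = x$window[1], window_end = x$window[2],
             units = x$units, n_frames = x$n_frames,
             note = if (is.null(x$note)) "" else x$note,
             stringsAsFactors = FALSE)
}

#' Block standard deviation of a per-frame series
#'
#' Splits a series into \code{n_blocks} consecutive, near-equal, non-empty
#' blocks, evaluates the metric independently on each block, and returns the
#' sample standard deviation of the block values.  Invariant under
#' permutation of the block values.
#'
#' @param x per-frame series (already restricted to the analysis window).
#' @param n_blocks number of blocks (>= 2).
#' @param stat the per-block metric; default the mean.
#' @return the sample standard deviation across blocks, with the block
#'   values attached as attribute \code{"block_values"}.
#' @export
block_std <- function(x, n_blocks = 4, stat = mean) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  n <- length(x)
  if (n < n_blocks)
    stop("window cannot be divided into ", n_blocks, " non-empty blocks")
  grp <- ceiling(seq_len(n) / (n / n_blocks))
  vals <- vapply(split(x, grp), stat, 0)
  structure(sd(vals), block_values = unname(vals))
}

# block sd helper tolerating short series (returns NA instead of erroring)
block_std_or_na <- function(x, n_blocks, stat = mean) {
  if (length(x) >= n_blocks && n_blocks >= 2)
    as.numeric(block_std(x, n_blocks, stat))
  else NA_real_
}
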