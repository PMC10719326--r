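#' Mean square displacement of the drug centre of mass
#'
#' Time-origin-averaged MSD of the drug centre of mass, total and per axis,
#' for lag times up to \code{max_lag_fraction} of the analyzed window.
#' Periodic-image jumps in x/y (the generator stores those axes wrapped) are
#' healed by minimum-image reconstruction of the per-frame displacements
#' when \code{unwrap = TRUE}; with \code{unwrap = FALSE} any jump larger
#' than half the box raises an error instead.
#'
#' @param traj a [trajectory()] with at least 10 frames in the window.
#' @param drug drug atom indices.
#' @param max_lag_fraction largest lag as a fraction of the window length.
#' @param window analyzed time range (ps); \code{NULL} for all frames.
#' @param unwrap heal wrapped coordinates via minimum image?
#' @return data frame of class \code{"msd_curve"} with columns \code{lag}
#'   (frames), \code{tau} (ps), \code{x}, \code{y}, \code{z} and
#'   \code{total} (nm^2).  \code{MSD(0) = 0} by construction.
#' @export
msd <- function(traj, drug, max_lag_fraction = 0.5, window = NULL,
                unwrap = TRUE) {
  idx <- window_frames(traj, window)
  if (length(idx) < 10) stop("MSD needs at least 10 frames")
  pos <- com_series(traj, drug)[idx, , drop = FALSE]
  box <- traj$boxes[idx[1], ]
  d <- diff(pos)
  jump <- abs(d) > matrix(box / 2, nrow(d), 3, byrow = TRUE)
  if (any(jump)) {
    if (!unwrap)
      stop("wrapped-coordinate jump exceeding half the box between ",
           "consecutive frames; the generator stores x/y wrapped - ",
           "rerun with unwrap = TRUE or supply unwrapped coordinates")
    d <- mic_displacements(d, box)
  }
  upos <- rbind(pos[1, ], sweep(apply(d, 2, cumsum), 2, -pos[1, ]))
  n <- nrow(upos)
  max_lag <- max(1L, floor((n - 1) * max_lag_fraction))
  lags <- 0:max_lag
  out <- matrix(0, length(lags), 3)
  for (li in seq_along(lags)[-1]) {
    L <- lags[li]
    dd <- upos[(1 + L):n, , drop = FALSE] - upos[1:(n - L), , drop = FALSE]
    out[li, ] <- colMeans(dd * dd)
  }
  tau <- (traj$times[idx] - traj$times[idx][1])[lags + 1]
  res <- data.frame(lag = lags, tau = tau, x = out[, 1], y = out[, 2],
                    z = out[, 3], total = rowSums(out))
  class(res) <- c("msd_curve", "data.frame")
  res
}

#' Diffusion coefficient from an MSD curve (Einstein relation)
#'
#' Least-squares line through MSD(tau) over the fit window; the diffusion
#' coefficient is the slope divided by \code{2 * dim}.  The default window
#' is 10-50 percent of the maximum lag.  A negative fitted slope is clamped
#' to zero with a warning.
#'
#' @param curve an [msd()] result.
#' @param fit_window \code{c(tau_lo, tau_hi)} in ps; \code{NULL} for the
#'   default window.
#' @param axes which axes enter the fitted MSD (\code{c("x","y","z")} for
#'   the full 3-D MSD, \code{c("x","y")} for lateral, \code{"z"} for the
#'   membrane normal).
#' @param dim dimensionality for the Einstein relation; defaults to
#'   \code{length(axes)}.
#' @return object of class \code{"diffusion_result"} with fields \code{D}
#'   (nm^2/ps), \code{D_1e5_cm2_s} (same value in 1e-5 cm^2/s),
#'   \code{per_axis_D}, \code{fit_r2}, \code{fit_window}, \code{dim} and
#'   \code{ratio_pct} (\code{NA} until paired via [diffusivity_ratio()]).
#' @export
diffusion_coefficient <- function(curve, fit_window = NULL,
                                  axes = c("x", "y", "z"), dim = length(axes)) {
  stopifnot(inherits(curve, "msd_curve"))
  tmax <- max(curve$tau)
  if (is.null(fit_window)) fit_window <- c(0.1, 0.5) * tmax
  sel <- curve$lag > 0 & curve$tau >= fit_window[1] &
    curve$tau <= fit_window[2]
  if (sum(sel) < 3)
    stop("fewer than 3 MSD points in the fit window [",
         fit_window[1], ", ", fit_window[2], "] ps")
  y <- rowSums(curve[sel, axes, drop = FALSE])
  tau <- curve$tau[sel]
  fit <- lm(y ~ tau)
  slope <- unname(coef(fit)[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  D <- slope / (2 * dim)
  if (D < 0) {
    warning("negative MSD slope; clamping diffusion coefficient to 0")
    D <- 0
  }
  per_axis <- vapply(c("x", "y", "z"), function(ax) {
    s <- unname(coef(lm(curve[[ax]][sel] ~ tau))[2]) / 2
    max(s, 0)
  }, 0)
  structure(list(D = D, D_1e5_cm2_s = D * 1000, per_axis_D = per_axis,
                 fit_r2 = r2, fit_window = fit_window, dim = dim,
                 axes = axes, ratio_pct = NA_real_),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("D = %.4g nm^2/ps (%.4g x 1e-5 cm^2/s), fit R^2 = %.4f\n",
              x$D, x$D_1e5_cm2_s, x$fit_r2))
  cat(sprintf("  per-axis D (nm^2/ps): x %.4g, y %.4g, z %.4g\n",
              x$per_axis_D[1], x$per_axis_D[2], x$per_axis_D[3]))
  if (!is.na(x$ratio_pct))
    cat(sprintf("  membrane/bulk diffusivity ratio: %.1f%%\n", x$ratio_pct))
  invisible(x)
}

#' Membrane/bulk diffusivity ratio
#'
#' The percentage ratio between a molecule's diffusivity near the membrane
#' and its diffusivity in bulk water; surface immobilization shows up as a
#' ratio well below 100.
#'
#' @param d_membrane [diffusion_coefficient()] result (or numeric D) near
#'   the membrane.
#' @param d_bulk the paired bulk-water result (or numeric D).
#' @return the membrane result with \code{ratio_pct} filled in (or, for
#'   numeric input, the ratio itself).
#' @export
diffusivity_ratio <- function(d_membrane, d_bulk) {
  Dm <- if (inherits(d_membrane, "diffusion_result")) d_membrane$D
        else d_membrane
  Db <- if (inherits(d_bulk, "diffusion_result")) d_bulk$D else d_bulk
  if (Db <= 0) stop("bulk diffusivity must be > 0")
  ratio <- 100 * Dm / Db
  if (inherits(d_membrane, "diffusion_result")) {
    d_membrane$ratio_pct <- ratio
    d_membrane
  } else ratio
}
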