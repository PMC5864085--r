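# Lateral self-diffusion from mean-square displacements (Einstein relation,
# two dimensions): D = slope(MSD)/4, with the MSD averaged over the beads of
# the protein and over time origins, after removing the centre-of-mass
# motion of the protein-membrane system.

#' Mean-square displacement of a bead cloud (lateral)
#'
#' MSD(tau) averaged over beads and over all time origins, using xy
#' displacements only. When `com` is supplied, its per-frame drift is
#' subtracted from every bead position before displacements are accumulated
#' (removal of the protein-membrane system's centre-of-mass motion).
#'
#' @param traj n_frames x n_beads x 3 (or x 2) coordinate array (nm).
#' @param times frame times in ns (length n_frames, equally spaced).
#' @param com optional n_frames x 2 (or x 3) matrix of the system
#'   centre-of-mass per frame to subtract.
#' @param max_lag_frac largest lag as a fraction of the trajectory length
#'   (default 0.25; origin averaging degrades beyond that).
#' @param max_lag optional absolute cap on the largest lag (ns); for slope
#'   fitting only lags up to the fit window are needed, and skipping longer
#'   ones saves substantial work on long trajectories.
#' @return an `msd_curve` data.frame: `lag` (ns), `msd` (nm^2), starting at
#'   MSD(0) = 0.
#' @export
msd <- function(traj, times, com = NULL, max_lag_frac = 0.25,
                max_lag = NULL) {
  stopifnot(length(dim(traj)) == 3L)
  nf <- dim(traj)[1]
  if (nf < 2L) stop("need at least two frames")
  if (length(times) != nf) stop("times length must match frame count")
  x <- traj[, , 1, drop = FALSE][, , 1]
  y <- traj[, , 2, drop = FALSE][, , 1]
  if (is.null(dim(x))) { x <- matrix(x, ncol = 1); y <- matrix(y, ncol = 1) }
  if (!is.null(com)) {
    x <- x - com[, 1]
    y <- y - com[, 2]
  }
  dt0 <- times[2] - times[1]
  lag_cap <- max(1L, floor((nf - 1L) * max_lag_frac))
  if (!is.null(max_lag))
    lag_cap <- min(lag_cap, max(1L, ceiling(max_lag / dt0)))
  lags <- seq_len(lag_cap)
  m <- vapply(lags, function(l) {
    dx <- x[(1L + l):nf, , drop = FALSE] - x[1L:(nf - l), , drop = FALSE]
    dy <- y[(1L + l):nf, , drop = FALSE] - y[1L:(nf - l), , drop = FALSE]
    mean(dx^2 + dy^2)
  }, 0)
  dt <- times[2] - times[1]
  structure(data.frame(lag = c(0, lags * dt), msd = c(0, m)),
            class = c("msd_curve", "data.frame"))
}

#' Fit a lateral diffusion coefficient to an MSD curve
#'
#' Least-squares line on the stated lag window; D = slope/4 (Einstein
#' relation in two dimensions). Reported in nm^2/ns and in units of
#' 1e-7 cm^2/s (1 nm^2/ns = 100 x 1e-7 cm^2/s).
#'
#' @param curve an `msd_curve`.
#' @param window c(min, max) lag window in ns (default 5-20).
#' @return a `diffusion_fit`: list(D, D_1e7_cm2_s, r2, window, slope,
#'   intercept, n_points).
#' @export
fit_diffusion <- function(curve, window = c(5, 20)) {
  sel <- curve$lag >= window[1] & curve$lag <= window[2]
  if (sum(sel) < 3L) stop("fewer than 3 MSD points in the fit window")
  fit <- stats::lm(msd ~ lag, data = curve[sel, ])
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((curve$msd[sel] - mean(curve$msd[sel]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  D <- slope / 4
  structure(list(D = D, D_1e7_cm2_s = D * 100, r2 = r2,
                 window = window, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = sum(sel)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Lateral diffusion: D = %.4g nm^2/ns = %.4g x 1e-7 cm^2/s (R^2 = %.4f, window %g-%g ns)\n",
              x$D, x$D_1e7_cm2_s, x$r2, x$window[1], x$window[2]))
  invisible(x)
}

#' Diffusion analysis of a monomeric-receptor trajectory
#'
#' Convenience driver: restricts to the analysis window, optionally removes
#' system centre-of-mass motion, computes the MSD and fits D on the fit
#' window. Replicas in which protein-protein interaction starts before
#' `monomer_until` ns should be excluded upstream when the trajectory stems
#' from a dimerization ensemble.
#'
#' @param traj n_frames x n_beads x 3 array of protein bead positions (nm).
#' @param times frame times (ns).
#' @param com optional per-frame system centre of mass to subtract.
#' @param analysis_window c(min, max) ns of trajectory analysed (default
#'   first 200 ns).
#' @param fit_window MSD lag window for the slope fit (default 5-20 ns).
#' @return a `diffusion_fit` with the `msd_curve` attached as `curve`.
#' @export
lateral_diffusion <- function(traj, times, com = NULL,
                              analysis_window = c(0, 200),
                              fit_window = c(5, 20)) {
  sel <- times >= analysis_window[1] & times <= analysis_window[2]
  if (sum(sel) < 2L) stop("analysis window leaves fewer than 2 frames")
  curve <- msd(traj[sel, , , drop = FALSE], times[sel],
               com = if (is.null(com)) NULL else com[sel, , drop = FALSE],
               max_lag = 2 * fit_window[2])
  out <- fit_diffusion(curve, fit_window)
  out$curve <- curve
  out
}
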