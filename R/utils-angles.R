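# Angular helpers. All angles are degrees on the half-open circle [0, 360).

#' Wrap angles into [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap360 <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0
  y
}

#' Signed minimal angular difference a - b in (-180, 180]
#'
#' @param a,b angles in degrees.
#' @return signed difference in degrees.
#' @export
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Absolute circular distance between angles
#'
#' @param a,b angles in degrees.
#' @return distances in `[0, 180]` degrees.
#' @export
circ_dist <- function(a, b) abs(ang_diff(a, b))

# Circular mean of angles in degrees; NA-free input assumed.
circ_mean <- function(x) {
  r <- x * pi / 180
  wrap360(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

# Wrapped-Gaussian kernel matrix: rows = grid points, cols = sample centers.
# Truncated at +-3 periodic images, ample for bandwidths up to ~60 degrees.
wrapped_gauss <- function(grid, centers, bw) {
  stopifnot(bw > 0)
  d <- outer(grid, centers, "-")
  k <- matrix(0, nrow(d), ncol(d))
  for (j in -3:3) k <- k + stats::dnorm(d + 360 * j, mean = 0, sd = bw)
  k
}

# azimuth (deg in [0,360)) of 2D points, counterclockwise from +x
azimuth_deg <- function(x, y) wrap360(atan2(y, x) * 180 / pi)

# Minimal circular arc [start, end] (going counterclockwise from start)
# covering a set of angles. Returns c(start, end, width).
circ_span <- function(angles) {
  a <- sort(wrap360(angles))
  if (length(a) == 1L) return(c(start = a, end = a, width = 0))
  gaps <- diff(c(a, a[1] + 360))
  i <- which.max(gaps)
  start <- if (i == length(a)) a[1] else a[i + 1L]
  width <- 360 - gaps[i]
  c(start = start, end = wrap360(start + width), width = width)
}

# TRUE where angle lies on the arc [start, start+width] (circular).
on_arc <- function(angle, start, width) {
  ang_rel <- (angle - start) %% 360
  ang_rel <= width + 1e-9
}

# circular distance from an angle to an arc (0 if on it)
dist_to_arc <- function(angle, start, width) {
  ifelse(on_arc(angle, start, width), 0,
         pmin(circ_dist(angle, start), circ_dist(angle, wrap360(start + width))))
}
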