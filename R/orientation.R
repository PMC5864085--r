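# Relative orientation geometry on the membrane plane.
#
# Each receptor carries a molecular frame: origin at the centre of mass of
# its TM backbone beads, z along the membrane normal (+z extracellular), and
# in-plane axes from the principal components of the xy-projected TM
# backbone beads. The principal direction fixes x only up to sign; the sign
# is chosen so that the TM1 backbone centroid has an azimuth in [-90, 90)
# within the frame. Without such a convention the binding angle beta would
# only be defined up to 180-degree flips.
#
# For a dimer A-B, three angles describe the configuration:
#   beta: azimuth of B's origin in A's frame (where B binds on A),
#   phi:  rotation of B about its own z relative to A's in-plane axes,
#   chi = (180 + beta - phi) mod 360: the reciprocal binding azimuth of A
#         in B's frame.

#' Build the molecular frame of a receptor
#'
#' @param receptor a `receptor_model`.
#' @param coords n_beads x 3 coordinates (nm); defaults to the reference
#'   frame stored in the model.
#' @return a `molecular_frame`: list(origin, x_axis, y_axis, z_axis).
#' @export
build_frame <- function(receptor, coords = receptor$reference_coords) {
  idx <- tm_backbone_indices(receptor)
  if (any(idx > nrow(coords))) stop("coords do not cover all TM backbone beads")
  xyz <- coords[idx, , drop = FALSE]
  origin <- colMeans(xyz)
  xy <- sweep(xyz[, 1:2, drop = FALSE], 2, origin[1:2])
  cv <- crossprod(xy) / nrow(xy)
  eg <- eigen(cv, symmetric = TRUE)
  # degenerate when the in-plane spread is isotropic (no unique major axis)
  # or collinear (no in-plane plane at all)
  if (eg$values[1] - eg$values[2] < 1e-12 * max(eg$values[1], 1e-300) ||
      eg$values[2] < 1e-10 * eg$values[1])
    stop("principal axes undefined: degenerate xy projection")
  e1 <- eg$vectors[, 1]
  x_axis <- c(e1, 0)
  z_axis <- c(0, 0, 1)
  y_axis <- c(-x_axis[2], x_axis[1], 0)      # z cross x
  # sign convention: TM1 centroid azimuth within [-90, 90)
  tm1 <- helix_backbone_indices(receptor, "TM1")
  c1 <- colMeans(coords[tm1, , drop = FALSE]) - origin
  a <- atan2(sum(c1 * y_axis), sum(c1 * x_axis)) * 180 / pi
  if (a < -90 || a >= 90) {
    x_axis <- -x_axis
    y_axis <- -y_axis
  }
  structure(list(origin = origin, x_axis = x_axis, y_axis = y_axis,
                 z_axis = z_axis),
            class = "molecular_frame")
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat(sprintf("Molecular frame: origin (%.3f, %.3f, %.3f) nm, x-axis azimuth %.2f deg\n",
              x$origin[1], x$origin[2], x$origin[3],
              azimuth_deg(x$x_axis[1], x$x_axis[2])))
  invisible(x)
}

# azimuth of a lab-frame vector within a molecular frame (degrees)
frame_azimuth <- function(frame, v) {
  wrap360(atan2(sum(v * frame$y_axis), sum(v * frame$x_axis)) * 180 / pi)
}

#' Relative orientation angles between two molecular frames
#'
#' @param frame_a reference frame (monomer A).
#' @param frame_b partner frame (monomer B).
#' @param time optional frame time (ns) carried into the output.
#' @return data.frame row with `time`, `beta`, `phi`, `chi` (degrees in
#'   `[0, 360)`).
#' @export
relative_angles <- function(frame_a, frame_b, time = NA_real_) {
  za <- frame_a$z_axis; zb <- frame_b$z_axis
  cosz <- sum(za * zb) / sqrt(sum(za^2) * sum(zb^2))
  if (acos(pmin(pmax(cosz, -1), 1)) * 180 / pi > 15)
    stop("membrane normals differ by more than 15 degrees; ",
         "planar angle system not applicable")
  d <- frame_b$origin - frame_a$origin
  if (sqrt(sum(d[1:2]^2)) < 1e-9) stop("coincident origins")
  beta <- frame_azimuth(frame_a, d)
  xa <- frame_a$x_axis; xb <- frame_b$x_axis
  cross_z <- xa[1] * xb[2] - xa[2] * xb[1]
  phi <- wrap360(atan2(cross_z, sum(xa * xb)) * 180 / pi)
  chi <- wrap360(180 + beta - phi)
  data.frame(time = time, beta = beta, phi = phi, chi = chi)
}

#' Orientation samples for a two-receptor trajectory
#'
#' Computes (beta, phi, chi) per frame for a dimer system whose coordinate
#' rows split into receptor A and receptor B blocks.
#'
#' @param model_a,model_b `receptor_model`s of the two protomers.
#' @param frames list of trajectory frames (`coords`, `time`), e.g. from
#'   [read_trajectory()].
#' @param idx_a,idx_b integer row indices of each protomer's beads within a
#'   frame's coordinate matrix.
#' @param replica_id attached to the output rows.
#' @return data.frame of orientation samples.
#' @export
orientation_samples <- function(model_a, model_b, frames, idx_a, idx_b,
                                replica_id = NA_character_) {
  out <- do.call(rbind, lapply(frames, function(fr) {
    fa <- build_frame(model_a, fr$coords[idx_a, , drop = FALSE])
    fb <- build_frame(model_b, fr$coords[idx_b, , drop = FALSE])
    relative_angles(fa, fb, time = fr$time)
  }))
  out$replica_id <- replica_id
  out
}

#' Per-helix angular map of a receptor
#'
#' Maps every helix to the azimuth interval spanned by its backbone beads in
#' the receptor's molecular frame, and marks for each 1-degree bin which
#' helix is exposed at the protein surface there: among helices whose
#' interval covers the bin, the one with the largest mean backbone-bead
#' radial distance wins (buried helices such as parts of TM2/TM3 lose to the
#' outer ring).
#'
#' @param receptor a `receptor_model`.
#' @param coords coordinates (nm); defaults to the reference frame.
#' @return a `helix_angular_map`: list(intervals = data.frame(helix, start,
#'   end, width, mean_radius), exposure = length-360 character vector (helix
#'   exposed in bin `[i-1, i)`, NA where no helix lies)).
#' @export
helix_angular_map <- function(receptor, coords = receptor$reference_coords) {
  frame <- build_frame(receptor, coords)
  labs <- names(receptor$helix_map)
  rows <- lapply(labs, function(h) {
    idx <- helix_backbone_indices(receptor, h)
    rel <- sweep(coords[idx, , drop = FALSE], 2, frame$origin)
    az <- vapply(seq_len(nrow(rel)),
                 function(i) frame_azimuth(frame, rel[i, ]), 0)
    r <- sqrt(rowSums(rel[, 1:2, drop = FALSE]^2))
    sp <- circ_span(az)
    data.frame(helix = h, start = sp["start"], end = sp["end"],
               width = sp["width"], mean_radius = mean(r))
  })
  intervals <- do.call(rbind, rows)
  rownames(intervals) <- NULL

  bin_centers <- 0:359 + 0.5
  exposure <- rep(NA_character_, 360)
  for (b in seq_along(bin_centers)) {
    covering <- which(on_arc(bin_centers[b], intervals$start, intervals$width))
    if (length(covering))
      exposure[b] <- intervals$helix[covering[which.max(
        intervals$mean_radius[covering])]]
  }
  structure(list(intervals = intervals, exposure = exposure, frame = frame),
            class = "helix_angular_map")
}

#' @export
print.helix_angular_map <- function(x, ...) {
  cat("Helix angular map:\n")
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %-4s [%6.1f, %6.1f) deg, mean radius %.2f nm\n",
                x$intervals$helix[i], x$intervals$start[i],
                x$intervals$end[i], x$intervals$mean_radius[i]))
  invisible(x)
}

#' Binding-position density over the angular circle
#'
#' Circular kernel density (wrapped-Gaussian kernel, 1-degree grid) of the
#' binding azimuths. For homodimers beta and chi describe the same binding
#' position on either protomer and are pooled into a single density; for
#' heterodimers the beta density (binding position on receptor A) and the
#' chi density (on receptor B) are returned separately.
#'
#' @param samples data.frame with `beta` and `chi` columns (degrees).
#' @param homodimer pool beta and chi (default TRUE).
#' @param bandwidth kernel bandwidth in degrees (default 10).
#' @return an `angular_density` (data.frame angle/density summing to 1 per
#'   degree), or for heterodimers a list with elements `beta` and `chi`.
#' @export
binding_position_density <- function(samples, homodimer = TRUE, bandwidth = 10) {
  if (!nrow(samples)) stop("no orientation samples")
  one <- function(angles) {
    grid <- 0:359 + 0.5
    k <- wrapped_gauss(grid, wrap360(angles), bandwidth)
    dens <- rowMeans(k)
    dens <- dens / sum(dens)            # integral over the 1-degree grid = 1
    structure(data.frame(angle = grid, density = dens),
              class = c("angular_density", "data.frame"),
              bandwidth = bandwidth, n = length(angles))
  }
  if (homodimer) one(c(samples$beta, samples$chi))
  else list(beta = one(samples$beta), chi = one(samples$chi))
}

#' Modes of an angular density
#'
#' @param dens an `angular_density`.
#' @param min_height fraction of the maximum below which local maxima are
#'   ignored.
#' @return data.frame of mode angles and heights.
#' @export
angular_density_modes <- function(dens, min_height = 0.05) {
  v <- dens$density
  n <- length(v)
  up <- v > v[c(n, seq_len(n - 1L))]
  dn <- v >= v[c(seq_len(n)[-1L], 1L)]
  is_mode <- up & dn & v >= min_height * max(v)
  data.frame(angle = dens$angle[is_mode], height = v[is_mode])
}
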