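# Interface classification on the (beta, chi) angle torus.
#
# Dimer configurations sampled over the last part of each dimer-forming
# replica populate a doubly periodic density ("height-field") over
# (beta, chi). Its watershed basins define the interface classes; basin
# populations, helix-pair labels and representative replicas follow.

#' Periodic 2D kernel density height-field of (beta, chi) samples
#'
#' Wrapped-Gaussian product kernel on a 1-degree 360 x 360 grid, periodic in
#' both axes. Local maxima (8-neighbourhood on the torus) below
#' `floor` x the global maximum are regarded as noise and merged into their
#' nearest surviving basin during watershed segmentation.
#'
#' @param beta,chi sample angles in degrees.
#' @param bandwidth kernel bandwidth in degrees (default 10).
#' @param floor noise floor as a fraction of the global maximum height
#'   (default 0.05).
#' @return a `heightfield`: list(grid (360 x 360, rows = beta bins, cols =
#'   chi bins, sums to 1), maxima (data.frame beta, chi, height), bandwidth,
#'   floor, n).
#' @export
kde_heightfield <- function(beta, chi, bandwidth = 10, floor = 0.05) {
  stopifnot(length(beta) == length(chi), length(beta) >= 1)
  grid <- 0:359 + 0.5
  kb <- wrapped_gauss(grid, wrap360(beta), bandwidth)   # 360 x n
  kc <- wrapped_gauss(grid, wrap360(chi), bandwidth)
  g <- tcrossprod(kb, kc) / length(beta)                # 360 x 360
  g <- g / sum(g)
  mx <- torus_local_maxima(g)
  keep <- mx$height >= floor * max(mx$height)
  structure(list(grid = g,
                 maxima = mx[keep, , drop = FALSE],
                 all_maxima = mx,
                 bandwidth = bandwidth, floor = floor, n = length(beta)),
            class = "heightfield")
}

# Local maxima of a doubly periodic matrix (8-neighbourhood). Plateaus of
# tied cells keep exactly one representative: a cell must be strictly above
# its "later" neighbours in scan order and at least equal to the earlier
# ones.
torus_local_maxima <- function(g) {
  n <- nrow(g); m <- ncol(g)
  sh <- function(di, dj) g[((seq_len(n) - 1 + di) %% n) + 1,
                           ((seq_len(m) - 1 + dj) %% m) + 1]
  is_max <- matrix(TRUE, n, m)
  for (di in -1:1) for (dj in -1:1) {
    if (!di && !dj) next
    later <- dj > 0 || (dj == 0 && di > 0)
    is_max <- is_max & if (later) (g > sh(di, dj)) else (g >= sh(di, dj))
  }
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(beta = idx[, 1] - 0.5, chi = idx[, 2] - 0.5,
                    height = g[idx])
  out[order(-out$height), , drop = FALSE]
}

#' @export
print.heightfield <- function(x, ...) {
  cat(sprintf("Height-field: %d samples, bandwidth %g deg, %d retained maxima\n",
              x$n, x$bandwidth, nrow(x$maxima)))
  if (!is.null(x$basin_map))
    cat(sprintf("  %d watershed basins\n", length(unique(as.vector(x$basin_map)))))
  invisible(x)
}

#' Watershed segmentation of a height-field into interface basins
#'
#' Watershed on the height-field with periodic boundary handling by 3 x 3
#' tiling and central-tile extraction (via \pkg{EBImage}). Basins whose
#' maxima fall below the noise floor are merged into the nearest surviving
#' basin (wrapped Euclidean metric between maxima). Every cell is assigned;
#' basin ids are ordered by decreasing maximum height.
#'
#' @param hf a `heightfield` from [kde_heightfield()].
#' @return the height-field with `basin_map` (360 x 360 integer matrix),
#'   `basins` (data.frame: basin, beta, chi, height, n_cells) and a
#'   `degenerate` flag set.
#' @export
watershed_basins <- function(hf) {
  g <- hf$grid
  n <- nrow(g)
  rng <- max(g) - min(g)
  if (rng <= 1e-12 * max(abs(g), 1e-300)) {
    # uniform field: one catch-all basin
    hf$basin_map <- matrix(1L, n, n)
    hf$basins <- data.frame(basin = 1L, beta = NA_real_, chi = NA_real_,
                            height = max(g), n_cells = n * n)
    hf$degenerate <- TRUE
    return(hf)
  }
  tiled <- g[rep(seq_len(n), 3), rep(seq_len(n), 3)]
  lab_t <- EBImage::imageData(EBImage::watershed(EBImage::as.Image(tiled),
                                                 tolerance = 0))
  centre <- lab_t[n + seq_len(n), n + seq_len(n)]

  # canonicalize labels by the wrapped position of each label's peak cell
  labs <- sort(unique(as.vector(centre)))
  labs <- labs[labs > 0]
  peak_of <- function(l) {
    cells <- which(centre == l, arr.ind = TRUE)
    p <- cells[which.max(g[cells]), ]
    c(p[1], p[2])
  }
  peaks <- t(vapply(labs, peak_of, c(1, 1)))
  key <- paste(peaks[, 1], peaks[, 2])
  canon <- match(key, unique(key))
  map <- stats::setNames(canon, labs)
  basin <- matrix(map[as.character(centre)], n, n)

  upeaks <- peaks[!duplicated(key), , drop = FALSE]
  heights <- g[upeaks]
  # merge sub-floor basins into the nearest surviving one (wrapped metric)
  keep <- heights >= hf$floor * max(heights)
  if (!any(keep)) keep[which.max(heights)] <- TRUE
  if (any(!keep)) {
    survivors <- which(keep)
    for (b in which(!keep)) {
      d2 <- (pmin(abs(upeaks[survivors, 1] - upeaks[b, 1]),
                  360 - abs(upeaks[survivors, 1] - upeaks[b, 1])))^2 +
            (pmin(abs(upeaks[survivors, 2] - upeaks[b, 2]),
                  360 - abs(upeaks[survivors, 2] - upeaks[b, 2])))^2
      basin[basin == b] <- survivors[which.min(d2)]
    }
  }
  # cells the tiled watershed left unlabelled (plateaus at numerical zero)
  # go to the nearest surviving peak in the wrapped metric
  if (anyNA(basin)) {
    nas <- which(is.na(basin), arr.ind = TRUE)
    survivors <- which(keep)
    for (r in seq_len(nrow(nas))) {
      d2 <- (pmin(abs(upeaks[survivors, 1] - nas[r, 1]),
                  360 - abs(upeaks[survivors, 1] - nas[r, 1])))^2 +
            (pmin(abs(upeaks[survivors, 2] - nas[r, 2]),
                  360 - abs(upeaks[survivors, 2] - nas[r, 2])))^2
      basin[nas[r, 1], nas[r, 2]] <- survivors[which.min(d2)]
    }
  }
  # relabel 1..K by decreasing height
  final <- sort(unique(as.vector(basin)))
  ord <- final[order(-heights[final])]
  relab <- stats::setNames(seq_along(ord), ord)
  basin <- matrix(relab[as.character(basin)], n, n)

  hf$basin_map <- basin
  hf$basins <- data.frame(
    basin = seq_along(ord),
    beta = upeaks[ord, 1] - 0.5,
    chi = upeaks[ord, 2] - 0.5,
    height = heights[ord],
    n_cells = as.integer(table(factor(as.vector(basin),
                                      levels = seq_along(ord)))))
  hf$degenerate <- FALSE
  hf
}

#' Assign (beta, chi) points to watershed basins
#'
#' @param hf a segmented `heightfield` (after [watershed_basins()]).
#' @param beta,chi angles in degrees.
#' @return integer basin ids.
#' @export
assign_basins <- function(hf, beta, chi) {
  if (is.null(hf$basin_map)) stop("height-field has no basin map yet")
  i <- (floor(wrap360(beta)) %% 360) + 1L
  j <- (floor(wrap360(chi)) %% 360) + 1L
  hf$basin_map[cbind(i, j)]
}

#' Per-replica basin assignment and basin populations
#'
#' Each dimer-forming replica is assigned by the circular mean of its
#' last-window (beta, chi) samples; populations are fractions of the
#' assigned replicas. Replicas whose dimer lifetime is shorter than the
#' angle window carry too few samples and are excluded with a warning by
#' the caller that aggregates the samples.
#'
#' @param hf a segmented `heightfield`.
#' @param samples data.frame with `replica_id`, `beta`, `chi` (per-frame
#'   samples of the assignment window).
#' @return data.frame: basin, count, fraction, plus replica assignments as
#'   attribute `assignments`.
#' @export
assign_and_count <- function(hf, samples) {
  agg <- split(samples, samples$replica_id)
  reps <- names(agg)
  mb <- vapply(agg, function(d) circ_mean(d$beta), 0)
  mc <- vapply(agg, function(d) circ_mean(d$chi), 0)
  basin <- assign_basins(hf, mb, mc)
  tab <- table(factor(basin, levels = sort(unique(hf$basins$basin))))
  pops <- data.frame(basin = as.integer(names(tab)),
                     count = as.integer(tab),
                     fraction = as.numeric(tab) / length(basin))
  pops <- pops[order(-pops$count), ]
  rownames(pops) <- NULL
  attr(pops, "assignments") <- data.frame(replica_id = reps, beta = mb,
                                          chi = mc, basin = basin,
                                          stringsAsFactors = FALSE)
  pops
}

#' Mean last-window angles per replica
#'
#' Restricts per-frame orientation samples to the final `window` ns of each
#' replica and drops replicas whose dimer lifetime is shorter than the
#' window (too few frames for a stable assignment).
#'
#' @param samples data.frame with `replica_id`, `time`, `beta`, `chi`.
#' @param window window length in ns (default 50).
#' @param dimer_since optional named vector: last dimerization time per
#'   replica (ns); replicas whose final dimer is younger than `window` are
#'   excluded with a warning.
#' @return filtered per-frame samples.
#' @export
last_window_samples <- function(samples, window = 50, dimer_since = NULL) {
  out <- do.call(rbind, lapply(split(samples, samples$replica_id), function(d) {
    t_end <- max(d$time)
    if (!is.null(dimer_since)) {
      t_dim <- dimer_since[[as.character(d$replica_id[1])]]
      if (!is.null(t_dim) && !is.na(t_dim) && t_end - t_dim < window)
        return(NULL)
    }
    d[d$time > t_end - window, , drop = FALSE]
  }))
  n_in <- length(unique(samples$replica_id))
  n_out <- if (is.null(out)) 0L else length(unique(out$replica_id))
  if (n_out < n_in)
    warning(sprintf("%d replica(s) excluded: dimer lifetime shorter than the %g ns window",
                    n_in - n_out, window))
  out
}

#' Helix-pair label of a basin maximum
#'
#' Names the interface by the helices whose angular intervals contain (or
#' lie within `half_width` degrees of) the maximum's beta on receptor A,
#' paired with those near chi on receptor B. Runs of consecutive
#' transmembrane helices are compacted (e.g. "TM5-7"); two-helix
#' combinations drop the repeated prefix (e.g. "TM4,5"). If no exposed helix
#' lies within reach, the nearest exposed helix is used and the label is
#' flagged.
#'
#' @param beta_max,chi_max basin maximum coordinates (degrees).
#' @param map_a,map_b `helix_angular_map`s of the two receptors.
#' @param half_width contact half-width in degrees (default 15).
#' @return character label "helicesA/helicesB"; attribute `flagged` is TRUE
#'   when a nearest-helix fallback was needed.
#' @export
label_basin <- function(beta_max, chi_max, map_a, map_b, half_width = 15) {
  side <- function(angle, map) {
    iv <- map$intervals
    d <- dist_to_arc(angle, iv$start, iv$width)
    hit <- iv$helix[d <= half_width]
    flagged <- FALSE
    if (!length(hit)) {
      hit <- iv$helix[which.min(d)]
      flagged <- TRUE
    }
    list(label = format_helix_set(hit), flagged = flagged)
  }
  a <- side(wrap360(beta_max), map_a)
  b <- side(wrap360(chi_max), map_b)
  structure(paste0(a$label, "/", b$label),
            flagged = a$flagged || b$flagged)
}

# "TM1","H8" -> "TM1,H8"; "TM4","TM5" -> "TM4,5"; "TM5","TM6","TM7" -> "TM5-7"
format_helix_set <- function(helices) {
  helices <- unique(helices)
  ord <- match(helices, HELIX_LABELS)
  helices <- helices[order(ord)]
  tm <- helices[startsWith(helices, "TM")]
  other <- helices[!startsWith(helices, "TM")]
  parts <- character()
  if (length(tm)) {
    nums <- as.integer(sub("TM", "", tm))
    runs <- split(nums, cumsum(c(1, diff(nums) != 1)))
    parts <- vapply(runs, function(r) {
      if (length(r) >= 3) sprintf("TM%d-%d", r[1], r[length(r)])
      else if (length(r) == 2) sprintf("TM%d,%d", r[1], r[2])
      else sprintf("TM%d", r)
    }, "")
  }
  paste(c(parts, other), collapse = ",")
}

#' Representative replica of an interface basin
#'
#' Among basin members whose final (beta, chi) lies in the lowest decile of
#' wrapped distance to the basin maximum, picks the one with the lowest
#' (most negative) final interaction energy, i.e. the most compact interface
#' closest to the population mode.
#'
#' @param members data.frame: `replica_id`, `beta`, `chi`, `energy`
#'   (final-frame values of the basin's replicas).
#' @param maximum length-2 numeric c(beta, chi) of the basin maximum.
#' @return a `representative_pick`: list(replica_id, beta, chi, energy,
#'   distance).
#' @export
select_representative <- function(members, maximum) {
  if (!nrow(members)) stop("empty basin")
  d <- sqrt(circ_dist(members$beta, maximum[1])^2 +
            circ_dist(members$chi, maximum[2])^2)
  n_keep <- max(1L, ceiling(nrow(members) / 10))
  thresh <- sort(d)[n_keep]
  cand <- which(d <= thresh + 1e-9)    # ties at the decile boundary stay in
  pick <- cand[which.min(members$energy[cand])]
  structure(list(replica_id = members$replica_id[pick],
                 beta = members$beta[pick], chi = members$chi[pick],
                 energy = members$energy[pick], distance = d[pick]),
            class = "representative_pick")
}

#' @export
print.representative_pick <- function(x, ...) {
  cat(sprintf("Representative: %s at (beta, chi) = (%.1f, %.1f), E = %.1f kJ/mol (%.2f deg from maximum)\n",
              x$replica_id, x$beta, x$chi, x$energy, x$distance))
  invisible(x)
}
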