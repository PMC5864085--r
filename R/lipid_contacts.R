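# Cholesterol-receptor contact analysis.
#
# A cholesterol molecule (8 coarse-grained beads, one polar ROH headgroup
# bead) counts as bound to a residue in a frame if any of its beads lies
# within the contact cutoff (0.62 nm, inclusive) of any bead of the residue.
# Spatial densities accumulate the beads of the N nearest cholesterol
# molecules per frame in the receptor-fixed frame after least-squares
# superposition on the TM backbone.

#' Contact analysis parameters
#'
#' @param cutoff contact distance in nm (default 0.62, inclusive boundary).
#' @param n_nearest number of nearest cholesterol molecules entering the
#'   spatial densities (default 5).
#' @param chol_beads_per_molecule beads per cholesterol (default 8).
#' @param headgroup_bead_name polar headgroup bead name (default "ROH").
#' @param equilibration_discard initial trajectory stretch to discard, ns
#'   (default 200).
#' @param grid_spacing density voxel edge in nm (default 0.1).
#' @return a `contact_params` object.
#' @export
contact_params <- function(cutoff = 0.62, n_nearest = 5,
                           chol_beads_per_molecule = 8,
                           headgroup_bead_name = "ROH",
                           equilibration_discard = 200,
                           grid_spacing = 0.1) {
  stopifnot(cutoff > 0, n_nearest >= 1, chol_beads_per_molecule >= 1,
            grid_spacing > 0, equilibration_discard >= 0)
  structure(list(cutoff = cutoff, n_nearest = n_nearest,
                 chol_beads_per_molecule = chol_beads_per_molecule,
                 headgroup_bead_name = headgroup_bead_name,
                 equilibration_discard = equilibration_discard,
                 grid_spacing = grid_spacing),
            class = "contact_params")
}

# A cholesterol trajectory frame, as produced by gen_chol_field() or
# assembled from read_trajectory() output: list(time, receptor_coords,
# chol_coords (n_chol*beads x 3), box). chol molecule/headgroup bookkeeping
# travels alongside as `chol_mol` (molecule id per chol bead row) and
# `headgroup` (logical per chol bead row).

#' Residue-resolved cholesterol occupancy
#'
#' Occupancy of a residue is the fraction of analysed frames in which the
#' minimum distance between any of its beads and any cholesterol bead is at
#' most the cutoff (inclusive), under minimum-image convention.
#'
#' @param frames list of frames (each: `time`, `receptor_coords`,
#'   `chol_coords`, `box`).
#' @param receptor a `receptor_model` (bead rows index `receptor_coords`).
#' @param params [contact_params()].
#' @return an `occupancy_profile`: data.frame(resid, resname, helix,
#'   occupancy) with `n_frames` attribute.
#' @export
residue_occupancy <- function(frames, receptor, params = contact_params()) {
  times <- vapply(frames, function(fr) fr$time %||% 0, 0)
  use <- times >= params$equilibration_discard
  frames <- frames[use]
  if (!length(frames)) stop("no frames left after equilibration discard")
  res <- receptor$residues
  nres <- nrow(res)
  res_of_bead <- rep(NA_integer_, nrow(receptor$atoms))
  for (i in seq_len(nres)) res_of_bead[receptor$bead_index[[i]]] <- i

  warned <- FALSE
  bound_frames <- matrix(FALSE, nres, length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (is.null(fr$chol_coords) || !nrow(fr$chol_coords)) {
      warned <- TRUE
      next
    }
    d <- cross_dist(fr$receptor_coords, fr$chol_coords, box = fr$box)
    mind <- vapply(seq_len(nres), function(i)
      min(d[receptor$bead_index[[i]], , drop = FALSE]), 0)
    bound_frames[, f] <- mind <= params$cutoff
  }
  if (warned) warning("frames without cholesterol present; zero occupancy there")
  structure(data.frame(resid = res$resid, resname = res$resname,
                       helix = res$helix,
                       occupancy = rowMeans(bound_frames)),
            class = c("occupancy_profile", "data.frame"),
            n_frames = length(frames))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Spatial density of the N nearest cholesterol molecules
#'
#' Per frame, cholesterol molecules are ranked by their minimum bead
#' distance to any receptor bead (minimum-image); the beads of the
#' `n_nearest` molecules are accumulated on a 3D grid in the receptor-fixed
#' frame (each frame is rigid-body superposed onto the receptor reference
#' pose via its TM backbone beads). Headgroup (ROH) beads of the same
#' molecules are accumulated separately.
#'
#' @inheritParams residue_occupancy
#' @param chol_mol integer molecule id per cholesterol bead row.
#' @param headgroup logical headgroup flag per cholesterol bead row.
#' @param margin grid margin around the receptor reference pose, nm.
#' @return a `spatial_density`: list(all (3D array), headgroup (3D array),
#'   origin, spacing, n_frames, counts = c(all, headgroup, dropped)).
#'   Grids are normalized to per-frame bead counts.
#' @export
nearest_n_density <- function(frames, receptor, chol_mol, headgroup,
                              params = contact_params(), margin = 3) {
  times <- vapply(frames, function(fr) fr$time %||% 0, 0)
  frames <- frames[times >= params$equilibration_discard]
  if (!length(frames)) stop("no frames left after equilibration discard")

  ref <- receptor$reference_coords
  tm <- tm_backbone_indices(receptor)
  lo <- apply(ref, 2, min) - margin
  hi <- apply(ref, 2, max) + margin
  sp <- params$grid_spacing
  dims <- pmax(1L, ceiling((hi - lo) / sp))
  acc_all <- array(0, dims)
  acc_roh <- array(0, dims)
  dropped <- 0L
  total_all <- 0L; total_roh <- 0L

  for (fr in frames) {
    if (is.null(fr$chol_coords) || !nrow(fr$chol_coords)) next
    mols <- unique(chol_mol)
    d <- cross_dist(fr$receptor_coords, fr$chol_coords, box = fr$box)
    min_by_mol <- vapply(mols, function(m)
      min(d[, chol_mol == m, drop = FALSE]), 0)
    n_take <- min(params$n_nearest, length(mols))
    if (n_take < params$n_nearest)
      warning("fewer cholesterol molecules than n_nearest; using all")
    take <- mols[order(min_by_mol)[seq_len(n_take)]]
    sel <- chol_mol %in% take

    fit <- kabsch(ref[tm, , drop = FALSE],
                  fr$receptor_coords[tm, , drop = FALSE])
    pts <- apply_rigid(fr$chol_coords[sel, , drop = FALSE], fit)
    hg <- headgroup[sel]

    ijk <- floor(sweep(pts, 2, lo) / sp) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
          ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
    dropped <- dropped + sum(!ok)
    idx <- ijk[ok, , drop = FALSE]
    total_all <- total_all + nrow(idx)
    for (r in seq_len(nrow(idx)))
      acc_all[idx[r, 1], idx[r, 2], idx[r, 3]] <-
        acc_all[idx[r, 1], idx[r, 2], idx[r, 3]] + 1
    idx_h <- ijk[ok & hg, , drop = FALSE]
    total_roh <- total_roh + nrow(idx_h)
    for (r in seq_len(nrow(idx_h)))
      acc_roh[idx_h[r, 1], idx_h[r, 2], idx_h[r, 3]] <-
        acc_roh[idx_h[r, 1], idx_h[r, 2], idx_h[r, 3]] + 1
  }
  nf <- length(frames)
  structure(list(all = acc_all / nf, headgroup = acc_roh / nf,
                 origin = lo, spacing = sp, n_frames = nf,
                 counts = c(all = total_all, headgroup = total_roh,
                            dropped = dropped)),
            class = "spatial_density")
}

#' @export
print.spatial_density <- function(x, ...) {
  cat(sprintf("Spatial density: %s voxels @ %g nm, %d frames, %d beads (%d headgroup)\n",
              paste(dim(x$all), collapse = "x"), x$spacing, x$n_frames,
              x$counts["all"], x$counts["headgroup"]))
  invisible(x)
}

#' Write the spatial density grids as OpenDX files
#'
#' @param dens a `spatial_density`.
#' @param prefix output path prefix; writes `<prefix>_all.dx` and
#'   `<prefix>_headgroup.dx`.
#' @return the written paths, invisibly.
#' @export
write_density_dx <- function(dens, prefix) {
  p1 <- paste0(prefix, "_all.dx")
  p2 <- paste0(prefix, "_headgroup.dx")
  write_dx(dens$all, dens$origin, dens$spacing, p1)
  write_dx(dens$headgroup, dens$origin, dens$spacing, p2)
  invisible(c(p1, p2))
}

#' Ranked occupancy report
#'
#' @param profile an `occupancy_profile`.
#' @param highlight optional residue numbers of external interest (e.g.
#'   mutagenesis hits such as Ile52/Val150 on CCR5); residues absent from
#'   the model are reported as "not in model".
#' @return a [result_table()] ranked by occupancy, with a `highlight` flag
#'   column when `highlight` is given.
#' @export
occupancy_report <- function(profile, highlight = NULL) {
  df <- as.data.frame(profile)[order(-profile$occupancy), ]
  rownames(df) <- NULL
  if (!is.null(highlight) && length(highlight)) {
    df$highlight <- df$resid %in% highlight
    absent <- setdiff(highlight, df$resid)
    if (length(absent)) {
      df <- rbind(df, data.frame(resid = absent, resname = "not in model",
                                 helix = NA_character_, occupancy = NA_real_,
                                 highlight = TRUE))
    }
  }
  result_table(df, units = c(occupancy = "fraction"),
               provenance = list(n_frames = attr(profile, "n_frames")))
}
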