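# Structure-level metrics and the elastic-network builder.

#' Elastic-network (rubber band) parameters
#'
#' Distance-decayed harmonic restraints between backbone beads preserve
#' secondary/tertiary structure in coarse-grained models. The force constant
#' follows k_ij = f * exp(-a * d_ij^(2p)); with the defaults (f = 500
#' kJ/mol/nm^2, a = 3, p = 6) the constant decays smoothly from ~500 at
#' contact to ~214 kJ/mol/nm^2 at the 0.9 nm cutoff. The exponent grouping
#' d^(2p) is configurable via `exponent_fun` should a different reading of
#' the kernel be wanted.
#'
#' @param f force-constant scale, kJ/mol/nm^2 (default 500).
#' @param a decay coefficient (default 3).
#' @param p decay power (default 6; the distance enters as d^(2p)).
#' @param cutoff bond distance cutoff in nm (default 0.9).
#' @param excluded_offsets sequence separations |i-j| excluded because the
#'   base force field already bonds them (default 1 and 2).
#' @param exponent_fun optional function(d, a, p) replacing the default
#'   exponent a * d^(2p).
#' @return a `rubber_band_params` object.
#' @export
rubber_band_params <- function(f = 500, a = 3, p = 6, cutoff = 0.9,
                               excluded_offsets = c(1L, 2L),
                               exponent_fun = NULL) {
  stopifnot(f > 0, cutoff > 0, all(excluded_offsets >= 1))
  structure(list(f = f, a = a, p = p, cutoff = cutoff,
                 excluded_offsets = as.integer(excluded_offsets),
                 exponent_fun = exponent_fun),
            class = "rubber_band_params")
}

#' Rubber-band force constant at a distance
#'
#' @param d distance(s) in nm.
#' @param params [rubber_band_params()].
#' @return force constants in kJ/mol/nm^2.
#' @export
rubber_band_constant <- function(d, params = rubber_band_params()) {
  expo <- if (is.null(params$exponent_fun)) params$a * d^(2 * params$p)
          else params$exponent_fun(d, params$a, params$p)
  params$f * exp(-expo)
}

#' Build the rubber-band bond list of a backbone bead chain
#'
#' Bonds all bead pairs within the cutoff whose sequence separation is not
#' excluded; k_ij = f * exp(-a * d_ij^(2p)).
#'
#' @param coords ordered n x 3 backbone bead positions (nm), n >= 3.
#' @param params [rubber_band_params()].
#' @return data.frame with columns `i`, `j` (i < j), `d` (nm), `k`
#'   (kJ/mol/nm^2).
#' @export
build_rubber_bands <- function(coords, params = rubber_band_params()) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L, nrow(coords) >= 3L)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  pair <- which(upper.tri(d), arr.ind = TRUE)
  dij <- d[pair]
  sep <- pair[, 2] - pair[, 1]
  keep <- dij <= params$cutoff & !(sep %in% params$excluded_offsets)
  out <- data.frame(i = pair[keep, 1], j = pair[keep, 2], d = dij[keep])
  out$k <- rubber_band_constant(out$d, params)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Write a rubber-band bond list as TSV
#'
#' @param bonds data.frame from [build_rubber_bands()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_rubber_bands <- function(bonds, path) {
  tab <- result_table(bonds, units = c(d = "nm", k = "kJ/mol/nm^2"),
                      provenance = list(kind = "rubber_band_network"))
  write_result_table(tab, path)
}

#' Superposed root-mean-square deviation
#'
#' Least-squares rigid superposition (Kabsch) of `coords_b` onto `coords_a`
#' over the fit selection, then RMSD over the deviation selection. The
#' partial-fit mode (fit on one protomer, RMSD over the whole dimer)
#' reproduces crystal-versus-simulation comparisons in which only monomer A
#' is aligned.
#'
#' @param coords_a,coords_b matched n x 3 coordinate sets (nm).
#' @param fit_sel row indices used for the superposition (default: all).
#' @param rmsd_sel row indices entering the RMSD (default: all).
#' @return an `rmsd_result`: list(nm, angstrom, fit) where `fit` is the
#'   rigid transform applied to `coords_b`.
#' @export
superposed_rmsd <- function(coords_a, coords_b, fit_sel = NULL, rmsd_sel = NULL) {
  if (!all(dim(coords_a) == dim(coords_b)))
    stop("coordinate sets must match in size")
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(coords_a))
  if (is.null(rmsd_sel)) rmsd_sel <- seq_len(nrow(coords_a))
  fit <- kabsch(coords_a[fit_sel, , drop = FALSE],
                coords_b[fit_sel, , drop = FALSE])
  moved <- apply_rigid(coords_b, fit)
  dev <- coords_a[rmsd_sel, , drop = FALSE] - moved[rmsd_sel, , drop = FALSE]
  r <- sqrt(mean(rowSums(dev^2)))
  structure(list(nm = r, angstrom = 10 * r, fit = fit),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("RMSD = %.4f nm (%.2f A)\n", x$nm, x$angstrom))
  invisible(x)
}

#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' Deterministic golden-spiral surface points on each expanded sphere
#' (radius + probe); a point is buried if it lies within any other bead's
#' expanded radius (inclusive boundary). Reported at the expanded radius.
#'
#' @param coords n x 3 bead positions (nm).
#' @param radii bead radii (nm), scalar or per-bead.
#' @param probe probe radius in nm (default 0.191).
#' @param n_points surface sample points per bead (default 960).
#' @return SASA in nm^2.
#' @export
sasa <- function(coords, radii, probe = 0.191, n_points = 960) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L)
  n <- nrow(coords)
  if (length(radii) == 1L) radii <- rep(radii, n)
  stopifnot(length(radii) == n)
  pts <- sphere_points(n_points)
  rexp_ <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    p <- sweep(pts * rexp_[i], 2, coords[i, ], "+")
    others <- setdiff(seq_len(n), i)
    # only beads close enough can occlude
    if (length(others)) {
      dc <- sqrt(rowSums(sweep(coords[others, , drop = FALSE], 2,
                               coords[i, ])^2))
      near <- others[dc <= rexp_[i] + rexp_[others]]
    } else near <- integer()
    if (length(near)) {
      d <- cross_dist(p, coords[near, , drop = FALSE])
      buried <- rowSums(sweep(d, 2, rexp_[near] + 1e-12, "<=")) > 0
      acc <- sum(!buried)
    } else acc <- n_points
    total <- total + acc / n_points * 4 * pi * rexp_[i]^2
  }
  total
}

#' Buried surface area of a two-body complex
#'
#' BSA = SASA(A) + SASA(B) - SASA(A union B), with SASA from [sasa()].
#'
#' @param coords_a,coords_b bead positions (nm) of the two bodies.
#' @param radii_a,radii_b bead radii (nm), scalar or per-bead (default
#'   0.264 nm, a typical coarse-grained bead radius).
#' @param probe probe radius (nm, default 0.191).
#' @param n_points surface sample points per bead.
#' @return BSA in nm^2.
#' @export
buried_surface_area <- function(coords_a, coords_b,
                                radii_a = 0.264, radii_b = 0.264,
                                probe = 0.191, n_points = 960) {
  if (length(radii_a) == 1L) radii_a <- rep(radii_a, nrow(coords_a))
  if (length(radii_b) == 1L) radii_b <- rep(radii_b, nrow(coords_b))
  sa <- sasa(coords_a, radii_a, probe, n_points)
  sb <- sasa(coords_b, radii_b, probe, n_points)
  sab <- sasa(rbind(coords_a, coords_b), c(radii_a, radii_b), probe, n_points)
  bsa <- sa + sb - sab
  if (bsa < -1e-6 * max(sa, sb))
    stop("negative buried surface area: check radii/probe configuration")
  max(bsa, 0)
}

#' Percent sequence identity from a pairwise alignment
#'
#' Identities divided by aligned positions (columns with a residue in both
#' sequences), times 100. Optionally restricted to a residue-number range of
#' the first sequence (for per-helix identities). The denominator is
#' configurable to the full alignment length.
#'
#' @param a,b aligned sequences of equal length (character strings with `-`
#'   gaps, or character vectors of single letters).
#' @param range optional c(first, last) residue numbers of sequence `a`
#'   delimiting the columns considered.
#' @param denominator "aligned" (default) or "alignment" (full length).
#' @return percent identity.
#' @export
percent_identity <- function(a, b, range = NULL,
                             denominator = c("aligned", "alignment")) {
  denominator <- match.arg(denominator)
  sa <- toupper(if (length(a) == 1L) strsplit(a, "")[[1L]] else a)
  sb <- toupper(if (length(b) == 1L) strsplit(b, "")[[1L]] else b)
  if (length(sa) != length(sb)) stop("aligned sequences differ in length")
  both_gap <- sa == "-" & sb == "-"
  sa <- sa[!both_gap]; sb <- sb[!both_gap]
  cols <- seq_along(sa)
  if (!is.null(range)) {
    resno <- cumsum(sa != "-")          # residue numbering of sequence a
    cols <- cols[sa != "-" & resno >= range[1] & resno <= range[2]]
    if (!length(cols)) stop("empty overlap after range restriction")
  }
  aligned <- cols[sa[cols] != "-" & sb[cols] != "-"]
  denom <- if (denominator == "aligned") length(aligned) else length(cols)
  if (denom == 0) stop("no aligned positions")
  100 * sum(sa[aligned] == sb[aligned]) / denom
}

#' Read a pairwise alignment from aligned FASTA
#'
#' @param path aligned FASTA with at least two records.
#' @param which indices of the two records (default first two).
#' @return list of two aligned character strings, named by record.
#' @export
read_alignment_fasta <- function(path, which = c(1L, 2L)) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readBStringSet(path)
    if (length(s) < max(which)) stop("alignment has too few records")
    stats::setNames(as.list(as.character(s[which])), names(s)[which])
  } else {
    lines <- readLines(path, warn = FALSE)
    idx <- grep("^>", lines)
    if (length(idx) < max(which)) stop("alignment has too few records")
    ends <- c(idx[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(idx), function(i)
      paste(lines[(idx[i] + 1L):ends[i]], collapse = ""), "")
    stats::setNames(as.list(seqs[which]), sub("^>\\s*", "", lines[idx[which]]))
  }
}
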