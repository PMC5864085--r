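# Receptor domain model: residues, bead bookkeeping, helix assignments and a
# reference frame of coordinates. The canonical seven transmembrane helices
# are labelled TM1..TM7; the amphipathic helix 8 (H8) is optional (it is not
# resolved, e.g., in the available CXCR4 crystal structures).

HELIX_LABELS <- c(paste0("TM", 1:7), "H8")

#' Construct a receptor model
#'
#' @param name receptor name.
#' @param atoms data.frame with one row per bead: `resid`, `resname`, `atom`
#'   (bead name; the backbone bead is `"BB"` for Martini models, `"CA"` for
#'   atomistic PDB input).
#' @param helix_map named list mapping helix labels (TM1..TM7, optionally H8)
#'   to inclusive residue-number ranges `c(first, last)`.
#' @param reference_coords n_beads x 3 matrix of reference positions (nm).
#' @param backbone_atom bead name identifying the backbone bead.
#' @return an object of class `receptor_model` with per-residue bead indices
#'   and backbone bead indices resolved.
#' @export
receptor_model <- function(name, atoms, helix_map, reference_coords,
                           backbone_atom = "BB") {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(reference_coords))
  unknown <- setdiff(names(helix_map), HELIX_LABELS)
  if (length(unknown))
    stop("unknown helix label: ", paste(unknown, collapse = ", "))
  missing_tm <- setdiff(paste0("TM", 1:7), names(helix_map))
  if (length(missing_tm))
    stop("helix map must cover TM1-TM7; missing: ",
         paste(missing_tm, collapse = ", "))

  resids <- unique(atoms$resid)
  for (h in names(helix_map)) {
    rng <- helix_map[[h]]
    if (length(rng) != 2L || rng[1] > rng[2])
      stop("helix range for ", h, " must be c(first, last)")
    absent <- setdiff(seq(rng[1], rng[2]), resids)
    if (length(absent))
      stop("helix ", h, " references absent residues: ",
           paste(absent, collapse = ", "))
  }
  # non-overlap
  hm <- do.call(rbind, lapply(names(helix_map), function(h)
    data.frame(helix = h, first = helix_map[[h]][1], last = helix_map[[h]][2])))
  hm <- hm[order(hm$first), ]
  if (nrow(hm) > 1L && any(hm$first[-1] <= hm$last[-nrow(hm)]))
    stop("helix ranges overlap")

  bead_index <- split(seq_len(nrow(atoms)), factor(atoms$resid, levels = resids))
  nb <- lengths(bead_index)
  if (any(nb < 1L)) stop("every residue needs at least one bead")
  bb <- vapply(bead_index, function(i) {
    j <- i[atoms$atom[i] == backbone_atom]
    if (length(j) != 1L) NA_integer_ else j
  }, 1L)
  if (anyNA(bb))
    stop("residues without exactly one backbone bead ('", backbone_atom, "'): ",
         paste(resids[is.na(bb)], collapse = ", "))

  residues <- data.frame(resid = resids,
                         resname = vapply(bead_index,
                                          function(i) atoms$resname[i[1]], ""),
                         helix = residue_helix(resids, helix_map),
                         stringsAsFactors = FALSE)
  structure(list(name = name, atoms = atoms, residues = residues,
                 bead_index = bead_index,
                 backbone_bead_index = stats::setNames(bb, resids),
                 helix_map = helix_map,
                 reference_coords = reference_coords),
            class = "receptor_model")
}

residue_helix <- function(resids, helix_map) {
  h <- rep(NA_character_, length(resids))
  for (lab in names(helix_map)) {
    rng <- helix_map[[lab]]
    h[resids >= rng[1] & resids <= rng[2]] <- lab
  }
  h
}

#' @export
print.receptor_model <- function(x, ...) {
  cat(sprintf("Receptor model '%s': %d residues, %d beads, helices: %s\n",
              x$name, nrow(x$residues), nrow(x$atoms),
              paste(names(x$helix_map), collapse = " ")))
  invisible(x)
}

# Bead row indices of the TM backbone (used for frames, superposition, RMSD).
tm_backbone_indices <- function(receptor) {
  tm <- receptor$residues$resid[receptor$residues$helix %in% paste0("TM", 1:7)]
  unname(receptor$backbone_bead_index[as.character(tm)])
}

helix_backbone_indices <- function(receptor, helix) {
  r <- receptor$residues$resid[receptor$residues$helix %in% helix]
  unname(receptor$backbone_bead_index[as.character(r)])
}

#' Read a receptor structure from a GRO or PDB file
#'
#' Coordinates are stored in nm regardless of the input convention: GRO files
#' are already nm, PDB Angstrom coordinates are divided by 10. PDB parsing is
#' delegated to \pkg{bio3d}; the C-alpha atom serves as the backbone bead for
#' atomistic input.
#'
#' @param path structure file (`.gro` or `.pdb`).
#' @param helix_table data.frame with columns `helix`, `first`, `last`
#'   (inclusive residue-number ranges for TM1..TM7 and optionally H8).
#' @param name receptor name (defaults to the file stem).
#' @return a `receptor_model`.
#' @export
read_structure <- function(path, helix_table,
                           name = sub("\\.(gro|pdb)$", "", basename(path))) {
  stopifnot(all(c("helix", "first", "last") %in% names(helix_table)))
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    fr <- read_gro(path)
    atoms <- fr$atoms
    coords <- fr$coords
    backbone <- "BB"
  } else if (ext == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("reading PDB files requires the bio3d package")
    pdb <- bio3d::read.pdb(path)
    sel <- pdb$atom$type %in% c("ATOM", "HETATM")
    a <- pdb$atom[sel, ]
    atoms <- data.frame(resid = a$resno, resname = a$resid, atom = a$elety,
                        atomid = a$eleno, stringsAsFactors = FALSE)
    coords <- cbind(a$x, a$y, a$z) / 10   # Angstrom -> nm
    backbone <- "CA"
  } else stop("unsupported structure format: .", ext)
  helix_map <- stats::setNames(
    lapply(seq_len(nrow(helix_table)),
           function(i) c(helix_table$first[i], helix_table$last[i])),
    helix_table$helix)
  receptor_model(name, atoms, helix_map, coords, backbone_atom = backbone)
}
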