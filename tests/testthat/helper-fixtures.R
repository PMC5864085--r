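# Shared fixture builders. Everything is generated in code at test time;
# nothing binary is stored.

# a minimal two-replica manifest on disk, with real energy files
make_tiny_manifest <- function(dir = tempfile("ens"), chol = 0.3, n = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("r%03d", seq_len(n))
  for (id in ids) {
    tr <- energy_trace(c(0, 100, 200), c(0, -60, -70), replica_id = id)
    write_energy_xvg(tr, file.path(dir, paste0(id, ".xvg")))
    b <- gen_bundle()
    write_gro(b$atoms, b$coords, c(12, 12, 10),
              file.path(dir, paste0(id, ".gro")))
    write_gro(b$atoms, b$coords, c(12, 12, 10),
              file.path(dir, paste0(id, ".trj.gro")), title = "frame t= 0")
  }
  m <- ensemble_manifest("tiny", "CCR5", "CCR5",
                         popc_fraction = 1 - chol,
                         cholesterol_fraction = chol, t_sim = 3,
                         replicas = data.frame(
                           replica_id = ids,
                           coordinate = paste0(ids, ".gro"),
                           trajectory = paste0(ids, ".trj.gro"),
                           energy = paste0(ids, ".xvg"),
                           stringsAsFactors = FALSE))
  path <- file.path(dir, "manifest.txt")
  write_manifest(m, path)
  path
}

# energy trace from a plain energy vector at 100 ns spacing
toy_trace <- function(energies, dt = 100) {
  energy_trace(seq_along(energies) * dt - dt, energies, replica_id = "toy")
}

# brute-force occupancy oracle: naive loops over residues and cholesterol
# beads with the same minimum-image convention
brute_occupancy <- function(frames, receptor, cutoff) {
  res <- receptor$residues
  occ <- numeric(nrow(res))
  for (i in seq_len(nrow(res))) {
    beads <- receptor$bead_index[[i]]
    hits <- 0L
    for (fr in frames) {
      bound <- FALSE
      for (b in beads) {
        d <- fr$chol_coords
        dx <- d[, 1] - fr$receptor_coords[b, 1]
        dy <- d[, 2] - fr$receptor_coords[b, 2]
        dz <- d[, 3] - fr$receptor_coords[b, 3]
        dx <- dx - fr$box[1] * round(dx / fr$box[1])
        dy <- dy - fr$box[2] * round(dy / fr$box[2])
        dz <- dz - fr$box[3] * round(dz / fr$box[3])
        if (min(sqrt(dx^2 + dy^2 + dz^2)) <= cutoff) { bound <- TRUE; break }
      }
      if (bound) hits <- hits + 1L
    }
    occ[i] <- hits / length(frames)
  }
  occ
}

# random rigid molecular frame (unit in-plane axes, shared membrane normal)
random_frame <- function() {
  a <- runif(1, 0, 360) * pi / 180
  o <- c(runif(2, -5, 5), 0)
  structure(list(origin = o,
                 x_axis = c(cos(a), sin(a), 0),
                 y_axis = c(-sin(a), cos(a), 0),
                 z_axis = c(0, 0, 1)),
            class = "molecular_frame")
}
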