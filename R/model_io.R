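# ---------------------------------------------------------------------------
# Ensemble manifest
#
# One documented plain-text schema holds the ensemble bookkeeping: a
# key = value preamble followed by a `[replicas]` table with one row per
# replica (id, coordinate file, trajectory file, energy file). Paths are
# interpreted relative to the manifest location.
# ---------------------------------------------------------------------------

#' Construct an ensemble manifest
#'
#' An ensemble manifest describes a set of replica self-assembly simulations
#' of two receptors in a lipid bilayer: identities, membrane composition,
#' simulation length and the per-replica file inventory.
#'
#' @param ensemble_id character identifier.
#' @param receptor_a,receptor_b receptor identifiers (e.g. "CCR5").
#' @param popc_fraction,cholesterol_fraction mole fractions in `[0, 1]`.
#' @param t_sim simulation length per replica in microseconds.
#' @param dt_out trajectory/energy output interval in nanoseconds.
#' @param temperature simulation temperature in Kelvin.
#' @param area_density receptors per nm^2 (metadata).
#' @param replicas data.frame with columns `replica_id`, `coordinate`,
#'   `trajectory`, `energy` (file paths, possibly relative).
#' @return an object of class `ensemble_manifest`.
#' @export
ensemble_manifest <- function(ensemble_id, receptor_a, receptor_b,
                              popc_fraction = 1, cholesterol_fraction = 0,
                              t_sim, dt_out = 1, temperature = 310,
                              area_density = 0.015,
                              replicas = data.frame(replica_id = character(),
                                                    coordinate = character(),
                                                    trajectory = character(),
                                                    energy = character())) {
  m <- structure(list(
    ensemble_id = as.character(ensemble_id),
    receptor_a = as.character(receptor_a),
    receptor_b = as.character(receptor_b),
    membrane = list(popc_fraction = popc_fraction,
                    cholesterol_fraction = cholesterol_fraction),
    n_replicas = nrow(replicas),
    t_sim = t_sim, dt_out = dt_out,
    temperature = temperature, area_density = area_density,
    replicas = replicas,
    dir = "."
  ), class = "ensemble_manifest")
  stop_on_problems(validate_manifest(m), "manifest")
  m
}

#' Validate an ensemble manifest
#'
#' Checks the structural invariants: replica count consistency, positive
#' simulation length, cholesterol fraction in `[0, 1]` and unique replica ids.
#'
#' @param m an `ensemble_manifest`.
#' @return character vector of problems (empty when valid).
#' @export
validate_manifest <- function(m) {
  p <- character()
  req <- c("replica_id", "coordinate", "trajectory", "energy")
  if (!all(req %in% names(m$replicas)))
    p <- c(p, paste("replica table missing columns:",
                    paste(setdiff(req, names(m$replicas)), collapse = ", ")))
  if (m$n_replicas != nrow(m$replicas))
    p <- c(p, sprintf("n_replicas (%d) != number of replica rows (%d)",
                      m$n_replicas, nrow(m$replicas)))
  if (!is.finite(m$t_sim) || m$t_sim <= 0) p <- c(p, "t_sim must be > 0")
  ch <- m$membrane$cholesterol_fraction
  if (!is.finite(ch) || ch < 0 || ch > 1)
    p <- c(p, "cholesterol fraction must lie in [0, 1]")
  if (anyDuplicated(m$replicas$replica_id))
    p <- c(p, paste("duplicate replica_id:",
                    paste(unique(m$replicas$replica_id[
                      duplicated(m$replicas$replica_id)]), collapse = ", ")))
  p
}

stop_on_problems <- function(problems, what) {
  if (length(problems))
    stop(sprintf("invalid %s:\n  - %s", what,
                 paste(problems, collapse = "\n  - ")), call. = FALSE)
  invisible(TRUE)
}

#' Read an ensemble manifest file
#'
#' Parses the key = value preamble and the `[replicas]` table, validates all
#' invariants and checks that the referenced files exist. Missing files are
#' collected in a warning (attribute `missing_files`), not an error, so that
#' partially staged ensembles can still be inspected.
#'
#' @param path manifest file path.
#' @return a validated `ensemble_manifest`; its `dir` field holds the
#'   manifest directory for resolving relative paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sect <- which(lines == "[replicas]")
  if (length(sect) != 1L)
    stop("malformed manifest: expected exactly one [replicas] section")
  head_lines <- lines[seq_len(sect - 1L)]
  kv <- regmatches(head_lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", head_lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop("malformed manifest: cannot parse line '", head_lines[bad[1]], "'")
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  get <- function(key, default = NULL, num = FALSE) {
    i <- match(key, keys)
    if (is.na(i)) {
      if (is.null(default)) stop("malformed manifest: missing field '", key, "'")
      return(default)
    }
    if (num) {
      v <- suppressWarnings(as.numeric(vals[i]))
      if (is.na(v)) stop("malformed manifest: field '", key, "' is not numeric")
      v
    } else vals[i]
  }
  body <- lines[(sect + 1L):length(lines)]
  if (!length(body)) stop("malformed manifest: empty replica table")
  con <- textConnection(body)
  on.exit(close(con))
  reps <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE)
  if (!is.character(reps$replica_id)) reps$replica_id <- as.character(reps$replica_id)

  m <- structure(list(
    ensemble_id = get("ensemble_id"),
    receptor_a = get("receptor_a"),
    receptor_b = get("receptor_b"),
    membrane = list(popc_fraction = get("popc_fraction", 1, num = TRUE),
                    cholesterol_fraction = get("cholesterol_fraction", num = TRUE)),
    n_replicas = get("n_replicas", num = TRUE),
    t_sim = get("t_sim_us", num = TRUE),
    dt_out = get("dt_out_ns", 1, num = TRUE),
    temperature = get("temperature_K", 310, num = TRUE),
    area_density = get("area_density_nm2", 0.015, num = TRUE),
    replicas = reps,
    dir = dirname(path)
  ), class = "ensemble_manifest")
  stop_on_problems(validate_manifest(m), "manifest")

  files <- file.path(m$dir, unlist(m$replicas[c("coordinate", "trajectory", "energy")]))
  missing <- unique(files[!file.exists(files)])
  if (length(missing)) {
    warning("manifest references missing files: ",
            paste(basename(missing), collapse = ", "))
    attr(m, "missing_files") <- missing
  }
  m
}

#' Write an ensemble manifest file
#'
#' @param m an `ensemble_manifest`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  hdr <- c(
    "# dimerscope ensemble manifest",
    paste0("ensemble_id = ", m$ensemble_id),
    paste0("receptor_a = ", m$receptor_a),
    paste0("receptor_b = ", m$receptor_b),
    paste0("popc_fraction = ", m$membrane$popc_fraction),
    paste0("cholesterol_fraction = ", m$membrane$cholesterol_fraction),
    paste0("n_replicas = ", m$n_replicas),
    paste0("t_sim_us = ", m$t_sim),
    paste0("dt_out_ns = ", m$dt_out),
    paste0("temperature_K = ", m$temperature),
    paste0("area_density_nm2 = ", m$area_density),
    "[replicas]")
  tab <- utils::capture.output(
    utils::write.table(m$replicas, sep = "\t", quote = FALSE, row.names = FALSE))
  writeLines(c(hdr, tab), path)
  invisible(path)
}

#' @export
print.ensemble_manifest <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %s/%s, %d replicas, %g us each\n",
              x$ensemble_id, x$receptor_a, x$receptor_b, x$n_replicas, x$t_sim))
  cat(sprintf("  membrane: POPC %.2f / cholesterol %.2f, %g K\n",
              x$membrane$popc_fraction, x$membrane$cholesterol_fraction,
              x$temperature))
  invisible(x)
}

# ---------------------------------------------------------------------------
# GRO coordinates and multi-frame GRO trajectories
# ---------------------------------------------------------------------------

#' Read a GRO coordinate file
#'
#' Fixed-width GROMACS GRO parsing. Coordinates are already in nm by the
#' format's convention.
#'
#' @param path GRO file.
#' @return list with `title`, `atoms` (data.frame: resid, resname, atom,
#'   atomid), `coords` (n x 3 matrix, nm) and `box` (length-3, nm).
#' @export
read_gro <- function(path) {
  fr <- read_gro_frames(path, max_frames = 1L)[[1L]]
  fr
}

# Parse one or more concatenated GRO frames. Used for both single structures
# and trajectories written as multi-frame GRO (the text format trjconv emits).
read_gro_frames <- function(path, max_frames = Inf) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && length(frames) < max_frames) {
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO file at line ", i + 1L, ": bad atom count")
    if (i + 1L + n + 1L > length(lines))
      stop("truncated GRO frame starting at line ", i)
    at <- lines[(i + 2L):(i + 1L + n)]
    resid <- as.integer(substr(at, 1, 5))
    resname <- trimws(substr(at, 6, 10))
    atom <- trimws(substr(at, 11, 15))
    atomid <- as.integer(substr(at, 16, 20))
    # coordinate column width auto-detected (GROMACS writes 8 chars for the
    # default 3 decimals, wider for higher-precision output)
    w <- (nchar(at[1L]) - 20L) %/% 3L
    if (w < 8L) stop("malformed GRO coordinate line at line ", i + 2L)
    x <- as.numeric(substr(at, 21, 20 + w))
    y <- as.numeric(substr(at, 21 + w, 20 + 2L * w))
    z <- as.numeric(substr(at, 21 + 2L * w, 20 + 3L * w))
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1L]])[1:3]
    tm <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1L]]
    time <- if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_
    frames[[length(frames) + 1L]] <- list(
      title = title, time = time,
      atoms = data.frame(resid = resid, resname = resname,
                         atom = atom, atomid = atomid,
                         stringsAsFactors = FALSE),
      coords = cbind(x = x, y = y, z = z),
      box = box)
    i <- i + n + 3L
  }
  frames
}

#' Read a multi-frame GRO trajectory
#'
#' @param path multi-frame GRO file (concatenated frames; frame times are
#'   parsed from `t=` in the title line when present).
#' @return list of frames, each with `time` (ns), `coords`, `box`, `atoms`.
#' @export
read_trajectory <- function(path) read_gro_frames(path)

#' Stream a multi-frame GRO trajectory frame by frame
#'
#' Applies `fun` to every frame without holding the whole trajectory in
#' memory, so large replica ensembles can be reduced incrementally.
#'
#' @param path multi-frame GRO file.
#' @param fun function of (frame, frame_index).
#' @return list of `fun` results, invisibly.
#' @export
traj_apply <- function(path, fun) {
  con <- file(path, open = "r")
  on.exit(close(con))
  out <- list()
  k <- 0L
  repeat {
    title <- readLines(con, n = 1L)
    if (!length(title)) break
    n <- as.integer(trimws(readLines(con, n = 1L)))
    block <- readLines(con, n = n + 1L)
    txt <- c(title, n, block)
    fr <- read_gro_frames_text(txt)
    k <- k + 1L
    out[[k]] <- fun(fr, k)
  }
  invisible(out)
}

read_gro_frames_text <- function(lines) {
  tf <- tempfile(fileext = ".gro")
  on.exit(unlink(tf))
  writeLines(as.character(lines), tf)
  read_gro_frames(tf, max_frames = 1L)[[1L]]
}

#' Write a GRO frame (or append a trajectory frame)
#'
#' @param atoms data.frame with resid, resname, atom, atomid.
#' @param coords n x 3 coordinate matrix (nm).
#' @param box length-3 box vector (nm).
#' @param path output file.
#' @param title title line; a `t=` entry marks the frame time in ns.
#' @param append append as an additional trajectory frame.
#' @param ndec coordinate decimals (3 is the GROMACS default; higher values
#'   widen the columns as GROMACS' high-precision output does).
#' @return `path`, invisibly.
#' @export
write_gro <- function(atoms, coords, box, path, title = "dimerscope",
                      append = FALSE, ndec = 3L) {
  n <- nrow(coords)
  fmt <- sprintf("%%5d%%-5s%%5s%%5d%%%d.%df%%%d.%df%%%d.%df",
                 ndec + 5L, ndec, ndec + 5L, ndec, ndec + 5L, ndec)
  body <- sprintf(fmt,
                  atoms$resid %% 100000L, substr(atoms$resname, 1, 5),
                  substr(atoms$atom, 1, 5), atoms$atomid %% 100000L,
                  coords[, 1], coords[, 2], coords[, 3])
  txt <- c(title, sprintf("%5d", n), body,
           sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  if (append) cat(txt, file = path, sep = "\n", append = TRUE)
  else writeLines(txt, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# XVG-dialect energy traces
# ---------------------------------------------------------------------------

#' Read a two-column XVG-dialect energy time series
#'
#' Lines starting with `#` or `@` are comments/headers. Data rows are
#' whitespace-separated time (ns) and transmembrane interaction energy
#' (kJ/mol, sum of Lennard-Jones and Coulomb terms).
#'
#' @param path XVG file.
#' @param replica_id optional replica identifier attached to the trace.
#' @return an `energy_trace`: list(replica_id, times, energies, state, events);
#'   `state`/`events` are unset until [annotate_events()].
#' @export
read_energy_xvg <- function(path, replica_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  ln <- which(keep)
  if (!length(ln)) stop("no data rows in XVG file: ", path)
  parts <- strsplit(trimws(lines[ln]), "\\s+")
  short <- which(lengths(parts) < 2L)
  if (length(short))
    stop(sprintf("parse error in %s at line %d: fewer than 2 columns",
                 path, ln[short[1L]]))
  times <- as.numeric(vapply(parts, `[`, "", 1L))
  energies <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(times) || anyNA(energies))
    stop("non-numeric data in XVG file: ", path)
  energy_trace(times, energies, replica_id = replica_id)
}

#' Construct an energy trace
#'
#' @param times frame times in ns, strictly increasing.
#' @param energies TM-TM interaction energies in kJ/mol.
#' @param replica_id optional identifier.
#' @return an `energy_trace` object.
#' @export
energy_trace <- function(times, energies, replica_id = NA_character_) {
  if (!length(times)) stop("empty energy trace")
  if (length(times) != length(energies))
    stop("times and energies differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(replica_id = replica_id, times = as.numeric(times),
                 energies = as.numeric(energies),
                 state = NULL, events = NULL),
            class = "energy_trace")
}

#' @export
print.energy_trace <- function(x, ...) {
  cat(sprintf("Energy trace%s: %d frames, %.1f-%.1f ns\n",
              if (is.na(x$replica_id)) "" else paste0(" ", x$replica_id),
              length(x$times), x$times[1], x$times[length(x$times)]))
  if (!is.null(x$events) && nrow(x$events))
    cat(sprintf("  %d event(s): %s\n", nrow(x$events),
                paste(sprintf("%s@%.1f", x$events$kind, x$events$time),
                      collapse = ", ")))
  invisible(x)
}

#' Write an energy trace in XVG dialect
#'
#' @param trace an `energy_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_energy_xvg <- function(trace, path) {
  hdr <- c("# dimerscope energy trace",
           "@ title \"TM-TM interaction energy\"",
           "@ xaxis label \"time (ns)\"",
           "@ yaxis label \"energy (kJ/mol)\"")
  writeLines(c(hdr, sprintf("%.6g %.6g", trace$times, trace$energies)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result tables with provenance
# ---------------------------------------------------------------------------

#' Construct a result table
#'
#' A plain data.frame plus unit strings per column and a provenance record
#' (ensemble id, parameters, package version) that is preserved through the
#' TSV round-trip.
#'
#' @param data data.frame of results.
#' @param units named character vector (one entry per physical column;
#'   dimensionless columns may be omitted or "").
#' @param provenance named list of provenance fields.
#' @return an object of class `result_table`.
#' @export
result_table <- function(data, units = character(), provenance = list()) {
  stopifnot(is.data.frame(data))
  if (length(units) && is.null(names(units)))
    stop("units must be a named vector")
  bad <- setdiff(names(units), names(data))
  if (length(bad)) stop("units for unknown columns: ", paste(bad, collapse = ", "))
  provenance$software <- paste0("dimerscope ",
                                as.character(utils::packageVersion("dimerscope")))
  structure(list(data = data, units = units, provenance = provenance),
            class = "result_table")
}

#' Write a result table as TSV with a provenance header
#'
#' @param tab a `result_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path) {
  stopifnot(inherits(tab, "result_table"))
  prov <- vapply(tab$provenance, function(v) paste(as.character(v), collapse = ","), "")
  hdr <- c(sprintf("#provenance %s=%s", names(prov), prov),
           if (length(tab$units))
             sprintf("#units %s=%s", names(tab$units), tab$units))
  body <- utils::capture.output(
    utils::write.table(tab$data, sep = "\t", quote = FALSE, row.names = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path TSV file.
#' @return a `result_table`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  parse_kv <- function(prefix) {
    h <- hdr[startsWith(hdr, prefix)]
    h <- sub(paste0("^", prefix, " "), "", h)
    kv <- strsplit(h, "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                    vapply(kv, `[`, "", 1L))
  }
  prov <- as.list(parse_kv("#provenance"))
  units <- parse_kv("#units")
  if (length(body) < 1L) stop("result table has no header row")
  con <- textConnection(body)
  on.exit(close(con))
  data <- utils::read.table(con, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  tab <- result_table(data, units = units, provenance = list())
  tab$provenance <- prov
  tab
}

# ---------------------------------------------------------------------------
# OpenDX scalar grids
# ---------------------------------------------------------------------------

#' Write a 3D scalar grid in OpenDX format
#'
#' @param grid 3D numeric array.
#' @param origin length-3 grid origin (nm).
#' @param spacing scalar or length-3 voxel spacing (nm).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, origin, spacing, path) {
  stopifnot(length(dim(grid)) == 3L)
  d <- dim(grid)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  hdr <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", origin[1], origin[2], origin[3]),
    sprintf("delta %g 0 0", spacing[1]),
    sprintf("delta 0 %g 0", spacing[2]),
    sprintf("delta 0 0 %g", spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d)))
  # DX stores with z fastest
  vals <- as.vector(aperm(grid, c(3, 2, 1)))
  pad <- ceiling(length(vals) / 3) * 3 - length(vals)
  v <- c(vals, rep(NA_real_, pad))
  rows <- matrix(v, ncol = 3, byrow = TRUE)
  body <- apply(rows, 1, function(r) paste(format(r[!is.na(r)], digits = 7),
                                           collapse = " "))
  writeLines(c(hdr, body,
               'attribute "dep" string "positions"',
               'object "density" class field'), path)
  invisible(path)
}
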