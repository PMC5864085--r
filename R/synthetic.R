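# Synthetic-data generators with machine-readable ground truth.
#
# These emulate the statistical structure of large self-assembly ensembles
# (hundreds of replicas with exponential first-dimerization times and rare
# dissociations, basin-clustered orientation angles, idealized 7-TM bead
# bundles, 8-bead cholesterol with a polar ROH headgroup, 2D Brownian
# protein diffusion) so that every analysis stage can be validated against
# known truth without running molecular dynamics. All generators are
# deterministic for a fixed seed.

#' Generate an ensemble of synthetic interaction-energy traces
#'
#' Per replica: an exponential first-dimerization time at rate `k_on`; on
#' every dimerization a Bernoulli(`p_diss`) draw decides whether the dimer
#' dissociates, in which case the dimer lifetime is exponential with mean
#' `tau_dimer` (a lifetime reaching past the horizon is censored: the dimer
#' persists to the end and no dissociation is recorded, which keeps the
#' monomer/dimer time bookkeeping memoryless and hence unbiased; the
#' realized dissociation propensity sits marginally below `p_diss` by the
#' small censoring probability). After a dissociation the pair stays
#' monomeric for an exponential period whose mean is set by the stationary
#' dimer `occupancy`, then re-dimerizes. Monomeric frames carry jitter in
#' (-1, 0) kJ/mol; dimeric frames fluctuate (AR(1), clamped below -55
#' kJ/mol) around `mean_dimer_energy`, so the two-threshold event detector
#' recovers the ground-truth schedule at frame resolution.
#'
#' @param n_replicas number of replicas (default 500).
#' @param t_sim simulation length per replica, microseconds (default 3).
#' @param dt output interval, ns (default 1).
#' @param k_on first-order dimerization rate, 1/us (default 0.25).
#' @param p_diss per-dimerization dissociation probability (default 0.1).
#' @param mean_dimer_energy mean dimeric TM-TM energy, kJ/mol (default -120).
#' @param energy_sd dimeric energy fluctuation scale, kJ/mol (default 15).
#' @param tau_dimer mean dimer lifetime before a decided dissociation, us
#'   (default 0.3).
#' @param occupancy stationary dimer occupancy after first binding, used to
#'   set the mean post-dissociation monomer period
#'   `tau_dimer * (1 - occupancy)/occupancy` (default 0.95).
#' @param seed integer seed.
#' @return a `synthetic_ensemble`: list(traces, truth (data.frame of all
#'   ground-truth events), params).
#' @export
gen_energy_ensemble <- function(n_replicas = 500, t_sim = 3, dt = 1,
                                k_on = 0.25, p_diss = 0.1,
                                mean_dimer_energy = -120, energy_sd = 15,
                                occupancy = 0.95, tau_dimer = 0.3,
                                seed = 1) {
  stopifnot(k_on >= 0, p_diss >= 0, p_diss <= 1, t_sim > 0,
            mean_dimer_energy < -55, occupancy > 0, occupancy < 1)
  t_ns <- t_sim * 1000
  if (dt >= t_ns) stop("dt must be smaller than the simulation length")
  tau_mono <- tau_dimer * (1 - occupancy) / occupancy
  set.seed(seed)
  times <- seq(dt, t_ns, by = dt)
  nf <- length(times)
  phi <- exp(-dt / 10)                    # 10 ns energy autocorrelation
  sig_in <- energy_sd * sqrt(1 - phi^2)

  traces <- vector("list", n_replicas)
  truth <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    ev_t <- numeric(); ev_k <- character()
    t <- if (k_on > 0) stats::rexp(1, k_on) * 1000 else Inf
    while (t < t_ns) {
      ev_t <- c(ev_t, t); ev_k <- c(ev_k, "dimerization")
      if (stats::runif(1) >= p_diss) break        # dimer persists to horizon
      life <- stats::rexp(1, 1 / (tau_dimer * 1000))
      if (t + life >= t_ns) break                 # censored at the horizon
      t <- t + life
      ev_t <- c(ev_t, t); ev_k <- c(ev_k, "dissociation")
      mono <- stats::rexp(1, 1 / (tau_mono * 1000))
      if (t + mono >= t_ns) break                 # monomeric to the end
      t <- t + mono
    }
    state <- integer(nf)
    if (length(ev_t)) {
      idx <- findInterval(times, ev_t)
      on <- idx %% 2L == 1L
      state[on] <- 1L
    }
    e <- numeric(nf)
    mono_frames <- which(state == 0L)
    e[mono_frames] <- stats::runif(length(mono_frames), -0.999, -0.001)
    dim_frames <- which(state == 1L)
    if (length(dim_frames)) {
      z <- stats::rnorm(length(dim_frames))
      ed <- numeric(length(dim_frames))
      prev_new <- c(TRUE, diff(dim_frames) > 1L)
      for (i in seq_along(dim_frames)) {
        ed[i] <- if (prev_new[i]) mean_dimer_energy + energy_sd * z[i]
                 else mean_dimer_energy + phi * (ed[i - 1] - mean_dimer_energy) +
                      sig_in * z[i]
      }
      e[dim_frames] <- pmin(ed, -55)
    }
    id <- sprintf("r%04d", r)
    traces[[r]] <- energy_trace(times, e, replica_id = id)
    truth[[r]] <- if (length(ev_t))
      data.frame(replica_id = id, time = ev_t, kind = ev_k,
                 stringsAsFactors = FALSE) else NULL
  }
  structure(list(traces = traces,
                 truth = do.call(rbind, truth),
                 params = list(n_replicas = n_replicas, t_sim = t_sim,
                               dt = dt, k_on = k_on, p_diss = p_diss,
                               mean_dimer_energy = mean_dimer_energy,
                               energy_sd = energy_sd, occupancy = occupancy,
                               tau_dimer = tau_dimer, seed = seed)),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf("Synthetic ensemble: %d replicas x %g us (k_on = %g 1/us, p_diss = %g)\n",
              x$params$n_replicas, x$params$t_sim, x$params$k_on,
              x$params$p_diss))
  invisible(x)
}

#' Write a synthetic ensemble to disk as manifest + XVG files
#'
#' Emits the same file formats the readers consume, so I/O paths can be
#' exercised end to end.
#'
#' @param ens a `synthetic_ensemble`.
#' @param dir output directory (created if needed).
#' @param ensemble_id manifest identifier.
#' @param cholesterol_fraction membrane cholesterol mole fraction recorded
#'   in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_ensemble <- function(ens, dir, ensemble_id = "synthetic",
                           cholesterol_fraction = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(ens$traces, function(tr) tr$replica_id, "")
  reps <- data.frame(replica_id = ids,
                     coordinate = paste0(ids, ".gro"),
                     trajectory = paste0(ids, ".trj.gro"),
                     energy = paste0(ids, ".xvg"),
                     stringsAsFactors = FALSE)
  b <- gen_bundle()
  box <- c(11, 11, 10)
  for (tr in ens$traces) {
    write_energy_xvg(tr, file.path(dir, paste0(tr$replica_id, ".xvg")))
    write_gro(b$atoms, b$coords, box,
              file.path(dir, paste0(tr$replica_id, ".gro")))
    write_gro(b$atoms, b$coords, box,
              file.path(dir, paste0(tr$replica_id, ".trj.gro")),
              title = "frame t= 0")
  }
  m <- ensemble_manifest(ensemble_id, "synthA", "synthB",
                         popc_fraction = 1 - cholesterol_fraction,
                         cholesterol_fraction = cholesterol_fraction,
                         t_sim = ens$params$t_sim, dt_out = ens$params$dt,
                         replicas = reps)
  path <- file.path(dir, "manifest.txt")
  write_manifest(m, path)
  invisible(path)
}

#' Generate an idealized transmembrane helix bundle
#'
#' Helices stand vertically at azimuths 360 i / n on a ring whose radius is
#' modulated as R (1 + bias cos(2 azimuth)); the second-harmonic modulation
#' elongates the xy bead cloud along the TM1 direction without moving its
#' centroid, so the principal axes are well defined while each helix azimuth
#' stays exact. Each helix contributes
#' two backbone bead columns at azimuth +- delta (a small angular
#' half-width emulating the helix cross-section). By construction the
#' molecular frame of the bundle in reference pose has its x-axis at
#' azimuth 0 (through TM1).
#'
#' @param n_helices number of TM helices (default 7).
#' @param ring_radius ring radius in nm (default 1.2).
#' @param beads_per_helix backbone beads per helix (even; default 10).
#' @param rise vertical bead spacing in nm (default 0.3).
#' @param helix_halfwidth_deg angular half-width of a helix (default 6).
#' @param radial_bias ring-radius modulation amplitude (default 0.25).
#' @param h8 add an amphipathic helix 8 as an in-plane radial appendage.
#' @return list(model (`receptor_model`), coords, atoms, truth (helix
#'   azimuths and half-width)).
#' @export
gen_bundle <- function(n_helices = 7, ring_radius = 1.2, beads_per_helix = 10,
                       rise = 0.3, helix_halfwidth_deg = 6,
                       radial_bias = 0.25, h8 = FALSE) {
  stopifnot(n_helices >= 3, beads_per_helix %% 2 == 0)
  az <- 360 * (seq_len(n_helices) - 1) / n_helices
  coords <- NULL
  resid <- integer(); resname <- character(); atom <- character()
  rid <- 0L
  for (h in seq_len(n_helices)) {
    r_h <- ring_radius * (1 + radial_bias * cos(2 * az[h] * pi / 180))
    for (k in seq_len(beads_per_helix)) {
      rid <- rid + 1L
      a <- az[h] + if (k %% 2 == 1L) -helix_halfwidth_deg else helix_halfwidth_deg
      xy <- r_h * c(cos(a * pi / 180), sin(a * pi / 180))
      z <- (k - (beads_per_helix + 1) / 2) * rise
      coords <- rbind(coords, c(xy, z))
      resid <- c(resid, rid); resname <- c(resname, "ALA"); atom <- c(atom, "BB")
    }
  }
  helix_map <- stats::setNames(
    lapply(seq_len(n_helices), function(h)
      c((h - 1L) * beads_per_helix + 1L, h * beads_per_helix)),
    paste0("TM", seq_len(n_helices)))
  if (h8) {
    az8 <- az[n_helices] + 180 / n_helices    # between the last TM and TM1
    n8 <- 4L
    start <- rid
    for (k in seq_len(n8)) {
      rid <- rid + 1L
      r8 <- ring_radius * (1 + radial_bias * cos(2 * az8 * pi / 180)) + 0.3 * k
      xy <- r8 * c(cos(az8 * pi / 180), sin(az8 * pi / 180))
      z <- -(beads_per_helix / 2) * rise - 0.3
      coords <- rbind(coords, c(xy, z))
      resid <- c(resid, rid); resname <- c(resname, "ALA"); atom <- c(atom, "BB")
    }
    helix_map$H8 <- c(start + 1L, start + n8)
  }
  atoms <- data.frame(resid = resid, resname = resname, atom = atom,
                      atomid = seq_along(resid), stringsAsFactors = FALSE)
  colnames(coords) <- c("x", "y", "z")
  model <- receptor_model("synthetic-bundle", atoms, helix_map, coords)
  list(model = model, coords = coords, atoms = atoms,
       truth = list(azimuths = az, halfwidth = helix_halfwidth_deg,
                    h8_azimuth = if (h8) wrap360(az[n_helices] + 180 / n_helices)
                                 else NULL))
}

#' Place two bundles as a dimer with exact ground-truth angles
#'
#' Bundle A stays in its reference pose (frame x-axis at azimuth 0); B is
#' rotated by `phi` about its own z-axis and translated so its centre sits
#' at azimuth `beta` and distance `separation` in A's frame. The returned
#' ground truth includes chi = (180 + beta - phi) mod 360.
#'
#' @param bundle_a,bundle_b outputs of [gen_bundle()].
#' @param beta,phi placement angles in degrees.
#' @param separation centre-centre distance in nm.
#' @return list(coords (stacked A then B), idx_a, idx_b, truth =
#'   c(beta, phi, chi)).
#' @export
place_dimer <- function(bundle_a, bundle_b, beta, phi, separation = 3.5) {
  ca <- bundle_a$coords
  cb <- bundle_b$coords
  if (separation <= 0.5 * max(stats::dist(ca[, 1:2])))
    warning("bundles overlap at this separation")
  # origins are the TM-backbone centres of mass, matching the frame origin
  com_a <- colMeans(ca[tm_backbone_indices(bundle_a$model), , drop = FALSE])
  com_b <- colMeans(cb[tm_backbone_indices(bundle_b$model), , drop = FALSE])
  cb0 <- sweep(cb, 2, com_b)
  cbr <- cb0 %*% rot_z(phi)
  shift <- separation * c(cos(beta * pi / 180), sin(beta * pi / 180), 0)
  cb_final <- sweep(cbr, 2, com_a + shift, "+")
  coords <- rbind(ca, cb_final)
  list(coords = coords,
       idx_a = seq_len(nrow(ca)),
       idx_b = nrow(ca) + seq_len(nrow(cb)),
       truth = c(beta = wrap360(beta), phi = wrap360(phi),
                 chi = wrap360(180 + beta - phi)))
}

#' Generate basin-clustered (beta, chi) samples
#'
#' Mixture of wrapped normals on the angle torus with source labels.
#'
#' @param modes data.frame with columns `beta`, `chi`, `weight`, `sd`
#'   (degrees).
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame: beta, chi, label (mode row index).
#' @export
gen_angle_mixture <- function(modes, n, seed = 1) {
  stopifnot(all(c("beta", "chi", "weight", "sd") %in% names(modes)))
  if (any(modes$sd <= 0)) stop("mode sd must be > 0")
  if (abs(sum(modes$weight) - 1) > 1e-9) stop("weights must sum to 1")
  set.seed(seed)
  lab <- sample.int(nrow(modes), n, replace = TRUE, prob = modes$weight)
  data.frame(beta = wrap360(stats::rnorm(n, modes$beta[lab], modes$sd[lab])),
             chi = wrap360(stats::rnorm(n, modes$chi[lab], modes$sd[lab])),
             label = lab)
}

#' Generate a cholesterol-field trajectory with planted binding hotspots
#'
#' The receptor bundle sits at the box centre. Per frame, each hotspot
#' residue is occupied with its stated probability by one cholesterol
#' molecule whose headgroup (ROH) bead is placed inside the contact shell
#' (0.4 nm from the residue's backbone bead, radially outward); the
#' remaining molecules are placed uniformly in the box. Each cholesterol
#' has 8 beads (ROH first, 7 tail beads in a 0.3 nm radial line).
#'
#' @param bundle output of [gen_bundle()].
#' @param hotspots data.frame with columns `resid`, `p` (binding
#'   probability per frame).
#' @param n_chol cholesterol molecules (default 25).
#' @param n_frames trajectory frames.
#' @param box length-3 box (nm, default c(12, 12, 10)).
#' @param dt frame interval in ns (default 1); frame times start at 0.
#' @param seed integer seed.
#' @return list(frames (each: time, receptor_coords, chol_coords, box),
#'   chol_mol, headgroup, truth = hotspots).
#' @export
gen_chol_field <- function(bundle, hotspots = NULL, n_chol = 25, n_frames = 200,
                           box = c(12, 12, 10), dt = 1, seed = 1) {
  model <- bundle$model
  if (!is.null(hotspots)) {
    absent <- setdiff(hotspots$resid, model$residues$resid)
    if (length(absent))
      stop("hotspot residues absent from bundle: ", paste(absent, collapse = ", "))
    if (nrow(hotspots) > n_chol)
      stop("more simultaneous hotspots than cholesterol molecules")
  }
  set.seed(seed)
  centre <- box / 2
  rec <- sweep(bundle$coords, 2, centre - colMeans(bundle$coords), "+")
  nb <- 8L
  tail_dirs <- seq_len(nb - 1L) * 0.3

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    chol <- matrix(NA_real_, n_chol * nb, 3)
    used <- 0L
    if (!is.null(hotspots)) {
      for (hrow in seq_len(nrow(hotspots))) {
        if (stats::runif(1) < hotspots$p[hrow]) {
          used <- used + 1L
          ridx <- model$backbone_bead_index[[as.character(hotspots$resid[hrow])]]
          anchor <- rec[ridx, ]
          out_dir <- c(anchor[1:2] - centre[1:2], 0)
          out_dir <- out_dir / sqrt(sum(out_dir^2))
          roh <- anchor + 0.4 * out_dir
          tailpts <- t(vapply(tail_dirs, function(s) roh + s * out_dir,
                              numeric(3)))
          chol[(used - 1L) * nb + seq_len(nb), ] <- rbind(roh, tailpts)
        }
      }
    }
    n_free <- n_chol - used
    if (n_free > 0L) {
      base <- cbind(stats::runif(n_free, 0, box[1]),
                    stats::runif(n_free, 0, box[2]),
                    stats::runif(n_free, 0, box[3]))
      dirs <- matrix(stats::rnorm(n_free * 3), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      for (m in seq_len(n_free)) {
        pts <- rbind(base[m, ],
                     t(vapply(tail_dirs, function(s) base[m, ] + s * dirs[m, ],
                              numeric(3))))
        chol[(used + m - 1L) * nb + seq_len(nb), ] <- pts
      }
    }
    frames[[f]] <- list(time = (f - 1L) * dt, receptor_coords = rec,
                        chol_coords = chol, box = box)
  }
  list(frames = frames,
       chol_mol = rep(seq_len(n_chol), each = nb),
       headgroup = rep(c(TRUE, rep(FALSE, nb - 1L)), n_chol),
       receptor = receptor_model(model$name, model$atoms, model$helix_map,
                                 rec),
       truth = hotspots)
}

#' Generate a 2D Brownian random walk of a rigid bead cloud
#'
#' Gaussian xy steps with total variance 4 D dt per step (2 D dt per axis)
#' applied rigidly to a small bead cloud; z stays fixed.
#'
#' @param D diffusion coefficient in nm^2/ns (>= 0).
#' @param n_steps number of steps.
#' @param dt time step in ns (default 1, a typical coarse-grained
#'   trajectory output interval).
#' @param n_beads beads in the rigid cloud (default 8).
#' @param seed integer seed.
#' @return list(traj (n_steps+1 x n_beads x 3 array), times (ns),
#'   steps (n_steps x 2 matrix of the applied displacements)).
#' @export
gen_random_walk <- function(D, n_steps, dt = 1, n_beads = 8, seed = 1) {
  stopifnot(D >= 0, n_steps >= 1)
  set.seed(seed)
  cloud <- cbind(stats::runif(n_beads, -0.5, 0.5),
                 stats::runif(n_beads, -0.5, 0.5),
                 stats::runif(n_beads, -0.5, 0.5))
  sd_ax <- sqrt(2 * D * dt)
  steps <- cbind(stats::rnorm(n_steps, 0, sd_ax),
                 stats::rnorm(n_steps, 0, sd_ax))
  pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
  traj <- array(0, c(n_steps + 1L, n_beads, 3))
  for (f in seq_len(n_steps + 1L)) {
    traj[f, , 1] <- cloud[, 1] + pos[f, 1]
    traj[f, , 2] <- cloud[, 2] + pos[f, 2]
    traj[f, , 3] <- cloud[, 3]
  }
  list(traj = traj, times = (0:n_steps) * dt, steps = steps)
}
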