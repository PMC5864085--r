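test_that("generators are byte-identical under a fixed seed", {
  e1 <- gen_energy_ensemble(n_replicas = 5, t_sim = 1, dt = 5, seed = 99)
  e2 <- gen_energy_ensemble(n_replicas = 5, t_sim = 1, dt = 5, seed = 99)
  expect_identical(e1, e2)

  m1 <- gen_angle_mixture(data.frame(beta = 10, chi = 20, weight = 1, sd = 5),
                          50, seed = 4)
  m2 <- gen_angle_mixture(data.frame(beta = 10, chi = 20, weight = 1, sd = 5),
                          50, seed = 4)
  expect_identical(m1, m2)

  w1 <- gen_random_walk(0.02, 100, seed = 12)
  w2 <- gen_random_walk(0.02, 100, seed = 12)
  expect_identical(w1, w2)
})

test_that("zero association rate yields eventless monomeric traces", {
  ens <- gen_energy_ensemble(n_replicas = 10, t_sim = 3, dt = 10, k_on = 0,
                             seed = 2)
  expect_null(ens$truth)
  for (tr in lapply(ens$traces, annotate_events)) {
    expect_equal(nrow(tr$events), 0)
    expect_true(all(tr$state == 0L))
  }
})

test_that("first-passage times follow the censored exponential law", {
  ens <- gen_energy_ensemble(n_replicas = 500, t_sim = 3, dt = 5,
                             k_on = 0.25, p_diss = 0, seed = 55)
  t1 <- ens$truth$time[ens$truth$kind == "dimerization"] / 1000
  # censored-exponential MLE on the ground-truth times recovers k within 3 SE
  d <- length(t1)
  k_hat <- d / (sum(t1) + (500 - d) * 3)
  expect_lt(abs(k_hat - 0.25), 3 * k_hat / sqrt(d))
  # mean of observed (censored) times matches the truncated expectation
  expected_mean <- (1 / 0.25) - 3 * exp(-0.25 * 3) / (1 - exp(-0.25 * 3))
  expect_equal(mean(t1), expected_mean, tolerance = 0.1)
})

test_that("traces are consistent with their ground-truth event log", {
  # The detector sees the state only at output frames, so event pairs that
  # open and close within one interval are invisible by construction. The
  # reference is therefore the frame-sampled state derived from the truth
  # log alone (independent of the energies the detector consumes).
  ens <- gen_energy_ensemble(n_replicas = 30, t_sim = 2, dt = 2, k_on = 1,
                             p_diss = 0.5, tau_dimer = 0.2, seed = 8)
  for (tr in ens$traces) {
    truth <- ens$truth[ens$truth$replica_id == tr$replica_id, ]
    ref_state <- as.integer(findInterval(tr$times, truth$time) %% 2 == 1)
    ann <- annotate_events(tr)
    expect_identical(ann$state, ref_state)
    ch <- which(diff(ref_state) != 0L) + 1L
    expect_equal(ann$events$time, tr$times[ch])
    expect_equal(ann$events$kind,
                 as.character(ifelse(ref_state[ch] == 1L, "dimerization",
                                     "dissociation")))
  }
})

test_that("angle mixtures respect weights and wrap at the seam", {
  modes <- data.frame(beta = c(100, 300), chi = c(50, 250),
                      weight = c(0.6, 0.4), sd = 5)
  s <- gen_angle_mixture(modes, 1000, seed = 6)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.6) / 1000
  frac1 <- mean(s$label == 1)
  expect_gte(frac1, ci[1])
  expect_lte(frac1, ci[2])
  expect_true(all(s$beta >= 0 & s$beta < 360))

  # sd -> 0 collapses onto the mode
  s0 <- gen_angle_mixture(data.frame(beta = 42, chi = 84, weight = 1,
                                     sd = 1e-9), 20, seed = 1)
  expect_equal(s0$beta, rep(42, 20), tolerance = 1e-6)

  # a mode at the origin straddles 0/360
  sw <- gen_angle_mixture(data.frame(beta = 0, chi = 0, weight = 1, sd = 5),
                          500, seed = 2)
  expect_true(any(sw$beta > 350) && any(sw$beta < 10))

  expect_error(gen_angle_mixture(data.frame(beta = 0, chi = 0, weight = 1,
                                            sd = 0), 10), "sd")
  expect_error(gen_angle_mixture(data.frame(beta = 0, chi = 0, weight = 0.5,
                                            sd = 5), 10), "weights")
})

test_that("cholesterol fields realize hotspot probabilities", {
  b <- gen_bundle()
  # p = 1 hotspot is occupied every frame
  cf1 <- gen_chol_field(b, hotspots = data.frame(resid = 7, p = 1),
                        n_chol = 6, n_frames = 50, seed = 14)
  prof1 <- residue_occupancy(cf1$frames, cf1$receptor,
                             contact_params(equilibration_discard = 0))
  expect_equal(prof1$occupancy[prof1$resid == 7], 1)

  # p = 0.5 recovered within the binomial 99% CI (uniform background can
  # only add a small number of extra contacts)
  cf2 <- gen_chol_field(b, hotspots = data.frame(resid = 7, p = 0.5),
                        n_chol = 10, n_frames = 400, seed = 15)
  prof2 <- residue_occupancy(cf2$frames, cf2$receptor,
                             contact_params(equilibration_discard = 0))
  occ <- prof2$occupancy[prof2$resid == 7]
  ci <- qbinom(c(0.005, 0.995), 400, 0.5) / 400
  expect_gte(occ, ci[1])
  expect_lte(occ, ci[2] + 0.05)

  # no hotspots: only the uniform background collision rate remains
  cf0 <- gen_chol_field(b, hotspots = NULL, n_chol = 10, n_frames = 100,
                        seed = 16)
  prof0 <- residue_occupancy(cf0$frames, cf0$receptor,
                             contact_params(equilibration_discard = 0))
  expect_lt(max(prof0$occupancy), 0.25)
  expect_lt(mean(prof0$occupancy), 0.05)

  expect_error(gen_chol_field(b, hotspots = data.frame(resid = 9999, p = 1)),
               "absent")
  expect_error(gen_chol_field(b, hotspots = data.frame(resid = 1:3, p = 1),
                              n_chol = 2), "more simultaneous hotspots")
})

test_that("random-walk steps carry the stated variance", {
  w <- gen_random_walk(0.05, 5000, dt = 2, seed = 77)
  # per-axis variance 2 D dt; total squared step 4 D dt
  expect_equal(mean(rowSums(w$steps^2)), 4 * 0.05 * 2, tolerance = 0.1)
  # sample variance within 3 SE of the nominal per-axis variance
  v <- 2 * 0.05 * 2
  expect_lt(abs(var(w$steps[, 1]) - v), 3 * v * sqrt(2 / 5000))
  # D = 0 keeps the cloud stationary
  w0 <- gen_random_walk(0, 50, seed = 1)
  expect_equal(w0$traj[1, , ], w0$traj[51, , ])
})

test_that("written ensembles read back through the manifest path", {
  ens <- gen_energy_ensemble(n_replicas = 4, t_sim = 1, dt = 10, k_on = 1,
                             seed = 3)
  dir <- withr::local_tempdir()
  path <- write_ensemble(ens, dir, cholesterol_fraction = 0.3)
  m <- suppressWarnings(read_manifest(path))   # gro files are not written
  expect_equal(m$n_replicas, 4)
  tr <- read_energy_xvg(file.path(dir, m$replicas$energy[1]),
                        m$replicas$replica_id[1])
  expect_equal(tr$times, ens$traces[[1]]$times)
  expect_equal(tr$energies, ens$traces[[1]]$energies, tolerance = 1e-4)
})
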