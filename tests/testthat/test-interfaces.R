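test_that("height-field handles point masses and torus wrap", {
  hf1 <- kde_heightfield(rep(100, 20), rep(250, 20))
  expect_equal(sum(hf1$grid), 1, tolerance = 1e-9)
  expect_equal(nrow(hf1$maxima), 1)
  expect_lt(circ_dist(hf1$maxima$beta, 100), 1)
  expect_lt(circ_dist(hf1$maxima$chi, 250), 1)

  # samples straddling the seam collapse to one maximum at (0, 0)
  hf2 <- kde_heightfield(c(rep(359, 10), rep(1, 10)),
                         c(rep(359, 10), rep(1, 10)))
  expect_equal(nrow(hf2$maxima), 1)
  expect_lt(circ_dist(hf2$maxima$beta, 0), 1.5)
  expect_lt(circ_dist(hf2$maxima$chi, 0), 1.5)
})

test_that("two well-separated modes give two maxima near the truth", {
  s <- gen_angle_mixture(data.frame(beta = c(40, 220), chi = c(200, 60),
                                    weight = c(0.5, 0.5), sd = 8),
                         n = 400, seed = 21)
  hf <- kde_heightfield(s$beta, s$chi)
  expect_equal(nrow(hf$maxima), 2)
  ord <- order(hf$maxima$beta)
  expect_lt(circ_dist(hf$maxima$beta[ord][1], 40), 5)
  expect_lt(circ_dist(hf$maxima$chi[ord][1], 200), 5)
  expect_lt(circ_dist(hf$maxima$beta[ord][2], 220), 5)
  expect_lt(circ_dist(hf$maxima$chi[ord][2], 60), 5)
})

test_that("watershed segments the torus into one basin per retained maximum", {
  # single mode: one basin covering everything
  hf1 <- watershed_basins(kde_heightfield(rep(100, 30), rep(250, 30)))
  expect_equal(nrow(hf1$basins), 1)
  expect_true(all(hf1$basin_map == 1L))

  # uniform field: a single catch-all basin, flagged degenerate
  hfu <- kde_heightfield(1, 1)
  hfu$grid <- matrix(1 / 360^2, 360, 360)
  hfu <- watershed_basins(hfu)
  expect_true(hfu$degenerate)
  expect_equal(nrow(hfu$basins), 1)

  # two modes: two basins, and >= 95% of samples return to their source
  s <- gen_angle_mixture(data.frame(beta = c(40, 220), chi = c(200, 60),
                                    weight = c(0.5, 0.5), sd = 8),
                         n = 400, seed = 22)
  hf2 <- watershed_basins(kde_heightfield(s$beta, s$chi))
  expect_equal(nrow(hf2$basins), 2)
  ids <- assign_basins(hf2, s$beta, s$chi)
  # map generator labels onto basin ids via the dominant pairing
  tab <- table(s$label, ids)
  acc <- sum(apply(tab, 1, max)) / length(ids)
  expect_gte(acc, 0.95)
})

test_that("classification accuracy holds across seeds for separated modes", {
  accs <- vapply(1:10, function(s) {
    sm <- gen_angle_mixture(data.frame(beta = c(300, 80), chi = c(120, 330),
                                       weight = c(0.6, 0.4), sd = 8),
                            n = 400, seed = 400 + s)
    hf <- watershed_basins(kde_heightfield(sm$beta, sm$chi))
    ids <- assign_basins(hf, sm$beta, sm$chi)
    tab <- table(sm$label, ids)
    sum(apply(tab, 1, max)) / length(ids)
  }, 0)
  expect_true(all(accs >= 0.95))
})

test_that("basin segmentation is deterministic", {
  s <- gen_angle_mixture(data.frame(beta = c(40, 220), chi = c(200, 60),
                                    weight = c(0.5, 0.5), sd = 8),
                         n = 200, seed = 23)
  h1 <- watershed_basins(kde_heightfield(s$beta, s$chi))
  h2 <- watershed_basins(kde_heightfield(s$beta, s$chi))
  expect_identical(h1$basin_map, h2$basin_map)
  expect_identical(h1$basins, h2$basins)
})

test_that("per-replica assignment recovers generating populations", {
  set.seed(31)
  n_rep <- 120
  lab <- rep(1:2, c(72, 48))                     # 60/40 split
  modes <- data.frame(beta = c(40, 220), chi = c(200, 60))
  samples <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    m <- modes[lab[r], ]
    data.frame(replica_id = sprintf("r%03d", r),
               time = seq(2951, 3000),
               beta = wrap360(rnorm(50, m$beta, 8)),
               chi = wrap360(rnorm(50, m$chi, 8)))
  }))
  hf <- watershed_basins(kde_heightfield(samples$beta, samples$chi))
  pops <- assign_and_count(hf, samples)
  expect_equal(sum(pops$fraction), 1)
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.6) / n_rep
  expect_gte(pops$fraction[1], ci[1])
  expect_lte(pops$fraction[1], ci[2])

  # all replicas in one mode -> population 1
  one <- samples[samples$replica_id %in% sprintf("r%03d", 1:5), ]
  hf1 <- watershed_basins(kde_heightfield(one$beta, one$chi))
  p1 <- assign_and_count(hf1, one)
  expect_equal(p1$fraction[1], 1.0)
})

test_that("replicas with dimers shorter than the window are excluded", {
  s <- data.frame(replica_id = rep(c("a", "b"), each = 60),
                  time = rep(seq(2941, 3000), 2),
                  beta = 100, chi = 250)
  # replica b dimerized only 10 ns before the end
  expect_warning(
    out <- last_window_samples(s, window = 50,
                               dimer_since = c(a = 2000, b = 2990)),
    "excluded")
  expect_equal(unique(out$replica_id), "a")
  expect_true(all(out$time > 2950))
})

test_that("basin labels name the helices at both binding azimuths", {
  b <- gen_bundle(h8 = TRUE)
  hm <- helix_angular_map(b$model)
  az <- b$truth$azimuths

  # maximum inside TM1 on A and TM4 on B
  lab <- label_basin(az[1], az[4], hm, hm, half_width = 5)
  expect_equal(as.character(lab), "TM1/TM4")

  # a maximum between TM1 and H8 yields the composite label
  az_h8 <- b$truth$h8_azimuth
  mid <- wrap360(az[1] + ang_diff(az_h8, az[1]) / 2)
  lab2 <- label_basin(mid, az[4], hm, hm, half_width = 30)
  expect_match(as.character(lab2), "^TM1,H8/")

  # consecutive helices compact into a range label
  between <- wrap360((az[5] + az[6]) / 2)
  lab3 <- label_basin(between, az[2], hm, hm, half_width = 30)
  expect_match(as.character(lab3), "^TM5-7|^TM5,6")

  # construction recovery for random maxima placed inside known intervals
  set.seed(8)
  for (i in 1:20) {
    h <- sample(7, 2)
    la <- label_basin(az[h[1]], az[h[2]], hm, hm, half_width = 5)
    expect_equal(as.character(la), sprintf("TM%d/TM%d", h[1], h[2]))
  }

  # unexposed azimuth falls back to the nearest exposed helix, flagged
  gap_az <- wrap360(az[1] + 25.7)     # between TM1 and TM2 intervals
  lab4 <- label_basin(gap_az, az[4], hm, hm, half_width = 1)
  expect_true(attr(lab4, "flagged"))
})

test_that("representative picks prefer compact interfaces near the maximum", {
  # single member
  one <- data.frame(replica_id = "a", beta = 10, chi = 20, energy = -80)
  expect_equal(select_representative(one, c(0, 0))$replica_id, "a")

  # equidistant members: lowest energy wins
  two <- data.frame(replica_id = c("a", "b"), beta = c(5, 355),
                    chi = c(0, 0), energy = c(-80, -200))
  expect_equal(select_representative(two, c(0, 0))$replica_id, "b")

  # planted best member among 100: closest decile + strongest energy
  set.seed(9)
  mem <- data.frame(replica_id = sprintf("m%03d", 1:100),
                    beta = wrap360(rnorm(100, 50, 6)),
                    chi = wrap360(rnorm(100, 200, 6)),
                    energy = runif(100, -150, -60))
  mem$beta[7] <- 50.4; mem$chi[7] <- 200.3; mem$energy[7] <- -300
  pick <- select_representative(mem, c(50, 200))
  expect_equal(pick$replica_id, "m007")
})
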