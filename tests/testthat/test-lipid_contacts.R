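test_that("occupancy follows the inclusive contact rule frame by frame", {
  b <- gen_bundle()
  box <- c(12, 12, 10)
  centre <- box / 2
  rec <- sweep(b$coords, 2, centre - colMeans(b$coords), "+")
  model <- receptor_model(b$model$name, b$atoms, b$model$helix_map, rec)
  anchor <- rec[model$backbone_bead_index[["10"]], ]

  far <- matrix(rep(c(1, 1, 1), 8), ncol = 3, byrow = TRUE) +
    0.3 * cbind(seq_len(8), 0, 0)
  near <- matrix(rep(anchor, 8), ncol = 3, byrow = TRUE)
  near[, 1] <- near[, 1] + 0.50 + 0.3 * (seq_len(8) - 1)

  mk <- function(chol, t) list(time = t, receptor_coords = rec,
                               chol_coords = chol, box = box)
  frames <- c(lapply(1:50, function(t) mk(near, 200 + t)),
              lapply(1:50, function(t) mk(far, 250 + t)))
  prof <- residue_occupancy(frames, model,
                            contact_params(equilibration_discard = 200))
  expect_equal(prof$occupancy[prof$resid == 10], 0.5)

  # exactly at the cutoff counts as bound (inclusive boundary); shift the
  # system so the probed bead sits at the origin and the distance is an
  # exactly representable 0.62
  rec0 <- sweep(rec, 2, anchor)
  model0 <- receptor_model(b$model$name, b$atoms, b$model$helix_map, rec0)
  at <- cbind(0.62 + 0.3 * (seq_len(8) - 1), 0, 0)
  mk0 <- function(chol) list(time = 300, receptor_coords = rec0,
                             chol_coords = chol, box = box)
  prof2 <- residue_occupancy(list(mk0(at)), model0,
                             contact_params(equilibration_discard = 0))
  expect_equal(prof2$occupancy[prof2$resid == 10], 1)
  just_out <- cbind(0.6201 + 0.3 * (seq_len(8) - 1), 0, 0)
  prof3 <- residue_occupancy(list(mk0(just_out)), model0,
                             contact_params(equilibration_discard = 0))
  expect_equal(prof3$occupancy[prof3$resid == 10], 0)
})

test_that("occupancy equals the brute-force all-pairs oracle exactly", {
  b <- gen_bundle()
  cf <- gen_chol_field(b, hotspots = data.frame(resid = c(5, 33), p = c(0.8, 0.4)),
                       n_chol = 25, n_frames = 200, seed = 77)
  params <- contact_params(equilibration_discard = 0)
  prof <- residue_occupancy(cf$frames, cf$receptor, params)
  oracle <- brute_occupancy(cf$frames, cf$receptor, params$cutoff)
  expect_identical(prof$occupancy, oracle)

  # planted hotspot probabilities recovered within the binomial 99% CI
  for (i in seq_len(nrow(cf$truth))) {
    p <- cf$truth$p[i]
    ci <- qbinom(c(0.005, 0.995), 200, p) / 200
    occ <- prof$occupancy[prof$resid == cf$truth$resid[i]]
    # uniform background cholesterol can only add contacts
    expect_gte(occ, ci[1])
    expect_lte(occ, ci[2] + 0.05)
  }
})

test_that("occupancy is monotone in the cutoff and frame-order invariant", {
  b <- gen_bundle()
  cf <- gen_chol_field(b, hotspots = data.frame(resid = 12, p = 0.5),
                       n_chol = 10, n_frames = 60, seed = 5)
  occ <- lapply(c(0.4, 0.62, 0.9, 1.5), function(ct)
    residue_occupancy(cf$frames, cf$receptor,
                      contact_params(cutoff = ct,
                                     equilibration_discard = 0))$occupancy)
  for (i in seq_along(occ)[-1]) expect_true(all(occ[[i]] >= occ[[i - 1]]))

  set.seed(1)
  shuffled <- cf$frames[sample(length(cf$frames))]
  p1 <- residue_occupancy(cf$frames, cf$receptor,
                          contact_params(equilibration_discard = 0))
  p2 <- residue_occupancy(shuffled, cf$receptor,
                          contact_params(equilibration_discard = 0))
  expect_identical(p1$occupancy, p2$occupancy)
})

test_that("nearest-N density bookkeeping and hotspot localization", {
  b <- gen_bundle()
  cf <- gen_chol_field(b, hotspots = NULL, n_chol = 8, n_frames = 20, seed = 2)
  params <- contact_params(n_nearest = 5, equilibration_discard = 0,
                           grid_spacing = 0.2)
  dens <- nearest_n_density(cf$frames, cf$receptor, cf$chol_mol,
                            cf$headgroup, params, margin = 8)
  # integral identity: frames x n_nearest x 8 beads before normalization
  expect_equal(unname(dens$counts["all"] + dens$counts["dropped"]),
               20 * 5 * 8)
  expect_equal(sum(dens$all) * dens$n_frames + dens$counts["dropped"],
               20 * 5 * 8, ignore_attr = TRUE)
  expect_equal(unname(dens$counts["headgroup"] <= dens$counts["all"]), TRUE)

  # a single rigid cholesterol concentrates all density in its voxels
  one <- gen_chol_field(b, hotspots = data.frame(resid = 1, p = 1),
                        n_chol = 1, n_frames = 10, seed = 3)
  d1 <- nearest_n_density(one$frames, one$receptor, one$chol_mol,
                          one$headgroup,
                          contact_params(n_nearest = 1,
                                         equilibration_discard = 0),
                          margin = 5)
  expect_lte(sum(d1$all > 0), 8)     # at most one voxel per bead

  # planted hotspot: headgroup density maximum lands near the contact shell
  for (s in 1:5) {
    hs <- gen_chol_field(b, hotspots = data.frame(resid = 25, p = 0.8),
                         n_chol = 12, n_frames = 60, seed = 30 + s)
    dh <- nearest_n_density(hs$frames, hs$receptor, hs$chol_mol,
                            hs$headgroup,
                            contact_params(equilibration_discard = 0),
                            margin = 6)
    peak <- which(dh$headgroup == max(dh$headgroup), arr.ind = TRUE)[1, ]
    peak_nm <- dh$origin + (peak - 0.5) * dh$spacing
    anchor <- hs$receptor$reference_coords[
      hs$receptor$backbone_bead_index[["25"]], ]
    expect_lt(sqrt(sum((peak_nm - anchor)^2)), 0.62 + 0.2)
  }
})

test_that("occupancy reports rank residues and flag external highlights", {
  prof <- structure(data.frame(resid = c(52, 150, 60),
                               resname = c("ILE", "VAL", "ALA"),
                               helix = c("TM1", "TM4", "TM2"),
                               occupancy = c(0.9, 0.6, 0.1)),
                    class = c("occupancy_profile", "data.frame"),
                    n_frames = 100L)
  rep1 <- occupancy_report(prof, highlight = c(52, 9999))
  expect_equal(rep1$data$resid[1], 52)
  expect_true(rep1$data$highlight[1])
  expect_true("not in model" %in% rep1$data$resname)

  rep2 <- occupancy_report(prof)
  expect_false("highlight" %in% names(rep2$data))
})
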