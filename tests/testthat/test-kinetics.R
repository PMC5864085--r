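test_that("two-threshold event detection applies hysteresis", {
  cases <- list(
    # energies, expected kinds, expected final state
    list(e = c(0, -20, -60, -120), kinds = "dimerization", final = 1L),
    list(e = c(0, -60, -30, -0.5, -70),
         kinds = c("dimerization", "dissociation", "dimerization"), final = 1L),
    list(e = c(-0.9, -0.5, -1, -0.2), kinds = character(), final = 0L)
  )
  for (cs in cases) {
    tr <- annotate_events(toy_trace(cs$e))
    expect_equal(tr$events$kind, cs$kinds)
    expect_equal(tr$state[length(tr$state)], cs$final)
  }
  # event times land on the crossing frames
  tr <- annotate_events(toy_trace(c(0, -60, -30, -0.5, -70)))
  expect_equal(tr$events$time, c(100, 300, 400))
  # a first frame below e_on is a dimer from t=0 with no event
  tr0 <- annotate_events(toy_trace(c(-80, -70)))
  expect_true(tr0$left_censored)
  expect_equal(nrow(tr0$events), 0L)
  expect_equal(tr0$state, c(1L, 1L))
})

test_that("dimerization and dissociation events strictly alternate", {
  ens <- gen_energy_ensemble(n_replicas = 40, t_sim = 2, dt = 2,
                             k_on = 1, p_diss = 0.6, tau_dimer = 0.1,
                             seed = 11)
  for (tr in lapply(ens$traces, annotate_events)) {
    k <- tr$events$kind
    if (length(k) > 1) expect_true(all(k[-1] != k[-length(k)]))
    if (length(k) >= 1 && !tr$left_censored)
      expect_equal(k[1], "dimerization")
  }
})

test_that("tightening the dimerization criterion never increases event counts", {
  ens <- gen_energy_ensemble(n_replicas = 50, t_sim = 2, dt = 2,
                             k_on = 0.8, p_diss = 0.4, mean_dimer_energy = -130,
                             energy_sd = 25, seed = 7)
  counts <- vapply(c(-50, -100, -150, -200), function(level) {
    th <- event_thresholds(e_on = level, scan_levels = level)
    sum(vapply(ens$traces, function(tr)
      sum(annotate_events(tr, th)$events$kind == "dimerization"), 0))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("rate fitting inverts exact exponential decay", {
  t <- seq(0.5, 15, length.out = 30)
  expect_equal(fit_rate_from_survival(t, exp(-0.2 * t)), 0.2,
               tolerance = 1e-9)
})

test_that("rate recovery on censored-exponential ensembles", {
  # per-seed estimates stay within 3 standard errors of the truth; the
  # pooled estimate across seeds recovers the rate within a few percent.
  # (With ~70 events at k = 0.05 the per-seed sampling SE is ~12%, so a
  # fixed per-seed percentage bound would not be a statistically valid
  # property there.)
  for (k_true in c(0.05, 0.25)) {
    fits <- lapply(1:5, function(s) {
      ens <- gen_energy_ensemble(n_replicas = 500, t_sim = 3, dt = 5,
                                 k_on = k_true, p_diss = 0, seed = 100 + s)
      ann <- lapply(ens$traces, annotate_events)
      fit_first_order_rate(first_dimerization_table(ann))
    })
    for (fit in fits) {
      expect_lt(abs(fit$k_mle - k_true), 3 * fit$se)
      # the survival-curve fit tracks the closed-form MLE
      if (k_true == 0.25)
        expect_lt(abs(fit$k - fit$k_mle) / fit$k_mle, 0.10)
    }
    pooled <- mean(vapply(fits, `[[`, 0, "k_mle"))
    expect_lt(abs(pooled - k_true) / k_true, 0.15)
  }
})

test_that("degenerate rate fits are flagged", {
  expect_warning(f0 <- fit_first_order_rate(rep(NA_real_, 10), horizon = 3000),
                 "degenerate")
  expect_equal(f0$k, 0)
  expect_warning(fit_first_order_rate(rep(1, 10), horizon = 3000),
                 "resolution limit")
})

test_that("dimerization propensity follows the final-dimer count", {
  expect_equal(dimerization_propensity(251, 501, 3), 251 / 501 / 3)
  expect_equal(round(dimerization_propensity(251, 501, 3), 3), 0.167)
  expect_equal(dimerization_propensity(0, 500, 3), 0)
  expect_equal(dimerization_propensity(500, 500, 8), 0.125)
  expect_error(dimerization_propensity(501, 500, 3), "exceeds")
  # non-normalized variant
  expect_equal(dimerization_propensity(251, 501, 3, per_replica = FALSE),
               251 / 3)
})

test_that("dissociation propensity recovers the generator's probability", {
  tr1 <- annotate_events(toy_trace(c(0, -60, -0.5, -70, -0.4, -80)))
  tr2 <- annotate_events(toy_trace(c(0, -60, -70, -80, -90, -95)))
  expect_equal(dissociation_propensity(list(tr1, tr2)), 2 / 4)

  ens <- gen_energy_ensemble(n_replicas = 400, t_sim = 3, dt = 2, k_on = 2,
                             p_diss = 0.2, tau_dimer = 0.2, seed = 5)
  ann <- lapply(ens$traces, annotate_events)
  prop <- dissociation_propensity(ann)
  n_dim <- sum(vapply(ann, function(tr)
    sum(tr$events$kind == "dimerization"), 0))
  ci <- qbinom(c(0.005, 0.995), n_dim, 0.2) / n_dim
  expect_gte(prop, ci[1])
  expect_lte(prop, ci[2])

  # a criterion no trace reaches yields no events and a missing value
  th <- event_thresholds(e_on = -2000, scan_levels = -2000)
  ann2 <- lapply(ens$traces[1:20], annotate_events, thresholds = th)
  expect_true(is.na(dissociation_propensity(ann2)))
})

test_that("P0/P1 counts only post-dissociation monomer time", {
  # dimer 1-2 us, dissociation at 2 us, monomeric to 3 us -> ratio 1
  t_ns <- seq(0, 3000, by = 10)
  e <- ifelse(t_ns < 1000, -0.5, ifelse(t_ns < 2000, -80, -0.5))
  tr <- annotate_events(energy_trace(t_ns, e, "p"))
  pp <- accumulate_P0_P1(list(tr))
  expect_equal(pp$ratio, 1.0, tolerance = 0.02)

  # a replica that never dissociates contributes P1 only
  e2 <- ifelse(t_ns < 1000, -0.5, -80)
  tr2 <- annotate_events(energy_trace(t_ns, e2, "q"))
  pp2 <- accumulate_P0_P1(list(tr2))
  expect_equal(pp2$P0, 0)
  expect_gt(pp2$P1, 0)

  # stationary occupancy 95% after first binding -> P0/P1 near 1/19
  ens <- gen_energy_ensemble(n_replicas = 300, t_sim = 3, dt = 2, k_on = 2,
                             p_diss = 1, occupancy = 0.95, tau_dimer = 0.2,
                             seed = 3)
  ann <- lapply(ens$traces, annotate_events)
  pp3 <- accumulate_P0_P1(ann)
  expect_equal(pp3$ratio, 0.95^-1 - 1, tolerance = 0.15)
})

test_that("binding free energy closed form and its standard state", {
  # K_D = c0 by construction -> dG exactly 0
  V <- 484
  r0 <- 6.02214076e23 * V * 1e-24
  expect_identical(lower_bound_binding_free_energy(r0, V, 310)$dG, 0)

  fe <- lower_bound_binding_free_energy(0.05, 484, 310)
  expect_equal(fe$K_D, 1.715e-4, tolerance = 3e-4)
  expect_equal(fe$dG, -22.35, tolerance = 0.005)

  # published lower-bound value inverts to ~6.3e-5 M at 310 K
  expect_equal(kd_from_dg(-24.95, 310), 6.3e-5, tolerance = 0.01)

  # never-dissociated sentinel
  fe0 <- lower_bound_binding_free_energy(0, 484, 310)
  expect_equal(fe0$dG, -Inf)
  expect_equal(fe0$status, "unbound-never-observed")

  # monotone increasing in P0/P1
  r <- c(0.01, 0.05, 0.2, 1, 5)
  dg <- vapply(r, function(x)
    lower_bound_binding_free_energy(x, V, 310)$dG, 0)
  expect_true(all(diff(dg) > 0))
})

test_that("ensemble kinetics summary assembles a coherent table", {
  ens <- gen_energy_ensemble(n_replicas = 60, t_sim = 2, dt = 2, k_on = 1,
                             p_diss = 0.3, seed = 9)
  kin <- ensemble_kinetics(ens$traces, V = slab_volume(c(11, 11)))
  expect_s3_class(kin, "dimer_kinetics")
  expect_true(kin$n_dimers_final <= kin$n_replicas)
  expect_gte(kin$dissociation_propensity, 0)
  tab <- summary(kin)
  expect_s3_class(tab, "result_table")
  expect_equal(tab$data$k, kin$k$k)
  # threshold scan: tighter criteria give fewer dimerizations
  kin2 <- ensemble_kinetics(ens$traces, V = slab_volume(c(11, 11)), scan = TRUE)
  expect_true(all(diff(kin2$scan$n_dimerizations) <= 0))
})
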