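# Event detection and association kinetics.
#
# Two receptors count as a dimer once the TM-TM interaction energy (sum of
# Lennard-Jones and Coulomb terms) drops below e_on = -50 kJ/mol; an existing
# dimer dissociates only when the energy rises above e_off = -1 kJ/mol.
# Energies in between leave the current state unchanged (Schmitt-trigger
# hysteresis), which is the only reading under which entry and exit
# thresholds produce a well-defined state sequence.

PHYS <- list(N_AVOGADRO = 6.02214076e23,     # 1/mol
             R_GAS = 8.31446261815324e-3)    # kJ/(mol K)

#' Event detection thresholds
#'
#' @param e_on dimerization threshold in kJ/mol (default -50): a monomeric
#'   pair becomes a dimer when the energy first drops below this value.
#' @param e_off dissociation threshold in kJ/mol (default -1): a dimer ends
#'   when the energy rises above this value.
#' @param scan_levels alternative, tighter dimerization criteria (kJ/mol)
#'   used for threshold scans of dissociation propensity and binding free
#'   energy.
#' @return an `event_thresholds` object.
#' @export
event_thresholds <- function(e_on = -50, e_off = -1,
                             scan_levels = c(-50, -100, -150, -200)) {
  if (!(e_on < e_off && e_off <= 0))
    stop("thresholds must satisfy e_on < e_off <= 0")
  if (any(scan_levels > e_on))
    stop("scan levels must be at or below e_on")
  structure(list(e_on = e_on, e_off = e_off, scan_levels = scan_levels),
            class = "event_thresholds")
}

#' Annotate dimerization/dissociation events on an energy trace
#'
#' Applies the two-threshold criterion with hysteresis. The system starts
#' monomeric unless the very first frame is already below `e_on`, in which
#' case it is a dimer from t = 0 with no recorded dimerization event
#' (left-censored; flagged via `left_censored`).
#'
#' @param trace an `energy_trace`.
#' @param thresholds an [event_thresholds()] object.
#' @return the trace with `state` (integer, 0 = monomer, 1 = dimer per
#'   frame), `events` (data.frame: time, kind) and `left_censored` set.
#' @export
annotate_events <- function(trace, thresholds = event_thresholds()) {
  stopifnot(inherits(trace, "energy_trace"))
  e <- trace$energies
  trig <- rep(NA_integer_, length(e))
  trig[e < thresholds$e_on] <- 1L
  trig[e > thresholds$e_off] <- 0L
  # last-observation-carried-forward with initial monomer state
  known <- !is.na(trig)
  idx <- cumsum(known)
  vals <- c(0L, trig[known])
  state <- vals[idx + 1L]

  ch <- which(diff(state) != 0L) + 1L
  events <- data.frame(time = trace$times[ch],
                       kind = as.character(ifelse(state[ch] == 1L,
                                                  "dimerization",
                                                  "dissociation")),
                       stringsAsFactors = FALSE)
  left_censored <- state[1L] == 1L
  if (left_censored && nrow(events) && events$kind[1L] == "dimerization")
    stop("internal: left-censored trace cannot open with a dimerization")
  trace$state <- state
  trace$events <- events
  trace$left_censored <- left_censored
  trace$thresholds <- thresholds
  trace
}

# First-dimerization time of an annotated trace; NA when censored at the
# horizon (never dimerized) or left-censored (dimer from frame one).
first_dimerization <- function(trace) {
  ev <- trace$events
  t_dim <- ev$time[ev$kind == "dimerization"]
  if (length(t_dim)) t_dim[1L] else NA_real_
}

#' First-dimerization event table of an annotated ensemble
#'
#' @param traces list of annotated `energy_trace` objects.
#' @return data.frame with `replica_id`, `time` (ns; NA if no dimerization
#'   was observed), `censored`, `left_censored` and `horizon` (ns).
#' @export
first_dimerization_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    t1 <- first_dimerization(tr)
    data.frame(replica_id = tr$replica_id,
               time = t1,
               censored = is.na(t1) && !isTRUE(tr$left_censored),
               left_censored = isTRUE(tr$left_censored),
               horizon = tr$times[length(tr$times)],
               stringsAsFactors = FALSE)
  }))
}

#' Fit a first-order dimerization rate from first-passage times
#'
#' Builds the surviving-monomer fraction f(t) over the replica ensemble and
#' fits f(t) = exp(-k t) by weighted least squares on ln f(t) (weights equal
#' to the number of still-monomeric replicas). The censored-exponential
#' maximum-likelihood estimate k = d / (sum of event times + sum of censoring
#' horizons) is computed alongside as a cross-check; its standard error is
#' k / sqrt(d). Left-censored replicas (dimeric from the first frame) are
#' excluded from the fit.
#'
#' @param events data.frame from [first_dimerization_table()], or a numeric
#'   vector of first-dimerization times with NA for censored replicas (then
#'   `horizon` must be given).
#' @param horizon censoring horizon in ns (required for vector input).
#' @param unit time unit of the reported rate: `"us"` (rate per microsecond,
#'   default; equals 1e6/s) or `"ns"`.
#' @return a `rate_fit` object: k (WLS estimate), k_mle, se, n, n_events,
#'   flags.
#' @export
fit_first_order_rate <- function(events, horizon = NULL, unit = c("us", "ns")) {
  unit <- match.arg(unit)
  if (is.data.frame(events)) {
    events <- events[!events$left_censored, , drop = FALSE]
    times <- events$time
    horizons <- events$horizon
  } else {
    if (is.null(horizon)) stop("horizon required with vector input")
    times <- as.numeric(events)
    horizons <- rep(horizon, length(times))
  }
  n <- length(times)
  if (!n) stop("no replicas to fit")
  if (any(horizons <= 0)) stop("censoring horizon must be > 0")
  obs <- !is.na(times)
  d <- sum(obs)
  flags <- character()

  scale <- if (unit == "us") 1000 else 1   # internal times are ns

  if (d == 0L) {
    warning("no dimerization events: degenerate fit, k = 0")
    out <- list(k = 0, k_mle = 0, se = NA_real_, n = n, n_events = 0L,
                unit = unit, flags = "no-events")
    class(out) <- "rate_fit"
    return(out)
  }

  k_mle <- d / (sum(times[obs]) + sum(horizons[!obs]))

  # surviving fraction at each observed event time
  ts <- sort(times[obs])
  surv <- (n - seq_along(ts)) / n
  keep <- surv > 0
  tt <- c(0, ts[keep])
  ff <- c(1, surv[keep])
  w <- ff * n                      # number still at risk
  if (length(tt) >= 2L) {
    k_wls <- -sum(w * tt * log(ff)) / sum(w * tt^2)
  } else {
    k_wls <- k_mle
    flags <- c(flags, "single-event")
  }

  dt_min <- min(ts[ts > 0], Inf)
  if (all(times[obs] <= dt_min) && d == n) {
    flags <- c(flags, "rate at resolution limit")
    warning("all replicas dimerized within the first output interval; ",
            "rate at resolution limit")
  }

  out <- list(k = k_wls * scale, k_mle = k_mle * scale,
              se = k_mle / sqrt(d) * scale,
              n = n, n_events = d, unit = unit, flags = flags)
  class(out) <- "rate_fit"
  out
}

#' Fit an exponential decay rate to a surviving-monomer curve
#'
#' Weighted least squares on ln f(t) through the origin:
#' k = -sum(w t ln f) / sum(w t^2), restricted to points with f(t) > 0.
#' Exact data f(t) = exp(-k t) is recovered to machine precision.
#'
#' @param times time points (any consistent unit; the rate comes back in its
#'   inverse).
#' @param fraction surviving monomer fraction at `times`, in (0, 1].
#' @param weights optional fit weights (default: proportional to `fraction`,
#'   the number still at risk).
#' @return rate k.
#' @export
fit_rate_from_survival <- function(times, fraction, weights = NULL) {
  keep <- fraction > 0 & times >= 0
  t <- times[keep]; f <- fraction[keep]
  if (length(t) < 2L) stop("need at least two usable points")
  if (is.null(weights)) weights <- f else weights <- weights[keep]
  -sum(weights * t * log(f)) / sum(weights * t^2)
}

#' @export
print.rate_fit <- function(x, ...) {
  u <- if (x$unit == "us") "1/us" else "1/ns"
  cat(sprintf("First-order rate fit: k = %.4g %s (WLS), k = %.4g +- %.2g %s (MLE)\n",
              x$k, u, x$k_mle, x$se, u))
  cat(sprintf("  %d events in %d replicas%s\n", x$n_events, x$n,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Dimerization propensity
#'
#' Relative number of dimers formed per microsecond: the final number of
#' dimers divided by the number of replicas (per-replica normalization,
#' configurable) and by the simulation time in microseconds.
#'
#' @param n_dimers_final dimers present at the end of the ensemble.
#' @param n_replicas replica count.
#' @param t_sim simulation length per replica (microseconds).
#' @param per_replica divide by the replica count (default TRUE).
#' @return propensity in 1/us.
#' @export
dimerization_propensity <- function(n_dimers_final, n_replicas, t_sim,
                                    per_replica = TRUE) {
  if (t_sim <= 0) stop("t_sim must be > 0")
  if (n_dimers_final > n_replicas)
    stop("n_dimers_final exceeds n_replicas")
  if (per_replica) (n_dimers_final / n_replicas) / t_sim
  else n_dimers_final / t_sim
}

#' Dissociation propensity
#'
#' Total number of dissociation events divided by the total number of
#' dimerization events, optionally restricted to replicas whose final dimer
#' belongs to the most populated interface basins (top 3 for homodimers,
#' top 5 for heterodimers).
#'
#' @param traces list of annotated `energy_trace` objects.
#' @param keep_replicas optional character vector of replica ids to include
#'   (e.g. members of the top interface basins); NULL keeps all.
#' @return ratio, or NA with a message when no dimerization event exists.
#' @export
dissociation_propensity <- function(traces, keep_replicas = NULL) {
  if (!is.null(keep_replicas)) {
    ids <- vapply(traces, function(tr) tr$replica_id, "")
    traces <- traces[ids %in% keep_replicas]
  }
  counts <- vapply(traces, function(tr) {
    c(dim = sum(tr$events$kind == "dimerization"),
      diss = sum(tr$events$kind == "dissociation"))
  }, c(dim = 0, diss = 0))
  n_dim <- sum(counts["dim", ])
  n_diss <- sum(counts["diss", ])
  if (n_dim == 0) return(NA_real_)
  n_diss / n_dim
}

#' Accumulate the monomer/dimer time ratio P0/P1
#'
#' P1 is the total time spent in dimeric states; P0 the total monomeric time
#' occurring after at least one dissociation in the same replica.
#' Pre-first-dimerization monomer time is excluded, and re-dimerization
#' closes a P0 interval.
#'
#' @param traces list of annotated `energy_trace` objects.
#' @param keep_replicas optional replica-id filter as in
#'   [dissociation_propensity()].
#' @return list with `P0`, `P1` (ns) and `ratio` (NA when P1 = 0).
#' @export
accumulate_P0_P1 <- function(traces, keep_replicas = NULL) {
  if (!is.null(keep_replicas)) {
    ids <- vapply(traces, function(tr) tr$replica_id, "")
    traces <- traces[ids %in% keep_replicas]
  }
  p0 <- 0; p1 <- 0
  for (tr in traces) {
    if (is.null(tr$state)) stop("traces must be annotated first")
    tt <- tr$times
    dt <- diff(tt)
    st <- tr$state[-length(tr$state)]   # state holds over [t_i, t_{i+1})
    p1 <- p1 + sum(dt[st == 1L])
    diss <- tr$events$time[tr$events$kind == "dissociation"]
    if (length(diss)) {
      after <- tt[-length(tt)] >= diss[1L]
      p0 <- p0 + sum(dt[st == 0L & after])
    }
  }
  ratio <- if (p1 > 0) p0 / p1 else NA_real_
  if (p1 == 0) warning("no dimeric time accumulated; P0/P1 undefined")
  list(P0 = p0, P1 = p1, ratio = ratio)
}

#' Lower-bound binding free energy from the monomer/dimer time ratio
#'
#' For a single receptor pair in a box, the dissociation constant is
#' estimated as K_D = (P0/P1) / (N_Av V) in mol/L, where V is the volume of
#' the protein-lipid bilayer slab and P0/P1 the ratio of post-dissociation
#' monomeric to dimeric simulation time. The lower-bound binding free energy
#' is dG = R T ln(K_D / c0) with standard concentration c0 = 1 mol/L.
#'
#' @param P0_over_P1 monomer/dimer time ratio (>= 0).
#' @param V slab volume in nm^3.
#' @param T temperature in K.
#' @return list with `K_D` (mol/L), `dG` (kJ/mol; `-Inf` with status
#'   "unbound-never-observed" when P0/P1 = 0), `V`, `T`.
#' @export
lower_bound_binding_free_energy <- function(P0_over_P1, V, T = 310) {
  if (is.na(P0_over_P1)) return(list(K_D = NA_real_, dG = NA_real_, V = V, T = T,
                                     status = "undefined"))
  if (P0_over_P1 < 0) stop("P0_over_P1 must be >= 0")
  if (V <= 0) stop("V must be > 0")
  V_litre <- V * 1e-24                      # nm^3 -> L
  K_D <- P0_over_P1 / (PHYS$N_AVOGADRO * V_litre)
  if (K_D == 0) {
    return(list(K_D = 0, dG = -Inf, V = V, T = T,
                status = "unbound-never-observed"))
  }
  dG <- PHYS$R_GAS * T * log(K_D / 1)
  list(K_D = K_D, dG = dG, V = V, T = T, status = "ok")
}

#' Invert a binding free energy to a dissociation constant
#'
#' @param dG binding free energy in kJ/mol.
#' @param T temperature in K.
#' @return K_D in mol/L.
#' @export
kd_from_dg <- function(dG, T = 310) exp(dG / (PHYS$R_GAS * T))

#' Slab volume of the protein-lipid bilayer
#'
#' @param box_xy length-2 box edge lengths in nm.
#' @param thickness membrane slab thickness in nm (default 4).
#' @return volume in nm^3.
#' @export
slab_volume <- function(box_xy, thickness = 4) {
  stopifnot(length(box_xy) >= 2, all(box_xy[1:2] > 0), thickness > 0)
  box_xy[1] * box_xy[2] * thickness
}

#' Ensemble kinetics summary
#'
#' Runs the full kinetics chain on an annotated ensemble: first-order rate,
#' dimerization and dissociation propensities, P0/P1 and the lower-bound
#' binding free energy, optionally at each threshold scan level.
#'
#' @param traces list of (raw or annotated) `energy_trace` objects.
#' @param thresholds [event_thresholds()].
#' @param t_sim simulation length (us); defaults to the trace horizon.
#' @param V slab volume in nm^3.
#' @param T temperature (K).
#' @param keep_replicas optional basin filter (replica ids) applied to the
#'   dissociation propensity and P0/P1 accumulation.
#' @param scan also compute the dissociation propensity and dG at each
#'   `thresholds$scan_levels` dimerization criterion.
#' @return a `dimer_kinetics` object.
#' @export
ensemble_kinetics <- function(traces, thresholds = event_thresholds(),
                              t_sim = NULL, V, T = 310,
                              keep_replicas = NULL, scan = FALSE) {
  ann <- lapply(traces, function(tr)
    if (is.null(tr$state)) annotate_events(tr, thresholds) else tr)
  horizon_ns <- max(vapply(ann, function(tr) tr$times[length(tr$times)], 0))
  if (is.null(t_sim)) t_sim <- horizon_ns / 1000
  ev <- first_dimerization_table(ann)
  fit <- fit_first_order_rate(ev)
  final_dimer <- vapply(ann, function(tr) tr$state[length(tr$state)] == 1L, TRUE)
  n_dim_final <- sum(final_dimer)
  prop_dim <- dimerization_propensity(n_dim_final, length(ann), t_sim)
  prop_diss <- dissociation_propensity(ann, keep_replicas)
  pp <- accumulate_P0_P1(ann, keep_replicas)
  fe <- lower_bound_binding_free_energy(pp$ratio, V = V, T = T)

  scan_tab <- NULL
  if (scan) {
    scan_tab <- do.call(rbind, lapply(thresholds$scan_levels, function(level) {
      th <- event_thresholds(e_on = level, e_off = thresholds$e_off,
                             scan_levels = level)
      a2 <- lapply(traces, annotate_events, thresholds = th)
      pd <- dissociation_propensity(a2, keep_replicas)
      # tight criteria legitimately yield no dimeric time; the NA ratio in
      # the scan table carries that information
      p2 <- suppressWarnings(accumulate_P0_P1(a2, keep_replicas))
      f2 <- lower_bound_binding_free_energy(p2$ratio, V = V, T = T)
      data.frame(e_on = level,
                 n_dimerizations = sum(vapply(a2, function(tr)
                   sum(tr$events$kind == "dimerization"), 0)),
                 dissociation_propensity = pd,
                 P0_over_P1 = p2$ratio, dG = f2$dG)
    }))
  }

  structure(list(k = fit, n_replicas = length(ann),
                 n_dimers_final = n_dim_final,
                 n_dimerizations = sum(vapply(ann, function(tr)
                   sum(tr$events$kind == "dimerization"), 0)),
                 n_dissociations = sum(vapply(ann, function(tr)
                   sum(tr$events$kind == "dissociation"), 0)),
                 dimerization_propensity = prop_dim,
                 dissociation_propensity = prop_diss,
                 P0_over_P1 = pp$ratio, P0 = pp$P0, P1 = pp$P1,
                 K_D = fe$K_D, dG = fe$dG, V = V, T = T, t_sim = t_sim,
                 scan = scan_tab),
            class = "dimer_kinetics")
}

#' @export
print.dimer_kinetics <- function(x, ...) {
  cat(sprintf("Dimerization kinetics over %d replicas (%g us each):\n",
              x$n_replicas, x$t_sim))
  cat(sprintf("  k = %.4g 1/us (MLE %.4g +- %.2g)\n",
              x$k$k, x$k$k_mle, x$k$se))
  cat(sprintf("  dimers at end: %d; events: %d dimerizations, %d dissociations\n",
              x$n_dimers_final, x$n_dimerizations, x$n_dissociations))
  cat(sprintf("  propensities: dimerization %.4g 1/us, dissociation %s\n",
              x$dimerization_propensity,
              ifelse(is.na(x$dissociation_propensity), "NA",
                     sprintf("%.4g", x$dissociation_propensity))))
  cat(sprintf("  P0/P1 = %s, K_D = %s M, dG(lower bound) = %s kJ/mol (V = %g nm^3, T = %g K)\n",
              format(x$P0_over_P1, digits = 4), format(x$K_D, digits = 4),
              format(x$dG, digits = 4), x$V, x$T))
  invisible(x)
}

#' Summarise a kinetics object as a result table
#'
#' @param object a `dimer_kinetics` object.
#' @param ... unused.
#' @return a [result_table()] with one row of Table-shaped kinetics columns.
#' @export
summary.dimer_kinetics <- function(object, ...) {
  df <- data.frame(n_replicas = object$n_replicas,
                   n_dimers_final = object$n_dimers_final,
                   k = object$k$k,
                   dimerization_propensity = object$dimerization_propensity,
                   dissociation_propensity = object$dissociation_propensity,
                   P0_over_P1 = object$P0_over_P1,
                   K_D = object$K_D, dG_lower_bound = object$dG)
  result_table(df,
               units = c(k = "1/us", dimerization_propensity = "1/us",
                         K_D = "mol/L", dG_lower_bound = "kJ/mol"),
               provenance = list(V_nm3 = object$V, T_K = object$T,
                                 t_sim_us = object$t_sim))
}
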