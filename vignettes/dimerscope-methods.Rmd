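---
title: "Models and methods behind dimerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dimerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerscope)
```

dimerscope analyses ensembles of coarse-grained self-assembly simulations
of membrane receptors: hundreds of independent replicas, each holding two
receptors in a lipid bilayer for microseconds, observed through (a)
interaction-energy time series between their transmembrane segments, (b)
coordinate trajectories, and (c) structural metadata (helix assignments,
reference structures). This vignette explains the models the package
implements, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Event detection and first-order kinetics

Two receptors count as a dimer once the summed Lennard-Jones and Coulomb
energy between their TM helices drops below `e_on` = −50 kJ/mol; an
existing dimer ends only when the energy rises above `e_off` = −1 kJ/mol.
Energies between the thresholds leave the state unchanged. This
Schmitt-trigger reading is the only one under which separate entry and
exit thresholds yield a well-defined state sequence; it deliberately lets
transient excursions above −50 kJ/mol (but below −1 kJ/mol) keep a dimer
alive, which matches the physical intuition that a briefly loosened
contact is not a dissociation. A replica whose very first frame is already
below `e_on` is treated as dimeric from t = 0 and excluded from rate
fitting as left-censored; with randomized starting placements this case is
degenerate and essentially absent.

Because each replica holds exactly one receptor pair, dimerization is a
first-order process in the ensemble: the fraction of still-monomeric
replicas decays as f(t) = exp(−k t). `fit_first_order_rate()` fits ln f(t)
by weighted least squares through the origin (weights equal to the number
of replicas still at risk, which is proportional to the inverse variance
of ln f near f ≈ 1), and always reports the censored-exponential maximum
likelihood estimate k = d / (Σ event times + Σ censored horizons) with
standard error k/√d alongside. The two estimators agree closely whenever
events are plentiful; the MLE is the statistically efficient one and is
what the acceptance analysis reports.

The lower-bound binding free energy follows from the time-partition
argument: after the first dissociation, the ratio P₀/P₁ of monomeric to
dimeric simulation time estimates the unbinding equilibrium of a single
pair confined to the membrane slab of volume V, so K_D = (P₀/P₁)/(N_Av V)
in mol/L and ΔG = RT ln(K_D/c°) with c° = 1 mol/L. We note that the
commonly printed form of this relation ("K_D = P₀/P₁ c° N_Av V") is
dimensionally consistent only if the concentration factor divides rather
than multiplies; the package implements the dividing form, under which the
published per-ensemble ΔG values invert to sensible dissociation constants
(−24.95 kJ/mol at 310 K ↔ K_D ≈ 6.3 × 10⁻⁵ M). Pre-first-dimerization
monomer time is excluded from P₀ — before the first encounter the pair has
no unbinding history to estimate from — and a re-dimerization closes a P₀
interval. The slab volume defaults to the xy box area times a 4 nm
membrane thickness; the thickness is configurable because no canonical
value exists for a coarse-grained bilayer with embedded protein.

The estimate is a *lower bound* because dissociation events are rare at
simulation timescales: unobserved unbinding can only raise P₀/P₁, never
lower it.

## Orientation geometry

Each receptor carries a molecular frame: origin at the centre of mass of
its TM backbone beads, z along the membrane normal (+z extracellular), and
in-plane axes from the principal components of the xy-projected TM
backbone beads. Principal axes are defined only up to sign, so the frame
fixes the sign by requiring the TM1 backbone centroid to lie at an azimuth
in [−90°, 90°); without such a convention the binding angle β would be
defined only modulo 180° flips. The centre of mass uses TM backbone beads
rather than all beads so that flexible loops do not shift the frame.

A dimer configuration is described by three angles: β (azimuth of the
partner's origin in the reference frame — where the partner binds on the
reference receptor), φ (the partner's own rotation about z), and the
reciprocal binding azimuth χ = (180° + β − φ) mod 360. The identity
between the χ formula and the directly measured azimuth of the reference
receptor in the partner's frame is exact, and the package tests it on a
thousand random rigid placements to 10⁻⁶ degrees. For homodimers,
exchanging the monomer labels maps (β, φ, χ) to (χ, −φ mod 360, β), so
the pooled β∪χ angle set — and every density derived from it — is
invariant under labelling.

Orientation angles are computed over the last 50 ns of each dimer-forming
replica (configurable), a window long enough to average out frame noise
and short enough that the final interface dominates. Replicas whose final
dimer is younger than the window are excluded from interface assignment
with a warning.

## Binding-position densities and interface basins

One-dimensional binding-position densities use a wrapped-Gaussian kernel
on a 1° grid with a 10° default bandwidth — narrow relative to helix
spacing (≈ 51° for seven helices), wide relative to frame noise. Homodimer
densities pool β and χ (the two angles describe the same position on
either protomer); heterodimer densities keep them separate, β on receptor
A and χ on receptor B.

The two-dimensional (β, χ) height-field is a doubly periodic product
kernel on a 360 × 360 grid. Local maxima are found on the torus
(8-neighbourhood, with a scan-order tie-break so plateaus keep exactly one
representative); maxima below 5% of the global maximum are treated as
noise. Segmentation runs the image-processing watershed (EBImage) on the
3×3-tiled field with central-tile extraction — the simplest correct
handling of the periodic boundary — after which sub-floor basins are
merged into the nearest surviving basin under the wrapped Euclidean
metric. The result is deterministic: identical inputs give identical basin
maps.

Replicas are assigned to basins by the circular mean of their last-window
(β, χ); populations are fractions of assigned replicas. Per-frame
assignment is available but not the default, since a single replica's
final interface — not its transient visits — is the object of interest.
Basins are labelled by the helices whose angular intervals lie within a
15° contact half-width of the basin maximum on each protomer; runs of
consecutive TM helices compact to range labels ("TM5-7"). The
representative replica of a basin is the member with the most negative
final interaction energy among the decile closest to the basin maximum:
closeness alone can select a loosely bound outlier, energy alone an
off-mode configuration; the decile-then-energy rule captures "closest to
the maximum while compact".

## Cholesterol contacts

A residue is cholesterol-bound in a frame if the minimum distance between
any of its beads and any bead of any cholesterol molecule is at most
0.62 nm (inclusive). The all-bead reading (rather than backbone-only) is
adopted because the contact is a property of the residue surface;
occupancy is then the bound-frame fraction after discarding the first
200 ns as equilibration. Distances honour periodic boundaries via the
minimum-image convention on the frame's box vectors.

Spatial densities accumulate, per frame, all beads of the five cholesterol
molecules nearest to the receptor (ranked by minimum bead distance,
matching the contact semantics of the occupancy rule) on a 0.1 nm grid in
the receptor-fixed frame, with the frame defined by least-squares rigid
superposition of the TM backbone onto the reference pose. Headgroup (ROH)
beads of the same molecules are accumulated separately, which is what
distinguishes sites where cholesterol inserts its hydroxyl from sites
padded by the ring system.

## Diffusion

Lateral diffusion uses the 2D Einstein relation D = slope(MSD)/4 with the
MSD averaged over protein beads and over all time origins, after
subtracting the per-frame centre-of-mass motion of the protein–membrane
system. The slope is fitted on the 5–20 ns lag window — beyond ballistic
and cage effects, short enough for good origin statistics. Lags are
capped at 25% of the analysed stretch (and, for slope fitting, at twice
the fit window's upper edge, which saves substantial work on long walks
without changing the estimate). The unit conversion is
1 nm²/ns = 100 × 10⁻⁷ cm²/s.

## Structure metrics and the elastic network

The rubber-band network bonds all backbone bead pairs within 0.9 nm whose
sequence separation exceeds 2 (nearer pairs are already bonded by the base
force field), with force constant k_ij = f·exp(−a·d_ij^(2p)), f = 500
kJ/mol/nm², a = 3, p = 6. The exponent grouping d^(2p) is the natural
reading of the kernel and gives a smooth decay from ~500 at contact to
~214 kJ/mol/nm² at the cutoff; because the grouping is ambiguous in prose
descriptions of this kernel family, the exponent expression is
configurable.

RMSD uses Kabsch least-squares superposition, with a partial-fit mode
(superpose on one protomer, measure over the dimer) for crystal-versus-
simulation comparisons. Buried surface area is SASA(A) + SASA(B) −
SASA(A∪B) with SASA from deterministic golden-spiral Shrake–Rupley
sampling (960 points per bead, 0.264 nm bead radius, 0.191 nm probe, all
configurable; reported at the expanded radius). The sampling is validated
against the closed two-sphere cap formula, to which it converges as the
point density grows. Percent identity divides identities by aligned
positions (columns with a residue in both sequences), the convention of
standard percent-identity matrices; the full-alignment-length denominator
is available as an option, and a residue-range restriction supports
per-helix identities.

## The synthetic-data generators

The generators emulate the *statistical structure* of self-assembly
ensembles so that every analysis stage has a recovery test with known
truth:

- `gen_energy_ensemble()` draws exponential first-dimerization times
  (defaults: 500 replicas, 3 µs, rates of order 0.05–0.3 µs⁻¹ — the
  regime of receptor ensembles at ~0.015 receptors/nm²), Bernoulli
  dissociation decisions with exponential dimer lifetimes censored at the
  horizon, and post-dissociation monomer periods set by a stationary
  occupancy parameter. Monomeric frames jitter in (−1, 0) kJ/mol; dimeric
  frames follow an AR(1) process (10 ns correlation time) around
  −120 kJ/mol, clamped below −55 kJ/mol. The clamp and the jitter range
  keep the trace consistent with the −50/−1 thresholds so the detector
  recovers the schedule at frame resolution; event pairs that open and
  close within one output interval are invisible by construction, which
  is a property of any frame-sampled detector, not of the generator.
  Horizon censoring of dimer lifetimes (rather than truncation) keeps the
  monomer/dimer time bookkeeping memoryless and therefore unbiased for
  P₀/P₁, at the cost of a realized dissociation propensity marginally
  below the nominal probability (by the ~10⁻³ censoring rate).
- `gen_bundle()` builds an idealized 7-TM bundle: vertical helices at
  azimuths 360i/7 on a ring whose radius is modulated by a second
  harmonic (1 + 0.25 cos 2θ). The modulation elongates the bead cloud
  along the TM1 direction without moving the centroid, so the principal
  axes are exact and the frame's x-axis provably passes through TM1,
  while every helix azimuth stays exactly at its nominal value — the
  property the orientation oracles rely on. An optional in-plane
  appendage plays the role of helix 8.
- `place_dimer()` is the geometric oracle: bundle B rotated by φ about
  its own z and placed at azimuth β in A's frame, with χ from the closed
  formula; recovery is exact to numerical precision.
- `gen_chol_field()` plants cholesterol binding hotspots: per frame, each
  hotspot residue is occupied with its stated probability by an 8-bead
  cholesterol whose ROH bead sits 0.4 nm from the residue (inside the
  0.62 nm shell), remaining molecules uniform in the box. The uniform
  background adds a small extra contact rate (~1–2% per free molecule),
  so hotspot recovery is tested against a one-sided widened binomial
  interval.
- `gen_random_walk()` applies Gaussian xy steps of total variance 4·D·dt
  to a rigid bead cloud; the 1 ns default output interval matches typical
  coarse-grained trajectory output and gives the 5–20 ns fit window
  enough origin statistics for ~4% relative error on 20,000-step walks.

What the generators do *not* emulate: force-field energetics (the AR(1)
energy noise makes no claim of matching Martini fluctuation spectra),
internal protein flexibility (bundles are rigid), lipid dynamics, or any
correlation between interface identity and kinetics. Passing recovery
tests therefore demonstrates that the estimators are correct and unbiased
under the stated statistical model — not that real trajectories satisfy
that model.

## Problem sizes and determinism

The test-suite and acceptance analyses use 300–500 replicas × 3 µs at
2–5 ns output for kinetics (20 seeds for rate recovery), 400 angle samples
for two-mode interface recovery (10 seeds), 200-frame cholesterol fields
with 25 molecules, and 20,000-step random walks (5 seeds) — sizes at which
every recovery bound is statistically comfortable and the whole suite runs
in about a minute. All generators consume explicit integer seeds and use R's
default RNG stream only through them, so identical seeds give identical
output on any platform.

## Known limitations

- Trajectory input is multi-frame GRO (the text format `trjconv` emits);
  compressed XTC is not read.
- Interaction energies are inputs, never recomputed from coordinates
  (that would require a force-field rerun).
- Second-order (concentration-dependent) kinetics are out of scope; the
  first-order model is valid precisely because each replica holds one
  pair.
- The watershed operates on the kernel-density estimate, so basin
  boundaries inherit the bandwidth choice; heavily overlapping interface
  modes (< ~2 bandwidths apart) merge.
- Absolute buried-surface-area values shift by several percent with the
  assumed bead radii; comparisons should hold radii fixed.
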