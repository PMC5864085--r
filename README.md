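# dimerscope

Analysis of large ensembles of coarse-grained self-assembly simulations of
membrane receptors — the setting in which GPCR (e.g. chemokine receptor)
homo- and heterodimerization is studied by running hundreds of independent
replicas of two receptors in a lipid bilayer and asking *how fast* they
dimerize, *how strongly* they bind, *which interface* they form, and *how
membrane cholesterol changes all three*.

The package is aimed at computational biophysicists who already have such
ensembles (or want to prototype the statistics before spending cluster
time): every analysis stage is exercised end-to-end against a bundled
synthetic-data generator with known ground truth, so no molecular dynamics
run or download is needed to validate the machinery.

## What it computes

**Event kinetics.** Two receptors count as a dimer once the interaction
energy between their transmembrane segments (Lennard-Jones + Coulomb) drops
below −50 kJ/mol, and the dimer ends only when the energy rises above
−1 kJ/mol (two-threshold detection with hysteresis). From the per-replica
event tables the package derives:

- the first-order association rate *k* from the surviving-monomer fraction
  *f(t) = e^(−kt)*, with the censored-exponential maximum-likelihood
  estimate *k̂ = d / (Σ tᵢ + Σ T_cens)* as a cross-check;
- dimerization and dissociation propensities;
- the lower-bound binding free energy from the ratio *P₀/P₁* of
  post-dissociation monomeric to dimeric simulation time:
  *K_D = (P₀/P₁) / (N_Av·V)* in mol/L and *ΔG = RT·ln(K_D/c°)* with
  c° = 1 mol/L, where *V* is the volume of the protein–lipid bilayer slab.

**Interface classification.** Each receptor carries a molecular frame from
the principal components of its xy-projected TM backbone beads. A dimer is
described by three angles: β (azimuth of the partner in the reference
frame), φ (the partner's own rotation about the membrane normal), and
χ = (180° + β − φ) mod 360 (the reciprocal binding azimuth). (β, χ)
samples over the last 50 ns of each dimer-forming replica populate a doubly
periodic kernel-density height-field whose watershed basins define the
interface classes; basins are labelled by the helices at both binding
azimuths (e.g. `TM1,H8/TM4,5`) and each basin nominates a representative
replica (closest to the maximum with the most negative final energy).

**Lipid contacts.** Residue-resolved cholesterol occupancy (a residue is
bound in a frame if any of the 8 cholesterol beads lies within 0.62 nm of
any of its beads) and 3D spatial densities of the 5 nearest cholesterol
molecules and their ROH headgroups in the receptor-fixed frame.

**Diffusion and structure metrics.** Lateral diffusion via the 2D Einstein
relation D = slope(MSD)/4 (fit on the 5–20 ns lag window, system-COM motion
removed); superposed RMSD (full or partial-fit); buried surface area by
Shrake–Rupley sampling; percent sequence identity from pairwise alignments;
and the distance-decayed elastic-network ("rubber band") bond list
*k_ij = f·exp(−a·d_ij^(2p))* with f = 500 kJ/mol/nm², a = 3, p = 6 for
backbone pairs within 0.9 nm (|i−j| ≤ 2 excluded).

## Worked example

Generate a 200-replica synthetic ensemble (association rate 0.25 µs⁻¹,
15% dissociation probability per dimerization) and run the kinetics chain:

```r
library(dimerscope)

ens <- gen_energy_ensemble(n_replicas = 200, t_sim = 3, dt = 2,
                           k_on = 0.25, p_diss = 0.15, seed = 7)
kin <- ensemble_kinetics(ens$traces, V = slab_volume(c(11, 11)))
kin
#> Dimerization kinetics over 200 replicas (3 us each):
#>   k = 0.2641 1/us (MLE 0.2678 +- 0.025)
#>   dimers at end: 111; events: 129 dimerizations, 18 dissociations
#>   propensities: dimerization 0.185 1/us, dissociation 0.1395
#>   P0/P1 = 0.001479, K_D = 5.076e-06 M, dG(lower bound) = -31.42 kJ/mol (V = 484 nm^3, T = 310 K)
```

The fitted rate (0.264 ± 0.025 µs⁻¹) recovers the generating 0.25 µs⁻¹;
the dissociation propensity (0.14) recovers the generating 0.15; with only
18 dissociations in 600 µs of dimer time the monomer/dimer time ratio is
small and the lower-bound ΔG is correspondingly deep.

Classify interfaces on a two-mode angle ensemble and label the top basin:

```r
s  <- gen_angle_mixture(data.frame(beta = c(40, 220), chi = c(200, 60),
                                   weight = c(0.6, 0.4), sd = 8),
                        n = 400, seed = 7)
hf <- watershed_basins(kde_heightfield(s$beta, s$chi))
hf$basins
#>   basin  beta   chi       height n_cells
#> 1     1  39.5 199.5 0.0005537070   64836
#> 2     2 219.5  59.5 0.0004273384   64764

b  <- gen_bundle(h8 = TRUE)
hm <- helix_angular_map(b$model)
label_basin(hf$basins$beta[1], hf$basins$chi[1], hm, hm)
#> [1] "TM2/TM5"
```

The watershed finds the two planted modes within half a degree and splits
the torus into two basins; the label names the helices whose angular
intervals contain the basin maximum on either protomer.

A thin command-line wrapper lives in `inst/cli/dimerscope.R`
(`validate`, `kinetics`, `simulate` subcommands).

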