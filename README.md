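# arpdyn

Quantitative analysis of subunit reorientation in molecular-dynamics
trajectories of the Arp2/3 complex, and of the actin-assembly kinetics used
to characterise its nucleation activity.

The Arp2/3 complex nucleates branched actin filaments. In its inactive
(crystallographic) conformation the Arp2 and Arp3 subunits sit apart; to
nucleate, they must reorient into an actin-dimer-like "short-pitch"
arrangement. Testing whether a perturbation (e.g. phosphorylation of Arp2)
drives that reorientation requires a specific set of measurements on MD
trajectories and on pyrene-actin assembly assays. `arpdyn` implements that
measurement pipeline for structural biologists and biochemists:

* **Trajectory geometry** — PDB / plain-text trajectory parsing with
  declarative atom selections; least-squares (Kabsch) superposition; RMSD
  time series of one subunit after alignment on another (e.g. Arp2 Cα RMSD
  after alignment of Arp3 subdomains 1–2); per-residue RMSD profiles;
  histograms over analysis windows.
* **Contacts** — inter-subunit heavy-atom contact census (count of group-B
  atoms within an inclusive 3.5 Å of any group-A atom, cell-list
  accelerated with an all-pairs oracle), and salt-bridge donor–acceptor
  minimum-distance tracking with pooled distributions.
* **Essential dynamics** — coordinate PCA of aligned Cα frames (SVD of the
  centred frame matrix; unbiased covariance), variance fractions,
  projections, and porcupine mode displacements.
* **Assembly kinetics** — conversion of pyrene fluorescence to polymer
  concentration, half-times, the assembly rate at a stated polymerization
  fraction, filament-end concentrations via the elongation relationship
  **R = k₊[A][E]** (k₊ = 10 µM⁻¹s⁻¹), ends-vs-nucleator tables, and
  pointed-end binding isotherm (K_d) fits.
* **Synthetic data** — generators for rigid-body reorientation trajectories
  (with the closed-form aligned RMSD `2·sin(θ/2)·r_rms` as ground truth),
  salt-bridge partner switches, and assembly curves from a known
  filament-end concentration, so every analysis stage is verifiable end to
  end.

The two analysis tracks are orchestrated by `run_trajectory_track()` and
`run_kinetics_track()`, driven by a YAML or list config, writing tidy CSVs
plus a JSON manifest.

## Worked example

```r
library(arpdyn)

## --- a subunit rotating 30 degrees relative to a fixed partner ---
spec <- traj_sim_spec(angle_schedule = seq(0, 30, length.out = 101),
                      noise_sd = 0.5)          # 0.5 A thermal noise
sim <- simulate_reorientation_traj(spec, seed = 1)
ref <- md_structure(sim$traj$topology$atoms, sim$traj$topology$xyz)
ser <- aligned_rmsd_series(sim$traj, ref,
                           align_sel   = atom_selection(chains = "F"),
                           measure_sel = atom_selection(chains = "M"),
                           reference_tag = "INITIAL")
sprintf("final aligned RMSD: %.2f A (ground truth %.2f A)",
        ser$values[101], sim$truth$rmsd[101])
#> "final aligned RMSD: 10.49 A (ground truth 10.18 A)"

## --- a pyrene assembly curve with 0.193 nM growing ends ---
ksim <- simulate_assembly_curve(
  curve_sim_spec(filament_ends = 0.193, duration = 5000), seed = 1)
res <- analyze_assembly_curve(ksim$curve, ksim$calibration, arp_conc = 5)
sprintf("t1/2 = %.0f s, rate at 80%% = %.3f nM/s, ends = %.3f nM",
        res$t_half, res$rate_nM_s, res$filament_ends_nM)
#> "t1/2 = 358 s, rate at 80% = 1.574 nM/s, ends = 0.197 nM"
```

The first block shows the headline geometry measurement: the mobile group's
Cα RMSD *after superposition on the fixed group only*, which isolates
rigid-body reorientation from internal motion; the measured 10.49 Å tracks
the noise-free ground truth (10.18 Å for a 30° rotation of this geometry).
The second block runs the full kinetics inversion: the synthetic assay was
built with 0.193 nM filament ends, and analysing its (noisy) fluorescence —
normalise, read the assembly rate at 80 % polymerization, invert
R = k₊[A][E] with [A] = 0.8 µM — recovers 0.197 nM.

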