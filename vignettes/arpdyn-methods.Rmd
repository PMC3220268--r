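---
title: "Measuring subunit reorientation and nucleation activity with arpdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subunit reorientation and nucleation activity with arpdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arpdyn)
```

# The scientific problem

The Arp2/3 complex nucleates a new actin filament only after its Arp2 and
Arp3 subunits adopt a short-pitch, actin-dimer-like mutual orientation. A
perturbation hypothesised to activate the complex — phosphorylation of Arp2,
or mutation of the ARPC4 arginines that clamp the inactive state — should
therefore show up in simulations as a *rigid-body reorientation* of Arp2
relative to Arp3, and in biochemistry as a change in *nucleation activity*
measured by pyrene-actin assembly assays. `arpdyn` implements both
measurement tracks and a synthetic-data module that makes every stage
verifiable against known ground truth.

# Trajectory geometry

## Superposition and reorientation RMSD

All alignment is unweighted least-squares superposition (Kabsch): the SVD
of the cross-covariance of the centred point sets gives the optimal proper
rotation; reflections are corrected by flipping the smallest singular
direction, so the result is always a physical rotation even for
mirror-image inputs. Weights are uniform over the selected atoms — nothing
in the analyses calls for mass-weighting, and uniform weights keep the
closed-form checks exact.

The reorientation measurement is deliberately two-selection:
`aligned_rmsd_series()` fits each frame to the reference on the *alignment*
selection (e.g. Cα atoms of Arp3 subdomains 1–2, residues 3–39, 51–151,
376–410 — the part of Arp3 that is well resolved and conformationally
stable), applies that transform to the whole frame, and only then measures
RMSD over the *measure* selection (e.g. all Arp2 Cα atoms). Because the
measured group takes no part in the fit, a rigid rotation of the measured
group by θ about an axis through its centroid produces exactly

\[ \mathrm{RMSD} = 2 \sin(\theta/2)\, r_\mathrm{rms}, \]

where \(r_\mathrm{rms}\) is the root-mean-square atom distance from the
axis. This identity is the package's primary geometric oracle: the
synthetic generator emits it as ground truth and the test suite checks it
to 10⁻⁸ for θ ∈ {10°, 30°, 90°}.

Per-residue profiles use the same alignment; the per-residue value is the
root of the time-mean squared Cα displacement, so the mean of the squared
per-residue values reproduces the time-mean squared subset RMSD — an
algebraic identity the tests assert on random data.

The "active orientation" reference deserves a note: no public model of the
short-pitch dimer exists, so the package never hard-codes one. Instead,
`make_active_surrogate()` builds a surrogate by applying an explicit,
config-declared rigid transform to the mobile selection of the initial
model. Every number computed against an ACTIVE reference is therefore
relative to a *documented, versioned* surrogate, not to an irreproducible
artifact.

## Contact census

A contact is defined asymmetrically: the count of group-B heavy atoms
having at least one group-A heavy atom within the cutoff. The comparison is
*inclusive* (≤ 3.5 Å by default) — "within" is ambiguous at the boundary,
and an exact convention is required for the cell-list and brute-force paths
to agree bit-for-bit. The cell list bins the probe atoms into cubic cells
of edge equal to the cutoff so each counted atom examines 27 cells; the
all-pairs O(N²) census is retained as an always-available oracle and the
suite checks equality on 100 random configurations. Selections passed to
`contact_spec()` are forced to heavy atoms unless they already restrict the
element class. No periodic-boundary imaging is applied: inputs are assumed
to be whole, imaged molecules, which is how post-processed solute
trajectories are normally delivered.

Salt bridges are tracked as the minimum distance over all donor–acceptor
atom pairs of a residue pair. The per-residue-type donor/acceptor roster
(Arg NE/NH1/NH2, Lys NZ, Tyr OH; Glu OE1/OE2, Asp OD1/OD2,
phosphothreonine O1P/O2P/O3P/OG1) ships as a plain-text table
(`inst/extdata/donor_acceptor_roster.tsv`) and is user-overridable; the
criterion is distance-only, with no angular term. Replicate series are
pooled by concatenation before histogramming.

## Coordinate PCA

`fit_pca()` aligns each frame on the alignment selection, collects the
measure-selection Cα coordinates into an F×3M matrix, and
eigendecomposes the covariance about the mean with the unbiased (n−1)
denominator. The decomposition runs through the SVD of the centred frame
matrix — the dual (Gram) route whenever 3M exceeds the frame count, and
numerically identical to the direct covariance eigendecomposition in all
cases. Two conventions make outputs reproducible: eigenvalues are clipped
at zero (tiny negative values are numerical noise), and each eigenvector is
signed so its largest-magnitude component is positive, fixing the otherwise
arbitrary "positive direction" of each mode. Porcupine output displaces the
mean structure by ±s·√λ along a mode (s in standard deviations of the
conformer distribution), so the total tip-to-base norm is 2·s·√λ exactly.

## Analysis windows

`traj_window()` implements the standard production-analysis restriction:
keep frames in an inclusive time interval (e.g. the final 20 ns of a run),
then every k-th frame (e.g. every 10th frame at 10 ps output spacing =
100 ps). Windowing is associative with the stride, which the suite checks
as a property.

# Assembly kinetics

## From fluorescence to filament ends

Pyrene fluorescence is mapped linearly onto polymer concentration between
the calibration anchors (baseline = 0 % polymer, plateau = 100 % of the
polymerizable pool, i.e. total actin minus the critical concentration;
0.1 µM is the standard barbed-end critical concentration, 0 idealises it
away for closed-form tests). The half-time is the first crossing of 50 % of
the plateau, linearly interpolated. The nucleation readout follows the
elongation relationship R = k₊[A][E] with k₊ = 10 µM⁻¹s⁻¹: the assembly
rate R is the least-squares slope on a symmetric window (5 % of the points,
at least 7) centred at the crossing of the stated polymerized fraction
(80 % by default), and the free monomer there is
[A] = (1−f)·(A_total − c_c) + c_c, giving [E] = R/(k₊[A]) in nM.
Concentrations supplied in µM or nM are canonicalized internally, and the
tests assert unit invariance.

Two numerical choices matter on noisy data. First, crossings are located on
a centred running mean (0.5 % of the points, minimum 5): the first *raw*
sample above a target is biased early because any upward noise excursion
triggers it, while the mean's curvature bias on an exponential-approach
curve (~k·w²/24) stays below 0.3 % of the half-time at this width. Second,
a curve is declared censored (no half-time, no rate) when it has not
flattened — the average slope over its final 10 % exceeding 5 % of the peak
slope marks a truncated, still-rising curve. Both rules are tested on
constructed fixtures.

## Pointed-end binding

Gelsolin-capped seeds elongate only at their pointed ends; a capper that
binds those ends depresses the elongation rate following the isotherm
rate(c) = rate_free − (rate_free − rate_bound)·c/(K_d + c). The fit is
Levenberg–Marquardt least squares (via `minpack.lm`) with K_d bounded
positive; asymptotic standard errors are reported. A titration whose rates
do not separate beyond twice the residual noise is flagged
non-identifiable rather than returning a spurious K_d. Monte-Carlo recovery
(200 titrations, 8 points, 5 % multiplicative noise) keeps the median
fitted K_d within a few percent of truth; the acceptance suite asserts the
20 % band.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated, and they are fixed once:

* **Reorientation trajectories** — a static group of 40 atoms near the
  origin and a mobile rigid group of 40 atoms centred 20 Å from the
  rotation axis (blob radius scale 5 Å), rotated per a per-frame angle
  schedule, with isotropic Gaussian coordinate noise of sd 0.5 Å (a typical
  Cα thermal fluctuation) added to every atom of every frame; frames are
  10 ps apart, matching common trajectory output rates. Ground truth is the
  noise-free closed-form aligned RMSD and the noise-free contact counts.
* **Assembly curves** — the closed-form solution of
  dP/dt = k₊(A_total − c_c − P)·E for fixed E, mapped onto the fluorescence
  anchors, with additive Gaussian noise of 0.5 % of the baseline-to-plateau
  range (typical pyrene-assay noise), sampled every 1 s as in the real
  assays at 4 µM actin with 5 % pyrene label. Nucleation is deliberately
  omitted: the end-counting inversion itself assumes a fixed end
  concentration at the readout point, so the generator and the analysis
  share exactly that assumption — no more.
* **Salt-bridge switches** — a two-level minimum-distance series with
  Gaussian noise, for bimodality and pooling tests.

All generators are pure functions of (spec, seed): they set the RNG stream
locally and restore the caller's state, and the suite checks both bitwise
reproducibility and seed sensitivity.

What passing these tests shows — and what it does not. The generators
emulate the *geometry* of rigid-body reorientation and the *rate law* of
elongation, under isotropic/additive Gaussian noise. They do not emulate
internal subunit flexibility, force-field physics, solvent, correlated
noise, photobleaching, or nucleation transients. Green tests therefore
demonstrate that the measurement pipeline is correct and self-consistent,
not that any particular biological system behaves this way.

# Scale and determinism choices

The validation problem sizes are chosen to exercise the estimators well
past their asymptotic regime while staying desk-sized: 10,000 frames for
the PCA variance-fraction fixture, 100 random 500-atom configurations for
the contact-census oracle equivalence, 200 Monte-Carlo titrations for the
K_d recovery, and assembly curves of up to ~7,500 one-second samples
(14 half-times, so the plateau is fully established before the half-time
and rate readouts). Every stochastic result in the package and its scripts
derives from an explicit integer seed.

# Known limitations

* PDB parsing covers ATOM/HETATM/MODEL records with author numbering;
  mmCIF and binary trajectory formats (DCD/XTC) are out of scope — convert
  externally, or use the plain-text dialect.
* Correspondence between mobile and reference selections is positional
  (same selection resolved in both); there is no sequence alignment.
* The contact census and distance tracking assume imaged coordinates (no
  periodic-boundary minimum-image correction).
* The kinetics inversion assumes the linear pyrene–polymer relationship
  and a fixed end concentration at the readout point; systems with strong
  ongoing nucleation violate the latter and will read out an effective
  (time-local) end concentration.
* The isotherm fit reports asymptotic standard errors, which understate
  uncertainty near non-identifiability; the explicit flag should be
  consulted first.
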