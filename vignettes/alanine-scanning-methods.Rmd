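---
title: "Alanine scanning with MM/GBSA and interaction entropy: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alanine scanning with MM/GBSA and interaction entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iescan)
```

## The model

Single-trajectory computational alanine scanning estimates each pocket
residue's contribution to binding as the free-energy penalty of
truncating its sidechain to alanine in an existing trajectory. The
estimate decomposes into a gas-phase part and a solvation part.

The gas-phase part uses the pairwise molecular-mechanics interaction
energy between the residue and the ligand — Coulomb plus 12-6
Lennard-Jones with Lorentz–Berthelot combination, no distance cutoff
(end-state reweighting is cutoff-free even when the MD engine that
produced the trajectory used one). Its entropic component is the
interaction-entropy (IE) exponential average
$-T\Delta S = kT\,\ln\langle e^{\beta \Delta E_{int}}\rangle$ over the
fluctuations $\Delta E_{int} = E_{int} - \langle E_{int}\rangle$ of the
per-frame series; the $\Delta\Delta$ entropy of a mutation is the
difference of the wild and mutant IE values, each computed on its own
independently filtered series. The estimator is evaluated through a
log-sum-exp guard, is translation-invariant, non-negative (Jensen), and
reduces to $\sigma^2/2kT$ for Gaussian fluctuations — the property
tests lean on all four facts.

The solvation part is MM/GBSA: polar solvation from the OBC
generalized-Born model and nonpolar solvation from the linear SASA
formula $\Delta G_{np} = \gamma\,\mathrm{SASA} + \beta$. Complexation
solvation is assembled species-wise per frame,
$G(\text{complex}) - G(\text{protein}) - G(\text{ligand})$, with Born
radii recomputed for each species' own atom set; the ligand terms (and
the $\beta$ offsets) cancel in wild-vs-mutant differences, which the
tests assert rather than assume.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| temperature | 300 | K | matches the simulation thermostat |
| pocket cutoff | 5.0 | Å | heavy-atom residue–ligand distance |
| window length | 5000 | ps | five windows per replicate |
| enthalpy frames / window | 100 | – | equally spaced |
| entropy frames / window | all | – | every recorded frame |
| outlier filter | 3 | SD | single pass, unfiltered mean/SD |
| hot-spot threshold | 1.0 | kcal/mol | strict inequality |
| dielectrics (nonpolar/polar/charged) | 1 / 3 / 10 | – | per residue class |
| $\varepsilon_{out}$ | 80 | – | zero salt |
| OBC offset, $\alpha,\beta,\gamma$ | 0.09 Å, 1.0, 0.8, 4.85 | – | igb = 2 constants |
| SASA probe, points | 1.4 Å, 960 | – | Fibonacci point set |
| $\gamma,\beta$ (nonpolar) | 0.00542, 0.92 | kcal/(mol·Å²), kcal/mol | |
| Coulomb constant | 332.0636 | kcal·Å/(mol·e²) | AMBER convention |
| $k_B$ | 1.9872041×10⁻³ | kcal/(mol·K) | |

Residue polarity classes follow standard sidechain chemistry: charged =
{ASP, GLU, LYS, ARG, HIP}; polar = {SER, THR, ASN, GLN, HIS/HIE/HID,
TYR, TRP, CYS, ASH, GLH, LYN}; nonpolar = {ALA, VAL, LEU, ILE, PRO,
PHE, MET, GLY, CYX}. TYR and TRP sit in the polar class by default but
the lookup table is an argument of `classify_residue()`, so either
placement is a one-line override.

## Design choices that were genuinely open

**Dielectric placement.** The class dielectrics 1/3/10 could divide
only the GB term or also the gas-phase Coulomb term. We apply them to
both — but through a single, shared mixing rule: every atom pair
interacts through $\varepsilon_{ij} = \sqrt{\varepsilon_i
\varepsilon_j}$, in the direct Coulomb term (residue–ligand pairs see
$\sqrt{\varepsilon_{class}\cdot 1}$) exactly as in the GB prefactor
$(1/\varepsilon_{ij} - 1/\varepsilon_{out})$. Using a bare
$1/\varepsilon_{class}$ divisor on the direct term while GB mixes
geometrically is internally inconsistent: for polar and charged
residues $1/\varepsilon < 1/\sqrt{\varepsilon} - 1/80$, so the reaction
field would over-cancel the direct attraction and flip the sign of
electrostatic $\Delta\Delta G$ contributions — we observed exactly this
on toy systems. The mutant series keeps the wild position's dielectric:
the class dielectric models the local environment of the position, not
the identity of the (now truncated) sidechain.

**Hydrogen completion at C$\beta$.** Truncation retains the $\gamma$
heavy atom (or first $\gamma$ hydrogen) as HB1, repositioned to 1.09 Å
along the original C$\beta\rightarrow\gamma$ bond vector — standard
single-trajectory practice that preserves frame alignment. The methyl
group receives alanine library parameters and the residual charge is
folded into HB1 so the mutant residue is exactly neutral; without this
the class-dielectric model would be ill-defined for the mutant.
PRO→ALA is supported with the backbone left untouched (an approximation
flagged in the record: the ring constrains the backbone in ways a true
alanine would not).

**Window selection.** Stable windows are chosen greedily to minimize
the within-window standard deviation of the ligand heavy-atom RMSD to
the reference frame, earliest start winning ties; explicit starts
override. The stability metric is ligand RMSD because that is the
series used to judge complex stability before any energy work.

**Whole-complex totals.** Two totals are reported: the residue-level
sum of aggregated $\Delta\Delta G$ values, and a window-level summary
that sums residues within each window first and aggregates across
windows. Their means coincide by linearity, but the SDs differ, and
published tables aggregated at different levels can disagree by a few
tenths of a kcal/mol once rounding enters; reporting both makes the
discrepancy inspectable instead of mysterious.

**Hydrogen-bond averages.** Occupancy counts frames satisfying both
inclusive cutoffs (≤ 3.5 Å, ≥ 120°), while mean distance and angle are
averaged over *all* frames — that is the only convention under which a
bond can report a mean angle below the angular cutoff with nonzero
occupancy, as reference occupancy tables for these systems do. Carbon
donors (CA–HA, CB–HB) are deliberately allowed.

## Numerical choices

Born radii use the Hawkins–Cramer–Truhlar pairwise descreening closed
form with screened neighbor radii, rescaled through the OBC tanh
function; the closed form is verified against a semi-analytic
quadrature of the $r^{-4}$ descreening integral to 10⁻³ Å. The GB pair
function $f_{GB} = \sqrt{r^2 + R_iR_j\exp(-r^2/4R_iR_j)}$ evaluates the
self term $f_{ii} = R_i$ without special-casing. SASA uses a
deterministic Fibonacci spiral (960 points by default, ~0.3 % area
quadrature error), making every SASA value bit-reproducible. The IE
exponential average runs through log-sum-exp so kcal-scale fluctuations
cannot overflow, and round-off that would produce a vanishingly
negative entropy is clamped at zero. Overlapping atoms (r < 10⁻⁶ Å)
raise singularity errors rather than silently returning infinities.
Degenerate inputs — GLY mutation targets, empty trajectories,
misaligned series, sub-window replicates — error early with the stage
named.

## What the synthetic generators emulate — and what they do not

`make_toy_complex()` builds a ring of 5–9-atom residues (alanine-,
serine-, and glutamate-like templates with net charges 0/0/−1) around
a 5-atom +1 ligand, each residue placed so its sidechain tip sits at a
fixed clearance from the ligand, with seeded Gaussian jitter as the
"trajectory". Planted per-residue interaction strengths scale the
sidechain Lennard-Jones well depths beyond C$\beta$; because the pair
well depth combines as a square root and the IE term grows with
fluctuation size, $\Delta\Delta G$ grows sublinearly in the planted
strength, and the default ranking ladder (1, 2, 4, 8, 16) is spaced
geometrically so adjacent residues stay separable above the jitter
noise. `gaussian_energy_series()` and `planted_hbond_trajectory()`
provide exact ground truth for the entropy estimator and the occupancy
logic.

What passing these tests shows: the estimators are implemented
correctly — closed forms, oracles, invariances, and planted orderings
are recovered. What it does not show: anything quantitative about real
PARP energetics. The toys have no explicit solvent history, no
conformational transitions, isotropic uncorrelated jitter instead of
physical dynamics, and simplified charges; the full-scale per-residue
tables require hundreds of nanoseconds of explicit-solvent MD of the
real complexes, which this package consumes but does not produce.

## Problem sizes used in the shipped analyses

The analysis scripts and tests run the complete pipeline at reduced
scale, chosen to exercise every code path with comfortable margins:
toy complexes of 26–40 atoms, 24–60-frame trajectories, two windows of
8–20 frames per replicate, three replicates, 3–5 enthalpy frames per
window, and 120–240 SASA points; the entropy closed-form checks use
10⁶-sample Gaussian series. The production protocol (5 × 5000-frame
windows, 100 enthalpy frames, three 100-ns replicates) is the package
default in `scan_config()`.

## Known limitations

No Poisson–Boltzmann or surface-GB (igb = 8) solvation; no salt
(Debye–Hückel) screening; no normal-mode or quasi-harmonic entropy; no
separate-trajectory (three-trajectory) variant; no periodic-boundary
re-imaging (frames must contain whole, imaged molecules); non-alanine
mutations are out of scope. Protonation states are taken as given in
the input topology — pocket histidines and ligand formal charges must
be resolved upstream, and the parameter CSV makes every charge
assignment explicit.
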