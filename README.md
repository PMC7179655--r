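# iescan

Computational alanine scanning of protein–ligand MD trajectories with
MM/GBSA energetics and the interaction-entropy (IE) estimator, written
for the kind of question the method was designed to answer: why does an
inhibitor bind one receptor isoform more strongly than a near-identical
one? The motivating system is the selective PARP-1 inhibitor NMS-P118
bound to the catalytic domains of PARP-1 (PDB 5A00) and PARP-2 (PDB
4ZZY), whose binding pockets differ by well under an Angstrom of RMSD
yet differ by a 154-fold Kd ratio.

## The method

For every pocket residue *x* (all protein residues with a heavy atom
within 5 Å of the ligand in the crystal frame), a mutant trajectory is
made from the wild-type trajectory by deleting all sidechain atoms
beyond C&beta; and converting C&beta; into an alanine methyl group (the
&gamma; atom is retained as a hydrogen repositioned at 1.09 Å). The
residue's contribution is the binding free-energy difference

&Delta;&Delta;G<sub>bind</sub><sup>x&rarr;a</sup> =
&Delta;&Delta;G<sub>gas</sub> + &Delta;&Delta;G<sub>sol</sub>

with, per analysis window,

- **gas phase**: &Delta;&Delta;E<sub>vdw</sub> and
  &Delta;&Delta;E<sub>ele</sub> from pairwise Lennard-Jones and Coulomb
  residue–ligand energies (no cutoff; Coulomb constant 332.0636
  kcal·Å/(mol·e²)), plus the entropic term
  &minus;T&Delta;&Delta;S = kT ln&#9001;e<sup>&beta;&Delta;E<sup>a</sup></sup>&#9002; &minus;
  kT ln&#9001;e<sup>&beta;&Delta;E<sup>x</sup></sup>&#9002;,
  the interaction-entropy exponential average over the
  interaction-energy fluctuations of each series (log-sum-exp guarded;
  3-SD single-pass outlier filter);
- **solvation**: &Delta;&Delta;G<sub>gb</sub> from the OBC
  generalized-Born model (igb = 2 constants: offset 0.09 Å, &alpha; = 1.0,
  &beta; = 0.8, &gamma; = 4.85; &epsilon;<sub>out</sub> = 80) with
  residue-class interior dielectrics 1/3/10 for
  nonpolar/polar/charged residues, and &Delta;&Delta;G<sub>np</sub> =
  &gamma;·SASA + &beta; with &gamma; = 0.00542 kcal/(mol·Å²), &beta; = 0.92
  kcal/mol (Shrake–Rupley areas on a deterministic point set).

The production protocol selects five stable non-overlapping 5-ns
windows per 100-ns replicate (three replicates, 15 windows), uses 100
equally spaced frames per window for the enthalpy terms and all 5000
frames for the entropy, and reports mean ± SD across windows. The
total binding free energy is the negated sum of the per-residue
contributions, &Delta;G<sub>bind</sub> = &minus;&Sigma;<sub>x</sub>
&Delta;&Delta;G<sup>x&rarr;a</sup>; residues above 1 kcal/mol are hot
spots.

Alongside the free-energy machinery the package implements the
trajectory analytics used to interpret the scan: Kabsch-superposed
RMSD and 2D-RMSD, isotropic B-factors (8&pi;²/3 &middot; &#9001;&Delta;r²&#9002;),
hydrogen-bond occupancy (donor–acceptor &le; 3.5 Å and donor–H–acceptor
&ge; 120°, averages over all frames), and mass-weighted center-of-mass
distances — plus seeded synthetic generators (toy host–guest
complexes with planted interaction strengths, Gaussian energy series,
planted hydrogen-bond trajectories) so every estimator is testable
without external data.

## Worked example

The numbered scripts under `analysis/` run the study end to end on
synthetic fixtures (`01_simulate.R` → `04_published_comparison.R`),
writing tables under `results/`. The scan step
(`analysis/03_alanine_scan.R`) runs the full pipeline on a 6-residue
toy complex with three jittered replicates and prints:

```
per-residue ddG (kcal/mol), descending:
 Mutation       ddG       ddH      -TddS
      E4A 2.59±0.09 2.71±0.05 -0.12±0.06
      E2A 1.71±0.02 1.80±0.02 -0.09±0.02
      S3A 0.54±0.03 0.59±0.01 -0.05±0.02
      S1A 0.18±0.03 0.21±0.03 -0.03±0.01
      A5A 0.00±0.00 0.00±0.00  0.00±0.00

hot spots (> 1 kcal/mol): E4, E2
residue-sum total dG: -5.013 kcal/mol
window-level summary: dH -5.305, -TdS 0.292, dG -5.013 (+/- 0.101)
Spearman rho, ddG vs planted strengths (all-SER toy): 1.00
IE of Gaussian series: 0.837 kcal/mol (closed form 0.839)
```

Reading the output: the two glutamate-like residues facing the +1
ligand dominate (&Delta;&Delta;G > 1 kcal/mol &rArr; hot spots), the
identity mutation A5A is exactly zero, the ranking of a homogeneous
all-serine complex recovers the planted sidechain strengths
(&rho; = 1), and the entropy estimator reproduces the Gaussian closed
form &sigma;²/(2kT) = 0.839 kcal/mol. The comparison step applies the
same classification and Welch-test machinery to the published
per-residue tables of the two PARP complexes and prints the hot-spot
sets, the 3.04 kcal/mol window-level selectivity against kT ln(154) =
3.00 kcal/mol, and the paired residue differences (e.g. Y889A−Y455A =
0.55 kcal/mol).

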