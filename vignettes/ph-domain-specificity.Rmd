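---
title: "Sequence and structure determinants of PH-domain binding specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence and structure determinants of PH-domain binding specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phspec)
```

## The problem

Pleckstrin-homology (PH) domains are ~100–120-residue modules that target
membranes by binding phosphoinositides or their soluble inositol-phosphate
headgroups. Their sequences are barely alignable (average pairwise identity
around 16%), yet their fold — seven β-strands plus a C-terminal helix — is
highly conserved, and so is the basic, positively charged pocket around the
β1/β2 loop that grips the phosphate groups. Functionally they fall into four
binding-specificity groups: Group 1 binds Ins(1,3,4,5)P4 specifically and
tightly; Group 2 prefers Ins(1,4,5)P3 with severalfold weaker affinity;
Group 3 binds 3-phosphorylated species such as Ins(1,3,4)P3; Group 4 binds
weakly and unspecifically.

`phspec` implements the combined sequence/structure analysis behind that
classification: physicochemical sequence profiles, solvent accessibility and
buried-surface analysis, ligand–protein contact complementarity,
finite-difference Poisson–Boltzmann electrostatics, signature-motif
scanning, and the decision procedure that turns these signals into a group
label. A synthetic-data generator produces labelled PH-like sequences and
toy complexes so that every stage is testable without downloads.

## Sequence profiles

A profile is a sliding-window mean of a per-residue scale. Four scales ship
as editable data files:

* **H** — hydropathy (Kyte–Doolittle),
* **F** — flexibility (Vihinen normalized B-factors),
* **E** — electronic charge concentration (Collantes–Dunn ECI),
* **I** — isotropic surface area (Collantes–Dunn ISA).

The window is truncated at the termini (the mean runs over the residues that
exist; no padding values are invented), and `window = 1` returns the raw
scale. The default window of 9 residues is a conventional smoothing width
for a ~110-residue domain: narrow enough to keep a loop-sized feature
visible, wide enough to suppress single-residue noise. It is an argument
everywhere, with odd values 1–21 sensible. Nonstandard letters (X, B, Z, U,
O) take the scale mean under a logged warning, which keeps profiles defined
without biasing any class. Profiles can be placed onto the columns of a
Pfam-style alignment (Stockholm or aligned FASTA; `-` and `.` gaps are
normalized), and `average_pairwise_identity()` uses the pairwise-deletion
convention — only columns where both rows are non-gap count — because the
published identity figure for this family depends on that convention.

```{r profiles}
h <- load_scale("H")
p <- compute_profile("MKKGDILSNWQRAS", h, window = 5)
round(p$values, 2)
```

## Solvent accessibility

`lee_richards_sasa()` implements the Lee–Richards construction directly:
each probe-expanded sphere (probe 1.4 Å for water) is cut into parallel
slices, the exposed arc of each slice circle is measured against every
neighbouring circle, and arc length × slice thickness is integrated. The
default slice of 0.1 Å puts the isolated-sphere error below 0.5%; halving it
changes a 50-atom cluster total by under 0.2% (a convergence the tests
assert). Radii are a Bondi-style element table (C 1.70, N 1.55, O 1.52,
S/P 1.80, H 1.20 Å), packaged and overridable; crystal structures without
hydrogens are used as they are, with no united-atom inflation — an explicit
choice in favour of a documented radius set over guessing what some legacy
software used.

Exposure fractions divide residue SASA by an empirical Gly-X-Gly
extended-tripeptide maximum (Tien et al. 2013), clipped to [0, 1]. The
empirical set is used rather than the theoretical per-residue maxima because
an actual extended conformation exposes what the empirical table records;
the tests verify that a generated extended Gly-Ala-Gly lands within 10% of
its reference. `delta_sasa()` subtracts complexed from apo areas per residue
(floored at zero) and flags residues burying more than 1 Å² as binding-site
residues; the threshold is a reporting choice, and the flag set can only
shrink as it rises.

NMR entries without an averaged structure contribute their first model;
alternate locations resolve to the highest-occupancy copy (ties to the
first).

## Contact complementarity

For each phosphate group of the ligand (a phosphorus plus its bonded
oxygens, inferred from P–O distances ≤ 1.8 Å; ester oxygens belong to the
phosphate), the accessible surface lost on complexation is attributed to
protein atoms by nearest expanded-surface distance over a deterministic
spherical lattice. Every attributed patch is *legitimate* or *illegitimate*
according to a class-pair table over five atom classes (donor, acceptor,
donor/acceptor, hydrophobic, neutral): hydrophilic–hydrophilic contacts are
legitimate where donor/acceptor pairing holds, hydrophobic–hydrophobic is
legitimate, hydrophilic–hydrophobic is always illegitimate, neutral pairs
with anything. The table is editable data, but a validator rejects any edit
that legalizes hydrophilic–hydrophobic contact — that incompatibility is the
load-bearing chemistry.

Complementarity is `C = S_legit − S_illegit` (Å²). The normalization of
`NC = C / reference_area` is defined here as the group's accessible surface
on the isolated ligand, making NC the net compatibility per unit of
available group surface; the choice is configurable because no unique
normalization is forced by the statistic itself. Single-owner attribution
(rather than pairwise overlap decomposition) makes the partition well
defined and checkable: the tests compare it against a dense-sampling
nearest-owner oracle and require exact conservation of buried area.

## Poisson–Boltzmann electrostatics

`solve_pb()` solves the finite-difference Poisson–Boltzmann equation with
red-black successive over-relaxation (compiled code). Conditions follow the
analysis this package reproduces: solute dielectric 2, a grid extending
20 Å beyond the molecule with 123 points along the longest edge. Solvent
dielectric 80, 0.145 M 1:1 salt and 298 K (fixing the kT/e unit) are
field-standard defaults, all overridable. The dielectric boundary is the
probe-inflated atom envelope (no reentrant surface — a simplification,
stated as such); ionic screening acts only outside it; boundary faces carry
superposed per-charge Debye–Hückel values, which keeps the boundary
condition linear in the charges so that linear-mode solutions superpose.
Charges default to a formal scheme (+1 Lys NZ and Arg CZ, −0.5 per
carboxylate oxygen, charged termini, His neutral) chosen to reproduce the
positive β1/β2 pocket without dragging in a force field. Nonlinear mode
applies local Newton updates to the sinh term and agrees with linear mode
in the weak-field exterior to under 1%. The Born-ion test pins the
absolute scale: exterior potential within 5% (in practice < 1%) of
561·q/(80·d) kT/e. Non-convergence is an error carrying the residual
history, never a silent return.

## Motif and classifier

The 3-phosphate-binding signature motif is a bounded pattern
(`K-x-[SG]-x(6,11)-[KR]-x-R` by default) shipped as an editable pattern
file — the classifier needs *a* deterministic pattern near the β1/β2 loop,
and the file records the provenance without hard-coding the choice.
Unbounded repeats are rejected so every hit has bounded length.

The decision flow runs in fixed order: **motif → hydropathy → charge**.

1. An in-loop motif hit sends the sequence to {1, 3}, otherwise {2, 4}.
2. Within {1, 3}: a smoothed-hydropathy peak in the β1/β2 window at or
   above `tau_hydrophobic_peak` ("a notable hydrophobic peak") gives
   Group 3, else Group 1.
3. Within {2, 4}: a charge-concentration peak below `tau_charge` *and*
   loop hydrophilicity (negated mean smoothed hydropathy — a deliberate
   single-scale operationalization consistent with the H track) below
   `tau_hydrophilic` gives Group 4, else Group 2.

The flow is qualitative in its source; the three thresholds make it
operational. They were calibrated **once** as midpoints between the
synthetic archetype group means (100 cases per group, full effect,
calibration seed 42) and shipped as
`inst/extdata/classifier_defaults.yaml`; the calibration script
(`analysis/03_calibrate_thresholds.R`) regenerates them and asserts the
shipped copy matches. Flexibility and surface-area profiles are computed
and reported but take no part in the default rules, which name only
hydropathy and charge. Every prediction carries an evidence record and a
rule trace; replaying the trace reproduces the label, and the tests assert
the monotonicities the rules imply (raising the hydrophobic threshold can
only turn 3 into 1; lowering the charge threshold never turns 2 into 4).
β1/β2 windows come from configuration (sequence or alignment coordinates),
not from a secondary-structure algorithm — this is a sequence pipeline.

## The synthetic generator

The generator defines the conditions under which the pipeline is evaluated.
Sequences are 110 residues of uniform background (uniform rather than
natural frequencies, to keep contrast fully under the control of one
parameter); the β1/β2 window (positions 9–32, 0-based) is rewritten by
archetype: Groups 1/3 get a literal motif instance at the window start,
with the spacer and window tail hydrophilic/basic (K, R, N, S) for Group 1
or a hydrophobic run (I, L, V, F) in the spacer for Group 3; Group 2 gets a
basic/hydrophilic window without the motif; Group 4 stays near background.
Each archetype letter is used with probability `effect`; at `effect = 0`
all groups are statistically identical (the negative control recovers
~25%), and at `effect = 1` planting is verified — exactly one in-window
match for Groups 1/3, no match anywhere for Groups 2/4, by rejection
sampling. Each case runs on a private stream seeded by (master seed, case
index), so any case regenerates bit-identically and effect levels can be
coupled through a common seed.

Toy complexes pack protein atoms into a sphere (minimum separation 2.4 Å
by rejection) with classes drawn from a configurable composition, realized
through real residue/atom names so the packaged class table applies, and
place a six-carbon-ring ligand with phosphate groups at chosen ring
positions: the C4 substituent faces the protein, C1 points to solvent.
Optional "pockets" add protein atoms of a chosen class around a group at
contact distance. What the toys deliberately do **not** emulate: a real PH
fold, realistic ligand poses, backbone connectivity, or crystallographic
disorder. Passing tests therefore demonstrate the correctness of the
operations (areas, partitions, potentials, decisions), not biological
accuracy on real structures — real-structure conclusions require the PDB
entries as inputs, which the pipeline accepts but does not bundle.

## Numerical choices and problem sizes

The test suite runs at deliberately modest sizes chosen to exercise every
code path: 50-atom clusters for surface-area validation (against a
≥10,000-point sampling oracle), 30-atom toy complexes for contact
attribution (20 random complexes against a ~24,000-point rotated-lattice
oracle, 2% of buried area), the Born ion on the full 123-point grid, grid
refinement compared at 83 vs 165 points, and 400-sequence cohorts for
classifier recovery (≥95% at full effect; ~25% at zero effect). Ties in
owner attribution resolve to the first (lowest-index) protein atom;
coincident atoms collapse to one with a warning; degenerate single-atom
molecules get a 1 Å minimum bounding box before padding.

## Known limitations

* NC values depend on the normalization choice; only the complementarity
  differences `C` are normalization-free, so cross-study NC comparisons
  need care.
* The dielectric boundary is the inflated-sphere envelope, not a molecular
  (reentrant) surface; potentials very close to crevices are smoothed.
* The formal-charge model ignores partial charges and His protonation;
  it is meant for qualitative surface maps, not energetics.
* The classifier consumes one loop window; domains with decisive
  contributions from other loops (e.g. β6/β7) are judged on β1/β2 evidence
  alone.
* Quantum-mechanical ligand descriptors (dipole moments, spatial extents,
  energies) are packaged reference values for reporting context and are
  never recomputed.
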