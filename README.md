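# phspec

Sequence and structure analysis of pleckstrin-homology (PH) domain binding
specificity for inositol phosphates.

PH domains share a conserved seven-stranded fold and a basic β1/β2-loop
pocket but almost no sequence identity, and they split into four functional
groups by what they bind: Group 1 (specific, high-affinity
Ins(1,3,4,5)P4), Group 2 (weaker Ins(1,4,5)P3), Group 3
(3-phosphorylated species incl. Ins(1,3,4)P3), Group 4 (low affinity,
little specificity). `phspec` is an R package for the combined analysis
that explains and predicts this split, aimed at structural
bioinformaticians and anyone annotating PH domains from sequence:

* **Sequence profiles** — sliding-window means of hydropathy (H,
  Kyte–Doolittle), flexibility (F), electronic charge concentration (E)
  and isotropic surface area (I), mappable onto Pfam-style alignments
  (Stockholm / aligned FASTA).
* **Solvent accessibility** — a Lee–Richards slicing implementation
  (probe 1.4 Å), residue exposure fractions against Gly-X-Gly reference
  maxima, and apo-vs-complex buried surface with binding-site flags.
* **Contact complementarity** — per-phosphate-group partition of buried
  ligand surface into *legitimate* and *illegitimate* contacts by atom
  hydropathy classes, with complementarity `C = S_legit − S_illegit` (Å²)
  and normalized complementarity `NC = C / reference area`.
* **Electrostatics** — a finite-difference Poisson–Boltzmann solver
  (solute dielectric 2, grid 20 Å beyond the molecule, 123 points along
  the longest edge, potentials in kT/e; compiled SOR kernel) with
  per-atom surface potentials and OpenDX export.
* **Classification** — signature-motif scan (3-phosphate-binding pattern)
  plus profile thresholds, implementing the decision flow
  motif → hydropathy → charge that assigns Groups 1–4, with a replayable
  rule trace per prediction.
* **Synthetic data** — a generator of labelled PH-like sequences and toy
  protein–ligand complexes, so the entire pipeline is testable offline.

## Worked example

Classify synthetic PH-like sequences and inspect the evidence:

```r
library(phspec)

cases <- generate_sequence_set(n_per_group = 2, effect = 1, seed = 1)
seqs  <- setNames(vapply(cases, `[[`, "", "sequence"),
                  vapply(cases, `[[`, "", "case_id"))
classify_sequences(seqs, loop_window = cases[[1]]$loop_window)
```

```
       id group motif_hit loop_H_max loop_E_max loop_hydrophilicity
1 g1_r001     1      TRUE -2.0111111  1.0966667          2.78611111
2 g1_r002     1      TRUE -0.7666667  1.3511111          2.71111111
3 g2_r001     2     FALSE -1.5000000  1.2188889          2.84398148
4 g2_r002     2     FALSE -0.6222222  1.2222222          2.48425926
5 g3_r001     3      TRUE  3.4555556  0.7233333         -0.24537037
6 g3_r002     3      TRUE  3.9000000  1.1711111         -0.03796296
7 g4_r001     4     FALSE -0.3444444  0.8022222          1.07314815
8 g4_r002     4     FALSE  1.4555556  0.8055556          0.15092593
```

Groups 1/3 carry an in-loop motif hit and are split by the β1/β2
hydropathy peak (`loop_H_max` ≥ 0.99 ⇒ Group 3); motif-less sequences are
split by the charge-concentration peak and loop hydrophilicity (both low ⇒
Group 4). Contact analysis of a toy complex mirrors the published table
layout:

```r
tc <- generate_toy_complex(seed = 1,
        ligand_spec = list(phosphate_positions = c(1, 3, 4, 5), offset = 2),
        class_probs = c(donor = 0.5, donor_acceptor = 0.2, neutral = 0.3))
print(contact_report(tc$structure), digits = 4)
```

```
  group S_legit S_illegit     C     NC reference_area
1    P1    0.00         0  0.00 0.0000          137.8
2    P3   41.09         0 41.09 0.3429          119.8
3    P4   93.38         0 93.38 0.8846          105.6
4    P5   37.30         0 37.30 0.3020          123.5
```

The solvent-facing C1-analogue group buries nothing and has the lowest NC;
the protein-facing C4 group buries the most compatible surface.

## Analysis workflow

The `analysis/` scripts run the study end to end on generated data, each a
thin driver over the package:

1. `01_simulate.R` — 400 labelled sequences + 5 toy complexes
2. `02_profiles.R` — H/F/E/I profiles, loop-window group means
3. `03_calibrate_thresholds.R` — the one-off threshold calibration
4. `04_classify.R` — predictions, confusion table, effect-size sweep
5. `05_structure_contacts.R` — SASA, buried surface, contact tables
6. `06_electrostatics.R` — Born validation + surface potentials

Outputs land under `results/` (bulky grids and full tables under
`scratch/`). `run_pipeline()` provides the same flow as one configurable
call for user-supplied FASTA/alignment/PDB inputs.

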