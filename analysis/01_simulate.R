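#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 100 labelled PH-like sequences per
# binding-specificity group at full archetype strength, plus a handful of
# toy protein-ligand complexes exercising the structural stages.
# Outputs: results/synthetic/{cases.fa,labels.tsv,toy_*.pdb}

suppressPackageStartupMessages(library(phspec))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cases <- generate_sequence_set(n_per_group = 100, effect = 1, seed = 1)
seqs <- setNames(vapply(cases, `[[`, "", "sequence"),
                 vapply(cases, `[[`, "", "case_id"))
write_fasta(seqs, file.path(out, "cases.fa"))
labels <- data.frame(
  id = names(seqs),
  true_group = vapply(cases, `[[`, 1L, "true_group"),
  loop_start = vapply(cases, function(c) c$loop_window[1], 0L),
  loop_end = vapply(cases, function(c) c$loop_window[2], 0L))
write.table(labels, file.path(out, "labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", length(seqs), "sequences;",
    "group sizes:", paste(table(labels$true_group), collapse = "/"), "\n")

# toy complexes with a basic, hydrogen-bond-donor-rich contact surface,
# emulating the Lys/Arg-lined phosphate pockets of PH domains
for (seed in 1:5) {
  tc <- generate_toy_complex(
    seed = seed,
    ligand_spec = list(phosphate_positions = c(1, 3, 4, 5), offset = 2),
    class_probs = c(donor = 0.5, donor_acceptor = 0.2, neutral = 0.3),
    pockets = list(list(group = "P4", class = "donor", n = 5,
                        distance = 3.4)))
  write_structure_pdb(tc$structure,
                      file.path(out, sprintf("toy_%02d.pdb", seed)))
}
cat("wrote 5 toy complexes (Ins(1,3,4,5)P4-like ligand, resname IPT)\n")
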