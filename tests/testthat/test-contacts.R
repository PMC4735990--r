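test_that("atom classes follow the chemistry table", {
  st <- make_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                       element = c("N", "C", "N"),
                       atom_name = c("NZ", "CD1", "ND2"),
                       residue_name = c("LYS", "LEU", "ASN"),
                       residue_seq_id = 1:3)
  cls <- classify_atoms(st)
  expect_equal(cls, c("donor", "hydrophobic", "donor"))

  lig <- make_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(5, 0, 0),
                              c(6.4, 0, 0)),
                        element = c("P", "O", "O", "C"),
                        atom_name = c("P1", "O11", "O6", "C6"),
                        residue_name = "IPT", residue_seq_id = 1L,
                        is_hetero = TRUE)
  cls <- classify_atoms(lig)
  expect_equal(cls, c("neutral", "acceptor", "donor_acceptor",
                      "hydrophobic"))

  unk <- make_structure(matrix(0, 1, 3), element = "C", atom_name = "QQ7",
                        residue_name = "UNK")
  expect_warning(cu <- classify_atoms(unk), "neutral")
  expect_equal(cu, "neutral")
})

test_that("the legitimacy matrix validator enforces the
           hydrophilic-hydrophobic rule", {
  m <- legitimacy_matrix()
  expect_true(all(m[c("donor", "acceptor", "donor_acceptor"),
                    "hydrophobic"] == 0))
  expect_equal(m["donor", "acceptor"], 1, ignore_attr = TRUE)
  bad <- tempfile(fileext = ".tsv")
  m2 <- m
  m2["donor", "hydrophobic"] <- 1  # marked legitimate (symmetrically)
  m2["hydrophobic", "donor"] <- 1
  utils::write.table(cbind(class = rownames(m2), as.data.frame(m2)), bad,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(legitimacy_matrix(bad), "illegitimate")
})

test_that("phosphate group inference matches the ligand topology", {
  tc4 <- generate_toy_complex(seed = 71,
                              ligand_spec = list(
                                phosphate_positions = c(1, 3, 4, 5),
                                offset = 3))
  g4 <- define_phosphate_groups(tc4$structure)
  expect_setequal(names(g4), c("P1", "P3", "P4", "P5"))
  expect_true(all(vapply(g4, function(g) length(g$atoms), 0L) == 5L))

  tc3 <- generate_toy_complex(seed = 72,
                              ligand_spec = list(
                                phosphate_positions = c(1, 4, 5),
                                offset = 3))
  g3 <- define_phosphate_groups(tc3$structure)
  expect_setequal(names(g3), c("P1", "P4", "P5"))

  # ester O (bonded to both C and P) belongs to the phosphate group
  a <- tc4$structure$atoms
  ester <- which(a$atom_name == "O1" & a$is_hetero)
  expect_true(ester %in% g4$P1$atoms)
  # hydroxyl oxygens form their own groups on request
  gh <- define_phosphate_groups(tc4$structure, include_hydroxyls = TRUE)
  expect_true("C2-OH" %in% names(gh))
  expect_length(gh[["C2-OH"]]$atoms, 1L)
})

test_that("a lone phosphorus with too few oxygens still forms a group,
           with a warning", {
  st <- make_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(40, 0, 0)),
                       element = c("P", "O", "C"),
                       atom_name = c("P2", "O21", "CA"),
                       residue_name = c("IPT", "IPT", "GLY"),
                       residue_seq_id = c(1, 1, 2),
                       is_hetero = c(TRUE, TRUE, FALSE))
  expect_warning(g <- define_phosphate_groups(st), "only 1")
  expect_equal(names(g), "P2")
})

test_that("complementarity is the exact difference of contact areas", {
  expect_equal(complementarity(31.3, 10.6), 20.7)
  expect_equal(complementarity(114.8, 8.5), 106.3)
  expect_equal(complementarity(0, 0), 0)
  expect_error(complementarity(-1, 0))
  expect_equal(normalized_complementarity(0, 50), 0)
  expect_equal(normalized_complementarity(50, 50), 1)
  expect_error(normalized_complementarity(10, 0), "positive")
})

test_that("distant ligands contribute no contact surface", {
  tc <- generate_toy_complex(seed = 73,
                             ligand_spec = list(
                               phosphate_positions = c(1, 4), offset = 25))
  rep3 <- contact_report(tc$structure)
  expect_true(all(rep3$S_legit == 0))
  expect_true(all(rep3$S_illegit == 0))
  expect_true(all(rep3$C == 0))
})

test_that("an all-donor environment yields no illegitimate contact for a
           hydrophilic group", {
  # single phosphate group pocketed by donors only
  tc <- generate_toy_complex(
    n_protein_atoms = 10, seed = 74,
    ligand_spec = list(phosphate_positions = 4, offset = 12),
    class_probs = c(donor = 1),
    pockets = list(list(group = "P4", class = "donor", n = 8,
                        distance = 3.4)))
  classes <- classify_atoms(tc$structure)
  groups <- define_phosphate_groups(tc$structure)
  s <- contact_surfaces(groups$P4, tc$structure, classes)
  expect_gt(s[["S_legit"]], 0)
  expect_equal(s[["S_illegit"]], 0)
})

test_that("three-atom toy partition matches the dense-sampling owner
           oracle", {
  # one ligand O equidistant between a donor (Lys NZ) and a hydrophobic
  # (Leu CD1) protein atom
  st <- make_structure(rbind(c(-2.6, 0, 0), c(2.6, 0, 0), c(0, 0, 0)),
                       element = c("N", "C", "O"),
                       atom_name = c("NZ", "CD1", "O41"),
                       residue_name = c("LYS", "LEU", "IPT"),
                       residue_seq_id = c(1, 2, 3),
                       is_hetero = c(FALSE, FALSE, TRUE))
  classes <- classify_atoms(st)
  grp <- list(label = "P4", atoms = 3L)
  s <- contact_surfaces(grp, st, classes, slice_spacing = 0.05)
  set.seed(75)
  oracle <- contact_oracle(st, classes, n_points = 20000L)
  expect_gt(s[["S_legit"]], 0)
  expect_gt(s[["S_illegit"]], 0)
  tol <- 0.02 * oracle$buried
  expect_lt(abs(s[["S_legit"]] - oracle$S_legit), tol)
  expect_lt(abs(s[["S_illegit"]] - oracle$S_illegit), tol)
})

test_that("attributed area conserves buried area exactly", {
  set.seed(80)
  for (seed in 81:85) {
    tc <- generate_toy_complex(seed = seed,
                               ligand_spec = list(
                                 phosphate_positions = c(1, 3, 4, 5),
                                 offset = stats::runif(1, 1, 4)))
    st <- tc$structure
    classes <- classify_atoms(st)
    groups <- define_phosphate_groups(st)
    iso <- lee_richards_sasa(st, 1.4, 0.1, include = st$atoms$is_hetero)
    cpx <- lee_richards_sasa(st, 1.4, 0.1)
    lig <- which(st$atoms$is_hetero)
    for (g in groups) {
      s <- contact_surfaces(g, st, classes)
      buried <- sum(pmax(0, iso$atoms$area[match(g$atoms, lig)] -
                            cpx$atoms$area[g$atoms]))
      expect_equal(s[["S_legit"]] + s[["S_illegit"]], buried,
                   tolerance = 1e-9)
      expect_equal(complementarity(s[["S_legit"]], s[["S_illegit"]]),
                   s[["S_legit"]] - s[["S_illegit"]])
    }
  }
})

test_that("a solvent-pointing C1-analogue group has the minimum NC", {
  # C4 substituent faces the protein; C1 points into solvent by
  # construction, so P1 buries the least compatible surface
  tc <- generate_toy_complex(
    n_protein_atoms = 30, seed = 86,
    ligand_spec = list(phosphate_positions = c(1, 3, 4, 5), offset = 1.5),
    class_probs = c(donor = 0.7, neutral = 0.3),
    pockets = list(list(group = "P4", class = "donor", n = 6,
                        distance = 3.4)))
  rep3 <- contact_report(tc$structure)
  p1 <- rep3$NC[rep3$group == "P1"]
  expect_equal(min(rep3$NC), p1)
})
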