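test_that("isolated and disjoint spheres match the closed forms", {
  st1 <- make_structure(matrix(0, 1, 3), "C")  # r = 1.7, probe 1.4
  s1 <- lee_richards_sasa(st1, probe = 1.4, slice_spacing = 0.1)
  expect_equal(s1$atoms$area, 4 * pi * 3.1^2, tolerance = 0.005)
  st2 <- make_structure(rbind(c(0, 0, 0), c(10, 0, 0)), "C")
  s2 <- lee_richards_sasa(st2, probe = 1.4, slice_spacing = 0.1)
  expect_equal(sum(s2$atoms$area), 2 * 4 * pi * 3.1^2, tolerance = 0.005)
})

test_that("two intersecting equal spheres match the spherical-cap formula", {
  st <- make_structure(rbind(c(0, 0, 0), c(3, 0, 0)), "C")
  s <- lee_richards_sasa(st, probe = 1.4, slice_spacing = 0.05)
  analytic <- two_sphere_cap_area(3.1, 3.0)
  expect_equal(s$atoms$area[1], analytic, tolerance = 0.005)
  expect_equal(s$atoms$area[2], analytic, tolerance = 0.005)
})

test_that("a 50-atom packed cluster agrees with a dense-sampling oracle", {
  st <- random_cluster(50, spread = 5, seed = 61)
  s <- lee_richards_sasa(st, probe = 1.4, slice_spacing = 0.1)
  set.seed(62)
  oracle <- sr_sasa_oracle(st, probe = 1.4, n_points = 10000L)
  expect_equal(sum(s$atoms$area), sum(oracle), tolerance = 0.01)
})

test_that("SASA is monotone under approach, convergent under refinement,
           and rigid-motion invariant", {
  areas <- vapply(c(8, 6, 5, 4, 3.2, 2.5), function(d) {
    st <- make_structure(rbind(c(0, 0, 0), c(d, 0, 0)), "C")
    sum(lee_richards_sasa(st, 1.4, 0.1)$atoms$area)
  }, 0)
  expect_true(all(diff(areas) <= 1e-9))

  st <- random_cluster(50, spread = 5, seed = 63)
  t1 <- sum(lee_richards_sasa(st, 1.4, 0.1)$atoms$area)
  t2 <- sum(lee_richards_sasa(st, 1.4, 0.05)$atoms$area)
  expect_lt(abs(t2 - t1) / t1, 0.002)

  # rotate + translate
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz2 <- atom_xyz(st) %*% t(Rz)
  xyz2 <- sweep(xyz2, 2, c(5, -3, 11), `+`)
  st2 <- st
  st2$atoms[, c("x", "y", "z")] <- xyz2
  t3 <- sum(lee_richards_sasa(st2, 1.4, 0.1)$atoms$area)
  expect_equal(t3, t1, tolerance = 1e-6)
})

test_that("per-residue areas are exact sums of their atoms", {
  st <- random_cluster(40, spread = 5, seed = 64)
  s <- lee_richards_sasa(st, 1.4, 0.1)
  expect_equal(sum(s$atoms$area), sum(s$per_residue$area), tolerance = 1e-9)
  one <- s$per_residue$area[1]
  key <- s$atoms$residue_seq_id == s$per_residue$residue_seq_id[1]
  expect_equal(sum(s$atoms$area[key]), one, tolerance = 1e-9)
})

test_that("coincident atoms collapse to one with a warning", {
  st <- make_structure(rbind(c(0, 0, 0), c(0, 0, 0)), "C")
  expect_warning(s <- lee_richards_sasa(st, 1.4, 0.1), "coincident")
  expect_equal(sum(s$atoms$area), 4 * pi * 3.1^2, tolerance = 0.005)
})

test_that("exposure fractions clip, flag unknown residues, and agree with
           the reference on an extended tripeptide", {
  st <- gly_x_gly("ALA")
  s <- lee_richards_sasa(st, 1.4, 0.05)
  ef <- exposure_fractions(s)
  ala <- ef[ef$residue_name == "ALA", ]
  raw <- ala$area / ala$reference
  expect_true(raw >= 0.9 && raw <= 1.1)

  # clipping and unknown handling on a synthetic per-residue table
  fake <- s
  fake$per_residue$area <- fake$per_residue$area * 2
  ef2 <- exposure_fractions(fake)
  expect_true(all(ef2$fraction <= 1))
  fake$per_residue$residue_name[1] <- "XXX"
  expect_warning(ef3 <- exposure_fractions(fake), "XXX")
  expect_true(is.na(ef3$fraction[1]))
  expect_false(ef3$known[1])
})

test_that("buried area flags only the contacted residue and the flag
           threshold is monotone", {
  # protein: three well-separated residues on a line; ligand sphere sits on
  # residue 2 only
  prot <- make_structure(rbind(c(0, 0, 0), c(12, 0, 0), c(24, 0, 0)),
                         element = "C", atom_name = "CA",
                         residue_name = "GLY", residue_seq_id = 1:3)
  lig <- make_structure(matrix(c(12, 4.5, 0), 1), element = "P",
                        atom_name = "P1", residue_name = "IPT",
                        residue_seq_id = 4L, is_hetero = TRUE)
  cplx <- make_structure(rbind(atom_xyz(prot), atom_xyz(lig)),
                         element = c("C", "C", "C", "P"),
                         atom_name = c("CA", "CA", "CA", "P1"),
                         residue_name = c(rep("GLY", 3), "IPT"),
                         residue_seq_id = c(1:3, 4L),
                         is_hetero = c(rep(FALSE, 3), TRUE))
  apo <- lee_richards_sasa(cplx, 1.4, 0.05, include = !cplx$atoms$is_hetero)
  cpx <- lee_richards_sasa(cplx, 1.4, 0.05)
  ds <- delta_sasa(apo, cpx)
  expect_equal(ds$binding_site, c(FALSE, TRUE, FALSE))
  expect_equal(ds$buried[c(1, 3)], c(0, 0), tolerance = 1e-9)

  # ligand removed: identical atom sets, zero burial
  ds0 <- delta_sasa(apo, apo)
  expect_true(all(ds0$buried == 0))
  expect_false(any(ds0$binding_site))

  # raising the threshold never adds flagged residues
  flags <- vapply(c(0.1, 1, 5, 20, 100),
                  function(th) sum(delta_sasa(apo, cpx, th)$binding_site), 0)
  expect_true(all(diff(flags) <= 0))
})

test_that("delta_sasa rejects mismatched atom sets, naming orphans", {
  st <- random_cluster(8, spread = 6, seed = 65)
  s1 <- lee_richards_sasa(st, 1.4, 0.1)
  st2 <- subset_structure(st, 1:7)
  s2 <- lee_richards_sasa(st2, 1.4, 0.1)
  expect_error(delta_sasa(s1, s2), "orphan")
})
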