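poly_gly <- function(nres = 3) {
  # one N, CA, C, O per residue plus OXT on the last, spaced apart
  xyz <- NULL; nm <- c(); el <- c(); rs <- c()
  for (r in seq_len(nres)) {
    base <- c((r - 1) * 6, 0, 0)
    xyz <- rbind(xyz, base, base + c(1.5, 0, 0), base + c(3, 0, 0),
                 base + c(3, 1.3, 0))
    nm <- c(nm, "N", "CA", "C", "O")
    el <- c(el, "N", "C", "C", "O")
    rs <- c(rs, rep(r, 4))
  }
  xyz <- rbind(xyz, c((nres - 1) * 6 + 4.2, -1, 0))
  nm <- c(nm, "OXT"); el <- c(el, "O"); rs <- c(rs, nres)
  make_structure(xyz, element = el, atom_name = nm, residue_name = "GLY",
                 residue_seq_id = rs)
}

test_that("the formal charge scheme places charges on termini and
           ionizable side chains", {
  pg <- poly_gly(3)
  q <- assign_charges(pg)
  expect_equal(sum(q), 0)                      # +1 N-term, 2 x -0.5 C-term
  expect_equal(q[pg$atoms$atom_name == "N" &
                 pg$atoms$residue_seq_id == 1], 1)

  lys <- make_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0),
                              c(3, 1.3, 0), c(4.2, -1, 0), c(1.5, 2, 0)),
                        element = c("N", "C", "C", "O", "O", "N"),
                        atom_name = c("N", "CA", "C", "O", "OXT", "NZ"),
                        residue_name = "LYS", residue_seq_id = 1L)
  expect_equal(sum(assign_charges(lys)), 1)    # side chain +1, termini 0

  # table scheme: missing atoms get 0 with a warning
  tabf <- tempfile()
  writeLines("GLY\tN\t0.25", tabf)
  expect_warning(qt <- assign_charges(pg, tabf), "missing")
  expect_equal(sum(qt), 0.25 * 3)
})

test_that("grid geometry follows the stated spacing arithmetic", {
  st <- make_structure(rbind(c(0, 0, 0), c(40, 0, 0)), "C")
  g <- build_grid(st, padding = 20, n_longest = 123L)
  expect_equal(g$spacing, 80 / 122)
  expect_equal(g$dims[1], 123L)
  # single atom, zero padding: grid still covers a 1 A minimum box
  g0 <- build_grid(make_structure(matrix(0, 1, 3), "C"), padding = 0,
                   n_longest = 33L)
  expect_true(all(g0$dims >= 2L))
  # atoms sit inside the interior with at least padding - spacing clearance
  set.seed(91)
  st2 <- random_cluster(20, spread = 6, seed = 91)
  g2 <- build_grid(st2, padding = 10, n_longest = 61L)
  lo <- g2$origin
  hi <- g2$origin + (g2$dims - 1) * g2$spacing
  xyz <- atom_xyz(st2)
  m <- 10 - g2$spacing
  expect_true(all(sweep(xyz, 2, lo) >= m - 1e-9))
  expect_true(all(sweep(-xyz, 2, hi, `+`) >= m - 1e-9))
  expect_error(build_grid(st2, padding = 10, n_longest = 31L), "odd")
  expect_error(build_grid(st2, padding = 10, n_longest = 62L), "odd")
})

test_that("zero charge gives an identically zero potential", {
  st <- make_structure(matrix(0, 1, 3), "C")
  g <- solve_pb(st, charges = 0, ionic_strength = 0.145, mode = "nonlinear",
                padding = 8, n_longest = 33L)
  expect_true(all(g$potential == 0))
})

test_that("the Born ion reproduces the Coulomb closed form in the exterior
           dielectric", {
  st <- make_structure(matrix(0, 1, 3), "C")
  st$atoms$vdw_radius <- 2.0
  g <- solve_pb(st, charges = 1, eps_solute = 2, eps_solvent = 80,
                ionic_strength = 0, mode = "linear", padding = 20,
                n_longest = 83L, tol = 1e-5)
  # e^2/(4 pi eps0 kT A) at 298 K, recomputed here as the oracle constant
  Ckt <- (1.602176634e-19)^2 /
    (4 * pi * 8.8541878128e-12 * 1.380649e-23 * 298) * 1e10
  expect_equal(Ckt, 561.0, tolerance = 0.001)
  for (d in c(6, 9, 12)) {
    v <- mean(grid_interpolate(g, rbind(c(d, 0, 0), c(-d, 0, 0),
                                        c(0, d, 0), c(0, 0, d))))
    expect_equal(v, Ckt / (80 * d), tolerance = 0.05)
  }
  # every surface sample of a positive ion is positive
  sp <- surface_potential(st, g)
  expect_true(all(sp$mean_potential > 0))
})

test_that("linear solutions superpose within solver tolerance", {
  st <- make_structure(rbind(c(-3, 0, 0), c(3, 0, 0)), "C")
  base <- build_grid(st, padding = 12, n_longest = 61L)
  solve2 <- function(q) solve_pb(st, q, grid = base, eps_solute = 2,
                                 eps_solvent = 80, ionic_strength = 0.1,
                                 mode = "linear", tol = 1e-7)
  g1 <- solve2(c(1, 0))
  g2 <- solve2(c(0, -1))
  g12 <- solve2(c(1, -1))
  expect_equal(g12$potential, g1$potential + g2$potential,
               tolerance = 1e-3)
})

test_that("nonlinear and linear solutions agree in the weak-field limit", {
  # the sinh term acts only in the ionic (solvent) region, so the
  # weak-field comparison is made on exterior sample points
  st <- make_structure(matrix(0, 1, 3), "C")
  gl <- solve_pb(st, charges = 0.01, eps_solute = 2, eps_solvent = 80,
                 ionic_strength = 0.145, mode = "linear", padding = 10,
                 n_longest = 41L, tol = 1e-8)
  gn <- solve_pb(st, charges = 0.01, eps_solute = 2, eps_solvent = 80,
                 ionic_strength = 0.145, mode = "nonlinear", padding = 10,
                 n_longest = 41L, tol = 1e-8)
  pts <- as.matrix(expand.grid(x = c(-8, -5, 5, 8), y = c(-5, 0, 5),
                               z = c(-5, 0, 5)))
  vl <- grid_interpolate(gl, pts)
  vn <- grid_interpolate(gn, pts)
  expect_lt(max(abs(vl)), 0.2)
  expect_lt(max(abs(vn - vl)), 0.01 * max(abs(vl)))
})

test_that("grid refinement leaves exterior potentials stable and the
           surface patch near a buried positive charge is positive", {
  st <- make_structure(matrix(0, 1, 3), "C")
  st$atoms$vdw_radius <- 2.0
  pts <- rbind(c(7, 0, 0), c(0, 8, 0), c(0, 0, 9))
  vs <- lapply(c(83L, 165L), function(n) {
    g <- solve_pb(st, 1, eps_solute = 2, eps_solvent = 80,
                  ionic_strength = 0, mode = "linear", padding = 20,
                  n_longest = n, tol = 1e-5)
    grid_interpolate(g, pts)
  })
  expect_equal(vs[[2]], vs[[1]], tolerance = 0.03)
})

test_that("interpolation is exact at grid nodes and excludes points
           outside the grid", {
  st <- make_structure(matrix(0, 1, 3), "C")
  g <- solve_pb(st, 1, mode = "linear", padding = 8, n_longest = 33L,
                ionic_strength = 0)
  i <- c(5L, 10L, 17L)
  nodes <- cbind(g$origin[1] + (i - 1) * g$spacing, g$origin[2],
                 g$origin[3])
  v <- grid_interpolate(g, nodes)
  expect_equal(v, g$potential[cbind(i, 1L, 1L)], tolerance = 1e-12)
  expect_true(is.na(grid_interpolate(g, matrix(c(1e4, 0, 0), 1))))
  far <- make_structure(matrix(c(1e3, 0, 0), 1), "C")
  expect_warning(surface_potential(far, g), "outside")
})

test_that("OpenDX export carries the grid geometry and data count", {
  st <- make_structure(matrix(0, 1, 3), "C")
  g <- solve_pb(st, 1, mode = "linear", padding = 6, n_longest = 33L,
                ionic_strength = 0)
  p <- tempfile(fileext = ".dx")
  write_opendx(g, p)
  lines <- readLines(p)
  expect_true(any(grepl(sprintf("counts %d %d %d", g$dims[1], g$dims[2],
                                g$dims[3]), lines)))
  datal <- grep("data follows", lines)
  nvals <- length(scan(p, skip = datal, nlines = ceiling(prod(g$dims) / 3),
                       quiet = TRUE))
  expect_equal(nvals, prod(g$dims))
})
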