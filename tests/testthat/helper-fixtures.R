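# Fixture builders (all generated in code; nothing on disk).

# write a temporary scale file covering the 20 amino acids, with selected
# letters overridden
write_scale_file <- function(values = c(), default = 0) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  v <- stats::setNames(rep(default, 20), aa)
  v[names(values)] <- values
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(names(v), v, sep = "\t"), path)
  path
}

toy_scale <- function(values = c(), default = 0) {
  load_scale(write_scale_file(values, default))
}

# minimal two-model NMR-style PDB text
two_model_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       9.000   9.000   9.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       9.000   9.000  10.458  1.00  0.00           C",
    "ENDMDL",
    "END"), path)
  path
}

altloc_pdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60  0.00           N",
    "ATOM      2  N  BALA A   1       0.500   0.000   0.000  0.40  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A   2       8.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  path
}

# natural-extension-reference-frame placement: atom D from A-B-C with
# bond |CD|, angle BCD, dihedral ABCD (degrees)
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- (c - b) / sqrt(sum((c - b)^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# extended Gly-X-Gly tripeptide (heavy backbone + CB for X = ALA)
gly_x_gly <- function(x_res = "ALA") {
  # seed the first residue
  n1 <- c(0, 0, 0)
  ca1 <- c(1.458, 0, 0)
  c1 <- nerf_place(c(-1, 1, 0), n1, ca1, 1.525, 111.0, 180)
  o1 <- nerf_place(n1, ca1, c1, 1.231, 120.8, 0)
  coords <- list(n1, ca1, c1, o1)
  names <- c("N", "CA", "C", "O")
  res <- c(1, 1, 1, 1)
  prevN <- n1; prevCA <- ca1; prevC <- c1
  for (r in 2:3) {
    n <- nerf_place(prevN, prevCA, prevC, 1.329, 116.2, 180)   # psi
    ca <- nerf_place(prevCA, prevC, n, 1.458, 121.7, 180)      # omega
    cc <- nerf_place(prevC, n, ca, 1.525, 111.0, 180)          # phi
    o <- nerf_place(n, ca, cc, 1.231, 120.8, if (r < 3) 0 else 0)
    coords <- c(coords, list(n, ca, cc, o))
    names <- c(names, "N", "CA", "C", "O")
    res <- c(res, rep(r, 4))
    if (r == 2 && x_res != "GLY") {
      cb <- nerf_place(cc, n, ca, 1.530, 110.4, -122.5)
      coords <- c(coords, list(cb))
      names <- c(names, "CB")
      res <- c(res, 2)
    }
    prevN <- n; prevCA <- ca; prevC <- cc
  }
  xyz <- do.call(rbind, coords)
  resnames <- c("GLY", x_res, "GLY")[res]
  elem <- substr(names, 1, 1)
  make_structure(xyz, element = elem, atom_name = names,
                 residue_name = resnames, residue_seq_id = res)
}
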