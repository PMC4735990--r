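# e^2 / (4 pi eps0 kT Angstrom) at 298 K: Coulomb constant when potential
# is in kT/e, charge in e, length in Angstrom
coulomb_kt <- function(temperature = 298) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kT <- 1.380649e-23 * temperature
  e^2 / (4 * pi * eps0 * kT) * 1e10
}

# Debye kappa^2 in 1/Angstrom^2 for a 1:1 electrolyte
debye_kappa2 <- function(ionic_strength, eps_solvent, temperature = 298) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kT <- 1.380649e-23 * temperature
  NA_ <- 6.02214076e23
  # 2 * NA * e^2 * I[mol/m^3] / (eps0 * eps_r * kT), converted to A^-2
  2 * NA_ * e^2 * ionic_strength * 1000 / (eps0 * eps_solvent * kT) * 1e-20
}

#' Assign per-atom partial charges
#'
#' The default `formal` scheme places integer/half-integer formal charges
#' on ionizable groups: +1 on Lys NZ and Arg CZ, -0.5 on each Asp OD1/OD2
#' and Glu OE1/OE2 oxygen, +1 on each chain's N-terminal N, -0.5 on each
#' C-terminal carboxylate oxygen (O/OXT), His neutral. The `table` scheme
#' reads per-(residue, atom) charges from a whitespace-delimited file
#' (residue_name, atom_name, charge); atoms absent from the table get 0
#' with a warning.
#'
#' @param structure a `ph_structure`.
#' @param scheme `"formal"` or a charge-table file path.
#' @return numeric vector of charges (elementary units), one per atom,
#'   with attribute `scheme`.
#' @export
assign_charges <- function(structure, scheme = "formal") {
  a <- structure$atoms
  q <- numeric(nrow(a))
  if (identical(scheme, "formal")) {
    q[a$residue_name == "LYS" & a$atom_name == "NZ"] <- 1
    q[a$residue_name == "ARG" & a$atom_name == "CZ"] <- 1
    q[a$residue_name == "ASP" & a$atom_name %in% c("OD1", "OD2")] <- -0.5
    q[a$residue_name == "GLU" & a$atom_name %in% c("OE1", "OE2")] <- -0.5
    prot <- which(!a$is_hetero)
    for (ch in unique(a$chain_id[prot])) {
      idx <- prot[a$chain_id[prot] == ch]
      resids <- a$residue_seq_id[idx]
      first <- idx[resids == min(resids)]
      last <- idx[resids == max(resids)]
      q[first[a$atom_name[first] == "N"]] <-
        q[first[a$atom_name[first] == "N"]] + 1
      term_o <- last[a$atom_name[last] %in% c("O", "OXT")]
      q[term_o] <- q[term_o] - 0.5
    }
  } else {
    tab <- utils::read.table(scheme, comment.char = "#",
                             col.names = c("residue_name", "atom_name",
                                           "charge"),
                             colClasses = c("character", "character",
                                            "numeric"))
    key <- paste(a$residue_name, a$atom_name)
    hit <- match(key, paste(tab$residue_name, tab$atom_name))
    if (anyNA(hit)) {
      warning(sum(is.na(hit)), " atom(s) missing from charge table, ",
              "charge 0 assigned")
    }
    q <- ifelse(is.na(hit), 0, tab$charge[hit])
  }
  attr(q, "scheme") <- if (identical(scheme, "formal")) "formal" else scheme
  q
}

#' Build the finite-difference grid geometry
#'
#' Cubic voxels; the longest padded box edge receives exactly `n_longest`
#' points, fixing the spacing, and the other dimensions are sized to cover
#' their padded edges at the same spacing. The grid is centred on the
#' molecule.
#'
#' @param structure a `ph_structure`.
#' @param padding clearance beyond the molecular bounding box on every
#'   face, Angstrom (20 reproduces the analysis conditions).
#' @param n_longest odd grid-point count (>= 33) along the longest edge
#'   (123 reproduces the analysis conditions).
#' @return a `pb_grid`: list with `origin`, `spacing`, `dims` and empty
#'   `potential`.
#' @export
build_grid <- function(structure, padding = 20, n_longest = 123L) {
  stopifnot(padding >= 0)
  n_longest <- as.integer(n_longest)
  if (n_longest < 33L || n_longest %% 2L == 0L) {
    stop("n_longest must be odd and >= 33")
  }
  xyz <- atom_xyz(structure)
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  edges <- pmax(hi - lo, 1.0)  # degenerate molecules get a 1 A box
  h <- (max(edges) + 2 * padding) / (n_longest - 1L)
  dims <- ifelse(edges == max(edges), n_longest,
                 pmax(2L, ceiling((edges + 2 * padding) / h) + 1L))
  dims <- as.integer(dims)
  centre <- (lo + hi) / 2
  origin <- centre - (dims - 1L) * h / 2
  structure(list(origin = origin, spacing = h, dims = dims,
                 potential = NULL),
            class = "pb_grid")
}

#' @export
print.pb_grid <- function(x, ...) {
  cat("<pb_grid> ", paste(x$dims, collapse = " x "), " nodes, spacing ",
      sprintf("%.3f", x$spacing), " A",
      if (!is.null(x$potential)) ", solved", "\n", sep = "")
  invisible(x)
}

#' Solve the finite-difference Poisson-Boltzmann equation
#'
#' Dielectric boundary: probe-inflated atom spheres (interior
#' `eps_solute`, exterior `eps_solvent`); ionic screening outside the
#' molecule only; Debye-Hueckel single-sphere boundary condition on the
#' grid faces; atom charges spread trilinearly onto nodes. Red-black
#' successive over-relaxation; nonlinear mode applies local Newton updates
#' to the sinh term. Potential in kT/e at the given temperature.
#'
#' @param structure a `ph_structure`.
#' @param charges per-atom charges, see [assign_charges()].
#' @param grid a [build_grid()] geometry (built from `structure` if NULL).
#' @param eps_solute,eps_solvent dielectric constants (2 and 80 defaults).
#' @param ionic_strength 1:1 salt, mol/L.
#' @param mode `"nonlinear"` or `"linear"`.
#' @param tol convergence tolerance on max potential update, kT/e.
#' @param max_iter sweep limit; non-convergence is an error carrying the
#'   residual history.
#' @param probe dielectric-boundary inflation, Angstrom.
#' @param temperature Kelvin (fixes the kT/e unit).
#' @param padding,n_longest forwarded to [build_grid()] when `grid` is
#'   NULL.
#' @return the `pb_grid` with `potential` (3-d array, kT/e), `iterations`,
#'   and the solver parameters.
#' @export
solve_pb <- function(structure, charges, grid = NULL,
                     eps_solute = 2, eps_solvent = 80,
                     ionic_strength = 0.145,
                     mode = c("nonlinear", "linear"),
                     tol = 1e-4, max_iter = 5000L, probe = 1.4,
                     temperature = 298, padding = 20, n_longest = 123L) {
  mode <- match.arg(mode)
  stopifnot(tol > 0)
  if (is.null(grid)) grid <- build_grid(structure, padding, n_longest)
  dims <- grid$dims; h <- grid$spacing; origin <- grid$origin
  a <- structure$atoms
  Ckt <- coulomb_kt(temperature)
  kappa2 <- debye_kappa2(ionic_strength, eps_solvent, temperature)
  kappa <- sqrt(kappa2)

  radii <- a$vdw_radius + probe
  # node insideness and face dielectrics (face midpoints = shifted grids)
  inside <- grid_inside(dims, origin, h, a$x, a$y, a$z, radii)
  epsx <- ifelse(grid_inside(c(dims[1] - 1L, dims[2], dims[3]),
                             origin + c(h / 2, 0, 0), h,
                             a$x, a$y, a$z, radii), eps_solute, eps_solvent)
  epsy <- ifelse(grid_inside(c(dims[1], dims[2] - 1L, dims[3]),
                             origin + c(0, h / 2, 0), h,
                             a$x, a$y, a$z, radii), eps_solute, eps_solvent)
  epsz <- ifelse(grid_inside(c(dims[1], dims[2], dims[3] - 1L),
                             origin + c(0, 0, h / 2), h,
                             a$x, a$y, a$z, radii), eps_solute, eps_solvent)
  kap2 <- ifelse(inside, 0, eps_solvent * kappa2)

  # trilinear charge spreading: src = 4 pi C q / h at nodes
  src <- numeric(prod(dims))
  nz_q <- which(charges != 0)
  for (i in nz_q) {
    g <- (c(a$x[i], a$y[i], a$z[i]) - origin) / h
    g0 <- floor(g)
    f <- g - g0
    if (any(g0 < 0) || any(g0 + 1 > dims - 1)) {
      stop("charged atom outside grid; increase padding")
    }
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      idx <- (g0[1] + dx) + dims[1] * ((g0[2] + dy) +
             dims[2] * (g0[3] + dz)) + 1
      src[idx] <- src[idx] + 4 * pi * Ckt * charges[i] * w / h
    }
  }

  # Debye-Hueckel sphere boundary values, superposed per charge so the
  # boundary condition stays linear in the charges
  centre <- colMeans(atom_xyz(structure))
  arad <- max(sqrt(rowSums(sweep(atom_xyz(structure), 2, centre)^2))) +
    max(radii)
  phi <- array(0, dims)
  if (length(nz_q)) {
    bidx <- boundary_indices(dims)
    coords <- arrayInd(bidx, dims)
    pts <- sweep((coords - 1) * h, 2, origin, `+`)
    bvals <- numeric(length(bidx))
    for (i in nz_q) {
      d <- pmax(sqrt((pts[, 1] - a$x[i])^2 + (pts[, 2] - a$y[i])^2 +
                     (pts[, 3] - a$z[i])^2), h)
      bvals <- bvals + Ckt * charges[i] * exp(-kappa * pmax(d - arad, 0)) /
        (eps_solvent * (1 + kappa * arad) * d)
    }
    phi[bidx] <- bvals
  }

  omega <- 2 / (1 + sin(pi / max(dims)))
  sol <- pb_sor(as.numeric(phi), dims, epsx, epsy, epsz, kap2, src, h,
                nonlinear = (mode == "nonlinear"), tol = tol,
                maxit = as.integer(max_iter), omega = omega)
  if (!sol$converged) {
    hist <- sol$residual_history
    stop("PB solver did not converge in ", max_iter, " sweeps; last ",
         "residuals: ",
         paste(sprintf("%.2e", utils::tail(hist, 5)), collapse = ", "))
  }
  grid$potential <- array(sol$phi, dims)
  grid$iterations <- sol$iterations
  grid$params <- list(eps_solute = eps_solute, eps_solvent = eps_solvent,
                      ionic_strength = ionic_strength, mode = mode,
                      tol = tol, probe = probe, temperature = temperature)
  grid
}

boundary_indices <- function(dims) {
  idx <- array(seq_len(prod(dims)), dims)
  unique(c(idx[c(1, dims[1]), , ], idx[, c(1, dims[2]), ],
           idx[, , c(1, dims[3])]))
}

#' Trilinear interpolation of grid potential
#'
#' @param grid a solved `pb_grid`.
#' @param points n x 3 matrix of coordinates, Angstrom.
#' @return numeric vector, kT/e; `NA` for points outside the grid.
#' @export
grid_interpolate <- function(grid, points) {
  if (is.null(grid$potential)) stop("grid has no potential; run solve_pb")
  pts <- as.matrix(points)
  g <- sweep(pts, 2, grid$origin) / grid$spacing
  dims <- grid$dims
  out <- rep(NA_real_, nrow(pts))
  ok <- g[, 1] >= 0 & g[, 1] <= dims[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= dims[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= dims[3] - 1
  if (!any(ok)) return(out)
  g <- g[ok, , drop = FALSE]
  g0 <- pmin(floor(g), matrix(rep(dims - 2, each = nrow(g)), ncol = 3))
  f <- g - g0
  p <- grid$potential
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    val <- val + w * p[cbind(g0[, 1] + dx + 1, g0[, 2] + dy + 1,
                             g0[, 3] + dz + 1)]
  }
  out[ok] <- val
  out
}

#' Surface electrostatic potential per atom
#'
#' Samples the solved potential on each atom's solvent-accessible sphere
#' (radius + probe) over a deterministic point lattice and reports the
#' per-atom mean, plus the mean clamped to the +/- `clamp` kT/e colouring
#' scale. Sample points falling outside the grid are excluded with a
#' warning.
#'
#' @param structure a `ph_structure`.
#' @param grid a solved `pb_grid`.
#' @param probe probe radius, Angstrom.
#' @param n_points lattice points per atom.
#' @param clamp colouring clamp, kT/e.
#' @return data.frame: atom keys, `mean_potential`, `clamped`, `n_samples`.
#' @export
surface_potential <- function(structure, grid, probe = 1.4,
                              n_points = 64L, clamp = 10) {
  a <- structure$atoms
  unit <- fibonacci_sphere(n_points)
  means <- numeric(nrow(a))
  nsamp <- integer(nrow(a))
  dropped <- 0L
  for (i in seq_len(nrow(a))) {
    pts <- sweep(unit * (a$vdw_radius[i] + probe), 2,
                 c(a$x[i], a$y[i], a$z[i]), `+`)
    v <- grid_interpolate(grid, pts)
    dropped <- dropped + sum(is.na(v))
    means[i] <- mean(v, na.rm = TRUE)
    nsamp[i] <- sum(!is.na(v))
  }
  if (dropped > 0L) {
    warning(dropped, " sample point(s) outside the grid excluded")
  }
  data.frame(chain_id = a$chain_id, residue_seq_id = a$residue_seq_id,
             residue_name = a$residue_name, atom_name = a$atom_name,
             mean_potential = means,
             clamped = pmin(clamp, pmax(-clamp, means)),
             n_samples = nsamp)
}

#' Export a solved grid in OpenDX scalar-field format
#'
#' @param grid a solved `pb_grid`.
#' @param path output `.dx` file.
#' @export
write_opendx <- function(grid, path) {
  if (is.null(grid$potential)) stop("grid has no potential; run solve_pb")
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field: electrostatic potential (kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d ",
                   "data follows"), prod(d))), con)
  # DX order: z fastest
  vals <- aperm(grid$potential, c(3, 2, 1))
  vals <- as.numeric(vals)
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals)) {
    writeLines(paste(sprintf("%.6e", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  }
  writeLines(c('attribute "dep" string "positions"',
               'object "potential" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
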