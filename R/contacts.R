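.class_cache <- new.env(parent = emptyenv())

CONTACT_CLASSES <- c("donor", "acceptor", "donor_acceptor", "hydrophobic",
                     "neutral")

protein_class_table <- function(path = NULL) {
  if (is.null(path) && !is.null(.class_cache$tab)) return(.class_cache$tab)
  p <- if (is.null(path)) phspec_file("protein_atom_classes.tsv") else path
  tab <- utils::read.table(p, comment.char = "#",
                           col.names = c("residue_name", "atom_name", "class"),
                           colClasses = "character")
  bad <- setdiff(tab$class, CONTACT_CLASSES)
  if (length(bad)) stop("unknown atom class(es) in table: ",
                        paste(bad, collapse = ", "))
  if (is.null(path)) .class_cache$tab <- tab
  tab
}

#' Contact legitimacy matrix between atom hydropathy classes
#'
#' Loads (and validates) the packaged class-pair matrix. Validation
#' enforces the load-bearing chemistry rule: a hydrophilic class (donor,
#' acceptor, donor_acceptor) paired with hydrophobic is always
#' illegitimate, under any user edit.
#'
#' @param path optional override matrix file.
#' @return 5x5 0/1 matrix with class dimnames.
#' @export
legitimacy_matrix <- function(path = NULL) {
  p <- if (is.null(path)) phspec_file("legitimacy_matrix.tsv") else path
  tab <- utils::read.table(p, header = TRUE, comment.char = "#",
                           row.names = 1)
  m <- as.matrix(tab)
  if (!setequal(rownames(m), CONTACT_CLASSES) ||
      !setequal(colnames(m), CONTACT_CLASSES)) {
    stop("legitimacy matrix must cover exactly the classes: ",
         paste(CONTACT_CLASSES, collapse = ", "))
  }
  m <- m[CONTACT_CLASSES, CONTACT_CLASSES]
  if (!isTRUE(all.equal(m, t(m)))) stop("legitimacy matrix must be symmetric")
  hydrophilic <- c("donor", "acceptor", "donor_acceptor")
  if (any(m[hydrophilic, "hydrophobic"] != 0)) {
    stop("invalid legitimacy matrix: hydrophilic-hydrophobic contacts ",
         "must be illegitimate")
  }
  m
}

#' Assign hydropathy classes to every atom
#'
#' Protein atoms are classed from the packaged (residue, atom) table
#' (backbone N donor, backbone O acceptor, aliphatic/aromatic C
#' hydrophobic, ...). Ligand (hetero) atoms are classed by element and
#' bonded connectivity: phosphate O (bonded to P) are hydrophilic
#' acceptors, hydroxyl O (bonded to C only, implicit H) donor/acceptors,
#' P neutral, C hydrophobic. Unmatched atoms fall back to `neutral` with
#' a warning.
#'
#' @param structure a `ph_structure`.
#' @param table protein class table (data.frame or path); packaged default.
#' @return character vector of classes, one per atom.
#' @export
classify_atoms <- function(structure, table = protein_class_table()) {
  if (is.character(table)) table <- protein_class_table(table)
  a <- structure$atoms
  cls <- rep(NA_character_, nrow(a))

  prot <- !a$is_hetero
  if (any(prot)) {
    backbone <- table[table$residue_name == "*", ]
    side <- table[table$residue_name != "*", ]
    key <- paste(a$residue_name[prot], a$atom_name[prot])
    hit <- side$class[match(key, paste(side$residue_name, side$atom_name))]
    bb <- backbone$class[match(a$atom_name[prot], backbone$atom_name)]
    cls[prot] <- ifelse(!is.na(hit), hit, bb)
  }

  het <- which(a$is_hetero)
  if (length(het)) {
    cls[het] <- classify_ligand_atoms(a[het, , drop = FALSE])
  }

  un <- is.na(cls)
  if (any(un)) {
    warning("unmatched atom(s) classed neutral: ",
            paste(unique(paste(a$residue_name[un], a$atom_name[un])),
                  collapse = ", "))
    cls[un] <- "neutral"
  }
  cls
}

# element/connectivity rules for ligand heavy atoms
classify_ligand_atoms <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$element
  n <- nrow(atoms)
  d <- as.matrix(stats::dist(xyz))
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cls[i] <- switch(el[i],
      P = "neutral",
      C = "hydrophobic",
      N = "donor",
      S = "donor_acceptor",
      O = {
        near_p <- any(el == "P" & d[i, ] > 0 & d[i, ] <= 1.8)
        if (near_p) "acceptor" else "donor_acceptor"
      },
      NA_character_)
  }
  cls
}

#' Partition a ligand into phosphate (and hydroxyl) groups
#'
#' Bonds are inferred by distance: each phosphorus claims the oxygens
#' within 1.8 Angstrom (ester O bonded to both C and P belong to the
#' phosphate). Groups are labelled `P<k>` from the digits of the
#' phosphorus atom name (override with `labels`). With
#' `include_hydroxyls`, remaining O atoms bonded to C (<= 1.6 Angstrom)
#' form one-atom `C<k>-OH` groups.
#'
#' @param structure a `ph_structure`; only hetero (ligand) atoms are used.
#' @param labels optional named map phosphorus_atom_name -> group label.
#' @param include_hydroxyls also emit hydroxyl groups.
#' @param p_o_bond,c_o_bond bond-distance cutoffs, Angstrom.
#' @return list of `ligand_group`s: each a list with `label` and `atoms`
#'   (integer indices into the structure's atom table).
#' @export
define_phosphate_groups <- function(structure, labels = NULL,
                                    include_hydroxyls = FALSE,
                                    p_o_bond = 1.8, c_o_bond = 1.6) {
  a <- structure$atoms
  lig <- which(a$is_hetero)
  if (!length(lig)) stop("structure has no hetero (ligand) atoms")
  el <- a$element[lig]
  if (!any(el == "P")) stop("ligand contains no phosphorus atoms")
  xyz <- as.matrix(a[lig, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))

  groups <- list()
  taken <- logical(length(lig))
  for (pi in which(el == "P")) {
    ox <- which(el == "O" & d[pi, ] > 0 & d[pi, ] <= p_o_bond)
    if (length(ox) < 3L) {
      warning("phosphorus ", a$atom_name[lig[pi]], " has only ",
              length(ox), " bonded oxygen(s); group formed anyway")
    }
    pname <- a$atom_name[lig[pi]]
    lab <- if (!is.null(labels) && pname %in% names(labels)) {
      labels[[pname]]
    } else {
      digit <- regmatches(pname, regexpr("[0-9]+", pname))
      if (length(digit)) paste0("P", digit) else pname
    }
    groups[[lab]] <- list(label = lab, atoms = lig[c(pi, ox)])
    taken[c(pi, ox)] <- TRUE
  }
  if (include_hydroxyls) {
    for (oi in which(el == "O" & !taken)) {
      cc <- which(el == "C" & d[oi, ] > 0 & d[oi, ] <= c_o_bond)
      if (!length(cc)) next
      cname <- a$atom_name[lig[cc[1]]]
      digit <- regmatches(cname, regexpr("[0-9]+", cname))
      lab <- paste0("C", if (length(digit)) digit else "", "-OH")
      groups[[lab]] <- list(label = lab, atoms = lig[oi])
    }
  }
  groups
}

#' Contact surfaces of a ligand group against the protein
#'
#' For each group atom, the accessible area lost upon complexation
#' (isolated-ligand SASA minus in-complex SASA, atomwise, Lee-Richards) is
#' attributed to protein atoms by nearest expanded-surface distance, using
#' a deterministic spherical point lattice; each attributed patch is
#' legitimate or illegitimate according to the (ligand class, protein
#' class) legitimacy matrix. Attribution conserves buried area exactly:
#' `S_legit + S_illegit` equals the group's total buried area.
#'
#' @param group a `ligand_group` from [define_phosphate_groups()].
#' @param complex a `ph_structure` holding protein + ligand.
#' @param classes per-atom classes from [classify_atoms()].
#' @param probe probe radius, Angstrom.
#' @param slice_spacing Lee-Richards slice thickness.
#' @param legit legitimacy matrix.
#' @param n_points lattice points per atom sphere for ownership sampling.
#' @return named numeric: `S_legit`, `S_illegit` (Angstrom^2).
#' @export
contact_surfaces <- function(group, complex, classes, probe = 1.4,
                             slice_spacing = 0.1,
                             legit = legitimacy_matrix(),
                             n_points = 2000L) {
  a <- complex$atoms
  lig <- which(a$is_hetero)
  prot <- which(!a$is_hetero)
  if (!length(prot)) stop("complex contains no protein atoms")
  sasa_iso <- lee_richards_sasa(complex, probe, slice_spacing,
                                include = a$is_hetero)
  sasa_cpx <- lee_richards_sasa(complex, probe, slice_spacing)

  # atomwise buried area, indexed like `lig`
  iso_area <- sasa_iso$atoms$area
  cpx_lig_area <- sasa_cpx$atoms$area[lig]
  buried <- pmax(0, iso_area - cpx_lig_area)

  px <- a$x[prot]; py <- a$y[prot]; pz <- a$z[prot]
  pR <- a$vdw_radius[prot] + probe
  pcls <- classes[prot]

  lx <- a$x[lig]; ly <- a$y[lig]; lz <- a$z[lig]
  lR <- a$vdw_radius[lig] + probe

  S <- c(S_legit = 0, S_illegit = 0)
  unit <- fibonacci_sphere(n_points)
  for (gi in group$atoms) {
    li <- match(gi, lig)
    if (is.na(li)) stop("group atom ", gi, " is not a ligand atom")
    b <- buried[li]
    if (b <= 0) next
    pts <- sweep(unit * lR[li], 2, c(lx[li], ly[li], lz[li]), `+`)
    # accessible on the isolated ligand: outside every other ligand sphere
    other <- setdiff(seq_along(lig), li)
    acc <- rep(TRUE, nrow(pts))
    for (j in other) {
      acc <- acc & ((pts[, 1] - lx[j])^2 + (pts[, 2] - ly[j])^2 +
                    (pts[, 3] - lz[j])^2 >= lR[j]^2)
    }
    # squared distances to protein atom centres
    d2 <- outer(pts[, 1], px, `-`)^2 + outer(pts[, 2], py, `-`)^2 +
          outer(pts[, 3], pz, `-`)^2
    covered <- sweep(d2, 2, pR^2, `<`)
    buried_pt <- acc & rowSums(covered) > 0
    if (any(buried_pt)) {
      # owner: protein atom whose expanded surface is nearest
      surf_d <- sweep(sqrt(d2[buried_pt, , drop = FALSE]), 2, pR, `-`)
      owner <- max.col(-surf_d, ties.method = "first")
      frac <- tabulate(owner, nbins = length(prot)) / sum(buried_pt)
    } else {
      # burial too small for the lattice: give it to the nearest atom
      surf_d <- sqrt((lx[li] - px)^2 + (ly[li] - py)^2 +
                     (lz[li] - pz)^2) - pR
      frac <- as.numeric(seq_along(prot) == which.min(surf_d))
    }
    lcls <- classes[gi]
    ok <- legit[lcls, pcls] == 1
    S["S_legit"] <- S["S_legit"] + b * sum(frac[ok])
    S["S_illegit"] <- S["S_illegit"] + b * sum(frac[!ok])
  }
  S
}

# deterministic golden-spiral lattice on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z * z))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Complementarity of a contact partition
#'
#' `C = S_legit - S_illegit` (Angstrom^2): net chemically compatible
#' contact surface of a ligand group.
#'
#' @param s_legit,s_illegit non-negative contact surface areas.
#' @return complementarity, Angstrom^2.
#' @export
#' @examples
#' complementarity(31.3, 10.6)  # 20.7
complementarity <- function(s_legit, s_illegit) {
  stopifnot(all(s_legit >= 0), all(s_illegit >= 0))
  s_legit - s_illegit
}

#' Normalized complementarity
#'
#' `NC = C / reference_area`. The default reference is the group's total
#' accessible surface on the isolated ligand, making NC the net
#' compatibility per unit of available group surface.
#'
#' @param C complementarity, Angstrom^2.
#' @param reference_area positive reference area, Angstrom^2.
#' @return dimensionless NC.
#' @export
normalized_complementarity <- function(C, reference_area) {
  if (any(reference_area <= 0)) stop("reference_area must be positive")
  C / reference_area
}

#' Full contact report for a ligand (Table-3-style)
#'
#' Runs [define_phosphate_groups()], [classify_atoms()] and
#' [contact_surfaces()] over every phosphate group and assembles the
#' legitimate/illegitimate areas, complementarity and normalized
#' complementarity per group.
#'
#' @param complex a `ph_structure` with protein + hetero ligand.
#' @param probe,slice_spacing,n_points forwarded to the contact engine.
#' @param labels,include_hydroxyls forwarded to group definition.
#' @param legit legitimacy matrix.
#' @return data.frame: `group`, `S_legit`, `S_illegit`, `C`, `NC`,
#'   `reference_area`.
#' @export
contact_report <- function(complex, probe = 1.4, slice_spacing = 0.1,
                           n_points = 2000L, labels = NULL,
                           include_hydroxyls = FALSE,
                           legit = legitimacy_matrix()) {
  classes <- classify_atoms(complex)
  groups <- define_phosphate_groups(complex, labels = labels,
                                    include_hydroxyls = include_hydroxyls)
  iso <- lee_richards_sasa(complex, probe, slice_spacing,
                           include = complex$atoms$is_hetero)
  lig <- which(complex$atoms$is_hetero)
  rows <- lapply(groups, function(g) {
    s <- contact_surfaces(g, complex, classes, probe, slice_spacing,
                          legit = legit, n_points = n_points)
    ref <- sum(iso$atoms$area[match(g$atoms, lig)])
    C <- complementarity(s[["S_legit"]], s[["S_illegit"]])
    data.frame(group = g$label, S_legit = s[["S_legit"]],
               S_illegit = s[["S_illegit"]], C = C,
               NC = if (ref > 0) normalized_complementarity(C, ref) else NA,
               reference_area = ref)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}
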