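.vdw_cache <- new.env(parent = emptyenv())

#' Packaged van der Waals radius table
#'
#' @param path optional override table (element, radius in Angstrom).
#' @return named numeric vector keyed by uppercase element symbol.
#' @export
vdw_radii <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.vdw_cache$tab)) {
      tab <- utils::read.table(phspec_file("vdw_radii.tsv"),
                               col.names = c("element", "radius"),
                               colClasses = c("character", "numeric"),
                               comment.char = "#")
      .vdw_cache$tab <- stats::setNames(tab$radius, toupper(tab$element))
    }
    return(.vdw_cache$tab)
  }
  tab <- utils::read.table(path, col.names = c("element", "radius"),
                           colClasses = c("character", "numeric"),
                           comment.char = "#")
  stats::setNames(tab$radius, toupper(tab$element))
}

#' Read a PDB structure
#'
#' Parses PDB text (via bio3d), selects one model, resolves alternate
#' locations to the highest-occupancy copy (ties: first), excludes water,
#' flags HETATM ligand atoms, and assigns van der Waals radii by element.
#'
#' @param pdb_source path to a PDB file.
#' @param model_policy `"first"` (default; NMR ensembles without an average
#'   structure use model 1) or an integer model number.
#' @param radii optional named radius vector, see [vdw_radii()].
#' @param keep_water keep water (HOH/WAT/DOD) atoms.
#' @return a `ph_structure`: list with `atoms` (data.frame: `atom_name`,
#'   `element`, `residue_name`, `residue_seq_id`, `chain_id`, `x`, `y`,
#'   `z`, `vdw_radius`, `occupancy`, `is_hetero`) and `model_id`.
#' @export
read_structure <- function(pdb_source, model_policy = "first",
                           radii = vdw_radii(), keep_water = FALSE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_source, multi = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("no ATOM/HETATM records parseable from '",
                             pdb_source, "': ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("no ATOM/HETATM records in '", pdb_source, "'")
  }
  model_id <- if (identical(model_policy, "first")) 1L
              else as.integer(model_policy)
  nmodels <- nrow(pdb$xyz)
  if (is.na(model_id) || model_id < 1L || model_id > nmodels) {
    stop("model ", model_policy, " not present (file has ", nmodels,
         " model(s))")
  }
  xyz <- matrix(pdb$xyz[model_id, ], ncol = 3L, byrow = TRUE)

  occ <- at$o
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    atom_name = trimws(at$elety),
    element = toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                    guess_element(at$elety), at$elesy))),
    residue_name = trimws(at$resid),
    residue_seq_id = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)

  if (!keep_water) {
    atoms <- atoms[!atoms$residue_name %in% c("HOH", "WAT", "DOD"), ,
                   drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no non-water atoms in '", pdb_source, "'")

  # alternate locations: highest occupancy wins, ties go to the first copy
  key <- paste(atoms$chain_id, atoms$residue_seq_id, atoms$insert,
               atoms$residue_name, atoms$atom_name, sep = "|")
  ord <- order(match(key, unique(key)), -atoms$occupancy,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL

  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown)) {
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            ": fallback radius 1.70 A assigned")
  }
  atoms$vdw_radius <- unname(radii[atoms$element])
  atoms$vdw_radius[is.na(atoms$vdw_radius)] <- 1.70
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite coordinates in '", pdb_source, "'")
  }
  structure(list(atoms = atoms, model_id = model_id), class = "ph_structure")
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA"), two, one)
}

#' @export
print.ph_structure <- function(x, ...) {
  a <- x$atoms
  cat("<ph_structure> ", nrow(a), " atoms (", sum(a$is_hetero),
      " hetero), model ", x$model_id, "\n", sep = "")
  invisible(x)
}

#' Construct a structure from atom fields (generator/test plumbing)
#'
#' @param atom_name,residue_name,residue_seq_id,chain_id,element per-atom
#'   character/integer vectors, recycled to the coordinate length.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param is_hetero logical vector.
#' @param radii named radius table.
#' @return a `ph_structure`.
#' @export
make_structure <- function(xyz, element, atom_name = element,
                           residue_name = "TOY",
                           residue_seq_id = seq_len(nrow(xyz)),
                           chain_id = "A", is_hetero = FALSE,
                           radii = vdw_radii()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  atoms <- data.frame(
    atom_name = rep_len(atom_name, n),
    element = toupper(rep_len(element, n)),
    residue_name = rep_len(residue_name, n),
    residue_seq_id = rep_len(residue_seq_id, n),
    insert = "", chain_id = rep_len(chain_id, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "",
    is_hetero = rep_len(is_hetero, n),
    stringsAsFactors = FALSE)
  atoms$vdw_radius <- unname(radii[atoms$element])
  if (anyNA(atoms$vdw_radius)) stop("unknown element in make_structure")
  structure(list(atoms = atoms, model_id = 1L), class = "ph_structure")
}

#' Write a structure as PDB text
#'
#' @param structure a `ph_structure`.
#' @param path output file.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$atom_name) < 4L & nchar(a$element) == 1L,
                  sprintf(" %-3s", a$atom_name),
                  sprintf("%-4s", a$atom_name))
  lines <- sprintf(
    "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), name4, a$residue_name, a$chain_id,
    a$residue_seq_id, a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

atom_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Select a subset of atoms
#'
#' @param structure a `ph_structure`.
#' @param which logical or integer index over atoms.
#' @return a `ph_structure` with the subset.
#' @export
subset_structure <- function(structure, which) {
  atoms <- structure$atoms[which, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = structure$model_id),
            class = "ph_structure")
}

#' Logical mask of ligand atoms by residue name
#'
#' @param structure a `ph_structure`.
#' @param resnames ligand residue name(s).
#' @export
ligand_mask <- function(structure, resnames) {
  structure$atoms$residue_name %in% toupper(resnames)
}
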