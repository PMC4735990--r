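#' @useDynLib phspec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
names(AA3) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.builtin_scale_files <- c(
  H = "scales/hydropathy.tsv",
  F = "scales/flexibility.tsv",
  E = "scales/electronic_charge.tsv",
  I = "scales/isotropic_surface_area.tsv"
)

phspec_file <- function(...) {
  path <- system.file("extdata", ..., package = "phspec", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development the package may be loaded from source
    path <- file.path("inst", "extdata", ...)
  }
  path
}

#' Load an amino-acid property scale
#'
#' A property scale maps each of the 20 standard amino acids to a real
#' number. Four scales ship with the package, matching the profile tracks
#' of the analysis: hydropathy (`"H"`, Kyte-Doolittle), flexibility (`"F"`,
#' Vihinen normalized B-factors), electronic charge concentration (`"E"`,
#' Collantes-Dunn ECI) and isotropic surface area (`"I"`, Collantes-Dunn
#' ISA). Any whitespace-delimited two-column file (letter, value; `#`
#' comments) can be loaded instead.
#'
#' Nonstandard letters (X, B, Z, U, O) are looked up as the mean of the 20
#' standard values, with a warning at profile time.
#'
#' @param source one of `"H"`, `"F"`, `"E"`, `"I"`, or a file path.
#' @return a `property_scale` object: named numeric vector of length 20
#'   with attributes `name` and `source`.
#' @export
#' @examples
#' h <- load_scale("H")
#' h[["I"]] > h[["R"]]
load_scale <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% names(.builtin_scale_files)) {
    path <- phspec_file(.builtin_scale_files[[source]])
    name <- source
  } else {
    path <- source
    name <- tools::file_path_sans_ext(basename(source))
    if (!file.exists(path)) {
      stop("scale source '", source,
           "' is neither a built-in name (H, F, E, I) nor an existing file")
    }
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("aa", "value"),
                           colClasses = c("character", "numeric"))
  tab$aa <- toupper(tab$aa)
  dup <- unique(tab$aa[duplicated(tab$aa)])
  if (length(dup)) {
    stop("duplicate amino-acid letters in scale: ", paste(dup, collapse = ", "))
  }
  missing <- setdiff(AA1, tab$aa)
  if (length(missing)) {
    stop("scale is missing amino acids: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(tab$aa, AA1)
  if (length(extra)) {
    stop("scale contains non-standard letters: ", paste(extra, collapse = ", "))
  }
  values <- stats::setNames(tab$value, tab$aa)[AA1]
  if (any(!is.finite(values))) stop("scale contains non-finite values")
  structure(values, name = name, source = path, class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat("<property_scale> ", attr(x, "name"), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

scale_name <- function(scale) attr(scale, "name")

#' Look up scale values for a residue string
#'
#' Applies the nonstandard-letter policy: letters outside the 20 standard
#' amino acids take the scale mean, with one warning per call.
#'
#' @param residues character vector of single letters, or a single string.
#' @param scale a [load_scale()] object.
#' @return numeric vector of per-residue values.
#' @export
scale_values <- function(residues, scale) {
  stopifnot(inherits(scale, "property_scale"))
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(residues)
  v <- unclass(scale)[residues]
  bad <- is.na(v)
  if (any(bad)) {
    warning("nonstandard residue letter(s) ",
            paste(unique(residues[bad]), collapse = ", "),
            " assigned the scale mean (", scale_name(scale), ")")
    v[bad] <- mean(unclass(scale))
  }
  unname(v)
}
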