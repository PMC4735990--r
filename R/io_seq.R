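#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences (uppercased, as written).
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  # minimal fallback, same contract
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple alignment (Stockholm or aligned FASTA)
#'
#' Format is sniffed from the first non-blank line (`# STOCKHOLM` vs `>`).
#' Stockholm sequence lines may be wrapped over several blocks; `#=`
#' annotation lines are ignored. Gap characters `.` and `-` are both
#' accepted and normalized to `-`.
#'
#' @param path alignment file.
#' @return named character vector of equal-length gapped rows.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) stop("empty alignment file: ", path)
  rows <- if (startsWith(first, "# STOCKHOLM")) {
    parse_stockholm(lines)
  } else if (startsWith(first, ">")) {
    tmp <- read_fasta(path)
    tmp
  } else {
    stop("unrecognized alignment format in ", path,
         " (expected Stockholm or aligned FASTA)")
  }
  rows <- normalize_alignment(rows)
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length in ", path)
  }
  rows
}

parse_stockholm <- function(lines) {
  acc <- list()
  order <- character()
  for (ln in lines) {
    ln <- trimws(ln, which = "right")
    if (!nzchar(ln) || startsWith(ln, "#") || ln == "//") next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed Stockholm line: ", ln)
    id <- parts[1]
    if (is.null(acc[[id]])) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], parts[2])
  }
  if (!length(acc)) stop("no sequence rows in Stockholm input")
  toupper(unlist(acc)[order])
}
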