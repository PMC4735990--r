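#' Compile a restricted motif pattern
#'
#' The pattern language covers literal residue letters, `.`/`x` wildcards,
#' character sets `[KR]`, bounded repeats `x(6,11)` or `.{6,11}`, and
#' optional PROSITE-style `-` separators. Unbounded repeats (`*`, `+`,
#' `{m,}`) are rejected so every pattern has bounded length.
#'
#' @param pattern pattern text.
#' @param name motif name.
#' @param note free-text provenance note.
#' @return a `motif_pattern`: list with `name`, `pattern`, `regex`, `note`.
#' @export
motif_pattern <- function(pattern, name = "motif", note = "") {
  rx <- gsub("-", "", pattern, fixed = TRUE)
  rx <- gsub("x", ".", rx, fixed = TRUE)
  rx <- gsub("X", ".", rx, fixed = TRUE)
  rx <- gsub("\\(([0-9]+),([0-9]+)\\)", "{\\1,\\2}", rx)
  rx <- gsub("\\(([0-9]+)\\)", "{\\1}", rx)
  if (grepl("[*+]|\\{[0-9]+,\\}", rx)) {
    stop("unbounded repeats are not allowed in motif patterns: ", pattern)
  }
  if (!grepl("^([A-Z.]|\\[[A-Z]+\\]|\\{[0-9]+(,[0-9]+)?\\})+$", rx)) {
    stop("pattern does not compile under the restricted syntax: ", pattern)
  }
  structure(list(name = name, pattern = pattern, regex = rx, note = note),
            class = "motif_pattern")
}

#' Read a motif pattern file
#'
#' Whitespace-delimited `name pattern` lines, `#` comments. The packaged
#' default file carries the 3-phosphate-binding signature.
#'
#' @param path pattern file; default the packaged motif file.
#' @return list of `motif_pattern`s.
#' @export
read_motif_patterns <- function(path = NULL) {
  p <- if (is.null(path)) phspec_file("motifs.tsv") else path
  tab <- utils::read.table(p, comment.char = "#",
                           col.names = c("name", "pattern"),
                           colClasses = "character")
  lapply(seq_len(nrow(tab)),
         function(i) motif_pattern(tab$pattern[i], tab$name[i]))
}

#' Default 3-phosphate-binding signature motif
#' @return a `motif_pattern`.
#' @export
default_motif <- function() read_motif_patterns()[[1]]

#' Scan a sequence for motif hits
#'
#' Returns all leftmost non-overlapping matches, ordered by start. When a
#' `loop_window` is given (0-based half-open sequence range), each hit's
#' `in_loop` flag records whether its span intersects the window.
#'
#' @param sequence one-letter residue string.
#' @param pattern a [motif_pattern()] (or pattern text).
#' @param loop_window `c(start, end)`, 0-based half-open, or NULL.
#' @param sequence_id identifier for the hits.
#' @return data.frame: `sequence_id`, `start`, `end` (0-based half-open),
#'   `matched`, `in_loop`; zero rows when nothing matches.
#' @export
scan_motif <- function(sequence, pattern = default_motif(),
                       loop_window = NULL, sequence_id = "seq") {
  if (is.character(pattern)) pattern <- motif_pattern(pattern)
  stopifnot(nchar(sequence) > 0)
  sequence <- toupper(sequence)
  m <- gregexpr(pattern$regex, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      in_loop = logical()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  in_loop <- if (is.null(loop_window)) {
    rep(NA, length(start))
  } else {
    start < loop_window[2] & end > loop_window[1]
  }
  data.frame(sequence_id = sequence_id, start = start, end = end,
             matched = substring(sequence, start + 1L, end),
             in_loop = in_loop)
}
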