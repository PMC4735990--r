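#' Sliding-window physicochemical profile of a sequence
#'
#' Position `i` carries the arithmetic mean of the scale values over an odd
#' window centred at `i`. Windows are truncated at the sequence ends: the
#' mean runs over the positions that exist, so no values are invented
#' beyond the termini. With `window = 1` the profile equals the raw
#' per-residue scale values.
#'
#' @param sequence one-letter residue string (or character vector).
#' @param scale a [load_scale()] object.
#' @param window odd integer >= 1 and <= sequence length.
#' @param sequence_id identifier stored with the profile.
#' @return a `sequence_profile`: list with `sequence_id`, `residues`,
#'   `window`, `scale_name`, and numeric `values` (same length as the
#'   sequence).
#' @export
compute_profile <- function(sequence, scale, window = 9L,
                            sequence_id = "seq") {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  n <- length(sequence)
  if (n == 0L) stop("sequence is empty")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer, got ", window)
  }
  if (window > n) stop("window (", window, ") exceeds sequence length (", n, ")")
  raw <- scale_values(sequence, scale)
  values <- sliding_mean(raw, window)
  structure(
    list(sequence_id = sequence_id, residues = paste(sequence, collapse = ""),
         window = window, scale_name = scale_name(scale), values = values),
    class = "sequence_profile")
}

# truncated-window running mean via cumulative sums
sliding_mean <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat("<sequence_profile> ", x$sequence_id, ": scale ", x$scale_name,
      ", window ", x$window, ", length ", nchar(x$residues), "\n", sep = "")
  invisible(x)
}

#' Place per-sequence profiles onto alignment columns
#'
#' Every profile's ungapped sequence must equal its alignment row with gaps
#' removed; values are then placed at the row's non-gap columns, gap cells
#' stay `NA`. The column map (alignment column -> 0-based residue index, NA
#' at gaps) is strictly increasing over non-gap cells by construction.
#'
#' @param profiles list of [compute_profile()] objects (possibly several
#'   scales per sequence), named or carrying matching `sequence_id`s.
#' @param alignment named character vector of gapped rows (`-` or `.`),
#'   e.g. from [read_alignment()].
#' @return an `alignment_profile_set`: list with `alignment` (normalized to
#'   `-` gaps), `column_map` (per sequence), and `profiles`, a list per
#'   scale of matrices (rows = sequences, cols = alignment columns).
#' @export
map_profiles_to_alignment <- function(profiles, alignment) {
  alignment <- normalize_alignment(alignment)
  ids <- names(alignment)
  width <- unique(nchar(alignment))
  if (length(width) != 1L) stop("alignment rows differ in length")

  column_map <- lapply(alignment, function(row) {
    chars <- strsplit(row, "")[[1]]
    idx <- rep(NA_integer_, length(chars))
    idx[chars != "-"] <- seq_len(sum(chars != "-")) - 1L
    idx
  })

  by_scale <- split(profiles, vapply(profiles, `[[`, "", "scale_name"))
  out_profiles <- lapply(by_scale, function(plist) {
    m <- matrix(NA_real_, nrow = length(ids), ncol = width,
                dimnames = list(ids, NULL))
    for (p in plist) {
      id <- p$sequence_id
      if (!id %in% ids) stop("profile sequence '", id, "' not in alignment")
      ungapped <- gsub("-", "", alignment[[id]], fixed = TRUE)
      if (ungapped != p$residues) {
        a <- strsplit(ungapped, "")[[1]]
        b <- strsplit(p$residues, "")[[1]]
        k <- min(length(a), length(b))
        mism <- which(a[seq_len(k)] != b[seq_len(k)])
        pos <- if (length(mism)) mism[1] else k + 1L
        stop("sequence/alignment mismatch for '", id,
             "' at ungapped position ", pos - 1L, " (0-based)")
      }
      cm <- column_map[[id]]
      m[id, !is.na(cm)] <- p$values[cm[!is.na(cm)] + 1L]
    }
    m
  })
  structure(list(alignment = alignment, column_map = column_map,
                 profiles = out_profiles),
            class = "alignment_profile_set")
}

normalize_alignment <- function(alignment) {
  if (is.null(names(alignment)) || anyNA(names(alignment))) {
    stop("alignment rows must be named")
  }
  vapply(alignment, function(s) chartr(".", "-", toupper(s)), "")
}

#' Average pairwise sequence identity of an alignment
#'
#' Mean over all unordered row pairs of the fraction of identical aligned
#' residues, counting only columns where both rows are non-gap
#' (pairwise-deletion denominator). Pairs with no shared non-gap column are
#' excluded with a warning.
#'
#' @param alignment named character vector of gapped rows.
#' @return a fraction in \[0, 1\].
#' @export
average_pairwise_identity <- function(alignment) {
  alignment <- normalize_alignment(alignment)
  n <- length(alignment)
  if (n < 2L) stop("need at least two alignment rows")
  if (length(unique(nchar(alignment))) != 1L) {
    stop("alignment rows differ in length")
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  idents <- c()
  dropped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(both)) {
        dropped <- dropped + 1L
        next
      }
      idents <- c(idents, sum(mat[i, both] == mat[j, both]) / sum(both))
    }
  }
  if (dropped > 0L) {
    warning(dropped, " pair(s) with no shared non-gap columns excluded")
  }
  if (!length(idents)) stop("no comparable pairs in alignment")
  mean(idents)
}
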