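#' Lee-Richards solvent-accessible surface area
#'
#' Slices every probe-expanded atom sphere into parallel planes, measures
#' the exposed arc length of each slice circle against all neighbouring
#' circles, and integrates arc length x slice thickness on the expanded
#' sphere (so an isolated atom reports `4*pi*(r + probe)^2`). Deterministic
#' for fixed inputs. Coincident atoms (same centre and radius) are
#' collapsed to one with a warning; the duplicate reports zero area.
#'
#' @param structure a `ph_structure`.
#' @param probe probe radius in Angstrom (1.4 for water).
#' @param slice_spacing target slice thickness in Angstrom; each atom uses
#'   the nearest spacing that covers its sphere with whole slices.
#' @param include optional logical mask of atoms participating (as both
#'   surface and occluders); default all.
#' @return a `sasa_result`: list with `atoms` (key columns + `area` in
#'   Angstrom^2), `per_residue` (summed by residue), `probe`,
#'   `slice_spacing`.
#' @export
lee_richards_sasa <- function(structure, probe = 1.4, slice_spacing = 0.1,
                              include = NULL) {
  stopifnot(probe >= 0, slice_spacing > 0)
  a <- structure$atoms
  if (is.null(include)) include <- rep(TRUE, nrow(a))
  a <- a[include, , drop = FALSE]
  n <- nrow(a)
  if (n == 0L) stop("no atoms selected for SASA")

  x <- a$x; y <- a$y; z <- a$z
  R <- a$vdw_radius + probe
  dup_of <- integer(0)
  if (n > 1L) {
    key <- paste(round(x, 6), round(y, 6), round(z, 6), round(R, 6))
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " coincident atom(s) removed as duplicates")
      dup_of <- which(dup)
    }
  }
  active <- setdiff(seq_len(n), dup_of)
  area <- numeric(n)

  xa <- x[active]; ya <- y[active]; za <- z[active]; Ra <- R[active]
  na <- length(active)
  for (ii in seq_len(na)) {
    Ri <- Ra[ii]
    dx <- xa - xa[ii]; dy <- ya - ya[ii]; dz3 <- za - za[ii]
    nb <- which(dx * dx + dy * dy + dz3 * dz3 < (Ra + Ri)^2)
    nb <- nb[nb != ii]
    k <- max(1L, ceiling(2 * Ri / slice_spacing))
    dz <- 2 * Ri / k
    zmid <- za[ii] - Ri + (seq_len(k) - 0.5) * dz
    if (!length(nb)) {
      # isolated within this selection: band sum equals 4*pi*R^2 exactly
      area[active[ii]] <- k * 2 * pi * Ri * dz
      next
    }
    nx <- xa[nb]; ny <- ya[nb]; nz <- za[nb]; nR <- Ra[nb]
    dxy <- sqrt((nx - xa[ii])^2 + (ny - ya[ii])^2)
    theta <- atan2(ny - ya[ii], nx - xa[ii])
    acc <- 0
    for (s in seq_len(k)) {
      zm <- zmid[s]
      rho_i <- sqrt(Ri^2 - (zm - za[ii])^2)
      sel <- which(abs(zm - nz) < nR)
      if (!length(sel)) { acc <- acc + 2 * pi; next }
      rho_j <- sqrt(nR[sel]^2 - (zm - nz[sel])^2)
      d <- dxy[sel]
      if (any(d + rho_i <= rho_j)) next  # slice circle fully covered
      occl <- which(d < rho_i + rho_j & d + rho_j > rho_i & d > 0)
      if (!length(occl)) { acc <- acc + 2 * pi; next }
      csa <- (d[occl]^2 + rho_i^2 - rho_j[occl]^2) / (2 * d[occl] * rho_i)
      alpha <- acos(pmin(1, pmax(-1, csa)))
      occluded <- arc_union(theta[sel][occl], alpha)
      acc <- acc + (2 * pi - occluded)
    }
    area[active[ii]] <- acc * Ri * dz
  }

  keys <- c("chain_id", "residue_seq_id", "insert", "residue_name")
  atoms_out <- cbind(a[, c(keys, "atom_name", "is_hetero")], area = area)
  rownames(atoms_out) <- NULL
  res_key <- interaction(a[keys], drop = TRUE, lex.order = FALSE)
  per_res <- atoms_out[!duplicated(res_key), keys, drop = FALSE]
  per_res$area <- as.numeric(tapply(area, res_key, sum)[
    as.character(unique(res_key))])
  rownames(per_res) <- NULL
  structure(list(atoms = atoms_out, per_residue = per_res,
                 probe = probe, slice_spacing = slice_spacing),
            class = "sasa_result")
}

# total angular measure of the union of arcs [theta - alpha, theta + alpha]
# on the circle (radians in [0, 2*pi])
arc_union <- function(theta, alpha) {
  if (any(alpha >= pi)) return(2 * pi)
  start <- (theta - alpha) %% (2 * pi)
  end <- start + 2 * alpha
  wrap <- end > 2 * pi
  if (any(wrap)) {
    start <- c(start[!wrap], start[wrap], rep(0, sum(wrap)))
    end <- c(end[!wrap], rep(2 * pi, sum(wrap)), end[wrap] - 2 * pi)
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  min(total + (cur_e - cur_s), 2 * pi)
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<sasa_result> ", nrow(x$atoms), " atoms, total ",
      sprintf("%.1f", sum(x$atoms$area)), " A^2 (probe ", x$probe,
      " A, slice ", x$slice_spacing, " A)\n", sep = "")
  invisible(x)
}

.max_sasa_cache <- new.env(parent = emptyenv())

#' Packaged maximal residue areas (Gly-X-Gly extended tripeptides)
#'
#' @param path optional override table (residue_name, area).
#' @return named numeric vector, Angstrom^2.
#' @export
max_sasa_reference <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.max_sasa_cache$tab)) {
      tab <- utils::read.table(phspec_file("max_sasa.tsv"),
                               col.names = c("residue_name", "area"),
                               colClasses = c("character", "numeric"),
                               comment.char = "#")
      .max_sasa_cache$tab <- stats::setNames(tab$area, tab$residue_name)
    }
    return(.max_sasa_cache$tab)
  }
  tab <- utils::read.table(path, col.names = c("residue_name", "area"),
                           colClasses = c("character", "numeric"),
                           comment.char = "#")
  stats::setNames(tab$area, tab$residue_name)
}

#' Residue exposure fractions
#'
#' Fraction = residue SASA / maximal reference area, clipped to \[0, 1\].
#' Residues without a reference entry get `NA`, are flagged, and are
#' excluded from smoothing (the window runs over the remaining residues).
#'
#' @param sasa a [lee_richards_sasa()] result.
#' @param reference named residue_name -> area vector
#'   ([max_sasa_reference()] by default).
#' @param window odd smoothing window (same operator as sequence
#'   profiles); 1 = no smoothing.
#' @return data.frame per residue: keys, `area`, `reference`, `fraction`,
#'   `smoothed`, `known`.
#' @export
exposure_fractions <- function(sasa, reference = max_sasa_reference(),
                               window = 1L) {
  pr <- sasa$per_residue
  ref <- unname(reference[pr$residue_name])
  known <- !is.na(ref)
  if (any(!known)) {
    warning("no reference area for residue(s): ",
            paste(unique(pr$residue_name[!known]), collapse = ", "),
            "; excluded from smoothing")
  }
  fraction <- rep(NA_real_, nrow(pr))
  fraction[known] <- pmin(1, pmax(0, pr$area[known] / ref[known]))
  smoothed <- rep(NA_real_, nrow(pr))
  if (any(known)) {
    w <- min(window, 2 * floor((sum(known) - 1) / 2) + 1)
    smoothed[known] <- sliding_mean(fraction[known], w)
  }
  out <- cbind(pr, reference = ref, fraction = fraction,
               smoothed = smoothed, known = known)
  rownames(out) <- NULL
  out
}

#' Per-residue buried area between apo and complex SASA
#'
#' `buried = apo - complex` per residue, floored at 0. Residues burying
#' more than `threshold` Angstrom^2 are flagged as binding-site residues.
#' Only non-hetero (protein) atoms are compared; the two results must
#' cover identical protein atoms.
#'
#' @param apo,complex [lee_richards_sasa()] results sharing protein atoms.
#' @param threshold binding-site flag threshold, Angstrom^2.
#' @return data.frame per residue: keys, `apo_area`, `complex_area`,
#'   `buried`, `binding_site`.
#' @export
delta_sasa <- function(apo, complex, threshold = 1.0) {
  keys <- c("chain_id", "residue_seq_id", "insert", "residue_name")
  pa <- apo$atoms[!apo$atoms$is_hetero, , drop = FALSE]
  pc <- complex$atoms[!complex$atoms$is_hetero, , drop = FALSE]
  ka <- do.call(paste, c(pa[c(keys, "atom_name")], sep = "|"))
  kc <- do.call(paste, c(pc[c(keys, "atom_name")], sep = "|"))
  orphans <- c(setdiff(ka, kc), setdiff(kc, ka))
  if (!length(orphans) && length(ka) != length(kc)) {
    orphans <- names(which(table(c(ka, kc)) %% 2 == 1))
    if (!length(orphans)) {
      stop("apo/complex protein atom counts differ (", length(ka), " vs ",
           length(kc), ")")
    }
  }
  if (length(orphans)) {
    stop("apo/complex protein atom sets differ; orphan atoms: ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) " ...")
  }
  pc <- pc[match(ka, kc), , drop = FALSE]
  rkey <- do.call(paste, c(pa[keys], sep = "|"))
  ukey <- unique(rkey)
  buried_atom <- pa$area - pc$area
  buried <- as.numeric(tapply(buried_atom, rkey, sum)[ukey])
  buried <- pmax(0, buried)
  out <- pa[match(ukey, rkey), keys, drop = FALSE]
  out$apo_area <- as.numeric(tapply(pa$area, rkey, sum)[ukey])
  out$complex_area <- as.numeric(tapply(pc$area, rkey, sum)[ukey])
  out$buried <- buried
  out$binding_site <- buried > threshold
  rownames(out) <- NULL
  out
}
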