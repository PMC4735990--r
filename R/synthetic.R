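with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

case_seed <- function(master_seed, case_index) {
  (abs(as.integer(master_seed)) %% 20000L) * 100000L + as.integer(case_index)
}

HYDROPHILIC_SET <- c("K", "R", "N", "S")
HYDROPHOBIC_SET <- c("I", "L", "V", "F")

#' Generate one labelled synthetic PH-like sequence
#'
#' Background residues are uniform over the 20 amino acids; the
#' beta1/beta2 window (fixed offset) is rewritten according to the group
#' archetype. Groups 1 and 3 carry a planted instance of the 3-phosphate
#' signature motif at the window start; Group 1 fills the rest of the
#' window (and the motif's spacer) with hydrophilic/basic residues
#' (K, R, N, S), Group 3 puts a hydrophobic run (I, L, V, F) in the
#' motif spacer; Group 2 has no motif but a basic/hydrophilic window;
#' Group 4's window stays near background. Each archetype letter is used
#' with probability `effect` (else a uniform draw), so `effect = 0` makes
#' all groups indistinguishable. Groups 2 and 4 are rejection-verified to
#' contain no motif match anywhere; at `effect = 1`, Groups 1 and 3 are
#' rejection-verified to contain exactly one in-window match.
#'
#' @param group true group, 1-4.
#' @param length sequence length (>= 60; 110 mimics a PH domain).
#' @param effect archetype strength in \[0, 1\].
#' @param seed integer seed for this case's private stream.
#' @param loop_start,loop_len 0-based window offset and width.
#' @param pattern motif used for planting/verification.
#' @param case_id identifier.
#' @return a `synthetic_case`: list with `case_id`, `true_group`,
#'   `sequence`, `loop_window` (0-based half-open), `effect`, `seed`.
#' @export
generate_sequence_case <- function(group, length = 110L, effect = 1,
                                   seed = 1L, loop_start = 9L,
                                   loop_len = 24L,
                                   pattern = default_motif(),
                                   case_id = paste0("case_g", group)) {
  stopifnot(group %in% 1:4, length >= 60L, effect >= 0, effect <= 1,
            loop_start + loop_len <= length)
  win <- c(loop_start, loop_start + loop_len)
  seq_chars <- with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      s <- draw_archetype_sequence(group, length, effect, loop_start,
                                   loop_len)
      txt <- paste(s, collapse = "")
      hits <- scan_motif(txt, pattern, loop_window = win)
      ok <- if (group %in% c(2L, 4L)) {
        nrow(hits) == 0L
      } else if (effect >= 1) {
        sum(hits$in_loop) == 1L
      } else TRUE
      if (ok) break
    }
    if (!ok) {
      warning("rejection sampling exhausted for group ", group,
              "; reseeding")
      set.seed(case_seed(seed + 7L, 1L))
      s <- draw_archetype_sequence(group, length, effect, loop_start,
                                   loop_len)
    }
    s
  })
  structure(list(case_id = case_id, true_group = as.integer(group),
                 sequence = paste(seq_chars, collapse = ""),
                 loop_window = win, effect = effect, seed = seed),
            class = "synthetic_case")
}

# one draw of the archetype; consumes an RNG stream whose layout does not
# depend on `effect`, so a shared seed couples draws across effect levels
draw_archetype_sequence <- function(group, length, effect, loop_start,
                                    loop_len) {
  s <- sample(AA1, length, replace = TRUE)
  idx <- loop_start + seq_len(loop_len)  # 1-based window positions

  gap <- sample(6:11, 1)
  x1 <- sample(AA1, 1); x2 <- sample(AA1, 1)
  sg <- sample(c("S", "G"), 1)
  kr <- sample(c("K", "R"), 1)
  motif_letters <- c("K", x1, sg, rep(NA, gap), kr, x2, "R")
  inst_len <- length(motif_letters)

  archetype <- rep(NA_character_, loop_len)
  if (group %in% c(1L, 3L)) {
    archetype[seq_len(inst_len)] <- motif_letters
    spacer <- 3L + seq_len(gap)
    tail_pos <- (inst_len + 1L):loop_len
    if (group == 1L) {
      archetype[spacer] <- sample(HYDROPHILIC_SET, gap, replace = TRUE)
      archetype[tail_pos] <- sample(HYDROPHILIC_SET, length(tail_pos),
                                    replace = TRUE)
    } else {
      archetype[spacer] <- sample(HYDROPHOBIC_SET, gap, replace = TRUE)
      archetype[tail_pos] <- s[idx[tail_pos]]  # background tail
    }
  } else if (group == 2L) {
    archetype <- sample(HYDROPHILIC_SET, loop_len, replace = TRUE)
  }
  u <- stats::runif(loop_len)
  alt <- sample(AA1, loop_len, replace = TRUE)
  planted <- ifelse(!is.na(archetype) & u < effect, archetype,
                    ifelse(is.na(archetype), s[idx], alt))
  # positions without an archetype letter keep the background residue
  planted[is.na(archetype)] <- s[idx][is.na(archetype)]
  s[idx] <- planted
  s
}

#' Generate a labelled case set across groups
#'
#' Case `i` of the set runs on its own stream seeded by
#' `(master seed, case index)`, so any case regenerates bit-identically
#' in isolation.
#'
#' @param n_per_group cases per group.
#' @param groups group labels to generate.
#' @param effect archetype strength.
#' @param seed master seed.
#' @param ... forwarded to [generate_sequence_case()].
#' @return list of `synthetic_case`s.
#' @export
generate_sequence_set <- function(n_per_group = 100L, groups = 1:4,
                                  effect = 1, seed = 1L, ...) {
  cases <- list()
  k <- 0L
  for (g in groups) {
    for (r in seq_len(n_per_group)) {
      k <- k + 1L
      cases[[k]] <- generate_sequence_case(
        g, effect = effect, seed = case_seed(seed, k),
        case_id = sprintf("g%d_r%03d", g, r), ...)
    }
  }
  cases
}

#' Run the classifier over a generated case set
#'
#' @param cases list from [generate_sequence_set()].
#' @param thresholds classifier thresholds.
#' @param window profile smoothing window.
#' @return list: `results` data.frame (id, true_group, group, ...),
#'   `recovery` overall fraction correct.
#' @export
recover_groups <- function(cases, thresholds = default_thresholds(),
                           window = 9L) {
  seqs <- stats::setNames(vapply(cases, `[[`, "", "sequence"),
                          vapply(cases, `[[`, "", "case_id"))
  win <- cases[[1]]$loop_window
  res <- classify_sequences(seqs, win, window = window,
                            thresholds = thresholds)
  res$true_group <- vapply(cases, `[[`, 1L, "true_group")
  list(results = res, recovery = mean(res$group == res$true_group))
}

#' Generate a toy protein-ligand complex
#'
#' Protein atoms are packed sequentially into a sphere (uniform rejection
#' sampling, minimum separation 2.4 Angstrom, also against the ligand)
#' and assigned hydropathy classes via real residue/atom names (GLY
#' CA/N/O/C, SER OG) so the packaged class table applies. The ligand is
#' an inositol-phosphate-like hetero residue (`IPT`): a six-carbon ring
#' with phosphate groups (P + ester O + three terminal O) at the
#' configured ring positions and hydroxyl O elsewhere. The ring is placed
#' along +x beyond the protein sphere: the C4 substituent faces the
#' protein, the C1 substituent points to solvent. Optional `pockets` add
#' protein atoms of a chosen class around a group, creating controlled
#' contact chemistry.
#'
#' @param n_protein_atoms number of packed protein atoms (>= 3).
#' @param ligand_spec list: `phosphate_positions` (ring carbons carrying
#'   phosphates), `offset` (gap between protein sphere surface and ring
#'   centre, Angstrom; larger = less contact).
#' @param seed integer seed.
#' @param hydrophobic_fraction fraction of packed atoms that are
#'   hydrophobic.
#' @param pockets list of `list(group, class, n, distance)` entries.
#' @param class_probs optional named probability vector over the five
#'   classes, overriding `hydrophobic_fraction`.
#' @param case_id identifier.
#' @return a `synthetic_case` with `structure` (a `ph_structure`),
#'   `ligand_resname`, and the generator parameters.
#' @export
generate_toy_complex <- function(n_protein_atoms = 40L,
                                 ligand_spec = list(
                                   phosphate_positions = c(1, 3, 4, 5),
                                   offset = 2.5),
                                 seed = 1L, hydrophobic_fraction = 0.5,
                                 pockets = NULL, class_probs = NULL,
                                 case_id = "toy_complex") {
  stopifnot(n_protein_atoms >= 3L)
  pos <- ligand_spec$phosphate_positions
  offset <- ligand_spec$offset %||% 2.5
  stopifnot(all(pos %in% 1:6))

  rp <- 2.4 * n_protein_atoms^(1 / 3)
  lig <- build_toy_ligand(pos, centre = c(rp + offset, 0, 0))

  with_seed(seed, {
    pxyz <- matrix(NA_real_, n_protein_atoms, 3)
    placed <- 0L
    attempts <- 0L
    while (placed < n_protein_atoms) {
      attempts <- attempts + 1L
      if (attempts > 1000L * n_protein_atoms) {
        stop("cannot pack ", n_protein_atoms,
             " atoms without clashes; reduce the count")
      }
      cand <- stats::runif(3, -rp, rp)
      if (sum(cand^2) > rp^2) next
      ok <- TRUE
      if (placed > 0L) {
        d2 <- rowSums(sweep(pxyz[seq_len(placed), , drop = FALSE], 2,
                            cand)^2)
        ok <- all(d2 >= 2.4^2)
      }
      if (ok && any(rowSums(sweep(lig$xyz, 2, cand)^2) < 2.4^2)) ok <- FALSE
      if (ok) {
        placed <- placed + 1L
        pxyz[placed, ] <- cand
      }
    }
    cls_names <- c("hydrophobic", "donor", "acceptor", "donor_acceptor",
                   "neutral")
    probs <- if (is.null(class_probs)) {
      c(hydrophobic_fraction, rep((1 - hydrophobic_fraction) / 4, 4))
    } else {
      p <- stats::setNames(rep(0, 5), cls_names)
      p[names(class_probs)] <- class_probs
      p
    }
    classes <- sample(cls_names, n_protein_atoms, replace = TRUE,
                      prob = probs)

    if (!is.null(pockets)) {
      dirs <- fibonacci_sphere(96L)
      for (pk in pockets) {
        ganchor <- lig$group_anchor[[pk$group]]
        if (is.null(ganchor)) stop("pocket group ", pk$group, " not in ligand")
        added <- 0L
        for (d in seq_len(nrow(dirs))) {
          if (added >= pk$n) break
          cand <- ganchor + dirs[d, ] * pk$distance
          d2p <- if (nrow(pxyz)) rowSums(sweep(pxyz, 2, cand)^2) else Inf
          d2l <- rowSums(sweep(lig$xyz, 2, cand)^2)
          if (all(d2p >= 2.4^2) && all(d2l >= 2.4^2)) {
            pxyz <- rbind(pxyz, cand)
            classes <- c(classes, pk$class)
            added <- added + 1L
          }
        }
        if (added < pk$n) {
          warning("placed only ", added, "/", pk$n, " pocket atoms for ",
                  pk$group)
        }
      }
    }

    class_atom <- c(hydrophobic = "CA", donor = "N", acceptor = "O",
                    donor_acceptor = "OG", neutral = "C")
    class_res <- c(hydrophobic = "GLY", donor = "GLY", acceptor = "GLY",
                   donor_acceptor = "SER", neutral = "GLY")
    class_elem <- c(hydrophobic = "C", donor = "N", acceptor = "O",
                    donor_acceptor = "O", neutral = "C")
    np <- nrow(pxyz)
    atoms_xyz <- rbind(pxyz, lig$xyz)
    st <- make_structure(
      atoms_xyz,
      element = c(class_elem[classes], lig$element),
      atom_name = c(class_atom[classes], lig$atom_name),
      residue_name = c(class_res[classes], rep("IPT", nrow(lig$xyz))),
      residue_seq_id = c(seq_len(np), rep(np + 1L, nrow(lig$xyz))),
      chain_id = c(rep("A", np), rep("L", nrow(lig$xyz))),
      is_hetero = c(rep(FALSE, np), rep(TRUE, nrow(lig$xyz))))

    structure(list(case_id = case_id, structure = st,
                   ligand_resname = "IPT",
                   protein_classes = classes,
                   phosphate_positions = pos, offset = offset,
                   seed = seed,
                   params = list(n_protein_atoms = n_protein_atoms,
                                 hydrophobic_fraction = hydrophobic_fraction,
                                 pockets = pockets)),
              class = "synthetic_case")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# six-carbon ring + phosphates/hydroxyls, centred at `centre`,
# substituents radial in the xy-plane (C1 at +x)
build_toy_ligand <- function(phosphate_positions, centre = c(0, 0, 0)) {
  ang <- (seq_len(6) - 1) * pi / 3
  ring <- cbind(1.46 * cos(ang), 1.46 * sin(ang), 0)
  xyz <- ring
  name <- paste0("C", 1:6)
  elem <- rep("C", 6)
  anchor <- list()
  for (k in 1:6) {
    dir <- c(cos(ang[k]), sin(ang[k]), 0)
    if (k %in% phosphate_positions) {
      o_est <- ring[k, ] + dir * 1.43
      p <- ring[k, ] + dir * (1.43 + 1.60)
      # three terminal oxygens, tetrahedral-ish around P
      perp1 <- c(-sin(ang[k]), cos(ang[k]), 0)
      perp2 <- c(0, 0, 1)
      term <- rbind(
        p + 1.50 * (dir * 0.333 + perp1 * 0.943),
        p + 1.50 * (dir * 0.333 - perp1 * 0.471 + perp2 * 0.816),
        p + 1.50 * (dir * 0.333 - perp1 * 0.471 - perp2 * 0.816))
      xyz <- rbind(xyz, o_est, p, term)
      name <- c(name, paste0("O", k), paste0("P", k),
                paste0("O", k, 1:3))
      elem <- c(elem, "O", "P", rep("O", 3))
      anchor[[paste0("P", k)]] <- p + centre
    } else {
      xyz <- rbind(xyz, ring[k, ] + dir * 1.43)
      name <- c(name, paste0("O", k))
      elem <- c(elem, "O")
    }
  }
  xyz <- sweep(xyz, 2, centre, `+`)
  list(xyz = xyz, atom_name = name, element = elem, group_anchor = anchor)
}

#' @export
print.synthetic_case <- function(x, ...) {
  if (!is.null(x$sequence)) {
    cat("<synthetic_case> ", x$case_id, ": group ", x$true_group,
        ", length ", nchar(x$sequence), ", effect ", x$effect, "\n",
        sep = "")
  } else {
    cat("<synthetic_case> ", x$case_id, ": toy complex, ",
        nrow(x$structure$atoms), " atoms\n", sep = "")
  }
  invisible(x)
}
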