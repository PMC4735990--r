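#' Build a validated run configuration
#'
#' A run configuration collects every tunable of the end-to-end analysis.
#' It can come from a YAML file ([read_run_config()]) or be built in code.
#' The configuration is serialized into the output directory on every run
#' so results are reproducible from their own copy.
#'
#' @param sequences FASTA path (optional if `alignment` given).
#' @param alignment Stockholm/aligned-FASTA path (optional).
#' @param pdbs named list of structure entries: each
#'   `list(path, ligand_resname)` (optional).
#' @param scales character vector of scale names/paths (default H, F, E,
#'   I built-ins).
#' @param window odd smoothing window.
#' @param loop_windows list of named windows, at least `beta1_beta2 =
#'   c(start, end)` (0-based half-open).
#' @param loop_coordinates `"sequence"` or `"alignment"` (windows given
#'   in alignment columns are mapped through each row's column map).
#' @param probe probe radius, Angstrom.
#' @param pb list of Poisson-Boltzmann settings (`padding`, `n_longest`,
#'   `eps_solute`, `eps_solvent`, `ionic_strength`, `mode`).
#' @param thresholds a [classifier_thresholds()] object.
#' @param motif_file pattern file path (packaged default if NULL).
#' @param out_dir output directory.
#' @param seed integer seed recorded and applied at run start.
#' @return a `run_config` list.
#' @export
run_config <- function(sequences = NULL, alignment = NULL, pdbs = NULL,
                       scales = c("H", "F", "E", "I"), window = 9L,
                       loop_windows = list(beta1_beta2 = c(9L, 33L)),
                       loop_coordinates = c("sequence", "alignment"),
                       probe = 1.4,
                       pb = list(padding = 20, n_longest = 123L,
                                 eps_solute = 2, eps_solvent = 80,
                                 ionic_strength = 0.145,
                                 mode = "nonlinear"),
                       thresholds = default_thresholds(),
                       motif_file = NULL, out_dir = "phspec_run",
                       seed = 1L) {
  loop_coordinates <- match.arg(loop_coordinates)
  if (is.null(sequences) && is.null(alignment)) {
    stop("config needs at least sequences or an alignment")
  }
  if (window %% 2L == 0L || window < 1L) stop("window must be odd, >= 1")
  if (is.null(loop_windows$beta1_beta2)) {
    stop("loop_windows must include beta1_beta2")
  }
  structure(list(sequences = sequences, alignment = alignment, pdbs = pdbs,
                 scales = scales, window = as.integer(window),
                 loop_windows = loop_windows,
                 loop_coordinates = loop_coordinates, probe = probe,
                 pb = pb, thresholds = thresholds, motif_file = motif_file,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- if (!is.null(y$thresholds)) {
    classifier_thresholds(y$thresholds$tau_hydrophobic_peak,
                          y$thresholds$tau_charge,
                          y$thresholds$tau_hydrophilic)
  } else default_thresholds()
  args <- y[setdiff(names(y), "thresholds")]
  args$thresholds <- thr
  if (!is.null(args$loop_windows)) {
    args$loop_windows <- lapply(args$loop_windows, as.integer)
  }
  do.call(run_config, args)
}

# hash of the scientific configuration (the output location does not
# change what is computed, so it is excluded)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- serialize_config(config)
  cfg$out_dir <- NULL
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$thresholds <- unclass(cfg$thresholds)
  cfg
}

#' Run the end-to-end analysis
#'
#' Stages: physicochemical profiles (and alignment mapping when an
#' alignment is supplied), motif scanning, group classification, then per
#' structure input: SASA/exposure (apo and complex, with buried-area
#' binding-site flags), contact report, and Poisson-Boltzmann surface
#' potentials. Structure stages are skipped with a notice when no PDB
#' inputs are configured. Outputs land in `config$out_dir`: a copy of the
#' config, `profiles.tsv`, `motif_hits.tsv`, `predictions.tsv`,
#' `summary.tsv`, and per-structure `sasa_<id>.tsv`, `contacts_<id>.tsv`,
#' `potential_<id>.dx`, `surface_<id>.tsv`, plus `run_log.txt`. Every
#' tabular output names the config hash in a header comment. Repeated
#' runs from the same config are byte-identical.
#'
#' @param config a [run_config()] (or YAML path).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  log_add("phspec pipeline, config hash ", hash)
  yaml::write_yaml(serialize_config(config), file.path(out, "config.yaml"))

  stage <- "profiles"
  results <- list()
  tryCatch({
    # ---- sequences & alignment ----
    aln <- NULL
    if (!is.null(config$alignment)) {
      aln <- read_alignment(config$alignment)
      seqs <- vapply(aln, function(s) gsub("-", "", s, fixed = TRUE), "")
    } else {
      seqs <- read_fasta(config$sequences)
    }
    scales <- lapply(config$scales, load_scale)
    names(scales) <- vapply(scales, scale_name, "")

    profs <- list()
    for (id in names(seqs)) {
      for (sc in names(scales)) {
        profs[[paste(id, sc)]] <- compute_profile(seqs[[id]], scales[[sc]],
                                                  config$window, id)
      }
    }
    aps <- NULL
    if (!is.null(aln)) {
      aps <- map_profiles_to_alignment(profs, aln)
    }
    write_profiles_tsv(profs, aps, names(scales),
                       file.path(out, "profiles.tsv"), hash)
    results$profiles <- profs
    log_add("stage profiles: ", length(seqs), " sequence(s), scales ",
            paste(names(scales), collapse = ","))

    # ---- loop windows in sequence coordinates ----
    stage <- "loops"
    wins <- resolve_loop_windows(config, seqs, aps)

    # ---- motif + classification ----
    stage <- "classify"
    pattern <- if (is.null(config$motif_file)) default_motif()
               else read_motif_patterns(config$motif_file)[[1]]
    hits <- do.call(rbind, lapply(names(seqs), function(id) {
      scan_motif(seqs[[id]], pattern, loop_window = wins[[id]],
                 sequence_id = id)
    }))
    write_tsv(hits, file.path(out, "motif_hits.tsv"), hash)
    preds <- classify_sequences(seqs, wins, window = config$window,
                                pattern = pattern,
                                thresholds = config$thresholds,
                                scales = list(H = scales$H, E = scales$E))
    write_tsv(preds, file.path(out, "predictions.tsv"), hash)
    results$predictions <- preds
    log_add("stage classify: ", nrow(preds), " prediction(s)")

    # ---- structures ----
    if (length(config$pdbs)) {
      for (sid in names(config$pdbs)) {
        stage <- paste0("structure:", sid)
        entry <- config$pdbs[[sid]]
        st <- read_structure(entry$path)
        lig <- ligand_mask(st, entry$ligand_resname %||% "IPT")
        st$atoms$is_hetero <- st$atoms$is_hetero | lig
        apo <- lee_richards_sasa(st, config$probe,
                                 include = !st$atoms$is_hetero)
        expo <- exposure_fractions(apo, window = config$window)
        if (any(lig)) {
          cpx <- lee_richards_sasa(st, config$probe)
          ds <- delta_sasa(apo, cpx)
          expo <- merge(expo, ds[, c("chain_id", "residue_seq_id", "insert",
                                     "residue_name", "buried",
                                     "binding_site")],
                        sort = FALSE)
          rep3 <- contact_report(st, probe = config$probe)
          write_tsv(cbind(complex_id = sid, rep3),
                    file.path(out, paste0("contacts_", sid, ".tsv")), hash)
          results$contacts[[sid]] <- rep3
        }
        write_tsv(expo, file.path(out, paste0("sasa_", sid, ".tsv")), hash)

        charges <- assign_charges(st)
        grid <- solve_pb(st, charges,
                         eps_solute = config$pb$eps_solute %||% 2,
                         eps_solvent = config$pb$eps_solvent %||% 80,
                         ionic_strength = config$pb$ionic_strength %||% 0.145,
                         mode = config$pb$mode %||% "nonlinear",
                         padding = config$pb$padding %||% 20,
                         n_longest = config$pb$n_longest %||% 123L)
        write_opendx(grid, file.path(out, paste0("potential_", sid, ".dx")))
        sp <- surface_potential(st, grid, probe = config$probe)
        write_tsv(sp, file.path(out, paste0("surface_", sid, ".tsv")), hash)
        log_add("stage ", stage, ": ", nrow(st$atoms), " atoms, PB ",
                grid$iterations, " sweeps")
      }
    } else {
      log_add("stage structures: skipped (no PDB inputs configured)")
    }

    # ---- summary against packaged reference labels ----
    stage <- "summary"
    ref <- reference_groups()
    shared <- intersect(preds$id, ref$domain)
    summary_df <- data.frame(n_sequences = nrow(preds),
                             n_reference_matched = length(shared),
                             accuracy = NA_real_)
    if (length(shared)) {
      ev <- evaluate_against_reference(preds, ref)
      summary_df$accuracy <- ev$accuracy
      results$evaluation <- ev
    }
    write_tsv(summary_df, file.path(out, "summary.tsv"), hash)
  }, error = function(e) {
    log_add("FAILED at stage ", stage, ": ", conditionMessage(e))
    writeLines(log_lines, file.path(out, "run_log.txt"))
    stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
         " (partial outputs in ", out, ")", call. = FALSE)
  })
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(results)
}

resolve_loop_windows <- function(config, seqs, aps) {
  win <- as.integer(config$loop_windows$beta1_beta2)
  if (config$loop_coordinates == "sequence") {
    return(stats::setNames(rep(list(win), length(seqs)), names(seqs)))
  }
  if (is.null(aps)) {
    stop("alignment-coordinate loop windows need an alignment input")
  }
  out <- lapply(names(seqs), function(id) {
    cm <- aps$column_map[[id]]
    cols <- (win[1] + 1L):win[2]
    res <- cm[cols]
    res <- res[!is.na(res)]
    if (!length(res)) {
      stop("loop window maps to no residues for sequence '", id, "'")
    }
    c(min(res), max(res) + 1L)
  })
  stats::setNames(out, names(seqs))
}

write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_profiles_tsv <- function(profs, aps, scale_names, path, hash) {
  ids <- unique(vapply(profs, `[[`, "", "sequence_id"))
  rows <- lapply(ids, function(id) {
    p1 <- profs[[paste(id, scale_names[1])]]
    n <- nchar(p1$residues)
    res <- strsplit(p1$residues, "")[[1]]
    if (!is.null(aps)) {
      cm <- aps$column_map[[id]]
      cols <- which(!is.na(cm)) - 1L
      ridx <- cm[!is.na(cm)]
    } else {
      cols <- ridx <- seq_len(n) - 1L
    }
    df <- data.frame(sequence_id = id, alignment_column = cols,
                     residue_index = ridx, residue = res[ridx + 1L])
    for (sc in scale_names) {
      df[[sc]] <- profs[[paste(id, sc)]]$values[ridx + 1L]
    }
    df
  })
  write_tsv(do.call(rbind, rows), path, hash)
}
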