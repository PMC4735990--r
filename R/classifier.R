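#' Classifier thresholds
#'
#' Three numbers operationalize the qualitative decision flow: a
#' "notable hydrophobic peak" level on the smoothed hydropathy profile
#' (`tau_hydrophobic_peak`, Kyte-Doolittle units), the minimum beta1/beta2
#' charge-concentration peak of specific binders (`tau_charge`, ECI
#' units), and the minimum loop hydrophilicity of Group 2
#' (`tau_hydrophilic`, negated Kyte-Doolittle units). Packaged defaults
#' are calibrated as midpoints between the synthetic archetype group
#' means (see the calibration script under `analysis/`).
#'
#' @param tau_hydrophobic_peak,tau_charge,tau_hydrophilic finite numbers.
#' @return a `classifier_thresholds` list.
#' @export
classifier_thresholds <- function(tau_hydrophobic_peak, tau_charge,
                                  tau_hydrophilic) {
  vals <- c(tau_hydrophobic_peak, tau_charge, tau_hydrophilic)
  if (!all(is.finite(vals))) stop("thresholds must be finite")
  structure(list(tau_hydrophobic_peak = tau_hydrophobic_peak,
                 tau_charge = tau_charge,
                 tau_hydrophilic = tau_hydrophilic),
            class = "classifier_thresholds")
}

#' Packaged default thresholds
#' @return a [classifier_thresholds()] object.
#' @export
default_thresholds <- function() {
  y <- yaml::read_yaml(phspec_file("classifier_defaults.yaml"))
  classifier_thresholds(y$tau_hydrophobic_peak, y$tau_charge,
                        y$tau_hydrophilic)
}

#' Assign a PH-domain sequence to a binding-specificity group
#'
#' The decision flow: (1) an in-loop 3-phosphate signature hit sends the
#' sequence to the \{1, 3\} branch, otherwise \{2, 4\}; (2) within
#' \{1, 3\}, a smoothed-hydropathy peak in the beta1/beta2 window at or
#' above `tau_hydrophobic_peak` gives Group 3, else Group 1; (3) within
#' \{2, 4\}, a charge-concentration peak below `tau_charge` together with
#' loop hydrophilicity (negated mean smoothed hydropathy) below
#' `tau_hydrophilic` gives Group 4, else Group 2.
#'
#' @param profiles named list with `H` (hydropathy) and `E`
#'   (charge-concentration) [compute_profile()] objects for the sequence.
#' @param motif_hits data.frame from [scan_motif()] (with `in_loop` set).
#' @param loops list with `beta1_beta2 = c(start, end)` (0-based,
#'   half-open, sequence coordinates).
#' @param thresholds a [classifier_thresholds()] object.
#' @return a `group_prediction`: list with `group` (1-4), `evidence`
#'   (motif hit, loop statistics) and `rule_trace` (replayable decisions).
#' @export
classify <- function(profiles, motif_hits, loops,
                     thresholds = default_thresholds()) {
  for (need in c("H", "E")) {
    if (is.null(profiles[[need]])) {
      stop("missing required profile: ", need)
    }
  }
  if (is.null(loops$beta1_beta2)) stop("missing beta1/beta2 loop window")
  win <- loops$beta1_beta2
  n <- nchar(profiles$H$residues)
  if (win[1] < 0 || win[2] > n || win[2] <= win[1]) {
    stop("beta1/beta2 window [", win[1], ", ", win[2],
         ") out of sequence bounds (length ", n, ")")
  }
  cols <- (win[1] + 1L):win[2]
  h <- profiles$H$values[cols]
  e <- profiles$E$values[cols]
  evidence <- list(
    motif_hit = nrow(motif_hits) > 0 && any(motif_hits$in_loop %in% TRUE),
    motif_start = if (nrow(motif_hits) && any(motif_hits$in_loop %in% TRUE))
      motif_hits$start[which(motif_hits$in_loop %in% TRUE)[1]] else NA_integer_,
    loop_hydropathy_max = max(h),
    loop_charge_max = max(e),
    loop_hydrophilicity = -mean(h))

  trace <- list(list(rule = "motif", value = evidence$motif_hit,
                     outcome = if (evidence$motif_hit) "{1,3}" else "{2,4}"))
  if (evidence$motif_hit) {
    hot <- evidence$loop_hydropathy_max >= thresholds$tau_hydrophobic_peak
    trace <- c(trace, list(list(
      rule = "hydrophobic_peak", value = evidence$loop_hydropathy_max,
      threshold = thresholds$tau_hydrophobic_peak,
      decision = hot, outcome = if (hot) "3" else "1")))
    group <- if (hot) 3L else 1L
  } else {
    low_e <- evidence$loop_charge_max < thresholds$tau_charge
    low_phil <- evidence$loop_hydrophilicity < thresholds$tau_hydrophilic
    trace <- c(trace, list(list(
      rule = "charge_and_hydrophilicity",
      value = c(charge = evidence$loop_charge_max,
                hydrophilicity = evidence$loop_hydrophilicity),
      threshold = c(charge = thresholds$tau_charge,
                    hydrophilicity = thresholds$tau_hydrophilic),
      decision = low_e && low_phil,
      outcome = if (low_e && low_phil) "4" else "2")))
    group <- if (low_e && low_phil) 4L else 2L
  }
  structure(list(group = group, evidence = evidence, rule_trace = trace),
            class = "group_prediction")
}

#' @export
print.group_prediction <- function(x, ...) {
  cat("<group_prediction> Group ", x$group, " (motif: ",
      x$evidence$motif_hit, ", H max ",
      sprintf("%.2f", x$evidence$loop_hydropathy_max), ", E max ",
      sprintf("%.2f", x$evidence$loop_charge_max), ")\n", sep = "")
  invisible(x)
}

#' Replay a recorded rule trace
#'
#' Re-executes the decisions stored in a prediction's trace and returns
#' the group label they imply; equals `prediction$group` by construction.
#'
#' @param prediction a [classify()] result.
#' @return group label in 1..4.
#' @export
replay_trace <- function(prediction) {
  tr <- prediction$rule_trace
  stopifnot(tr[[1]]$rule == "motif")
  if (tr[[1]]$value) {
    step <- tr[[2]]
    if (step$value >= step$threshold) 3L else 1L
  } else {
    step <- tr[[2]]
    if (step$value[["charge"]] < step$threshold[["charge"]] &&
        step$value[["hydrophilicity"]] < step$threshold[["hydrophilicity"]])
      4L else 2L
  }
}

#' Classify a set of sequences end to end
#'
#' Convenience wrapper: computes H and E profiles, scans the motif, and
#' applies [classify()] per sequence.
#'
#' @param sequences named character vector.
#' @param loop_window `c(start, end)` 0-based half-open, shared, or a
#'   named list per sequence.
#' @param window profile smoothing window.
#' @param pattern motif pattern.
#' @param thresholds classifier thresholds.
#' @param scales named list with `H` and `E` scales (defaults loaded).
#' @return data.frame: `id`, `group`, `motif_hit`, `loop_H_max`,
#'   `loop_E_max`, `loop_hydrophilicity`; predictions attached as the
#'   `predictions` attribute.
#' @export
classify_sequences <- function(sequences, loop_window, window = 9L,
                               pattern = default_motif(),
                               thresholds = default_thresholds(),
                               scales = list(H = load_scale("H"),
                                             E = load_scale("E"))) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  preds <- vector("list", length(sequences))
  rows <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    win <- if (is.list(loop_window)) loop_window[[ids[i]]] else loop_window
    prof <- list(
      H = compute_profile(sequences[[i]], scales$H, window, ids[i]),
      E = compute_profile(sequences[[i]], scales$E, window, ids[i]))
    hits <- scan_motif(sequences[[i]], pattern, loop_window = win,
                       sequence_id = ids[i])
    p <- classify(prof, hits, list(beta1_beta2 = win), thresholds)
    preds[[i]] <- p
    rows[[i]] <- data.frame(
      id = ids[i], group = p$group, motif_hit = p$evidence$motif_hit,
      loop_H_max = p$evidence$loop_hydropathy_max,
      loop_E_max = p$evidence$loop_charge_max,
      loop_hydrophilicity = p$evidence$loop_hydrophilicity)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictions") <- stats::setNames(preds, ids)
  out
}

#' Compare predictions against reference group labels
#'
#' @param predictions data.frame with `id` and `group` (or named vector).
#' @param reference named vector of true groups, or a data.frame with
#'   columns `id`/`domain` and `group`.
#' @return list: `confusion` (4x4, rows = reference), `accuracy`,
#'   `per_group_recall`, `unmatched` ids (excluded).
#' @export
evaluate_against_reference <- function(predictions, reference) {
  if (is.data.frame(predictions)) {
    pred <- stats::setNames(predictions$group, predictions$id)
  } else {
    pred <- predictions
  }
  if (is.data.frame(reference)) {
    idcol <- intersect(c("id", "domain"), names(reference))[1]
    reference <- stats::setNames(reference$group, reference[[idcol]])
  }
  shared <- intersect(names(pred), names(reference))
  unmatched <- c(setdiff(names(pred), shared), setdiff(names(reference),
                                                       shared))
  if (!length(shared)) stop("no shared identifiers to evaluate")
  truth <- factor(reference[shared], levels = 1:4)
  guess <- factor(pred[shared], levels = 1:4)
  confusion <- table(reference = truth, prediction = guess)
  recall <- diag(confusion) / pmax(1, rowSums(confusion))
  recall[rowSums(confusion) == 0] <- NA
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / length(shared),
       per_group_recall = recall,
       unmatched = unmatched)
}

#' Packaged reference group labels of representative PH domains
#'
#' @return data.frame: `domain`, `group`, `pdb_ids`.
#' @export
reference_groups <- function() {
  utils::read.table(phspec_file("reference_groups.tsv"), header = TRUE,
                    sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Packaged quantum-mechanical ligand descriptor table
#'
#' Read-only report context (dipole moments, electronic spatial extents,
#' energies of the inositol phosphates); never recomputed by this package.
#'
#' @return data.frame keyed by `ligand`.
#' @export
ligand_descriptors <- function() {
  utils::read.table(phspec_file("ligand_descriptors.tsv"), header = TRUE,
                    sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
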