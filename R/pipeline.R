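# End-to-end pipeline drivers: classify an existing archive, or stream a
# simulated cohort through classification without retaining trajectories
# (large cohorts would not fit in memory otherwise).

#' Classify every molecule of an archive
#'
#' @param archive A `mol_archive` whose metadata carries a `timeline` (or
#'   pass `tl` explicitly).
#' @param tl A [protocol_timeline()]; defaults to the archive metadata.
#' @param cfg A [classify_config()].
#' @param p A [wlc_params()].
#' @param bead A [bead_model()].
#' @return List with `classification` (one row per molecule), `bursts`
#'   (named list by uid), `breaks` (output of [detect_breaks()] over the
#'   accepted molecules), and `archive` (records tagged and parameterized).
#' @export
classify_cohort <- function(archive, tl = NULL, cfg = classify_config(),
                            p = wlc_params(), bead = bead_model()) {
  if (is.null(tl)) {
    if (is.null(archive$metadata$timeline)) {
      stop("classify_cohort: no timeline in archive metadata; pass tl")
    }
    tl <- as_protocol_timeline(archive$metadata$timeline)
  }
  rows <- vector("list", length(archive))
  bursts <- list()
  uids <- archive_uids(archive)
  for (i in seq_along(uids)) {
    rec <- get_record(archive, uids[i])
    res <- classify_molecule(rec, tl, cfg, p, bead)
    rows[[i]] <- res$classification
    bursts[[uids[i]]] <- res$bursts
    cl <- res$classification
    for (tag in c("mobile", "coilable", "single", "accepted")) {
      if (isTRUE(cl[[tag]])) rec$tags <- union(rec$tags, tag)
    }
    if (!is.na(cl$mode)) rec$tags <- union(rec$tags, cl$mode)
    rec$parameters$force_pN <- cl$force_pN
    rec$parameters$length_um <- cl$length_um
    rec$parameters$turn_slope_nm_per_turn <- cl$turn_slope_nm_per_turn
    rec$parameters$reversal_amplitude_um <- cl$reversal_amplitude
    archive <- update_record(archive, rec, "classified by feature pipeline")
  }
  classification <- do.call(rbind, rows)
  rownames(classification) <- NULL
  acc <- classification[classification$accepted, , drop = FALSE]
  brk <- if (nrow(acc) >= 2) detect_breaks(acc, bursts, tl) else NULL
  list(classification = classification, bursts = bursts, breaks = brk,
       archive = archive)
}

#' Simulate a cohort and classify it, streaming molecule by molecule
#'
#' Equivalent to `classify_cohort(simulate_cohort(spec, tl), tl)` but each
#' trajectory is discarded right after classification, so cohorts of tens
#' of thousands of molecules stay within memory.
#'
#' @param spec A [cohort_spec()].
#' @param tl A [protocol_timeline()].
#' @param cfg A [classify_config()].
#' @param p A [wlc_params()].
#' @param bead A [bead_model()].
#' @return List with `classification`, `bursts`, `breaks`, and `truth`
#'   (the generator's per-molecule design plus injected kinetics).
#' @export
run_cohort_pipeline <- function(spec = cohort_spec(), tl = default_timeline(),
                                cfg = classify_config(), p = wlc_params(),
                                bead = bead_model()) {
  design <- cohort_truth_design(spec)
  rows <- vector("list", nrow(design))
  bursts <- list()
  truth_rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    rec <- simulate_protocol_trace(
      class = design$class[i], tl = tl, kinetics = spec$kinetics,
      model = spec$model, p = p, bead = bead,
      force_pN = design$force_pN[i], noise_sd_um = spec$noise_sd_um,
      attachment = c(design$attach_x[i], design$attach_y[i]),
      uid = design$uid[i], seed = design$seed[i])
    res <- classify_molecule(rec, tl, cfg, p, bead)
    rows[[i]] <- res$classification
    bursts[[design$uid[i]]] <- res$bursts
    truth_rows[[i]] <- data.frame(
      uid = design$uid[i], class = design$class[i],
      force_pN = design$force_pN[i],
      mode = rec$parameters$truth_mode %||% NA_character_,
      v_pos = rec_param(rec, "truth_v_pos"),
      v_neg = rec_param(rec, "truth_v_neg"),
      t_break = rec_param(rec, "truth_t_break"),
      stringsAsFactors = FALSE)
  }
  classification <- do.call(rbind, rows)
  truth <- do.call(rbind, truth_rows)
  rownames(classification) <- rownames(truth) <- NULL
  acc <- classification[classification$accepted, , drop = FALSE]
  brk <- if (nrow(acc) >= 2) detect_breaks(acc, bursts, tl) else NULL
  list(classification = classification, bursts = bursts, breaks = brk,
       truth = truth)
}
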