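#' Run the full signature-whistle pipeline
#'
#' Convenience wrapper chaining the whole analysis on annotated contours:
#' merge short breaks, assemble whistles, build the REWT catalogue with
#' copy removal, apply the SIGID criteria to flag signature whistle types,
#' census bouts and single occurrences, compute IWI/ILI statistics with
#' boat-noise exclusion, measure the acoustic parameter panel of the
#' signature types, and (given enough encounters) fit the diversity GAMs.
#'
#' @param contours list of [contour_trace()] objects.
#' @param encounters encounter metadata data.frame (see
#'   [read_encounters()]).
#' @param linked_pairs passed to [assemble_whistles()].
#' @param models diversity GAM model tags to fit (default `1:3`); set to
#'   `NULL` to skip the diversity model.
#' @param min_encounters_for_gam minimum encounters required before GAMs
#'   are attempted (default 10).
#' @return list with `whistles`, `catalogue` (with `is_signature` filled),
#'   `kept`/`removed` per-type whistle lists, `signature_types`, `bouts`
#'   (occasion census for signature types), `iwi`, `ili`, `params`
#'   (per-type panel) and `param_summary`, `diversity` (table),
#'   `gam_fits`, `gam_comparison`, `catalogue_summary`.
#' @export
run_whistle_pipeline <- function(contours, encounters, linked_pairs = NULL,
                                 models = 1:3,
                                 min_encounters_for_gam = 10) {
  merged <- merge_breaks(contours)
  whistles <- assemble_whistles(merged, linked_pairs = linked_pairs)
  cat_out <- build_catalogue(whistles, encounters)
  catalogue <- cat_out$catalogue

  catalogue$is_signature <- vapply(catalogue$type_id, function(tid) {
    catalogue$is_rewt[catalogue$type_id == tid] &&
      sigid_flag(cat_out$kept[[tid]])
  }, logical(1))
  signature_types <- catalogue$type_id[catalogue$is_signature]

  sig_kept <- cat_out$kept[signature_types]
  bouts <- if (length(sig_kept)) {
    do.call(rbind, lapply(signature_types, function(tid) {
      b <- detect_bouts(sig_kept[[tid]])
      if (nrow(b)) cbind(type_id = tid, b) else NULL
    }))
  } else NULL
  iwi <- iwi_statistics(sig_kept, encounters)
  ili <- suppressWarnings(
    ili_statistics(unlist(sig_kept, recursive = FALSE)))

  # parameter panel uses pre-copy-removal sequences: both members of a
  # copying pair are disqualified inside the selection step
  tab <- whistle_table(whistles)
  by_type_all <- split(whistles, tab$type_label)
  params <- measure_type_parameters(by_type_all[signature_types])
  param_summary <- if (nrow(params)) summarize_parameters(params) else NULL

  diversity <- build_diversity_table(whistles, signature_types, encounters)
  gam_fits <- NULL; gam_comparison <- NULL
  if (!is.null(models) && nrow(diversity) >= min_encounters_for_gam) {
    gam_fits <- lapply(models, function(m) fit_gam(diversity, model = m))
    gam_comparison <- compare_models(gam_fits)
  }

  list(whistles = whistles, catalogue = catalogue,
       kept = cat_out$kept, removed = cat_out$removed,
       signature_types = signature_types,
       bouts = bouts, iwi = iwi, ili = ili,
       params = params, param_summary = param_summary,
       diversity = diversity, gam_fits = gam_fits,
       gam_comparison = gam_comparison,
       catalogue_summary = summarize_catalogue(catalogue))
}
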