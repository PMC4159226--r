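# REWT catalogue: repetition flagging, copy handling and per-type /
# catalogue-level occurrence summaries.

#' Flag a whistle type as repeatedly emitted (REWT)
#'
#' A whistle category is a repeatedly emitted whistle type when its
#' whistles are produced at least twice within 0.25 s to 10 s of each other
#' during a recording section. Separation is measured from the end of one
#' whistle's last loop to the start of the next whistle's first loop, per
#' section (here: per encounter, each synthetic encounter being one
#' continuous recording).
#'
#' @param whistles list of `whistle` objects of one type.
#' @param min_sep,max_sep repetition window, seconds (defaults 0.25, 10).
#' @return `TRUE` iff some adjacent same-section pair falls in the window.
#' @export
flag_rewt <- function(whistles, min_sep = 0.25, max_sep = 10) {
  if (length(whistles) < 2L) return(FALSE)
  tab <- whistle_table(whistles)
  for (enc in unique(tab$encounter_id)) {
    sub <- tab[tab$encounter_id == enc, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) < 2L) next
    sep <- sub$start[-1L] - sub$end[-nrow(sub)]
    if (any(in_interval(sep, min_sep, max_sep))) return(TRUE)
  }
  FALSE
}

#' Classify one contour against the REWT catalogue
#'
#' Pass-2 bookkeeping around the human (or synthetic) label: a label
#' present in the catalogue is passed through (low-SNR contours may still
#' be assigned, flagged `low_snr`); the sentinels `VARIABLE` and
#' `UNCLASSIFIED` pass through; an unlabelled contour is `UNCLASSIFIED`;
#' any other label is an error.
#'
#' @param contour a [contour_trace()].
#' @param catalogue_ids character vector of catalogued type ids.
#' @return character scalar (type id or sentinel), with attribute
#'   `low_snr` when an SNR-1 contour was assigned to a REWT.
#' @export
classify_to_catalogue <- function(contour, catalogue_ids) {
  lab <- contour$type_label
  if (is.na(lab) || lab == "UNCLASSIFIED") return("UNCLASSIFIED")
  if (lab == "VARIABLE") return("VARIABLE")
  if (!lab %in% catalogue_ids)
    stopf("label '%s' is neither catalogued nor a sentinel", lab)
  structure(lab, low_snr = contour$snr_grade == 1L)
}

#' Remove overlapping same-type whistle copies
#'
#' Whistle copying is detected as two whistles of the same type overlapping
#' in time. The decision rule keeps the first whistle produced and removes
#' the later-starting one; in a mutually overlapping chain every whistle
#' overlapping an already-kept whistle is removed. Exact start-time ties
#' are broken by whistle id and logged in the `"tie_log"` attribute.
#'
#' @param whistles list of same-type `whistle` objects.
#' @return list with `kept` and `removed` whistle lists; `kept` contains no
#'   same-type overlaps and `|kept| + |removed|` equals the input size.
#' @export
remove_copies <- function(whistles) {
  if (length(whistles) == 0L) return(list(kept = list(), removed = list()))
  starts <- vapply(whistles, `[[`, 0, "start_time")
  ids <- vapply(whistles, `[[`, "", "whistle_id")
  ties <- character(0)
  if (anyDuplicated(starts)) {
    dup <- starts[duplicated(starts)]
    ties <- ids[starts %in% dup]
  }
  ord <- order(starts, ids)
  whistles <- whistles[ord]
  kept <- list(); removed <- list()
  for (w in whistles) {
    overlap <- any(vapply(kept, function(k)
      k$encounter_id == w$encounter_id &&
        spans_intersect(k$start_time, k$end_time, w$start_time, w$end_time),
      logical(1)))
    if (overlap) removed[[length(removed) + 1L]] <- w
    else kept[[length(kept) + 1L]] <- w
  }
  out <- list(kept = kept, removed = removed)
  if (length(ties)) attr(out, "tie_log") <- ties
  out
}

format_years <- function(years) {
  years <- sort(unique(as.integer(years)))
  if (length(years) == 0L) return("")
  paste(c(years[1L], sprintf("%02d", years[-1L] %% 100)), collapse = "/")
}

#' Summarise one whistle type (catalogue row)
#'
#' Emits one catalogue row for a type: category size after copy removal,
#' number of days the type appeared exactly once, encounter count, years
#' and sites, and the loop-structure split as integer percentages of the
#' category size (halves rounded away from zero).
#'
#' @param type_id type id.
#' @param whistles copy-removed list of the type's `whistle` objects.
#' @param encounters encounter metadata (data.frame with `encounter_id`,
#'   `date`, `site`), used for day/year/site attribution.
#' @return one-row data.frame with the catalogue columns.
#' @export
summarize_type <- function(type_id, whistles, encounters) {
  tab <- whistle_table(whistles)
  idx <- match(tab$encounter_id, encounters$encounter_id)
  if (anyNA(idx))
    stopf("type %s: whistles reference unknown encounter(s): %s", type_id,
          paste(unique(tab$encounter_id[is.na(idx)]), collapse = ", "))
  dates <- encounters$date[idx]
  sites <- encounters$site[idx]
  per_day <- table(as.character(dates))
  struct <- factor(tab$structure, levels = c("SE", "CML", "DCML"))
  pct <- round_half_up(100 * as.vector(table(struct)) / nrow(tab))
  data.frame(type_id = type_id,
             category_size = nrow(tab),
             single_occurrence_days = sum(per_day == 1L),
             n_encounters = length(unique(tab$encounter_id)),
             n_days = length(per_day),
             years = format_years(format(dates, "%Y")),
             sites = paste(sort(unique(sites)), collapse = "/"),
             pct_se = pct[1L], pct_cml = pct[2L], pct_dcml = pct[3L],
             stringsAsFactors = FALSE)
}

#' Build the REWT catalogue from classified whistles
#'
#' Groups whistles by type label (sentinels and unlabelled whistles are set
#' aside), applies the copy rule per type, flags repetition (REWT) and
#' emits the catalogue table. Signature status is filled in by
#' [sigid_flag()] via [run_whistle_pipeline()] or by the caller.
#'
#' @param whistles list of `whistle` objects (assembled, classified).
#' @param encounters encounter metadata data.frame.
#' @return list with `catalogue` (data.frame, one row per type, with
#'   `is_rewt` and `is_signature` columns - the latter `NA` until the
#'   SIGID pass), `kept` (named list of copy-removed whistles per type) and
#'   `removed` (copies).
#' @export
build_catalogue <- function(whistles, encounters) {
  tab <- whistle_table(whistles)
  usable <- !is.na(tab$type_label) &
    !tab$type_label %in% c("VARIABLE", "UNCLASSIFIED")
  by_type <- split(whistles[usable], tab$type_label[usable])
  rows <- list(); kept <- list(); removed <- list()
  for (type_id in names(by_type)) {
    cr <- remove_copies(by_type[[type_id]])
    kept[[type_id]] <- cr$kept
    removed[[type_id]] <- cr$removed
    row <- summarize_type(type_id, cr$kept, encounters)
    row$is_rewt <- flag_rewt(cr$kept)
    row$is_signature <- NA
    rows[[type_id]] <- row
  }
  catalogue <- if (length(rows)) do.call(rbind, rows)
               else summarize_type_empty()
  rownames(catalogue) <- NULL
  list(catalogue = catalogue, kept = kept, removed = removed)
}

summarize_type_empty <- function() {
  data.frame(type_id = character(), category_size = integer(),
             single_occurrence_days = integer(), n_encounters = integer(),
             n_days = integer(), years = character(), sites = character(),
             pct_se = numeric(), pct_cml = numeric(), pct_dcml = numeric(),
             is_rewt = logical(), is_signature = logical(),
             stringsAsFactors = FALSE)
}

#' Catalogue-level occurrence summary
#'
#' Summarises a catalogue table: total whistles, mean +/- SD of category
#' sizes and encounter counts, and the derived stability fractions - share
#' of types recorded in two or more years, in more than one encounter, with
#' at least one single-occurrence day, and the number recorded at more than
#' one site. Percentages are integers, halves rounded away from zero. The
#' loop-structure mean is reported both unweighted across types and
#' weighted by category size (the two differ; both are labelled).
#'
#' @param catalogue data.frame with the catalogue columns (from
#'   [build_catalogue()], [read_catalogue()] or [walvis_catalogue()]).
#' @return list of summary statistics.
#' @export
summarize_catalogue <- function(catalogue) {
  if (nrow(catalogue) == 0L) stopf("catalogue is empty")
  n <- nrow(catalogue)
  n_years <- if ("n_years" %in% names(catalogue)) catalogue$n_years
             else lengths(strsplit(catalogue$years, "/", fixed = TRUE))
  multi_site <- lengths(strsplit(catalogue$sites, "/", fixed = TRUE)) > 1L
  w <- catalogue$category_size
  unweighted <- c(se = mean(catalogue$pct_se), cml = mean(catalogue$pct_cml),
                  dcml = mean(catalogue$pct_dcml))
  weighted <- c(se = sum(catalogue$pct_se * w), cml = sum(catalogue$pct_cml * w),
                dcml = sum(catalogue$pct_dcml * w)) / sum(w)
  list(n_types = n,
       total_whistles = sum(w),
       mean_category_size = mean(w),
       sd_category_size = stats::sd(w),
       max_category_size = max(w),
       mean_encounters = mean(catalogue$n_encounters),
       sd_encounters = stats::sd(catalogue$n_encounters),
       pct_multi_year = round_half_up(100 * mean(n_years >= 2L)),
       pct_multi_encounter = round_half_up(100 * mean(catalogue$n_encounters > 1L)),
       pct_single_occurrences = round_half_up(
         100 * mean(catalogue$single_occurrence_days > 0L)),
       n_multi_site = sum(multi_site),
       structure_mean_unweighted = unweighted,
       structure_mean_weighted = weighted)
}
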