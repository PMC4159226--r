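#' Read contour annotations
#'
#' Reads per-contour time-frequency traces from disk and validates them
#' against the contour criteria (>= 0.1 s duration, fundamental partly
#' above 3 kHz). Two dialects are supported:
#'
#' \describe{
#'   \item{`trace_csv`}{the canonical long format, one row per trace
#'     point: `contour_id, encounter_id, time_s, freq_hz, amp_db?, snr,
#'     masked, type_label?, loop_count?`.}
#'   \item{`raven_selection`}{a Raven-Pro-style tab-delimited selection
#'     table with columns `Begin Time (s)`, `End Time (s)`,
#'     `Low Freq (Hz)`, `High Freq (Hz)`. Each selection becomes a
#'     two-point trace flagged `coarse = TRUE`; no intra-contour shape is
#'     available, so shape-dependent parameters refuse coarse traces.}
#' }
#'
#' Contours that violate the contour criteria are not silently dropped:
#' they are reported in the `"rejected"` attribute of the returned list
#' (columns `contour_id`, `reason`) and a message summarises the count.
#'
#' @param path file path.
#' @param dialect `"trace_csv"` (default) or `"raven_selection"`.
#' @param encounter_id encounter to assign to Raven selections (that
#'   dialect carries none); ignored for trace CSVs.
#' @return list of [contour_trace()] objects, with attribute `"rejected"`,
#'   a data.frame reporting contours that failed validation.
#' @export
read_contours <- function(path, dialect = c("trace_csv", "raven_selection"),
                          encounter_id = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "trace_csv") read_trace_csv(path)
  else read_raven_selection(path, encounter_id)
}

read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("contour_id", "encounter_id", "time_s", "freq_hz", "snr", "masked")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("trace CSV %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  if (!"amp_db" %in% names(df)) df$amp_db <- NA_real_
  if (!"type_label" %in% names(df)) df$type_label <- NA_character_
  df$type_label[!nzchar(trimws(as.character(df$type_label)))] <- NA
  if (!"loop_count" %in% names(df)) df$loop_count <- NA_integer_
  ids <- unique(df$contour_id)
  contours <- list()
  rejected <- data.frame(contour_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (id in ids) {
    rows <- df[df$contour_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    res <- tryCatch(
      contour_trace(
        contour_id = id,
        encounter_id = rows$encounter_id[1L],
        points = data.frame(time = rows$time_s, freq = rows$freq_hz,
                            amp = rows$amp_db),
        snr_grade = rows$snr[1L],
        masked = isTRUE(as.logical(rows$masked[1L])),
        type_label = as.character(rows$type_label[1L]),
        loop_count = suppressWarnings(as.integer(rows$loop_count[1L]))),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rejected <- rbind(rejected, data.frame(contour_id = id, reason = res,
                                             stringsAsFactors = FALSE))
    } else {
      contours[[length(contours) + 1L]] <- res
    }
  }
  if (nrow(rejected))
    message(sprintf("read_contours: %d contour(s) rejected by the contour criteria (see attr(x, 'rejected'))",
                    nrow(rejected)))
  attr(contours, "rejected") <- rejected
  contours
}

read_raven_selection <- function(path, encounter_id) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Begin Time (s)", "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("Raven selection table %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  sel_id <- if ("Selection" %in% names(df)) as.character(df$Selection)
            else sprintf("sel_%d", seq_len(nrow(df)))
  contours <- list()
  rejected <- data.frame(contour_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(
      contour_trace(
        contour_id = sel_id[i], encounter_id = encounter_id,
        points = data.frame(time = c(df[["Begin Time (s)"]][i],
                                     df[["End Time (s)"]][i]),
                            freq = c(df[["Low Freq (Hz)"]][i],
                                     df[["High Freq (Hz)"]][i])),
        coarse = TRUE),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rejected <- rbind(rejected, data.frame(contour_id = sel_id[i],
                                             reason = res,
                                             stringsAsFactors = FALSE))
    } else {
      contours[[length(contours) + 1L]] <- res
    }
  }
  if (nrow(rejected))
    message(sprintf("read_contours: %d selection(s) rejected by the contour criteria",
                    nrow(rejected)))
  attr(contours, "rejected") <- rejected
  contours
}

#' Write a contour table to the canonical trace CSV
#'
#' Inverse of [read_contours()] for the `trace_csv` dialect.
#'
#' @param contours list of [contour_trace()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  rows <- do.call(rbind, lapply(contours, function(x) {
    data.frame(contour_id = x$contour_id, encounter_id = x$encounter_id,
               time_s = x$points$time, freq_hz = x$points$freq,
               amp_db = x$points$amp, snr = x$snr_grade, masked = x$masked,
               type_label = x$type_label, loop_count = x$loop_count,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read encounter metadata
#'
#' One row per encounter: date, site, estimated group size, calf presence
#' and recording effort, with optional intervals of high boat noise in a
#' `"start-end;start-end"` syntax (seconds, recording-relative).
#'
#' @param path CSV path with columns `encounter_id, date, site, group_size,
#'   calves_present, recording_minutes` and optionally `noise_intervals`.
#' @return data.frame with one row per encounter; `noise_intervals` is a
#'   list column of two-column matrices (`start`, `end`).
#' @export
read_encounters <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("encounter_id", "date", "site", "group_size",
                "calves_present", "recording_minutes")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("encounter table %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  if (any(!is.finite(df$group_size) | df$group_size <= 0))
    stopf("encounter table: group_size must be a positive integer")
  if (any(!is.finite(df$recording_minutes) | df$recording_minutes <= 0))
    stopf("encounter table: recording_minutes must be positive")
  df$date <- as.Date(df$date)
  df$calves_present <- as.logical(df$calves_present)
  raw <- if ("noise_intervals" %in% names(df)) df$noise_intervals
         else rep("", nrow(df))
  df$noise_intervals <- lapply(seq_len(nrow(df)), function(i)
    parse_noise_intervals(raw[i], df$recording_minutes[i] * 60,
                          df$encounter_id[i]))
  df
}

parse_noise_intervals <- function(s, span, encounter_id) {
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (is.na(s) || !nzchar(trimws(s))) return(empty)
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  out <- t(vapply(parts, function(p) {
    ab <- suppressWarnings(as.numeric(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (length(ab) != 2 || any(!is.finite(ab)))
      stopf("encounter %s: malformed noise interval '%s'", encounter_id, p)
    ab
  }, numeric(2)))
  dimnames(out) <- list(NULL, c("start", "end"))
  if (any(out[, 1] > out[, 2]) || any(out < 0) || any(out[, 2] > span))
    stopf("encounter %s: noise intervals must be well-ordered, non-negative and within the recording span",
          encounter_id)
  if (nrow(out) > 1 && any(diff(out[, 1]) < 0))
    out <- out[order(out[, 1]), , drop = FALSE]
  out
}

#' Write encounter metadata
#'
#' Inverse of [read_encounters()]; noise intervals are serialised back to
#' the `"start-end;start-end"` syntax.
#'
#' @param encounters data.frame as returned by [read_encounters()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_encounters <- function(encounters, path) {
  out <- encounters
  out$noise_intervals <- vapply(encounters$noise_intervals, function(m) {
    if (is.null(m) || nrow(m) == 0) return("")
    paste(sprintf("%g-%g", m[, 1], m[, 2]), collapse = ";")
  }, character(1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

catalogue_columns <- c("type_id", "category_size", "single_occurrence_days",
                       "n_encounters", "years", "sites",
                       "pct_se", "pct_cml", "pct_dcml")

#' Write / read the whistle-type catalogue table
#'
#' The catalogue table mirrors the published summary layout: one row per
#' whistle type with its category size (after copy removal), the number of
#' days it appeared exactly once, encounter/day counts, years and sites of
#' occurrence, and the per-type loop-structure percentages (SE / CML /
#' DCML, integer percent of category size). Round-trips losslessly.
#'
#' @param records data.frame with columns `type_id, category_size,
#'   single_occurrence_days, n_encounters, years, sites, pct_se, pct_cml,
#'   pct_dcml` (extra columns such as `is_rewt`/`is_signature` are kept).
#' @param path tab-delimited output path.
#' @return for `write_catalogue`, `path` invisibly; for `read_catalogue`,
#'   the catalogue data.frame.
#' @export
write_catalogue <- function(records, path) {
  missing <- setdiff(catalogue_columns, names(records))
  if (length(missing))
    stopf("catalogue is missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(records$type_id))
    stopf("catalogue has duplicate type ids: %s",
          paste(unique(records$type_id[duplicated(records$type_id)]),
                collapse = ", "))
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(type_id = "character",
                                         years = "character",
                                         sites = "character"))
  missing <- setdiff(catalogue_columns, names(df))
  if (length(missing))
    stopf("catalogue %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Read a two-stage rating task from CSV
#'
#' Stage 1 is a similarity-rating table (`judge_id, item_id, template_id,
#' rating` on a 1-5 scale); stage 2 a forced-choice assignment table
#' (`judge_id, item_id, assigned_template`). Returns a rating tensor in the
#' layout used by the agreement module.
#'
#' @param stage1_path,stage2_path CSV paths.
#' @return a `rating_tensor`: list with `stage1` (array judge x item x
#'   template), `stage2` (matrix item x judge), and the id vectors.
#' @export
read_rating_task <- function(stage1_path, stage2_path) {
  r1 <- utils::read.csv(stage1_path, stringsAsFactors = FALSE)
  r2 <- utils::read.csv(stage2_path, stringsAsFactors = FALSE)
  need1 <- c("judge_id", "item_id", "template_id", "rating")
  need2 <- c("judge_id", "item_id", "assigned_template")
  if (length(setdiff(need1, names(r1))))
    stopf("stage-1 ratings need columns: %s", paste(need1, collapse = ", "))
  if (length(setdiff(need2, names(r2))))
    stopf("stage-2 assignments need columns: %s", paste(need2, collapse = ", "))
  if (!all(r1$rating %in% 1:5))
    stopf("stage-1 ratings must be integers on the 1-5 scale")
  judges <- sort(unique(c(r1$judge_id, r2$judge_id)))
  items <- sort(unique(c(r1$item_id, r2$item_id)))
  templates <- sort(unique(r1$template_id))
  stage1 <- array(NA_real_, dim = c(length(judges), length(items),
                                    length(templates)),
                  dimnames = list(judges, items, templates))
  stage1[cbind(match(r1$judge_id, judges), match(r1$item_id, items),
               match(r1$template_id, templates))] <- r1$rating
  stage2 <- matrix(NA_character_, nrow = length(items), ncol = length(judges),
                   dimnames = list(items, judges))
  stage2[cbind(match(r2$item_id, items), match(r2$judge_id, judges))] <-
    r2$assigned_template
  bad <- stats::na.omit(unique(as.vector(stage2)))
  bad <- setdiff(bad, templates)
  if (length(bad))
    stopf("stage-2 assignments outside the template set: %s",
          paste(bad, collapse = ", "))
  structure(list(stage1 = stage1, stage2 = stage2, judges = judges,
                 items = items, templates = templates, truth = NULL),
            class = "rating_tensor")
}
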