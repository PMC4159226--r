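#' Annotated whistle contour traces
#'
#' A contour is the basic annotated unit of the analysis: a narrow-band
#' tonal trace of the fundamental frequency, lasting at least 0.1 s with at
#' least part of the fundamental above 3 kHz. `contour_trace()` constructs
#' and validates one contour from its time-frequency samples plus quality
#' metadata (harmonics are never represented; only the fundamental is).
#'
#' Times are recording-relative seconds (continuous, not sample indices);
#' frequencies are Hz internally and reported in kHz by the parameter
#' module.
#'
#' @param contour_id opaque contour identifier.
#' @param encounter_id opaque encounter identifier.
#' @param points data.frame with numeric columns `time` (s, strictly
#'   increasing), `freq` (Hz, > 0) and optionally `amp` (relative dB).
#' @param snr_grade integer signal-to-noise grade: 1 (faint), 2 (clear),
#'   3 (prominent).
#' @param masked logical; was the contour partly masked by other sound?
#' @param type_label whistle-type label from visual classification, or one
#'   of the sentinels `"VARIABLE"` / `"UNCLASSIFIED"`, or `NA` when
#'   unlabelled.
#' @param coarse logical; `TRUE` for two-point traces imported from
#'   selection tables, which carry no intra-contour shape.
#' @param loop_count optional integer annotation: number of connected loop
#'   repeats within this single contour (connected multi-loop whistles).
#' @param validate logical; check the contour criteria (default `TRUE`).
#' @param min_duration minimum contour duration in seconds (default 0.1).
#' @param min_peak_freq minimum value the contour's maximum fundamental
#'   frequency must exceed, Hz (default 3000).
#' @return an object of class `"contour_trace"`.
#' @examples
#' tr <- contour_trace("c1", "E1",
#'   data.frame(time = seq(0, 0.5, 0.1), freq = seq(4000, 9000, 1000)))
#' ct_duration(tr)
#' @export
contour_trace <- function(contour_id, encounter_id, points,
                          snr_grade = 2L, masked = FALSE,
                          type_label = NA_character_, coarse = FALSE,
                          loop_count = NA_integer_, validate = TRUE,
                          min_duration = 0.1, min_peak_freq = 3000) {
  if (!is.data.frame(points) || !all(c("time", "freq") %in% names(points)))
    stopf("`points` must be a data.frame with columns time and freq")
  if (!"amp" %in% names(points)) points$amp <- NA_real_
  points <- points[, c("time", "freq", "amp")]
  x <- structure(
    list(contour_id = as.character(contour_id),
         encounter_id = as.character(encounter_id),
         points = points,
         snr_grade = as.integer(snr_grade),
         masked = isTRUE(masked),
         type_label = as.character(type_label),
         coarse = isTRUE(coarse),
         loop_count = as.integer(loop_count)),
    class = "contour_trace")
  if (validate) validate_contour(x, min_duration = min_duration,
                                 min_peak_freq = min_peak_freq)
  x
}

#' Validate a contour against the contour criteria
#'
#' Checks the structural invariants (finite, strictly increasing times,
#' positive frequencies, SNR grade in 1..3) and the contour criteria: a
#' duration of at least `min_duration` seconds and a maximum fundamental
#' frequency above `min_peak_freq` Hz.
#'
#' @inheritParams contour_trace
#' @param x a `contour_trace`.
#' @return `x`, invisibly; errors describe the first violated criterion.
#' @export
validate_contour <- function(x, min_duration = 0.1, min_peak_freq = 3000) {
  p <- x$points
  if (nrow(p) < 2L)
    stopf("contour %s: needs at least 2 trace points", x$contour_id)
  if (any(!is.finite(p$time)) || any(p$time < 0))
    stopf("contour %s: times must be finite and non-negative", x$contour_id)
  if (any(diff(p$time) <= 0))
    stopf("contour %s: times must be strictly increasing", x$contour_id)
  if (any(!is.finite(p$freq)) || any(p$freq <= 0))
    stopf("contour %s: frequencies must be finite and positive", x$contour_id)
  if (!x$snr_grade %in% 1:3)
    stopf("contour %s: snr_grade must be 1, 2 or 3", x$contour_id)
  dur <- ct_duration(x)
  if (dur < min_duration)
    stopf("contour %s: duration %.3f s below the %.2f s contour criterion",
          x$contour_id, dur, min_duration)
  if (max(p$freq) <= min_peak_freq)
    stopf("contour %s: maximum frequency %.0f Hz does not exceed %.0f Hz",
          x$contour_id, max(p$freq), min_peak_freq)
  invisible(x)
}

#' @rdname contour_trace
#' @export
ct_start <- function(x) x$points$time[1L]

#' @rdname contour_trace
#' @export
ct_end <- function(x) x$points$time[nrow(x$points)]

#' @rdname contour_trace
#' @export
ct_duration <- function(x) ct_end(x) - ct_start(x)

#' @export
print.contour_trace <- function(x, ...) {
  cat(sprintf(
    "<contour_trace %s> encounter %s | %.3f-%.3f s | %.2f-%.2f kHz | %d pts%s\n",
    x$contour_id, x$encounter_id, ct_start(x), ct_end(x),
    min(x$points$freq) / 1000, max(x$points$freq) / 1000, nrow(x$points),
    if (is.na(x$type_label)) "" else paste0(" | ", x$type_label)))
  invisible(x)
}

#' Tabulate a list of contours
#'
#' One row per contour: identifiers, span, frequency extent and quality
#' metadata. Convenient for joins and quick inspection.
#'
#' @param contours list of `contour_trace` objects.
#' @return data.frame with one row per contour.
#' @export
contour_table <- function(contours) {
  if (length(contours) == 0L)
    return(data.frame(contour_id = character(), encounter_id = character(),
                      start = numeric(), end = numeric(),
                      min_freq = numeric(), max_freq = numeric(),
                      snr_grade = integer(), masked = logical(),
                      type_label = character(), coarse = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(contours, function(x) {
    data.frame(contour_id = x$contour_id, encounter_id = x$encounter_id,
               start = ct_start(x), end = ct_end(x),
               min_freq = min(x$points$freq), max_freq = max(x$points$freq),
               snr_grade = x$snr_grade, masked = x$masked,
               type_label = x$type_label, coarse = x$coarse,
               stringsAsFactors = FALSE)
  }))
}
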