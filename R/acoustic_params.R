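# Acoustic parameter panel: per-whistle measurements and per-type /
# population summaries of the standard signature-whistle parameters.

param_names <- c("start_freq", "end_freq", "min_freq", "max_freq",
                 "freq_range", "peak_freq", "start_aspect", "end_aspect",
                 "duration", "inflections")

#' Count frequency inflection points of a contour
#'
#' An inflection point is a change of the contour's frequency slope from
#' positive to negative aspect or vice versa. The frequency trace is
#' smoothed with a centred moving average of `smooth_window` points before
#' the point-to-point slopes are signed; slopes whose magnitude falls below
#' `flat_tol` (Hz/s) keep the prior sign, so jitter on an otherwise
#' monotone contour does not create spurious inflections.
#'
#' @param points contour points (data.frame `time`, `freq`).
#' @param smooth_window moving-average window, points (default 5).
#' @param flat_tol slope magnitude treated as flat, Hz/s (default 500).
#' @return non-negative integer count (0 with a warning for < 3 points).
#' @export
count_inflections <- function(points, smooth_window = 5L, flat_tol = 500) {
  n <- nrow(points)
  if (n < 3L) {
    warnf("count_inflections: contour has fewer than 3 points")
    return(0L)
  }
  half <- max(0L, (as.integer(smooth_window) - 1L) %/% 2L)
  f <- vapply(seq_len(n), function(i) {
    mean(points$freq[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  slopes <- diff(f) / diff(points$time)
  last_sign <- 0L
  count <- 0L
  for (s in slopes) {
    if (abs(s) < flat_tol) next        # flat keeps the prior sign
    sgn <- if (s > 0) 1L else -1L
    if (last_sign != 0L && sgn != last_sign) count <- count + 1L
    last_sign <- sgn
  }
  count
}

#' Aspect of the start or end slope
#'
#' Sign of the least-squares frequency slope over the first (or last)
#' `edge_fraction` of the contour's duration: +1 positive, 0 constant
#' (|slope| below `flat_tol`), -1 negative. At least 3 points are always
#' used, expanding beyond the edge window if necessary.
#'
#' @param points contour points (data.frame `time`, `freq`).
#' @param edge `"start"` or `"end"`.
#' @param edge_fraction fraction of the duration used (default 0.1).
#' @param flat_tol slope magnitude treated as constant, Hz/s (default 500).
#' @return -1, 0 or +1.
#' @export
slope_aspect <- function(points, edge = c("start", "end"),
                         edge_fraction = 0.1, flat_tol = 500) {
  edge <- match.arg(edge)
  n <- nrow(points)
  if (n < 2L) return(0L)
  span <- (points$time[n] - points$time[1L]) * edge_fraction
  idx <- if (edge == "start") which(points$time <= points$time[1L] + span)
         else which(points$time >= points$time[n] - span)
  if (length(idx) < 3L) {
    idx <- if (edge == "start") seq_len(min(3L, n))
           else seq(max(1L, n - 2L), n)
  }
  tt <- points$time[idx]; ff <- points$freq[idx]
  slope <- sum((tt - mean(tt)) * (ff - mean(ff))) / sum((tt - mean(tt))^2)
  if (!is.finite(slope) || abs(slope) < flat_tol) return(0L)
  if (slope > 0) 1L else -1L
}

#' Measure the acoustic parameter panel of one whistle
#'
#' Start and end frequency are the first and last trace frequencies; the
#' minimum, maximum and peak (frequency at maximal amplitude) are taken
#' over all loop points; range is maximum minus minimum; duration runs
#' from the start of the first loop to the end of the last loop (loop gaps
#' included). Inflection points are counted separately per loop and
#' summed; start/end aspects come from the first loop's start edge and the
#' last loop's end edge. Frequencies are reported in kHz.
#'
#' @param w a `whistle` with full (non-coarse) traces.
#' @param smooth_window,flat_tol passed to [count_inflections()] /
#'   [slope_aspect()].
#' @param edge_fraction passed to [slope_aspect()].
#' @return one-row data.frame of class `whistle_params`; `peak_freq` is
#'   `NA` when no per-point amplitude is available.
#' @export
measure_whistle <- function(w, smooth_window = 5L, flat_tol = 500,
                            edge_fraction = 0.1) {
  if (any(vapply(w$loops, `[[`, FALSE, "coarse")))
    stopf("whistle %s has coarse (selection-table) traces; shape parameters need full traces - supply trace CSV input",
          w$whistle_id)
  pts <- do.call(rbind, lapply(w$loops, `[[`, "points"))
  first <- w$loops[[1L]]$points
  last <- w$loops[[length(w$loops)]]$points
  peak <- if (all(is.na(pts$amp))) NA_real_
          else pts$freq[which.max(pts$amp)] / 1000
  infl <- sum(vapply(w$loops, function(l)
    count_inflections(l$points, smooth_window, flat_tol), integer(1)))
  out <- data.frame(
    whistle_id = w$whistle_id,
    start_freq = first$freq[1L] / 1000,
    end_freq = last$freq[nrow(last)] / 1000,
    min_freq = min(pts$freq) / 1000,
    max_freq = max(pts$freq) / 1000,
    freq_range = (max(pts$freq) - min(pts$freq)) / 1000,
    peak_freq = peak,
    start_aspect = slope_aspect(first, "start", edge_fraction, flat_tol),
    end_aspect = slope_aspect(last, "end", edge_fraction, flat_tol),
    duration = w$end_time - w$start_time,
    inflections = infl,
    stringsAsFactors = FALSE)
  class(out) <- c("whistle_params", class(out))
  out
}

#' Select the measurement sample of a whistle type
#'
#' Parameter measurement uses only high-quality whistles: SNR 2 or 3, not
#' masked, full traces, and neither member of a copying (overlapping)
#' interaction. Within each encounter's same-type sequence, the first run
#' of at least `min_n` consecutive qualifying whistles is taken, capped at
#' `max_n` to prevent large variation in per-type sample size; a type with
#' no such run is excluded from the parameter analysis.
#'
#' @param whistles list of same-type `whistle` objects in production order
#'   (*before* copy removal: both members of each copying pair are
#'   disqualified here, not just the later one).
#' @param min_n,max_n run bounds (defaults 4 and 10).
#' @return list of selected whistles (possibly empty).
#' @export
select_measurement_whistles <- function(whistles, min_n = 4L, max_n = 10L) {
  if (length(whistles) == 0L) return(list())
  tab <- whistle_table(whistles)
  ord <- order(tab$encounter_id, tab$start)
  whistles <- whistles[ord]; tab <- tab[ord, , drop = FALSE]
  in_copy <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    same <- tab$encounter_id == tab$encounter_id[i]
    ovl <- same & spans_intersect(tab$start, tab$end, tab$start[i], tab$end[i])
    ovl[i] <- FALSE
    if (any(ovl)) in_copy[i] <- TRUE
  }
  qualifies <- tab$snr_grade >= 2L & !tab$masked & !tab$coarse & !in_copy
  for (enc in unique(tab$encounter_id)) {
    idx <- which(tab$encounter_id == enc)
    q <- qualifies[idx]
    run_start <- NA_integer_
    for (j in seq_along(q)) {
      if (q[j] && is.na(run_start)) run_start <- j
      if ((!q[j] || j == length(q)) && !is.na(run_start)) {
        run_end <- if (q[j]) j else j - 1L
        if (run_end - run_start + 1L >= min_n) {
          take <- idx[run_start:min(run_end, run_start + max_n - 1L)]
          return(whistles[take])
        }
        run_start <- NA_integer_
      }
    }
  }
  list()
}

#' Per-type acoustic parameter summaries
#'
#' Runs [select_measurement_whistles()] and [measure_whistle()] for every
#' type and reports, per type, the sample size and each parameter's mean
#' and SD (CV = SD/mean x 100 is recomputed on demand). Types without a
#' qualifying run of `min_n` high-quality whistles are omitted.
#'
#' @param whistles_by_type named list of same-type whistle lists.
#' @param min_n,max_n passed to [select_measurement_whistles()].
#' @param ... passed to [measure_whistle()].
#' @return data.frame: `type_id`, `n`, then `<param>_mean` / `<param>_sd`
#'   for each panel parameter.
#' @export
measure_type_parameters <- function(whistles_by_type, min_n = 4L,
                                    max_n = 10L, ...) {
  rows <- list()
  for (type_id in names(whistles_by_type)) {
    sel <- select_measurement_whistles(whistles_by_type[[type_id]],
                                       min_n = min_n, max_n = max_n)
    if (length(sel) == 0L) next
    panel <- do.call(rbind, lapply(sel, measure_whistle, ...))
    row <- data.frame(type_id = type_id, n = nrow(panel),
                      stringsAsFactors = FALSE)
    for (p in param_names) {
      row[[paste0(p, "_mean")]] <- mean(panel[[p]])
      row[[paste0(p, "_sd")]] <- stats::sd(panel[[p]])
    }
    rows[[type_id]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(type_id = character(), n = integer(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Population summary of per-type acoustic parameters
#'
#' Unweighted summary across types (each type one vote): for every
#' parameter, the mean, SD and CV of the per-type means, together with
#' their minimum and maximum (the "ranged from ... to ..." values).
#' `NA` per-type means (e.g. peak frequency without amplitude data) are
#' dropped from that parameter's summary.
#'
#' @param per_type data.frame as returned by [measure_type_parameters()]
#'   or [walvis_type_parameters()].
#' @return list with `population` (data.frame: parameter, mean, sd, cv,
#'   min, max, n_types), `n_types` and `mean_n`.
#' @export
summarize_parameters <- function(per_type) {
  if (nrow(per_type) == 0L) stopf("no per-type parameter summaries supplied")
  rows <- lapply(param_names, function(p) {
    col <- paste0(p, "_mean")
    if (!col %in% names(per_type)) return(NULL)
    x <- per_type[[col]]
    x <- x[is.finite(x)]
    if (length(x) == 0L) return(NULL)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               cv = if (mean(x) != 0) stats::sd(x) / abs(mean(x)) * 100
                    else NA_real_,
               min = min(x), max = max(x), n_types = length(x),
               stringsAsFactors = FALSE)
  })
  population <- do.call(rbind, rows)
  rownames(population) <- NULL
  list(population = population, n_types = nrow(per_type),
       mean_n = mean(per_type$n))
}
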