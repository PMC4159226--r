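# Whistle assembly: merging broken contours, chaining loops into whistles,
# and classifying loop structure (SE / CML / DCML).

labels_same <- function(a, b) {
  (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
}
is_sentinel <- function(lab) !is.na(lab) && lab %in% c("VARIABLE", "UNCLASSIFIED")

#' Merge contours interrupted by very short breaks
#'
#' Contours interrupted by silences shorter than `max_break` (default
#' 0.03 s, open bound) are treated as one continuous contour. Only
#' consecutive contours of the same type label (or both unlabelled) in the
#' same encounter are merged; temporal overlap between two fragments of the
#' same `contour_id` signals corrupt annotation and is an error. The
#' operation is idempotent.
#'
#' @param contours list of [contour_trace()] objects.
#' @param max_break merge silences strictly shorter than this, seconds.
#' @return list of merged contours, sorted by encounter and start time.
#' @export
merge_breaks <- function(contours, max_break = 0.03) {
  if (length(contours) == 0L) return(contours)
  by_enc <- split(contours, vapply(contours, `[[`, "", "encounter_id"))
  out <- list()
  for (group in by_enc) {
    ord <- order(vapply(group, ct_start, numeric(1)))
    group <- group[ord]
    merged <- list(group[[1L]])
    for (x in group[-1L]) {
      prev <- merged[[length(merged)]]
      gap <- ct_start(x) - ct_end(prev)
      if (identical(prev$contour_id, x$contour_id) && gap < 0)
        stopf("overlapping fragments share contour id %s", x$contour_id)
      if (gap >= 0 && gap < max_break &&
          labels_same(prev$type_label, x$type_label) &&
          !is_sentinel(prev$type_label)) {
        prev$points <- rbind(prev$points, x$points)
        prev$snr_grade <- min(prev$snr_grade, x$snr_grade)
        prev$masked <- prev$masked || x$masked
        prev$coarse <- prev$coarse || x$coarse
        if (is.na(prev$loop_count)) prev$loop_count <- x$loop_count
        merged[[length(merged)]] <- prev
      } else {
        merged[[length(merged) + 1L]] <- x
      }
    }
    out <- c(out, merged)
  }
  ord <- order(vapply(out, `[[`, "", "encounter_id"),
               vapply(out, ct_start, numeric(1)))
  out[ord]
}

#' Assemble contours into whistles
#'
#' A whistle is one continuous contour (single element, SE, or connected
#' multi-loop, CML) or two or more repeated contours (loops) separated by
#' silences of `min_gap` to `max_gap` seconds (disconnected multi-loop,
#' DCML; closed interval). Consecutive contours chain into one whistle when
#' their silent gap falls in that window and their type labels agree;
#' contours of *different* labels are never chained unless the label pair
#' has passed the 80\% co-occurrence gate ([check_cooccurrence()]) and is
#' listed in `linked_pairs` (for such pairs temporal overlap is also
#' allowed, since the one known non-identical loop pair overlaps in time).
#' Unlabelled contours chain by the temporal rule alone and the resulting
#' whistle is flagged `provisional`.
#'
#' @param contours list of [contour_trace()] objects, already passed
#'   through [merge_breaks()].
#' @param min_gap,max_gap loop-gap window, seconds (defaults 0.03, 0.25).
#' @param linked_pairs optional list of length-2 character vectors of type
#'   labels allowed to form one whistle unit.
#' @return list of `whistle` objects; every contour belongs to exactly one.
#' @export
assemble_whistles <- function(contours, min_gap = 0.03, max_gap = 0.25,
                              linked_pairs = NULL) {
  if (length(contours) == 0L) return(list())
  linked <- vapply(linked_pairs %||% list(), function(p)
    paste(sort(p), collapse = "\r"), character(1))
  by_enc <- split(contours, vapply(contours, `[[`, "", "encounter_id"))
  whistles <- list()
  for (group in by_enc) {
    ord <- order(vapply(group, ct_start, numeric(1)))
    group <- group[ord]
    current <- list(group[[1L]])
    flush <- function(loops) {
      w <- new_whistle(loops)
      whistles[[length(whistles) + 1L]] <<- w
    }
    for (x in group[-1L]) {
      prev <- current[[length(current)]]
      gap <- ct_start(x) - ct_end(prev)
      la <- prev$type_label; lb <- x$type_label
      pair_linked <- !is.na(la) && !is.na(lb) &&
        paste(sort(c(la, lb)), collapse = "\r") %in% linked
      chain <-
        if (pair_linked) gap <= max_gap
        else if (is_sentinel(la) || is_sentinel(lb)) FALSE
        else labels_same(la, lb) && in_interval(gap, min_gap, max_gap)
      if (chain) {
        current[[length(current) + 1L]] <- x
      } else {
        flush(current)
        current <- list(x)
      }
    }
    flush(current)
  }
  ord <- order(vapply(whistles, `[[`, "", "encounter_id"),
               vapply(whistles, `[[`, 0, "start_time"))
  whistles[ord]
}

new_whistle <- function(loops) {
  labs <- vapply(loops, `[[`, "", "type_label")
  lab <- if (all(is.na(labs))) NA_character_
         else if (length(unique(stats::na.omit(labs))) == 1L)
           stats::na.omit(labs)[1L]
         else paste(unique(stats::na.omit(labs)), collapse = "+")
  w <- structure(
    list(whistle_id = paste0("w_", loops[[1L]]$contour_id),
         encounter_id = loops[[1L]]$encounter_id,
         loops = loops,
         structure = NA_character_,
         start_time = ct_start(loops[[1L]]),
         end_time = max(vapply(loops, ct_end, numeric(1))),
         type_label = lab,
         snr_grade = min(vapply(loops, `[[`, 0L, "snr_grade")),
         masked = any(vapply(loops, `[[`, FALSE, "masked")),
         coarse = any(vapply(loops, `[[`, FALSE, "coarse")),
         provisional = all(is.na(labs))),
    class = "whistle")
  w$structure <- classify_structure(w)
  w
}

#' @export
print.whistle <- function(x, ...) {
  cat(sprintf("<whistle %s> %s | %s | %d loop(s) | %.3f-%.3f s%s\n",
              x$whistle_id, x$encounter_id, x$structure, length(x$loops),
              x$start_time, x$end_time,
              if (is.na(x$type_label)) "" else paste0(" | ", x$type_label)))
  invisible(x)
}

#' Classify whistle loop structure
#'
#' DCML (disconnected multi-loop) when the whistle holds two or more
#' disconnected loops; otherwise CML (connected multi-loop) when its single
#' contour contains two or more repeats of a loop motif - taken from the
#' `loop_count` annotation when present, else detected as near-identical
#' sub-segments of the frequency trace ([detect_motif_repeats()]); else SE
#' (single element).
#'
#' @param w a `whistle`.
#' @param motif_threshold minimum correlation between consecutive
#'   sub-segments for motif autodetection (default 0.9).
#' @return one of `"SE"`, `"CML"`, `"DCML"`.
#' @export
classify_structure <- function(w, motif_threshold = 0.9) {
  if (length(w$loops) >= 2L) return("DCML")
  loop <- w$loops[[1L]]
  if (!is.na(loop$loop_count) && loop$loop_count >= 2L) return("CML")
  if (!loop$coarse &&
      detect_motif_repeats(loop$points, threshold = motif_threshold) >= 2L)
    return("CML")
  "SE"
}

#' Detect repeated loop motifs within a single contour
#'
#' Best-effort autodetection used when no `loop_count` annotation is
#' supplied: the frequency trace is cut into `k` equal-duration segments
#' (k = 2..`max_loops`), each resampled onto a common normalised time grid,
#' and `k` is accepted when every pair of consecutive segments correlates
#' at `threshold` or better *and* matches in absolute frequency (RMS
#' difference within `rms_tol` of the trace's frequency range - repeated
#' loops repeat the same frequencies, whereas e.g. the two halves of a
#' monotone sweep correlate perfectly but sit at different levels).
#' Returns the largest accepted `k`, or 1.
#'
#' @param points contour points (data.frame `time`, `freq`).
#' @param max_loops largest repeat count tried.
#' @param threshold correlation threshold (default 0.9).
#' @param rms_tol maximum RMS segment difference as a fraction of the
#'   trace's frequency range (default 0.15).
#' @param grid_n points per resampled segment.
#' @return integer >= 1: the detected number of motif repeats.
#' @export
detect_motif_repeats <- function(points, max_loops = 6L, threshold = 0.9,
                                 rms_tol = 0.15, grid_n = 40L) {
  n <- nrow(points)
  if (n < 8L) return(1L)
  t0 <- points$time[1L]; t1 <- points$time[n]
  frange <- max(points$freq) - min(points$freq)
  if (frange <= 0) return(1L)
  best <- 1L
  for (k in 2:max_loops) {
    if (n / k < 4L) break
    seg_len <- (t1 - t0) / k
    segs <- lapply(seq_len(k) - 1L, function(j) {
      lo <- t0 + j * seg_len; hi <- lo + seg_len
      grid <- seq(lo, hi, length.out = grid_n)
      stats::approx(points$time, points$freq, xout = grid, rule = 2)$y
    })
    ok <- TRUE
    for (j in seq_len(k - 1L)) {
      a <- segs[[j]]; b <- segs[[j + 1L]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) { ok <- FALSE; break }
      if (stats::cor(a, b) < threshold) { ok <- FALSE; break }
      if (sqrt(mean((a - b)^2)) > rms_tol * frange) { ok <- FALSE; break }
    }
    if (ok) best <- k
  }
  best
}

#' Co-occurrence gate for non-identical loop pairs
#'
#' Two contour types may be treated as loops of a single whistle unit only
#' if they occur together - separated by at most `max_gap` seconds of
#' silence, temporal overlap included - at least 80\% of the time. Returns
#' the co-occurrence fraction for each label (share of its occurrences with
#' the partner adjacent) and the verdict `min(frac_a, frac_b) >= frac`.
#'
#' @param label_a,label_b the two type labels.
#' @param contours classified dataset (list of [contour_trace()]).
#' @param max_gap maximum silent separation, seconds (default 0.25).
#' @param frac required fraction (default 0.80).
#' @return list with `frac_a`, `frac_b`, `n_a`, `n_b`, `verdict`.
#' @export
check_cooccurrence <- function(label_a, label_b, contours,
                               max_gap = 0.25, frac = 0.80) {
  tab <- contour_table(contours)
  a <- tab[!is.na(tab$type_label) & tab$type_label == label_a, ]
  b <- tab[!is.na(tab$type_label) & tab$type_label == label_b, ]
  if (nrow(a) == 0L) stopf("label %s absent from dataset", label_a)
  if (nrow(b) == 0L) stopf("label %s absent from dataset", label_b)
  near <- function(x, other) {
    vapply(seq_len(nrow(x)), function(i) {
      o <- other[other$encounter_id == x$encounter_id[i], , drop = FALSE]
      if (nrow(o) == 0L) return(FALSE)
      sep <- pmax(0, pmax(o$start - x$end[i], x$start[i] - o$end))
      any(sep <= max_gap)
    }, logical(1))
  }
  frac_a <- mean(near(a, b))
  frac_b <- mean(near(b, a))
  list(frac_a = frac_a, frac_b = frac_b, n_a = nrow(a), n_b = nrow(b),
       verdict = min(frac_a, frac_b) >= frac)
}

#' Temporal overlap between two contours
#'
#' Length of the intersection of the two contours' time spans, in seconds;
#' 0 when disjoint. Used to quantify the loop overlap of non-identical
#' disconnected-loop whistle types.
#'
#' @param a,b [contour_trace()] objects from the same encounter.
#' @return overlap in seconds (>= 0).
#' @export
measure_loop_overlap <- function(a, b) {
  max(0, min(ct_end(a), ct_end(b)) - max(ct_start(a), ct_start(b)))
}

#' Tabulate a list of whistles
#'
#' A data.frame input (already in whistle-table form, e.g. from
#' [simulate_whistle_times()]) is passed through unchanged, so the
#' temporal operations accept either representation.
#'
#' @param whistles list of `whistle` objects, or a whistle-table
#'   data.frame with at least `whistle_id`, `encounter_id`, `type_label`,
#'   `start`, `end`.
#' @return data.frame with one row per whistle.
#' @export
whistle_table <- function(whistles) {
  if (is.data.frame(whistles)) return(whistles)
  if (length(whistles) == 0L)
    return(data.frame(whistle_id = character(), encounter_id = character(),
                      type_label = character(), structure = character(),
                      start = numeric(), end = numeric(),
                      n_loops = integer(), snr_grade = integer(),
                      masked = logical(), coarse = logical(),
                      provisional = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(whistles, function(w) {
    data.frame(whistle_id = w$whistle_id, encounter_id = w$encounter_id,
               type_label = w$type_label, structure = w$structure,
               start = w$start_time, end = w$end_time,
               n_loops = length(w$loops), snr_grade = w$snr_grade,
               masked = w$masked, coarse = w$coarse,
               provisional = w$provisional, stringsAsFactors = FALSE)
  }))
}
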