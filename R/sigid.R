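# SIGID: inter-whistle intervals, bout detection and the temporal criteria
# that promote a REWT to a signature whistle type.

sorted_type_table <- function(whistles) {
  tab <- whistle_table(whistles)
  tab[order(tab$encounter_id, tab$start), , drop = FALSE]
}

#' Inter-whistle intervals for one whistle type
#'
#' IWIs are measured from the end of the last loop of one whistle to the
#' start of the first loop of the next same-type whistle, per encounter,
#' after copy removal. Intervals whose span intersects a flagged high
#' boat-noise interval are dropped and counted (`noise_excluded`), since
#' masking makes them unreliable.
#'
#' @param whistles copy-removed list of same-type `whistle` objects.
#' @param encounters optional encounter metadata with a `noise_intervals`
#'   list column (as from [read_encounters()]); omit for no exclusion.
#' @return data.frame with one row per retained adjacent pair
#'   (`encounter_id`, `from`, `to`, `iwi`) and attribute `noise_excluded`.
#' @export
compute_iwis <- function(whistles, encounters = NULL) {
  tab <- sorted_type_table(whistles)
  out <- list(); dropped <- 0L
  for (enc in unique(tab$encounter_id)) {
    sub <- tab[tab$encounter_id == enc, , drop = FALSE]
    if (nrow(sub) < 2L) next
    noise <- NULL
    if (!is.null(encounters)) {
      i <- match(enc, encounters$encounter_id)
      if (!is.na(i)) noise <- encounters$noise_intervals[[i]]
    }
    for (k in seq_len(nrow(sub) - 1L)) {
      iwi <- sub$start[k + 1L] - sub$end[k]
      if (iwi < 0)
        stopf("negative inter-whistle interval in encounter %s: overlapping same-type whistles must be copy-removed first",
              enc)
      noisy <- !is.null(noise) && nrow(noise) > 0 &&
        any(spans_intersect(sub$end[k], sub$start[k + 1L],
                            noise[, 1L], noise[, 2L]))
      if (noisy) {
        dropped <- dropped + 1L
      } else {
        out[[length(out) + 1L]] <- data.frame(
          encounter_id = enc, from = sub$whistle_id[k],
          to = sub$whistle_id[k + 1L], iwi = iwi, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(encounter_id = character(), from = character(),
                         to = character(), iwi = numeric(),
                         stringsAsFactors = FALSE)
  attr(res, "noise_excluded") <- dropped
  res
}

#' SIGID criteria for one whistle type
#'
#' A REWT qualifies as a signature whistle type when, in some encounter, 4
#' or more whistles of the type were recorded and on at least one occasion
#' they were produced in a sequence with 75\% or more occurring within 1 to
#' 10 s of a same-type neighbour. A whistle is "in-interval" when its IWI
#' to the preceding *or* following same-type whistle lies in `[lo, hi]`
#' (the criterion counts whistles, not intervals, which is what makes 3 of
#' 4 attainable with 3 intervals); the 75\% test is evaluated over every
#' window of `window` or more consecutive same-type whistles.
#'
#' @param whistles copy-removed list of same-type `whistle` objects
#'   (whistles of other types are irrelevant and may be absent).
#' @param window minimum sequence length (default 4).
#' @param frac required in-interval fraction (default 0.75).
#' @param lo,hi IWI window in seconds (defaults 1 and 10).
#' @return `TRUE` iff the type meets the criteria in some encounter.
#' @export
sigid_flag <- function(whistles, window = 4L, frac = 0.75, lo = 1, hi = 10) {
  tab <- sorted_type_table(whistles)
  for (enc in unique(tab$encounter_id)) {
    sub <- tab[tab$encounter_id == enc, , drop = FALSE]
    n <- nrow(sub)
    if (n < window) next
    iwi <- sub$start[-1L] - sub$end[-n]
    ok <- in_interval(iwi, lo, hi)
    status <- logical(n)
    for (i in seq_len(n)) {
      status[i] <- (i > 1L && ok[i - 1L]) || (i < n && ok[i])
    }
    for (L in window:n) {
      for (s in seq_len(n - L + 1L)) {
        if (mean(status[s:(s + L - 1L)]) >= frac) return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect production bouts of one whistle type
#'
#' Maximal runs of two or more same-type whistles in which every linking
#' IWI lies in `[lo, hi]` seconds are bouts; whistles outside any bout are
#' single occurrences. Bout count plus single count equals the number of
#' production occasions.
#'
#' @inheritParams sigid_flag
#' @param lo,hi bout-linking IWI window, seconds (defaults 1 and 10).
#' @return data.frame with one row per occasion: `encounter_id`,
#'   `n_whistles`, `start`, `end`, `is_bout`.
#' @export
detect_bouts <- function(whistles, lo = 1, hi = 10) {
  tab <- sorted_type_table(whistles)
  rows <- list()
  for (enc in unique(tab$encounter_id)) {
    sub <- tab[tab$encounter_id == enc, , drop = FALSE]
    n <- nrow(sub)
    linked <- if (n > 1L) in_interval(sub$start[-1L] - sub$end[-n], lo, hi)
              else logical(0)
    run_start <- 1L
    for (i in seq_len(n)) {
      if (i == n || !linked[i]) {
        rows[[length(rows) + 1L]] <- data.frame(
          encounter_id = enc, n_whistles = i - run_start + 1L,
          start = sub$start[run_start], end = sub$end[i],
          is_bout = (i - run_start + 1L) >= 2L, stringsAsFactors = FALSE)
        run_start <- i + 1L
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(encounter_id = character(), n_whistles = integer(),
                  start = numeric(), end = numeric(), is_bout = logical(),
                  stringsAsFactors = FALSE)
}

#' IWI summary statistics over measurement bouts
#'
#' For temporal-production statistics a *measurement bout* is the full
#' sequence of consecutive same-type whistles within an encounter,
#' regardless of gap length, provided it holds at least `min_bout`
#' whistles - long intervals (e.g. hundreds of seconds) are therefore
#' retained, unlike the 1-10 s bout-linking used for SIGID flagging.
#' Intervals masked by boat noise are excluded via [compute_iwis()].
#'
#' @param whistles_by_type named list: per type, a copy-removed list of
#'   `whistle` objects.
#' @param encounters optional encounter metadata for noise exclusion.
#' @param min_bout minimum whistles per encounter for inclusion (default 4).
#' @return list with `per_type` (data.frame: type_id, n_intervals, mean,
#'   sd, median, max, noise_excluded) and `population` (mean/sd/median of
#'   the per-type means, plus the overall maximum).
#' @export
iwi_statistics <- function(whistles_by_type, encounters = NULL,
                           min_bout = 4L) {
  per <- list()
  for (type_id in names(whistles_by_type)) {
    wl <- whistles_by_type[[type_id]]
    tab <- whistle_table(wl)
    keep_enc <- names(which(table(tab$encounter_id) >= min_bout))
    if (length(keep_enc) == 0L) next
    sel <- wl[tab$encounter_id %in% keep_enc]
    iwis <- compute_iwis(sel, encounters)
    if (nrow(iwis) == 0L) next
    per[[type_id]] <- data.frame(
      type_id = type_id, n_intervals = nrow(iwis),
      mean = mean(iwis$iwi), sd = stats::sd(iwis$iwi),
      median = stats::median(iwis$iwi), max = max(iwis$iwi),
      noise_excluded = attr(iwis, "noise_excluded"),
      stringsAsFactors = FALSE)
  }
  per_type <- if (length(per)) do.call(rbind, per)
              else data.frame(type_id = character(), n_intervals = integer(),
                              mean = numeric(), sd = numeric(),
                              median = numeric(), max = numeric(),
                              noise_excluded = integer(),
                              stringsAsFactors = FALSE)
  rownames(per_type) <- NULL
  population <- if (nrow(per_type)) list(
    n_types = nrow(per_type),
    mean = mean(per_type$mean), sd = stats::sd(per_type$mean),
    median = stats::median(per_type$mean), max = max(per_type$max),
    pct_types_mean_under_10s = round_half_up(100 * mean(per_type$mean < 10)))
  else list(n_types = 0L)
  list(per_type = per_type, population = population)
}

#' Inter-loop interval statistics for disconnected multi-loop whistles
#'
#' Collects the silent gaps between consecutive loops of DCML whistles
#' (each necessarily within the 0.03-0.25 s loop window) and summarises
#' them per type and pooled.
#'
#' @param whistles list of `whistle` objects (non-DCML entries ignored).
#' @return list with `per_type` (type_id, n_intervals, mean), `population`
#'   (pooled n/mean/sd and the range of per-type means); empty with a
#'   warning when no DCML whistle is present.
#' @export
ili_statistics <- function(whistles) {
  gaps <- list()
  for (w in whistles) {
    if (is.null(w$structure) || w$structure != "DCML") next
    ends <- vapply(w$loops, ct_end, numeric(1))
    starts <- vapply(w$loops, ct_start, numeric(1))
    g <- starts[-1L] - ends[-length(ends)]
    gaps[[length(gaps) + 1L]] <- data.frame(
      type_id = w$type_label, ili = g, stringsAsFactors = FALSE)
  }
  if (length(gaps) == 0L) {
    warnf("no disconnected multi-loop whistles: empty ILI summary")
    return(list(per_type = data.frame(type_id = character(),
                                      n_intervals = integer(),
                                      mean = numeric(),
                                      stringsAsFactors = FALSE),
                population = list(n_intervals = 0L)))
  }
  all_g <- do.call(rbind, gaps)
  per_type <- do.call(rbind, lapply(split(all_g$ili, all_g$type_id),
    function(x) data.frame(n_intervals = length(x), mean = mean(x))))
  per_type <- data.frame(type_id = rownames(per_type), per_type,
                         stringsAsFactors = FALSE)
  rownames(per_type) <- NULL
  list(per_type = per_type,
       population = list(n_intervals = nrow(all_g),
                         mean = mean(all_g$ili), sd = stats::sd(all_g$ili),
                         min_type_mean = min(per_type$mean),
                         max_type_mean = max(per_type$mean)))
}
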