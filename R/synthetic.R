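# Synthetic data: parametric whistle-type templates, a bout-structured
# emission model and full annotated encounters, so the entire pipeline is
# testable without field recordings.

#' Whistle-type templates
#'
#' Each template is a parametric frequency contour over normalised time
#' (piecewise-linear through random anchor points, forced to visit the
#' template's minimum and maximum frequency), plus a loop plan and a jitter
#' model. Template parameter ranges emulate the published Walvis Bay
#' signature-type panel: mean minimum frequencies in 2.6-8.3 kHz, mean
#' maxima in 9.9-20 kHz, durations in 0.46-2.35 s. Structure probabilities
#' make most types single-element with occasional connected and rare
#' disconnected multi-loops. Disconnected-loop gaps are drawn near 0.14 s
#' (SD 0.03 s) within the 0.03-0.25 s loop window. Deterministic given a
#' seed.
#'
#' @param n_types number of templates.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return list of `type_template` objects with ids `"SW 1"`, `"SW 2"`, ...
#' @export
generate_templates <- function(n_types, seed = NULL) {
  stopifnot(n_types >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_types), function(i) {
    duration <- stats::runif(1, 0.46, 2.35)
    fmin <- stats::runif(1, 2600, 8300)
    fmax <- stats::runif(1, max(fmin + 4000, 9900), 20000)
    n_anchor <- sample(3:6, 1)
    at <- sort(c(0, stats::runif(n_anchor - 2), 1))
    af <- stats::runif(n_anchor, fmin, fmax)
    af[sample(n_anchor, 1)] <- fmin
    hi_pos <- sample(setdiff(seq_len(n_anchor), which(af == fmin)), 1)
    af[hi_pos] <- fmax
    dominant <- sample(c("SE", "CML", "DCML"), 1,
                       prob = c(0.75, 0.18, 0.07))
    p_structure <- switch(dominant,
      SE = c(SE = 0.90, CML = 0.07, DCML = 0.03),
      CML = c(SE = 0.30, CML = 0.65, DCML = 0.05),
      DCML = c(SE = 0.45, CML = 0.15, DCML = 0.40))
    structure(list(
      type_id = sprintf("SW %d", i),
      duration = duration, fmin = fmin, fmax = fmax,
      anchors_t = at, anchors_f = af,
      p_structure = p_structure,
      cml_loops = sample(2:3, 1), dcml_loops = sample(2:3, 1),
      ili_mean = 0.14, ili_sd = 0.03,
      amp_peak_frac = stats::runif(1, 0.2, 0.8),
      freq_scale_sd = 0.03, freq_offset_sd = 150, dur_scale_sd = 0.05),
      class = "type_template")
  })
}

#' @export
print.type_template <- function(x, ...) {
  cat(sprintf("<type_template %s> %.2f s | %.2f-%.2f kHz | P(SE/CML/DCML) = %.2f/%.2f/%.2f\n",
              x$type_id, x$duration, x$fmin / 1000, x$fmax / 1000,
              x$p_structure["SE"], x$p_structure["CML"],
              x$p_structure["DCML"]))
  invisible(x)
}

template_freq <- function(tpl, tfrac) {
  stats::approx(tpl$anchors_t, tpl$anchors_f, xout = tfrac, rule = 2)$y
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

# Realise one whistle emission of a template at time origin 0.
# Returns list(loops = list of point frames, structure, loop_count).
synth_whistle <- function(tpl, dt = 0.01, structure = NULL) {
  structure <- structure %||%
    sample(names(tpl$p_structure), 1, prob = tpl$p_structure)
  fscale <- exp(stats::rnorm(1, 0, tpl$freq_scale_sd))
  foff <- stats::rnorm(1, 0, tpl$freq_offset_sd)
  dur <- tpl$duration * exp(stats::rnorm(1, 0, tpl$dur_scale_sd))
  loop_points <- function(t0, loop_dur, reps = 1L) {
    tt <- seq(0, loop_dur, by = dt)
    if (length(tt) < 3L) tt <- seq(0, loop_dur, length.out = 3L)
    tfrac <- (tt %% (loop_dur / reps)) / (loop_dur / reps)
    if (reps > 1L) tfrac[length(tfrac)] <- 1
    f <- template_freq(tpl, tfrac) * fscale + foff
    f <- pmax(f, 500)
    amp <- 60 - 25 * ((tt / loop_dur) - tpl$amp_peak_frac)^2 / 0.25 +
      stats::rnorm(length(tt), 0, 0.5)
    data.frame(time = t0 + tt, freq = f, amp = amp)
  }
  if (structure == "SE") {
    list(loops = list(loop_points(0, max(dur, 0.12))),
         structure = "SE", loop_count = NA_integer_)
  } else if (structure == "CML") {
    reps <- tpl$cml_loops
    total <- max(dur, 0.12 * reps)
    list(loops = list(loop_points(0, total, reps = reps)),
         structure = "CML", loop_count = as.integer(reps))
  } else {
    reps <- tpl$dcml_loops
    loop_dur <- max(dur / reps, 0.12)
    ilis <- rtrunc_norm(reps - 1L, tpl$ili_mean, tpl$ili_sd, 0.03, 0.25)
    t0 <- 0
    loops <- vector("list", reps)
    for (r in seq_len(reps)) {
      loops[[r]] <- loop_points(t0, loop_dur)
      t0 <- t0 + loop_dur + if (r < reps) ilis[r] else 0
    }
    list(loops = loops, structure = "DCML", loop_count = NA_integer_)
  }
}

#' Emission model parameters
#'
#' Collects the temporal-production parameters of the generator: signature
#' types are emitted in bouts (size >= 2, mode around 4-8) whose
#' within-bout IWIs are log-normal, truncated to 1-10 s, with a small
#' heavy-tail component producing occasional very long gaps (so the
#' measurement-bout statistics see intervals of hundreds of seconds);
#' additional single occurrences happen at `single_prob`. Non-signature
#' REWTs are emitted as pairs/triples separated by 0.3-0.95 s - inside the
#' 0.25-10 s repetition window (so they are REWTs) but below the 1 s SIGID
#' floor (so they are not signature types). Copies are rare overlapping
#' same-type pairs. SNR is categorical 1/2/3 and masking probability rises
#' inside boat-noise intervals.
#'
#' @param ... overrides of the default parameters.
#' @return list of emission parameters.
#' @export
emission_model <- function(...) {
  defaults <- list(
    n_bouts_lambda = 0.5,      # bouts per active type = 1 + Pois
    bout_size_lambda = 4.5,    # bout size = 2 + Pois
    iwi_meanlog = log(4.5), iwi_sdlog = 0.5,
    iwi_lo = 1, iwi_hi = 10,
    iwi_tail_prob = 0.04, iwi_tail_max = 200,
    single_prob = 0.4,
    copy_prob = 0.03,
    nonsig_gap_range = c(0.3, 0.95),
    nonsig_n_range = c(2L, 3L),
    variable_rate_per_min = 0.15,
    snr_probs = c(0.15, 0.5, 0.35),
    mask_prob = 0.05, mask_prob_noise = 0.6,
    drop_label_prob = 0.5,     # masked SNR-1 contours lose their label
    frag_prob = 0.05,          # short-break fragmentation of a contour
    noise_lambda = 1, noise_len_range = c(20, 120))
  utils::modifyList(defaults, list(...))
}

draw_iwi <- function(emission) {
  if (stats::runif(1) < emission$iwi_tail_prob)
    return(stats::runif(1, emission$iwi_hi + 1, emission$iwi_tail_max))
  repeat {
    x <- stats::rlnorm(1, emission$iwi_meanlog, emission$iwi_sdlog)
    if (x >= emission$iwi_lo && x <= emission$iwi_hi) return(x)
  }
}

#' Simulate the start/end times of one type's whistles in one encounter
#'
#' Timing backbone shared by [generate_encounter()] and the recovery
#' tests: given per-whistle spans, lays the whistles out in bouts (role
#' `"signature"`) or in sub-second repetition clusters (role `"nonsig"`)
#' and returns a whistle table usable directly by [sigid_flag()],
#' [detect_bouts()] and [flag_rewt()].
#'
#' @param spans numeric vector of whistle span lengths (seconds); its
#'   length fixes the whistle count.
#' @param emission an [emission_model()].
#' @param role `"signature"` or `"nonsig"`.
#' @param encounter_id encounter id for the output table.
#' @param type_id type label for the output table.
#' @param t0 time origin of the first whistle (default 0).
#' @return data.frame: `whistle_id`, `encounter_id`, `type_label`,
#'   `start`, `end`, `bout_id`.
#' @export
simulate_whistle_times <- function(spans, emission = emission_model(),
                                   role = c("signature", "nonsig"),
                                   encounter_id = "E1", type_id = "SW 1",
                                   t0 = 0) {
  role <- match.arg(role)
  n <- length(spans)
  if (n == 0L)
    return(data.frame(whistle_id = character(), encounter_id = character(),
                      type_label = character(), start = numeric(),
                      end = numeric(), bout_id = integer(),
                      stringsAsFactors = FALSE))
  if (role == "signature") {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, 2L + stats::rpois(1, emission$bout_size_lambda))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0L]
    bout_id <- rep(seq_along(sizes), sizes)
    gaps <- vapply(seq_len(n - 1L), function(k) {
      if (bout_id[k + 1L] == bout_id[k]) draw_iwi(emission)
      else stats::runif(1, 60, 600)
    }, numeric(1))
  } else {
    bout_id <- rep(1L, n)
    gaps <- stats::runif(n - 1L, emission$nonsig_gap_range[1L],
                         emission$nonsig_gap_range[2L])
  }
  start <- numeric(n); start[1L] <- t0
  if (n > 1L) for (k in 2:n) start[k] <- start[k - 1L] + spans[k - 1L] + gaps[k - 1L]
  data.frame(whistle_id = sprintf("%s_%s_w%03d", encounter_id,
                                  gsub(" ", "", type_id), seq_len(n)),
             encounter_id = encounter_id, type_label = type_id,
             start = start, end = start + spans,
             bout_id = bout_id, stringsAsFactors = FALSE)
}

# saturating-linear diversity link: expected distinct signature types
diversity_link <- function(group_size, calves_present,
                           slope = 1 / 5, cap = 40, calf_offset = 1.5) {
  pmin(group_size, cap) * slope + calf_offset * as.numeric(calves_present)
}

#' Generate one synthetic encounter
#'
#' Emits time-ordered annotated contours for one encounter. The number of
#' distinct active signature types is a saturating-linear function of
#' group size plus a calf-presence offset plus Gaussian noise (so
#' recovered diversity increases with group size and calf presence);
#' active types emit bout-structured whistles per the [emission_model()],
#' non-signature REWTs and one-off variable contours are mixed in, copies
#' are injected as overlapping same-type pairs, and SNR/masking follow the
#' boat-noise intervals. A truth table records every planted whistle.
#'
#' @param templates list from [generate_templates()].
#' @param emission an [emission_model()].
#' @param covariates list or one-row data.frame with `encounter_id`,
#'   `group_size`, `calves_present`, `recording_minutes` and optionally
#'   `date`, `site`.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param signature_ids template ids eligible as signature types
#'   (default: all templates).
#' @param nonsig_ids template ids used as non-signature REWTs (default:
#'   none).
#' @return list with `contours` (list of [contour_trace()]), `truth`
#'   (data.frame: whistle_id, type_id, role, bout_id, is_copy, start,
#'   end), and `encounter` (one-row metadata data.frame including
#'   generated `noise_intervals`).
#' @export
generate_encounter <- function(templates, emission = emission_model(),
                               covariates, seed = NULL,
                               signature_ids = NULL, nonsig_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- as.list(as.data.frame(covariates, stringsAsFactors = FALSE)[1L, ])
  enc_id <- as.character(cov$encounter_id)
  dur_s <- cov$recording_minutes * 60
  if (dur_s < 60) stopf("encounter %s: recording too short for the emission model", enc_id)
  tpl_ids <- vapply(templates, `[[`, "", "type_id")
  signature_ids <- signature_ids %||% tpl_ids
  sig_pool <- templates[tpl_ids %in% signature_ids]
  nonsig_pool <- templates[tpl_ids %in% (nonsig_ids %||% character(0))]

  n_noise <- stats::rpois(1, emission$noise_lambda)
  noise <- if (n_noise > 0) {
    len <- stats::runif(n_noise, emission$noise_len_range[1L],
                        emission$noise_len_range[2L])
    st <- stats::runif(n_noise, 0, pmax(1, dur_s - len))
    m <- cbind(start = st, end = pmin(st + len, dur_s))
    m[order(m[, 1L]), , drop = FALSE]
  } else matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("start", "end")))

  target <- round(diversity_link(cov$group_size, cov$calves_present) +
                    stats::rnorm(1, 0, 0.8))
  target <- max(0L, min(as.integer(target), length(sig_pool)))
  active_sig <- if (target > 0L) sample(seq_along(sig_pool), target)
                else integer(0)
  n_nonsig <- min(stats::rpois(1, 1), length(nonsig_pool))
  active_nonsig <- if (n_nonsig > 0L) sample(seq_along(nonsig_pool), n_nonsig)
                   else integer(0)

  contours <- list(); truth <- list(); counter <- 0L
  in_noise <- function(t) nrow(noise) > 0 && any(t >= noise[, 1L] & t <= noise[, 2L])

  emit_whistle <- function(tpl, start, role, bout_id, is_copy = FALSE,
                           label = tpl$type_id, realized = NULL) {
    w <- realized %||% synth_whistle(tpl)
    first_id <- NULL
    for (li in seq_along(w$loops)) {
      counter <<- counter + 1L
      cid <- sprintf("%s_c%05d", enc_id, counter)
      if (is.null(first_id)) first_id <- cid
      pts <- w$loops[[li]]
      pts$time <- pts$time + start
      noisy <- in_noise(pts$time[1L])
      masked <- stats::runif(1) < if (noisy) emission$mask_prob_noise
                                  else emission$mask_prob
      snr <- sample(1:3, 1, prob = emission$snr_probs)
      if (noisy && snr > 1L && stats::runif(1) < 0.5) snr <- 1L
      lab <- label
      if (masked && snr == 1L && !is.na(lab) && lab != "VARIABLE" &&
          stats::runif(1) < emission$drop_label_prob)
        lab <- NA_character_
      frag <- w$structure != "DCML" && nrow(pts) >= 12L &&
        stats::runif(1) < emission$frag_prob
      if (frag) {
        cut <- sample(5:(nrow(pts) - 5L), 1)
        gap <- stats::runif(1, 0.004, 0.024)
        p2 <- pts[(cut + 1L):nrow(pts), , drop = FALSE]
        p2$time <- p2$time + gap
        contours[[length(contours) + 1L]] <<- contour_trace(
          cid, enc_id, pts[1:cut, , drop = FALSE], snr_grade = snr,
          masked = masked, type_label = lab, loop_count = w$loop_count,
          validate = FALSE)
        contours[[length(contours) + 1L]] <<- contour_trace(
          paste0(cid, "b"), enc_id, p2, snr_grade = snr, masked = masked,
          type_label = lab, loop_count = w$loop_count, validate = FALSE)
      } else {
        contours[[length(contours) + 1L]] <<- contour_trace(
          cid, enc_id, pts, snr_grade = snr, masked = masked,
          type_label = lab, loop_count = w$loop_count)
      }
    }
    span <- max(vapply(w$loops, function(p) p$time[nrow(p)], numeric(1))) -
      w$loops[[1L]]$time[1L]
    truth[[length(truth) + 1L]] <<- data.frame(
      whistle_id = paste0("w_", first_id), type_id = tpl$type_id,
      role = role, bout_id = bout_id, is_copy = is_copy,
      start = start, end = start + span,
      structure = w$structure, stringsAsFactors = FALSE)
    start + span
  }

  for (si in active_sig) {
    tpl <- sig_pool[[si]]
    n_bouts <- 1L + stats::rpois(1, emission$n_bouts_lambda)
    # successive bouts of a type follow each other at tens-of-seconds to
    # minutes, so measurement-bout IWIs occasionally reach a few hundred s
    t_next_bout <- stats::runif(1, 0, max(1, dur_s / 2))
    for (b in seq_len(n_bouts)) {
      size <- 2L + stats::rpois(1, emission$bout_size_lambda)
      t <- min(t_next_bout, dur_s - 120)
      bout_tag <- sprintf("%s_b%d", gsub(" ", "", tpl$type_id), b)
      bout_whistles <- lapply(seq_len(size), function(k) synth_whistle(tpl))
      for (k in seq_len(size)) {
        w_end <- emit_whistle(tpl, t, "signature", bout_tag,
                              realized = bout_whistles[[k]])
        if (stats::runif(1) < emission$copy_prob) {
          span <- w_end - t
          emit_whistle(tpl, t + 0.3 * span, "signature", bout_tag,
                       is_copy = TRUE)
        }
        if (k < size) t <- w_end + draw_iwi(emission)
      }
      t_next_bout <- t + stats::runif(1, 10, 90)
    }
    # a type's production is clustered within an encounter: single
    # occurrences trail the last bout rather than landing anywhere in a
    # possibly hours-long recording
    if (stats::runif(1) < emission$single_prob) {
      emit_whistle(tpl, min(t_next_bout + stats::runif(1, 5, 30),
                            dur_s - 10), "signature",
                   sprintf("%s_single", gsub(" ", "", tpl$type_id)))
    }
  }

  for (ni in active_nonsig) {
    tpl <- nonsig_pool[[ni]]
    n <- sample(seq(emission$nonsig_n_range[1L], emission$nonsig_n_range[2L]), 1)
    t <- stats::runif(1, 0, dur_s - 60)
    for (k in seq_len(n)) {
      w_end <- emit_whistle(tpl, t, "nonsig", "nonsig_b1")
      if (k < n) t <- w_end + stats::runif(1, emission$nonsig_gap_range[1L],
                                           emission$nonsig_gap_range[2L])
    }
  }

  n_var <- stats::rpois(1, emission$variable_rate_per_min * cov$recording_minutes)
  if (n_var > 0) {
    var_tpls <- generate_templates(n_var)
    for (v in seq_len(n_var)) {
      tpl <- var_tpls[[v]]
      emit_whistle(tpl, stats::runif(1, 0, dur_s - 10), "variable",
                   NA_character_, label = "VARIABLE",
                   realized = synth_whistle(tpl, structure = "SE"))
    }
  }

  truth_df <- if (length(truth)) do.call(rbind, truth)
              else data.frame(whistle_id = character(), type_id = character(),
                              role = character(), bout_id = character(),
                              is_copy = logical(), start = numeric(),
                              end = numeric(), structure = character(),
                              stringsAsFactors = FALSE)
  enc_row <- data.frame(
    encounter_id = enc_id,
    date = as.Date(cov$date %||% "2012-06-01"),
    site = as.character(cov$site %||% "WB"),
    group_size = cov$group_size,
    calves_present = cov$calves_present,
    recording_minutes = cov$recording_minutes,
    stringsAsFactors = FALSE)
  enc_row$noise_intervals <- list(noise)
  ord <- order(vapply(contours, ct_start, numeric(1)))
  list(contours = contours[ord], truth = truth_df, encounter = enc_row)
}

#' Generate a complete synthetic dataset
#'
#' Encounter covariates (group size, calf presence - more likely in larger
#' groups - recording effort, dates over three field seasons, two sites)
#' plus per-encounter contours and truth labels, fully deterministic under
#' the master seed.
#'
#' @param n_encounters number of encounters (default 64).
#' @param n_signature_types size of the signature-type template pool
#'   (default 28).
#' @param n_nonsig_types non-signature REWT templates (default 15, giving
#'   a 43-type catalogue universe).
#' @param emission an [emission_model()].
#' @param seed master seed (default 1).
#' @return list with `contours`, `encounters` (metadata data.frame),
#'   `truth` (row-bound per-whistle truth), `templates`, `signature_ids`.
#' @export
generate_dataset <- function(n_encounters = 64, n_signature_types = 28,
                             n_nonsig_types = 15,
                             emission = emission_model(), seed = 1) {
  set.seed(seed)
  templates <- generate_templates(n_signature_types + n_nonsig_types)
  tpl_ids <- vapply(templates, `[[`, "", "type_id")
  sig_ids <- tpl_ids[seq_len(n_signature_types)]
  nonsig_ids <- setdiff(tpl_ids, sig_ids)
  dates <- as.Date("2011-06-01") +
    sort(sample(0:900, n_encounters, replace = TRUE))
  contours <- list(); truth <- list(); encounters <- list()
  for (i in seq_len(n_encounters)) {
    gs <- max(1L, stats::rnbinom(1, size = 3, mu = 11))
    cov <- list(encounter_id = sprintf("E%02d", i),
                group_size = gs,
                calves_present = stats::runif(1) < stats::plogis(-1.2 + 0.12 * gs),
                recording_minutes = stats::runif(1, 30, 208),
                date = dates[i],
                site = sample(c("WB", "LUD"), 1, prob = c(0.95, 0.05)))
    enc <- generate_encounter(templates, emission, cov,
                              signature_ids = sig_ids,
                              nonsig_ids = nonsig_ids)
    contours <- c(contours, enc$contours)
    truth[[i]] <- enc$truth
    encounters[[i]] <- enc$encounter
  }
  list(contours = contours,
       encounters = do.call(rbind, encounters),
       truth = do.call(rbind, truth),
       templates = templates,
       signature_ids = sig_ids)
}

#' Generate a synthetic two-stage rating task
#'
#' Emulates the visual classification task: `n_repeats` whistles of each
#' template are presented to `n_judges` naive judges, who rate similarity
#' to every template on a 1-5 scale (stage 1) and then assign each whistle
#' to a single most-similar template (stage 2). Each judge's stage-2 pick
#' equals the true template with probability `accuracy` (otherwise a
#' uniformly random other template); stage-1 ratings are high for the pick
#' and the true template and low elsewhere. With probability
#' `1 - consistency` a judge's assignment deviates from their own highest
#' stage-1 rating.
#'
#' @param templates list of templates or an integer template count.
#' @param n_judges number of judges (default 5).
#' @param n_repeats items per template (default 5).
#' @param accuracy probability a stage-2 pick equals the truth.
#' @param consistency probability a pick is the judge's own stage-1 argmax
#'   (default 1).
#' @param seed optional seed.
#' @return a `rating_tensor` with `truth` filled in.
#' @export
generate_rating_task <- function(templates = 10, n_judges = 5,
                                 n_repeats = 5, accuracy = 0.9,
                                 consistency = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  template_ids <- if (is.numeric(templates)) sprintf("T%02d", seq_len(templates))
                  else vapply(templates, `[[`, "", "type_id")
  k <- length(template_ids)
  items <- sprintf("item%03d", seq_len(k * n_repeats))
  truth <- rep(template_ids, each = n_repeats)
  judges <- sprintf("judge%d", seq_len(n_judges))
  stage1 <- array(NA_real_, dim = c(n_judges, length(items), k),
                  dimnames = list(judges, items, template_ids))
  stage2 <- matrix(NA_character_, nrow = length(items), ncol = n_judges,
                   dimnames = list(items, judges))
  for (j in seq_len(n_judges)) {
    for (i in seq_along(items)) {
      ti <- match(truth[i], template_ids)
      pick <- if (stats::runif(1) < accuracy) ti
              else sample(setdiff(seq_len(k), ti), 1)
      r <- sample(1:3, k, replace = TRUE)
      r[ti] <- 4L
      r[pick] <- 5L
      assigned <- pick
      if (stats::runif(1) >= consistency) {
        low <- which(r < max(r))
        if (length(low)) assigned <- low[sample.int(length(low), 1)]
      }
      stage1[j, i, ] <- r
      stage2[i, j] <- template_ids[assigned]
    }
  }
  structure(list(stage1 = stage1, stage2 = stage2, judges = judges,
                 items = items, templates = template_ids, truth = truth),
            class = "rating_tensor")
}
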