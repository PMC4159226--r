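# In-code fixtures: small contour/whistle builders and independent oracles
# used across the suite.

lin_shape <- function(f0, f1) function(x) f0 + (f1 - f0) * x

mk_points <- function(t0, dur, shape, n = 11) {
  x <- seq(0, 1, length.out = n)
  data.frame(time = t0 + x * dur, freq = shape(x))
}

mk_contour <- function(id, t0, dur = 0.2, f0 = 5000, f1 = 9000,
                       enc = "E1", label = "A", n = 11, ...) {
  contour_trace(id, enc, mk_points(t0, dur, lin_shape(f0, f1), n),
                type_label = label, ...)
}

# whistles with prescribed spans: one SE contour each, assembled
mk_whistles <- function(starts, ends, enc = "E1", label = "A", ...) {
  contours <- lapply(seq_along(starts), function(i)
    mk_contour(sprintf("c%02d", i), starts[i], dur = ends[i] - starts[i],
               enc = enc, label = label, ...))
  # spans may overlap (copies); assemble never chains overlapping
  # same-label contours, so each becomes its own single-loop whistle
  assemble_whistles(contours)
}

# whistle table with prescribed consecutive IWIs (span fixed per whistle)
iwi_table <- function(iwis, span = 0.5, enc = "E1", label = "A") {
  n <- length(iwis) + 1L
  start <- numeric(n)
  for (k in seq_len(n - 1L)) start[k + 1L] <- start[k] + span + iwis[k]
  data.frame(whistle_id = sprintf("w%02d", seq_len(n)), encounter_id = enc,
             type_label = label, start = start, end = start + span,
             stringsAsFactors = FALSE)
}

basic_encounters <- function(ids = "E1", date = as.Date("2012-06-01"),
                             site = "WB") {
  df <- data.frame(encounter_id = ids, date = date, site = site,
                   group_size = 10, calves_present = FALSE,
                   recording_minutes = 120, stringsAsFactors = FALSE)
  df$noise_intervals <- rep(list(matrix(numeric(0), ncol = 2,
    dimnames = list(NULL, c("start", "end")))), nrow(df))
  df
}

# synthetic diversity dataset with a known saturating smooth + calf offset
mk_diversity <- function(n = 200, seed = 1,
                         f = function(g) 8 * g / (g + 10),
                         calf_offset = 1.5, sigma = 1) {
  set.seed(seed)
  gs <- sample(1:40, n, replace = TRUE)
  calves <- runif(n) < 0.4
  mins <- runif(n, 30, 208)
  data.frame(encounter_id = sprintf("E%03d", seq_len(n)),
             n_types = f(gs) + calf_offset * calves + rnorm(n, 0, sigma),
             group_size = gs, calves_present = calves,
             recording_minutes = mins, stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# SIGID by direct restatement of the rule: per-whistle in-interval status
# from neighbouring gaps, then every contiguous stretch of >= window
# whistles checked for the 75% fraction.
sigid_oracle <- function(starts, ends, window = 4L, frac = 0.75,
                         lo = 1, hi = 10) {
  n <- length(starts)
  if (n < window) return(FALSE)
  gap_ok <- function(i, j) {
    iwi <- starts[j] - ends[i]
    iwi >= lo && iwi <= hi
  }
  status <- vapply(seq_len(n), function(i) {
    (i > 1L && gap_ok(i - 1L, i)) || (i < n && gap_ok(i, i + 1L))
  }, logical(1))
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (e - s + 1L >= window && mean(status[s:e]) >= frac) return(TRUE)
    }
  }
  FALSE
}

# chaining oracle for assembly: given inter-contour gaps of a same-label
# sequence, classify each gap (merge / chain / break) and return the loop
# counts of the resulting whistles
chain_oracle <- function(gaps, merge_lt = 0.03, min_gap = 0.03,
                         max_gap = 0.25) {
  kind <- ifelse(gaps < merge_lt, "m",
                 ifelse(gaps <= max_gap, "c", "b"))
  loops <- integer(0)
  cur <- 1L
  for (k in kind) {
    if (k == "m") next            # merged into the current loop
    if (k == "c") cur <- cur + 1L # new loop in the same whistle
    if (k == "b") { loops <- c(loops, cur); cur <- 1L }
  }
  c(loops, cur)
}

# definitional Fleiss kappa via pairwise rater agreement (independent of
# the count-based implementation)
kappa_oracle <- function(mat) {
  N <- nrow(mat); m <- ncol(mat)
  cats <- sort(unique(as.vector(mat)))
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    agree <- 0L
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) if (mat[i, a] == mat[i, b]) agree <- agree + 1L
    }
    P_i[i] <- agree / (m * (m - 1) / 2)
  }
  p_j <- vapply(cats, function(cc) mean(mat == cc), numeric(1))
  Pe <- sum(p_j^2)
  if (1 - Pe < 1e-12) return(NA_real_)
  (mean(P_i) - Pe) / (1 - Pe)
}
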