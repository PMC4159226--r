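test_that("inflection counting matches shape ground truth", {
  v <- mk_points(0, 1, function(x) 10000 - 6000 * (1 - abs(2 * x - 1)),
                 n = 41)
  expect_equal(count_inflections(v), 1L)

  # 1.75 sine cycles: interior extrema at x = 1/7, 3/7, 5/7
  sine <- mk_points(0, 1, function(x) 9000 + 4000 * sin(2 * pi * 1.75 * x),
                    n = 81)
  expect_equal(count_inflections(sine), 3L)

  # jitter below flat_tol on a monotone trace: oracle is the noiseless
  # generator contour, which has zero inflections
  set.seed(2)
  mono <- mk_points(0, 1, lin_shape(5000, 12000), n = 101)
  mono$freq <- mono$freq + rnorm(101, 0, 30)
  expect_equal(count_inflections(mono, flat_tol = 500), 0L)

  expect_warning(z <- count_inflections(mk_points(0, 1, lin_shape(1, 2), 2)),
                 "fewer than 3")
  expect_equal(z, 0L)
})

test_that("slope aspect signs the edge regression with a flat tolerance", {
  rise <- mk_points(0, 1, lin_shape(5000, 9000), n = 41)
  expect_equal(slope_aspect(rise, "start"), 1L)
  expect_equal(slope_aspect(rise, "end"), 1L)
  fall <- mk_points(0, 1, lin_shape(9000, 5000), n = 41)
  expect_equal(slope_aspect(fall, "start"), -1L)
  flat <- mk_points(0, 1, function(x) 8000 + 100 * x, n = 41)
  expect_equal(slope_aspect(flat, "start"), 0L)
  # fall-flat-fall: both edges negative
  fff <- mk_points(0, 1, function(x)
    ifelse(x < 0.3, 12000 - 10000 * x,
           ifelse(x < 0.7, 9000, 9000 - 10000 * (x - 0.7))), n = 101)
  expect_equal(slope_aspect(fff, "start"), -1L)
  expect_equal(slope_aspect(fff, "end"), -1L)
})

test_that("the parameter panel measures a known contour", {
  shape <- function(x) ifelse(x < 0.5, 4000 + 16000 * x, 12000 - 12000 * (x - 0.5))
  pts <- mk_points(0, 1, shape, n = 101)
  pts$amp <- 50 - abs(pts$freq - 12000) / 1000   # loudest at the apex
  w <- assemble_whistles(list(contour_trace("c1", "E1", pts,
                                            type_label = "A")))[[1]]
  p <- measure_whistle(w)
  expect_equal(p$start_freq, 4, tolerance = 1e-6)
  expect_equal(p$end_freq, 6, tolerance = 1e-6)
  expect_equal(p$min_freq, 4, tolerance = 1e-6)
  expect_equal(p$max_freq, 12, tolerance = 1e-6)
  expect_equal(p$freq_range, 8, tolerance = 1e-6)
  expect_equal(p$peak_freq, 12, tolerance = 0.2)
  expect_equal(p$duration, 1)
  expect_equal(p$inflections, 1L)
  expect_equal(p$start_aspect, 1L)
  expect_equal(p$end_aspect, -1L)
})

test_that("DCML inflections are counted per loop and summed; duration spans gaps", {
  vshape <- function(x) 11000 - 6000 * (1 - abs(2 * x - 1))
  contours <- list(contour_trace("c1", "E1", mk_points(0, 0.4, vshape, 41),
                                 type_label = "A"),
                   contour_trace("c2", "E1", mk_points(0.5, 0.4, vshape, 41),
                                 type_label = "A"))
  w <- assemble_whistles(contours)[[1]]
  expect_equal(w$structure, "DCML")
  p <- measure_whistle(w)
  expect_equal(p$inflections, 2L)
  expect_equal(p$duration, 0.9)
})

test_that("per-whistle parameter invariants hold on synthetic whistles", {
  set.seed(9)
  tpls <- generate_templates(6)
  for (tpl in tpls) {
    for (rep in 1:3) {
      w <- sigwhistle:::synth_whistle(tpl)
      loops <- lapply(seq_along(w$loops), function(i)
        contour_trace(sprintf("c%d", i), "E1", w$loops[[i]],
                      type_label = tpl$type_id, loop_count = w$loop_count))
      wh <- assemble_whistles(loops)[[1]]
      p <- measure_whistle(wh)
      expect_lte(p$min_freq, min(p$start_freq, p$end_freq, p$peak_freq))
      expect_gte(p$max_freq, max(p$start_freq, p$end_freq, p$peak_freq))
      expect_equal(p$freq_range, p$max_freq - p$min_freq, tolerance = 1e-12)
      expect_gt(p$duration, 0)
      # measured extremes recover template truth within jitter tolerance
      # (3% scale + 150 Hz offset + trace sampling)
      expect_equal(p$max_freq, tpl$fmax / 1000, tolerance = 0.15)
      expect_equal(p$min_freq, min(tpl$anchors_f) / 1000, tolerance = 0.3)
    }
  }
})

test_that("measurement selection enforces quality, copies and the 4-10 cap", {
  long <- mk_whistles(seq(0, 55, by = 5), seq(0, 55, by = 5) + 1)
  sel <- select_measurement_whistles(long)
  expect_length(sel, 10L)
  expect_equal(sel[[1]]$whistle_id, "w_c01")

  few <- mk_whistles(c(0, 5, 10), c(1, 6, 11))
  expect_length(select_measurement_whistles(few), 0L)

  # a copying pair inside the run disqualifies both members
  starts <- c(0, 5, 10, 10.4, 15, 20, 25, 30)
  ends <- starts + 1
  w <- mk_whistles(starts, ends)
  sel2 <- select_measurement_whistles(w)
  ids <- vapply(sel2, `[[`, "", "whistle_id")
  expect_false(any(c("w_c03", "w_c04") %in% ids))
  expect_length(sel2, 4L)

  # low SNR / masked whistles break the qualifying run
  wq <- c(mk_whistles(c(0, 5), c(1, 6)),
          mk_whistles(10, 11, snr_grade = 1L),
          mk_whistles(c(15, 20, 25, 30, 35), c(16, 21, 26, 31, 36)))
  sel3 <- select_measurement_whistles(wq)
  expect_length(sel3, 5L)
  expect_equal(sel3[[1]]$start_time, 15)
})

test_that("population parameter summary is unweighted with ranges and CV", {
  per <- data.frame(type_id = c("A", "B"), n = c(10, 6),
                    start_freq_mean = c(4, 8), start_freq_sd = c(1, 1),
                    duration_mean = c(1, 2), duration_sd = c(0.1, 0.2))
  s <- summarize_parameters(per)
  pop <- s$population
  expect_equal(pop$mean[pop$parameter == "start_freq"], 6)
  expect_equal(pop$min[pop$parameter == "start_freq"], 4)
  expect_equal(pop$max[pop$parameter == "start_freq"], 8)
  one <- summarize_parameters(per[1, ])
  expect_equal(one$population$mean[1], 4)
  expect_equal(one$population$sd[1], NA_real_)

  # CV is scale invariant
  scaled <- per
  scaled$start_freq_mean <- per$start_freq_mean * 3.7
  expect_equal(
    summarize_parameters(scaled)$population$cv[pop$parameter == "start_freq"],
    pop$cv[pop$parameter == "start_freq"], tolerance = 1e-12)
})
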