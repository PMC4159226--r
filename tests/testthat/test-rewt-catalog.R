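test_that("repetition flag uses the 0.25-10 s window per section", {
  expect_true(flag_rewt(mk_whistles(c(0, 5.5), c(0.5, 6.0))))    # 5 s apart
  # 30 s apart plus a 0.1 s pair: the sub-0.25 s gap is a loop candidate,
  # not a repetition
  expect_false(flag_rewt(mk_whistles(c(0, 30.5, 31.1), c(0.5, 31.0, 31.6))))
  expect_false(flag_rewt(mk_whistles(0, 0.5)))
  # boundary separations count (closed interval); tables bypass assembly
  expect_true(flag_rewt(iwi_table(0.25)))
  expect_true(flag_rewt(iwi_table(10)))
  expect_false(flag_rewt(iwi_table(10.01)))
  # repetition must happen within one recording section
  w <- c(mk_whistles(0, 0.5, enc = "E1"), mk_whistles(3, 3.5, enc = "E2"))
  expect_false(flag_rewt(w))
})

test_that("pass-2 classification passes labels through with bookkeeping", {
  catalogue_ids <- c("SW 5", "SW 7")
  ok <- classify_to_catalogue(mk_contour("c", 0, label = "SW 5"),
                              catalogue_ids)
  expect_equal(as.character(ok), "SW 5")
  expect_false(attr(ok, "low_snr"))
  low <- classify_to_catalogue(mk_contour("c", 0, label = "SW 5",
                                          snr_grade = 1L), catalogue_ids)
  expect_true(attr(low, "low_snr"))
  expect_equal(classify_to_catalogue(
    mk_contour("c", 0, label = NA_character_, snr_grade = 1L, masked = TRUE),
    catalogue_ids), "UNCLASSIFIED")
  expect_equal(classify_to_catalogue(mk_contour("c", 0, label = "VARIABLE"),
                                     catalogue_ids), "VARIABLE")
  expect_error(classify_to_catalogue(mk_contour("c", 0, label = "SW 99"),
                                     catalogue_ids), "SW 99")
})

test_that("copy removal keeps the first whistle of each overlapping pair", {
  pair <- mk_whistles(c(1.0, 1.5), c(2.0, 2.5))
  out <- remove_copies(pair)
  expect_equal(vapply(out$kept, `[[`, "", "whistle_id"), "w_c01")
  expect_equal(vapply(out$removed, `[[`, "", "whistle_id"), "w_c02")

  none <- remove_copies(mk_whistles(c(0, 5), c(1, 6)))
  expect_length(none$removed, 0L)

  chain <- mk_whistles(c(0, 0.5, 1.0), c(1.2, 1.7, 2.2))  # mutual overlaps
  out2 <- remove_copies(chain)
  expect_equal(vapply(out2$kept, `[[`, "", "whistle_id"), "w_c01")
  expect_length(out2$removed, 2L)
})

test_that("copy removal satisfies its defining properties on random inputs", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:4, 1)
    starts <- sort(round(runif(n, 0, 4), 2))
    ends <- starts + round(runif(n, 0.3, 2.0), 2)
    # keep silent gaps out of the 0.03-0.25 s loop window so each contour
    # assembles into its own whistle (overlaps are the point here)
    for (i in seq_len(n - 1L)) {
      if (starts[i + 1L] - ends[i] <= 0.27 && starts[i + 1L] > ends[i])
        ends[i] <- starts[i + 1L] + 0.05
    }
    out <- remove_copies(mk_whistles(starts, ends))
    expect_equal(length(out$kept) + length(out$removed), n)
    kt <- whistle_table(out$kept)
    # (a) kept set has no internal overlaps
    if (nrow(kt) > 1L) {
      for (i in seq_len(nrow(kt) - 1L)) {
        expect_true(all(kt$start[-(1:i)] > kt$end[i] |
                          kt$end[-(1:i)] < kt$start[i]))
      }
    }
    # (b) every removed whistle overlaps an earlier-starting kept whistle
    for (w in out$removed) {
      expect_true(any(kt$start <= w$start_time & kt$end >= w$start_time))
    }
  }
})

test_that("per-type summaries count sizes, single days and structure", {
  enc <- basic_encounters(c("E1", "E2", "E3"),
                          date = as.Date(c("2011-06-01", "2012-06-02",
                                           "2012-06-02")),
                          site = c("WB", "WB", "LUD"))
  w <- c(mk_whistles(c(0, 3, 8), c(1, 4, 9), enc = "E1"),
         mk_whistles(5, 6, enc = "E2"),
         mk_whistles(2, 3, enc = "E3"))
  row <- summarize_type("SW 1", w, enc)
  expect_equal(row$category_size, 5L)
  # E2 and E3 share a date: that day saw 2 whistles, so only... E1's day
  # has 3; no day with exactly one? E2+E3 day has 2 -> zero single days
  expect_equal(row$single_occurrence_days, 0L)
  expect_equal(row$n_encounters, 3L)
  expect_equal(row$n_days, 2L)
  expect_equal(row$years, "2011/12")
  expect_equal(row$sites, "LUD/WB")
  expect_equal(row$pct_se + row$pct_cml + row$pct_dcml, 100)

  one <- summarize_type("SW 2", mk_whistles(0, 1, enc = "E1"), enc)
  expect_equal(one$category_size, 1L)
  expect_equal(one$single_occurrence_days, 1L)
})

test_that("catalogue build flags REWTs and feeds the summary", {
  enc <- basic_encounters(c("E1", "E2"),
                          date = as.Date(c("2011-06-01", "2012-06-02")))
  contours <- c(
    lapply(1:4, function(i) mk_contour(sprintf("a%d", i), 10 + i * 3,
                                       dur = 0.5, label = "SW 1")),
    list(mk_contour("b1", 50, dur = 0.5, label = "SW 2"),
         mk_contour("b2", 100, dur = 0.5, label = "SW 2"),
         mk_contour("v1", 200, dur = 0.5, label = "VARIABLE"),
         mk_contour("u1", 210, dur = 0.5, label = NA_character_)),
    list(mk_contour("a9", 10, dur = 0.5, label = "SW 1", enc = "E2")))
  out <- build_catalogue(assemble_whistles(contours), enc)
  expect_equal(sort(out$catalogue$type_id), c("SW 1", "SW 2"))
  expect_true(out$catalogue$is_rewt[out$catalogue$type_id == "SW 1"])
  expect_false(out$catalogue$is_rewt[out$catalogue$type_id == "SW 2"])
  s <- summarize_catalogue(out$catalogue)
  expect_equal(s$n_types, 2L)
  expect_equal(s$total_whistles, 7L)
})

test_that("catalogue summary fractions use half-up integer rounding", {
  expect_equal(round_half_up(100 * 26 / 28), 93)
  expect_equal(round_half_up(100 * 22 / 28), 79)
  expect_equal(round_half_up(100 * 23 / 28), 82)
  # base round() would give 92 here
  expect_equal(round_half_up(92.5), 93)
})
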