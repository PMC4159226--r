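test_that("trace CSV round-trips and enforces the contour criteria", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "traces.csv")
  good <- data.frame(contour_id = "c1", encounter_id = "E1",
                     time_s = seq(0, 0.5, length.out = 5),
                     freq_hz = seq(4000, 8000, length.out = 5),
                     amp_db = 50, snr = 2, masked = FALSE,
                     type_label = "SW 1")
  short <- data.frame(contour_id = "c2", encounter_id = "E1",
                      time_s = c(1.0, 1.05), freq_hz = c(5000, 6000),
                      amp_db = 50, snr = 2, masked = FALSE,
                      type_label = "SW 1")
  low <- data.frame(contour_id = "c3", encounter_id = "E1",
                    time_s = c(2.0, 2.3), freq_hz = c(1000, 2500),
                    amp_db = 50, snr = 2, masked = FALSE,
                    type_label = "SW 1")
  write.csv(rbind(good, short, low), path, row.names = FALSE)
  out <- suppressMessages(read_contours(path))
  expect_length(out, 1L)
  expect_equal(ct_duration(out[[1]]), 0.5)
  expect_equal(max(out[[1]]$points$freq), 8000)
  rej <- attr(out, "rejected")
  expect_equal(sort(rej$contour_id), c("c2", "c3"))
  expect_match(rej$reason[rej$contour_id == "c2"], "0.10 s")
  # accepted + rejected account for every input contour
  expect_equal(length(out) + nrow(rej), 3L)
})

test_that("trace CSV write/read is lossless for accepted contours", {
  dir <- withr::local_tempdir()
  cts <- list(mk_contour("a", 0, label = "SW 1"),
              mk_contour("b", 1, f0 = 9000, f1 = 4000, label = NA_character_))
  path <- file.path(dir, "rt.csv")
  write_contours(cts, path)
  back <- read_contours(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$points$freq, cts[[1]]$points$freq)
  expect_equal(back[[2]]$type_label, NA_character_)
})

test_that("missing required columns are reported by name", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  write.csv(data.frame(contour_id = "c1", time_s = 1), path,
            row.names = FALSE)
  expect_error(read_contours(path), "encounter_id")
})

test_that("Raven selection tables import as coarse two-point traces", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sel.txt")
  df <- data.frame(a = c(1.0, 5.0), b = c(1.8, 5.4),
                   c = c(4000, 5000), d = c(9000, 12000))
  names(df) <- c("Begin Time (s)", "End Time (s)",
                 "Low Freq (Hz)", "High Freq (Hz)")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out <- read_contours(path, dialect = "raven_selection",
                       encounter_id = "E9")
  expect_length(out, 2L)
  expect_true(all(vapply(out, `[[`, FALSE, "coarse")))
  expect_equal(ct_start(out[[1]]), 1.0)
  expect_equal(ct_end(out[[1]]), 1.8)
  expect_equal(out[[2]]$encounter_id, "E9")
  expect_error(measure_whistle(assemble_whistles(out)[[1]]), "coarse")
})

test_that("encounter tables parse, validate and round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "enc.csv")
  df <- data.frame(encounter_id = c("E1", "E2", "E3"),
                   date = c("2012-06-01", "2012-06-02", "2013-01-05"),
                   site = c("WB", "WB", "LUD"),
                   group_size = c(12, 3, 30),
                   calves_present = c(TRUE, FALSE, TRUE),
                   recording_minutes = c(95, 8, 208),
                   noise_intervals = c("10-60;300-420", "", "5-100"))
  write.csv(df, path, row.names = FALSE)
  enc <- read_encounters(path)
  expect_equal(enc$group_size[1], 12)
  expect_equal(nrow(enc$noise_intervals[[1]]), 2L)
  expect_equal(enc$noise_intervals[[1]][2, ], c(start = 300, end = 420))
  expect_equal(nrow(enc$noise_intervals[[2]]), 0L)
  # both extremes of observed recording effort accepted
  expect_true(all(c(8, 208) %in% enc$recording_minutes))
  path2 <- file.path(dir, "enc2.csv")
  write_encounters(enc, path2)
  enc2 <- read_encounters(path2)
  expect_equal(enc2$noise_intervals, enc$noise_intervals)

  df$group_size[2] <- 0
  write.csv(df, path, row.names = FALSE)
  expect_error(read_encounters(path), "group_size")
  df$group_size[2] <- 3
  df$noise_intervals[1] <- "x-y"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_encounters(path), "malformed")
})

test_that("catalogue tables round-trip, including the empty catalogue", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cat.tsv")
  cat0 <- walvis_catalogue()[0, ]
  write_catalogue(cat0, path)
  expect_equal(nrow(read_catalogue(path)), 0L)

  cat1 <- walvis_catalogue()
  write_catalogue(cat1, path)
  back <- read_catalogue(path)
  expect_equal(back, cat1)

  dup <- rbind(cat1, cat1[1, ])
  expect_error(write_catalogue(dup, path), "duplicate")
})

test_that("rating task CSVs load into a rating tensor", {
  dir <- withr::local_tempdir()
  s1 <- expand.grid(judge_id = c("j1", "j2"), item_id = c("i1", "i2"),
                    template_id = c("T1", "T2"), stringsAsFactors = FALSE)
  s1$rating <- c(5, 5, 1, 2, 1, 2, 5, 5)
  s2 <- expand.grid(judge_id = c("j1", "j2"), item_id = c("i1", "i2"),
                    stringsAsFactors = FALSE)
  s2$assigned_template <- c("T1", "T1", "T2", "T2")
  p1 <- file.path(dir, "s1.csv"); p2 <- file.path(dir, "s2.csv")
  write.csv(s1, p1, row.names = FALSE); write.csv(s2, p2, row.names = FALSE)
  rt <- read_rating_task(p1, p2)
  expect_s3_class(rt, "rating_tensor")
  expect_equal(dim(rt$stage1), c(2, 2, 2))
  expect_equal(consistency_rate(rt)$rate, 1)
})
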