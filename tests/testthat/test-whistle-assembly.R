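test_that("merge_breaks joins sub-0.03 s fragments and is idempotent", {
  frag <- list(mk_contour("c1", 0.0, dur = 0.15),
               mk_contour("c2", 0.17, dur = 0.15),   # 0.02 s gap -> merge
               mk_contour("c3", 0.36, dur = 0.15))   # 0.04 s gap -> keep
  m <- merge_breaks(frag)
  expect_length(m, 2L)
  expect_equal(ct_start(m[[1]]), 0.0)
  expect_equal(ct_end(m[[1]]), 0.32)
  m2 <- merge_breaks(m)
  expect_equal(whistle_table(assemble_whistles(m2)),
               whistle_table(assemble_whistles(m)))
  expect_length(m2, 2L)

  ovl <- list(mk_contour("x", 0, dur = 0.3), mk_contour("x", 0.2, dur = 0.3))
  expect_error(merge_breaks(ovl), "overlapping")
})

test_that("assemble_whistles chains loops by gap and label", {
  three <- list(mk_contour("c1", 0.0, dur = 0.2),
                mk_contour("c2", 0.3, dur = 0.2),
                mk_contour("c3", 0.6, dur = 0.2))
  w <- assemble_whistles(three)
  expect_length(w, 1L)
  expect_equal(w[[1]]$structure, "DCML")
  expect_length(w[[1]]$loops, 3L)

  far <- list(mk_contour("c1", 0.0, dur = 0.2),
              mk_contour("c2", 0.7, dur = 0.2))
  w2 <- assemble_whistles(far)
  expect_length(w2, 2L)
  expect_true(all(vapply(w2, `[[`, "", "structure") == "SE"))

  mixed <- list(mk_contour("c1", 0.0, dur = 0.2, label = "A"),
                mk_contour("c2", 0.3, dur = 0.2, label = "B"))
  expect_length(assemble_whistles(mixed), 2L)
  # ... unless the pair has passed the co-occurrence gate
  expect_length(assemble_whistles(mixed, linked_pairs = list(c("A", "B"))), 1L)
  expect_length(assemble_whistles(list()), 0L)
})

test_that("assembly agrees with the chaining oracle on all short sequences", {
  gap_grid <- c(0.01, 0.04, 0.1, 0.3)
  for (n in 2:6) {
    combos <- expand.grid(rep(list(gap_grid), n - 1L))
    for (r in seq_len(nrow(combos))) {
      gaps <- as.numeric(combos[r, ])
      starts <- cumsum(c(0, 0.2 + gaps))
      contours <- lapply(seq_len(n), function(i)
        mk_contour(sprintf("c%02d", i), starts[i], dur = 0.2))
      got <- assemble_whistles(merge_breaks(contours))
      want_loops <- chain_oracle(gaps)
      expect_equal(vapply(got, function(w) length(w$loops), integer(1)),
                   want_loops,
                   info = paste("gaps:", paste(gaps, collapse = ",")))
    }
  }
})

test_that("gap boundaries 0.03 and 0.25 are inside the loop window", {
  at_lo <- list(mk_contour("c1", 0.0, dur = 0.2),
                mk_contour("c2", 0.23, dur = 0.2))   # gap exactly 0.03
  expect_length(assemble_whistles(at_lo), 1L)
  at_hi <- list(mk_contour("c1", 0.0, dur = 0.2),
                mk_contour("c2", 0.45, dur = 0.2))   # gap exactly 0.25
  expect_length(assemble_whistles(at_hi), 1L)
  # a gap of exactly 0.03 s is *not* merged (break rule is open at 0.03)
  expect_length(merge_breaks(at_lo), 2L)
})

test_that("partition and monotonicity invariants hold on random sequences", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    gaps <- sample(c(0.01, 0.05, 0.1, 0.2, 0.5, 2), n - 1, replace = TRUE)
    starts <- cumsum(c(0, 0.2 + gaps))
    contours <- lapply(seq_len(n), function(i)
      mk_contour(sprintf("c%02d", i), starts[i], dur = 0.2))
    merged <- merge_breaks(contours)
    w1 <- assemble_whistles(merged, max_gap = 0.25)
    # every merged contour sits in exactly one whistle
    expect_equal(sum(vapply(w1, function(w) length(w$loops), integer(1))),
                 length(merged))
    # raising max_gap never increases the whistle count
    w2 <- assemble_whistles(merged, max_gap = 0.6)
    expect_lte(length(w2), length(w1))
  }
})

test_that("loop structure is classified from loops, annotation or motif", {
  se <- assemble_whistles(list(mk_contour("c1", 0, dur = 0.4)))[[1]]
  expect_equal(se$structure, "SE")

  dcml <- assemble_whistles(list(mk_contour("c1", 0, dur = 0.2),
                                 mk_contour("c2", 0.3, dur = 0.2),
                                 mk_contour("c3", 0.6, dur = 0.2)))[[1]]
  expect_equal(dcml$structure, "DCML")

  ann <- assemble_whistles(list(
    mk_contour("c1", 0, dur = 0.6, loop_count = 3L)))[[1]]
  expect_equal(ann$structure, "CML")

  # motif autodetection: three identical rise-fall loops in one contour
  loopshape <- function(x) {
    ph <- (x * 3) %% 1
    5000 + 6000 * (1 - abs(2 * ph - 1))
  }
  cml <- assemble_whistles(list(contour_trace("c1", "E1",
    mk_points(0, 0.9, loopshape, n = 91), type_label = "A")))[[1]]
  expect_equal(cml$structure, "CML")

  # a monotone sweep must not be mistaken for repeated loops
  mono <- assemble_whistles(list(contour_trace("c1", "E1",
    mk_points(0, 0.9, lin_shape(4000, 16000), n = 91),
    type_label = "A")))[[1]]
  expect_equal(mono$structure, "SE")
})

test_that("co-occurrence gate measures partner adjacency fractions", {
  # 10 sequences of a; in 9 of them b follows within the loop window
  contours <- list()
  for (i in 1:10) {
    t0 <- (i - 1) * 100
    contours[[length(contours) + 1L]] <-
      mk_contour(sprintf("a%d", i), t0, dur = 0.3, label = "A")
    gap <- if (i <= 9) 0.1 else 5
    contours[[length(contours) + 1L]] <-
      mk_contour(sprintf("b%d", i), t0 + 0.3 + gap, dur = 0.3, label = "B")
  }
  cc <- check_cooccurrence("A", "B", contours)
  expect_equal(cc$frac_a, 0.9)
  expect_equal(cc$frac_b, 0.9)
  expect_true(cc$verdict)

  # 7 of 10 fails the 80% rule
  contours2 <- contours
  for (i in 8:9) {
    idx <- 2 * i
    contours2[[idx]] <- mk_contour(sprintf("b%d", i), (i - 1) * 100 + 8,
                                   dur = 0.3, label = "B")
  }
  cc2 <- check_cooccurrence("A", "B", contours2)
  expect_equal(cc2$frac_a, 0.7)
  expect_false(cc2$verdict)
  expect_error(check_cooccurrence("A", "Z", contours), "absent")
})

test_that("overlapping loop pairs pass the gate (two-voice structure)", {
  # 152 down-sweeps; 143 with an overlapping high-frequency partner
  contours <- list()
  for (i in 1:152) {
    t0 <- (i - 1) * 30 + 10
    contours[[length(contours) + 1L]] <-
      mk_contour(sprintf("ds%d", i), t0, dur = 0.5, f0 = 12000, f1 = 5000,
                 label = "DS")
    if (i <= 143) {
      contours[[length(contours) + 1L]] <-
        mk_contour(sprintf("hf%d", i), t0 - 0.15, dur = 0.27, f0 = 18000,
                   f1 = 18500, label = "HF")
    }
  }
  cc <- check_cooccurrence("DS", "HF", contours)
  expect_equal(cc$frac_a, 143 / 152, tolerance = 1e-12)
  expect_equal(cc$frac_b, 1)
  expect_true(cc$verdict)

  a <- mk_contour("a", 0, dur = 1.0)
  b <- mk_contour("b", 0.9, dur = 0.6)
  expect_equal(measure_loop_overlap(a, b), 0.1, tolerance = 1e-12)
  expect_equal(measure_loop_overlap(a, mk_contour("c", 5, dur = 1)), 0)
  expect_equal(measure_loop_overlap(a, a), 1.0)
})
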