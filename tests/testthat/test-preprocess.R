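test_that("windowing cuts non-overlapping 60 s windows and drops the tail", {
  rec <- stats::rnorm(600 * 100)
  w <- window_signal(rec, fs = 100)
  expect_length(w, 10L)
  expect_true(all(vapply(w, function(x) length(x$samples), 0L) == 6000L))
  expect_length(window_signal(stats::rnorm(59 * 100), fs = 100), 0L)
  # windows concatenated reproduce the record prefix
  expect_equal(unlist(lapply(w, `[[`, "samples")), rec[1:60000])
})

test_that("peak detection recovers beat spacing and ignores offsets", {
  rr <- rep(1.0, 70)
  x <- as.numeric(synthesize_pulse_train(rr, 100))[1:6000]
  pk <- detect_systolic_peaks(x, 100)
  expect_true(all(abs(diff(pk) - 100) <= 2))
  expect_identical(detect_systolic_peaks(x + 5, 100), pk)
  expect_length(detect_systolic_peaks(rep(1, 6000), 100), 0L)
})

test_that("subdivision groups peaks in fives with midpoint boundaries", {
  # 25 evenly spaced peaks: brute-force oracle expects 5 groups of 5
  pk <- seq(100, by = 240, length.out = 25)
  spans <- subdivide_by_peaks(6000, pk)
  expect_equal(nrow(spans), 5L)
  expect_true(all(vapply(spans$peaks, length, 0L) == 5L))
  # oracle: boundary between consecutive groups is the midpoint of the
  # bordering peaks
  for (k in 1:4) {
    expect_equal(spans$end[k],
                 (pk[5 * k] + pk[5 * k + 1]) %/% 2)
  }
  # spans tile the window
  expect_equal(spans$start[1], 0L)
  expect_equal(spans$end[5], 6000L)
  expect_true(all(spans$start[-1] == spans$end[-5]))

  s7 <- subdivide_by_peaks(6000, seq(100, by = 700, length.out = 7))
  expect_equal(nrow(s7), 1L)
  expect_length(s7$peaks[[1]], 7L)
  expect_null(subdivide_by_peaks(6000, c(1, 2)))
})

test_that("mask and label assignment follows the annotation cover", {
  ann <- data.frame(start = c(0, 2000, 4000),
                    end = c(2000, 4000, 6000),
                    class = c("Normal", "AF", "Normal"))
  inside_af <- build_mask_and_label(2500, 3000, ann)
  expect_true(all(inside_af$mask == 1))
  expect_equal(inside_af$label, "AF")
  inside_n <- build_mask_and_label(100, 600, ann)
  expect_true(all(inside_n$mask == 0))
  expect_equal(inside_n$label, "Normal")
  # straddling one abnormal class: partial mask, abnormal label
  strad <- build_mask_and_label(1800, 2400, ann)
  expect_equal(sum(strad$mask), 400)
  expect_equal(strad$label, "AF")
  # two distinct non-Normal classes: excluded
  ann2 <- data.frame(start = c(0, 3000), end = c(3000, 6000),
                     class = c("AF", "Bradycardia"))
  expect_identical(build_mask_and_label(2500, 3500, ann2), "EXCLUDED")
  # gap in the cover is an annotation error
  gap <- data.frame(start = c(0, 2500), end = c(2000, 6000),
                    class = c("Normal", "AF"))
  expect_error(build_mask_and_label(100, 300, gap), "tile")
})

test_that("quality control rejects flatlines and sparse-peak windows", {
  expect_false(qc_segment(rep(2, 300), 10)$pass)
  expect_equal(qc_segment(rep(2, 300), 10)$reason, "flatline")
  expect_false(qc_segment(stats::rnorm(300), 2)$pass)
  x <- as.numeric(synthesize_pulse_train(rep(0.8, 5), 100))
  expect_true(qc_segment(x, 60)$pass)
  # sd exactly at threshold passes (strict-less rejection)
  y <- c(rep(0, 299), 1)
  y <- y / stats::sd(y) * 0.01
  expect_true(qc_segment(y, 10)$pass)
})

test_that("waveform resampling is linear with preserved endpoints", {
  expect_equal(resample_waveform(rep(3.5, 100)), rep(3.5, 286))
  ramp <- seq(0, 1, length.out = 572)
  out <- resample_waveform(ramp)
  expect_lt(max(abs(out - seq(0, 1, length.out = 286))), 1e-9)
  x <- stats::rnorm(286)
  expect_equal(resample_waveform(x), x)
  expect_error(resample_waveform(1), "at least 2")
})

test_that("mask resampling is nearest-neighbour and stays binary", {
  expect_equal(resample_mask(rep(1, 700)), rep(1, 286))
  # single 0->1 transition lands within one sample of the oracle position
  set.seed(3)
  for (n in c(300, 450, 785)) {
    cut <- sample(50:(n - 50), 1)
    m <- c(rep(0, cut), rep(1, n - cut))
    out <- resample_mask(m)
    expect_true(all(out %in% c(0, 1)))
    # brute-force nearest-neighbour oracle
    oracle <- m[round(seq(0, n - 1, length.out = 286)) + 1]
    expect_equal(out, oracle)
    trans <- which(diff(out) == 1)
    expect_lte(abs(trans - round(cut / n * 285)), 1)
  }
  m286 <- rep(c(0, 1), length.out = 286)
  expect_identical(resample_mask(m286), m286)
  expect_error(resample_mask(c(0, 2, 1)), "binary")
})

test_that("z-scoring normalizes and is affine invariant", {
  x <- stats::rnorm(286, 5, 3)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  expect_equal(zscore(2.5 * x + 7), z, tolerance = 1e-12)
  expect_error(zscore(rep(1, 286)), "degenerate")
})

test_that("segment pipeline is deterministic and emits valid segments", {
  cohort <- test_cohort()
  p <- cohort$patients[[1]]
  r1 <- segment_record(p)
  r2 <- segment_record(p)
  expect_identical(r1, r2)
  expect_gt(length(r1$segments), 0L)
  for (s in r1$segments[seq_len(min(20, length(r1$segments)))]) {
    expect_length(s$x_norm, 286L)
    expect_lt(abs(mean(s$x_norm)), 1e-6)
    expect_lt(abs(stats::sd(s$x_norm) - 1), 1e-6)
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(s$label %in% rhythm_classes())
  }
})

test_that("raw segment lengths concentrate in the observed clinical range", {
  prep <- test_prep()
  rl <- prep$manifest$raw_length
  expect_gte(mean(rl >= 286 & rl <= 785), 0.95)
})
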