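test_that("rhythm specs enforce their heart-rate bands", {
  expect_error(rhythm_spec("Bradycardia", rr_mean = 0.9), "HR < 60")
  expect_error(rhythm_spec("Tachycardia", rr_mean = 0.7), "HR > 100")
  expect_error(rhythm_spec("Normal", rr_mean = 1.2), "60, 100")
  expect_equal(rhythm_spec("AF")$rr_model, "irregular")
  expect_error(rhythm_spec("Sinus"), "unknown rhythm class")
})

test_that("RR sampling respects clipping, bands and duration", {
  sp <- rhythm_spec("Bradycardia", rr_mean = 1.2, rr_sd = 0.04)
  rr <- sample_rr_series(sp, 60, seed = 1)
  expect_true(all(rr >= 1.0 & rr <= 1.4))
  expect_lt(60 / mean(rr), 60)
  expect_gte(sum(rr), 60)

  sp2 <- rhythm_spec("Tachycardia", rr_mean = 0.5, rr_sd = 0.015)
  rr2 <- sample_rr_series(sp2, 60, seed = 2)
  expect_gt(60 / mean(rr2), 100)

  expect_identical(sample_rr_series(sp, 30, seed = 5),
                   sample_rr_series(sp, 30, seed = 5))
  expect_error(sample_rr_series(sp, -1), "positive")
})

test_that("AF RR series carry the irregularly-irregular signature", {
  rr_ms <- sample_rr_series(rhythm_spec("AF"), 300, seed = 3) * 1000
  expect_gt(pnn50(rr_ms), 50)
  expect_gt(rmssd(rr_ms), 60)
})

test_that("pulse trains place one systolic peak per beat", {
  rr <- rep(1.0, 60)
  x <- synthesize_pulse_train(rr, fs = 100)
  # independent oracle: argmax within each cycle
  peaks <- vapply(seq_along(rr), function(k) {
    lo <- (k - 1) * 100 + 1
    (lo - 1) + which.max(x[lo:min(lo + 99, length(x))]) - 1
  }, numeric(1))
  expect_lte(abs(length(peaks) - 60), 1)
  expect_true(all(abs(diff(peaks) - 100) <= 2))
  # noiseless constant-RR train is periodic
  c1 <- as.numeric(x)[1:100]; c2 <- as.numeric(x)[101:200]
  expect_gt(stats::cor(c1, c2), 0.999)
  # determinism with noise
  a <- synthesize_pulse_train(rr, 100, noise_sd = 0.05, wander_amp = 0.1,
                              seed = 4)
  b <- synthesize_pulse_train(rr, 100, noise_sd = 0.05, wander_amp = 0.1,
                              seed = 4)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(synthesize_pulse_train(numeric(0), 100), "non-empty")
})

test_that("episode injection rewrites the annotation cover", {
  cfg <- cohort_config(1, class_mix = c(Normal = 1, AF = 0, Bradycardia = 0,
                                        Tachycardia = 0),
                       duration_s = 300, seed = 9)
  p <- generate_patient("T01", "Normal", cfg, seed = 9)
  p2 <- inject_episode(p, "AF", start_s = 120, duration_s = 60, seed = 1)
  af <- p2$annotations[p2$annotations$class == "AF", ]
  expect_equal(nrow(af), 1L)
  expect_equal(af$end - af$start, 6000)
  # cover invariant: sorted intervals tile the record
  ann <- p2$annotations[order(p2$annotations$start), ]
  expect_equal(ann$start[1], 0)
  expect_equal(ann$end[nrow(ann)], length(p2$waveform))
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))

  expect_identical(inject_episode(p, "AF", 10, 0), p)
  expect_error(inject_episode(p2, "Bradycardia", 130, 20), "overlaps")

  # bradycardia episode slows the detected rhythm over its span
  p3 <- inject_episode(p, "Bradycardia", 60, 120, seed = 2)
  span <- p3$waveform[6001:18000]
  pk <- detect_systolic_peaks(span[1:6000], 100)
  expect_lt(unname(hrv_vector(pk, 100)[["hr"]]), 60)
})

test_that("clinical profiles are plausible and deterministic", {
  p <- sample_clinical_profile("AF", seed = 5, p_miss = 0)
  expect_false(any(vapply(p, is.na, TRUE)))
  expect_gte(p$age, 18); expect_lte(p$age, 90)
  expect_true(all(unlist(p[clinical_fields()$binary]) %in% c(0, 1)))
  expect_gte(p$sodium, 125); expect_lte(p$sodium, 150)
  expect_identical(sample_clinical_profile("Normal", seed = 7),
                   sample_clinical_profile("Normal", seed = 7))
  # missingness only hits continuous fields
  set.seed(1)
  miss <- replicate(30, {
    q <- sample_clinical_profile("Normal", seed = sample.int(1e6, 1),
                                 p_miss = 0.5)
    any(vapply(q[clinical_fields()$binary], is.na, TRUE))
  })
  expect_false(any(miss))
})

test_that("cohort generation writes a consistent, reproducible layout", {
  cfg <- cohort_config(4, duration_s = 120, seed = 31)
  d1 <- withr::local_tempdir()
  cohort <- generate_cohort(cfg, out_dir = d1)
  expect_length(unique(names(cohort$patients)), 4L)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(sort(man$patient_id), sort(names(cohort$patients)))

  # byte-identical clinical table under the same seed
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "clinical.csv")),
                   readLines(file.path(d2, "clinical.csv")))

  # all-Normal mix produces exclusively Normal annotations
  cfgN <- cohort_config(2, class_mix = c(Normal = 1, AF = 0,
                                         Bradycardia = 0, Tachycardia = 0),
                        duration_s = 120, seed = 8)
  cN <- generate_cohort(cfgN)
  for (p in cN$patients) expect_true(all(p$annotations$class == "Normal"))

  # round trip through disk
  rc <- read_cohort(d1)
  expect_equal(length(rc$patients), 4L)
  expect_equal(rc$patients[[1]]$waveform,
               cohort$patients[[1]]$waveform, tolerance = 1e-6)
})

test_that("annotation covers tile every generated record", {
  cohort <- test_cohort()
  for (p in cohort$patients) {
    ann <- p$annotations[order(p$annotations$start), ]
    expect_equal(ann$start[1], 0)
    expect_equal(ann$end[nrow(ann)], length(p$waveform))
    expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))
  }
})

test_that("class-conditional RR structure recovers the HRV signatures", {
  set.seed(11)
  stats_by_class <- lapply(rhythm_classes(), function(cl) {
    t(replicate(20, {
      rr_ms <- sample_rr_series(rhythm_spec(cl), 240,
                                seed = sample.int(1e6, 1)) * 1000
      c(hr = oracle_hr(rr_ms), rmssd = oracle_rmssd(rr_ms),
        pnn50 = oracle_pnn50(rr_ms))
    }))
  })
  names(stats_by_class) <- rhythm_classes()
  means <- vapply(stats_by_class, colMeans, numeric(3))
  expect_true(means["hr", "Bradycardia"] < 60)
  expect_true(means["hr", "Normal"] >= 60 && means["hr", "Normal"] <= 100)
  expect_true(means["hr", "Tachycardia"] > 100)
  expect_equal(names(which.max(means["rmssd", ])), "AF")
  expect_equal(names(which.max(means["pnn50", ])), "AF")
})
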