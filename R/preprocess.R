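# Raw record -> fixed-length labelled segments.
#
# Pipeline: 60 s non-overlapping windows -> adaptive systolic peak detection
# -> subdivision into ~5-peak spans -> per-span abnormal mask and rhythm
# label from the annotation cover -> quality control -> resampling to 286
# samples (linear for waveform, nearest-neighbour for the mask) -> per-
# segment z-score normalization. Coordinates are 0-based, intervals
# half-open throughout.

SEGMENT_LENGTH <- 286L

#' Split a record into non-overlapping 60 s windows
#'
#' @param record Numeric waveform.
#' @param fs Sampling frequency in Hz.
#' @param window_s Window length in seconds.
#' @return List of windows, each `list(samples, start_index)` with
#'   `start_index` the 0-based offset in the record. A trailing partial
#'   window is dropped; a record shorter than one window gives an empty
#'   list.
#' @export
window_signal <- function(record, fs = 100, window_s = 60) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  wlen <- round(window_s * fs)
  n_win <- length(record) %/% wlen
  lapply(seq_len(n_win), function(k) {
    start <- (k - 1L) * wlen
    list(samples = record[(start + 1L):(start + wlen)], start_index = start)
  })
}

#' Detect systolic peaks in a PPG window
#'
#' Deterministic adaptive detector: zero-phase band-pass (0.5-8 Hz,
#' second-order Butterworth, forward-backward), candidate peaks are local
#' maxima above a moving 75th-percentile threshold (2 s blocks, linearly
#' interpolated), and a 0.25 s refractory period keeps the larger of two
#' competing candidates. The band-pass removes baseline wander and any
#' constant offset, so peak positions are offset-invariant.
#'
#' @param window Numeric samples of one window.
#' @param fs Sampling frequency in Hz.
#' @param refractory_s Minimum inter-peak distance in seconds.
#' @return Strictly increasing 0-based peak indices (empty for flat input).
#' @export
detect_systolic_peaks <- function(window, fs = 100, refractory_s = 0.25) {
  n <- length(window)
  if (n == 0L) stop("window must be non-empty", call. = FALSE)
  if (stats::sd(window) < 1e-12 || n < 12L) return(integer(0))
  bf <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  # remove the mean first: a constant through the band-pass only creates
  # boundary transients, so this makes detection exactly offset-invariant
  xf <- as.numeric(signal::filtfilt(bf, window - mean(window)))
  # local maxima (plateau-tolerant on the right edge)
  i <- 2:(n - 1)
  cand <- i[xf[i] > xf[i - 1] & xf[i] >= xf[i + 1]]
  if (length(cand) == 0L) return(integer(0))
  # moving 75th-percentile threshold from 2 s blocks
  blk <- max(1L, round(2 * fs))
  starts <- seq(1L, n, by = blk)
  centers <- pmin(starts + (blk - 1) / 2, n)
  q75 <- vapply(starts, function(s) {
    stats::quantile(xf[s:min(s + blk - 1L, n)], 0.75, names = FALSE)
  }, numeric(1))
  thr <- if (length(q75) >= 2L) {
    stats::approx(centers, q75, xout = seq_len(n), rule = 2)$y
  } else {
    rep(q75, n)
  }
  cand <- cand[xf[cand] > thr[cand]]
  if (length(cand) == 0L) return(integer(0))
  # refractory: greedy scan keeping the larger of competing candidates
  min_gap <- round(refractory_s * fs)
  keep <- cand[1]
  for (c0 in cand[-1]) {
    last <- keep[length(keep)]
    if (c0 - last < min_gap) {
      if (xf[c0] > xf[last]) keep[length(keep)] <- c0
    } else {
      keep <- c(keep, c0)
    }
  }
  as.integer(keep - 1L)
}

#' Subdivide a window into ~5-peak spans
#'
#' The P detected peaks are partitioned into `floor(P / peaks_per_segment)`
#' consecutive groups (at least one; the last group absorbs the remainder).
#' Span boundaries sit at the midpoint between the bordering peaks of
#' adjacent groups; the first span starts at the window start and the last
#' ends at the window end, so the spans tile the window.
#'
#' @param window_length Window length in samples.
#' @param peak_indices 0-based peak indices within the window (>= 3).
#' @param peaks_per_segment Target peaks per span.
#' @return Data frame with 0-based half-open columns `start`, `end` and a
#'   list-column `peaks` of each span's peak indices, or `NULL` as the
#'   rejection signal when fewer than 3 peaks are available.
#' @export
subdivide_by_peaks <- function(window_length, peak_indices,
                               peaks_per_segment = 5L) {
  P <- length(peak_indices)
  if (P < 3L) return(NULL)
  n_groups <- max(1L, P %/% peaks_per_segment)
  sizes <- rep(peaks_per_segment, n_groups)
  sizes[n_groups] <- P - peaks_per_segment * (n_groups - 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  bounds <- integer(0)
  if (n_groups > 1L) {
    bounds <- vapply(seq_len(n_groups - 1L), function(k) {
      as.integer((peak_indices[ends[k]] + peak_indices[starts[k + 1L]]) %/% 2)
    }, integer(1))
  }
  lo <- c(0L, bounds)
  hi <- c(bounds, as.integer(window_length))
  data.frame(
    start = lo, end = hi,
    peaks = I(lapply(seq_len(n_groups), function(k) {
      peak_indices[starts[k]:ends[k]]
    }))
  )
}

#' Abnormal-rhythm mask and label for a span
#'
#' Given the record's annotation cover, builds the per-sample binary mask
#' (1 where the covering annotation class is non-Normal) and the span's
#' rhythm label: the unique non-Normal class overlapping the span, or
#' Normal if none. Spans overlapping two distinct non-Normal classes are
#' excluded (mixed-rhythm supervision is ambiguous).
#'
#' @param span_start,span_end 0-based half-open span bounds in record
#'   coordinates.
#' @param annotations Data frame `start`, `end`, `class` tiling the record.
#' @return `list(mask, label)` or the string `"EXCLUDED"` for mixed spans.
#' @export
build_mask_and_label <- function(span_start, span_end, annotations) {
  ann <- annotations[order(annotations$start), , drop = FALSE]
  if (nrow(ann) == 0L || any(ann$start[-1] != ann$end[-nrow(ann)])) {
    stop("annotations must tile the record without gaps or overlaps",
         call. = FALSE)
  }
  ov <- ann[ann$start < span_end & ann$end > span_start, , drop = FALSE]
  if (nrow(ov) == 0L || min(ov$start) > span_start || max(ov$end) < span_end) {
    stop("annotations do not cover the span", call. = FALSE)
  }
  abn <- unique(ov$class[ov$class != "Normal"])
  if (length(abn) >= 2L) return("EXCLUDED")
  mask <- numeric(span_end - span_start)
  for (i in seq_len(nrow(ov))) {
    if (ov$class[i] == "Normal") next
    lo <- max(ov$start[i], span_start) - span_start
    hi <- min(ov$end[i], span_end) - span_start
    mask[(lo + 1L):hi] <- 1
  }
  list(mask = mask, label = if (length(abn)) abn else "Normal")
}

#' Quality control for a candidate span
#'
#' Rejects near-flatline spans (sd below machine-level tolerance), spans
#' with extremely low variability (sd strictly below `sd_min`, measured on
#' the raw, pre-normalization samples), and spans whose parent 60 s window
#' has fewer than three valid systolic peaks.
#'
#' @param samples Raw span samples.
#' @param window_peak_count Peak count of the parent window.
#' @param sd_min Variability threshold in raw amplitude units; a span with
#'   sd exactly at the threshold passes.
#' @return `list(pass, reason)` with `reason` one of `"ok"`, `"flatline"`,
#'   `"low_sd"`, `"few_peaks"`.
#' @export
qc_segment <- function(samples, window_peak_count, sd_min = 0.01) {
  if (window_peak_count < 3L) return(list(pass = FALSE, reason = "few_peaks"))
  s <- stats::sd(samples)
  if (s < 1e-12) return(list(pass = FALSE, reason = "flatline"))
  # strict-less rejection with a relative guard so a span sitting exactly
  # at the threshold passes despite floating-point round-off
  if (s < sd_min * (1 - 1e-9)) return(list(pass = FALSE, reason = "low_sd"))
  list(pass = TRUE, reason = "ok")
}

#' Resample a waveform to a fixed length by linear interpolation
#'
#' Query points are `L` uniformly spaced positions from the first to the
#' last input index inclusive, so endpoints are preserved and an input
#' already of length `L` is returned unchanged.
#'
#' @param samples Numeric input of length >= 2.
#' @param L Output length.
#' @return Numeric vector of length `L`.
#' @export
resample_waveform <- function(samples, L = SEGMENT_LENGTH) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to resample", call. = FALSE)
  stats::approx(seq(0, n - 1), samples,
                xout = seq(0, n - 1, length.out = L))$y
}

#' Resample a binary mask by nearest-neighbour interpolation
#'
#' Preserves boundary sharpness and binarity: each output value is the mask
#' value at the rounded source position.
#'
#' @param mask Binary vector.
#' @param L Output length.
#' @return Binary vector of length `L`.
#' @export
resample_mask <- function(mask, L = SEGMENT_LENGTH) {
  if (!is_binary(mask)) stop("mask must be binary", call. = FALSE)
  n <- length(mask)
  if (n < 1L) stop("mask must be non-empty", call. = FALSE)
  if (n == 1L) return(rep(mask, L))
  idx <- round(seq(0, n - 1, length.out = L))
  mask[idx + 1L]
}

#' Z-score normalize a segment
#'
#' Subtracts the segment mean and divides by the segment sample standard
#' deviation, removing perfusion/contact-pressure amplitude variation.
#' Invariant under positive affine transforms of the input.
#'
#' @param samples Numeric input with positive standard deviation.
#' @return Normalized vector with mean 0 and sd 1.
#' @export
zscore <- function(samples) {
  s <- stats::sd(samples)
  if (!is.finite(s) || s < 1e-12) {
    stop("degenerate segment: zero standard deviation", call. = FALSE)
  }
  (samples - mean(samples)) / s
}

new_qc_report <- function() {
  list(n_input = 0L, n_rejected_flatline = 0L, n_rejected_low_sd = 0L,
       n_rejected_few_peaks = 0L, n_rejected_mixed = 0L)
}

#' Preprocess one record into labelled segments
#'
#' Runs the full windowing / peak detection / subdivision / labelling / QC /
#' resampling / normalization pipeline and attaches HRV features to each
#' segment (computed from the span's own peaks when it has at least three,
#' otherwise from the parent window's peaks).
#'
#' @param patient A `ppg_patient` (or any list with `waveform`, `fs`,
#'   `annotations`, `patient_id`).
#' @param L Target segment length.
#' @param sd_min QC variability threshold.
#' @param peaks_per_segment Subdivision target.
#' @return `list(segments, qc)`. Each segment is a list with `x_norm`
#'   (length `L`, mean 0, sd 1), `mask` (binary, length `L`), `label`,
#'   `hrv` (hr/sdnn/rmssd/pnn50), `patient_id`, `raw_length`, `peak_count`,
#'   `window_index`, `start_index`.
#' @export
segment_record <- function(patient, L = SEGMENT_LENGTH, sd_min = 0.01,
                           peaks_per_segment = 5L) {
  fs <- patient$fs
  qc <- new_qc_report()
  segments <- list()
  windows <- window_signal(patient$waveform, fs = fs)
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    peaks <- detect_systolic_peaks(w$samples, fs = fs)
    if (length(peaks) < 3L) {
      qc$n_input <- qc$n_input + 1L
      qc$n_rejected_few_peaks <- qc$n_rejected_few_peaks + 1L
      next
    }
    spans <- subdivide_by_peaks(length(w$samples), peaks,
                                peaks_per_segment = peaks_per_segment)
    win_rr_fallback <- peaks
    for (si in seq_len(nrow(spans))) {
      qc$n_input <- qc$n_input + 1L
      s0 <- spans$start[si]; s1 <- spans$end[si]
      samples <- w$samples[(s0 + 1L):s1]
      q <- qc_segment(samples, length(peaks), sd_min = sd_min)
      if (!q$pass) {
        f <- paste0("n_rejected_", q$reason)
        qc[[f]] <- qc[[f]] + 1L
        next
      }
      ml <- build_mask_and_label(w$start_index + s0, w$start_index + s1,
                                 patient$annotations)
      if (identical(ml, "EXCLUDED")) {
        qc$n_rejected_mixed <- qc$n_rejected_mixed + 1L
        next
      }
      span_peaks <- spans$peaks[[si]] - s0
      hrv <- hrv_vector(span_peaks, fs, fallback_peaks = win_rr_fallback)
      if (is.null(hrv)) {
        qc$n_rejected_few_peaks <- qc$n_rejected_few_peaks + 1L
        next
      }
      x_norm <- tryCatch(zscore(resample_waveform(samples, L)),
                         error = function(e) NULL)
      if (is.null(x_norm)) {
        qc$n_rejected_flatline <- qc$n_rejected_flatline + 1L
        next
      }
      segments[[length(segments) + 1L]] <- list(
        x_norm = x_norm,
        mask = resample_mask(ml$mask, L),
        label = ml$label,
        hrv = hrv,
        patient_id = patient$patient_id,
        raw_length = length(samples),
        peak_count = length(span_peaks),
        window_index = wi - 1L,
        start_index = w$start_index + s0
      )
    }
  }
  list(segments = segments, qc = qc)
}

#' Preprocess an entire cohort
#'
#' @param cohort A `ppg_cohort`.
#' @param ... Passed to [segment_record()].
#' @return `list(segments, qc, manifest)` where `manifest` is a data frame
#'   (segment_id, patient_id, label, raw_length, hr, sdnn, rmssd, pnn50).
#' @export
preprocess_cohort <- function(cohort, ...) {
  all_segments <- list()
  qc <- new_qc_report()
  for (p in cohort$patients) {
    res <- segment_record(p, ...)
    all_segments <- c(all_segments, res$segments)
    for (f in names(qc)) qc[[f]] <- qc[[f]] + res$qc[[f]]
  }
  manifest <- if (length(all_segments)) {
    data.frame(
      segment_id = seq_along(all_segments),
      patient_id = vapply(all_segments, `[[`, "", "patient_id"),
      label = vapply(all_segments, `[[`, "", "label"),
      raw_length = vapply(all_segments, `[[`, 0L, "raw_length"),
      hr = vapply(all_segments, function(s) s$hrv[["hr"]], 0),
      sdnn = vapply(all_segments, function(s) s$hrv[["sdnn"]], 0),
      rmssd = vapply(all_segments, function(s) s$hrv[["rmssd"]], 0),
      pnn50 = vapply(all_segments, function(s) s$hrv[["pnn50"]], 0),
      stringsAsFactors = FALSE)
  } else {
    data.frame()
  }
  list(segments = all_segments, qc = qc, manifest = manifest)
}
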