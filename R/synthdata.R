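# Synthetic rhythm-labelled PPG cohorts.
#
# Emulates perioperative finger-probe PPG at 100 Hz: ~9-10 min per patient,
# one systolic pulse plus a smaller dicrotic bump per beat, additive sensor
# noise and slow respiratory baseline wander. Rhythm structure is imposed
# through the RR-interval model: regular classes draw i.i.d. clipped-normal
# RR intervals inside their clinical heart-rate band, atrial fibrillation
# draws i.i.d. heavy-jitter lognormal intervals ("irregularly irregular").

DEFAULT_SPECS <- list(
  Normal      = list(rr_mean = 0.85, rr_sd = 0.03, rr_model = "gaussian-regular",
                     rr_clip = c(0.65, 1.00)),
  AF          = list(rr_mean = 0.70, rr_sd = 0.25, rr_model = "irregular",
                     rr_clip = c(0.35, 1.40)),
  Bradycardia = list(rr_mean = 1.20, rr_sd = 0.04, rr_model = "gaussian-regular",
                     rr_clip = c(1.00, 1.40)),
  # Mean RR chosen so that a ~5-beat span at 100 Hz stays at or above the
  # 286-sample minimum segment length the preprocessing pipeline is built
  # around, while the heart-rate band (> 100 bpm) still holds with margin.
  Tachycardia = list(rr_mean = 0.58, rr_sd = 0.008, rr_model = "gaussian-regular",
                     rr_clip = c(0.565, 0.595))
)

#' Rhythm specification for RR-interval sampling
#'
#' Defines the beat-to-beat interval model for one rhythm class. Regular
#' rhythms (Normal, Bradycardia, Tachycardia) use i.i.d. normal RR intervals
#' clipped to `rr_clip`; atrial fibrillation uses i.i.d. lognormal intervals
#' `rr_mean * exp(N(0, rr_sd))` (here `rr_sd` is the log-scale sd), whose
#' successive differences exceed 50 ms more often than not.
#'
#' Class invariants on the implied heart rate are enforced:
#' Bradycardia < 60 bpm, Normal in [60, 100], Tachycardia > 100 bpm.
#'
#' @param rhythm_class One of [rhythm_classes()].
#' @param rr_mean Mean RR interval in seconds (lognormal scale for AF).
#' @param rr_sd RR standard deviation in seconds (log-scale sd for AF).
#' @param rr_clip Length-2 clipping bounds in seconds. When `rr_mean` is
#'   overridden without `rr_clip`, the clip defaults to `rr_mean +/- 5 rr_sd`.
#' @return Object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rhythm_class, rr_mean = NULL, rr_sd = NULL,
                        rr_clip = NULL) {
  assert_rhythm_class(rhythm_class)
  def <- DEFAULT_SPECS[[rhythm_class]]
  custom_mean <- !is.null(rr_mean)
  rr_mean <- rr_mean %||% def$rr_mean
  rr_sd <- rr_sd %||% def$rr_sd
  if (is.null(rr_clip)) {
    rr_clip <- if (custom_mean) c(rr_mean - 5 * rr_sd, rr_mean + 5 * rr_sd)
               else def$rr_clip
  }
  if (rr_mean <= 0) stop("rr_mean must be positive", call. = FALSE)
  if (rr_sd < 0) stop("rr_sd must be non-negative", call. = FALSE)
  hr <- 60 / rr_mean
  if (rhythm_class == "Bradycardia" && hr >= 60) {
    stop("Bradycardia spec implies HR < 60 bpm (got ", round(hr, 1), ")",
         call. = FALSE)
  }
  if (rhythm_class == "Tachycardia" && hr <= 100) {
    stop("Tachycardia spec implies HR > 100 bpm (got ", round(hr, 1), ")",
         call. = FALSE)
  }
  if (rhythm_class == "Normal" && (hr < 60 || hr > 100)) {
    stop("Normal spec implies HR in [60, 100] bpm (got ", round(hr, 1), ")",
         call. = FALSE)
  }
  structure(
    list(rhythm_class = rhythm_class, rr_mean = rr_mean, rr_sd = rr_sd,
         rr_model = if (rhythm_class == "AF") "irregular" else def$rr_model,
         rr_clip = sort(rr_clip)),
    class = "rhythm_spec"
  )
}

#' Sample an RR-interval series covering a given duration
#'
#' Draws RR intervals from the spec's model until their cumulative sum
#' reaches `duration_s`.
#'
#' @param spec A [rhythm_spec()].
#' @param duration_s Span to cover, in seconds (> 0).
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @return Numeric vector of RR intervals in seconds whose sum is
#'   >= `duration_s`.
#' @export
sample_rr_series <- function(spec, duration_s, seed = NULL) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  with_seed(seed, {
    rr <- numeric(0)
    while (sum(rr) < duration_s) {
      n <- max(16L, ceiling((duration_s - sum(rr)) / spec$rr_mean * 1.3))
      draw <- if (spec$rr_model == "irregular") {
        spec$rr_mean * exp(stats::rnorm(n, 0, spec$rr_sd))
      } else {
        stats::rnorm(n, spec$rr_mean, spec$rr_sd)
      }
      rr <- c(rr, pmin(pmax(draw, spec$rr_clip[1]), spec$rr_clip[2]))
    }
    rr[seq_len(which(cumsum(rr) >= duration_s)[1])]
  })
}

#' Synthesize a PPG pulse train from RR intervals
#'
#' Renders one pulse per beat as the sum of two Gaussians: the systolic peak
#' (amplitude 1.0 at 30% of the beat) and a smaller dicrotic bump (amplitude
#' 0.35 at 65%), both widths proportional to the local RR so morphology is
#' rate-invariant. Optionally adds white sensor noise and sinusoidal
#' baseline wander (0.2 Hz, respiratory band).
#'
#' @param rr RR intervals in seconds (all > 0).
#' @param fs Sampling frequency in Hz.
#' @param pulse_params List with `sys_frac`, `sys_amp`, `sys_width`,
#'   `dic_frac`, `dic_amp`, `dic_width` (fractions of the beat).
#' @param noise_sd Gaussian noise sd, arbitrary units.
#' @param wander_amp Baseline wander amplitude, arbitrary units.
#' @param seed Integer seed for the noise/wander phase.
#' @return Numeric waveform of length `round(sum(rr) * fs)` with attributes
#'   `fs` and `systolic_times` (ground-truth systolic peak times, seconds).
#' @export
synthesize_pulse_train <- function(rr, fs = 100,
                                   pulse_params = list(),
                                   noise_sd = 0, wander_amp = 0,
                                   seed = NULL) {
  if (length(rr) == 0L) stop("rr must be non-empty", call. = FALSE)
  if (any(rr <= 0)) stop("all RR intervals must be positive", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  pp <- utils::modifyList(
    list(sys_frac = 0.30, sys_amp = 1.0, sys_width = 0.10,
         dic_frac = 0.65, dic_amp = 0.35, dic_width = 0.12),
    pulse_params
  )
  onsets <- cumsum(c(0, rr))[seq_along(rr)]
  n <- round(sum(rr) * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  add_gauss <- function(x, center, amp, sd) {
    lo <- max(1L, floor((center - 4 * sd) * fs) + 1L)
    hi <- min(n, ceiling((center + 4 * sd) * fs) + 1L)
    if (lo <= hi) {
      idx <- lo:hi
      x[idx] <- x[idx] + amp * exp(-0.5 * ((t[idx] - center) / sd)^2)
    }
    x
  }
  for (k in seq_along(rr)) {
    r <- rr[k]
    x <- add_gauss(x, onsets[k] + pp$sys_frac * r, pp$sys_amp, pp$sys_width * r)
    x <- add_gauss(x, onsets[k] + pp$dic_frac * r, pp$dic_amp, pp$dic_width * r)
  }
  if (noise_sd > 0 || wander_amp > 0) {
    x <- x + with_seed(seed, {
      phase <- stats::runif(1, 0, 2 * pi)
      noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
      noise + wander_amp * sin(2 * pi * 0.2 * t + phase)
    })
  }
  structure(x, fs = fs, systolic_times = onsets + pp$sys_frac * rr)
}

#' Cohort generation configuration
#'
#' @param n_patients Number of patients (>= 1).
#' @param class_mix Named proportions over [rhythm_classes()], summing to 1;
#'   the per-patient dominant rhythm mix. Default reflects an AF-dominated
#'   arrhythmia cohort with scarce tachycardia.
#' @param duration_s Record duration per patient in seconds (~9.5 min).
#' @param noise_sd Sensor noise sd (a.u.).
#' @param baseline_wander_amp Respiratory baseline wander amplitude (a.u.).
#' @param abnormal_frac Approximate fraction of an arrhythmia patient's
#'   record covered by abnormal episodes.
#' @param p_miss Per-field missingness probability for continuous clinical
#'   variables.
#' @param seed Integer master seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          class_mix = c(Normal = 0.40, AF = 0.35,
                                        Bradycardia = 0.18,
                                        Tachycardia = 0.07),
                          duration_s = 570, noise_sd = 0.03,
                          baseline_wander_amp = 0.10,
                          abnormal_frac = 0.5, p_miss = 0.05, seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (is.null(names(class_mix)) ||
      !setequal(names(class_mix), RHYTHM_CLASSES)) {
    stop("class_mix must be named over all four rhythm classes",
         call. = FALSE)
  }
  class_mix <- class_mix[RHYTHM_CLASSES]
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix proportions must sum to 1", call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients), class_mix = class_mix,
         duration_s = duration_s, noise_sd = noise_sd,
         baseline_wander_amp = baseline_wander_amp,
         abnormal_frac = abnormal_frac, p_miss = p_miss,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Build the alternating Normal/abnormal episode timeline for one patient.
# Returns data.frame(start_s, end_s, class) tiling [0, duration_s).
episode_timeline <- function(dominant_class, duration_s, abnormal_frac) {
  if (dominant_class == "Normal") {
    return(data.frame(start_s = 0, end_s = duration_s, class = "Normal",
                      stringsAsFactors = FALSE))
  }
  n_ep <- sample(2:3, 1)
  total_ab <- abnormal_frac * stats::runif(1, 0.9, 1.2) * duration_s
  total_ab <- min(total_ab, 0.75 * duration_s)
  ep_w <- stats::runif(n_ep, 0.5, 1)
  ep_dur <- pmax(30, total_ab * ep_w / sum(ep_w))
  gap_w <- stats::runif(n_ep + 1, 0.5, 1)
  gap_dur <- pmax(15, (duration_s - sum(ep_dur)) * gap_w / sum(gap_w))
  # rescale gaps so the timeline sums exactly to duration_s
  gap_dur <- gap_dur * (duration_s - sum(ep_dur)) / sum(gap_dur)
  durs <- as.vector(rbind(gap_dur, c(ep_dur, NA)))
  durs <- durs[!is.na(durs)]
  cls <- rep(c("Normal", dominant_class), length.out = length(durs))
  ends <- cumsum(durs)
  data.frame(start_s = c(0, ends[-length(ends)]), end_s = ends, class = cls,
             stringsAsFactors = FALSE)
}

# Synthesize a patient record from a timeline: each span's waveform is drawn
# from its class spec and concatenated; noise and wander are added once over
# the full record for continuity.
synthesize_record <- function(timeline, fs, noise_sd, wander_amp, seed) {
  with_seed(seed, {
    pieces <- vector("list", nrow(timeline))
    ann <- timeline
    for (i in seq_len(nrow(timeline))) {
      span_s <- timeline$end_s[i] - timeline$start_s[i]
      span_n <- round(timeline$end_s[i] * fs) - round(timeline$start_s[i] * fs)
      rr <- sample_rr_series(rhythm_spec(timeline$class[i]), span_s + 2)
      x <- synthesize_pulse_train(rr, fs)
      pieces[[i]] <- as.numeric(x)[seq_len(span_n)]
    }
    x <- unlist(pieces)
    n <- length(x)
    t <- (seq_len(n) - 1) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + stats::rnorm(n, 0, noise_sd) +
      wander_amp * sin(2 * pi * 0.2 * t + phase)
    ann$start <- round(ann$start_s * fs)
    ann$end <- round(ann$end_s * fs)
    list(waveform = x,
         annotations = ann[, c("start", "end", "class")])
  })
}

#' Generate one synthetic patient
#'
#' @param patient_id Identifier string.
#' @param dominant_class The patient's dominant rhythm; abnormal classes get
#'   a Normal background interleaved with 2-3 episodes of the class covering
#'   roughly `abnormal_frac` of the record.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this patient.
#' @return Object of class `ppg_patient`: list with `patient_id`, `waveform`,
#'   `fs`, `annotations` (data.frame start/end/class, 0-based half-open
#'   sample intervals tiling the record), `clinical`, `dominant_class`,
#'   `seed`.
#' @export
generate_patient <- function(patient_id, dominant_class, config, seed) {
  assert_rhythm_class(dominant_class)
  tl <- with_seed(derive_seed(seed, "timeline"),
                  episode_timeline(dominant_class, config$duration_s,
                                   config$abnormal_frac))
  rec <- synthesize_record(tl, fs = 100, config$noise_sd,
                           config$baseline_wander_amp,
                           derive_seed(seed, "waveform"))
  clin <- sample_clinical_profile(dominant_class,
                                  seed = derive_seed(seed, "clinical"),
                                  p_miss = config$p_miss)
  structure(
    list(patient_id = patient_id, waveform = rec$waveform, fs = 100,
         annotations = rec$annotations, clinical = clin,
         dominant_class = dominant_class, seed = seed,
         params = list(noise_sd = config$noise_sd,
                       wander_amp = config$baseline_wander_amp)),
    class = "ppg_patient"
  )
}

#' Inject a rhythm episode into an existing record
#'
#' Regenerates the waveform over `[start_s, start_s + duration_s)` with the
#' episode class's RR model and updates the annotation cover. Injecting over
#' an existing non-Normal episode is an error (annotations stay single-class).
#'
#' @param patient A `ppg_patient`.
#' @param rhythm_class Episode class.
#' @param start_s,duration_s Episode location and length in seconds.
#' @param seed Integer seed.
#' @return The modified `ppg_patient`.
#' @export
inject_episode <- function(patient, rhythm_class, start_s, duration_s,
                           seed = NULL) {
  stopifnot(inherits(patient, "ppg_patient"))
  assert_rhythm_class(rhythm_class)
  if (duration_s == 0) return(patient)
  if (duration_s < 0) stop("duration_s must be >= 0", call. = FALSE)
  fs <- patient$fs
  n <- length(patient$waveform)
  s0 <- round(start_s * fs); s1 <- round((start_s + duration_s) * fs)
  if (s0 < 0 || s1 > n) stop("episode outside record bounds", call. = FALSE)
  ann <- patient$annotations
  hit <- ann$start < s1 & ann$end > s0 & ann$class != "Normal"
  if (any(hit)) {
    stop("episode overlaps an existing non-Normal episode", call. = FALSE)
  }
  seg <- with_seed(seed, {
    rr <- sample_rr_series(rhythm_spec(rhythm_class), duration_s + 2)
    x <- as.numeric(synthesize_pulse_train(rr, fs))[seq_len(s1 - s0)]
    x + stats::rnorm(s1 - s0, 0, patient$params$noise_sd)
  })
  patient$waveform[(s0 + 1):s1] <- seg
  # rebuild the annotation cover: clip existing intervals, insert the episode
  kept <- list()
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    if (a$end <= s0 || a$start >= s1) { kept[[length(kept) + 1L]] <- a; next }
    if (a$start < s0) kept[[length(kept) + 1L]] <-
        data.frame(start = a$start, end = s0, class = a$class)
    if (a$end > s1) kept[[length(kept) + 1L]] <-
        data.frame(start = s1, end = a$end, class = a$class)
  }
  kept[[length(kept) + 1L]] <-
    data.frame(start = s0, end = s1, class = rhythm_class)
  ann <- do.call(rbind, kept)
  ann <- ann[order(ann$start), , drop = FALSE]
  # merge adjacent same-class intervals
  merged <- ann[1, , drop = FALSE]
  for (i in seq_len(nrow(ann))[-1]) {
    j <- nrow(merged)
    if (ann$class[i] == merged$class[j] && ann$start[i] == merged$end[j]) {
      merged$end[j] <- ann$end[i]
    } else {
      merged <- rbind(merged, ann[i, ])
    }
  }
  rownames(merged) <- NULL
  patient$annotations <- merged
  patient
}

# Clinical field schema shared with the clinical module: 9 continuous + 4
# binary variables, fixed alphabetical order.
CLINICAL_CONTINUOUS <- c("age", "bmi", "bun", "creatinine", "ephedrine",
                         "op_duration", "phenylephrine", "potassium",
                         "sodium")
CLINICAL_BINARY <- c("diabetes", "emergency", "hypertension", "sex")
CLINICAL_FIELDS <- sort(c(CLINICAL_CONTINUOUS, CLINICAL_BINARY))

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Sample a plausible clinical profile
#'
#' Draws the 13 structured clinical variables (9 continuous + 4 binary)
#' within documented physiological ranges, with mild class-conditional
#' shifts (AF patients skew older with more hypertension; emergency and
#' vasopressor use slightly elevated in arrhythmia classes). With
#' probability `p_miss`, each continuous field is set missing to exercise
#' downstream imputation; binary fields are never missing.
#'
#' @param rhythm_class Dominant rhythm of the patient.
#' @param seed Integer seed.
#' @param p_miss Missingness probability per continuous field.
#' @return Named list of the 13 fields (class `clinical_profile`).
#' @export
sample_clinical_profile <- function(rhythm_class, seed = NULL,
                                    p_miss = 0.05) {
  assert_rhythm_class(rhythm_class)
  with_seed(seed, {
    ab <- rhythm_class != "Normal"
    af <- rhythm_class == "AF"
    p <- list(
      age = rtrunc_norm(1, if (af) 68 else 55, 12, 18, 90),
      bmi = rtrunc_norm(1, 24.5, 3.5, 16, 40),
      bun = rtrunc_norm(1, 17, 6, 5, 60),
      creatinine = rtrunc_norm(1, 0.9, 0.3, 0.4, 4.0),
      diabetes = stats::rbinom(1, 1, if (ab) 0.30 else 0.15),
      emergency = stats::rbinom(1, 1, if (ab) 0.15 else 0.08),
      ephedrine = round(rtrunc_norm(1, if (ab) 8 else 4, 5, 0, 30), 1),
      hypertension = stats::rbinom(1, 1, if (af) 0.55 else 0.30),
      op_duration = round(rtrunc_norm(1, 240, 60, 120, 480)),
      phenylephrine = round(rtrunc_norm(1, if (ab) 120 else 60, 80, 0, 500)),
      potassium = rtrunc_norm(1, 4.1, 0.4, 2.8, 6.0),
      sex = stats::rbinom(1, 1, 0.5),
      sodium = rtrunc_norm(1, 139, 3, 125, 150)
    )
    for (f in CLINICAL_CONTINUOUS) {
      if (stats::runif(1) < p_miss) p[[f]] <- NA_real_
    }
    structure(p[CLINICAL_FIELDS], class = "clinical_profile")
  })
}

#' Generate a synthetic cohort
#'
#' Draws each patient's dominant rhythm from `config$class_mix`, generates
#' records and clinical profiles, and (optionally) writes the on-disk layout:
#' `waveforms/<id>.txt` (one sample per line) with JSON sidecars,
#' `annotations/<id>.json`, `clinical.csv` and `manifest.json`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `ppg_cohort`: list with `patients` (list of
#'   `ppg_patient`), `clinical` (data.frame, one row per patient) and
#'   `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- with_seed(derive_seed(config$seed, "classmix"),
                       sample(RHYTHM_CLASSES, config$n_patients,
                              replace = TRUE, prob = config$class_mix))
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  patients <- lapply(seq_len(config$n_patients), function(i) {
    generate_patient(ids[i], classes[i], config,
                     seed = derive_seed(config$seed, paste0("patient-", ids[i])))
  })
  names(patients) <- ids
  clinical <- do.call(rbind, lapply(patients, function(p) {
    cbind(data.frame(patient_id = p$patient_id,
                     dominant_class = p$dominant_class,
                     stringsAsFactors = FALSE),
          as.data.frame(lapply(p$clinical, function(v) v)))
  }))
  rownames(clinical) <- NULL
  cohort <- structure(list(patients = patients, clinical = clinical,
                           config = config), class = "ppg_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to disk
#'
#' @param cohort A `ppg_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "waveforms"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  for (p in cohort$patients) {
    wf <- file.path(out_dir, "waveforms", paste0(p$patient_id, ".txt"))
    writeLines(formatC(p$waveform, format = "g", digits = 9), wf)
    jsonlite::write_json(
      list(patient_id = p$patient_id, fs = p$fs,
           length = length(p$waveform)),
      file.path(out_dir, "waveforms", paste0(p$patient_id, ".json")),
      auto_unbox = TRUE)
    jsonlite::write_json(
      p$annotations,
      file.path(out_dir, "annotations", paste0(p$patient_id, ".json")))
  }
  utils::write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  manifest <- data.frame(
    patient_id = vapply(cohort$patients, `[[`, "", "patient_id"),
    waveform = file.path("waveforms",
                         paste0(names(cohort$patients), ".txt")),
    annotations = file.path("annotations",
                            paste0(names(cohort$patients), ".json")),
    dominant_class = vapply(cohort$patients, `[[`, "", "dominant_class"),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return A `ppg_cohort` (without generator parameters).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  patients <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$patient_id[i]
    side <- jsonlite::read_json(
      file.path(dir, "waveforms", paste0(id, ".json")), simplifyVector = TRUE)
    structure(
      list(patient_id = id,
           waveform = as.numeric(readLines(file.path(dir, manifest$waveform[i]))),
           fs = side$fs,
           annotations = jsonlite::read_json(file.path(dir, manifest$annotations[i]),
                                             simplifyVector = TRUE),
           clinical = as.list(clinical[clinical$patient_id == id,
                                       CLINICAL_FIELDS]),
           dominant_class = manifest$dominant_class[i]),
      class = "ppg_patient")
  })
  names(patients) <- manifest$patient_id
  structure(list(patients = patients, clinical = clinical, config = NULL),
            class = "ppg_cohort")
}
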