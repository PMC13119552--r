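# Shared fixtures, built lazily in code and cached for the session.

.fixture_env <- new.env()

# small mixed cohort used across preprocessing / model / retrieval tests
test_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohort_config(
      10L,
      class_mix = c(Normal = 0.4, AF = 0.3, Bradycardia = 0.2,
                    Tachycardia = 0.1),
      seed = 424L)
    .fixture_env$cohort <- generate_cohort(cfg)
  }
  .fixture_env$cohort
}

test_prep <- function() {
  if (is.null(.fixture_env$prep)) {
    .fixture_env$prep <- preprocess_cohort(test_cohort())
  }
  .fixture_env$prep
}

# standardized clinical matrix for the whole test cohort (scaler fitted on
# all of it; fine for fixtures that are not about leakage)
test_clinical_mat <- function() {
  if (is.null(.fixture_env$cmat)) {
    cohort <- test_cohort()
    scaler <- fit_clinical_scaler(cohort$clinical)
    m <- clinical_transform(cohort$clinical, scaler)
    rownames(m) <- cohort$clinical$patient_id
    .fixture_env$cmat <- m
  }
  .fixture_env$cmat
}

# a tiny trained clip checkpoint shared by contrastive/model tests
test_clip_checkpoint <- function() {
  if (is.null(.fixture_env$ckpt)) {
    segs <- test_prep()$segments
    segs <- segs[seq_len(min(64L, length(segs)))]
    .fixture_env$ckpt <- train_clip(
      segs, test_clinical_mat(),
      contrastive_config(epochs = 2L, batch_size = 16L, seed = 99L,
                         stem_channels = 8L,
                         encoder_widths = c(16L, 32L, 64L)))
  }
  .fixture_env$ckpt
}

# literal transcriptions of the HRV definitions, kept deliberately naive
# and independent of the package implementation
oracle_hr <- function(rr_ms) 60 / (mean(rr_ms) / 1000)
oracle_sdnn <- function(rr_ms) {
  n <- length(rr_ms)
  sqrt(sum((rr_ms - mean(rr_ms))^2) / (n - 1))
}
oracle_rmssd <- function(rr_ms) {
  n <- length(rr_ms)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + (rr_ms[i + 1] - rr_ms[i])^2
  sqrt(s / (n - 1))
}
oracle_pnn50 <- function(rr_ms) {
  n <- length(rr_ms)
  cnt <- 0
  for (i in seq_len(n - 1)) if (abs(rr_ms[i + 1] - rr_ms[i]) > 50) cnt <- cnt + 1
  100 * cnt / (n - 1)
}

# brute-force InfoNCE transcriptions (double loops over the batch)
oracle_infonce_wc <- function(zw, zc, tau) {
  N <- ncol(zw)
  tot <- 0
  for (i in seq_len(N)) {
    num <- exp(sum(zw[, i] * zc[, i]) / tau)
    den <- 0
    for (j in seq_len(N)) den <- den + exp(sum(zw[, i] * zc[, j]) / tau)
    tot <- tot - log(num / den)
  }
  tot / N
}
oracle_infonce_ws <- function(zw, labels, zs, tau) {
  N <- ncol(zw); K <- ncol(zs)
  tot <- 0
  for (i in seq_len(N)) {
    num <- exp(sum(zw[, i] * zs[, labels[i]]) / tau)
    den <- 0
    for (k in seq_len(K)) den <- den + exp(sum(zw[, i] * zs[, k]) / tau)
    tot <- tot - log(num / den)
  }
  tot / N
}

random_unit_cols <- function(d, n) {
  z <- matrix(stats::rnorm(d * n), d)
  sweep(z, 2, sqrt(colSums(z^2)), `/`)
}

# confusion matrix of the proposed model on the clinical test set,
# reconstructed from the per-class counts reported with it
worked_confusion <- function() {
  m <- matrix(c(196, 4, 2, 0,
                1, 76, 3, 0,
                0, 19, 79, 0,
                2, 3, 0, 1),
              nrow = 4, byrow = TRUE,
              dimnames = list(true = rhythm_classes(),
                              pred = rhythm_classes()))
  m
}
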