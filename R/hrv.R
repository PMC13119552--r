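# Time-domain heart rate variability features from P-P (RR) intervals.
#
# All four features operate on an RR series in milliseconds. The 50 ms
# threshold of pNN50 makes milliseconds the natural internal unit; heart
# rate converts to seconds internally.

#' Convert systolic peak indices to an RR-interval series
#'
#' @param peak_indices Strictly increasing 0-based sample indices of systolic
#'   peaks.
#' @param fs Sampling frequency in Hz.
#' @return Object of class `rr_series`: numeric vector of successive P-P
#'   intervals in milliseconds.
#' @export
peaks_to_rr <- function(peak_indices, fs) {
  if (length(peak_indices) < 2L) {
    stop("need at least 2 peaks to form an RR interval", call. = FALSE)
  }
  if (is.unsorted(peak_indices, strictly = TRUE)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  rr <- diff(peak_indices) / fs * 1000
  structure(as.numeric(rr), class = "rr_series")
}

check_rr <- function(rr, min_n = 1L) {
  rr <- unclass(rr)
  if (!is.numeric(rr) || length(rr) < min_n) {
    stop("RR series too short (need >= ", min_n, " intervals)", call. = FALSE)
  }
  if (any(rr <= 0)) stop("RR intervals must be positive", call. = FALSE)
  rr
}

#' Mean heart rate in beats per minute
#'
#' HR = 60 / mean(RR in seconds).
#'
#' @param rr RR intervals in milliseconds.
#' @return Heart rate in bpm.
#' @export
heart_rate <- function(rr) {
  rr <- check_rr(rr, 1L)
  60000 * length(rr) / sum(rr)
}

#' Standard deviation of NN intervals (SDNN)
#'
#' Sample standard deviation (N - 1 denominator) of the RR series,
#' the conventional measure of overall heart-rate variability.
#'
#' @inheritParams heart_rate
#' @return SDNN in milliseconds.
#' @export
sdnn <- function(rr) {
  rr <- check_rr(rr, 2L)
  stats::sd(rr)
}

#' Root mean square of successive differences (RMSSD)
#'
#' sqrt( sum((RR[i+1] - RR[i])^2) / (N - 1) ) over the N-interval series;
#' the hallmark short-term variability statistic, elevated in the
#' irregularly irregular rhythm of atrial fibrillation.
#'
#' @inheritParams heart_rate
#' @return RMSSD in milliseconds.
#' @export
rmssd <- function(rr) {
  rr <- check_rr(rr, 2L)
  d <- diff(rr)
  sqrt(sum(d^2) / (length(rr) - 1L))
}

#' Percentage of successive differences exceeding 50 ms (pNN50)
#'
#' 100 x count(|RR[i+1] - RR[i]| > 50 ms) / (N - 1); strictly greater than,
#' so a difference of exactly 50 ms is not counted.
#'
#' @inheritParams heart_rate
#' @return pNN50 in percent, in [0, 100].
#' @export
pnn50 <- function(rr) {
  rr <- check_rr(rr, 2L)
  d <- diff(rr)
  100 * sum(abs(d) > 50) / (length(rr) - 1L)
}

#' Four-feature HRV vector from segment peaks
#'
#' Returns the fixed-order feature vector (hr, sdnn, rmssd, pnn50) computed
#' from the segment's own peaks when it has at least three, otherwise from
#' the parent 60 s window's peak set (short ~5-beat segments make
#' within-segment SDNN noisy).
#'
#' @param peak_indices 0-based peak indices within the segment.
#' @param fs Sampling frequency in Hz.
#' @param fallback_peaks Optional peak set of the parent window, used when
#'   `peak_indices` has fewer than 3 peaks.
#' @return Named numeric vector `c(hr, sdnn, rmssd, pnn50)`, or `NULL` when
#'   neither scope has enough peaks (segment dropped upstream).
#' @export
hrv_vector <- function(peak_indices, fs, fallback_peaks = NULL) {
  pk <- peak_indices
  if (length(pk) < 3L) pk <- fallback_peaks
  if (is.null(pk) || length(pk) < 3L) return(NULL)
  rr <- peaks_to_rr(pk, fs)
  c(hr = heart_rate(rr), sdnn = sdnn(rr), rmssd = rmssd(rr),
    pnn50 = pnn50(rr))
}
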