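#' Band-pass filter specification
#'
#' Defaults (0.5--40 Hz, order 3, zero-phase) are the conventional
#' monitoring band: the high-pass corner removes baseline wander while
#' preserving P-wave amplitude, the low-pass corner removes mains and
#' muscle noise while keeping QRS energy.
#'
#' @param low_hz Low cutoff, Hz.
#' @param high_hz High cutoff, Hz; must satisfy `low_hz < high_hz < fs/2`.
#' @param order Butterworth order (>= 1).
#' @param zero_phase Apply forward-backward (zero-phase) so wave timing is
#'   not shifted.
#' @return An object of class `ecgaf_filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 40, order = 3,
                        zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("filter cutoffs must satisfy 0 < low_hz < high_hz", call. = FALSE)
  if (order < 1) stop("filter order must be >= 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "ecgaf_filter_spec")
}

#' Band-pass Butterworth filtering
#'
#' @param recording An [ecg_recording()].
#' @param spec A [filter_spec()]; `high_hz` must be below the Nyquist
#'   frequency of the recording.
#' @return The filtered [ecg_recording()], same length.
#' @export
bandpass_filter <- function(recording, spec = filter_spec()) {
  fs <- recording$fs
  if (spec$high_hz >= fs / 2)
    stop(sprintf("high cutoff (%g Hz) must be below Nyquist (%g Hz)",
                 spec$high_hz, fs / 2), call. = FALSE)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  x <- recording$samples
  y <- if (spec$zero_phase) signal::filtfilt(bf, x)
       else as.numeric(signal::filter(bf, x))
  out <- recording
  out$samples <- as.numeric(y)
  out
}

# Centered moving average (zero delay).
moving_average <- function(x, w) {
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

#' Detect R peaks with an adaptive-threshold energy detector
#'
#' Pan-Tompkins-style chain: a 5--15 Hz band-pass isolates QRS energy, a
#' central-difference derivative is squared and integrated over a 150 ms
#' moving window, and candidate peaks of the integrated signal are accepted
#' against a running signal/noise threshold with a 200 ms refractory
#' period. Accepted detections are refined to the local signed extremum of
#' the input signal; if the median detected extremum is negative the lead
#' polarity is inverted before refinement. The first and last 0.5 s are
#' excluded from the search.
#'
#' @param recording An [ecg_recording()] of at least 2 s (typically already
#'   band-pass filtered).
#' @return Strictly increasing integer vector of 1-based R sample indices;
#'   empty when no peaks are found.
#' @export
detect_r_peaks <- function(recording) {
  x <- recording$samples
  fs <- recording$fs
  n <- length(x)
  if (n < 2 * fs) stop("recording shorter than 2 s", call. = FALSE)

  # QRS-band energy signal
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  deriv <- c(0, diff(xb))
  mwi <- moving_average(deriv^2, max(3L, as.integer(round(0.15 * fs))))
  if (max(mwi) <= 0) return(integer(0))

  refractory <- as.integer(round(0.2 * fs))
  edge <- as.integer(round(0.5 * fs))

  # candidate local maxima of the integrated energy
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[cand > edge & cand <= n - edge]
  if (length(cand) == 0) return(integer(0))

  init <- mwi[seq_len(min(n, 2L * as.integer(fs)))]
  spki <- max(init); npki <- stats::median(init)
  thr <- npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  for (i in cand) {
    a <- mwi[i]
    if (length(accepted) > 0 && i - accepted[length(accepted)] < refractory) {
      if (a > mwi[accepted[length(accepted)]]) # keep the stronger of the two
        accepted[length(accepted)] <- i
      next
    }
    if (a > thr) {
      accepted <- c(accepted, i)
      spki <- 0.125 * a + 0.875 * spki
    } else {
      npki <- 0.125 * a + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(accepted) == 0) return(integer(0))

  # refine to the signed extremum of the working signal; determine polarity
  half <- as.integer(round(0.10 * fs))
  refine <- function(sig) {
    vapply(accepted, function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      lo + which.max(sig[lo:hi]) - 1L
    }, integer(1))
  }
  peaks_pos <- refine(x)
  peaks_neg <- refine(-x)
  pol <- stats::median(x[peaks_pos]) + stats::median(x[peaks_neg])
  peaks <- if (pol >= 0) peaks_pos else peaks_neg

  peaks <- sort(unique(peaks))
  peaks <- peaks[peaks > edge & peaks <= n - edge]
  if (length(peaks) > 1) {
    # enforce the refractory period after refinement, keeping larger peaks
    sig <- if (pol >= 0) x else -x
    keep <- rep(TRUE, length(peaks))
    last <- 1L
    for (j in seq_along(peaks)[-1]) {
      if (peaks[j] - peaks[last] < refractory) {
        if (sig[peaks[j]] > sig[peaks[last]]) { keep[last] <- FALSE; last <- j }
        else keep[j] <- FALSE
      } else last <- j
    }
    peaks <- peaks[keep]
  }
  as.integer(peaks)
}

#' Build RR and delta-RR interval series from R-peak indices
#'
#' @param r_indices Strictly increasing 1-based R-peak sample indices; at
#'   least 3 are required.
#' @param fs Sampling frequency, Hz.
#' @return An object of class `beat_series` with `r_indices`, `rr_s`
#'   (successive R-to-R intervals, seconds) and `drr_s` (successive RR
#'   differences, seconds).
#' @export
build_beat_series <- function(r_indices, fs) {
  if (length(r_indices) < 3)
    stop(structure(class = c("ecgaf_insufficient_beats", "error",
                             "condition"),
                   list(message = "fewer than 3 R peaks: cannot build RR/dRR series",
                        call = NULL)))
  if (any(diff(r_indices) <= 0))
    stop("r_indices must be strictly increasing", call. = FALSE)
  rr <- diff(r_indices) / fs
  structure(list(r_indices = as.integer(r_indices), rr_s = rr,
                 drr_s = diff(rr), fs = fs),
            class = "beat_series")
}
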