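#' Specification for a synthetic single-lead ECG recording
#'
#' Describes one synthetic recording: rhythm class, duration, sampling rate,
#' heart rate, wave amplitudes, RR-interval variability and noise level.
#' The generator ([generate_ecg()]) is fully deterministic given the spec,
#' including its `seed` field.
#'
#' @param rhythm One of `"NSR"` (normal sinus rhythm), `"AF"` (atrial
#'   fibrillation) or `"NOISE"` (noise-dominated, no coherent beats).
#' @param duration_s Recording duration in seconds (> 0).
#' @param fs Sampling frequency in Hz (> 0).
#' @param heart_rate_bpm Mean heart rate in beats per minute, in \[20, 300\].
#' @param r_amplitude_mV R-wave amplitude in millivolts.
#' @param p_amplitude_mV P-wave amplitude in millivolts. Must be 0 for AF
#'   (fibrillation abolishes organised atrial activity).
#' @param rr_cv Coefficient of variation of the RR intervals
#'   (dimensionless). Small for NSR; at least 0.15 for AF.
#' @param noise_sd_mV Standard deviation of additive broadband noise, mV.
#'   For `"NOISE"` this is the dominant white component.
#' @param seed Integer seed; identical specs produce bit-identical output.
#'
#' @return An object of class `ecgaf_synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec("NSR", heart_rate_bpm = 80, seed = 7)
#' out <- generate_ecg(spec)
#' length(out$truth$r_positions)
synthetic_spec <- function(rhythm = c("NSR", "AF", "NOISE"),
                           duration_s = 30,
                           fs = 250,
                           heart_rate_bpm = 80,
                           r_amplitude_mV = 1.0,
                           p_amplitude_mV = if (match.arg(rhythm) == "NSR") 0.15 else 0,
                           rr_cv = switch(match.arg(rhythm), NSR = 0.03, AF = 0.25, NOISE = 0),
                           noise_sd_mV = if (match.arg(rhythm) == "NOISE") 0.3 else 0.02,
                           seed = 1L) {
  rhythm <- match.arg(rhythm)
  spec <- structure(
    list(rhythm = rhythm, duration_s = duration_s, fs = fs,
         heart_rate_bpm = heart_rate_bpm, r_amplitude_mV = r_amplitude_mV,
         p_amplitude_mV = p_amplitude_mV, rr_cv = rr_cv,
         noise_sd_mV = noise_sd_mV, seed = as.integer(seed)),
    class = "ecgaf_synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid synthetic spec: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(spec$duration_s) || spec$duration_s <= 0)
    stop_field("duration_s", "must be > 0")
  if (!is.numeric(spec$fs) || spec$fs <= 0)
    stop_field("fs", "must be > 0")
  if (spec$heart_rate_bpm < 20 || spec$heart_rate_bpm > 300)
    stop_field("heart_rate_bpm", "must lie in [20, 300]")
  if (spec$r_amplitude_mV < 0)
    stop_field("r_amplitude_mV", "must be >= 0")
  if (spec$noise_sd_mV < 0)
    stop_field("noise_sd_mV", "must be >= 0")
  if (spec$rhythm == "AF") {
    if (spec$p_amplitude_mV != 0)
      stop_field("p_amplitude_mV", "must be 0 for AF (P waves are absent)")
    if (spec$rr_cv < 0.15)
      stop_field("rr_cv", "must be >= 0.15 for AF")
  }
  if (spec$rr_cv < 0) stop_field("rr_cv", "must be >= 0")
  invisible(spec)
}

# Gaussian bump; the building block of all template waves.
gauss_wave <- function(t, mu, sigma, amp) amp * exp(-0.5 * ((t - mu) / sigma)^2)

# Template wave parameters, relative to the R peak (seconds, mV fractions of
# the R amplitude except P which is absolute). Chosen to give physiological
# intervals: PR ~ 0.14 s, QRS ~ 0.09 s, QT ~ 0.36 s at rest.
beat_template <- function(t_rel, r_amp, p_amp) {
  v <- gauss_wave(t_rel, 0, 0.013, r_amp) +             # R
    gauss_wave(t_rel, -0.025, 0.008, -0.10 * r_amp) +   # Q
    gauss_wave(t_rel, 0.028, 0.009, -0.15 * r_amp) +    # S
    gauss_wave(t_rel, 0.30, 0.050, 0.30 * r_amp)        # T
  if (p_amp != 0) v <- v + gauss_wave(t_rel, -0.17, 0.022, p_amp)  # P
  v
}

# Truncated-normal RR draws (floor 0.3 s, cap 2.0 s) by rejection.
draw_rr <- function(n, mean_rr, cv) {
  if (cv == 0) return(rep(mean_rr, n))
  sd <- cv * mean_rr
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean_rr, sd)
    out <- c(out, x[x >= 0.3 & x <= 2.0])
  }
  out[seq_len(n)]
}

#' Generate a synthetic single-lead ECG recording with ground truth
#'
#' Builds the recording described by a [synthetic_spec()]. NSR beats are a
#' sum of Gaussian template waves (P, Q, R, S, T) placed at RR intervals
#' drawn from a truncated normal distribution (floor 0.3 s) with mean
#' `60 / heart_rate_bpm` and coefficient of variation `rr_cv`. AF beats omit
#' the P wave, draw RR i.i.d. with `rr_cv >= 0.15`, and add a low-amplitude
#' fibrillatory baseline oscillation whose frequency drifts randomly within
#' 4--9 Hz. NOISE recordings contain broadband white noise, 50 Hz mains
#' interference and baseline wander, with no coherent beats.
#'
#' @param spec An [synthetic_spec()] object.
#' @return A list with components:
#'   \describe{
#'     \item{recording}{[ecg_recording()] of `floor(duration_s * fs)`
#'       samples in mV, labelled `Normal`, `AF` or `Noisy`.}
#'     \item{truth}{Ground truth: `r_positions` (1-based sample indices of
#'       the true R peaks), `rr_s` (true RR intervals, seconds),
#'       `p_amplitudes_mV` (per-beat P amplitude) and `label`.}
#'   }
#' @export
generate_ecg <- function(spec) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, generate_ecg_impl(spec))
}

generate_ecg_impl <- function(spec) {
  n <- floor(spec$duration_s * spec$fs)
  fs <- spec$fs
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)

  label <- switch(spec$rhythm, NSR = "Normal", AF = "AF", NOISE = "Noisy")

  if (spec$rhythm == "NOISE") {
    mains_amp <- 0.6 * spec$noise_sd_mV
    wander_amp <- 1.5 * spec$noise_sd_mV
    x <- stats::rnorm(n, 0, spec$noise_sd_mV) +
      mains_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi)) +
      wander_amp * sin(2 * pi * stats::runif(1, 0.15, 0.4) * t +
                         stats::runif(1, 0, 2 * pi))
    truth <- list(r_positions = integer(0), rr_s = numeric(0),
                  p_amplitudes_mV = numeric(0), label = label)
    rec <- ecg_recording(x, fs, record_id = sprintf("syn_noise_%d", spec$seed),
                         label = label)
    return(list(recording = rec, truth = truth))
  }

  mean_rr <- 60 / spec$heart_rate_bpm
  # First beat placed past the detector edge guard; then cumulative RR draws.
  t0 <- 0.55 + 0.1 * stats::runif(1)
  max_beats <- ceiling(spec$duration_s / 0.3) + 2
  rr <- draw_rr(max_beats, mean_rr, spec$rr_cv)
  beat_times <- t0 + c(0, cumsum(rr))
  beat_times <- beat_times[beat_times < spec$duration_s - 0.05]

  for (bt in beat_times) {
    lo <- max(1L, floor((bt - 0.6) * fs) + 1L)
    hi <- min(n, ceiling((bt + 0.6) * fs) + 1L)
    idx <- lo:hi
    x[idx] <- x[idx] + beat_template(t[idx] - bt, spec$r_amplitude_mV,
                                     spec$p_amplitude_mV)
  }

  if (spec$rhythm == "AF") {
    # f-wave-like baseline: 0.05 mV sinusoid, frequency random walk in 4-9 Hz
    f <- numeric(n)
    f[1] <- stats::runif(1, 4, 9)
    steps <- stats::rnorm(n - 1, 0, 0.02)
    f <- f[1] + c(0, cumsum(steps))
    f <- 4 + abs((f - 4) %% 10 - 5) # reflect into [4, 9]
    phase <- 2 * pi * cumsum(f) / fs
    x <- x + 0.05 * sin(phase)
  }

  if (spec$noise_sd_mV > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd_mV)

  r_positions <- round(beat_times * fs) + 1L
  keep <- r_positions >= 1L & r_positions <= n
  r_positions <- as.integer(r_positions[keep])
  truth <- list(
    r_positions = r_positions,
    rr_s = diff(beat_times[keep]),
    p_amplitudes_mV = rep(spec$p_amplitude_mV, sum(keep)),
    label = label)

  rec <- ecg_recording(x, fs,
                       record_id = sprintf("syn_%s_%d", tolower(spec$rhythm),
                                           spec$seed),
                       label = label)
  list(recording = rec, truth = truth)
}

#' Bench-verification preset
#'
#' The fixed spec used for end-to-end verification of the signal chain:
#' normal sinus rhythm, 80 BPM, 1.0 mV R amplitude, 30 s at 250 Hz, with a
#' fixed seed. Mirrors a standard patient-simulator check.
#'
#' @return An `ecgaf_synthetic_spec` for NSR at 80 BPM and 1.0 mV.
#' @export
#' @examples
#' verification_preset()$heart_rate_bpm
verification_preset <- function() {
  synthetic_spec("NSR", duration_s = 30, fs = 250, heart_rate_bpm = 80,
                 r_amplitude_mV = 1.0, p_amplitude_mV = 0.15,
                 rr_cv = 0.02, noise_sd_mV = 0.01, seed = 20170317L)
}

#' Generate a labelled corpus of synthetic recordings
#'
#' Draws per-recording physiological parameters from realistic ranges
#' (NSR: 55--100 BPM, RR CV 0.01--0.07; AF: 70--140 BPM, RR CV 0.18--0.35;
#' R amplitude 0.6--1.5 mV) and generates one recording per item. Seeded and
#' reproducible; used as the package's desk-scale benchmark corpus.
#'
#' @param counts Named integer vector with any of `Normal`, `AF`, `Noisy`.
#' @param seed Integer corpus seed.
#' @param duration_s Duration of each recording, seconds.
#' @param fs Sampling frequency, Hz.
#' @return A list with `recordings` (list of [ecg_recording()]) and
#'   `labels` (factor with levels [rhythm_classes()]).
#' @export
simulate_corpus <- function(counts = c(Normal = 10, AF = 10, Noisy = 5),
                            seed = 1L, duration_s = 30, fs = 250) {
  stopifnot(all(names(counts) %in% rhythm_classes()))
  n <- sum(counts)
  withr::with_seed(as.integer(seed), {
    item_seeds <- sample.int(.Machine$integer.max - 1L, n)
    pars <- lapply(seq_len(n), function(i) list(
      hr_nsr = stats::runif(1, 55, 100),
      hr_af = stats::runif(1, 70, 140),
      cv_nsr = stats::runif(1, 0.01, 0.07),
      cv_af = stats::runif(1, 0.18, 0.35),
      r_amp = stats::runif(1, 0.6, 1.5),
      p_amp = stats::runif(1, 0.08, 0.25),
      beat_noise = stats::runif(1, 0.01, 0.05),
      noise_sd = stats::runif(1, 0.2, 0.5)))
  })
  labels <- rep(names(counts), counts)
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pars[[i]]
    spec <- switch(labels[i],
      Normal = synthetic_spec("NSR", duration_s = duration_s, fs = fs,
                              heart_rate_bpm = p$hr_nsr,
                              r_amplitude_mV = p$r_amp,
                              p_amplitude_mV = p$p_amp, rr_cv = p$cv_nsr,
                              noise_sd_mV = p$beat_noise,
                              seed = item_seeds[i]),
      AF = synthetic_spec("AF", duration_s = duration_s, fs = fs,
                          heart_rate_bpm = p$hr_af,
                          r_amplitude_mV = p$r_amp, p_amplitude_mV = 0,
                          rr_cv = p$cv_af, noise_sd_mV = p$beat_noise,
                          seed = item_seeds[i]),
      Noisy = synthetic_spec("NOISE", duration_s = duration_s, fs = fs,
                             noise_sd_mV = p$noise_sd,
                             seed = item_seeds[i]))
    recordings[[i]] <- generate_ecg(spec)$recording
  }
  list(recordings = recordings,
       labels = factor(labels, levels = rhythm_classes()))
}
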