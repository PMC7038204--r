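# Fixture builders used across test files. Everything is generated in code
# at test time; nothing binary is stored in the repository.

# Independent MATLAB v4 writer (int16 row vector) used to fabricate
# Challenge-style record files for the reader tests.
write_mat_v4_int16 <- function(values, path, varname = "val") {
  con <- file(path, "wb")
  on.exit(close(con))
  # header: type (M O P T = 0 0 3 0 -> 30), mrows, ncols, imagf, namelen
  writeBin(as.integer(c(30, 1, length(values), 0, nchar(varname) + 1)),
           con, size = 4, endian = "little")
  writeBin(c(charToRaw(varname), as.raw(0)), con)
  writeBin(as.integer(round(values)), con, size = 2, endian = "little")
  invisible(path)
}

# A small Challenge-style directory: .mat records plus REFERENCE.csv.
make_challenge_dir <- function(dir, n_per_class = 2, seed = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  codes <- c(Normal = "N", AF = "A", Other = "O", Noisy = "~")
  rows <- character(0)
  k <- 0
  withr::with_seed(seed, {
    for (cls in names(codes)) for (j in seq_len(n_per_class)) {
      k <- k + 1
      id <- sprintf("A%05d", k)
      rhythm <- switch(cls, Normal = "NSR", AF = "AF", Other = "NSR",
                       Noisy = "NOISE")
      dur <- sample(10:60, 1)
      spec <- synthetic_spec(rhythm, duration_s = dur, fs = 300,
                             heart_rate_bpm = sample(60:110, 1),
                             seed = sample.int(1e6, 1))
      rec <- generate_ecg(spec)$recording
      write_mat_v4_int16(rec$samples * 1000,
                         file.path(dir, paste0(id, ".mat")))
      rows <- c(rows, paste0(id, ",", codes[cls]))
    }
  })
  writeLines(rows, file.path(dir, "REFERENCE.csv"))
  dir
}

# A regular 'recording' with identical synthetic beats at fixed spacing,
# for feature-level tests that need exact control of R positions.
make_pulse_recording <- function(n_beats = 20, rr_s = 0.752, fs = 250,
                                 beat_fun = NULL, noise_sd = 0) {
  if (is.null(beat_fun))
    beat_fun <- function(t) exp(-0.5 * (t / 0.013)^2)
  dur <- (n_beats + 1) * rr_s + 1
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  r_times <- 0.6 + (seq_len(n_beats) - 1) * rr_s
  for (bt in r_times) {
    idx <- which(abs(t - bt) <= 0.4)
    x[idx] <- x[idx] + beat_fun(t[idx] - bt)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  list(recording = ecg_recording(x, fs, record_id = "pulse"),
       r_indices = round(r_times * fs) + 1L)
}

# Ground-truth beat series for AF/NSR comparisons without the detector.
truth_beat_series <- function(rhythm, seed, duration_s = 60,
                              heart_rate_bpm = 80,
                              rr_cv = if (rhythm == "AF") 0.25 else 0.03) {
  out <- generate_ecg(synthetic_spec(
    rhythm, duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
    rr_cv = rr_cv, p_amplitude_mV = if (rhythm == "AF") 0 else 0.15,
    seed = seed))
  build_beat_series(out$truth$r_positions, out$recording$fs)
}
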