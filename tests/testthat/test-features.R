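test_that("Lorenz histogram conserves points and regions partition the grid", {
  withr::with_seed(21, drr <- rnorm(200, 0, 0.25))
  lh <- lorenz_histogram(drr)
  expect_equal(sum(lh$counts), length(drr) - 1)
  expect_equal(lh$n_points, length(drr) - 1)
  expect_true(all(lh$region %in% 0:12))
  expect_true(all(0:12 %in% lh$region))
  # tiny input
  expect_equal(sum(lorenz_histogram(c(0.1))$counts), 0)
})

test_that("AF evidence is negative for regular rhythm, positive for AF", {
  # perfectly regular: all points in the origin region
  bs <- build_beat_series(seq(1L, by = 188L, length.out = 40), 250)
  expect_lte(af_evidence(bs), 0)

  # seeded AF scores strictly above seeded NSR at matched beat count
  for (s in 1:20) {
    af <- truth_beat_series("AF", seed = s, duration_s = 90,
                            heart_rate_bpm = 80)
    nsr <- truth_beat_series("NSR", seed = s, duration_s = 90,
                             heart_rate_bpm = 80)
    expect_gt(af_evidence(af), af_evidence(nsr))
  }
})

test_that("ectopy discounting lowers the AF evidence of bigeminy patterns", {
  # regular rhythm with every third beat premature + compensatory pause
  rr <- rep(c(0.8, 0.55, 1.05), 20)
  r <- cumsum(c(1, round(rr * 250)))
  bs <- build_beat_series(as.integer(r), 250)
  af <- truth_beat_series("AF", seed = 1, duration_s = 60)
  expect_lt(af_evidence(bs), af_evidence(af))
})

test_that("dRR Shannon entropy matches its definition", {
  # constant dRR: a single occupied bin
  bs <- build_beat_series(seq(1L, by = 188L, length.out = 10), 250)
  expect_equal(shannon_entropy_drr(bs), 0)

  # uniform over all 16 bins: ln 16
  centers <- seq(-0.5 + 1 / 32, 0.5 - 1 / 32, length.out = 16)
  fake <- list(drr_s = rep(centers, 4), rr_s = numeric(0))
  expect_equal(shannon_entropy_drr(fake), log(16), tolerance = 1e-12)

  # brute-force oracle on seeded Gaussian dRR
  withr::with_seed(31, d <- rnorm(1000, 0, 0.12))
  fake2 <- list(drr_s = d, rr_s = numeric(0))
  expect_equal(shannon_entropy_drr(fake2), oracle_entropy_16bin(d),
               tolerance = 1e-12)
})

test_that("KS statistic matches a direct ECDF scan and hits its bounds", {
  ref <- structure(sort(rnorm(50)), class = "ks_reference")
  # identical samples: 0
  bs_same <- list(drr_s = as.numeric(ref), rr_s = c(1, 1, 1))
  expect_equal(ks_statistic(bs_same, ref), 0)
  # disjoint supports: 1
  bs_far <- list(drr_s = as.numeric(ref) + 100, rr_s = c(1, 1, 1))
  expect_equal(ks_statistic(bs_far, ref), 1)

  withr::with_seed(41, {
    x <- rnorm(73, 0.1, 1.2)
    y <- rnorm(41)
  })
  bs <- list(drr_s = x, rr_s = c(1, 1, 1))  # median RR 1: no rescaling
  expect_equal(ks_statistic(bs, structure(sort(y), class = "ks_reference")),
               oracle_ks_two_sample(x, y), tolerance = 1e-12)

  expect_error(ks_statistic(bs, numeric(0)), "empty")
})

test_that("dRR normalisation uses the median RR", {
  bs <- list(drr_s = c(0.2, -0.4), rr_s = c(2, 2, 2))
  ref <- structure(c(-0.2, 0.1), class = "ks_reference")
  # normalised sample is (0.1, -0.2) = reference -> statistic 0
  expect_equal(ks_statistic(bs, ref), 0)
})

test_that("KS reference pooling preserves counts and discriminates", {
  s1 <- list(drr_s = c(0.1, -0.2), rr_s = c(1, 1, 1))
  ref <- build_ks_reference(list(s1))
  expect_equal(as.numeric(ref), c(-0.2, 0.1))
  s2 <- list(drr_s = rnorm(10), rr_s = c(0.5, 0.5))
  ref2 <- build_ks_reference(list(s1, s2))
  expect_length(ref2, 12)
  expect_false(is.unsorted(as.numeric(ref2)))
  expect_error(build_ks_reference(list()), "empty")

  # held-out AF series sit closer to the AF reference than NSR series do
  ref_af <- build_ks_reference(lapply(1:10, function(s)
    truth_beat_series("AF", seed = 100 + s)))
  wins <- vapply(1:20, function(s) {
    ks_af <- ks_statistic(truth_beat_series("AF", seed = 200 + s), ref_af)
    ks_nsr <- ks_statistic(truth_beat_series("NSR", seed = 200 + s), ref_af)
    ks_af < ks_nsr
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("average beat recovers template amplitudes and fiducial order", {
  out <- generate_ecg(verification_preset())
  filt <- bandpass_filter(out$recording)
  peaks <- detect_r_peaks(filt)
  avg <- average_beat(filt, peaks)
  expect_lt(abs(avg$measures[["r_amplitude_mV"]] - 1.0), 0.1)
  expect_lt(abs(avg$measures[["p_amplitude_mV"]] - 0.15), 0.05)
  expect_error(average_beat(filt, peaks[1:2]), "fewer than 3")

  for (s in 4:8) {
    o <- generate_ecg(synthetic_spec("NSR", seed = s))
    fl <- bandpass_filter(o$recording)
    a <- average_beat(fl, detect_r_peaks(fl))
    expect_true(a$p < a$onset && a$onset <= a$q && a$q < a$r &&
                  a$r < a$s && a$s <= a$offset && a$offset < a$t)
  }
})

test_that("morphology variants agree on clean NSR and AF lacks P waves", {
  out <- generate_ecg(synthetic_spec("NSR", noise_sd_mV = 0.005,
                                     seed = 15))
  filt <- bandpass_filter(out$recording)
  peaks <- detect_r_peaks(filt)
  m <- morphology_features(filt, peaks)
  expect_length(m, 20)
  expect_lt(abs(m[["r_amplitude_mV_E"]] - m[["r_amplitude_mV_O"]]), 0.05)
  expect_gt(m[["qrs_duration_s_E"]], 0)
  expect_lt(m[["qrs_duration_s_E"]], 0.2)

  af <- generate_ecg(synthetic_spec("AF", noise_sd_mV = 0.005, seed = 15))
  fa <- bandpass_filter(af$recording)
  ma <- morphology_features(fa, detect_r_peaks(fa))
  expect_lt(ma[["p_amplitude_mV_E"]], 0.05)
  # the per-beat maximum cannot fall below the fibrillatory-wave crest
  # (0.05 mV), so the per-beat-median variant is bounded at twice that
  expect_lt(ma[["p_amplitude_mV_O"]], 0.1)
})

test_that("median RR matches a sort-and-pick oracle", {
  expect_equal(median_rr(list(rr_s = c(0.7, 0.8, 0.9))), 0.8)
  expect_equal(median_rr(list(rr_s = rep(0.75, 7))), 0.75)
  withr::with_seed(51, {
    for (i in 1:5) {
      rr <- runif(sample(3:30, 1), 0.4, 1.4)
      srt <- sort(rr); n <- length(rr)
      manual <- if (n %% 2 == 1) srt[(n + 1) / 2]
                else (srt[n / 2] + srt[n / 2 + 1]) / 2
      expect_equal(median_rr(list(rr_s = rr)), manual)
    }
  })
})

test_that("index of arrhythmia fires on ectopy and is monotone", {
  regular <- list(rr_s = rep(0.8, 20))
  expect_equal(index_of_arrhythmia(regular), 0L)

  ectopic <- list(rr_s = c(0.8, 0.8, 0.5, 1.1, 0.8, 0.8))
  expect_gte(index_of_arrhythmia(ectopic), 1L)

  withr::with_seed(61, {
    for (i in 1:10) {
      rr <- rep(0.8, 20)
      base <- index_of_arrhythmia(list(rr_s = rr))
      pos <- sample(3:17, 1)
      rr2 <- append(rr, 0.45, after = pos)  # premature beat inserted
      rr2[pos + 2] <- 1.15                  # compensatory pause
      expect_gte(index_of_arrhythmia(list(rr_s = rr2)), base)
    }
  })
})

test_that("QRS similarity matches the all-pairs correlation oracle", {
  pr <- make_pulse_recording(n_beats = 12)
  expect_equal(qrs_similarity(pr$recording, pr$r_indices), 1.0,
               tolerance = 1e-9)

  # independent white-noise windows: mean correlation near 0
  withr::with_seed(71, {
    noise <- ecg_recording(rnorm(30 * 250), 250)
  })
  r_idx <- seq(500L, by = 250L, length.out = 20)
  expect_lt(abs(qrs_similarity(noise, r_idx)), 0.15)

  # brute-force equivalence on a noisy pulse train
  withr::with_seed(72, pr2 <- make_pulse_recording(n_beats = 9,
                                                   noise_sd = 0.2))
  fs <- 250
  wins <- vapply(pr2$r_indices, function(r)
    pr2$recording$samples[(r - round(0.06 * fs)):(r + round(0.08 * fs))],
    numeric(round(0.06 * fs) + round(0.08 * fs) + 1))
  expect_equal(qrs_similarity(pr2$recording, pr2$r_indices),
               oracle_mean_pairwise_cor(wins), tolerance = 1e-12)
})

test_that("signal quality index counts corrupted isoelectric windows", {
  pr <- make_pulse_recording(n_beats = 20)
  expect_equal(signal_quality_index(pr$recording, pr$r_indices), 1.0)

  # corrupt the isoelectric window of exactly half the beats
  x <- pr$recording$samples
  fs <- 250
  withr::with_seed(81, {
    for (r in pr$r_indices[seq(1, 20, by = 2)]) {
      idx <- (r - round(0.09 * fs)):(r - round(0.07 * fs))
      x[idx] <- x[idx] + rnorm(length(idx), 0, 1)
    }
  })
  corrupted <- ecg_recording(x, fs)
  sqi <- signal_quality_index(corrupted, pr$r_indices)
  expect_lte(abs(sqi - 0.5), 1 / 20)
  expect_gte(sqi, 0); expect_lte(sqi, 1)
})

test_that("QR smoothness index counts upstroke roughness", {
  # smooth concave upstroke on a fabricated average beat
  fs <- 250
  smooth <- list(waveform = gauss_env <- exp(-0.5 * ((seq(-75, 125) / fs) /
                                                       0.013)^2),
                 onset = 60L, r = 76L)
  class(smooth) <- "average_beat"
  expect_equal(qr_smoothness_index(smooth), 1L)

  rough <- smooth
  rough$waveform <- rough$waveform +
    0.05 * rep_len(c(1, -1), length(rough$waveform))
  expect_gt(qr_smoothness_index(rough), 1L)

  degenerate <- list(waveform = c(0, 1), onset = 1L, r = 2L)
  class(degenerate) <- "average_beat"
  expect_equal(qr_smoothness_index(degenerate), 0L)
})

test_that("extract_features always returns 31 finite named values", {
  ref <- default_ks_reference()
  specs <- list(synthetic_spec("NSR", seed = 1),
                synthetic_spec("AF", seed = 1),
                synthetic_spec("NOISE", seed = 1))
  for (spec in specs) {
    f <- extract_features(generate_ecg(spec)$recording, ref)
    expect_length(f, 31)
    expect_identical(names(f), feature_names())
    expect_true(all(is.finite(f)))
  }
  # pathological flat input also imputes to 31 finite values
  flat <- ecg_recording(rep(0, 7500) + 0, 250)
  f0 <- extract_features(flat, ref)
  expect_true(all(is.finite(f0)))
  expect_equal(f0[["ks_statistic"]], 1)
  expect_equal(f0[["af_evidence"]], 0)
})

test_that("interval features are scale-invariant; amplitudes scale linearly", {
  ref <- default_ks_reference()
  rec <- generate_ecg(synthetic_spec("NSR", noise_sd_mV = 0.01,
                                     seed = 9))$recording
  f1 <- extract_features(rec, ref)
  rec2 <- rec; rec2$samples <- 2 * rec$samples
  f2 <- extract_features(rec2, ref)
  intervals <- c("qrs_duration_s_E", "pr_interval_s_E", "qt_interval_s_E",
                 "qs_interval_s_E", "median_rr_s", "mean_rr_s")
  expect_equal(f1[intervals], f2[intervals], tolerance = 1e-6)
  amps <- c("r_amplitude_mV_E", "p_amplitude_mV_E", "t_amplitude_mV_E")
  expect_equal(2 * f1[amps], f2[amps], tolerance = 0.02)
})

test_that("a stump on AF evidence separates synthetic AF from NSR", {
  corpus <- simulate_corpus(c(Normal = 100, AF = 100), seed = 31)
  afe <- vapply(corpus$recordings, function(r)
    extract_features(r)[["af_evidence"]], numeric(1))
  truth <- corpus$labels == "AF"
  # best single threshold found on the data
  accs <- vapply(sort(unique(afe)), function(thr)
    mean((afe >= thr) == truth), numeric(1))
  expect_gte(max(accs), 0.90)
})

test_that("feature names are unique and stable across runs", {
  expect_identical(anyDuplicated(feature_names()), 0L)
  expect_identical(feature_names(), feature_names())
  man <- feature_manifest()
  expect_identical(nrow(man), 31L)
  expect_identical(sum(man$gap_fill), 3L)
})
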