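#' Canonical feature manifest
#'
#' The fixed, ordered names of the 31 features: 3 AF rhythm features, 20
#' morphology features (10 kinds, each measured by the average-beat variant
#' `E` and the per-beat-median variant `O`), 5 RR-interval features and 3
#' noise features. `feature_manifest()` additionally reports the group of
#' each feature and flags the three conventional RR statistics that fill
#' the feature set out to its stated dimensionality.
#'
#' @return `feature_names()`: character vector of length 31.
#'   `feature_manifest()`: data frame with `name`, `group`, `gap_fill`.
#' @export
feature_names <- function() feature_manifest()$name

#' @rdname feature_names
#' @export
feature_manifest <- function() {
  kinds <- c("qrs_duration_s", "pr_interval_s", "qt_interval_s",
             "qs_interval_s", "st_amplitude_mV", "p_amplitude_mV",
             "q_amplitude_mV", "r_amplitude_mV", "s_amplitude_mV",
             "t_amplitude_mV")
  df <- data.frame(
    name = c("af_evidence", "shannon_entropy_drr", "ks_statistic",
             paste0(kinds, "_E"), paste0(kinds, "_O"),
             "median_rr_s", "index_of_arrhythmia", "mean_rr_s", "rmssd_s",
             "pnn50",
             "qrs_similarity", "signal_quality_index",
             "qr_smoothness_index"),
    group = c(rep("af", 3), rep("morphology", 20), rep("rr", 5),
              rep("noise", 3)),
    stringsAsFactors = FALSE)
  df$gap_fill <- df$name %in% c("mean_rr_s", "rmssd_s", "pnn50")
  df
}

## ---- AF features ----------------------------------------------------------

#' Two-dimensional Lorenz histogram of successive dRR pairs
#'
#' Bins the points `(drr[i], drr[i-1])` on a square grid (default 40 ms
#' bins spanning +/- 600 ms; points beyond the extent are clipped to the
#' edge bins) and assigns every bin to one of 13 regions: the origin box
#' (region 0, both coordinates within +/- 80 ms), the four axis strips, the
#' two main-diagonal quadrants, and the two anti-diagonal quadrants each
#' split into an anti-diagonal band plus its two off-band wings. Region
#' geometry is what the AF-evidence score is computed from.
#'
#' @param drr_s Numeric vector of successive RR differences, seconds.
#' @param bin_width_s Bin width, seconds.
#' @param extent_s Half-extent of the grid, seconds.
#' @return A list with the `counts` matrix, the matching `region` matrix,
#'   bin `centers`, and `n_points` (`length(drr_s) - 1`).
#' @export
lorenz_histogram <- function(drr_s, bin_width_s = 0.040, extent_s = 0.600) {
  nb <- as.integer(round(2 * extent_s / bin_width_s))
  centers <- -extent_s + (seq_len(nb) - 0.5) * bin_width_s
  m <- length(drr_s)
  if (m >= 2) {
    xi <- clip_bin(drr_s[2:m], extent_s, bin_width_s, nb)
    yi <- clip_bin(drr_s[1:(m - 1)], extent_s, bin_width_s, nb)
    counts <- matrix(0L, nb, nb)
    for (k in seq_along(xi))
      counts[yi[k], xi[k]] <- counts[yi[k], xi[k]] + 1L
  } else {
    counts <- matrix(0L, nb, nb)
  }
  region <- outer(centers, centers,
                  function(cy, cx) lorenz_region(cx, cy))
  list(counts = counts, region = region, centers = centers,
       n_points = max(0L, m - 1L))
}

clip_bin <- function(v, extent, width, nb) {
  i <- floor((v + extent) / width) + 1L
  pmin(pmax(i, 1L), nb)
}

# Region of a bin center (vectorised over cx, cy); boundary at 80 ms.
lorenz_region <- function(cx, cy) {
  b <- 0.08
  r <- integer(length(cx))
  inx <- abs(cx) < b; iny <- abs(cy) < b
  r[inx & iny] <- 0L
  r[inx & cy >= b] <- 5L   # top strip
  r[inx & cy <= -b] <- 7L  # bottom strip
  r[iny & cx <= -b] <- 6L  # left strip
  r[iny & cx >= b] <- 8L   # right strip
  r[cx >= b & cy >= b] <- 1L   # quadrant 1
  r[cx <= -b & cy <= -b] <- 3L # quadrant 3
  q2 <- cx <= -b & cy >= b     # anti-diagonal quadrants split in three
  q4 <- cx >= b & cy <= -b
  s <- cx + cy
  r[q2 & abs(s) < b] <- 2L; r[q2 & s >= b] <- 9L; r[q2 & s <= -b] <- 10L
  r[q4 & abs(s) < b] <- 4L; r[q4 & s >= b] <- 11L; r[q4 & s <= -b] <- 12L
  r
}

#' AF evidence score from the Lorenz histogram of dRR intervals
#'
#' Integer irregularity score: `IrregularityEvidence - OriginCount -
#' 2 * PACEvidence`, where IrregularityEvidence counts the occupied
#' histogram bins outside the origin region, OriginCount counts the points
#' inside it, and PACEvidence measures the excess of points in the
#' ectopy-pattern regions (anti-diagonal bands and vertical strips, where
#' premature-beat/compensatory-pause alternation concentrates) over the
#' remaining outer regions, floored at zero. Sustained AF scatters points
#' across many bins (large positive score); regular rhythm concentrates
#' points at the origin (negative score); ectopy patterns are discounted.
#'
#' @param beat_series A [build_beat_series()] result.
#' @return Integer score.
#' @export
af_evidence <- function(beat_series) {
  lh <- lorenz_histogram(beat_series$drr_s)
  if (lh$n_points == 0) return(0L)
  origin_count <- sum(lh$counts[lh$region == 0L])
  irregularity <- sum(lh$counts > 0L & lh$region != 0L)
  pac_regions <- c(2L, 4L, 5L, 7L)
  other_regions <- c(1L, 3L, 6L, 8L, 9L, 10L, 11L, 12L)
  pac <- max(0L, sum(lh$counts[lh$region %in% pac_regions]) -
               sum(lh$counts[lh$region %in% other_regions]))
  as.integer(irregularity - origin_count - 2L * pac)
}

#' Shannon entropy of the dRR histogram
#'
#' Entropy `-sum p_b log(p_b)` (natural log) over a fixed 16-bin histogram
#' of the dRR intervals clipped to \[-0.5, 0.5\] s. Empty bins contribute 0.
#'
#' @param beat_series A [build_beat_series()] result with >= 2 dRR values.
#' @return Non-negative scalar; 0 when all dRR fall in one bin.
#' @export
shannon_entropy_drr <- function(beat_series) {
  d <- pmin(pmax(beat_series$drr_s, -0.5), 0.5)
  if (length(d) == 0) return(0)
  breaks <- seq(-0.5, 0.5, length.out = 17)
  idx <- findInterval(d, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  p <- tabulate(idx, nbins = 16) / length(d)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Kolmogorov-Smirnov distance to the AF reference distribution
#'
#' Two-sample KS statistic `sup |F_rec - F_ref|` between the recording's
#' normalised dRR sample (dRR divided by the median RR interval) and a
#' reference sample of normalised dRR values pooled from AF recordings.
#'
#' @param beat_series A [build_beat_series()] result with >= 2 dRR values.
#' @param reference A [build_ks_reference()] result (or sorted numeric
#'   vector of normalised dRR values).
#' @return Scalar in \[0, 1\]; small for AF-like irregularity.
#' @export
ks_statistic <- function(beat_series, reference) {
  if (length(reference) == 0) stop("empty KS reference", call. = FALSE)
  med <- stats::median(beat_series$rr_s)
  x <- beat_series$drr_s / med
  unname(suppressWarnings(
    stats::ks.test(x, as.numeric(reference))$statistic))
}

#' Build the AF reference distribution for the KS feature
#'
#' Pools the normalised dRR values (dRR divided by median RR) of AF-labelled
#' beat series, sorted ascending. Serialised alongside the trained model so
#' that prediction reproduces training-time features exactly.
#'
#' @param af_beat_series List of [build_beat_series()] results from
#'   AF-labelled recordings; must be non-empty.
#' @param provenance Free-text note on where the series came from.
#' @return Sorted numeric vector of class `ks_reference`.
#' @export
build_ks_reference <- function(af_beat_series,
                               provenance = "pooled AF training dRR") {
  if (length(af_beat_series) == 0)
    stop("empty AF series collection", call. = FALSE)
  pooled <- unlist(lapply(af_beat_series, function(bs)
    bs$drr_s / stats::median(bs$rr_s)), use.names = FALSE)
  structure(sort(pooled), class = "ks_reference", provenance = provenance)
}

#' Default AF reference distribution
#'
#' Built once per session from 20 seeded synthetic 60 s AF recordings
#' (ground-truth R positions, so the reference is detector-independent).
#'
#' @return A `ks_reference` object.
#' @export
default_ks_reference <- function() {
  if (!is.null(.ecgaf_env$default_ks)) return(.ecgaf_env$default_ks)
  series <- lapply(seq_len(20), function(i) {
    out <- generate_ecg(synthetic_spec("AF", duration_s = 60,
                                       heart_rate_bpm = 70 + 3 * i,
                                       rr_cv = 0.25, seed = 411000L + i))
    build_beat_series(out$truth$r_positions, out$recording$fs)
  })
  ref <- build_ks_reference(series, provenance = "synthetic AF corpus")
  .ecgaf_env$default_ks <- ref
  ref
}

.ecgaf_env <- new.env(parent = emptyenv())

## ---- Morphology -----------------------------------------------------------

# Delineate one R-aligned beat waveform (window [-0.3, +0.5] s, R at index
# r_at). Fiducials: Q = minimum in [-60, 0] ms; S = minimum in [0, 80] ms;
# QRS onset/offset = where |slope| falls below 10% of the max |slope| in
# the QRS region, scanning outward from Q and S; P peak = maximum in
# [-250, -80] ms; T peak = extremum of larger magnitude in [+120, +400] ms.
# Amplitudes are relative to the isoelectric level (mean of [-90, -70] ms).
delineate_beat <- function(w, fs, r_at) {
  ms <- function(x) as.integer(round(x * fs / 1000))
  n <- length(w)
  win <- function(a_ms, b_ms) {
    lo <- max(1L, r_at + ms(a_ms)); hi <- min(n, r_at + ms(b_ms))
    if (lo > hi) return(NULL)
    lo:hi
  }
  iso_idx <- win(-90, -70)
  iso <- mean(w[iso_idx])

  r_idx <- {
    idx <- win(-40, 40)
    idx[which.max(abs(w[idx] - iso))]
  }
  q_region <- win(-60, 0); s_region <- win(0, 80)
  q_idx <- q_region[which.min(w[q_region])]
  s_idx <- s_region[which.min(w[s_region])]

  slope <- c(diff(w), 0)
  qrs_region <- win(-60, 80)
  max_slope <- max(abs(slope[qrs_region]))
  thr <- 0.10 * max_slope
  onset <- q_idx
  floor_idx <- max(1L, r_at + ms(-120))
  while (onset > floor_idx && abs(slope[onset - 1L]) > thr)
    onset <- onset - 1L
  offset <- s_idx
  cap_idx <- min(n - 1L, r_at + ms(140))
  while (offset < cap_idx && abs(slope[offset]) > thr)
    offset <- offset + 1L

  p_region <- win(-250, -80)
  p_idx <- p_region[which.max(w[p_region])]
  t_region <- win(120, 400)
  t_idx <- t_region[which.max(abs(w[t_region] - iso))]

  st_idx <- min(n, offset + ms(60))
  t_end <- min(n, t_idx + ms(80))

  list(iso = iso, r = r_idx, q = q_idx, s = s_idx, onset = onset,
       offset = offset, p = p_idx, t = t_idx,
    measures = c(
      qrs_duration_s = (offset - onset) / fs,
      pr_interval_s = (onset - p_idx) / fs,
      qt_interval_s = (t_end - onset) / fs,
      qs_interval_s = (s_idx - q_idx) / fs,
      st_amplitude_mV = w[st_idx] - iso,
      p_amplitude_mV = w[p_idx] - iso,
      q_amplitude_mV = w[q_idx] - iso,
      r_amplitude_mV = w[r_idx] - iso,
      s_amplitude_mV = w[s_idx] - iso,
      t_amplitude_mV = w[t_idx] - iso))
}

beat_windows <- function(recording, r_indices, pre_s = 0.3, post_s = 0.5) {
  fs <- recording$fs
  pre <- as.integer(round(pre_s * fs)); post <- as.integer(round(post_s * fs))
  n <- length(recording$samples)
  ok <- r_indices - pre >= 1L & r_indices + post <= n
  r_ok <- r_indices[ok]
  if (length(r_ok) == 0)
    return(list(mat = NULL, r_at = pre + 1L, r_used = integer(0)))
  mat <- vapply(r_ok, function(r)
    recording$samples[(r - pre):(r + post)], numeric(pre + post + 1))
  list(mat = mat, r_at = pre + 1L, r_used = r_ok)
}

#' Average beat aligned on the R peak
#'
#' Per-sample mean of all R-aligned windows (\[-0.3, +0.5\] s) that lie
#' fully inside the recording, delineated into P/QRS/T fiducials.
#'
#' @param recording An [ecg_recording()] (typically band-pass filtered).
#' @param r_indices R-peak sample indices.
#' @return An object of class `average_beat`: `waveform`, `fs`, `r_at`
#'   (index of R within the window), `n_beats`, `iso` (isoelectric level),
#'   the fiducial indices, and `measures` (the ten morphology scalars).
#' @export
average_beat <- function(recording, r_indices) {
  bw <- beat_windows(recording, r_indices)
  if (is.null(bw$mat) || ncol(bw$mat) < 3)
    stop(structure(class = c("ecgaf_insufficient_beats", "error",
                             "condition"),
                   list(message = "fewer than 3 beats with full windows",
                        call = NULL)))
  avg <- rowMeans(bw$mat)
  d <- delineate_beat(avg, recording$fs, bw$r_at)
  structure(c(list(waveform = avg, fs = recording$fs, r_at = bw$r_at,
                   n_beats = ncol(bw$mat)), d),
            class = "average_beat")
}

#' Morphology features: ten kinds, two estimation variants
#'
#' Variant `E` measures the ten morphology quantities (QRS duration, PR,
#' QT and QS intervals; ST, P, Q, R, S and T amplitudes) on the average
#' beat; variant `O` measures them on every individual beat and takes the
#' per-kind median across beats. Intervals are in seconds, amplitudes in mV
#' relative to the isoelectric level. A kind that cannot be delineated is
#' imputed as 0.
#'
#' @inheritParams average_beat
#' @return Named numeric vector of 20 values (`*_E` then `*_O`).
#' @export
morphology_features <- function(recording, r_indices) {
  kinds <- sub("_E$", "", grep("_E$", feature_names(), value = TRUE))
  zero <- stats::setNames(numeric(length(kinds)), kinds)
  e_vals <- tryCatch(average_beat(recording, r_indices)$measures,
                     error = function(e) zero)
  bw <- beat_windows(recording, r_indices)
  o_vals <- if (is.null(bw$mat)) zero else {
    per_beat <- apply(bw$mat, 2, function(w)
      tryCatch(delineate_beat(w, recording$fs, bw$r_at)$measures,
               error = function(e) rep(NA_real_, length(kinds))))
    med <- apply(per_beat, 1, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    stats::setNames(med, kinds)
  }
  c(stats::setNames(e_vals, paste0(kinds, "_E")),
    stats::setNames(o_vals, paste0(kinds, "_O")))
}

## ---- RR features -----------------------------------------------------------

#' Median RR interval
#' @param beat_series A [build_beat_series()] result.
#' @return Median of the RR intervals, seconds.
#' @export
median_rr <- function(beat_series) stats::median(beat_series$rr_s)

#' Index of arrhythmia: count of abnormal beats
#'
#' Each interior beat `i` is judged against the mean `m` of the three
#' consecutive RR intervals around it (`rr[i-1], rr[i], rr[i+1]`). The beat
#' is abnormal if any of four knowledge-based conditions fires:
#' premature-plus-pause (`rr[i] < 0.85 m` and `rr[i+1] > 1.15 m`), dropped
#' beat (`rr[i] > 1.5 m`), ectopic burst (`rr[i] < 0.4` s), or abrupt
#' change (`|rr[i] - rr[i-1]| > 0.3 m`).
#'
#' @param beat_series A [build_beat_series()] result with >= 3 RR
#'   intervals.
#' @return Non-negative integer count of abnormal beats.
#' @export
index_of_arrhythmia <- function(beat_series) {
  rr <- beat_series$rr_s
  k <- length(rr)
  if (k < 3) return(0L)
  i <- 2:(k - 1)
  m <- (rr[i - 1] + rr[i] + rr[i + 1]) / 3
  abnormal <- (rr[i] < 0.85 * m & rr[i + 1] > 1.15 * m) |
    (rr[i] > 1.5 * m) |
    (rr[i] < 0.4) |
    (abs(rr[i] - rr[i - 1]) > 0.3 * m)
  as.integer(sum(abnormal))
}

rr_gap_features <- function(beat_series) {
  rr <- beat_series$rr_s; drr <- beat_series$drr_s
  c(mean_rr_s = mean(rr),
    rmssd_s = if (length(drr) > 0) sqrt(mean(drr^2)) else 0,
    pnn50 = if (length(drr) > 0) mean(abs(drr) > 0.05) else 0)
}

## ---- Noise features --------------------------------------------------------

#' Similarity index of QRS waveforms
#'
#' Mean Pearson correlation over all unordered pairs of QRS windows
#' (\[-60, +80\] ms around each R peak). Near 1 for consistent beat
#' morphology, near 0 for noise.
#'
#' @inheritParams average_beat
#' @return Scalar in \[-1, 1\], or `NA` when fewer than 2 usable windows.
#' @export
qrs_similarity <- function(recording, r_indices) {
  bw <- beat_windows(recording, r_indices, pre_s = 0.06, post_s = 0.08)
  if (is.null(bw$mat) || ncol(bw$mat) < 2) return(NA_real_)
  mat <- bw$mat[, apply(bw$mat, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(mat) < 2) return(NA_real_)
  cm <- stats::cor(mat)
  mean(cm[upper.tri(cm)])
}

#' Signal quality index
#'
#' Ratio of high-quality beats: a beat is high quality when the
#' peak-to-peak amplitude of its isoelectric window (\[-90, -70\] ms before
#' R) is below 20% of the beat's R amplitude.
#'
#' @inheritParams average_beat
#' @param iso_fraction Threshold fraction of the R amplitude.
#' @return Scalar in \[0, 1\].
#' @export
signal_quality_index <- function(recording, r_indices,
                                 iso_fraction = 0.2) {
  fs <- recording$fs
  x <- recording$samples
  n <- length(x)
  ms <- function(v) as.integer(round(v * fs / 1000))
  usable <- r_indices[r_indices + ms(-90) >= 1 & r_indices <= n]
  if (length(usable) == 0) return(0)
  good <- vapply(usable, function(r) {
    iso <- x[(r + ms(-90)):(r + ms(-70))]
    ptp <- max(iso) - min(iso)
    r_amp <- abs(x[r] - mean(iso))
    r_amp > 0 && ptp < iso_fraction * r_amp
  }, logical(1))
  mean(good)
}

#' Q-R smoothness index (QRsi)
#'
#' Number of local maxima in the first-difference sequence of the average
#' beat's upstroke segment (QRS onset to R peak). A clean monotone
#' upstroke yields 1; high-frequency corruption raises the count.
#'
#' @param avg An [average_beat()] result.
#' @return Non-negative integer.
#' @export
qr_smoothness_index <- function(avg) {
  seg <- avg$waveform[avg$onset:avg$r]
  if (length(seg) < 3) return(0L)
  d <- diff(seg)
  if (length(d) < 3) return(0L)
  i <- 2:(length(d) - 1)
  as.integer(sum(d[i] > d[i - 1] & d[i] >= d[i + 1]))
}

## ---- Assembly --------------------------------------------------------------

# Imputation values used when a recording yields too few beats or a
# delineation fails: defaults push the segment toward the Noisy class
# rather than fabricating physiology.
impute_defaults <- function() {
  v <- stats::setNames(numeric(31), feature_names())
  v["ks_statistic"] <- 1
  v
}

#' Extract the full 31-dimensional feature vector from one recording
#'
#' Runs the preprocessing chain (band-pass filter, R-peak detection, RR/dRR
#' construction) and all feature computations, assembling the named
#' 31-vector in the canonical [feature_names()] order. Every failure path
#' imputes (intervals/amplitudes/scores to 0, `ks_statistic` to 1), so the
#' result always contains 31 finite values.
#'
#' @param recording An [ecg_recording()] (one 30 s segment or a whole
#'   short recording).
#' @param ks_reference A `ks_reference`; defaults to
#'   [default_ks_reference()].
#' @param filter A [filter_spec()].
#' @return Named numeric vector of length 31, all finite.
#' @export
extract_features <- function(recording, ks_reference = default_ks_reference(),
                             filter = filter_spec()) {
  out <- impute_defaults()
  filt <- tryCatch(bandpass_filter(recording, filter),
                   error = function(e) recording)
  peaks <- tryCatch(detect_r_peaks(filt), error = function(e) integer(0))
  bs <- tryCatch(build_beat_series(peaks, filt$fs),
                 error = function(e) NULL)

  if (!is.null(bs)) {
    if (length(bs$drr_s) >= 3) out["af_evidence"] <- af_evidence(bs)
    if (length(bs$drr_s) >= 2) {
      out["shannon_entropy_drr"] <- shannon_entropy_drr(bs)
      out["ks_statistic"] <- ks_statistic(bs, ks_reference)
    }
    out["median_rr_s"] <- median_rr(bs)
    out["index_of_arrhythmia"] <- index_of_arrhythmia(bs)
    out[names(rr_gap_features(bs))] <- rr_gap_features(bs)
  }

  if (length(peaks) >= 1) {
    morph <- morphology_features(filt, peaks)
    out[names(morph)] <- morph
    sim <- qrs_similarity(filt, peaks)
    out["qrs_similarity"] <- if (is.finite(sim)) sim else 0
    out["signal_quality_index"] <- signal_quality_index(filt, peaks)
    avg <- tryCatch(average_beat(filt, peaks), error = function(e) NULL)
    if (!is.null(avg))
      out["qr_smoothness_index"] <- qr_smoothness_index(avg)
  }

  out[!is.finite(out)] <- 0
  out
}

#' Extract a feature table from a collection of recordings
#'
#' @param recordings List of [ecg_recording()].
#' @param labels Optional label vector (same length).
#' @param ks_reference Passed to [extract_features()].
#' @param filter Passed to [extract_features()].
#' @return Data frame: `record_id`, `label`, and the 31 feature columns.
#' @export
extract_feature_table <- function(recordings, labels = NULL,
                                  ks_reference = default_ks_reference(),
                                  filter = filter_spec()) {
  feats <- t(vapply(recordings, extract_features,
                    numeric(31), ks_reference = ks_reference,
                    filter = filter))
  df <- as.data.frame(feats)
  df <- cbind(
    record_id = vapply(recordings, function(r) r$record_id, character(1)),
    label = if (is.null(labels))
      vapply(recordings, function(r)
        if (is.null(r$label)) NA_character_ else r$label, character(1))
    else as.character(labels),
    df, stringsAsFactors = FALSE)
  df
}
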