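#' The four rhythm classes
#'
#' Fixed class order used throughout the package: Normal sinus rhythm, AF,
#' Other arrhythmia, Noisy recording.
#'
#' @return Character vector of the four class names, in canonical order.
#' @export
rhythm_classes <- function() c("Normal", "AF", "Other", "Noisy")

#' Construct a single-lead ECG recording
#'
#' @param samples Numeric vector of voltages in millivolts; must be finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @param record_id Record identifier.
#' @param label Optional rhythm label, one of [rhythm_classes()].
#' @param channel 1-based channel index the samples were taken from.
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(samples, fs, record_id = "anonymous",
                          label = NULL, channel = 1L) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  if (!is.null(label)) label <- match.arg(label, rhythm_classes())
  structure(list(samples = as.numeric(samples), fs = fs,
                 record_id = as.character(record_id), label = label,
                 channel = as.integer(channel)),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording '%s': %d samples @ %g Hz (%.1f s)%s>\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Construct a rhythm annotation track
#'
#' A piecewise-constant rhythm labelling: each code applies from its change
#' point (1-based sample index) until the next change point.
#'
#' @param change_points Strictly increasing 1-based sample indices.
#' @param rhythm_codes Character codes (e.g. `"AFIB"`, `"AFL"`, `"J"`,
#'   `"N"`), one per change point.
#' @return An object of class `rhythm_track`.
#' @export
rhythm_track <- function(change_points, rhythm_codes) {
  if (length(change_points) != length(rhythm_codes))
    stop("change_points and rhythm_codes must have equal length",
         call. = FALSE)
  if (length(change_points) > 1 && any(diff(change_points) <= 0))
    stop("change_points must be strictly increasing", call. = FALSE)
  structure(list(change_points = as.integer(change_points),
                 rhythm_codes = as.character(rhythm_codes)),
            class = "rhythm_track")
}

# Map raw rhythm annotation codes to the four classes; unmapped -> NA.
rhythm_code_map <- c(AFIB = "AF", AFL = "Other", J = "Other", N = "Normal")

## ---- CSV ------------------------------------------------------------------

#' Write / read a recording as a two-column CSV (time_s, voltage_mV)
#'
#' @param recording An [ecg_recording()].
#' @param path Output CSV path.
#' @return `write_ecg_csv()` returns `path` invisibly; `read_ecg_csv()`
#'   returns an [ecg_recording()].
#' @export
write_ecg_csv <- function(recording, path) {
  t <- (seq_along(recording$samples) - 1) / recording$fs
  utils::write.csv(data.frame(time_s = t, voltage_mV = recording$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @param fs Sampling frequency to assume when the CSV has a single voltage
#'   column; ignored when a `time_s` column is present.
#' @param record_id Record id for the returned recording.
#' @export
read_ecg_csv <- function(path, fs = 250, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (is.null(record_id))
    record_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  if ("time_s" %in% names(df) && nrow(df) >= 2)
    fs <- 1 / stats::median(diff(df$time_s))
  v <- if ("voltage_mV" %in% names(df)) df$voltage_mV else df[[ncol(df)]]
  ecg_recording(v, fs, record_id = record_id)
}

#' Write ground truth to a JSON sidecar
#'
#' @param truth The `truth` component of [generate_ecg()] output.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- WFDB -----------------------------------------------------------------

# Minimal WFDB support: header (.hea), signal (.dat, formats 212 and 16),
# and MIT annotation files carrying rhythm aux strings. Enough to read the
# standard two-channel 250 Hz AF database layout and to round-trip records
# written by write_wfdb_record().

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1) stop("corrupt WFDB header: ", hea_path, call. = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3) stop("corrupt WFDB header: ", hea_path, call. = FALSE)
  record <- top[1]; nsig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))
  nsamp <- if (length(top) >= 4) as.numeric(top[4]) else NA_real_
  if (is.na(nsig) || is.na(fs))
    stop("corrupt WFDB header: ", hea_path, call. = FALSE)
  sig <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    fmt <- as.integer(sub("[x:+].*$", "", f[2]))
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.eE]+).*$", "\\1", gain_spec))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else NA_real_
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adczero
    if (is.na(gain) || gain == 0) gain <- 200
    sig[[i]] <- list(file = f[1], format = fmt, gain = gain,
                     baseline = baseline)
  }
  list(record = record, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

decode_dat_212 <- function(raw, nvals) {
  n3 <- (length(raw) %/% 3) * 3
  b <- as.integer(raw[seq_len(n3)])
  b0 <- b[seq(1, n3, by = 3)]; b1 <- b[seq(2, n3, by = 3)]
  b2 <- b[seq(3, n3, by = 3)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 15L), 8L)
  s2 <- b2 + bitwShiftL(bitwAnd(b1, 240L), 4L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- as.vector(rbind(s1, s2))
  out[seq_len(min(nvals, length(out)))]
}

#' Read a WFDB record (header, signal, rhythm annotations)
#'
#' Supports signal formats 212 (packed 12-bit, the AF database layout) and
#' 16 (little-endian 16-bit). Samples are converted to millivolts using the
#' header's gain and baseline. If an annotation file is present, rhythm aux
#' strings (e.g. `"(AFIB"`) are parsed into a [rhythm_track()].
#'
#' @param path Record path without extension (e.g. `"data/04015"`), or the
#'   `.hea` path.
#' @param channel 1-based channel to extract (the AF database convention is
#'   channel 1).
#' @param annotator Annotation file extension to look for (default `"atr"`).
#' @return A list with `recording` ([ecg_recording()]) and `track`
#'   ([rhythm_track()] or `NULL` when no annotation file exists).
#' @export
read_wfdb_record <- function(path, channel = 1L, annotator = "atr") {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
  hdr <- parse_wfdb_header(hea)
  if (channel < 1 || channel > hdr$nsig)
    stop(sprintf("channel %d out of range (record has %d channels)",
                 channel, hdr$nsig), call. = FALSE)
  dat <- file.path(dirname(hea), hdr$signals[[channel]]$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat,
                              call. = FALSE)
  fmt <- hdr$signals[[channel]]$format
  raw <- readBin(dat, "raw", n = file.size(dat))
  nsig <- hdr$nsig
  if (fmt == 212) {
    vals <- decode_dat_212(raw, length(raw) %/% 3 * 2)
  } else if (fmt == 16) {
    vals <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                    signed = TRUE, endian = "little")
  } else {
    stop("unsupported WFDB signal format: ", fmt, call. = FALSE)
  }
  nsamp_avail <- length(vals) %/% nsig
  nsamp <- if (is.na(hdr$nsamp) || hdr$nsamp <= 0) nsamp_avail
           else min(hdr$nsamp, nsamp_avail)
  adu <- vals[(seq_len(nsamp) - 1) * nsig + channel]
  mv <- (adu - hdr$signals[[channel]]$baseline) /
    hdr$signals[[channel]]$gain
  rec <- ecg_recording(mv, hdr$fs, record_id = hdr$record,
                       channel = as.integer(channel))
  atr <- paste0(base, ".", annotator)
  track <- if (file.exists(atr)) read_wfdb_annotations(atr) else NULL
  list(recording = rec, track = track)
}

# MIT annotation format: 16-bit LE words; code = bits 10..15, time
# increment = bits 0..9. Code 59 = SKIP (4-byte interval, high word first),
# 63 = AUX (byte count in the time field, padded to even), 60/61/62 carry
# NUM/SUB/CHN and are skipped, 0 with increment 0 ends the stream.
read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nb <- length(raw)
  pos <- 1L; t_now <- 0
  ann_time <- numeric(0); ann_aux <- character(0)
  pending_skip <- 0
  while (pos + 1L <= nb) {
    w <- as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
    pos <- pos + 2L
    code <- bitwShiftR(w, 10L); inc <- bitwAnd(w, 1023L)
    if (code == 0L && inc == 0L) break
    if (code == 59L) {
      if (pos + 3L > nb) break
      hi <- as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
      lo <- as.integer(raw[pos + 2L]) + 256L * as.integer(raw[pos + 3L])
      pos <- pos + 4L
      pending_skip <- pending_skip + hi * 65536 + lo
    } else if (code == 63L) {
      nbytes <- inc
      aux_raw <- raw[pos:(pos + nbytes - 1L)]
      aux <- trimws(rawToChar(aux_raw[aux_raw != as.raw(0)]))
      pos <- pos + nbytes + (nbytes %% 2L)
      if (length(ann_aux) > 0) ann_aux[length(ann_aux)] <- aux
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: no time advance
    } else {
      t_now <- t_now + inc + pending_skip
      pending_skip <- 0
      ann_time <- c(ann_time, t_now)
      ann_aux <- c(ann_aux, NA_character_)
    }
  }
  is_rhythm <- !is.na(ann_aux) & startsWith(ann_aux, "(")
  if (!any(is_rhythm)) return(rhythm_track(integer(0), character(0)))
  cp <- ann_time[is_rhythm] + 1  # annotations are 0-based sample times
  codes <- sub("^\\(", "", ann_aux[is_rhythm])
  keep <- c(TRUE, diff(cp) > 0)
  rhythm_track(cp[keep], codes[keep])
}

#' Write a WFDB record (format 16) with optional rhythm annotations
#'
#' Counterpart of [read_wfdb_record()], mainly used to materialise synthetic
#' corpora on disk. Signals are quantised at 200 ADC units per mV.
#'
#' @param recording An [ecg_recording()].
#' @param dir Output directory.
#' @param record_id Record name (defaults to the recording's id).
#' @param track Optional [rhythm_track()] written as an `.atr` file.
#' @param gain ADC units per millivolt.
#' @return The record base path (without extension), invisibly.
#' @export
write_wfdb_record <- function(recording, dir, record_id = recording$record_id,
                              track = NULL, gain = 200) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(recording$samples)
  adu <- as.integer(round(recording$samples * gain))
  adu <- pmax(pmin(adu, 32767L), -32768L)
  datfile <- paste0(record_id, ".dat")
  writeLines(c(sprintf("%s 1 %g %d", record_id, recording$fs, n),
               sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 ECG", datfile, gain,
                       adu[1])),
             file.path(dir, paste0(record_id, ".hea")))
  writeBin(adu, file.path(dir, datfile), size = 2, endian = "little")
  if (!is.null(track)) write_wfdb_annotations(track, file.path(
    dir, paste0(record_id, ".atr")))
  invisible(file.path(dir, record_id))
}

write_wfdb_annotations <- function(track, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  word <- function(w) writeBin(as.integer(w), con, size = 2,
                               endian = "little")
  t_prev <- 0
  for (i in seq_along(track$change_points)) {
    t0 <- track$change_points[i] - 1L  # back to 0-based
    dt <- t0 - t_prev
    if (dt > 1023) {
      word(bitwShiftL(59L, 10L))
      word(dt %/% 65536); word(dt %% 65536)
      dt <- 0
    }
    word(bitwShiftL(28L, 10L) + dt)  # RHYTHM annotation
    t_prev <- t0
    aux <- paste0("(", track$rhythm_codes[i])
    nb <- nchar(aux)
    word(bitwShiftL(63L, 10L) + nb)
    writeBin(charToRaw(aux), con)
    if (nb %% 2 == 1) writeBin(as.raw(0), con)
  }
  word(0L)
  invisible(path)
}

## ---- Challenge-style records ---------------------------------------------

# MATLAB v4 .mat parser: 20-byte header of five int32 (type, mrows, ncols,
# imagf, namelen), the variable name, then the data. The Challenge records
# store a single int16 row vector at 300 Hz with 1000 ADC units per mV.
read_mat_v4 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr <- readBin(raw, "integer", n = 5, size = 4, endian = "little")
  type <- hdr[1]; mrows <- hdr[2]; ncols <- hdr[3]; namlen <- hdr[5]
  if (type < 0 || type > 9999 || hdr[4] != 0)
    stop("unsupported .mat file (not MATLAB v4 real numeric): ", path,
         call. = FALSE)
  p <- (type %/% 10) %% 10
  sizes <- c(`0` = 8L, `1` = 4L, `2` = 4L, `3` = 2L, `4` = 2L, `5` = 1L)
  sz <- sizes[as.character(p)]
  if (is.na(sz)) stop("unsupported .mat element type: ", p, call. = FALSE)
  offset <- 20L + namlen
  nvals <- mrows * ncols
  body <- raw[(offset + 1):(offset + nvals * sz)]
  vals <- switch(as.character(p),
    `0` = readBin(body, "double", n = nvals, size = 8, endian = "little"),
    `1` = readBin(body, "double", n = nvals, size = 4, endian = "little"),
    `2` = readBin(body, "integer", n = nvals, size = 4, endian = "little"),
    `3` = readBin(body, "integer", n = nvals, size = 2, signed = TRUE,
                  endian = "little"),
    `4` = readBin(body, "integer", n = nvals, size = 2, signed = FALSE,
                  endian = "little"),
    `5` = as.integer(body))
  vals
}

#' Read the Challenge-style reference label table
#'
#' A headerless two-column CSV mapping record id to one of `N`, `A`, `O`,
#' `~`, translated to `Normal`, `AF`, `Other`, `Noisy`.
#'
#' @param path Path to the reference CSV.
#' @return Named character vector: labels indexed by record id.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("reference table not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, header = FALSE,
                        col.names = c("record", "code"),
                        colClasses = "character")
  map <- c(N = "Normal", A = "AF", O = "Other", `~` = "Noisy")
  labels <- map[trimws(df$code)]
  if (any(is.na(labels)))
    stop("unknown label code in reference table: ",
         paste(unique(df$code[is.na(labels)]), collapse = ", "),
         call. = FALSE)
  stats::setNames(labels, trimws(df$record))
}

#' Read a Challenge-style single-lead recording
#'
#' Accepts either a MATLAB v4 `.mat` signal file (int16, 1000 ADC units/mV,
#' 300 Hz — the distribution format of the 2017 Challenge corpus) or a CSV.
#' The label is looked up in the reference table.
#'
#' @param path Record file path (`.mat` or `.csv`), or the record base path.
#' @param reference Reference table path or the result of
#'   [read_reference_table()].
#' @param fs Sampling frequency for `.mat` input (Hz).
#' @param gain ADC units per millivolt for `.mat` input.
#' @return A labelled [ecg_recording()].
#' @export
read_challenge2017 <- function(path, reference, fs = 300, gain = 1000) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference))
    reference <- read_reference_table(reference)
  if (!grepl("\\.(mat|csv)$", path, ignore.case = TRUE)) {
    path <- if (file.exists(paste0(path, ".mat"))) paste0(path, ".mat")
            else paste0(path, ".csv")
  }
  if (!file.exists(path)) stop("record file not found: ", path,
                               call. = FALSE)
  id <- sub("\\.(mat|csv)$", "", basename(path), ignore.case = TRUE)
  if (!id %in% names(reference))
    stop("record '", id, "' absent from the reference label table",
         call. = FALSE)
  if (grepl("\\.mat$", path, ignore.case = TRUE)) {
    rec <- ecg_recording(read_mat_v4(path) / gain, fs, record_id = id)
  } else {
    rec <- read_ecg_csv(path, fs = fs, record_id = id)
  }
  rec$label <- unname(reference[id])
  rec
}

## ---- Segmentation and splitting ------------------------------------------

#' Cut an annotated recording into labelled fixed-length segments
#'
#' Consecutive non-overlapping windows of exactly `segment_s * fs` samples;
#' the trailing partial window is discarded. Each window takes the rhythm
#' code covering the majority of its duration (ties broken by earlier
#' code), mapped as AFIB to AF, AFL and J to Other, N to Normal. Windows
#' whose majority code has no mapping are dropped.
#'
#' @param recording An [ecg_recording()].
#' @param track A [rhythm_track()]; must be non-empty.
#' @param segment_s Window length in seconds.
#' @return A list of labelled [ecg_recording()] segments.
#' @export
segment_and_label <- function(recording, track, segment_s = 30) {
  if (length(track$change_points) == 0)
    stop("empty rhythm annotation track", call. = FALSE)
  fs <- recording$fs
  win <- as.integer(round(segment_s * fs))
  n <- length(recording$samples)
  nwin <- n %/% win
  if (nwin == 0) return(list())
  cp <- track$change_points
  codes <- track$rhythm_codes
  # Coverage boundaries over [1, n + 1): prepend an unlabelled region if the
  # track starts after sample 1.
  if (cp[1] > 1) { cp <- c(1L, cp); codes <- c("<unlabelled>", codes) }
  bounds <- c(cp, n + 1L)
  out <- list()
  for (k in seq_len(nwin)) {
    s0 <- (k - 1L) * win + 1L; s1 <- s0 + win  # half-open [s0, s1)
    cover <- pmin(bounds[-1], s1) - pmax(bounds[-length(bounds)], s0)
    cover[cover < 0] <- 0
    if (sum(cover) == 0) next
    per_code <- tapply(cover, codes, sum)
    maj_candidates <- names(per_code)[per_code == max(per_code)]
    # ties: earliest code in the window wins
    maj <- codes[codes %in% maj_candidates & cover > 0][1]
    label <- rhythm_code_map[maj]
    if (is.na(label)) next
    seg <- ecg_recording(recording$samples[s0:(s1 - 1L)], fs,
                         record_id = sprintf("%s_s%03d", recording$record_id,
                                             k),
                         label = unname(label), channel = recording$channel)
    out[[length(out) + 1L]] <- seg
  }
  out
}

#' Stratified train/test split
#'
#' Deterministic, label-stratified split of a labelled item collection.
#' Per class, `round(test_fraction * n_class)` items go to the test side.
#'
#' @param items List of items (e.g. recordings or feature rows).
#' @param labels Vector of labels, same length as `items`.
#' @param test_fraction Proportion held out, in (0, 1).
#' @param seed Integer seed controlling the assignment.
#' @return A list with `train` and `test`, each holding `items`, `labels`
#'   and the original `indices`.
#' @export
split_dataset <- function(items, labels, test_fraction = 0.2, seed = 1L) {
  if (length(items) == 0) stop("items must be non-empty", call. = FALSE)
  if (length(items) != length(labels))
    stop("items and labels must have equal length", call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  labels <- as.character(labels)
  test_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      n_test <- round(test_fraction * length(idx))
      if (n_test == 0) return(integer(0))
      sort(sample(idx, n_test))
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(items), test_idx)
  list(train = list(items = items[train_idx], labels = labels[train_idx],
                    indices = train_idx),
       test = list(items = items[test_idx], labels = labels[test_idx],
                   indices = test_idx))
}
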