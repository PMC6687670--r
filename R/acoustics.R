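#' Construct a call recording
#' @param samples Numeric vector in [-1, 1].
#' @param rate Sampling rate in Hz.
#' @return An object of class \code{call_recording}.
#' @export
call_recording <- function(samples, rate = 44100) {
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (rate <= 0) stop("sampling rate must be positive")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "call_recording")
}

#' @export
print.call_recording <- function(x, ...) {
  cat(sprintf("Call recording: %.3f s at %d Hz (%d samples)\n",
              length(x$samples) / x$rate, as.integer(x$rate),
              length(x$samples)))
  invisible(x)
}

# 24-bit little-endian raw triplets -> signed integers
.int24 <- function(raw) {
  n <- length(raw) / 3L
  b <- matrix(as.integer(raw), nrow = 3L)
  v <- b[1L, ] + b[2L, ] * 256L + b[3L, ] * 65536L
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Read a WAV recording
#'
#' Minimal RIFF/WAVE reader for PCM 16/24-bit integer and 32-bit float
#' encodings. Multi-channel audio is downmixed by averaging; integer samples
#' are normalized to [-1, 1].
#'
#' @param path Path to a WAV file.
#' @return A \code{\link{call_recording}}.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(size) == 0L) break
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      if (length(raw) < 16L) stop("truncated fmt chunk in ", path)
      u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0L), channels = u16(2L),
                  rate = u32(4L), bits = u16(14L))
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
      if (length(data) < size) stop("truncated data chunk in ", path)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt/data chunk in ", path)
  x <- switch(as.character(fmt$format),
    "1" = switch(as.character(fmt$bits),
      "16" = readBin(data, "integer", length(data) / 2L, 2L,
                     signed = TRUE, endian = "little") / 32768,
      "24" = .int24(data) / 8388608,
      stop("unsupported PCM bit depth: ", fmt$bits)),
    "3" = readBin(data, "double", length(data) / 4L, 4L, endian = "little"),
    stop("unsupported WAV encoding (format tag ", fmt$format, ")"))
  if (fmt$channels > 1L) {
    n <- floor(length(x) / fmt$channels) * fmt$channels
    x <- colMeans(matrix(x[seq_len(n)], nrow = fmt$channels))
  }
  call_recording(x, fmt$rate)
}

#' Write a recording as 16-bit PCM WAV
#' @param rec A \code{call_recording} (samples clipped to [-1, 1]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "call_recording"))
  x <- pmax(pmin(rec$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")           # PCM, mono
  writeBin(as.integer(rec$rate), con, 4L, endian = "little")
  writeBin(as.integer(rec$rate * 2L), con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

# Amplitude envelope: magnitude of the analytic signal (FFT construction),
# smoothed by a centered moving average of smooth_s seconds.
.envelope <- function(samples, rate, smooth_s = 0.005) {
  n <- length(samples)
  X <- stats::fft(samples)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) / 2L)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  w <- max(1L, round(smooth_s * rate))
  if (w > 1L) {
    k <- rep(1 / w, w)
    pad <- floor(w / 2L)
    padded <- c(rep(env[1L], pad), env, rep(env[n], w - pad - 1L))
    env <- as.numeric(stats::filter(padded, k, sides = 1L))[(w - 1L) + seq_len(n)]
  }
  env
}

#' Segment call notes from the amplitude envelope
#'
#' Detects notes on the smoothed analytic-signal envelope: samples above
#' \code{rel_threshold} times the envelope maximum form active regions,
#' regions separated by gaps shorter than \code{min_gap_s} are merged, and
#' regions shorter than \code{min_note_s} are dropped. Thresholding is
#' relative, so segmentation is invariant to global gain.
#'
#' @param rec A \code{\link{call_recording}}.
#' @param rel_threshold Fraction of the envelope maximum (default 0.1).
#' @param min_note_s Minimum note duration in seconds.
#' @param min_gap_s Gaps shorter than this merge adjacent regions.
#' @param smooth_s Envelope smoothing window in seconds.
#' @return Data frame with \code{start_s}, \code{end_s} per note, in time
#'   order; zero rows for silence.
#' @export
segment_notes <- function(rec, rel_threshold = 0.1, min_note_s = 0.02,
                          min_gap_s = 0.02, smooth_s = 0.005) {
  stopifnot(inherits(rec, "call_recording"))
  env <- .envelope(rec$samples, rec$rate, smooth_s)
  mx <- max(env)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (mx <= 0) return(empty)
  active <- env >= rel_threshold * mx
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  if (nrow(iv) == 0L) return(empty)
  # merge across short gaps
  merged <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (k in 2:nrow(iv)) {
      gap <- (iv[k, 1L] - merged[nrow(merged), 2L] - 1L) / rec$rate
      if (gap < min_gap_s) merged[nrow(merged), 2L] <- iv[k, 2L]
      else merged <- rbind(merged, iv[k, , drop = FALSE])
    }
  }
  dur <- (merged[, 2L] - merged[, 1L] + 1L) / rec$rate
  merged <- merged[dur >= min_note_s, , drop = FALSE]
  data.frame(start_s = (merged[, 1L] - 1L) / rec$rate,
             end_s = merged[, 2L] / rec$rate)
}

# Welch-style averaged power spectrum: Hann windows of up to nfft samples,
# hop = window/8, each periodogram zero-padded to nfft. Mirrors how a
# selection power spectrum is computed as the average of spectrogram slices.
.power_spectrum <- function(x, rate, nfft = 4096L) {
  n <- length(x)
  win_len <- min(nfft, n)
  hop <- max(1L, floor(win_len / 8L))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / (win_len + 1))
  starts <- seq(1L, max(1L, n - win_len + 1L), by = hop)
  nbins <- nfft %/% 2L + 1L
  pow <- numeric(nbins)
  for (s in starts) {
    seg <- x[s:(s + win_len - 1L)] * hann
    seg <- c(seg, numeric(nfft - win_len))
    sp <- stats::fft(seg)[seq_len(nbins)]
    pow <- pow + Mod(sp)^2
  }
  list(freq = (seq_len(nbins) - 1L) * rate / nfft, power = pow / length(starts),
       bin_hz = rate / nfft)
}

# parabolic interpolation of a spectral peak on log power; returns Hz
.interp_peak <- function(freq, power, i) {
  if (i <= 1L || i >= length(power)) return(freq[i])
  lp <- log(pmax(power[(i - 1L):(i + 1L)], .Machine$double.xmin))
  den <- lp[1L] - 2 * lp[2L] + lp[3L]
  if (den >= 0) return(freq[i])
  delta <- 0.5 * (lp[1L] - lp[3L]) / den
  freq[i] + delta * (freq[2L] - freq[1L])
}

# Short-time spectral-peak track over a note; linear fit extrapolated to the
# note boundaries estimates the initial and final frequency of a sweep
# without the half-window bias of a single edge spectrum.
.edge_frequencies <- function(x, rate, window_s, nfft) {
  n <- length(x)
  w <- min(n, max(8L, round(window_s * rate)))
  hop <- max(1L, floor(w / 4L))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  starts <- seq(1L, n - w + 1L, by = hop)
  centers <- (starts - 1L + w / 2) / rate
  nbins <- nfft %/% 2L + 1L
  fpk <- numeric(length(starts))
  en <- numeric(length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + w - 1L)]
    en[k] <- sum(seg^2)
    seg <- c(seg * hann, numeric(nfft - w))
    sp <- Mod(stats::fft(seg)[seq_len(nbins)])^2
    i <- which.max(sp)
    fpk[k] <- .interp_peak((seq_len(nbins) - 1L) * rate / nfft, sp, i)
  }
  keep <- en >= 0.05 * max(en)
  fpk <- fpk[keep]; centers <- centers[keep]
  dur <- n / rate
  if (length(fpk) < 2L || stats::var(centers) == 0) {
    f <- if (length(fpk) > 0L) fpk[1L] else NA_real_
    return(c(initial = f, final = f))
  }
  fit <- stats::lm(fpk ~ centers)
  pr <- unname(stats::predict(fit, data.frame(centers = c(0, dur))))
  c(initial = pr[1L], final = pr[2L])
}

#' Spectral and temporal features of a single call note
#'
#' Measures duration, peak time (envelope argmax relative to note start),
#' dominant frequency (argmax of the averaged power spectrum), initial and
#' final frequency (short-time peak track linearly extrapolated to the note
#' boundaries), frequency change (final minus initial), harmonic count
#' (spectral peaks within 2 bins of integer multiples of the fundamental
#' exceeding the maximum power minus \code{harmonic_floor_db}) and the
#' second-harmonic frequency.
#'
#' @param rec A \code{\link{call_recording}}.
#' @param start_s,end_s Note boundaries in seconds (see
#'   \code{\link{segment_notes}}).
#' @param dft_size DFT length; 4096 at 44.1 kHz gives 10.77 Hz bins.
#' @param edge_window_s Window for the initial/final frequency track.
#' @param harmonic_floor_db Harmonic counting threshold below the dominant
#'   peak (default 30 dB).
#' @return One-row data frame of per-note features.
#' @export
note_features <- function(rec, start_s, end_s, dft_size = 4096L,
                          edge_window_s = 0.025, harmonic_floor_db = 30) {
  stopifnot(inherits(rec, "call_recording"))
  dur_total <- length(rec$samples) / rec$rate
  if (!(start_s >= 0 && end_s > start_s && end_s <= dur_total + 1e-9))
    stop("note interval outside the recording")
  duration <- end_s - start_s
  if (duration < edge_window_s)
    stop(sprintf("note (%.3f s) shorter than edge window (%.3f s)",
                 duration, edge_window_s))
  i0 <- max(1L, floor(start_s * rec$rate) + 1L)
  i1 <- min(length(rec$samples), ceiling(end_s * rec$rate))
  x <- rec$samples[i0:i1]

  env <- .envelope(x, rec$rate, 0.005)
  peak_time <- (which.max(env) - 1L) / rec$rate

  ps <- .power_spectrum(x, rec$rate, dft_size)
  imax <- which.max(ps$power)
  dominant <- ps$freq[imax]
  f0 <- .interp_peak(ps$freq, ps$power, imax)
  pmax_db <- 10 * log10(ps$power[imax])

  band_peak <- function(center, halfwidth) {
    sel <- which(ps$freq >= center - halfwidth & ps$freq <= center + halfwidth)
    if (length(sel) == 0L) return(c(NA_real_, -Inf))
    i <- sel[which.max(ps$power[sel])]
    c(ps$freq[i], 10 * log10(ps$power[i]))
  }
  nyq <- rec$rate / 2
  n_harm <- 0L
  second <- NA_real_
  k <- 1L
  while (k * f0 < nyq) {
    bp <- band_peak(k * f0, 2 * ps$bin_hz)
    if (bp[2L] >= pmax_db - harmonic_floor_db) n_harm <- n_harm + 1L
    if (k == 2L) second <- bp[1L]
    k <- k + 1L
  }

  ef <- .edge_frequencies(x, rec$rate, edge_window_s, dft_size)
  data.frame(note_duration_s = duration,
             peak_time_s = peak_time,
             dominant_freq_hz = dominant,
             initial_freq_hz = unname(ef["initial"]),
             final_freq_hz = unname(ef["final"]),
             freq_change_hz = unname(ef["final"] - ef["initial"]),
             n_harmonics = n_harm,
             second_harmonic_hz = second)
}

#' The ten standard advertisement-call parameters of a recording
#'
#' Segments the recording into notes and averages the per-note measurements
#' into one feature set per call: notes per call, harmonic count, note
#' duration, inter-note interval (missing for single-note calls), peak time,
#' dominant frequency, second-harmonic frequency, initial and final
#' frequency, and frequency change per note.
#'
#' @param rec A \code{\link{call_recording}}.
#' @param rel_threshold,min_note_s,min_gap_s,smooth_s Segmentation
#'   parameters, see \code{\link{segment_notes}}.
#' @param dft_size,edge_window_s,harmonic_floor_db Feature parameters, see
#'   \code{\link{note_features}}.
#' @return An object of class \code{call_features} (also a one-row list):
#'   \code{notes_per_call}, \code{n_harmonics}, \code{note_duration_s},
#'   \code{internote_interval_s}, \code{peak_time_s},
#'   \code{dominant_freq_hz}, \code{second_harmonic_hz},
#'   \code{initial_freq_hz}, \code{final_freq_hz}, \code{freq_change_hz},
#'   plus \code{notes} (the intervals) and \code{per_note} (raw rows).
#' @export
call_features <- function(rec, rel_threshold = 0.1, min_note_s = 0.02,
                          min_gap_s = 0.02, smooth_s = 0.005,
                          dft_size = 4096L, edge_window_s = 0.025,
                          harmonic_floor_db = 30) {
  notes <- segment_notes(rec, rel_threshold, min_note_s, min_gap_s, smooth_s)
  if (nrow(notes) == 0L) stop("no notes detected in the recording")
  per_note <- do.call(rbind, lapply(seq_len(nrow(notes)), function(i)
    note_features(rec, notes$start_s[i], notes$end_s[i], dft_size,
                  edge_window_s, harmonic_floor_db)))
  internote <- if (nrow(notes) > 1L)
    mean(notes$start_s[-1L] - notes$end_s[-nrow(notes)]) else NA_real_
  structure(list(
    notes_per_call = nrow(notes),
    n_harmonics = as.integer(round(stats::median(per_note$n_harmonics))),
    note_duration_s = mean(per_note$note_duration_s),
    internote_interval_s = internote,
    peak_time_s = mean(per_note$peak_time_s),
    dominant_freq_hz = mean(per_note$dominant_freq_hz),
    second_harmonic_hz = mean(per_note$second_harmonic_hz),
    initial_freq_hz = mean(per_note$initial_freq_hz),
    final_freq_hz = mean(per_note$final_freq_hz),
    freq_change_hz = mean(per_note$freq_change_hz),
    notes = notes, per_note = per_note),
    class = "call_features")
}

#' @export
print.call_features <- function(x, ...) {
  cat("Advertisement-call features\n")
  cat(sprintf("  notes per call      : %d\n", x$notes_per_call))
  cat(sprintf("  harmonics           : %d\n", x$n_harmonics))
  cat(sprintf("  note duration (s)   : %.3f\n", x$note_duration_s))
  cat(sprintf("  inter-note interval : %s\n",
              if (is.na(x$internote_interval_s)) "NA"
              else sprintf("%.3f s", x$internote_interval_s)))
  cat(sprintf("  peak time (s)       : %.3f\n", x$peak_time_s))
  cat(sprintf("  dominant freq (Hz)  : %.1f\n", x$dominant_freq_hz))
  cat(sprintf("  2nd harmonic (Hz)   : %.1f\n", x$second_harmonic_hz))
  cat(sprintf("  initial freq (Hz)   : %.1f\n", x$initial_freq_hz))
  cat(sprintf("  final freq (Hz)     : %.1f\n", x$final_freq_hz))
  cat(sprintf("  freq change (Hz)    : %.1f\n", x$freq_change_hz))
  invisible(x)
}

#' Flatten call features to a one-row data frame
#' @param x A \code{call_features} object.
#' @param row.names,optional,... Passed for S3 compatibility, unused.
#' @return One-row data frame with the ten call parameters.
#' @export
as.data.frame.call_features <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(notes_per_call = x$notes_per_call,
             n_harmonics = x$n_harmonics,
             note_duration_s = x$note_duration_s,
             internote_interval_s = x$internote_interval_s,
             peak_time_s = x$peak_time_s,
             dominant_freq_hz = x$dominant_freq_hz,
             second_harmonic_hz = x$second_harmonic_hz,
             initial_freq_hz = x$initial_freq_hz,
             final_freq_hz = x$final_freq_hz,
             freq_change_hz = x$freq_change_hz)
}
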