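## LFCC feature extraction: framing, uniform 60-band linear filter bank,
## and orthonormal DCT-II cepstrum. The same filter bank (without log/DCT)
## supplies the band powers used by the F-ratio analysis.

N_BANDS <- 60L
N_FFT <- 1024L

#' Uniform band edges of the linear filter bank
#'
#' The 60 bands tile 0--8000 Hz (the Nyquist range at 16 kHz) with uniform
#' width; intervals are half-open `[low, high)`.
#'
#' @param n_bands number of bands.
#' @param rate sampling rate, Hz.
#' @return data.frame with columns `band`, `low_hz`, `high_hz`.
#' @export
band_edges <- function(n_bands = N_BANDS, rate = SAMPLE_RATE) {
  w <- (rate / 2) / n_bands
  data.frame(band = seq_len(n_bands),
             low_hz = (seq_len(n_bands) - 1) * w,
             high_hz = seq_len(n_bands) * w)
}

## Triangular filter bank matrix (one-sided FFT bins x bands). Filters peak
## at band centers and reach zero at the neighboring centers (50% overlap),
## so in the interior they sum to a constant.
linear_filterbank <- function(n_bands = N_BANDS, n_fft = N_FFT,
                              rate = SAMPLE_RATE) {
  freqs <- (0:(n_fft / 2)) * rate / n_fft
  w <- (rate / 2) / n_bands
  centers <- (seq_len(n_bands) - 0.5) * w
  fb <- vapply(centers, function(cc) pmax(0, 1 - abs(freqs - cc) / w),
               numeric(length(freqs)))
  fb
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

## Orthonormal DCT-II of each row of `x`, computed with the FFT even/odd
## reordering algorithm (mvfft runs all rows in one call).
dct2 <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  v <- cbind(x[, seq(1, n, by = 2), drop = FALSE],
             x[, rev(seq(2, n, by = 2)), drop = FALSE])
  V <- t(stats::mvfft(t(v)))
  tw <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
  y <- 2 * Re(V * rep(tw, each = nrow(x)))
  scale <- c(sqrt(1 / (4 * n)), rep(sqrt(1 / (2 * n)), n - 1))
  y * rep(scale, each = nrow(x))
}

#' Cut a clip into fixed-width voice samples
#'
#' Frames of `frame_ms` are taken every `frame_ms - overlap_ms` from the
#' start of the clip; a trailing partial frame is discarded. Silent frames
#' (RMS below `1e-3` of the clip peak) are eliminated.
#'
#' @param clip a `voice_clip`.
#' @param frame_ms frame width, ms.
#' @param overlap_ms overlap between consecutive frames, ms; must be
#'   smaller than `frame_ms`.
#' @return a `voice_samples` object: list with `frames` (matrix, one row
#'   per 800-sample frame), `frame_starts`, and the clip's labels. A clip
#'   shorter than one frame yields zero rows.
#' @export
extract_samples <- function(clip, frame_ms = 50, overlap_ms = 40) {
  if (overlap_ms >= frame_ms) {
    stop_invalid("'overlap_ms' must be smaller than 'frame_ms'")
  }
  x <- clip$waveform
  rate <- clip$rate
  flen <- round(frame_ms * rate / 1000)
  step <- round((frame_ms - overlap_ms) * rate / 1000)
  n_frames <- if (length(x) < flen) 0L else (length(x) - flen) %/% step + 1L
  starts <- if (n_frames > 0) (seq_len(n_frames) - 1L) * step + 1L else integer(0)
  frames <- matrix(0, nrow = n_frames, ncol = flen)
  for (i in seq_len(n_frames)) {
    frames[i, ] <- x[starts[i]:(starts[i] + flen - 1L)]
  }
  peak <- if (length(x)) max(abs(x)) else 0
  keep <- if (n_frames > 0 && peak > 0) {
    apply(frames, 1, rms) >= 1e-3 * peak
  } else {
    rep(FALSE, n_frames)
  }
  structure(list(frames = frames[keep, , drop = FALSE],
                 frame_starts = starts[keep],
                 speaker_id = clip$speaker_id, period = clip$period,
                 kind = clip$kind, vowel_label = clip$vowel_label),
            class = "voice_samples")
}

#' @export
print.voice_samples <- function(x, ...) {
  cat(sprintf("<voice_samples: %d frames x %d samples (%s %s %s)>\n",
              nrow(x$frames), ncol(x$frames), x$speaker_id, x$period, x$kind))
  invisible(x)
}

as_frame_matrix <- function(samples) {
  if (inherits(samples, "voice_samples")) return(samples$frames)
  if (is.vector(samples) && is.numeric(samples)) return(matrix(samples, nrow = 1))
  if (is.matrix(samples)) return(samples)
  stop_invalid("expected a voice_samples object, a matrix, or a numeric frame")
}

## Shared front end: peak-normalize each frame to [-1, 1], Hamming window,
## zero-pad to N_FFT, one-sided power spectrum, triangular filter bank.
frame_band_energies <- function(frames) {
  peaks <- apply(abs(frames), 1, max)
  if (any(peaks == 0)) {
    stop_invalid("all-zero frame: silent samples must be filtered out first")
  }
  frames <- frames / peaks
  win <- hamming_window(ncol(frames))
  windowed <- sweep(frames, 2, win, "*")
  fb <- linear_filterbank()
  ## FFT in blocks of rows to bound the complex workspace
  out <- matrix(0, nrow(frames), ncol(fb))
  block <- 2048L
  for (from in seq(1, nrow(frames), by = block)) {
    rows <- from:min(from + block - 1L, nrow(frames))
    padded <- rbind(t(windowed[rows, , drop = FALSE]),
                    matrix(0, N_FFT - ncol(frames), length(rows)))
    spec <- stats::mvfft(padded)[1:(N_FFT / 2 + 1), , drop = FALSE]
    out[rows, ] <- crossprod(Mod(spec)^2, fb)
  }
  out
}

#' Linear-frequency cepstral coefficients of voice samples
#'
#' Pipeline per frame: peak amplitude normalization to `[-1, 1]`, Hamming
#' window, FFT zero-padded to 1024 points, squared magnitude, 60 uniform
#' triangular filters over 0--8 kHz, log of floored band energies, and an
#' orthonormal DCT-II. All 60 coefficients are retained.
#'
#' @param samples a `voice_samples` object, a frame matrix, or one frame.
#' @param log_energies apply the log before the DCT (default). Without it
#'   the DCT is taken of the raw band energies.
#' @param floor lower floor applied to band energies before the log.
#' @return numeric matrix, one 60-coefficient row per frame.
#' @export
lfcc <- function(samples, log_energies = TRUE, floor = 1e-10) {
  frames <- as_frame_matrix(samples)
  if (nrow(frames) == 0) return(matrix(0, 0, N_BANDS))
  energies <- frame_band_energies(frames)
  if (log_energies) energies <- log(pmax(energies, floor))
  dct2(energies)
}

#' Per-frame band energies from the 60-band linear filter bank
#'
#' Same front end as [lfcc()] (normalization, Hamming window, 1024-point
#' FFT, squared magnitude, triangular filters) but stopping at the linear
#' band energies: this is the representation the Fisher F-ratio analysis
#' consumes.
#'
#' @param samples a `voice_samples` object or a frame matrix; must contain
#'   at least one frame.
#' @return numeric matrix, one row per frame, 60 non-negative columns.
#' @export
band_power_matrix <- function(samples) {
  frames <- as_frame_matrix(samples)
  if (nrow(frames) == 0) stop_invalid("'samples' must contain at least one frame")
  frame_band_energies(frames)
}

#' Extract a labeled feature table from a corpus
#'
#' Applies [extract_samples()] to every clip and assembles per-frame LFCCs
#' and band energies with their labels.
#'
#' @param clips list of `voice_clip`s.
#' @param frame_ms,overlap_ms framing parameters, ms.
#' @param log_energies passed to [lfcc()].
#' @return list with `meta` (data.frame: `speaker_id`, `period`, `kind`,
#'   `vowel_label`, `clip`, one row per retained frame), `lfcc` (matrix),
#'   and `band_power` (matrix).
#' @export
corpus_features <- function(clips, frame_ms = 50, overlap_ms = 40,
                            log_energies = TRUE) {
  metas <- list()
  frames <- list()
  for (i in seq_along(clips)) {
    vs <- extract_samples(clips[[i]], frame_ms, overlap_ms)
    if (nrow(vs$frames) == 0) next
    metas[[length(metas) + 1L]] <- data.frame(
      speaker_id = vs$speaker_id, period = vs$period, kind = vs$kind,
      vowel_label = vs$vowel_label, clip = i,
      stringsAsFactors = FALSE)[rep(1, nrow(vs$frames)), ]
    frames[[length(frames) + 1L]] <- vs$frames
  }
  if (!length(frames)) stop_invalid("no non-silent frames in the corpus")
  all_frames <- do.call(rbind, frames)
  energies <- frame_band_energies(all_frames)
  cepstra <- dct2(if (log_energies) log(pmax(energies, 1e-10)) else energies)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  list(meta = meta, lfcc = cepstra, band_power = energies)
}
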