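## Seeded source-filter generator for two-period voice corpora.
##
## Each synthetic speaker carries resonances ("invariant peaks") that are
## identical in the unstable (immature) and stable (mature) periods, while
## the fundamental frequency, a vowel-independent set of period resonances,
## and the vowel formant scale all drift with age. Downstream analyses can
## therefore be checked against known ground truth: individuality that
## should survive the period change lives exactly at the invariant peaks.

SAMPLE_RATE <- 16000L
VOWELS <- c("a", "i", "u", "e", "o")

## Canonical Japanese vowel formants (adult male reference), Hz.
VOWEL_FORMANTS <- list(
  a = data.frame(center_hz = c(750, 1200, 2600), bandwidth_hz = c(130, 150, 200)),
  i = data.frame(center_hz = c(300, 2300, 3000), bandwidth_hz = c(110, 160, 220)),
  u = data.frame(center_hz = c(350, 1300, 2300), bandwidth_hz = c(110, 150, 200)),
  e = data.frame(center_hz = c(450, 1900, 2600), bandwidth_hz = c(120, 150, 200)),
  o = data.frame(center_hz = c(450, 850, 2600), bandwidth_hz = c(120, 140, 200))
)

## Canonical vowel formants are held fixed across periods: age-related
## change is carried by the fundamental frequency shift and by the
## period-specific resonances in each profile's formants_by_period, so the
## drift is controllable and stays out of the designed invariant regions.
PERIOD_FORMANT_SCALE <- c(unstable = 1.00, stable = 1.00)

#' Specify a developmental period for corpus generation
#'
#' @param name `"unstable"` (vocal organs immature, under 20 y) or
#'   `"stable"` (mature, 21 y and over).
#' @param n_clips_per_speaker phrase clips generated per speaker.
#' @param n_vowel_clips vowel clips generated per speaker and vowel.
#' @param f0_jitter relative standard deviation of the per-clip fundamental
#'   frequency around the speaker's period mean.
#' @param noise_floor_db additive Gaussian noise level in dB relative to the
#'   clip peak.
#' @return a `period_spec` list.
#' @export
period_spec <- function(name, n_clips_per_speaker = 6L, n_vowel_clips = 4L,
                        f0_jitter = 0.03, noise_floor_db = -40) {
  name <- match.arg(name, c("unstable", "stable"))
  if (!is_count(n_clips_per_speaker) || n_clips_per_speaker < 1) {
    stop_invalid("'n_clips_per_speaker' must be a positive integer")
  }
  if (!is_count(n_vowel_clips) || n_vowel_clips < 1) {
    stop_invalid("'n_vowel_clips' must be a positive integer")
  }
  structure(list(name = name,
                 n_clips_per_speaker = as.integer(n_clips_per_speaker),
                 n_vowel_clips = as.integer(n_vowel_clips),
                 f0_jitter = f0_jitter,
                 noise_floor_db = noise_floor_db),
            class = "period_spec")
}

#' Default unstable/stable period pair
#'
#' The stable period has half as many clips per speaker as the unstable
#' period, mirroring the imbalance typical of longitudinal voice corpora
#' where mature-period material is scarcer, and a larger fundamental
#' frequency jitter in the unstable period (pitch is less controlled before
#' maturity).
#'
#' @return named list of two `period_spec` objects.
#' @export
default_periods <- function() {
  list(unstable = period_spec("unstable", n_clips_per_speaker = 6L,
                              n_vowel_clips = 6L, f0_jitter = 0.05),
       stable = period_spec("stable", n_clips_per_speaker = 3L,
                            n_vowel_clips = 3L, f0_jitter = 0.03))
}

#' Generate a cohort of synthetic speaker profiles
#'
#' Every speaker receives one invariant resonance inside 1--2 kHz and one
#' inside 4--6 kHz, identical in both periods and separated from every other
#' speaker's by at least 50 Hz: these are the designed carriers of
#' age-robust individuality. Fundamental frequency drops from the unstable
#' to the stable period, much more for male-like profiles than female-like
#' ones, and each period gets its own random vowel-independent resonances
#' (age-varying cues).
#'
#' @param n_male,n_female speaker counts; `n_male + n_female >= 2`.
#' @param seed integer seed; the cohort is a pure function of it.
#' @param peak_gain_db gain of the invariant peaks, dB.
#' @param peak_bandwidth_hz bandwidth of the invariant peaks, Hz.
#' @return list of `speaker_profile` objects. The first male and first
#'   female are flagged `role = "target"`.
#' @export
make_cohort <- function(n_male = 3L, n_female = 3L, seed = 1L,
                        peak_gain_db = 12, peak_bandwidth_hz = 150) {
  if (!is_count(n_male) || !is_count(n_female) || n_male < 0 || n_female < 0) {
    stop_invalid("'n_male' and 'n_female' must be non-negative integers")
  }
  n <- n_male + n_female
  if (n < 2) stop_invalid("a cohort needs at least two speakers")
  with_seed(seed, {
    ## Evenly spaced invariant peak centers (>= 50 Hz apart after jitter),
    ## assigned to speakers in random order.
    spread <- function(lo, hi) {
      centers <- if (n == 1) (lo + hi) / 2 else seq(lo, hi, length.out = n)
      jit <- min(20, if (n > 1) (centers[2] - centers[1]) / 4 else 20)
      (centers + stats::runif(n, -jit, jit))[sample.int(n)]
    }
    low_peaks <- spread(1080, 1920)
    high_peaks <- spread(4150, 5850)
    sexes <- rep(c("male", "female"), c(n_male, n_female))
    ids <- c(if (n_male) paste0("M", seq_len(n_male)),
             if (n_female) paste0("F", seq_len(n_female)))
    lapply(seq_len(n), function(i) {
      sex <- sexes[i]
      f0_offset <- stats::runif(1, -15, 15)
      f0 <- if (sex == "male") c(unstable = 180, stable = 120) else
        c(unstable = 250, stable = 220)
      ## age-varying resonances live outside the invariant 1-2 / 4-6 kHz
      ## regions so period drift and period-robust individuality occupy
      ## disjoint frequency real estate by construction; within each pool
      ## the two periods' centers are kept at least a third of the pool
      ## apart, so vocal-tract growth always moves every such resonance
      rand_formant_pair <- function() {
        pools <- rbind(c(300, 750), c(2300, 3700), c(6300, 7500))
        centers <- vapply(seq_len(nrow(pools)), function(r) {
          lo <- pools[r, 1]; hi <- pools[r, 2]
          sep <- 0.35 * (hi - lo)
          s <- stats::runif(1, lo, hi)
          left <- c(lo, min(s - sep, hi))
          right <- c(max(s + sep, lo), hi)
          len_l <- max(0, left[2] - left[1])
          len_r <- max(0, right[2] - right[1])
          u <- stats::runif(1, 0, len_l + len_r)
          u <- if (u <= len_l) left[1] + u else right[1] + (u - len_l)
          c(unstable = u, stable = s)
        }, numeric(2))
        bw <- stats::runif(nrow(pools), 100, 200)
        list(unstable = data.frame(center_hz = centers["unstable", ],
                                   bandwidth_hz = bw),
             stable = data.frame(center_hz = centers["stable", ],
                                 bandwidth_hz = bw))
      }
      structure(list(
        speaker_id = ids[i],
        sex = sex,
        role = if ((sex == "male" && ids[i] == "M1") ||
                   (sex == "female" && ids[i] == "F1")) "target" else "non_target",
        invariant_peaks = data.frame(
          center_hz = c(low_peaks[i], high_peaks[i]),
          bandwidth_hz = peak_bandwidth_hz,
          gain_db = peak_gain_db),
        f0_by_period = as.list(f0 + f0_offset),
        formants_by_period = rand_formant_pair(),
        ## canonical vowel formants are shared by all speakers (period-scaled
        ## only): speaker identity is carried by the invariant peaks and f0,
        ## not by formant idiosyncrasy, so the designed ground truth stays
        ## interpretable
        formant_scale = 1.00
      ), class = "speaker_profile")
    })
  })
}

#' @export
print.speaker_profile <- function(x, ...) {
  cat(sprintf("<speaker_profile %s (%s, %s)>\n", x$speaker_id, x$sex, x$role))
  cat(sprintf("  f0: unstable %.0f Hz, stable %.0f Hz\n",
              x$f0_by_period$unstable, x$f0_by_period$stable))
  cat(sprintf("  invariant peaks: %s Hz\n",
              paste(round(x$invariant_peaks$center_hz), collapse = ", ")))
  invisible(x)
}

## Clips are loudness-equalized to a fixed RMS (as recording levels would
## be), with a peak guard against clipping; band medians then reflect the
## spectral envelope rather than per-clip gain.
equalize_loudness <- function(y, target_rms = 0.1) {
  y <- y * target_rms / rms(y)
  if (max(abs(y)) > 0.98) y <- y * 0.98 / max(abs(y))
  y
}

new_voice_clip <- function(waveform, speaker_id, period, kind,
                           vowel_label = "none", seed_used = NA_integer_) {
  structure(list(waveform = waveform, rate = SAMPLE_RATE,
                 speaker_id = speaker_id, period = period, kind = kind,
                 vowel_label = vowel_label, seed_used = seed_used),
            class = "voice_clip")
}

#' @export
print.voice_clip <- function(x, ...) {
  cat(sprintf("<voice_clip %s %s %s%s: %.3f s at %d Hz>\n",
              x$speaker_id, x$period, x$kind,
              if (x$vowel_label != "none") paste0(" /", x$vowel_label, "/") else "",
              length(x$waveform) / x$rate, x$rate))
  invisible(x)
}

## Magnitude envelope of one resonance (Lorentzian, unity peak). `shape`
## powers the profile: 2 gives a faster-decaying tail, used for the
## age-drift resonances so their period-to-period movement stays local to
## their own frequency pools.
resonance_shape <- function(f, center, bandwidth, shape = 1) {
  (bandwidth^2 / ((f - center)^2 + bandwidth^2))^shape
}

## All resonances active for a profile/period/vowel, as center/bandwidth/gain.
active_resonances <- function(profile, period_name, vowel) {
  vf <- VOWEL_FORMANTS[[vowel]]
  scale <- profile$formant_scale * PERIOD_FORMANT_SCALE[[period_name]]
  res <- data.frame(center_hz = vf$center_hz * scale,
                    bandwidth_hz = vf$bandwidth_hz,
                    gain_db = c(18, 12, 8), shape = 1)
  peaks <- profile$invariant_peaks
  pf <- profile$formants_by_period[[period_name]]
  res <- rbind(res,
               cbind(peaks[, c("center_hz", "bandwidth_hz", "gain_db")],
                     shape = 1),
               data.frame(center_hz = pf$center_hz,
                          bandwidth_hz = pf$bandwidth_hz, gain_db = 6,
                          shape = 2))
  res[res$center_hz < 7800, , drop = FALSE]
}

## One voiced segment: impulse-train glottal source shaped in the frequency
## domain by a -6 dB/octave source tilt and the active resonances, plus a
## Gaussian noise floor. Assumes the RNG is already seeded by the caller.
## The fundamental drifts continuously within the segment (slow random walk
## plus a light 5 Hz vibrato), as natural pitch does, so analysis frames
## from one clip are not copies of each other.
synth_segment <- function(profile, period, vowel, n_samples) {
  f0 <- profile$f0_by_period[[period$name]]
  f0 <- f0 * exp(stats::rnorm(1, 0, period$f0_jitter))
  ## log-f0 modulation sampled at 100 Hz and interpolated
  n_nodes <- max(2L, ceiling(n_samples / SAMPLE_RATE * 100) + 1L)
  walk <- cumsum(stats::rnorm(n_nodes, 0, 0.006))
  tt <- seq(0, n_samples / SAMPLE_RATE, length.out = n_nodes)
  vibrato <- 0.01 * sin(2 * pi * 5 * tt + stats::runif(1, 0, 2 * pi))
  mod <- stats::approx(seq_len(n_nodes), exp(walk + vibrato),
                       xout = seq(1, n_nodes, length.out = n_samples))$y
  x <- numeric(n_samples)
  t_pos <- 1
  while (t_pos <= n_samples) {
    x[floor(t_pos)] <- 1
    t_pos <- t_pos + SAMPLE_RATE / (f0 * mod[floor(t_pos)])
  }
  ## aspiration: broadband glottal noise shaped by the same vocal-tract
  ## envelope, filling the spectrum between harmonics as breathy voices do
  x <- x + stats::rnorm(n_samples, 0, 0.05)
  idx <- 0:(n_samples - 1)
  f <- pmin(idx, n_samples - idx) * SAMPLE_RATE / n_samples
  H <- 1 / (1 + f / 800)                       # glottal spectral tilt
  res <- active_resonances(profile, period$name, vowel)
  for (r in seq_len(nrow(res))) {
    g <- db_to_amp(res$gain_db[r])
    H <- H * (1 + (g - 1) * resonance_shape(f, res$center_hz[r],
                                            res$bandwidth_hz[r], res$shape[r]))
  }
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n_samples
  y + stats::rnorm(n_samples, 0, db_to_amp(period$noise_floor_db) * max(abs(y)))
}

#' Synthesize one vowel clip
#'
#' Source-filter synthesis: an impulse train at the speaker's period
#' fundamental frequency (with per-clip jitter) is shaped by the canonical
#' formants of the requested vowel, the speaker's invariant peaks, and the
#' period's vowel-independent resonances, then a Gaussian noise floor is
#' added and the peak amplitude normalized to 0.95.
#'
#' @param profile a `speaker_profile`.
#' @param period a `period_spec`.
#' @param vowel one of `"a" "i" "u" "e" "o"`.
#' @param duration clip length in seconds, at least 0.05.
#' @param seed integer seed; the clip is a pure function of its arguments.
#' @return a `voice_clip`.
#' @export
synthesize_vowel <- function(profile, period, vowel, duration = 0.4, seed = 1L) {
  if (!vowel %in% VOWELS) {
    stop_invalid("unknown vowel label: '", vowel, "' (expected one of ",
                 paste(VOWELS, collapse = " "), ")")
  }
  if (duration < 0.05) stop_invalid("'duration' must be at least 0.05 s")
  n <- round(duration * SAMPLE_RATE)
  y <- with_seed(seed, synth_segment(profile, period, vowel, n))
  new_voice_clip(equalize_loudness(y), profile$speaker_id, period$name,
                 "vowel", vowel, as.integer(seed))
}

#' Synthesize one phrase clip
#'
#' A phrase is a chain of randomly chosen vowel-like segments joined with
#' 10 ms cross-fades; with probability 0.3 a short unvoiced noise burst (a
#' consonant stand-in) is inserted between segments.
#'
#' @param profile a `speaker_profile`.
#' @param period a `period_spec`.
#' @param n_segments number of voiced segments, at least 1.
#' @param segment_duration voiced segment length in seconds.
#' @param seed integer seed.
#' @return a `voice_clip` with `kind = "phrase"`.
#' @export
synthesize_phrase <- function(profile, period, n_segments = 5L,
                              segment_duration = 0.2, seed = 1L) {
  if (!is_count(n_segments) || n_segments < 1) {
    stop_invalid("'n_segments' must be a positive integer")
  }
  n_seg <- round(segment_duration * SAMPLE_RATE)
  n_fade <- round(0.010 * SAMPLE_RATE)
  n_burst <- round(0.030 * SAMPLE_RATE)
  y <- with_seed(seed, {
    vowels <- sample(VOWELS, n_segments, replace = TRUE)
    pieces <- list()
    for (i in seq_len(n_segments)) {
      seg <- synth_segment(profile, period, vowels[i], n_seg)
      pieces[[length(pieces) + 1L]] <- seg / max(abs(seg))
      if (i < n_segments && stats::runif(1) < 0.3) {
        pieces[[length(pieces) + 1L]] <- stats::rnorm(n_burst, 0, 0.15)
      }
    }
    out <- pieces[[1]]
    for (p in pieces[-1]) {
      k <- length(out)
      ramp <- seq(0, 1, length.out = n_fade)
      out[(k - n_fade + 1):k] <- out[(k - n_fade + 1):k] * rev(ramp) +
        p[seq_len(n_fade)] * ramp
      out <- c(out, p[-seq_len(n_fade)])
    }
    out + stats::rnorm(length(out), 0,
                       db_to_amp(period$noise_floor_db) * max(abs(out)))
  })
  new_voice_clip(equalize_loudness(y), profile$speaker_id, period$name,
                 "phrase", "none", as.integer(seed))
}

#' Generate a full two-period corpus for a cohort
#'
#' For every speaker and period this produces `n_clips_per_speaker` phrase
#' clips and `n_vowel_clips` clips of each of the five vowels, with every
#' clip's seed derived deterministically from `seed`.
#'
#' @param cohort list of `speaker_profile`s from [make_cohort()].
#' @param periods named list of `period_spec`s (see [default_periods()]).
#' @param seed master integer seed.
#' @param vowel_duration vowel clip length, seconds.
#' @param phrase_segments voiced segments per phrase clip.
#' @return list of `voice_clip`s.
#' @export
make_corpus <- function(cohort, periods = default_periods(), seed = 1L,
                        vowel_duration = 0.4, phrase_segments = 5L) {
  clips <- list()
  for (profile in cohort) {
    for (period in periods) {
      for (i in seq_len(period$n_clips_per_speaker)) {
        s <- derive_seed(seed, profile$speaker_id, period$name, "phrase", i)
        clips[[length(clips) + 1L]] <-
          synthesize_phrase(profile, period, phrase_segments, seed = s)
      }
      for (v in VOWELS) {
        for (i in seq_len(period$n_vowel_clips)) {
          s <- derive_seed(seed, profile$speaker_id, period$name, v, i)
          clips[[length(clips) + 1L]] <-
            synthesize_vowel(profile, period, v, vowel_duration, seed = s)
        }
      }
    }
  }
  clips
}

#' Write a corpus to disk as WAV files plus a manifest
#'
#' @param clips list of `voice_clip`s.
#' @param directory output directory (created if absent).
#' @return the manifest `data.frame` (columns `speaker_id`, `period`,
#'   `kind`, `vowel_label`, `path`, `seed`), also written to
#'   `manifest.csv` inside `directory`.
#' @export
write_corpus <- function(clips, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory, call. = FALSE)
  rows <- lapply(seq_along(clips), function(i) {
    cl <- clips[[i]]
    fname <- sprintf("%s_%s_%s_%s_%04d.wav", cl$speaker_id, cl$period,
                     cl$kind, cl$vowel_label, i)
    path <- file.path(directory, fname)
    write_wav(cl$waveform, path, cl$rate)
    data.frame(speaker_id = cl$speaker_id, period = cl$period, kind = cl$kind,
               vowel_label = cl$vowel_label, path = fname, seed = cl$seed_used)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a corpus written by [write_corpus()]
#'
#' @param directory directory containing `manifest.csv` and the WAV files.
#' @return list of `voice_clip`s.
#' @export
read_corpus <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", directory, call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    wav <- read_wav(file.path(directory, manifest$path[i]))
    new_voice_clip(wav$waveform, manifest$speaker_id[i], manifest$period[i],
                   manifest$kind[i], manifest$vowel_label[i], manifest$seed[i])
  })
}
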