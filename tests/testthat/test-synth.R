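test_that("cohort generation is seeded, counted and role-flagged", {
  cohort <- make_cohort(3, 3, seed = 7)
  expect_length(cohort, 6)
  expect_equal(sum(vapply(cohort, function(p) p$role == "target", logical(1))), 2)
  sexes <- vapply(cohort, `[[`, character(1), "sex")
  expect_equal(as.vector(table(sexes)[c("male", "female")]), c(3L, 3L))

  twice <- list(make_cohort(1, 1, seed = 1), make_cohort(1, 1, seed = 1))
  expect_identical(twice[[1]], twice[[2]])

  expect_error(make_cohort(-1, 3), "non-negative")
  expect_error(make_cohort(1, 0), "at least two")
})

test_that("invariant peaks are placed in the designed regions, distinct across speakers", {
  cohort <- make_cohort(3, 3, seed = 7)
  for (p in cohort) {
    cc <- p$invariant_peaks$center_hz
    expect_true(any(cc >= 1000 & cc <= 2000))
    expect_true(any(cc >= 4000 & cc <= 6000))
    expect_true(all(cc < 8000))
    expect_identical(p$formants_by_period$unstable$bandwidth_hz,
                     p$formants_by_period$stable$bandwidth_hz)
  }
  centers <- t(vapply(cohort, function(p) p$invariant_peaks$center_hz, numeric(2)))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gte(max(abs(centers[i, ] - centers[j, ])), 50)
  }
})

test_that("vowel synthesis produces the requested pitch (autocorrelation oracle)", {
  profile <- make_cohort(1, 1, seed = 2)[[1]]
  profile$f0_by_period$stable <- 200
  per <- period_spec("stable", f0_jitter = 0)
  for (seed in 1:3) {
    clip <- synthesize_vowel(profile, per, "a", 0.5, seed = seed)
    ac <- stats::acf(clip$waveform, lag.max = 200, plot = FALSE)$acf[-1]
    lag <- which.max(ac[20:200]) + 19
    expect_lte(abs(lag - 80), 5)
  }
})

test_that("vowel synthesis is a pure function of its arguments", {
  profile <- make_cohort(1, 1, seed = 2)[[1]]
  per <- period_spec("unstable")
  a <- synthesize_vowel(profile, per, "i", 0.4, seed = 11)
  b <- synthesize_vowel(profile, per, "i", 0.4, seed = 11)
  expect_identical(a$waveform, b$waveform)
  expect_lte(max(abs(a$waveform)), 1)
  expect_identical(a$rate, 16000L)
  expect_error(synthesize_vowel(profile, per, "x", 0.4), "unknown vowel")
  expect_error(synthesize_vowel(profile, per, "a", 0.01), "at least 0.05")
})

band_power_ratio <- function(waveform, lo1, hi1, lo2, hi2) {
  spec <- Mod(stats::fft(waveform))^2
  f <- (seq_along(spec) - 1) * 16000 / length(spec)
  mean(spec[f >= lo1 & f <= hi1]) / mean(spec[f >= lo2 & f <= hi2])
}

test_that("an invariant peak at 5 kHz raises band power in both periods", {
  profile <- make_cohort(1, 1, seed = 2)[[1]]
  profile$invariant_peaks$center_hz <- c(1500, 5000)
  for (pn in c("unstable", "stable")) {
    clip <- synthesize_vowel(profile, period_spec(pn, f0_jitter = 0), "o",
                             0.5, seed = 5)
    expect_gt(band_power_ratio(clip$waveform, 4750, 5250, 6750, 7250), 1)
  }
})

test_that("phrase synthesis: duration bounds, determinism, spectral peaks", {
  profile <- make_cohort(1, 1, seed = 2)[[1]]
  profile$invariant_peaks$center_hz <- c(1500, 5000)
  per <- period_spec("unstable", f0_jitter = 0)
  clip <- synthesize_phrase(profile, per, 5, segment_duration = 0.2, seed = 2)
  expect_gte(length(clip$waveform) / clip$rate, 0.8)
  expect_lte(length(clip$waveform) / clip$rate, 1.2)
  expect_identical(clip$kind, "phrase")
  expect_identical(clip$waveform,
                   synthesize_phrase(profile, per, 5, seed = 2)$waveform)
  expect_gt(band_power_ratio(clip$waveform, 4750, 5250, 6750, 7250), 1)
  expect_error(synthesize_phrase(profile, per, 0), "positive integer")
})

test_that("fundamental frequency drifts between periods by the configured amount", {
  est_f0 <- function(clip) {
    ac <- stats::acf(clip$waveform, lag.max = 400, plot = FALSE)$acf[-1]
    16000 / (which.max(ac[30:400]) + 29)
  }
  cohort <- make_cohort(1, 1, seed = 4)
  for (profile in cohort) {
    for (pn in c("unstable", "stable")) {
      per <- period_spec(pn, f0_jitter = 0.02)
      f0s <- vapply(1:5, function(i) {
        est_f0(synthesize_vowel(profile, per, "a", 0.5, seed = i))
      }, numeric(1))
      expect_lt(abs(mean(f0s) - profile$f0_by_period[[pn]]) /
                  profile$f0_by_period[[pn]], 0.10)
    }
  }
})

test_that("per-speaker band energy at the designed peaks exceeds the cohort mean", {
  cohort <- make_cohort(2, 2, seed = 9)
  edges <- band_edges()
  for (pn in c("unstable", "stable")) {
    per <- period_spec(pn, n_clips_per_speaker = 1L, n_vowel_clips = 1L)
    bp <- lapply(cohort, function(p) {
      cl <- synthesize_vowel(p, per, "e", 0.4,
                             seed = voiceinv:::derive_seed(5, p$speaker_id, pn))
      colMeans(band_power_matrix(extract_samples(cl)))
    })
    cohort_mean <- colMeans(do.call(rbind, bp))
    for (i in seq_along(cohort)) {
      own_bands <- findInterval(cohort[[i]]$invariant_peaks$center_hz,
                                edges$low_hz)
      expect_true(all(bp[[i]][own_bands] > cohort_mean[own_bands]))
    }
  }
})

test_that("corpus writing and reading round-trips WAV data and metadata", {
  cohort <- small_cohort()
  per <- period_spec("stable", n_clips_per_speaker = 1L, n_vowel_clips = 1L)
  clips <- c(
    lapply(1:5, function(i) synthesize_vowel(cohort[[1]], per, c("a","i","u","e","o")[i], 0.1,
                                             seed = i)),
    lapply(6:10, function(i) synthesize_phrase(cohort[[2]], per, 2,
                                               segment_duration = 0.1, seed = i)))
  dir <- withr::local_tempdir()
  manifest <- write_corpus(clips, dir)
  expect_equal(nrow(manifest), 10)
  expect_length(list.files(dir, pattern = "\\.wav$"), 10)

  wav <- read_wav(file.path(dir, manifest$path[1]))
  expect_equal(wav$rate, 16000L)
  expect_lte(max(abs(wav$waveform - clips[[1]]$waveform)), 2^-15)

  back <- read_corpus(dir)
  expect_length(back, 10)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$speaker_id, clips[[i]]$speaker_id)
    expect_identical(back[[i]]$period, clips[[i]]$period)
    expect_identical(back[[i]]$kind, clips[[i]]$kind)
    expect_identical(back[[i]]$vowel_label, clips[[i]]$vowel_label)
  }
  expect_error(read_wav(file.path(dir, "absent.wav")), "no such file")
})
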