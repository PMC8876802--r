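# Shared fixtures. Everything is generated in code at test time; the heavy
# default-cohort corpus is built lazily once and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A non-silent deterministic clip wrapper around an arbitrary waveform.
toy_clip <- function(waveform, speaker = "S1", period = "stable",
                     kind = "vowel", vowel = "a") {
  voiceinv:::new_voice_clip(waveform, speaker, period, kind, vowel, 0L)
}

sine_clip <- function(freq_hz, duration = 1, amp = 0.5, ...) {
  t <- seq(0, duration, length.out = round(duration * 16000))
  toy_clip(amp * sin(2 * pi * freq_hz * t), ...)
}

# Small two-speaker cohort for unit tests.
small_cohort <- function(seed = 3) cached(paste0("cohort", seed), {
  make_cohort(1, 1, seed = seed)
})

# Default study corpus and features (the conditions used by the
# acceptance-level checks), master seed fixed.
ACCEPT_SEED <- 101L

accept_cohort <- function() cached("acohort", {
  make_cohort(3, 3, seed = voiceinv:::derive_seed(ACCEPT_SEED, "cohort"))
})

accept_clips <- function() cached("aclips", {
  make_corpus(accept_cohort(), default_periods(),
              seed = voiceinv:::derive_seed(ACCEPT_SEED, "corpus"))
})

accept_features <- function() cached("afeats", {
  corpus_features(accept_clips())
})

accept_band_medians <- function() cached("abm", {
  corpus_band_medians(Filter(function(cl) cl$kind == "vowel", accept_clips()))
})

accept_distances <- function() cached("adist", {
  bm <- accept_band_medians()
  rbind(
    cross_period_distances(bm$medians, bm$meta$speaker_id, bm$meta$period,
                           "invariant", n_replicates = 3000L,
                           pairs_per_centroid = 50L,
                           seed = voiceinv:::derive_seed(ACCEPT_SEED, "inv")),
    cross_period_distances(bm$medians, bm$meta$speaker_id, bm$meta$period,
                           "other", n_replicates = 3000L,
                           pairs_per_centroid = 50L,
                           seed = voiceinv:::derive_seed(ACCEPT_SEED, "oth")))
})

# Band indices of the designed invariant regions.
region_bands <- function(low, high) {
  e <- band_edges()
  which((e$low_hz + e$high_hz) / 2 >= low & (e$low_hz + e$high_hz) / 2 <= high)
}
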