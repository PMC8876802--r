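# Fisher F-ratio per band: hand-worked cases, a naive triple-loop oracle,
# and the permutation null.

test_that("speaker and cohort band means are the plain and equal-weight means", {
  x <- matrix(c(1, 3), ncol = 1)
  expect_equal(speaker_band_mean(x, c("A", "A"), "A"), 2)

  const <- matrix(5, 4, 3)
  expect_equal(speaker_band_mean(const, rep("A", 4), "A"), rep(5, 3))

  set.seed(3)
  r <- matrix(stats::rnorm(600), 10)
  sp <- rep(c("A", "B"), 5)
  naive <- colSums(r[sp == "A", ]) / 5
  expect_lt(max(abs(speaker_band_mean(r, sp, "A") - naive)), 1e-12)
  expect_error(speaker_band_mean(r, sp, "C"), "no samples")

  expect_equal(global_band_mean(rbind(2, 6)), 4)
  expect_equal(global_band_mean(rbind(c(1, 2), c(1, 2))), c(1, 2))
  expect_error(global_band_mean(rbind(c(1, 2))), "two speakers")
})

test_that("equal speaker weighting differs from pooling when counts are unbalanced", {
  x <- matrix(c(rep(0, 9), 10), ncol = 1)        # A: nine zeros, B: one ten
  sp <- c(rep("A", 9), "B")
  means <- rbind(speaker_band_mean(x, sp, "A"), speaker_band_mean(x, sp, "B"))
  expect_equal(global_band_mean(means), 5)        # unweighted by sample count
  expect_equal(mean(x), 1)                        # pooled mean differs
})

test_that("the two-speaker one-band case matches the hand computation", {
  x <- matrix(c(1, 3, 5, 7), ncol = 1)
  sp <- c("A", "A", "B", "B")
  f <- f_ratio(x, sp)
  # mu_A = 2, mu_B = 6, mu = 4; numerator = ((2-4)^2 + (6-4)^2)/2 = 4;
  # denominator_A = ((1-2)^2 + (3-2)^2)/2 = 1
  expect_equal(unname(f["A", ]), 4)
  expect_equal(unname(f["B", ]), 4)
  expect_equal(unname(f_ratio(x, sp, speaker_id = "A")), 4)
})

test_that("degenerate cases: identical speakers, zero variance, scale invariance", {
  x <- matrix(rep(c(1, 3), 2), ncol = 1)
  sp <- c("A", "A", "B", "B")
  expect_equal(unname(f_ratio(x, sp)["A", ]), 0)   # no inter-speaker variance

  const <- matrix(c(1, 1, 2, 2), ncol = 1)
  expect_warning(f <- f_ratio(const, sp), "Inf")
  expect_true(all(is.infinite(f)))

  set.seed(6)
  r <- matrix(abs(stats::rnorm(40)), ncol = 2)
  sp2 <- rep(c("A", "B"), each = 10)
  expect_equal(f_ratio(r, sp2), f_ratio(3.7 * r, sp2))

  expect_error(f_ratio(r, rep("A", 20)), "two speakers")
  expect_error(f_ratio(r[1:11, ], c(rep("A", 10), "B")), "at least two samples")
})

test_that("vectorized F-ratio matches a naive triple-loop oracle", {
  naive_f_ratio <- function(x, speakers) {
    ids <- sort(unique(speakers))
    K <- ncol(x)
    mu_i <- matrix(0, length(ids), K)
    for (i in seq_along(ids)) for (k in 1:K) {
      mu_i[i, k] <- mean(x[speakers == ids[i], k])
    }
    out <- matrix(0, length(ids), K, dimnames = list(ids, NULL))
    for (i in seq_along(ids)) for (k in 1:K) {
      mu <- mean(mu_i[, k])
      num <- mean((mu_i[, k] - mu)^2)
      rows <- which(speakers == ids[i])
      den <- mean((x[rows, k] - mu_i[i, k])^2)
      out[ids[i], k] <- num / den
    }
    out
  }
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(stats::rexp(3 * 5 * 8), nrow = 15, ncol = 8)
    sp <- rep(c("s1", "s2", "s3"), each = 5)
    a <- f_ratio(x, sp)
    b <- naive_f_ratio(x, sp)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-300)), 1e-10)
  }
})

test_that("min-max normalization maps onto [0,1] as printed", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.3, 1)
  expect_equal(minmax_normalize(v), v)
  set.seed(2)
  out <- minmax_normalize(stats::rnorm(60))
  expect_equal(range(out), c(0, 1))
  expect_equal(minmax_normalize(c(1, 2, Inf)), c(0, 1, 1))
  expect_error(minmax_normalize(rep(1, 60)), "degenerate")
})

test_that("profiles are normalized per speaker-period and carry band edges", {
  set.seed(13)
  x <- matrix(stats::rexp(40 * 60), 40)
  sp <- rep(c("A", "B"), 20)
  per <- rep(c("unstable", "stable"), each = 20)
  profs <- fratio_profiles(x, sp, per)
  expect_s3_class(profs, "fratio_profiles")
  expect_equal(nrow(profs), 2 * 2 * 60)
  for (id in c("A", "B")) for (s in c("unstable", "stable")) {
    sub <- profs[profs$speaker_id == id & profs$period == s, ]
    expect_equal(range(sub$normalized), c(0, 1))
    expect_equal(sub$band_high_hz - sub$band_low_hz, rep(8000 / 60, 60))
  }
})

test_that("region report flags a constructed high-F-ratio region", {
  norm <- rep(0.5, 60)
  bands_in <- region_bands(1000, 2000)
  norm[bands_in] <- 1
  profs <- do.call(rbind, lapply(c("unstable", "stable"), function(s) {
    data.frame(speaker_id = "A", period = s, band = 1:60,
               band_low_hz = band_edges()$low_hz,
               band_high_hz = band_edges()$high_hz,
               raw = norm, normalized = norm)
  }))
  rep1 <- band_region_report(profs, regions = list(c(1000, 2000)))
  expect_true(all(rep1$robust$period_robust))

  rep2 <- band_region_report(profs, regions = list(c(0, 8000)))
  expect_equal(rep2$table$mean_inside, rep(mean(norm), 2))

  expect_error(band_region_report(profs, regions = list()), "non-empty")
  expect_error(band_region_report(profs, regions = list(c(2000, 1000))), "empty region")
})

test_that("shuffling speaker labels destroys the designed-region signal", {
  cohort <- make_cohort(2, 2, seed = 21)
  per <- list(unstable = period_spec("unstable", 1L, 3L, f0_jitter = 0.05),
              stable = period_spec("stable", 1L, 3L, f0_jitter = 0.03))
  clips <- make_corpus(cohort, per, seed = 22)
  # single-vowel analysis: the low-region signal is vowel-specific
  feats <- corpus_features(Filter(function(cl) {
    cl$kind == "vowel" && cl$vowel_label == "a"
  }, clips))
  x <- feats$band_power
  meta <- feats$meta
  regions <- list(c(1000, 2000), c(4000, 6000))

  flag_fraction <- function(speakers) {
    profs <- fratio_profiles(x, speakers, meta$period)
    mean(band_region_report(profs, regions)$robust$period_robust)
  }
  expect_gte(flag_fraction(meta$speaker_id), 0.75)

  set.seed(30)
  hits <- vapply(1:50, function(i) {
    shuffled <- meta$speaker_id
    for (s in unique(meta$period)) {
      shuffled[meta$period == s] <- sample(meta$speaker_id[meta$period == s])
    }
    flag_fraction(shuffled) >= 0.75
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})
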