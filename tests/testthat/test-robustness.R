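# Band medians, random median pairs, centroids, cross-period distances.

test_that("spectrogram band medians localize a tone and handle silence", {
  bm <- spectrogram_band_medians(sine_clip(1500, 0.5))
  expect_length(bm$medians, 60)
  edges <- band_edges()
  tone_band <- which(edges$low_hz <= 1500 & 1500 < edges$high_hz)
  band_7k <- which(edges$low_hz <= 7000 & 7000 < edges$high_hz)
  expect_gt(bm$medians[tone_band], bm$medians[band_7k])

  zero <- spectrogram_band_medians(toy_clip(numeric(16000)))
  expect_equal(zero$medians, rep(0, 60))

  expect_error(spectrogram_band_medians(toy_clip(numeric(100))),
               "shorter than one frame")
})

test_that("median pairs are counted, seeded and validated", {
  set.seed(1)
  m <- matrix(stats::rexp(5 * 60), 5)
  p <- sample_median_pairs(m, 1:5, 10:20, n_pairs = 100, seed = 4)
  expect_equal(dim(p), c(100L, 2L))
  expect_identical(p, sample_median_pairs(m, 1:5, 10:20, n_pairs = 100, seed = 4))

  single <- sample_median_pairs(m[1, , drop = FALSE], 3, 7, n_pairs = 20, seed = 1)
  expect_true(all(single[, "u"] == m[1, 3]))
  expect_true(all(single[, "v"] == m[1, 7]))

  expect_error(sample_median_pairs(m, 1:5, 5:10, 10), "disjoint")
  expect_error(sample_median_pairs(m, integer(0), 5:10, 10), "non-empty")
  expect_error(sample_median_pairs(m, 1:5, 10:20, 0), "n_pairs")
})

test_that("centroids are component-wise means with translation equivariance", {
  expect_equal(centroid(rbind(c(1, 2), c(3, 4))), c(u = 2, v = 3),
               ignore_attr = TRUE)
  expect_equal(centroid(rbind(c(5, 6))), c(5, 6), ignore_attr = TRUE)
  pts <- cbind(stats::runif(10), stats::runif(10))
  shifted <- sweep(pts, 2, c(3, -2), "+")
  expect_equal(centroid(shifted), centroid(pts) + c(3, -2))
  expect_error(centroid(matrix(0, 0, 2)), "non-empty")
})

test_that("cross-period distances: counts, degenerate exactness, error reporting", {
  # one clip per person-period; single-band regions make centroids exact
  medians <- matrix(0, 4, 60)
  medians[2, 10] <- 3; medians[2, 35] <- 4    # P1 stable at (3, 4)
  persons <- c("P1", "P1", "P2", "P2")
  periods <- c("unstable", "stable", "unstable", "stable")
  d <- cross_period_distances(medians, persons, periods, "invariant",
                              n_replicates = 5, pairs_per_centroid = 7, seed = 1,
                              invariant_regions = list(c(1266, 1267), c(4600, 4601)))
  # regions contain exactly band 10 (1200-1333 Hz) and band 35 (4533-4666)
  expect_equal(nrow(d), 10)
  expect_equal(d$distance[d$person_id == "P1"], rep(5, 5))  # 3-4-5 triangle
  expect_equal(d$distance[d$person_id == "P2"], rep(0, 5))  # identical periods

  expect_error(cross_period_distances(medians[1:3, ], persons[1:3], periods[1:3],
                                      "invariant", 2, 5, 1),
               "P2")
})

test_that("identical clips in both periods give zero distances in both conditions", {
  set.seed(7)
  m <- matrix(stats::rexp(60), 1)[rep(1, 4), ]
  persons <- rep("P1", 4)
  periods <- rep(c("unstable", "stable"), each = 2)
  for (cond in c("invariant", "other")) {
    d <- cross_period_distances(m, persons, periods, cond,
                                n_replicates = 50, pairs_per_centroid = 10,
                                seed = 3)
    expect_equal(nrow(d), 50)
    expect_true(all(d$distance < 1e-12))
  }
})

test_that("distance distributions are insensitive to clip order and period labels", {
  set.seed(15)
  m <- matrix(stats::rexp(12 * 60), 12)
  persons <- rep("P1", 12)
  periods <- rep(c("unstable", "stable"), each = 6)
  base <- cross_period_distances(m, persons, periods, "invariant", 400, 20, seed = 2)
  perm <- sample(12)
  reordered <- cross_period_distances(m[perm, ], persons, periods[perm],
                                      "invariant", 400, 20, seed = 2)
  expect_lt(abs(mean(base$distance) - mean(reordered$distance)) /
              mean(base$distance), 0.15)
  relabeled <- cross_period_distances(
    m, persons, c(stable = "unstable", unstable = "stable")[periods],
    "invariant", 400, 20, seed = 2)
  expect_lt(abs(mean(base$distance) - mean(relabeled$distance)) /
              mean(base$distance), 0.15)
})

test_that("distance summaries expose boxplot statistics and rank-sum tests", {
  const <- data.frame(person_id = "P1", condition = "invariant",
                      replicate = 1:10, distance = 2)
  s <- distance_summary(const)
  expect_equal(s$stats$q1, 2)
  expect_equal(s$stats$median, 2)
  expect_equal(s$stats$q3, 2)
  expect_null(s$tests)

  odd <- data.frame(person_id = "P1", condition = "invariant",
                    replicate = 1:5, distance = c(1, 2, 3, 4, 5))
  expect_equal(distance_summary(odd)$stats$median, 3)

  both <- rbind(
    data.frame(person_id = "P1", condition = "invariant", replicate = 1:30,
               distance = stats::runif(30, 0, 1)),
    data.frame(person_id = "P1", condition = "other", replicate = 1:30,
               distance = stats::runif(30, 2, 3)))
  s2 <- distance_summary(both)
  expect_equal(nrow(s2$tests), 1)
  expect_lt(s2$tests$p_value, 0.01)
  expect_error(distance_summary(data.frame()), "non-empty")
})
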