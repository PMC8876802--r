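## Band-median centroid robustness analysis: per clip, the median magnitude
## spectrogram value in each of the 60 bands; per person and period, random
## pairs of medians drawn from two frequency regions are averaged into a
## centroid; the Euclidean distance between a person's two period centroids
## measures how much the region's individuality moved with age.

#' Per-band medians of a clip's magnitude spectrogram
#'
#' The clip is framed exactly as in feature extraction (50 ms Hamming
#' window, 40 ms overlap, 1024-point FFT) but without the silence filter or
#' per-frame normalization; per band, the median over all (frame, bin)
#' magnitude cells whose bin frequency falls in the band.
#'
#' @param clip a `voice_clip` of at least one frame.
#' @param frame_ms,overlap_ms framing parameters, ms.
#' @return object of class `band_medians`: list with `medians` (length 60),
#'   and the clip labels.
#' @export
spectrogram_band_medians <- function(clip, frame_ms = 50, overlap_ms = 40) {
  x <- clip$waveform
  flen <- round(frame_ms * clip$rate / 1000)
  step <- round((frame_ms - overlap_ms) * clip$rate / 1000)
  if (length(x) < flen) stop_invalid("clip shorter than one frame")
  n_frames <- (length(x) - flen) %/% step + 1L
  win <- hamming_window(flen)
  padded <- vapply(seq_len(n_frames), function(i) {
    c(x[((i - 1L) * step + 1L):((i - 1L) * step + flen)] * win,
      numeric(N_FFT - flen))
  }, numeric(N_FFT))
  mags <- t(Mod(stats::mvfft(padded)[1:(N_FFT / 2 + 1), , drop = FALSE]))
  bin_freq <- (0:(N_FFT / 2)) * clip$rate / N_FFT
  w <- (clip$rate / 2) / N_BANDS
  band_of_bin <- pmin(floor(bin_freq / w) + 1L, N_BANDS)
  medians <- vapply(seq_len(N_BANDS), function(k) {
    stats::median(mags[, band_of_bin == k])
  }, numeric(1))
  structure(list(medians = medians, speaker_id = clip$speaker_id,
                 period = clip$period, kind = clip$kind,
                 vowel_label = clip$vowel_label),
            class = "band_medians")
}

#' Band-median table for a set of clips
#'
#' @param clips list of `voice_clip`s.
#' @param ... passed to [spectrogram_band_medians()].
#' @return list with `medians` (matrix, one row per clip, 60 columns) and
#'   `meta` (data.frame: `speaker_id`, `period`, `kind`, `vowel_label`).
#' @export
corpus_band_medians <- function(clips, ...) {
  bm <- lapply(clips, spectrogram_band_medians, ...)
  list(medians = do.call(rbind, lapply(bm, `[[`, "medians")),
       meta = do.call(rbind, lapply(bm, function(b) data.frame(
         speaker_id = b$speaker_id, period = b$period, kind = b$kind,
         vowel_label = b$vowel_label, stringsAsFactors = FALSE))))
}

#' Randomly paired band medians from two disjoint frequency regions
#'
#' Each pair is (a median from a uniformly chosen band of region A in a
#' uniformly chosen clip, a median from a uniformly chosen band of region B
#' in an independently chosen clip).
#'
#' @param vectors matrix of band medians, one row per clip.
#' @param region_a_bands,region_b_bands disjoint, non-empty band index sets.
#' @param n_pairs number of pairs to draw.
#' @param seed integer seed.
#' @return `n_pairs` x 2 matrix with columns `u`, `v`.
#' @export
sample_median_pairs <- function(vectors, region_a_bands, region_b_bands,
                                n_pairs, seed = 1L) {
  vectors <- as.matrix(vectors)
  if (!length(region_a_bands) || !length(region_b_bands)) {
    stop_invalid("both band regions must be non-empty")
  }
  if (length(intersect(region_a_bands, region_b_bands))) {
    stop_invalid("band regions must be disjoint")
  }
  if (!is_count(n_pairs) || n_pairs < 1) stop_invalid("'n_pairs' must be >= 1")
  with_seed(seed, draw_pairs(vectors, region_a_bands, region_b_bands, n_pairs))
}

## Unseeded core used both by sample_median_pairs() and the distance
## resampler (which manages one RNG stream for the whole run).
draw_pairs <- function(vectors, bands_a, bands_b, n_pairs) {
  n <- nrow(vectors)
  u <- vectors[cbind(sample.int(n, n_pairs, replace = TRUE),
                     bands_a[sample.int(length(bands_a), n_pairs, replace = TRUE)])]
  v <- vectors[cbind(sample.int(n, n_pairs, replace = TRUE),
                     bands_b[sample.int(length(bands_b), n_pairs, replace = TRUE)])]
  cbind(u = u, v = v)
}

#' Centroid of a set of median pairs
#'
#' @param pairs non-empty two-column matrix of `(u, v)` pairs.
#' @return length-2 numeric vector, the component-wise mean.
#' @export
centroid <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop_invalid("'pairs' must be non-empty")
  colMeans(pairs)
}

#' Cross-period centroid distances per person
#'
#' For each person and replicate, one centroid per period is computed from
#' freshly sampled median pairs and the Euclidean distance between the two
#' period centroids recorded; `n_replicates` distances (twice as many
#' centroids) per person. The replicate's random band choices are shared by
#' the two periods (a paired comparison: identical clips in both periods
#' give a distance of exactly zero), while clips are drawn independently
#' within each period. Under `condition = "invariant"` the two regions are
#' the bands inside 1--2 kHz and inside 4--6 kHz; under
#' `condition = "other"` each replicate draws two disjoint random band
#' subsets, size-matched to the invariant regions, entirely outside both.
#'
#' @param medians matrix of band medians, one row per clip.
#' @param persons,periods labels per row; every person must appear in both
#'   periods.
#' @param condition `"invariant"` or `"other"`.
#' @param n_replicates distances per person.
#' @param pairs_per_centroid median pairs averaged into each centroid.
#' @param seed integer seed; the whole resampling run is reproducible.
#' @param invariant_regions list of the two region frequency ranges, Hz.
#' @return data.frame of class `distance_samples` with columns `person_id`,
#'   `condition`, `replicate`, `distance`.
#' @export
cross_period_distances <- function(medians, persons, periods,
                                   condition = c("invariant", "other"),
                                   n_replicates = 3000L,
                                   pairs_per_centroid = 50L, seed = 1L,
                                   invariant_regions = list(c(1000, 2000),
                                                            c(4000, 6000))) {
  condition <- match.arg(condition)
  medians <- as.matrix(medians)
  if (nrow(medians) != length(persons) || nrow(medians) != length(periods)) {
    stop_invalid("'persons' and 'periods' must have one entry per row")
  }
  period_names <- sort(unique(as.character(periods)))
  if (length(period_names) != 2) stop_invalid("exactly two periods are required")
  ids <- sort(unique(as.character(persons)))
  missing <- ids[vapply(ids, function(id) {
    length(unique(periods[persons == id])) < 2
  }, logical(1))]
  if (length(missing)) {
    stop_invalid("person(s) missing a period: ", paste(missing, collapse = ", "))
  }
  bands_a <- bands_in_region(invariant_regions[[1]], ncol(medians))
  bands_b <- bands_in_region(invariant_regions[[2]], ncol(medians))
  outside <- setdiff(seq_len(ncol(medians)), c(bands_a, bands_b))
  out <- list()
  with_seed(seed, {
    for (id in ids) {
      m1 <- medians[persons == id & periods == period_names[1], , drop = FALSE]
      m2 <- medians[persons == id & periods == period_names[2], , drop = FALSE]
      d <- numeric(n_replicates)
      np <- pairs_per_centroid
      for (r in seq_len(n_replicates)) {
        if (condition == "invariant") {
          ba <- bands_a; bb <- bands_b
        } else {
          pick <- outside[sample.int(length(outside),
                                     length(bands_a) + length(bands_b))]
          ba <- pick[seq_along(bands_a)]
          bb <- pick[length(bands_a) + seq_along(bands_b)]
        }
        ba_draw <- ba[sample.int(length(ba), np, replace = TRUE)]
        bb_draw <- bb[sample.int(length(bb), np, replace = TRUE)]
        c1 <- c(mean(m1[cbind(sample.int(nrow(m1), np, TRUE), ba_draw)]),
                mean(m1[cbind(sample.int(nrow(m1), np, TRUE), bb_draw)]))
        c2 <- c(mean(m2[cbind(sample.int(nrow(m2), np, TRUE), ba_draw)]),
                mean(m2[cbind(sample.int(nrow(m2), np, TRUE), bb_draw)]))
        d[r] <- sqrt(sum((c1 - c2)^2))
      }
      out[[length(out) + 1L]] <- data.frame(
        person_id = id, condition = condition,
        replicate = seq_len(n_replicates), distance = d,
        stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("distance_samples", "data.frame")
  res
}

#' Summary of cross-period centroid distances
#'
#' Per (person, condition): boxplot statistics (min, quartiles, median,
#' max) and the mean. When both conditions are present, a one-sided
#' Wilcoxon rank-sum test per person checks whether invariant-region
#' distances are stochastically smaller than other-region distances.
#'
#' @param samples a `distance_samples` data.frame (possibly rbind of both
#'   conditions).
#' @return list with `stats` (data.frame) and `tests` (data.frame with
#'   per-person rank-sum `statistic` and `p_value`, or `NULL` if only one
#'   condition is present).
#' @export
distance_summary <- function(samples) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop_invalid("'samples' must be a non-empty data.frame")
  }
  groups <- split(samples$distance,
                  list(person = samples$person_id, condition = samples$condition),
                  drop = TRUE)
  stats_df <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    q <- stats::quantile(d, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(person_id = parts[1], condition = parts[2],
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               mean = mean(d), n = length(d), stringsAsFactors = FALSE)
  }))
  tests <- NULL
  conds <- unique(samples$condition)
  if (all(c("invariant", "other") %in% conds)) {
    tests <- do.call(rbind, lapply(unique(samples$person_id), function(id) {
      inv <- samples$distance[samples$person_id == id & samples$condition == "invariant"]
      oth <- samples$distance[samples$person_id == id & samples$condition == "other"]
      wt <- stats::wilcox.test(inv, oth, alternative = "less", exact = FALSE)
      data.frame(person_id = id, statistic = unname(wt$statistic),
                 p_value = wt$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(stats = stats_df, tests = tests)
}

#' Boxplot of cross-period centroid distances
#'
#' @param x a `distance_samples` data.frame.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.distance_samples <- function(x, ...) {
  graphics::boxplot(distance ~ condition + person_id, data = x,
                    ylab = "Cross-period centroid distance", las = 2, ...)
  invisible(x)
}
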