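## Per-band Fisher F-ratio: inter-speaker variance of per-speaker mean band
## powers over intra-speaker variance of band powers, computed per period.
## Band powers enter in the linear power domain. The numerator is shared by
## all speakers in a period; the denominator is speaker-specific, so each
## speaker gets its own 60-band profile.

#' Per-speaker mean band power
#'
#' @param x band power matrix, one row per voice sample.
#' @param speakers speaker id per row.
#' @param id the speaker whose mean is requested.
#' @return numeric vector of per-band means.
#' @export
speaker_band_mean <- function(x, speakers, id) {
  x <- as.matrix(x)
  if (nrow(x) != length(speakers)) {
    stop_invalid("'speakers' must have one entry per row of 'x'")
  }
  rows <- speakers == id
  if (!any(rows)) stop_invalid("no samples for speaker '", id, "'")
  colMeans(x[rows, , drop = FALSE])
}

#' Cohort mean band power (speakers weighted equally)
#'
#' The mean of per-speaker means: every speaker contributes equally
#' regardless of how many samples it has, so unbalanced sample counts do
#' not tilt the cohort mean.
#'
#' @param speaker_means matrix of per-speaker mean band powers, one row per
#'   speaker (at least two).
#' @return numeric vector of per-band means.
#' @export
global_band_mean <- function(speaker_means) {
  speaker_means <- as.matrix(speaker_means)
  if (nrow(speaker_means) < 2) stop_invalid("at least two speakers are required")
  colMeans(speaker_means)
}

#' Raw per-band F-ratios
#'
#' For band k the numerator is the inter-speaker variance
#' `mean_i (mu_ik - mu_k)^2` (identical for every speaker) and the
#' denominator for speaker i is the intra-speaker variance
#' `mean_j (x_ijk - mu_ik)^2`. A zero intra-speaker variance yields an
#' `Inf` sentinel (with a warning) rather than an error.
#'
#' @param x band power matrix, one row per voice sample.
#' @param speakers speaker id per row; at least two distinct speakers, each
#'   with at least two samples.
#' @param speaker_id if given, return that speaker's profile as a vector;
#'   otherwise a matrix with one row per speaker.
#' @return matrix (speakers x bands) of raw F-ratios, or a vector for one
#'   speaker.
#' @export
f_ratio <- function(x, speakers, speaker_id = NULL) {
  x <- as.matrix(x)
  if (nrow(x) != length(speakers)) {
    stop_invalid("'speakers' must have one entry per row of 'x'")
  }
  ids <- sort(unique(as.character(speakers)))
  if (length(ids) < 2) stop_invalid("at least two speakers are required")
  counts <- table(as.character(speakers))
  if (any(counts < 2)) {
    stop_invalid("every speaker needs at least two samples (short: ",
                 paste(names(counts)[counts < 2], collapse = ", "), ")")
  }
  K <- ncol(x)
  mu_i <- matrix(vapply(ids, function(id) speaker_band_mean(x, speakers, id),
                        numeric(K)), ncol = K, byrow = TRUE)
  mu <- global_band_mean(mu_i)
  numerator <- colMeans(sweep(mu_i, 2, mu, "-")^2)
  denom <- matrix(vapply(ids, function(id) {
    rows <- speakers == id
    colMeans(sweep(x[rows, , drop = FALSE], 2, mu_i[id == ids, ], "-")^2)
  }, numeric(K)), ncol = K, byrow = TRUE)
  if (any(denom == 0)) {
    warning("zero intra-speaker variance in some bands; F-ratio reported as Inf",
            call. = FALSE)
  }
  out <- sweep(1 / denom, 2, numerator, "*")
  out[denom == 0] <- Inf
  rownames(out) <- ids
  if (!is.null(speaker_id)) {
    if (!speaker_id %in% ids) stop_invalid("unknown speaker '", speaker_id, "'")
    return(out[speaker_id, ])
  }
  out
}

#' Min-max normalization to `[0, 1]`
#'
#' @param v numeric vector with at least two distinct finite values.
#' @return `(v - min) / (max - min)`; `Inf` entries map to 1.
#' @export
minmax_normalize <- function(v) {
  finite <- v[is.finite(v)]
  if (length(unique(finite)) < 2) {
    stop_invalid("min-max normalization is degenerate: fewer than two distinct finite values")
  }
  out <- (v - min(finite)) / (max(finite) - min(finite))
  out[is.infinite(v) & v > 0] <- 1
  out
}

#' Per-speaker, per-period F-ratio profiles
#'
#' Computes raw per-band F-ratios separately within each period and min-max
#' normalizes each (speaker, period) profile across its 60 bands, so the
#' curves are comparable across periods.
#'
#' @param x band power matrix, one row per voice sample.
#' @param speakers,periods labels per row.
#' @return data.frame of class `fratio_profiles` with columns `speaker_id`,
#'   `period`, `band`, `band_low_hz`, `band_high_hz`, `raw`, `normalized`.
#' @export
fratio_profiles <- function(x, speakers, periods) {
  x <- as.matrix(x)
  if (nrow(x) != length(speakers) || nrow(x) != length(periods)) {
    stop_invalid("'speakers' and 'periods' must have one entry per row of 'x'")
  }
  edges <- band_edges(ncol(x))
  out <- list()
  for (s in unique(as.character(periods))) {
    rows <- periods == s
    raw <- f_ratio(x[rows, , drop = FALSE], speakers[rows])
    for (id in rownames(raw)) {
      out[[length(out) + 1L]] <- data.frame(
        speaker_id = id, period = s, band = edges$band,
        band_low_hz = edges$low_hz, band_high_hz = edges$high_hz,
        raw = raw[id, ], normalized = minmax_normalize(raw[id, ]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fratio_profiles", "data.frame")
  res
}

#' Plot F-ratio profiles
#'
#' One panel per speaker with the normalized profile of each period
#' overlaid.
#'
#' @param x a `fratio_profiles` data.frame.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fratio_profiles <- function(x, ...) {
  ids <- unique(x$speaker_id)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)))
  on.exit(graphics::par(old), add = TRUE)
  for (id in ids) {
    sub <- x[x$speaker_id == id, ]
    wide <- stats::reshape(sub[, c("band_low_hz", "period", "normalized")],
                           idvar = "band_low_hz", timevar = "period",
                           direction = "wide")
    graphics::matplot(wide$band_low_hz, wide[, -1], type = "l", lty = 1,
                      xlab = "Frequency (Hz)", ylab = "Normalized F-ratio",
                      main = id, ...)
    graphics::legend("topright", legend = sub("normalized.", "", names(wide)[-1]),
                     col = seq_len(ncol(wide) - 1), lty = 1, bty = "n")
  }
  invisible(x)
}

## Band indices whose centers fall inside [low, high] Hz.
bands_in_region <- function(region, n_bands = N_BANDS, rate = SAMPLE_RATE) {
  edges <- band_edges(n_bands, rate)
  centers <- (edges$low_hz + edges$high_hz) / 2
  which(centers >= region[1] & centers <= region[2])
}

#' Region-level F-ratio report
#'
#' For every profile and frequency region, compares the mean normalized
#' F-ratio inside the region with the mean outside it. A region is flagged
#' period-robust for a speaker when inside > outside in both periods.
#'
#' @param profiles a `fratio_profiles` data.frame.
#' @param regions list of `c(low_hz, high_hz)` regions within 0--8 kHz.
#' @return list with `table` (per speaker, period, region: `mean_inside`,
#'   `mean_outside`) and `robust` (per speaker, region:
#'   `period_robust` flag).
#' @export
band_region_report <- function(profiles,
                               regions = list(c(1000, 2000), c(4000, 6000))) {
  if (!length(regions)) stop_invalid("'regions' must be non-empty")
  rows <- list()
  for (r in seq_along(regions)) {
    region <- regions[[r]]
    if (region[2] <= region[1]) stop_invalid("empty region: ", paste(region, collapse = "-"))
    bands <- bands_in_region(region)
    if (!length(bands)) stop_invalid("region contains no bands: ",
                                     paste(region, collapse = "-"))
    for (id in unique(profiles$speaker_id)) {
      for (s in unique(profiles$period)) {
        sub <- profiles[profiles$speaker_id == id & profiles$period == s, ]
        inside <- sub$normalized[sub$band %in% bands]
        outside <- sub$normalized[!sub$band %in% bands]
        rows[[length(rows) + 1L]] <- data.frame(
          speaker_id = id, period = s,
          region = sprintf("%g-%g Hz", region[1], region[2]),
          mean_inside = mean(inside),
          mean_outside = if (length(outside)) mean(outside) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  key <- interaction(tab$speaker_id, tab$region, drop = TRUE, sep = "\r")
  flags <- tapply(tab$mean_inside > tab$mean_outside, key,
                  function(z) all(z))
  parts <- strsplit(names(flags), "\r", fixed = TRUE)
  robust <- data.frame(speaker_id = vapply(parts, `[`, "", 1),
                       region = vapply(parts, `[`, "", 2),
                       period_robust = as.logical(flags),
                       stringsAsFactors = FALSE)
  list(table = tab, robust = robust)
}
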