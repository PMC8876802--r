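## Experiment driver: one config describes the synthetic cohort, feature
## settings, verifier, and the two analyses; run_experiment() executes the
## full design (both train/test period directions, phrase plus each vowel,
## per-target model ensembles, F-ratio profiles and the centroid-distance
## robustness comparison) and returns a consolidated, reproducible report.

#' Default experiment configuration
#'
#' @param seed master seed; every random draw in the run derives from it.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function(seed = 1L, output_dir = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    output_dir = output_dir,
    cohort = list(n_male = 3L, n_female = 3L, peak_gain_db = 12,
                  peak_bandwidth_hz = 150),
    periods = list(
      unstable = list(n_clips_per_speaker = 6L, n_vowel_clips = 4L,
                      f0_jitter = 0.04, noise_floor_db = -40),
      stable = list(n_clips_per_speaker = 3L, n_vowel_clips = 2L,
                    f0_jitter = 0.02, noise_floor_db = -40)),
    features = list(frame_ms = 50, overlap_ms = 40, log_energies = TRUE),
    verifier = list(hidden = c(128L, 64L, 32L), epochs = 300L,
                    batch_size = 32L, learning_rate = 1e-3, n_models = 5L,
                    max_train_frames_per_speaker = 150L),
    fratio = list(regions = list(c(1000, 2000), c(4000, 6000))),
    robustness = list(n_replicates = 3000L, pairs_per_centroid = 50L,
                      per_vowel = FALSE)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate an experiment configuration
#'
#' Accepts either a configuration list or the path of a YAML file; checks
#' every constraint and reports the complete list of violations at once.
#'
#' @param config a list, a `run_config`, or a YAML file path.
#' @return the validated `run_config` (invisible errors are not possible:
#'   on any violation the function stops with all of them listed).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("cannot read config file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_invalid("'config' must be a list or a YAML path")
  base <- unclass(default_config())
  config <- utils::modifyList(base, unclass(config))
  errs <- character(0)
  need <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  need(is_count(config$seed), "seed: required integer")
  need(is_count(config$cohort$n_male) && config$cohort$n_male >= 0,
       "cohort$n_male: non-negative integer required")
  need(is_count(config$cohort$n_female) && config$cohort$n_female >= 0,
       "cohort$n_female: non-negative integer required")
  if (is_count(config$cohort$n_male) && is_count(config$cohort$n_female)) {
    need(config$cohort$n_male + config$cohort$n_female >= 2,
         "cohort: at least two speakers required")
  }
  need(is.numeric(config$features$frame_ms) && config$features$frame_ms > 0,
       "features$frame_ms: positive number required")
  need(is.numeric(config$features$overlap_ms) && config$features$overlap_ms >= 0,
       "features$overlap_ms: non-negative number required")
  if (is.numeric(config$features$frame_ms) && is.numeric(config$features$overlap_ms)) {
    need(config$features$overlap_ms < config$features$frame_ms,
         "features$overlap_ms must be smaller than features$frame_ms")
  }
  for (p in c("unstable", "stable")) {
    pp <- config$periods[[p]]
    need(!is.null(pp), paste0("periods$", p, ": required"))
    if (!is.null(pp)) {
      need(is_count(pp$n_clips_per_speaker) && pp$n_clips_per_speaker >= 1,
           paste0("periods$", p, "$n_clips_per_speaker: positive integer required"))
      need(is_count(pp$n_vowel_clips) && pp$n_vowel_clips >= 1,
           paste0("periods$", p, "$n_vowel_clips: positive integer required"))
    }
  }
  need(is_count(config$verifier$epochs) && config$verifier$epochs >= 1,
       "verifier$epochs: positive integer required")
  need(is_count(config$verifier$batch_size) && config$verifier$batch_size >= 1,
       "verifier$batch_size: positive integer required")
  need(is_count(config$verifier$n_models) && config$verifier$n_models >= 1,
       "verifier$n_models: positive integer required")
  need(is_count(config$robustness$n_replicates) && config$robustness$n_replicates >= 1,
       "robustness$n_replicates: positive integer required")
  need(is_count(config$robustness$pairs_per_centroid) &&
         config$robustness$pairs_per_centroid >= 1,
       "robustness$pairs_per_centroid: positive integer required")
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  class(config) <- "run_config"
  config
}

## Cheap deterministic content hash (FNV-1a over the deparsed config) used
## for report provenance.
config_hash <- function(config) {
  config <- unclass(config)
  config$output_dir <- NULL      # where results land is not part of the design
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

build_period_specs <- function(config) {
  lapply(c(unstable = "unstable", stable = "stable"), function(p) {
    pp <- config$periods[[p]]
    period_spec(p, pp$n_clips_per_speaker, pp$n_vowel_clips,
                pp$f0_jitter, pp$noise_floor_db)
  })
}

## Cap the per-speaker training frames (seeded subsample) so ensemble
## training stays at desk scale; the cap is a config choice.
subsample_rows <- function(meta_speakers, max_per_speaker, seed) {
  if (is.null(max_per_speaker) || !is.finite(max_per_speaker)) {
    return(seq_along(meta_speakers))
  }
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_along(meta_speakers), meta_speakers),
                          function(idx) {
      if (length(idx) > max_per_speaker) sample(idx, max_per_speaker) else idx
    }))
    sort(keep)
  })
}

#' Run the full cross-period experiment
#'
#' Generates the synthetic cohort and two-period corpus, extracts LFCC
#' features, trains a model ensemble per target speaker and train/test
#' period direction for every utterance kind (phrase and each vowel),
#' scores EER-based verification accuracy, computes per-period F-ratio
#' profiles with a region report, and runs the centroid-distance robustness
#' comparison on the vowel samples. Fully reproducible from the config.
#'
#' @param config a `run_config` (see [default_config()]), a plain list of
#'   overrides, or a YAML path; validated before use.
#' @return object of class `run_report`: list with `accuracy` (one row per
#'   target x direction x utterance kind), `fratio` (profiles and region
#'   report for phrase and pooled-vowel samples), `robustness` (distance
#'   summary and rank-sum tests), and `provenance`.
#' @export
run_experiment <- function(config = default_config()) {
  config <- validate_config(config)
  seed <- config$seed
  cohort <- make_cohort(config$cohort$n_male, config$cohort$n_female,
                        seed = derive_seed(seed, "cohort"),
                        peak_gain_db = config$cohort$peak_gain_db,
                        peak_bandwidth_hz = config$cohort$peak_bandwidth_hz)
  periods <- build_period_specs(config)
  clips <- make_corpus(cohort, periods, seed = derive_seed(seed, "corpus"))
  feats <- corpus_features(clips, config$features$frame_ms,
                           config$features$overlap_ms,
                           config$features$log_energies)
  meta <- feats$meta
  targets <- vapply(Filter(function(p) p$role == "target", cohort),
                    `[[`, character(1), "speaker_id")
  kinds <- c("phrase", VOWELS)
  directions <- list(c(train = "unstable", test = "stable"),
                     c(train = "stable", test = "unstable"))

  acc_rows <- list()
  for (target in targets) {
    for (dir in directions) {
      for (kind in kinds) {
        sel_kind <- if (kind == "phrase") meta$kind == "phrase" else
          meta$kind == "vowel" & meta$vowel_label == kind
        tr <- which(sel_kind & meta$period == dir[["train"]])
        te <- which(sel_kind & meta$period == dir[["test"]])
        tr <- tr[subsample_rows(meta$speaker_id[tr],
                                config$verifier$max_train_frames_per_speaker,
                                derive_seed(seed, "subsample", target,
                                            dir[["train"]], kind))]
        labels <- ifelse(meta$speaker_id[tr] == target, "target", "non_target")
        ens <- train_ensemble(feats$lfcc[tr, , drop = FALSE], labels,
                              n_models = config$verifier$n_models,
                              seed = derive_seed(seed, "ensemble", target,
                                                 dir[["train"]], kind),
                              hidden = config$verifier$hidden,
                              epochs = config$verifier$epochs,
                              batch_size = config$verifier$batch_size,
                              learning_rate = config$verifier$learning_rate)
        res <- evaluate_cross_period(ens, feats$lfcc[te, , drop = FALSE],
                                     meta$speaker_id[te] == target)
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          target = target, kind = kind, train_period = dir[["train"]],
          test_period = dir[["test"]], n_train = length(tr), n_test = length(te),
          mean_accuracy = res$mean_accuracy,
          stringsAsFactors = FALSE)
      }
    }
  }
  accuracy <- do.call(rbind, acc_rows)

  fratio_out <- list()
  for (kind in c("phrase", "vowel")) {
    rows <- meta$kind == kind
    profs <- fratio_profiles(feats$band_power[rows, , drop = FALSE],
                             meta$speaker_id[rows], meta$period[rows])
    fratio_out[[kind]] <- list(
      profiles = profs,
      report = band_region_report(profs, config$fratio$regions))
  }

  vowel_clips <- Filter(function(cl) cl$kind == "vowel", clips)
  bm <- corpus_band_medians(vowel_clips, config$features$frame_ms,
                            config$features$overlap_ms)
  dist_inv <- cross_period_distances(
    bm$medians, bm$meta$speaker_id, bm$meta$period, "invariant",
    config$robustness$n_replicates, config$robustness$pairs_per_centroid,
    seed = derive_seed(seed, "robustness", "invariant"),
    invariant_regions = config$fratio$regions)
  dist_oth <- cross_period_distances(
    bm$medians, bm$meta$speaker_id, bm$meta$period, "other",
    config$robustness$n_replicates, config$robustness$pairs_per_centroid,
    seed = derive_seed(seed, "robustness", "other"),
    invariant_regions = config$fratio$regions)
  distances <- rbind(dist_inv, dist_oth)
  robustness <- distance_summary(distances)

  report <- structure(list(
    accuracy = accuracy,
    fratio = fratio_out,
    robustness = robustness,
    distances = distances,
    provenance = list(seed = seed, config_hash = config_hash(config),
                      package_version = as.character(utils::packageVersion("voiceinv")),
                      n_clips = length(clips), n_frames = nrow(meta))
  ), class = "run_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(accuracy, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(fratio_out$phrase$profiles, fratio_out$vowel$profiles),
                     file.path(config$output_dir, "fratio.csv"), row.names = FALSE)
    utils::write.csv(distances, file.path(config$output_dir, "distances.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = accuracy,
           fratio_robust = lapply(fratio_out, function(f) f$report$robust),
           robustness = robustness, provenance = report$provenance),
      file.path(config$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Cross-period voice individuality experiment\n")
  cat(sprintf("  seed %d, config %s, %d clips, %d frames\n",
              x$provenance$seed, x$provenance$config_hash,
              x$provenance$n_clips, x$provenance$n_frames))
  cat("\nVerification accuracy (mean over ensemble):\n")
  print(x$accuracy, row.names = FALSE)
  cat("\nPeriod-robust F-ratio regions (vowel samples):\n")
  print(x$fratio$vowel$report$robust, row.names = FALSE)
  if (!is.null(x$robustness$tests)) {
    cat("\nInvariant vs other centroid distances (one-sided rank-sum):\n")
    print(x$robustness$tests, row.names = FALSE)
  }
  invisible(x)
}
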