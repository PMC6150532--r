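#' Simulate a complete dyadic recording session
#'
#' Ground-truth-labelled study conditions for the full pipeline: a dyad
#' running in the arena at not-close separation, emitting `n_events`
#' frequency-modulated chirps (alternating emitters) in the 30-110 kHz
#' band, rendered into 8-channel array audio with free-field propagation.
#' Writes the session WAV, trajectory CSV and YAML config to `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param session_id session identifier.
#' @param n_events number of chirps (default 50).
#' @param noise_sd per-channel Gaussian noise sd (default 0: noise-free).
#' @param event_gap_s silence between consecutive chirp onsets.
#' @param seed RNG seed controlling chirp parameters and noise.
#' @param geometry microphone geometry (default 8-mic perimeter array).
#' @return list: `config` (YAML path), `bundle`, `truth` (ground-truth
#'   event table), `labels` (per-mouse frame labels).
#' @export
simulate_session <- function(out_dir, session_id = "simulated01",
                             n_events = 50, noise_sd = 0,
                             event_gap_s = 0.12, seed = 1,
                             geometry = default_array_geometry()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sample_rate <- 250000
  frame_rate <- 30
  onsets <- 0.3 + (seq_len(n_events) - 1) * event_gap_s
  duration_s <- max(onsets) + 0.3
  nfr <- ceiling(duration_s * frame_rate) + 3L

  script <- behavior_script("not_close", start_frame = 2L,
                            n_frames = nfr - 5L)
  traj <- simulate_trajectories(script, n_frames = nfr,
                                mouse_ids = c("M", "F"),
                                frame_rate = frame_rate,
                                not_close_gap_m = 0.25,
                                seed = seed)

  events <- with_seed(seed + 1L, {
    emitters <- rep(c("M", "F"), length.out = n_events)
    dur <- runif(n_events, 0.015, 0.030)
    f0 <- runif(n_events, 50000, 72000)
    bw <- runif(n_events, 12000, 24000) * sample(c(-1, 1), n_events, TRUE)
    f1 <- pmin(pmax(f0 + bw, 32000), 108000)
    do.call(rbind, lapply(seq_len(n_events), function(i) {
      emission_event(emitters[i], onsets[i], dur[i], f0[i], f1[i],
                     amplitude = 0.2)
    }))
  })

  sim <- simulate_array_audio(traj$tracks, events, geometry,
                              sample_rate = sample_rate,
                              noise_sd = noise_sd, seed = seed + 2L)
  audio_path <- file.path(out_dir, paste0(session_id, ".wav"))
  tracks_path <- file.path(out_dir, paste0(session_id, "_tracks.csv"))
  write_wav(sim$samples, audio_path, sample_rate, bits = 32L)
  write_tracks(traj$tracks, tracks_path)

  bundle <- structure(list(session_id = session_id,
                           audio = normalizePath(audio_path),
                           tracks = normalizePath(tracks_path),
                           geometry = geometry, frame_rate = frame_rate,
                           sample_rate = sample_rate),
                      class = "session_bundle")
  config <- file.path(out_dir, paste0(session_id, ".yaml"))
  # config carries paths relative to its own directory, so the session
  # directory stays relocatable
  cfg <- bundle
  cfg$audio <- basename(audio_path)
  cfg$tracks <- basename(tracks_path)
  write_session(cfg, config)
  utils::write.csv(sim$truth, file.path(out_dir, paste0(session_id, "_truth.csv")),
                   row.names = FALSE)
  list(config = config, bundle = bundle, truth = sim$truth,
       labels = traj$labels)
}

write_signal_artifacts <- function(signals, out_dir, prefix = "") {
  write.csv(signal_summary(signals),
            file.path(out_dir, paste0(prefix, "signals.csv")),
            row.names = FALSE)
  contours <- do.call(rbind, lapply(signals, function(s) {
    cbind(signal_id = s$id, s$contour)
  }))
  if (is.null(contours)) {
    contours <- data.frame(signal_id = integer(), time_s = numeric(),
                           freq_hz = numeric(), power = numeric())
  }
  write.csv(contours, file.path(out_dir, paste0(prefix, "contours.csv")),
            row.names = FALSE)
}

read_signal_artifacts <- function(out_dir, prefix = "") {
  summ <- read.csv(file.path(out_dir, paste0(prefix, "signals.csv")))
  contours <- read.csv(file.path(out_dir, paste0(prefix, "contours.csv")))
  lapply(seq_len(nrow(summ)), function(i) {
    s <- as.list(summ[i, ])
    s$contour <- contours[contours$signal_id == s$id,
                          c("time_s", "freq_hz", "power")]
    s$pixels <- NULL
    class(s) <- "vocal_signal"
    s
  })
}

mw_row <- function(test, label) {
  if (is.null(test)) return(NULL)
  data.frame(comparison = label, U = test$U, z = test$z, p = test$p,
             n1 = test$n1, n2 = test$n2,
             median1 = test$median1, q25_1 = test$iqr1[1], q75_1 = test$iqr1[2],
             median2 = test$median2, q25_2 = test$iqr2[1], q75_2 = test$iqr2[2],
             stringsAsFactors = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes an ordered subset of the stages `simulate`, `segment`,
#' `localize`, `features`, `behavior`, `stats`. Every stage reads the
#' previous stage's on-disk artifact from `out_dir` and writes its own, so
#' stages can be re-run independently; a JSON run report with per-stage
#' tallies is written at the end.
#'
#' For a stats-only run, `config` may instead point directly at an
#' S1-compatible feature table (CSV/XLSX).
#'
#' @param config session YAML (or feature table for `stages = "stats"`);
#'   ignored (and generated) when `simulate` is among the stages.
#' @param stages character vector, ordered subset of the six stage names.
#' @param seed integer seed used by the stochastic stages.
#' @param out_dir artifact directory.
#' @param n_events,noise_sd simulate-stage parameters.
#' @param min_pixels,alpha segment-stage parameters.
#' @param mpi_threshold localize-stage assignment threshold.
#' @param n_samples,sample_size stats-stage Monte-Carlo parameters.
#' @return the run report (list), invisibly; side effect: artifacts in
#'   `out_dir`.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("simulate", "segment", "localize",
                                    "features", "behavior", "stats"),
                         seed = 1, out_dir = "usvdyad_run",
                         n_events = 50, noise_sd = 0,
                         min_pixels = 1500, alpha = 0.05,
                         mpi_threshold = 0.95,
                         n_samples = 1000, sample_size = 500) {
  valid <- c("simulate", "segment", "localize", "features", "behavior", "stats")
  if (!all(stages %in% valid) ||
      is.unsorted(match(stages, valid), strictly = TRUE)) {
    stop_usv("stages must be an ordered subset of: %s",
             paste(valid, collapse = ", "), class = "usvdyad_validation_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "usvdyad",
                 version = as.character(utils::packageVersion("usvdyad")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 seed = seed, stages = list())

  stats_only_table <- length(stages) == 1L && stages == "stats" &&
    !is.null(config) && grepl("\\.(csv|xlsx|xls)$", config, ignore.case = TRUE)

  if ("simulate" %in% stages) {
    sim <- simulate_session(out_dir, n_events = n_events,
                            noise_sd = noise_sd, seed = seed)
    config <- sim$config
    report$stages$simulate <- list(n_events = nrow(sim$truth))
  }

  need_session <- any(c("segment", "localize", "features", "behavior") %in% stages)
  bundle <- NULL
  if (need_session || (any(stages == "stats") && !stats_only_table)) {
    if (is.null(config)) {
      stop_usv("config required for stages without 'simulate'",
               class = "usvdyad_dependency_error")
    }
  }
  if (need_session) bundle <- read_session(config)

  audio <- NULL
  load_audio <- function() {
    if (is.null(audio)) audio <<- read_wav(bundle$audio)$samples
    audio
  }

  if ("segment" %in% stages) {
    seg <- segment_audio(load_audio(), bundle$sample_rate,
                         alpha = alpha, min_pixels = min_pixels)
    write_signal_artifacts(seg$signals, out_dir)
    report$stages$segment <- list(n_signals = length(seg$signals))
  }

  if ("localize" %in% stages) {
    sig_path <- file.path(out_dir, "signals.csv")
    if (!file.exists(sig_path)) {
      stop_usv("missing upstream artifact '%s' (run the segment stage)",
               sig_path, class = "usvdyad_dependency_error")
    }
    signals <- read_signal_artifacts(out_dir)
    tracks <- read_tracks(bundle$tracks, bundle$frame_rate)
    filtered <- bandpass_usv(load_audio(), bundle$sample_rate)
    loc <- localize_signals(signals, filtered, bundle$geometry,
                            bundle$sample_rate, tracks,
                            threshold = mpi_threshold)
    write.csv(loc, file.path(out_dir, "localization.csv"), row.names = FALSE)
    report$stages$localize <- list(
      n_signals = nrow(loc),
      n_assigned = sum(!is.na(loc$assigned_to)))
  }

  if ("features" %in% stages) {
    loc_path <- file.path(out_dir, "localization.csv")
    if (!file.exists(loc_path)) {
      stop_usv("missing upstream artifact '%s' (run the localize stage)",
               loc_path, class = "usvdyad_dependency_error")
    }
    signals <- read_signal_artifacts(out_dir)
    loc <- read.csv(loc_path, stringsAsFactors = FALSE)
    feats <- compute_features(signals, load_audio(), bundle$sample_rate,
                              assignments = loc,
                              session_id = bundle$session_id)
    write_feature_table(feats, file.path(out_dir, "features.csv"))
    report$stages$features <- list(n_rows = nrow(feats))
  }

  if ("behavior" %in% stages) {
    feat_path <- file.path(out_dir, "features.csv")
    if (!file.exists(feat_path)) {
      stop_usv("missing upstream artifact '%s' (run the features stage)",
               feat_path, class = "usvdyad_dependency_error")
    }
    tracks <- read_tracks(bundle$tracks, bundle$frame_rate)
    bouts <- classify_bouts(tracks[[1]], tracks[[2]])
    write.csv(bouts, file.path(out_dir, "bouts.csv"), row.names = FALSE)
    feats <- read_feature_table(feat_path)
    signals <- read_signal_artifacts(out_dir)
    onsets <- vapply(signals, `[[`, 1, "start_s")[
      match(feats$voc_number, vapply(signals, `[[`, 1, "id"))]
    feats <- label_vocalizations(feats, bouts, onsets, bundle$frame_rate)
    write_feature_table(feats, file.path(out_dir, "features_labelled.csv"))
    tab <- table(feats$context, useNA = "no")
    report$stages$behavior <- list(n_bouts = nrow(bouts),
                                   context_counts = as.list(tab))
  }

  if ("stats" %in% stages) {
    tab <- if (stats_only_table) {
      read_feature_table(config)
    } else {
      lp <- file.path(out_dir, "features_labelled.csv")
      fp <- file.path(out_dir, "features.csv")
      path <- if (file.exists(lp)) lp else fp
      if (!file.exists(path)) {
        stop_usv("missing upstream artifact '%s' (run the features stage)",
                 path, class = "usvdyad_dependency_error")
      }
      read_feature_table(path)
    }
    summ <- summarize_feature_table(tab, n_samples = n_samples,
                                    sample_size = sample_size, seed = seed)
    stats_dir <- file.path(out_dir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    pooled <- do.call(rbind, Filter(Negate(is.null), c(
      lapply(names(summ$pooled), function(f) mw_row(summ$pooled[[f]], f)),
      lapply(names(summ$by_context), function(f)
        mw_row(summ$by_context[[f]], f)))))
    if (!is.null(pooled)) {
      write.csv(pooled, file.path(stats_dir, "tests.csv"), row.names = FALSE)
    }
    if (!is.null(summ$monte_carlo)) {
      idx <- do.call(rbind, lapply(summ$monte_carlo, function(m) {
        data.frame(feature = m$feature, sample = seq_along(m$indices),
                   index = m$indices)
      }))
      write.csv(idx, file.path(stats_dir, "index_distributions.csv"),
                row.names = FALSE)
    }
    write.csv(summ$context_counts, file.path(stats_dir, "context_counts.csv"),
              row.names = FALSE)
    report$stages$stats <- list(
      n_assigned = summ$counts$n_assigned,
      male_fraction_pct = summ$counts$male_fraction_pct)
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
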