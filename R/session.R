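#' Read a recording-session configuration
#'
#' A session bundles the multichannel audio, the trajectory table, the
#' microphone geometry and the two sampling rates. The YAML schema is:
#'
#' ```yaml
#' session_id: "2026-01-01_pair01"
#' audio: "session.wav"          # multichannel WAV
#' tracks: "tracks.csv"          # trajectory table
#' frame_rate: 30                # optional, frames/s
#' sample_rate: 250000           # optional, samples/s
#' arena: [0.762, 0.762]         # optional, metres
#' mic_positions:                # list of [x, y] in metres
#'   - [0.0, 0.0]
#'   - ...
#' ```
#'
#' Relative paths are resolved against the config file's directory. Omitted
#' `frame_rate` / `sample_rate` / `arena` / `mic_positions` fall back to
#' 30 fps, 250 kHz, the 0.762 m square cage, and the default 8-microphone
#' perimeter arrangement.
#'
#' @param config_path path to the YAML file.
#' @return an object of class `session_bundle`.
#' @export
read_session <- function(config_path) {
  if (!file.exists(config_path)) {
    stop_usv("config file '%s' does not exist", config_path,
             class = "usvdyad_schema_error")
  }
  cfg <- yaml::read_yaml(config_path)
  for (key in c("session_id", "audio", "tracks")) {
    if (is.null(cfg[[key]])) {
      stop_usv("config is missing required key '%s'", key,
               class = "usvdyad_schema_error")
    }
  }
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  arena <- as.numeric(cfg$arena %||% c(0.762, 0.762))
  geometry <- if (is.null(cfg$mic_positions)) {
    default_array_geometry(arena)
  } else {
    mic_array_geometry(cfg$mic_positions, arena)
  }
  bundle <- structure(list(
    session_id = as.character(cfg$session_id),
    audio = resolve(cfg$audio),
    tracks = resolve(cfg$tracks),
    geometry = geometry,
    frame_rate = as.numeric(cfg$frame_rate %||% 30),
    sample_rate = as.numeric(cfg$sample_rate %||% 250000)
  ), class = "session_bundle")
  validate_session(bundle)
  bundle
}

validate_session <- function(bundle) {
  if (!file.exists(bundle$audio)) {
    stop_usv("audio file '%s' does not exist", bundle$audio,
             class = "usvdyad_schema_error")
  }
  if (!file.exists(bundle$tracks)) {
    stop_usv("trajectory file '%s' does not exist", bundle$tracks,
             class = "usvdyad_schema_error")
  }
  info <- wav_info(bundle$audio)
  n_mics <- nrow(bundle$geometry$mic_positions)
  if (info$n_channels != n_mics) {
    stop_usv("audio has %d channels but geometry has %d microphones",
             info$n_channels, n_mics, class = "usvdyad_format_error")
  }
  tracks <- read_tracks(bundle$tracks, bundle$frame_rate)
  nfr <- max(vapply(tracks, n_frames, 1L))
  # allow one frame of slack between video span and audio span
  if ((nfr - 1) * bundle$sample_rate / bundle$frame_rate >
        info$n_samples + bundle$sample_rate / bundle$frame_rate) {
    stop_usv("trajectory (%d frames) extends past the audio (%d samples)",
             nfr, info$n_samples, class = "usvdyad_format_error")
  }
  invisible(bundle)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle '%s': %g Hz audio, %g fps tracks>\n",
              x$session_id, x$sample_rate, x$frame_rate))
  invisible(x)
}

#' Write a session configuration YAML
#'
#' Convenience writer used by the simulator and tests; inverse of
#' [read_session()].
#'
#' @param bundle a `session_bundle` (or list with the same fields).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  cfg <- list(
    session_id = bundle$session_id,
    audio = bundle$audio,
    tracks = bundle$tracks,
    frame_rate = bundle$frame_rate,
    sample_rate = bundle$sample_rate,
    arena = as.numeric(bundle$geometry$arena),
    mic_positions = lapply(seq_len(nrow(bundle$geometry$mic_positions)),
                           function(i) as.numeric(bundle$geometry$mic_positions[i, ]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
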