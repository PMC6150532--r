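#' An emission event for the audio simulator
#'
#' @param emitter_id mouse id.
#' @param onset_s onset time, seconds (>= 0).
#' @param duration_s duration, seconds (typical USVs: 0.010-0.030).
#' @param f_start_hz,f_end_hz chirp start/end frequencies, Hz, inside the
#'   30-110 kHz analysis band.
#' @param amplitude source level, arbitrary units.
#' @return an `emission_event` (one-row data frame).
#' @export
emission_event <- function(emitter_id, onset_s, duration_s,
                           f_start_hz, f_end_hz, amplitude = 1) {
  ev <- data.frame(emitter_id = as.character(emitter_id),
                   onset_s = onset_s, duration_s = duration_s,
                   f_start_hz = f_start_hz, f_end_hz = f_end_hz,
                   amplitude = amplitude, stringsAsFactors = FALSE)
  if (any(ev$onset_s < 0) || any(ev$duration_s <= 0)) {
    stop_usv("onset must be >= 0 and duration > 0",
             class = "usvdyad_validation_error")
  }
  f <- c(ev$f_start_hz, ev$f_end_hz)
  if (any(f < 30000) || any(f > 110000)) {
    stop_usv("chirp frequencies must lie in the 30-110 kHz band",
             class = "usvdyad_validation_error")
  }
  class(ev) <- c("emission_event", "data.frame")
  ev
}

#' Synthesize a single USV as a linear-FM chirp
#'
#' Instantaneous frequency moves linearly from `f_start_hz` to `f_end_hz`
#' over the event duration; the envelope has raised-cosine on/off ramps of
#' `ramp_s` seconds at each end (capped at 20% of the duration), matching
#' the fast on/offsets of recorded USVs while avoiding spectral splatter.
#'
#' @param event an [emission_event()] (single row).
#' @param sample_rate samples per second; must be at least 2.2 x the highest
#'   chirp frequency.
#' @param ramp_s amplitude ramp duration at each end, seconds.
#' @return numeric waveform of `round(duration_s * sample_rate)` samples.
#' @export
synth_usv <- function(event, sample_rate, ramp_s = 0.001) {
  fmax <- max(event$f_start_hz, event$f_end_hz)
  if (sample_rate < 2.2 * fmax) {
    stop_usv("sample rate %g too low for %g Hz (need >= %g)",
             sample_rate, fmax, 2.2 * fmax, class = "usvdyad_validation_error")
  }
  n <- round(event$duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  k <- (event$f_end_hz - event$f_start_hz) / event$duration_s
  phase <- 2 * pi * (event$f_start_hz * t + 0.5 * k * t^2)
  env <- rep(1, n)
  nr <- max(1L, round(min(ramp_s, 0.2 * event$duration_s) * sample_rate))
  ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  env[seq_len(nr)] <- ramp
  env[n + 1L - seq_len(nr)] <- ramp
  event$amplitude * env * sin(phase)
}

#' Render emission events into multichannel microphone-array audio
#'
#' Free-field propagation: each event is a point source at the emitter's
#' nose position at onset; every microphone receives the chirp delayed by
#' distance / 343 m/s and attenuated by 1/distance, plus independent
#' Gaussian noise.
#'
#' @param tracks named list of two [mouse_track()].
#' @param events data frame of [emission_event()] rows.
#' @param geometry a [mic_array_geometry()].
#' @param sample_rate samples per second (default 250000).
#' @param noise_sd per-channel Gaussian noise standard deviation (0 = none).
#' @param duration_s total audio length; defaults to the track duration.
#' @param seed RNG seed for the noise.
#' @param speed_of_sound m/s.
#' @return list with `samples` (matrix, samples x microphones),
#'   `sample_rate`, and `truth` (per-event ground-truth table with the true
#'   source coordinates).
#' @export
simulate_array_audio <- function(tracks, events, geometry,
                                 sample_rate = 250000, noise_sd = 0,
                                 duration_s = NULL, seed = NULL,
                                 speed_of_sound = 343) {
  frame_rate <- tracks[[1]]$frame_rate
  track_dur <- n_frames(tracks[[1]]) / frame_rate
  duration_s <- duration_s %||% track_dur
  n <- round(duration_s * sample_rate)
  mics <- geometry$mic_positions
  n_mic <- nrow(mics)
  samples <- matrix(0, n, n_mic)

  truth <- data.frame(event_id = seq_len(nrow(events)),
                      emitter = events$emitter_id,
                      onset_s = events$onset_s,
                      duration_s = events$duration_s,
                      f_start_hz = events$f_start_hz,
                      f_end_hz = events$f_end_hz,
                      amplitude = events$amplitude,
                      x = NA_real_, y = NA_real_,
                      stringsAsFactors = FALSE)

  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$emitter_id %in% names(tracks)) {
      stop_usv("event %d: emitter '%s' has no track", i, ev$emitter_id,
               class = "usvdyad_validation_error")
    }
    if (ev$onset_s + ev$duration_s > track_dur) {
      stop_usv("event %d extends past the track duration", i,
               class = "usvdyad_validation_error")
    }
    frame <- floor(ev$onset_s * frame_rate)
    src <- nose_position(tracks[[ev$emitter_id]], frame)
    if (src[1] < 0 || src[1] > geometry$arena[1] ||
        src[2] < 0 || src[2] > geometry$arena[2]) {
      stop_usv("event %d: source (%.3f, %.3f) outside the arena", i,
               src[1], src[2], class = "usvdyad_validation_error")
    }
    truth$x[i] <- src[1]; truth$y[i] <- src[2]
    wave <- synth_usv(ev, sample_rate)
    for (m in seq_len(n_mic)) {
      d <- sqrt(sum((src - mics[m, ])^2))
      d <- max(d, 1e-3)
      lag <- round((ev$onset_s + d / speed_of_sound) * sample_rate)
      idx <- lag + seq_along(wave)
      keep <- idx >= 1L & idx <= n
      samples[idx[keep], m] <- samples[idx[keep], m] + wave[keep] / d
    }
  }

  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(n * n_mic, sd = noise_sd))
    samples <- samples + matrix(noise, n, n_mic)
  }
  list(samples = samples, sample_rate = sample_rate, truth = truth)
}
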