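# Shared fixtures, generated once per test run and cached across files.
.fixture_cache <- new.env(parent = emptyenv())

# Small simulated dyad session with the pipeline run end to end:
# 5 noise-free chirps, segmentation + localization executed once.
tiny_run <- function() {
  if (is.null(.fixture_cache$tiny)) {
    dir <- file.path(tempdir(), "usvdyad_tiny_fixture")
    sim <- simulate_session(dir, n_events = 5, noise_sd = 0, seed = 11)
    aud <- read_wav(sim$bundle$audio)
    seg <- suppressWarnings(segment_audio(aud$samples, aud$sample_rate))
    tracks <- read_tracks(sim$bundle$tracks)
    filtered <- bandpass_usv(aud$samples, aud$sample_rate)
    loc <- localize_signals(seg$signals, filtered, sim$bundle$geometry,
                            aud$sample_rate, tracks)
    .fixture_cache$tiny <- list(sim = sim, audio = aud$samples,
                                sample_rate = aud$sample_rate,
                                signals = seg$signals, mask = seg$mask,
                                filtered = filtered, tracks = tracks,
                                loc = loc)
  }
  .fixture_cache$tiny
}

# Straight-line track moving along +x at `speed` m/s.
line_track <- function(id, n, x0 = 0.1, y0 = 0.3, speed = 0.25,
                       frame_rate = 30) {
  x <- x0 + (seq_len(n) - 1) * speed / frame_rate
  mouse_track(id, x, rep(y0, n), 0.08, 0.03, rep(0, n), frame_rate)
}

# Stationary track at a point.
still_track <- function(id, n, x, y, heading = 0, frame_rate = 30) {
  mouse_track(id, rep(x, n), rep(y, n), 0.08, 0.03, rep(heading, n),
              frame_rate)
}

# Hand-built vocal_signal with a given contour (for feature-level tests).
fake_signal <- function(contour, id = 1L, start_s = min(contour$time_s),
                        stop_s = max(contour$time_s)) {
  structure(list(id = id, start_s = start_s, stop_s = stop_s,
                 n_pixels = nrow(contour), pixels = NULL,
                 contour = contour, harmonic_flag = FALSE),
            class = "vocal_signal")
}

# Tie-free samples of size n vs n realizing a prescribed U statistic.
samples_with_u <- function(n, U) {
  s <- seq_len(n)
  extra <- U
  for (i in n:1) {
    add <- min(n, extra)
    s[i] <- s[i] + add
    extra <- extra - add
  }
  list(x = s, y = setdiff(seq_len(2 * n), s))
}

# S1-style synthetic feature table with moderate counts (cached).
synthetic_table <- function() {
  if (is.null(.fixture_cache$table)) {
    .fixture_cache$table <- simulate_feature_table(seed = 101)
  }
  .fixture_cache$table
}
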