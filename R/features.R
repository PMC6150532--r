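#' Contour-derived acoustic features
#'
#' From a frequency contour: high frequency = maximum contour frequency,
#' low = minimum, bandwidth = high - low, duration = last minus first
#' contour time, mean fundamental frequency = power-weighted mean of the
#' contour frequencies.
#'
#' @param contour data frame with `time_s`, `freq_hz`, `power`.
#' @return named list: `bandwidth_hz`, `duration_ms`, `high_freq_hz`,
#'   `low_freq_hz`, `mean_freq_hz`, `degenerate` (TRUE for single-point
#'   contours).
#' @export
contour_features <- function(contour) {
  if (is.null(contour) || nrow(contour) == 0L) {
    stop_usv("empty contour", class = "usvdyad_validation_error")
  }
  high <- max(contour$freq_hz)
  low <- min(contour$freq_hz)
  w <- contour$power
  mean_f <- if (sum(w) > 0) sum(w * contour$freq_hz) / sum(w) else mean(contour$freq_hz)
  list(bandwidth_hz = high - low,
       duration_ms = (max(contour$time_s) - min(contour$time_s)) * 1000,
       high_freq_hz = high, low_freq_hz = low, mean_freq_hz = mean_f,
       degenerate = nrow(contour) < 2L)
}

#' Contour slope by robust linear regression
#'
#' Change of frequency over time, estimated as the slope of an
#' iteratively-reweighted least-squares line (Tukey bisquare weights,
#' tuning constant 4.685, at most 50 iterations) of frequency on time, so
#' isolated contour outliers do not drag the fit. Falls back to ordinary
#' least squares when the residual scale is numerically zero (an exact
#' line, where both estimators coincide).
#'
#' @param contour data frame with `time_s` and `freq_hz` (>= 3 points).
#' @return slope in Hz/s, or `NA` (with a warning) for contours shorter
#'   than 3 points.
#' @export
contour_slope <- function(contour) {
  if (nrow(contour) < 3L) {
    warning("contour has fewer than 3 points; slope undefined")
    return(NA_real_)
  }
  t <- contour$time_s
  f <- contour$freq_hz
  ols <- lm(f ~ t)
  if (mad(stats::residuals(ols)) <= 1e-9 * max(1, diff(range(f)))) {
    return(unname(coef(ols)[2]))
  }
  fit <- tryCatch(
    MASS::rlm(f ~ t, psi = MASS::psi.bisquare, c = 4.685, maxit = 50),
    error = function(e) ols)
  unname(coef(fit)[2])
}

# least-squares sine fit at fixed frequency: amplitude (= peak - midpoint),
# phase and offset are linear given f
sine_ls <- function(trace, t, f) {
  X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t), 1)
  fit <- stats::lm.fit(X, trace)
  list(amplitude = sqrt(sum(coef(fit)[1:2]^2)),
       rss = sum(fit$residuals^2))
}

#' Signal amplitude from per-channel sine fits
#'
#' For each microphone channel, the raw voltage trace over the signal's
#' start-stop interval is fitted with a single sine wave (free amplitude,
#' frequency, phase and offset); the channel's amplitude is the fitted
#' wave's peak minus its midpoint, i.e. the sine's amplitude coefficient.
#' The signal amplitude is the largest value across channels.
#'
#' The non-convex frequency search is initialized at the magnitude peak of
#' a zero-padded FFT near the signal's mean contour frequency and refined
#' by golden-section search on the exact least-squares objective.
#'
#' @param signal a `vocal_signal` (contour supplies the frequency init).
#' @param audio raw (unfiltered) audio matrix, samples x channels.
#' @param sample_rate Hz.
#' @param search_frac half-width of the frequency search window as a
#'   fraction of the initial frequency.
#' @return amplitude in the audio's voltage units (mV when the recording is
#'   calibrated in mV); `NA` if every channel fails.
#' @export
signal_amplitude <- function(signal, audio, sample_rate, search_frac = 0.06) {
  i0 <- max(1L, floor(signal$start_s * sample_rate) + 1L)
  i1 <- min(nrow(audio), ceiling(signal$stop_s * sample_rate))
  if (i1 <= i0) return(NA_real_)
  w <- contour_weighted_mean(signal$contour)
  n <- i1 - i0 + 1L
  t <- (seq_len(n) - 1) / sample_rate
  amps <- vapply(seq_len(ncol(audio)), function(ch) {
    trace <- audio[i0:i1, ch]
    if (sd(trace) == 0) return(0)
    nfft <- nextn(8L * n, 2)
    spec <- Mod(fft(c(trace - mean(trace), numeric(nfft - n))))
    freqs <- (0:(nfft %/% 2L)) * sample_rate / nfft
    lo <- w * (1 - search_frac); hi <- w * (1 + search_frac)
    sel <- which(freqs >= lo & freqs <= hi)
    if (!length(sel)) sel <- which.min(abs(freqs - w))
    f_init <- freqs[sel[which.max(spec[sel])]]
    half <- max(sample_rate / nfft, 1 / (4 * n / sample_rate))
    opt <- optimize(function(f) sine_ls(trace, t, f)$rss,
                    lower = f_init - 2 * half, upper = f_init + 2 * half,
                    tol = 1e-3)
    a <- sine_ls(trace, t, opt$minimum)$amplitude
    if (is.finite(a)) a else NA_real_
  }, 1)
  if (all(is.na(amps))) return(NA_real_)
  max(amps, na.rm = TRUE)
}

contour_weighted_mean <- function(contour) {
  w <- contour$power
  if (sum(w) > 0) sum(w * contour$freq_hz) / sum(w) else mean(contour$freq_hz)
}

#' Build the per-signal feature table
#'
#' Combines contour features, robust slope and sine-fit amplitude with the
#' localization assignments into an S1-compatible [feature_table].
#' Harmonic-stack signals already carry the fundamental's contour
#' (see [resolve_harmonics()]), so all features refer to the fundamental.
#'
#' @param signals list of `vocal_signal`.
#' @param audio raw audio matrix (samples x channels) for the amplitude fit.
#' @param sample_rate Hz.
#' @param assignments data frame from [localize_signals()] (or NULL: all
#'   rows unassigned).
#' @param session_id recording identifier.
#' @return a `feature_table`, one row per signal, context unset.
#' @export
compute_features <- function(signals, audio, sample_rate,
                             assignments = NULL, session_id = "session01") {
  rows <- lapply(signals, function(sg) {
    cf <- contour_features(sg$contour)
    data.frame(
      session_id = session_id,
      voc_number = sg$id,
      emitter = NA_character_,
      bandwidth_hz = cf$bandwidth_hz,
      duration_ms = cf$duration_ms,
      high_freq_hz = cf$high_freq_hz,
      low_freq_hz = cf$low_freq_hz,
      mean_freq_hz = cf$mean_freq_hz,
      slope_hz_per_s = suppressWarnings(contour_slope(sg$contour)),
      amplitude_mv = signal_amplitude(sg, audio, sample_rate),
      context = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (!is.null(assignments)) {
    df$emitter <- assignments$assigned_to[match(df$voc_number,
                                                assignments$signal_id)]
  }
  as_feature_table(df)
}
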