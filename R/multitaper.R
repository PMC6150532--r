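#' Multitaper spectrogram with Thomson's harmonic F-test
#'
#' Slides a window of `nfft` samples (hop = `nfft/2`, 50% overlap) along one
#' audio channel, computes the `k` DPSS eigencoefficients per window, and
#' for every time-frequency bin in the analysis band returns the multitaper
#' power estimate together with Thomson's F statistic for a sinusoidal line
#' component, distributed F(2, 2k-2) under the locally-white noise null.
#' Bins with numerically zero energy (exact silence) get F = 0 and are never
#' significant.
#'
#' @param x one channel of (already bandpass-filtered) audio.
#' @param sample_rate samples per second.
#' @param nfft window length in samples.
#' @param k,nw taper count and time-bandwidth product.
#' @param band analysis band in Hz (default 30-110 kHz).
#' @param hop hop size in samples; default `nfft / 2`.
#' @return a `tf_ftest` list: `freq` (Hz, bins inside the band), `time`
#'   (window centres, s), `fstat` and `power` (freq x time matrices),
#'   `df` (the F degrees of freedom), `nfft`, `hop`, `sample_rate`.
#' @export
multitaper_ftest <- function(x, sample_rate, nfft, k = 5, nw = 3,
                             band = c(30000, 110000), hop = nfft %/% 2L) {
  n <- length(x)
  if (nfft > n) {
    stop_usv("nfft (%d) exceeds the audio length (%d)", nfft, n,
             class = "usvdyad_validation_error")
  }
  tapers <- dpss_tapers(nfft, k, nw)
  starts <- seq.int(1L, n - nfft + 1L, by = hop)
  n_win <- length(starts)
  seg <- matrix(x[outer(0:(nfft - 1L), starts, "+")], nfft, n_win)

  freq_all <- (0:(nfft %/% 2L)) * sample_rate / nfft
  sel <- which(freq_all >= band[1] & freq_all <= band[2])
  u0 <- colSums(tapers)
  sum_u0_sq <- sum(u0^2)

  num <- matrix(0 + 0i, length(sel), n_win)    # sum_k y_k * U_k(0)
  pow <- matrix(0, length(sel), n_win)
  ssq <- matrix(0, length(sel), n_win)         # sum_k |y_k|^2
  eig <- vector("list", k)
  for (j in seq_len(k)) {
    y <- mvfft(seg * tapers[, j])[sel, , drop = FALSE]
    eig[[j]] <- y
    num <- num + y * u0[j]
    pow <- pow + Re(y * Conj(y))
  }
  mu <- num / sum_u0_sq
  resid <- matrix(0, length(sel), n_win)
  for (j in seq_len(k)) {
    d <- eig[[j]] - mu * u0[j]
    resid <- resid + Re(d * Conj(d))
  }
  line_pow <- Re(mu * Conj(mu)) * sum_u0_sq
  fstat <- (k - 1) * line_pow / resid
  fstat[!is.finite(fstat)] <- 0               # exact silence -> never significant
  power <- pow / k

  structure(list(freq = freq_all[sel],
                 time = (starts - 1 + nfft / 2) / sample_rate,
                 fstat = fstat, power = power,
                 df = c(2, 2 * k - 2), nfft = nfft, hop = hop,
                 sample_rate = sample_rate, band = band),
            class = "tf_ftest")
}

#' Significance mask of an F-test spectrogram
#'
#' @param tf a `tf_ftest`.
#' @param alpha per-bin significance level (default 0.05).
#' @return logical freq x time matrix.
#' @export
ftest_mask <- function(tf, alpha = 0.05) {
  tf$fstat > stats::qf(1 - alpha, tf$df[1], tf$df[2])
}

#' Bandpass-filter audio to the USV analysis band
#'
#' 4th-order Butterworth applied forward-backward (zero phase) per channel.
#'
#' @param samples matrix (samples x channels) or vector.
#' @param sample_rate Hz.
#' @param band passband in Hz.
#' @return filtered data, same shape.
#' @export
bandpass_usv <- function(samples, sample_rate, band = c(30000, 110000)) {
  ny <- sample_rate / 2
  hi <- min(band[2] / ny, 0.99)
  bf <- signal::butter(4, c(band[1] / ny, hi), type = "pass")
  if (is.matrix(samples)) {
    apply(samples, 2, function(ch) signal::filtfilt(bf, ch))
  } else {
    signal::filtfilt(bf, samples)
  }
}
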