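#' Time difference of arrival between two channels (GCC-PHAT)
#'
#' Generalized cross-correlation with phase transform: the cross-spectrum is
#' whitened to unit magnitude, so the correlation peak depends only on the
#' relative delay. The peak is refined to sub-sample precision by parabolic
#' interpolation.
#'
#' @param x,y traces from the two microphones over the signal interval.
#' @param sample_rate Hz.
#' @param max_lag_s largest physically possible |delay| in seconds (arena
#'   diagonal / speed of sound); the search is restricted to it.
#' @return delay in seconds such that `y` lags `x` by the returned amount
#'   (positive = the source is closer to `x`'s microphone).
#' @export
gcc_phat <- function(x, y, sample_rate, max_lag_s) {
  n <- length(x)
  max_lag <- ceiling(max_lag_s * sample_rate)
  nfft <- nextn(n + max_lag, 2)
  X <- fft(c(x, numeric(nfft - n)))
  Y <- fft(c(y, numeric(nfft - n)))
  G <- Conj(X) * Y   # peak at +d when y(t) = x(t - d)
  mag <- Mod(G)
  w <- G / pmax(mag, 1e-12 * max(mag, 1e-300))
  r <- Re(fft(w, inverse = TRUE)) / nfft
  # lag k (y delayed by k relative to x) lives at index k+1 (mod nfft)
  lags <- c(0:max_lag, -(max_lag:1))
  idx <- c(1:(max_lag + 1L), nfft - (max_lag:1) + 1L)
  r_win <- r[idx]
  best <- which.max(r_win)
  lag <- lags[best]
  # parabolic refinement around the peak
  get_r <- function(l) r[(l %% nfft) + 1L]
  y0 <- get_r(lag - 1L); y1 <- get_r(lag); y2 <- get_r(lag + 1L)
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
  (lag + max(min(delta, 0.5), -0.5)) / sample_rate
}

# slice the audio matrix around a signal, with propagation margin
signal_traces <- function(signal, audio, sample_rate, margin_s = 0.004) {
  i0 <- max(1L, floor((signal$start_s - margin_s) * sample_rate))
  i1 <- min(nrow(audio), ceiling((signal$stop_s + margin_s) * sample_rate))
  audio[i0:i1, , drop = FALSE]
}

#' Planar source location from one microphone subset
#'
#' Measures GCC-PHAT delays for every microphone pair in the subset and
#' solves for the source position by nonlinear least squares on the delay
#' residuals (multi-start Nelder-Mead over the arena, estimate clamped to
#' the arena bounds).
#'
#' @param traces matrix (samples x microphones in the subset), already
#'   bandpass filtered, covering the signal plus propagation margin.
#' @param mic_positions subset microphone coordinates (n x 2, metres).
#' @param geometry the full [mic_array_geometry()] (for arena bounds).
#' @param sample_rate Hz.
#' @param speed_of_sound m/s.
#' @return `c(x, y)` with attribute `valid` (FALSE when the traces carry no
#'   signal).
#' @export
point_estimate <- function(traces, mic_positions, geometry, sample_rate,
                           speed_of_sound = 343) {
  n_mic <- nrow(mic_positions)
  if (n_mic < 4L) {
    stop_usv("need at least 4 microphones", class = "usvdyad_validation_error")
  }
  if (all(abs(traces) < 1e-12)) {
    out <- c(NA_real_, NA_real_)
    attr(out, "valid") <- FALSE
    return(out)
  }
  arena <- geometry$arena
  max_lag_s <- sqrt(sum(arena^2)) / speed_of_sound
  pairs <- which(upper.tri(matrix(0, n_mic, n_mic)), arr.ind = TRUE)
  tdoa <- apply(pairs, 1, function(pr) {
    gcc_phat(traces[, pr[1]], traces[, pr[2]], sample_rate, max_lag_s)
  })
  obj <- function(p) {
    d <- sqrt((mic_positions[, 1] - p[1])^2 + (mic_positions[, 2] - p[2])^2)
    # y lagging x by tau means mic i is closer: tau = (d_j - d_i) / c
    pred <- (d[pairs[, 2]] - d[pairs[, 1]]) / speed_of_sound
    sum((pred - tdoa)^2)
  }
  starts <- rbind(arena / 2,
                  expand.grid(x = arena[1] * c(0.25, 0.75),
                              y = arena[2] * c(0.25, 0.75)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out <- pmin(pmax(best$par, 0), arena)
  attr(out, "valid") <- TRUE
  out
}

#' Jackknife localization of one vocal signal
#'
#' Omits each microphone in turn and re-estimates the source from the
#' remaining microphones ([point_estimate()]), giving one estimate per
#' microphone. The overall source estimate is the coordinate-wise mean of
#' the leave-one-out points; the uncertainty is summarized as a bivariate
#' normal density centred there with covariance equal to the jackknife
#' scatter inflated by (m-1)^2/m, floored at `floor_sd` per axis so
#' coincident points never yield a singular density.
#'
#' @param signal a `vocal_signal`.
#' @param audio full bandpass-filtered audio matrix (samples x mics).
#' @param geometry a [mic_array_geometry()].
#' @param sample_rate Hz.
#' @param floor_sd minimum density standard deviation, metres (default 1 cm).
#' @param speed_of_sound m/s.
#' @return a `localization_result`: `signal_id`, `jack_points` (m x 2),
#'   `estimate`, `cov`, `valid` (FALSE when more than 2 leave-one-out
#'   estimates failed).
#' @export
jackknife_localize <- function(signal, audio, geometry, sample_rate,
                               floor_sd = 0.01, speed_of_sound = 343) {
  mics <- geometry$mic_positions
  m <- nrow(mics)
  traces <- signal_traces(signal, audio, sample_rate)
  pts <- matrix(NA_real_, m, 2)
  for (drop in seq_len(m)) {
    keep <- setdiff(seq_len(m), drop)
    est <- point_estimate(traces[, keep, drop = FALSE],
                          mics[keep, , drop = FALSE],
                          geometry, sample_rate, speed_of_sound)
    if (isTRUE(attr(est, "valid"))) pts[drop, ] <- est
  }
  ok <- stats::complete.cases(pts)
  res <- list(signal_id = signal$id, jack_points = pts,
              estimate = c(NA_real_, NA_real_),
              cov = diag(floor_sd^2, 2), valid = sum(!ok) <= 2)
  if (sum(ok) >= 2) {
    used <- pts[ok, , drop = FALSE]
    res$estimate <- colMeans(used)
    k <- nrow(used)
    cv <- stats::cov(used) * (k - 1)^2 / k
    eg <- eigen(cv, symmetric = TRUE)
    vals <- pmax(eg$values, floor_sd^2)
    res$cov <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  } else if (sum(ok) == 1) {
    res$estimate <- pts[ok, ]
  } else {
    res$valid <- FALSE
  }
  class(res) <- "localization_result"
  res
}

# bivariate normal density
dmvnorm2 <- function(x, mean, cov) {
  d <- x - mean
  det <- cov[1, 1] * cov[2, 2] - cov[1, 2] * cov[2, 1]
  q <- (d[1]^2 * cov[2, 2] - 2 * d[1] * d[2] * cov[1, 2] +
          d[2]^2 * cov[1, 1]) / det
  exp(-q / 2) / (2 * pi * sqrt(det))
}

#' Mouse probability index and signal assignment
#'
#' Evaluates the localization density at each mouse's nose position (the
#' density value D_n), normalizes to the mouse probability index
#' MPI_n = D_n / sum_i D_i, and assigns the signal to a mouse only when its
#' MPI strictly exceeds `threshold` (default 0.95).
#'
#' @param result a `localization_result`.
#' @param nose_positions matrix (mice x 2) with rownames = mouse ids, or a
#'   named list of `c(x, y)`.
#' @param threshold assignment threshold on MPI (strict inequality).
#' @return the result augmented with `D` (per-mouse density values), `mpi`,
#'   `assigned_to` (mouse id or `NA`) and `underflow` flag.
#' @export
assign_mpi <- function(result, nose_positions, threshold = 0.95) {
  if (is.list(nose_positions) && !is.matrix(nose_positions)) {
    nose_positions <- do.call(rbind, nose_positions)
  }
  ids <- rownames(nose_positions) %||% paste0("mouse", seq_len(nrow(nose_positions)))
  if (!result$valid || anyNA(result$estimate)) {
    result$D <- stats::setNames(rep(NA_real_, nrow(nose_positions)), ids)
    result$mpi <- result$D
    result$assigned_to <- NA_character_
    result$underflow <- FALSE
    return(result)
  }
  D <- vapply(seq_len(nrow(nose_positions)), function(i) {
    dmvnorm2(as.numeric(nose_positions[i, ]), result$estimate, result$cov)
  }, 1)
  names(D) <- ids
  result$D <- D
  if (!any(D > 0)) {
    result$mpi <- D * NA
    result$assigned_to <- NA_character_
    result$underflow <- TRUE
    return(result)
  }
  mpi <- D / sum(D)
  result$mpi <- mpi
  result$underflow <- FALSE
  top <- which.max(mpi)
  tied <- sum(mpi == mpi[top]) > 1L
  result$assigned_to <- if (!tied && mpi[top] > threshold) ids[top] else NA_character_
  result
}

#' Localize and assign every signal in a recording
#'
#' Runs [jackknife_localize()] + [assign_mpi()] per signal, using each
#' mouse's nose position at the signal's onset frame.
#'
#' @param signals list of `vocal_signal`.
#' @param audio bandpass-filtered audio matrix (samples x mics).
#' @param geometry a [mic_array_geometry()].
#' @param sample_rate Hz.
#' @param tracks named list of [mouse_track()].
#' @param threshold MPI assignment threshold.
#' @param floor_sd density floor, metres.
#' @return data frame: signal_id, x, y, one `mpi_<id>` column per mouse,
#'   assigned_to (NA when unassigned).
#' @export
localize_signals <- function(signals, audio, geometry, sample_rate, tracks,
                             threshold = 0.95, floor_sd = 0.01) {
  frame_rate <- tracks[[1]]$frame_rate
  rows <- lapply(signals, function(sg) {
    res <- jackknife_localize(sg, audio, geometry, sample_rate, floor_sd)
    frame <- min(floor(sg$start_s * frame_rate),
                 n_frames(tracks[[1]]) - 1L)
    noses <- do.call(rbind, lapply(tracks, nose_position, frame = frame))
    rownames(noses) <- names(tracks)
    res <- assign_mpi(res, noses, threshold)
    out <- data.frame(signal_id = sg$id, x = res$estimate[1],
                      y = res$estimate[2], assigned_to = res$assigned_to,
                      stringsAsFactors = FALSE)
    for (id in names(tracks)) out[[paste0("mpi_", id)]] <- unname(res$mpi[id])
    out
  })
  do.call(rbind, rows)
}
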