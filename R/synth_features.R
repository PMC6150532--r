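#' Per-sex feature distributions for the table simulator
#'
#' Location/scale parameters of the per-sex acoustic-feature distributions.
#' Strictly positive features (bandwidth, duration, low frequency,
#' amplitude) are log-normal, parameterized by their median and quartiles;
#' slope, the one signed feature, is a two-piece (asymmetric) Laplace
#' matched to its median and both quartiles. High frequency is derived as
#' low + bandwidth (so the bandwidth identity holds by construction) and
#' mean frequency as low + u * bandwidth with u ~ Beta(2, 2).
#'
#' Defaults reproduce the pooled per-sex medians and interquartile ranges
#' reported for 13 male-female dyads: e.g. median bandwidth 7.9 kHz (males)
#' vs 6.1 kHz (females), median duration 17.2 vs 17.9 ms, median low
#' frequency 66.4 vs 66.6 kHz, median amplitude 48.6 vs 45.0 mV, and slope
#' medians of opposite sign (-4.0 kHz/s males, +6.4 kHz/s females).
#'
#' @param male,female named lists of per-feature parameters; each positive
#'   feature is `c(q25, median, q75)` in the table's units, slope is
#'   `c(q25, median, q75)` in Hz/s.
#' @return a `sex_effect_spec` object.
#' @export
sex_effect_spec <- function(
    male = list(bandwidth_hz  = c(5100, 7900, 12000),
                duration_ms   = c(12.7, 17.2, 25.9),
                low_freq_hz   = c(61500, 66400, 73400),
                amplitude_mv  = c(33.4, 48.6, 74.1),
                slope_hz_per_s = c(-29000, -4000, 32000)),
    female = list(bandwidth_hz  = c(4100, 6100, 9400),
                  duration_ms   = c(12.9, 17.9, 27.5),
                  low_freq_hz   = c(61500, 66600, 74100),
                  amplitude_mv  = c(30.9, 45.0, 70.3),
                  slope_hz_per_s = c(-7800, 6400, 28000))) {
  for (sex in list(male, female)) {
    for (feat in names(sex)) {
      q <- sex[[feat]]
      if (length(q) != 3L || q[1] >= q[3]) {
        stop_usv("feature '%s': need q25 < q75", feat,
                 class = "usvdyad_validation_error")
      }
      if (feat != "slope_hz_per_s" && any(q <= 0)) {
        stop_usv("feature '%s': quartiles must be positive", feat,
                 class = "usvdyad_validation_error")
      }
      if (q[1] > q[2] || q[2] > q[3]) {
        stop_usv("feature '%s': quartiles must be ordered", feat,
                 class = "usvdyad_validation_error")
      }
    }
  }
  structure(list(male = male, female = female), class = "sex_effect_spec")
}

# log-normal draw matched to (q25, median, q75): meanlog = log(median),
# sdlog from the quartile ratio
rlnorm_quartiles <- function(n, q) {
  sdlog <- log(q[3] / q[1]) / (2 * qnorm(0.75))
  rlnorm(n, meanlog = log(q[2]), sdlog = sdlog)
}

# two-piece Laplace: median q[2], exponential tails scaled so that the 25th
# and 75th percentiles equal q[1] and q[3]
rlaplace2_quartiles <- function(n, q) {
  b_lower <- (q[2] - q[1]) / log(2)
  b_upper <- (q[3] - q[2]) / log(2)
  side <- runif(n) < 0.5
  e <- rexp(n)
  ifelse(side, q[2] - e * b_lower, q[2] + e * b_upper)
}

# default context mixture per sex, proportional to the behavioral-context
# vocalization counts observed in the study (incl. signals in no context)
default_context_probs <- function() {
  list(male   = c(not_close = 5013, followed = 137, following = 3386,
                  other = 32290 - 5013 - 137 - 3386) / 32290,
       female = c(not_close = 51, followed = 859, following = 16,
                  other = 5904 - 51 - 859 - 16) / 5904)
}

#' Simulate an S1-style per-vocalization feature table
#'
#' Draws per-session vocalization counts for a male-female dyad and one row
#' of acoustic features per vocalization, with the per-sex distributional
#' structure of [sex_effect_spec()]. Defaults emulate the recorded study:
#' 13 sessions; per-session male counts log-normal with median 3318 (IQR
#' 1368-3619) and female counts median 477 (IQR 202-622), coupled through a
#' Gaussian copula (rho = 0.9) so that pairs with talkative males also have
#' talkative females; males out-vocalize females in most sessions; feature
#' marginals are strongly non-Gaussian.
#'
#' @param n_sessions number of dyad recordings.
#' @param counts_per_sex list with `male = c(q25, median, q75)`,
#'   `female = c(q25, median, q75)` and `rho` (count copula correlation).
#' @param effects a [sex_effect_spec()].
#' @param context_probs per-sex context label probabilities (named list).
#' @param seed RNG seed.
#' @return a `feature_table` with emitters `M01..`/`F01..`, one session id
#'   per dyad, and context labels.
#' @export
simulate_feature_table <- function(n_sessions = 13,
                                   counts_per_sex = list(
                                     male = c(1368, 3318, 3619),
                                     female = c(202, 477, 622),
                                     rho = 0.9),
                                   effects = sex_effect_spec(),
                                   context_probs = default_context_probs(),
                                   seed = NULL) {
  for (s in c("male", "female")) {
    q <- counts_per_sex[[s]]
    if (any(q <= 0) || q[1] > q[2] || q[2] > q[3]) {
      stop_usv("counts_per_sex$%s must be ordered positive quartiles", s,
               class = "usvdyad_validation_error")
    }
  }
  with_seed(seed, {
    rho <- counts_per_sex$rho %||% 0.9
    sd_m <- log(counts_per_sex$male[3] / counts_per_sex$male[1]) /
      (2 * qnorm(0.75))
    sd_f <- log(counts_per_sex$female[3] / counts_per_sex$female[1]) /
      (2 * qnorm(0.75))
    z_m <- rnorm(n_sessions)
    z_f <- rho * z_m + sqrt(1 - rho^2) * rnorm(n_sessions)
    n_male <- pmax(1L, round(exp(log(counts_per_sex$male[2]) + sd_m * z_m)))
    n_female <- pmax(1L, round(exp(log(counts_per_sex$female[2]) + sd_f * z_f)))

    one_sex <- function(n, params, emitter, session, ctx_p) {
      bw <- pmin(rlnorm_quartiles(n, params$bandwidth_hz), 79000)
      low <- rlnorm_quartiles(n, params$low_freq_hz)
      low <- pmin(pmax(low, 30000), 110000 - bw)
      u <- stats::rbeta(n, 2, 2)
      data.frame(
        session_id = session,
        voc_number = NA_integer_,
        emitter = emitter,
        bandwidth_hz = bw,
        duration_ms = rlnorm_quartiles(n, params$duration_ms),
        high_freq_hz = low + bw,
        low_freq_hz = low,
        mean_freq_hz = low + u * bw,
        slope_hz_per_s = rlaplace2_quartiles(n, params$slope_hz_per_s),
        amplitude_mv = rlnorm_quartiles(n, params$amplitude_mv),
        context = sample(names(ctx_p), n, replace = TRUE, prob = ctx_p),
        stringsAsFactors = FALSE
      )
    }

    parts <- vector("list", 2L * n_sessions)
    for (s in seq_len(n_sessions)) {
      sid <- sprintf("session%02d", s)
      parts[[2L * s - 1L]] <- one_sex(n_male[s], effects$male,
                                      sprintf("M%02d", s), sid,
                                      context_probs$male)
      parts[[2L * s]] <- one_sex(n_female[s], effects$female,
                                 sprintf("F%02d", s), sid,
                                 context_probs$female)
    }
    df <- do.call(rbind, parts)
    df$voc_number <- seq_len(nrow(df))
    as_feature_table(df)
  })
}

#' Sex of each emitter id
#'
#' Emitter ids starting with "M"/"m" are male, "F"/"f" female; anything else
#' (including "unassigned") is `NA`.
#'
#' @param emitter character vector of emitter ids.
#' @return character vector `"male"`/`"female"`/`NA`.
#' @export
emitter_sex <- function(emitter) {
  first <- toupper(substr(as.character(emitter), 1L, 1L))
  out <- rep(NA_character_, length(emitter))
  out[first == "M"] <- "male"
  out[first == "F"] <- "female"
  out[emitter == "unassigned"] <- NA_character_
  out
}
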