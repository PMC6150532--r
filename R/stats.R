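#' Mann-Whitney U test with exact and tie-corrected approximate p-values
#'
#' Two-sided Mann-Whitney U test. When the smaller group has at most
#' `exact_max` observations and there are no ties, the p-value comes from
#' the exact permutation distribution of U; otherwise from the normal
#' approximation with tie correction and continuity correction. The z value
#' (tie- and continuity-corrected) is always reported, alongside group
#' medians and interquartile ranges.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max largest min(n1, n2) for which the exact distribution is
#'   used (default 8).
#' @return an object of class `mw_test`: `U`, `z`, `p`, `n1`, `n2`,
#'   `median1`, `iqr1`, `median2`, `iqr2`, `exact`, `degenerate`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) {
    stop_usv("both groups need at least one observation",
             class = "usvdyad_validation_error")
  }
  combined <- c(x, y)
  r <- rank(combined)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(combined)
  has_ties <- any(ties > 1L)
  degenerate <- length(ties) == 1L

  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) {
    (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
  } else 0

  use_exact <- min(n1, n2) <= exact_max && !has_ties
  p <- if (degenerate) {
    1
  } else if (use_exact) {
    stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
  } else {
    min(1, 2 * pnorm(-abs(z)))
  }
  m1 <- median_iqr(x); m2 <- median_iqr(y)
  structure(list(U = u1, z = z, p = p, n1 = n1, n2 = n2,
                 median1 = m1$median, iqr1 = c(m1$q25, m1$q75),
                 median2 = m2$median, iqr2 = c(m2$q25, m2$q75),
                 exact = use_exact && !degenerate, degenerate = degenerate),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %.1f, z = %.2f, p = %.3g (%s), n = %d vs %d\n",
    x$U, x$z, x$p, if (x$exact) "exact" else "normal approx.", x$n1, x$n2))
  cat(sprintf("  medians %.4g [%.4g-%.4g] vs %.4g [%.4g-%.4g]\n",
              x$median1, x$iqr1[1], x$iqr1[2],
              x$median2, x$iqr2[1], x$iqr2[2]))
  invisible(x)
}

#' Median and interquartile range
#'
#' Median with 25th/75th percentiles by linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param values numeric vector (non-empty).
#' @return list: `median`, `q25`, `q75`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) {
    stop_usv("median_iqr: no finite values", class = "usvdyad_validation_error")
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q25 = q[1], q75 = q[3])
}

#' Per-animal (per recording) feature medians
#'
#' One median per animal per recording session, the unit of analysis that
#' controls for unequal vocalization counts and individual variability:
#' 13 dyads give 13 male and 13 female data points.
#'
#' @param table a [feature_table] with session and emitter labels.
#' @param feature column name (e.g. "bandwidth_hz").
#' @return data frame: `session_id`, `emitter`, `sex`, `median`. Animal-
#'   sessions with no assigned signal contribute no row.
#' @export
per_animal_medians <- function(table, feature) {
  if (!feature %in% names(table)) {
    stop_usv("unknown feature '%s'", feature, class = "usvdyad_validation_error")
  }
  t2 <- table[table$emitter != "unassigned" & is.finite(table[[feature]]), ]
  if (!nrow(t2)) {
    return(data.frame(session_id = character(), emitter = character(),
                      sex = character(), median = numeric()))
  }
  agg <- stats::aggregate(t2[[feature]],
                          by = list(session_id = t2$session_id,
                                    emitter = t2$emitter),
                          FUN = median)
  names(agg)[3] <- "median"
  agg$sex <- emitter_sex(agg$emitter)
  agg[order(agg$session_id, agg$emitter), c("session_id", "emitter", "sex", "median")]
}

#' Sex-difference index of two medians
#'
#' (male - female) / (male + female): positive when the male median exceeds
#' the female median (male-driven), negative for female-driven. Requires
#' nonnegative inputs (apply the slope shift first for signed features).
#'
#' @param male_median,female_median group medians (>= 0, not both 0).
#' @return index in \[-1, 1\].
#' @export
sex_index <- function(male_median, female_median) {
  if (male_median < 0 || female_median < 0) {
    stop_usv("sex_index needs nonnegative medians (shift signed features first)",
             class = "usvdyad_validation_error")
  }
  s <- male_median + female_median
  if (s == 0) {
    stop_usv("sex_index undefined: zero denominator",
             class = "usvdyad_validation_error")
  }
  (male_median - female_median) / s
}

#' Monte-Carlo sex-difference index distribution
#'
#' Controls for the male-female sample-size imbalance: draws `n_samples`
#' independent subsamples of `sample_size` male-emitted and `sample_size`
#' female-emitted signals (without replacement within a subsample), computes
#' the per-sex medians of `feature` and the sex index for each, and counts
#' male-driven (positive) vs female-driven (negative) outcomes.
#'
#' For slope, the one signed feature, all values are first shifted by the
#' absolute value of the most negative slope over every assigned signal, so
#' the most negatively sloped signal maps to zero and the index formula
#' operates on nonnegative values while absolute differences are preserved.
#'
#' @param table a [feature_table].
#' @param feature feature column name.
#' @param n_samples number of Monte-Carlo samples (default 1000).
#' @param sample_size signals per sex per sample (default 500).
#' @param seed RNG seed.
#' @return an `index_distribution`: `feature`, `indices`, `n_samples`,
#'   `sample_size`, `n_positive`, `n_negative`, `n_zero`,
#'   `slope_shift_constant` (NA unless shifted), `seed`.
#' @export
monte_carlo_index <- function(table, feature, n_samples = 1000,
                              sample_size = 500, seed = NULL) {
  sex <- emitter_sex(table$emitter)
  vals <- table[[feature]]
  ok <- is.finite(vals) & !is.na(sex)
  males <- vals[ok & sex == "male"]
  females <- vals[ok & sex == "female"]
  if (length(males) < sample_size || length(females) < sample_size) {
    stop_usv("need >= %d signals per sex; have %d male, %d female",
             sample_size, length(males), length(females),
             class = "usvdyad_validation_error")
  }
  shift <- NA_real_
  if (grepl("slope", feature) && min(c(males, females)) < 0) {
    shift <- abs(min(c(males, females)))
    males <- males + shift
    females <- females + shift
  }
  indices <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      m <- median(males[sample.int(length(males), sample_size)])
      f <- median(females[sample.int(length(females), sample_size)])
      sex_index(m, f)
    }, 1)
  })
  structure(list(feature = feature, indices = indices,
                 n_samples = n_samples, sample_size = sample_size,
                 n_positive = sum(indices > 0),
                 n_negative = sum(indices < 0),
                 n_zero = sum(indices == 0),
                 slope_shift_constant = shift, seed = seed),
            class = "index_distribution")
}

#' @export
print.index_distribution <- function(x, ...) {
  cat(sprintf(
    "<index_distribution '%s': %d samples of %d/sex; %d male-driven, %d female-driven>\n",
    x$feature, x$n_samples, x$sample_size, x$n_positive, x$n_negative))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @return list: `r`, `p`, `n`; `r` is NA with a `degenerate` flag when
#'   either input has zero variance.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_usv("pearson_cor needs n >= 3", class = "usvdyad_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Split sessions into high and low vocalizer groups
#'
#' Sessions whose male emitted more than `threshold` signals (strictly) are
#' "high"; the paired female inherits her partner's group.
#'
#' @param male_counts named numeric vector: per-session male signal counts
#'   (names = session ids).
#' @param threshold count threshold (default 2200).
#' @return data frame: `session_id`, `male_count`, `group`.
#' @export
vocalizer_split <- function(male_counts, threshold = 2200) {
  data.frame(session_id = names(male_counts) %||%
               as.character(seq_along(male_counts)),
             male_count = as.numeric(male_counts),
             group = ifelse(male_counts > threshold, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov check against normality
#'
#' One-sample KS test of the values against a normal with the sample mean
#' and standard deviation; used to justify nonparametric tests in the run
#' report (parameters are estimated, so the p-value is approximate and
#' only read qualitatively).
#'
#' @param values numeric vector (n >= 10).
#' @return list: `p`, `statistic`, `degenerate` (TRUE for constant input,
#'   where p is NA).
#' @export
ks_nongaussian <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10L) {
    stop_usv("ks_nongaussian needs n >= 10", class = "usvdyad_validation_error")
  }
  if (sd(values) == 0) {
    return(list(p = NA_real_, statistic = NA_real_, degenerate = TRUE))
  }
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  list(p = kt$p.value, statistic = unname(kt$statistic), degenerate = FALSE)
}
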