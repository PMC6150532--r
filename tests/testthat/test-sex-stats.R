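# brute-force two-sided Mann-Whitney p by enumerating group labelings
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

test_that("Mann-Whitney exact p matches full enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- mann_whitney(x, y)
  expect_equal(res$U, 0)
  expect_true(res$exact)
  expect_equal(res$p, 0.1)                      # 2/20 labelings as extreme
  expect_equal(res$p, enumerate_mw_p(x, y))
  # a few random no-tie cases against the enumeration oracle
  set.seed(31)
  for (i in 1:4) {
    x <- rnorm(4); y <- rnorm(5) + 0.5
    expect_equal(mann_whitney(x, y)$p, enumerate_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("identical samples give z = 0, p = 1; large shifts reject", {
  x <- c(1, 2, 2, 5)
  same <- mann_whitney(x, x)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  deg <- mann_whitney(rep(3, 5), rep(3, 7))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  set.seed(40)
  big <- mann_whitney(rnorm(5000), rnorm(5000) + 1)
  expect_lt(big$p, 0.001)
  expect_false(big$exact)
  expect_true(big$U >= 0 && big$U <= 5000 * 5000)
})

test_that("normal approximation tracks the exact distribution for small n", {
  # exhaustive sweep over every achievable U; the discrepancy between the
  # exact and the continuity-corrected normal p is a property of the U
  # distribution itself, with worst cases 0.089 / 0.038 / 0.031 at
  # n = 2 / 3 / 4 and below 0.02 from n = 5 on
  bound <- c(`2` = 0.089, `3` = 0.038, `4` = 0.031,
             `5` = 0.02, `6` = 0.02, `7` = 0.02, `8` = 0.02)
  for (n in 2:8) {
    for (U in 0:(n * n)) {
      s <- samples_with_u(n, U)
      exact <- mann_whitney(s$x, s$y, exact_max = 8)
      approx <- mann_whitney(s$x, s$y, exact_max = 0)
      expect_equal(exact$U, U)
      expect_true(exact$exact); expect_false(approx$exact)
      expect_lt(abs(exact$p - approx$p), bound[[as.character(n)]])
      # independent oracle: two-sided p from the null CDF of U
      p_ref <- min(1, 2 * min(pwilcox(U, n, n), 1 - pwilcox(U - 1, n, n)))
      expect_equal(exact$p, p_ref, tolerance = 1e-12)
    }
  }
})

test_that("median and IQR use interpolated percentiles", {
  m <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(m$median, 3); expect_equal(m$q25, 2); expect_equal(m$q75, 4)
  one <- median_iqr(7.9)
  expect_equal(one$median, 7.9)
  expect_equal(one$q25, 7.9); expect_equal(one$q75, 7.9)
  expect_error(median_iqr(numeric(0)), class = "usvdyad_validation_error")
})

test_that("per-animal medians give one point per animal per session", {
  tab <- as_feature_table(data.frame(
    session_id = rep(c("s1", "s2"), each = 4),
    voc_number = 1:8,
    emitter = rep(c("M01", "M01", "F01", "F01"), 2),
    bandwidth_hz = c(8, 8, 6, 6, 9, 9, 5, 5) * 1000,
    duration_ms = 17, high_freq_hz = 80000, low_freq_hz = 70000,
    mean_freq_hz = 75000, slope_hz_per_s = 0, amplitude_mv = 40,
    context = NA))
  pm <- per_animal_medians(tab, "bandwidth_hz")
  expect_equal(nrow(pm), 4L)   # 2 animals x 2 sessions
  expect_equal(pm$median[pm$sex == "male"], c(8000, 9000))
  single <- per_animal_medians(tab[tab$session_id == "s1", ], "bandwidth_hz")
  expect_equal(nrow(single), 2L)
})

test_that("the sex index is the normalized median difference", {
  expect_equal(sex_index(5, 5), 0)
  expect_equal(sex_index(7.9, 6.1), 1.8 / 14, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    m <- runif(1, 0, 10); f <- runif(1, 0.1, 10)
    expect_equal(sex_index(m, f), -sex_index(f, m))
    expect_true(abs(sex_index(m, f)) <= 1)
  }
  expect_error(sex_index(0, 0), class = "usvdyad_validation_error")
  expect_error(sex_index(-1, 2), class = "usvdyad_validation_error")
})

test_that("Monte-Carlo indices straddle zero for identical sexes", {
  eff <- sex_effect_spec()
  eff$female <- eff$male   # erase the sex difference
  tab <- simulate_feature_table(
    n_sessions = 2,
    counts_per_sex = list(male = c(3000, 3000, 3000),
                          female = c(3000, 3000, 3000), rho = 0),
    effects = eff, seed = 61)
  mc <- monte_carlo_index(tab, "bandwidth_hz", seed = 62)
  # binomial(1000, 1/2) 99.9% band
  expect_gt(mc$n_positive, 440)
  expect_lt(mc$n_positive, 560)
  expect_true(all(mc$indices >= -1 & mc$indices <= 1))
})

test_that("a strong bandwidth effect drives every index positive", {
  eff <- sex_effect_spec()
  eff$male$bandwidth_hz <- c(7700, 7930, 8200)    # +30% over female, tight
  eff$female$bandwidth_hz <- c(5900, 6100, 6300)
  tab <- simulate_feature_table(
    n_sessions = 2,
    counts_per_sex = list(male = c(3000, 3000, 3000),
                          female = c(3000, 3000, 3000), rho = 0),
    effects = eff, seed = 63)
  mc <- monte_carlo_index(tab, "bandwidth_hz", seed = 64)
  expect_equal(mc$n_positive, 1000L)
})

test_that("the slope shift maps the most negative slope to zero", {
  tab <- synthetic_table()
  mc1 <- monte_carlo_index(tab, "slope_hz_per_s", seed = 70)
  mc2 <- monte_carlo_index(tab, "slope_hz_per_s", seed = 70)
  expect_identical(mc1$indices, mc2$indices)    # determinism
  sex <- emitter_sex(tab$emitter)
  expect_equal(mc1$slope_shift_constant,
               abs(min(tab$slope_hz_per_s[!is.na(sex)])))
  expect_true(all(mc1$indices >= -1 & mc1$indices <= 1))
  expect_equal(mc1$n_positive + mc1$n_negative + mc1$n_zero, 1000L)
  # unshifted features record no constant
  expect_true(is.na(monte_carlo_index(tab, "bandwidth_hz",
                                      seed = 71)$slope_shift_constant))
  expect_error(monte_carlo_index(tab[1:600, ], "bandwidth_hz", seed = 1),
               class = "usvdyad_validation_error")
})

test_that("adding a constant to all slopes preserves median rank order", {
  set.seed(73)
  m <- rnorm(2000, -4000, 30000); f <- rnorm(2000, 6400, 20000)
  shift <- abs(min(c(m, f)))
  for (i in 1:20) {
    im <- sample.int(2000, 500); if_ <- sample.int(2000, 500)
    raw <- median(m[im]) - median(f[if_])
    shifted <- median(m[im] + shift) - median(f[if_] + shift)
    expect_equal(sign(raw), sign(shifted))
  }
})

test_that("Pearson correlation behaves at the extremes", {
  x <- 1:10
  r <- pearson_cor(x, 2 * x)
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-6)
  set.seed(80)
  ind <- pearson_cor(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(ind$r), 0.03)
  expect_true(pearson_cor(rep(1, 5), 1:5)$degenerate)
  expect_error(pearson_cor(1:2, 1:2), class = "usvdyad_validation_error")
})

test_that("the vocalizer split is strict at the count threshold", {
  counts <- c(s1 = 3318, s2 = 477, s3 = 2200, s4 = 2201)
  sp <- vocalizer_split(counts)
  expect_equal(sp$group, c("high", "low", "low", "high"))
  expect_true(all(vocalizer_split(c(a = 10, b = 2000))$group == "low"))
})

test_that("the KS check flags non-Gaussian data and degenerate input", {
  set.seed(90)
  expect_lt(ks_nongaussian(rlnorm(1000))$p, 0.01)
  expect_true(ks_nongaussian(rep(2, 50))$degenerate)
  expect_error(ks_nongaussian(1:5), class = "usvdyad_validation_error")
})

test_that("the table summary reproduces its own column aggregates", {
  tab <- synthetic_table()
  summ <- summarize_feature_table(tab, n_samples = 50, seed = 5)
  sex <- emitter_sex(tab$emitter)
  expect_equal(summ$counts$n_assigned, sum(!is.na(sex)))
  expect_equal(summ$counts$male_fraction_pct,
               100 * sum(sex == "male", na.rm = TRUE) / sum(!is.na(sex)))
  expect_equal(summ$pooled$bandwidth_hz$median1,
               median(tab$bandwidth_hz[sex %in% "male"]))
  expect_equal(sum(summ$per_session$male), sum(sex == "male", na.rm = TRUE))
  # paired counts correlate strongly under the default copula
  expect_gt(summ$count_correlation$r, 0.5)
})
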