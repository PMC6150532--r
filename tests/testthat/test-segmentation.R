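test_that("DPSS tapers are orthonormal and concentrated", {
  h <- dpss_tapers(256, k = 5, nw = 3)
  expect_equal(dim(h), c(256L, 5L))
  expect_equal(crossprod(h), diag(5), tolerance = 1e-10)
  # taper 0 is the most concentrated: positive, bell-shaped
  expect_true(all(h[, 1] > 0))
})

test_that("the harmonic F-test flags a pure tone and nothing in silence", {
  fs <- 250000
  t <- (0:(fs * 0.02 - 1)) / fs
  tone <- sin(2 * pi * 70000 * t) + rnorm(length(t), sd = 0.05)
  tf <- multitaper_ftest(tone, fs, 128)
  bin <- which.min(abs(tf$freq - 70000))
  # closed-form threshold: 95th percentile of F(2, 2K-2) = F(2, 8)
  expect_true(all(tf$fstat[bin, ] > qf(0.95, 2, 8)))

  silent <- multitaper_ftest(numeric(5000), fs, 64)
  expect_true(all(silent$fstat == 0))
  expect_false(any(ftest_mask(silent)))

  expect_error(multitaper_ftest(numeric(100), fs, 256),
               class = "usvdyad_validation_error")
})

test_that("the per-bin rejection rate on white noise is calibrated", {
  set.seed(202)
  x <- rnorm(250000 * 0.7)
  tf <- multitaper_ftest(x, 250000, 64)
  expect_gt(length(tf$fstat), 1e5)
  rate <- mean(ftest_mask(tf, alpha = 0.05))
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("mask fusion ORs scales and the box kernel fills gaps", {
  mk <- function(sig) list(freq = seq(30000, 110000, by = 1000)[1:nrow(sig)],
                           time = seq(0, by = 0.001,
                                      length.out = ncol(sig)),
                           sig = sig, power = 1 * sig,
                           band = c(30000, 110000))
  # a single true pixel becomes an 11 x 15 neighbourhood
  sig <- matrix(FALSE, 31, 41); sig[16, 21] <- TRUE
  fused <- fuse_masks(list(mk(sig)))
  expect_equal(sum(fused$grid), 11 * 15)
  expect_true(all(which(fused$grid, arr.ind = TRUE)[, 1] %in% 11:21))
  # all-false in, all-false out
  expect_false(any(fuse_masks(list(mk(matrix(FALSE, 31, 41))))$grid))
  # two pixels 5 time-bins apart on one row merge into one region
  sig2 <- matrix(FALSE, 31, 41); sig2[16, c(18, 23)] <- TRUE
  fused2 <- fuse_masks(list(mk(sig2)))
  lab <- usvdyad:::.label_components(fused2$grid, TRUE)
  expect_equal(max(lab), 1L)
  # inconsistent analysis bands are rejected
  bad <- mk(sig); bad$band <- c(20000, 90000)
  expect_error(fuse_masks(list(mk(sig), bad)),
               class = "usvdyad_validation_error")
})

test_that("signals are 8-connected components above the pixel threshold", {
  grid <- matrix(FALSE, 60, 120)
  grid[10:49, 10:49] <- TRUE            # 40 x 40 = 1600 pixels
  mask <- structure(list(grid = grid, sig = grid, power = 1 * grid,
                         freqs = seq(30000, by = 976.5625, length.out = 60),
                         times = seq(0, by = 128e-6, length.out = 120),
                         freq_step_hz = 976.5625, time_step_s = 128e-6,
                         band = c(30000, 110000)), class = "tf_mask")
  expect_length(extract_signals(mask, 1500), 1L)

  grid2 <- matrix(FALSE, 60, 120)
  grid2[10:47, 10:48] <- TRUE           # 38 x 39 = 1482 < 1500
  mask$grid <- grid2; mask$sig <- grid2; mask$power <- 1 * grid2
  expect_length(extract_signals(mask, 1500), 0L)

  grid3 <- matrix(FALSE, 60, 120)
  grid3[10:49, 10:49] <- TRUE
  grid3[10:49, 70:109] <- TRUE          # two separated 1600 px blobs
  mask$grid <- grid3; mask$sig <- grid3; mask$power <- 1 * grid3
  expect_length(extract_signals(mask, 1500), 2L)
})

test_that("raising the pixel threshold never increases the signal count", {
  set.seed(7)
  grid <- matrix(runif(60 * 300) < 0.3, 60, 300)
  grid <- box_fill(grid, 5, 7)
  mask <- structure(list(grid = grid, sig = grid, power = 1 * grid,
                         freqs = seq(30000, by = 976.5625, length.out = 60),
                         times = seq(0, by = 128e-6, length.out = 300),
                         freq_step_hz = 976.5625, time_step_s = 128e-6,
                         band = c(30000, 110000)), class = "tf_mask")
  counts <- vapply(c(1, 10, 50, 200, 1000, 5000),
                   function(mp) length(extract_signals(mask, mp)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("harmonic stacks collapse to their fundamental", {
  mk_sig <- function(id, f, t0, t1) {
    ct <- data.frame(time_s = seq(t0, t1, by = 0.001), freq_hz = f, power = 1)
    fake_signal(ct, id = id)
  }
  # full overlap at 40/80 kHz: ratio 2 -> keep 40 kHz, flagged
  out <- resolve_harmonics(list(mk_sig(1, 40000, 0, 0.02),
                                mk_sig(2, 80000, 0, 0.02)))
  expect_length(out, 1L)
  expect_equal(median(out[[1]]$contour$freq_hz), 40000)
  expect_true(out[[1]]$harmonic_flag)
  # 50% overlap: both kept
  out2 <- resolve_harmonics(list(mk_sig(1, 40000, 0, 0.02),
                                 mk_sig(2, 80000, 0.01, 0.03)))
  expect_length(out2, 2L)
  # 40 vs 65 kHz (ratio 1.625): both kept
  out3 <- resolve_harmonics(list(mk_sig(1, 40000, 0, 0.02),
                                 mk_sig(2, 65000, 0, 0.02)))
  expect_length(out3, 2L)
  # three-member stack keeps only the fundamental
  out4 <- resolve_harmonics(list(mk_sig(1, 40000, 0, 0.02),
                                 mk_sig(2, 80000, 0, 0.02),
                                 mk_sig(3, 120000, 0, 0.02)))
  expect_length(out4, 1L)
})

test_that("contours are power-weighted column means", {
  mask <- structure(list(
    power = matrix(c(1, 1, 0, 3), 2, 2),
    freqs = c(60000, 62000), times = c(0, 0.001),
    band = c(30000, 110000)), class = "tf_mask")
  sig <- list(pixels = cbind(c(1, 2, 2), c(1, 1, 2)))
  ct <- extract_contour(sig, mask)
  expect_equal(ct$freq_hz, c(61000, 62000))  # equal-power mean, then single
  expect_equal(ct$power, c(2, 3))
  # single-column signal gives a length-1 contour
  ct1 <- extract_contour(list(pixels = cbind(1, 1)), mask)
  expect_equal(nrow(ct1), 1L)
})

test_that("noise-free planted chirps are each recovered exactly once", {
  fx <- tiny_run()
  expect_length(fx$signals, nrow(fx$sim$truth))
  summ <- signal_summary(fx$signals)
  # one detected signal per planted chirp, in onset order
  expect_equal(order(summ$start_s), seq_len(nrow(summ)))
  for (i in seq_len(nrow(summ))) {
    expect_lt(abs(summ$start_s[i] - fx$sim$truth$onset_s[i]), 0.004)
  }
  expect_true(all(summ$n_pixels >= 1500))
})

test_that("pure noise yields no signals at the component threshold", {
  set.seed(33)
  noise <- matrix(rnorm(250000 * 0.6 * 2, sd = 0.02), ncol = 2)
  seg <- segment_audio(noise, 250000)
  expect_length(seg$signals, 0L)
})

test_that("single-channel zero-delay chirps recover duration to the hop", {
  # duration resolution is tested without propagation (single channel),
  # so only the window/hop geometry limits the start/stop estimates
  fs <- 250000
  ev <- emission_event("M", 0.25, 0.022, 58000, 76000, amplitude = 1)
  x <- numeric(fs * 0.6)
  w <- synth_usv(ev, fs)
  x[round(0.25 * fs) + seq_along(w)] <- w
  seg <- segment_audio(x, fs)
  expect_length(seg$signals, 1L)
  s <- seg$signals[[1]]
  hop <- 128 / fs  # coarsest-scale hop (nfft 256, 50% overlap)
  expect_lt(abs(s$start_s - 0.25), 2 * hop)
  expect_lt(abs(s$stop_s - 0.272), 2 * hop)
  cf <- contour_features(s$contour)
  expect_equal(cf$bandwidth_hz, 18000, tolerance = 0.05)
  expect_equal(suppressWarnings(contour_slope(s$contour)),
               18000 / 0.022, tolerance = 0.05)
})
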