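test_that("behavior scripts are validated", {
  expect_error(behavior_script("chasing", 0, 10),
               class = "usvdyad_validation_error")
  expect_error(behavior_script("following", 5, 0),
               class = "usvdyad_validation_error")
  expect_error(behavior_script(c("following", "not_close"), c(10, 15),
                               c(10, 10), c("M", NA)),
               "overlap", class = "usvdyad_validation_error")
  sc <- behavior_script(c("not_close", "following"), c(40, 10), c(10, 20),
                        c(NA, "M"))
  expect_equal(sc$start_frame, c(10L, 40L))  # sorted by onset
})

test_that("simulated trajectories honour the scripted constraints", {
  sc <- behavior_script(c("following", "not_close"), c(10, 60), c(20, 15),
                        c("M", NA))
  tr <- simulate_trajectories(sc, n_frames = 100, seed = 4)
  expect_identical(tr$tracks,
                   simulate_trajectories(sc, n_frames = 100, seed = 4)$tracks)
  m <- tr$tracks$M; f <- tr$tracks$F
  d <- sqrt((m$x - f$x)^2 + (m$y - f$y)^2)
  # following frames: under 5 cm; not-close frames: 15 cm or more
  expect_true(all(d[11:30] < 0.05))
  expect_true(all(d[61:75] >= 0.15))
  # neutral frames sit between the two criteria
  expect_true(all(d[c(1:9, 35:58, 80:100)] > 0.05 & d[-(1:100)] >= 0))
  # everything inside the arena
  for (tk in tr$tracks) {
    expect_true(all(tk$x > 0 & tk$x < 0.762 & tk$y > 0 & tk$y < 0.762))
  }
  # headings follow the direction of travel
  kin <- kinematics(m)
  ok <- !is.na(kin$direction_rad)
  expect_lt(max(abs(wrap_angle(kin$direction_rad[ok] - m$heading[ok]))), 0.3)
  # ground-truth labels line up with the script
  expect_true(all(tr$labels$F[11:30] == "following"))
  expect_true(all(tr$labels$M[11:30] == "followed"))
  expect_true(all(tr$labels$M[61:75] == "not_close"))

  expect_error(simulate_trajectories(sc, n_frames = 50, seed = 1),
               class = "usvdyad_validation_error")
  expect_error(
    simulate_trajectories(behavior_script("following", 0, 10, "M"),
                          n_frames = 100, seed = 1),
    class = "usvdyad_validation_error")
})

test_that("synthesized chirps have the stated length, band and envelope", {
  ev <- emission_event("M", 0, 0.020, 60000, 80000, amplitude = 0.7)
  w <- synth_usv(ev, 250000)
  expect_length(w, 5000L)  # 20 ms at 250 kHz
  expect_lt(max(abs(w)), 0.7 + 1e-12)
  expect_gt(max(abs(w)), 0.69)
  # raised-cosine ramps pull the endpoints to (near) zero
  expect_lt(max(abs(w[1:5])), 0.02)
  expect_lt(max(abs(w[4996:5000])), 0.02)
  # Nyquist guard
  expect_error(synth_usv(emission_event("M", 0, 0.02, 60000, 100000), 200000),
               class = "usvdyad_validation_error")
  expect_error(emission_event("M", 0, 0.02, 20000, 80000),
               class = "usvdyad_validation_error")
  expect_error(emission_event("M", -1, 0.02, 60000, 80000),
               class = "usvdyad_validation_error")
})

test_that("array audio renders delay, 1/r gain, and ground truth", {
  # 4 microphones equidistant from the source: channels identical
  n <- 40L
  tracks <- list(M = still_track("M", n, 0.3, 0.3),
                 F = still_track("F", n, 0.6, 0.6))
  # nose at centroid + 0.04 in +x: (0.34, 0.3); recentre mics around it
  nose <- nose_position(tracks$M, 0)
  geom <- mic_array_geometry(sweep(rbind(c(-0.2, -0.2), c(-0.2, 0.2),
                                         c(0.2, -0.2), c(0.2, 0.2)),
                                   2, -nose),
                             arena = c(0.762, 0.762))
  ev <- emission_event("M", 0.2, 0.02, 60000, 80000)
  out <- simulate_array_audio(tracks, ev, geom, noise_sd = 0)
  expect_equal(out$truth$x, nose[1])
  expect_equal(out$truth$y, nose[2])
  for (ch in 2:4) expect_equal(out$samples[, ch], out$samples[, 1])
  # signal arrives delayed by distance / 343
  lag <- which(abs(out$samples[, 1]) > 0)[1] / 250000
  expect_equal(lag, 0.2 + sqrt(2 * 0.2^2) / 343, tolerance = 1e-4)

  # unknown emitter and out-of-track events are rejected
  expect_error(simulate_array_audio(tracks, emission_event("X", 0.2, 0.02,
                                                           60000, 70000),
                                    geom, noise_sd = 0),
               class = "usvdyad_validation_error")
  expect_error(simulate_array_audio(tracks, emission_event("M", 5, 0.02,
                                                           60000, 70000),
                                    geom, noise_sd = 0),
               class = "usvdyad_validation_error")

  # determinism of the noise under a fixed seed
  a1 <- simulate_array_audio(tracks, ev, geom, noise_sd = 0.01, seed = 9)
  a2 <- simulate_array_audio(tracks, ev, geom, noise_sd = 0.01, seed = 9)
  expect_identical(a1$samples, a2$samples)
})

test_that("simulated feature tables reproduce the configured per-sex medians", {
  # fixed per-session counts so the pooled n is large and stable
  tab <- simulate_feature_table(
    n_sessions = 2,
    counts_per_sex = list(male = c(25000, 25000, 25000),
                          female = c(25000, 25000, 25000), rho = 0.9),
    seed = 21)
  sex <- emitter_sex(tab$emitter)
  m_bw <- median(tab$bandwidth_hz[sex == "male"])
  f_bw <- median(tab$bandwidth_hz[sex == "female"])
  expect_equal(m_bw, 7900, tolerance = 0.02)
  expect_equal(f_bw, 6100, tolerance = 0.02)
  expect_equal(median(tab$duration_ms[sex == "male"]), 17.2, tolerance = 0.02)
  # slope medians keep their signs (male down, female up)
  expect_lt(median(tab$slope_hz_per_s[sex == "male"]), 0)
  expect_gt(median(tab$slope_hz_per_s[sex == "female"]), 0)
  # structural identities and band limits
  expect_equal(tab$high_freq_hz, tab$low_freq_hz + tab$bandwidth_hz)
  expect_true(all(tab$mean_freq_hz >= tab$low_freq_hz &
                    tab$mean_freq_hz <= tab$high_freq_hz))
  expect_true(all(tab$low_freq_hz >= 30000 & tab$high_freq_hz <= 110000))
  # marginals are decisively non-Gaussian
  ks <- ks_nongaussian(tab$bandwidth_hz[sex == "male"][1:5000])
  expect_lt(ks$p, 0.01)
})

test_that("feature-table generation is deterministic and male-dominated", {
  t1 <- simulate_feature_table(n_sessions = 3, seed = 7)
  t2 <- simulate_feature_table(n_sessions = 3, seed = 7)
  expect_identical(t1, t2)
  sex <- emitter_sex(t1$emitter)
  per <- table(t1$session_id, sex)
  # males out-vocalize females in every default session
  expect_true(all(per[, "male"] > per[, "female"]))
  expect_error(simulate_feature_table(counts_per_sex = list(
    male = c(0, 1, 2), female = c(1, 2, 3), rho = 0.5)),
    class = "usvdyad_validation_error")
})
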