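tone_window <- function(freqs, amps, rate = 25, secs = 8, base = c(180, 120, 100),
                        mix = NULL, noise = 0, seed = 1) {
  L <- rate * secs
  t <- (0:(L - 1)) / rate
  set.seed(seed)
  src <- vapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t + i), numeric(L))
  if (is.null(mix)) mix <- diag(length(freqs))[seq_len(3), , drop = FALSE]
  rows <- mix %*% t(src) + base +
    if (noise > 0) matrix(rnorm(3 * L, 0, noise), 3, L) else 0
  trc <- rgb_trace(rows[1, ], rows[2, ], rows[3, ], rate)
  preprocess_window(make_windows(trc, secs, 1)[[1]])
}

test_that("windowing yields the maximal set of full windows", {
  trc <- rgb_trace(rep(1, 750), rep(1, 750), rep(1, 750), 25)
  expect_length(make_windows(trc, 8, 1), 23)  # floor((30-8)/1)+1
  trc8 <- rgb_trace(rep(1, 200), rep(1, 200), rep(1, 200), 25)
  ws <- make_windows(trc8, 8, 1)
  expect_length(ws, 1)
  expect_equal(ws[[1]]$start_time, 0)
  short <- rgb_trace(rep(1, 197), rep(1, 197), rep(1, 197), 25)
  expect_error(make_windows(short, 8, 1), class = "insufficient_data_error")
})

test_that("preprocessing rejects drift, passes the pulse band, zeroes constants", {
  rate <- 25; L <- 200; t <- (0:(L - 1)) / rate
  drift <- 100 + 50 * sin(2 * pi * 0.2 * t)
  trc <- rgb_trace(drift, drift, drift, rate)
  w <- preprocess_window(make_windows(trc)[[1]])
  expect_lt(fitted_amplitude(w$samples[2, ], 0.2, rate), 0.05 * 50)

  tone <- 120 + 10 * sin(2 * pi * 1.5 * t)
  w2 <- preprocess_window(make_windows(rgb_trace(tone, tone, tone, rate))[[1]])
  mid <- 50:150
  amp <- fitted_amplitude(w2$samples[2, mid], 1.5, rate)
  expect_lt(abs(amp - 10), 0.5)

  const <- rgb_trace(rep(7, L), rep(7, L), rep(7, L), rate)
  w3 <- preprocess_window(make_windows(const)[[1]])
  expect_lt(max(abs(w3$samples)), 1e-8)

  # band edge at/above Nyquist is a configuration error
  slow <- rgb_trace(rep(1, 100), rep(1, 100), rep(1, 100), 8)
  expect_error(preprocess_window(make_windows(slow, 8, 1)[[1]]),
               class = "config_error")
})

test_that("GREEN returns the bandpassed green channel", {
  w <- tone_window(c(1.5, 1.5, 1.5), c(0, 10, 0))
  b <- bvp_green(w)
  expect_equal(b$signal, w$samples[2, ] - mean(w$samples[2, ]))
  expect_lt(abs(mean(b$signal)), 1e-10)
  expect_lt(abs(bpm_from_bvp(b, 25) - 90), 0.5)
})

test_that("ICA recovers a tone from an invertible mixture, deterministically", {
  mix <- rbind(c(0.8, 0.3, 0.2), c(0.2, 0.9, 0.4), c(0.4, 0.2, 0.7))
  L <- 200; t <- (0:(L - 1)) / 25
  set.seed(10)
  src <- rbind(10 * sin(2 * pi * 1.2 * t), rnorm(L, 0, 4), rnorm(L, 0, 4))
  rows <- mix %*% src + c(180, 120, 100)
  trc <- rgb_trace(rows[1, ], rows[2, ], rows[3, ], 25)
  w <- preprocess_window(make_windows(trc)[[1]])
  b1 <- bvp_ica(w, seed = 42)
  b2 <- bvp_ica(w, seed = 42)
  expect_identical(b1$signal, b2$signal)
  comps <- attr(b1, "components")
  peaks <- apply(comps, 1, function(x) 60 * pulseveil:::spectral_peak_hz(x, 25))
  expect_true(any(abs(peaks - 72) < 1))
  # the selected component is the pulse-like one
  expect_lt(abs(bpm_from_bvp(b1, 25) - 72), 1)
  # constant rows cannot be decomposed
  cw <- tone_window(c(1, 1, 1), c(0, 0, 0))
  expect_error(bvp_ica(cw), class = "decomposition_error")
})

test_that("CHROM is scale-invariant and finds the pulse frequency", {
  mix <- rbind(0.45, 1.5, 0.9)
  w <- tone_window(1.5, 1, mix = mix, noise = 0.4, seed = 2)
  expect_lt(abs(bpm_from_bvp(bvp_chrom(w), 25) - 90), 0.5)
  # doubling all channels leaves the normalized output identical
  w2 <- w
  w2$raw <- 2 * w$raw; w2$raw_means <- 2 * w$raw_means
  w2$samples <- 2 * w$samples
  expect_lt(max(abs(bvp_chrom(w2)$signal - bvp_chrom(w)$signal)), 1e-9)
  # constant input hits the zero-variance guard
  cw <- tone_window(c(1, 1, 1), c(0, 0, 0))
  expect_lt(max(abs(bvp_chrom(cw)$signal)), 1e-8)
})

test_that("POS is scale-invariant and finds the pulse frequency", {
  mix <- rbind(0.45, 1.5, 0.9)
  w <- tone_window(1.2, 1, mix = mix, noise = 0.4, seed = 3)
  expect_lt(abs(bpm_from_bvp(bvp_pos(w), 25) - 72), 1)
  w2 <- w
  w2$raw <- 2 * w$raw; w2$raw_means <- 2 * w$raw_means
  w2$samples <- 2 * w$samples
  expect_lt(max(abs(bvp_pos(w2)$signal - bvp_pos(w)$signal)), 1e-9)
  cw <- tone_window(c(1, 1, 1), c(0, 0, 0))
  expect_lt(max(abs(bvp_pos(cw)$signal)), 1e-8)
})

test_that("LGI projects out the dominant direction and keeps the pulse", {
  # rank-1 raw window: projection annihilates everything
  L <- 200; t <- (0:(L - 1)) / 25
  base <- 100 + 5 * sin(2 * pi * 1.1 * t)
  trc <- rgb_trace(2 * base, 3 * base, base, 25)
  w <- preprocess_window(make_windows(trc)[[1]])
  b <- bvp_lgi(w)
  expect_lt(max(abs(b$signal)), 1e-9)
  # projected rows are orthogonal to u1
  Y <- attr(b, "projection"); u1 <- attr(b, "u1")
  expect_lt(max(abs(drop(t(u1) %*% Y))), 1e-6)

  # pulse + 10x stronger common-mode intensity disturbance: pulse survives
  pulse <- sin(2 * pi * 1.2 * t)
  dist <- 10 * sin(2 * pi * 0.35 * t + 1)
  trc2 <- rgb_trace(180 + 0.45 * pulse + dist, 120 + 1.5 * pulse + dist,
                    100 + 0.9 * pulse + dist, 25)
  w2 <- preprocess_window(make_windows(trc2)[[1]])
  expect_lt(abs(bpm_from_bvp(bvp_lgi(w2), 25) - 72), 1)
})

test_that("spectral-peak bpm is band-restricted and grid-accurate", {
  t <- (0:199) / 25
  expect_lt(abs(bpm_from_bvp(sin(2 * pi * 1.5 * t), 25) - 90), 0.5)
  # out-of-band strong tone is ignored
  two <- 5 * sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 1.0 * t)
  expect_lt(abs(bpm_from_bvp(two, 25) - 60), 0.5)
  # estimates always fall inside the band edges x 60
  set.seed(8)
  for (i in 1:10) {
    bpm <- bpm_from_bvp(rnorm(200), 25)
    expect_gte(bpm, 39); expect_lte(bpm, 240)
  }
  expect_error(bpm_from_bvp(rep(0, 200), 25), class = "undefined_peak_error")
})

test_that("trace sampling averages skin patches and flags bad geometry", {
  sc <- cached_scene(duration = 1, seed = 5)
  gray <- video_sequence(rep(list(uniform_frame(128, 128, 99L)),
                             length(sc$video$frames)), 25)
  trc <- sample_rgb_trace(gray, sc$landmarks)
  expect_true(all(trc$r == 99) && all(trc$g == 99) && all(trc$b == 99))

  # green channel of a clean scene tracks the generating waveform
  sc0 <- cached_scene(duration = 10, sensor_noise_sigma = 0,
                      flicker_sigma = 0, wb_jitter_sigma = 0, seed = 5)
  trc0 <- sample_rgb_trace(sc0$video, sc0$landmarks)
  wave <- pulseveil:::pulse_value(sc0$config,
                                  (seq_along(trc0$g) - 1) / trc0$rate)
  expect_gt(abs(cor(trc0$g, wave)), 0.9)

  # landmarks far outside a tiny frame cannot be sampled
  lmset <- landmark_set(cbind(c(100, 100, 100), c(100, 100, 100)) +
                          rbind(c(0, 0), c(1, 0), c(0, 1)),
                        list(forehead = 1:3, left_cheek = 1:3,
                             right_cheek = 1:3, nose = 1:3))
  tiny <- video_sequence(list(uniform_frame(8, 8)), 25)
  expect_error(sample_rgb_trace(tiny, list(lmset)), class = "sampling_error")
})

test_that("video path and PPG path agree on a shared synthetic pulse", {
  sc <- cached_scene(duration = 12, sensor_noise_sigma = 0, seed = 5)
  gt <- bpm_series_from_ppg(sc$ppg)
  expect_equal(gt$times, 0:4)
  expect_true(all(abs(gt$bpm - 72) < 1))
  est <- estimate_bpm_series(sc$video, sc$landmarks, "GREEN")
  expect_true(all(abs(est$bpm - gt$bpm) < 1))
  expect_error(estimate_bpm_series(
    video_sequence(sc$video$frames[1:100], 25), sc$landmarks[1:100], "GREEN"),
    class = "insufficient_data_error")
  expect_error(estimate_bpm_series(sc$video, sc$landmarks, "BOGUS"),
               class = "config_error")
})
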