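all_mask <- function(f) full_frame_mask(f)

test_that("filter_config validates parameters", {
  expect_error(filter_config("XX"), class = "config_error")
  expect_error(filter_config("MB", kernel_size = 4), class = "config_error")
  expect_error(filter_config("BB", sigma_space = 0), class = "config_error")
  expect_error(filter_config("TA-S", window_frames = 0),
               class = "config_error")
  expect_error(filter_config("SPN", noise_params = list(amount = 1.5)),
               class = "config_error")
  expect_error(filter_config("AGN", noise_params = list(var = -1)),
               class = "config_error")
  expect_identical(filter_config("MB")$kernel_size, 5L)
  expect_identical(filter_config("BB")$sigma_space, 75)
  expect_identical(filter_config("BB")$sigma_range, 75)
  expect_identical(filter_config("TA-S")$window_frames, 20L)
})

test_that("spatial blurs leave uniform frames unchanged", {
  f <- uniform_frame(16, 16, 93L)
  expect_identical(median_blur(f, all_mask(f), filter_config("MB")), f)
  expect_identical(gaussian_blur(f, all_mask(f), filter_config("GB")), f)
  expect_identical(bilateral_blur(f, all_mask(f), filter_config("BB")), f)
})

test_that("median blur removes an isolated impulse and respects the mask", {
  f <- array(0L, c(11, 11, 3))
  f[6, 6, ] <- 255L
  out <- median_blur(f, all_mask(f), filter_config("MB", kernel_size = 5))
  expect_identical(out[6, 6, 1], 0L)  # median of 25 values, one of them 255
  # masked out: impulse survives
  m <- matrix(0L, 11, 11); m[1:3, 1:3] <- 1L
  partial <- structure(list(mask = m, roi_kind = "facial_skin"),
                       class = "roi_mask")
  out2 <- median_blur(f, partial, filter_config("MB"))
  expect_identical(out2[6, 6, 1], 255L)
})

test_that("gaussian blur kernel is normalized and preserves linear ramps", {
  # interior of a linear ramp is invariant under a symmetric normalized kernel
  ramp <- array(rep(seq(0L, 150L, by = 10L), each = 16), c(16, 16, 3))
  out <- gaussian_blur(ramp, all_mask(ramp), filter_config("GB"))
  interior <- out[5:12, 5:12, ]
  expect_true(all(abs(interior - ramp[5:12, 5:12, ]) <= 1L))
  # direct convolution oracle at one pixel
  k <- 5; sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  g1 <- exp(-((1:k) - 3)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  expect_lt(abs(sum(g1) - 1), 1e-12)
  expect_identical(g1, rev(g1))
  f <- random_frame(16, 16, seed = 3)
  out2 <- gaussian_blur(f, all_mask(f), filter_config("GB"))
  patch <- f[6:10, 6:10, 2] * 1.0
  oracle <- sum((g1 %o% g1) * patch)
  expect_equal(out2[8, 8, 2], floor(oracle + 0.5))
})

test_that("bilateral blur preserves a step edge better than gaussian blur", {
  f <- array(0L, c(16, 16, 3))
  f[, 9:16, ] <- 200L
  cfg <- filter_config("BB", sigma_range = 10, bilateral_diameter = 5)
  bb <- bilateral_blur(f, all_mask(f), cfg)
  gb <- gaussian_blur(f, all_mask(f), filter_config("GB"))
  # edge-adjacent pixel deviates less from its side's level under BB
  expect_lt(abs(bb[8, 8, 1] - 0), abs(gb[8, 8, 1] - 0))
  expect_lt(abs(bb[8, 9, 1] - 200), abs(gb[8, 9, 1] - 200))
})

test_that("cumulative averaging matches the brute-force running mean", {
  # alternating 0/255 pixel: at t = 3 the mean is 127.5 -> rounds to 128
  cfg <- filter_config("TA-C")
  state <- filter_state_init(cfg)
  vals <- c(0L, 255L, 0L, 255L)
  outs <- integer(4)
  for (i in 1:4) {
    f <- uniform_frame(4, 4, vals[i])
    st <- ta_cumulative_step(f, all_mask(f), state)
    outs[i] <- st$frame[1, 1, 1]
    state <- st$state
  }
  expect_identical(outs, c(0L, 128L, 85L, 128L))

  # oracle over a random video
  v <- random_video(6, 6, 20, seed = 9)
  state <- filter_state_init(cfg)
  acc <- array(0, dim = c(6, 6, 3))
  for (t in seq_along(v$frames)) {
    st <- ta_cumulative_step(v$frames[[t]], all_mask(v$frames[[t]]), state)
    state <- st$state
    acc <- acc + v$frames[[t]]
    expect_identical(st$frame, array(as.integer(floor(acc / t + 0.5)),
                                     dim = c(6, 6, 3)))
  }
  # shape change mid-video is rejected
  expect_error(ta_cumulative_step(uniform_frame(5, 6), all_mask(uniform_frame(5, 6)),
                                  state),
               class = "state_error")
})

test_that("sliding-window averaging: identity cases and window contents", {
  cfg1 <- filter_config("TA-S", window_frames = 1)
  v <- random_video(5, 5, 6, seed = 4)
  state <- filter_state_init(cfg1)
  for (t in seq_along(v$frames)) {
    st <- ta_sliding_step(v$frames[[t]], all_mask(v$frames[[t]]), state, cfg1)
    expect_identical(st$frame, v$frames[[t]])  # f = 1 is the identity
    state <- st$state
  }
  # constant video is invariant for any window
  cfg <- filter_config("TA-S", window_frames = 4)
  state <- filter_state_init(cfg)
  f <- uniform_frame(5, 5, 77L)
  for (t in 1:6) {
    st <- ta_sliding_step(f, all_mask(f), state, cfg)
    expect_identical(st$frame, f)
    state <- st$state
  }
  # brute-force window mean, including warm-up
  state <- filter_state_init(cfg)
  for (t in seq_along(v$frames)) {
    st <- ta_sliding_step(v$frames[[t]], all_mask(v$frames[[t]]), state, cfg)
    lo <- max(1, t - 4 + 1)
    ref <- Reduce(`+`, v$frames[lo:t]) / (t - lo + 1)
    expect_identical(st$frame, array(as.integer(floor(ref + 0.5)),
                                     dim = c(5, 5, 3)))
    state <- st$state
  }
})

test_that("sliding-window averaging attenuates sinusoids by the Dirichlet gain", {
  r <- 25; fr <- 1.5; w <- 20; A <- 60
  nf <- 200
  t <- (0:(nf - 1)) / r
  sig <- 128 + A * sin(2 * pi * fr * t)
  v <- video_sequence(lapply(sig, function(s)
    array(as.integer(floor(s + 0.5)), c(4, 4, 3))), r)
  cfg <- filter_config("TA-S", window_frames = w)
  out <- modify_video(v, "full_frame", cfg)
  y <- vapply(out$frames, function(f) f[1, 1, 1] * 1.0, numeric(1))
  steady <- w:nf
  gain <- fitted_amplitude(y[steady], fr, r) /
    fitted_amplitude(sig[steady], fr, r)
  expect_lt(abs(gain - moving_average_gain(fr, w, r)), 0.01)
})

test_that("noise injection is seeded, calibrated, and range-safe", {
  f <- uniform_frame(64, 64, 128L)
  for (method in c("AGN", "AGN-L", "SPN", "PoN", "PeN", "SN")) {
    cfg <- filter_config(method, seed = 11)
    a <- add_noise(f, all_mask(f), cfg, filter_state_init(cfg))$frame
    b <- add_noise(f, all_mask(f), cfg, filter_state_init(cfg))$frame
    expect_identical(a, b)  # same seed, same output
    expect_true(all(a >= 0L & a <= 255L))
    cfg2 <- filter_config(method, seed = 12)
    c2 <- add_noise(f, all_mask(f), cfg2, filter_state_init(cfg2))$frame
    expect_false(identical(a, c2))  # different seed, different noise
  }
  # pepper sets ~amount of elements to 0, never to other values
  cfg <- filter_config("PeN", seed = 5)
  out <- add_noise(f, all_mask(f), cfg, filter_state_init(cfg))$frame
  changed <- out != 128L
  expect_true(all(out[changed] == 0L))
  expect_lt(abs(mean(changed) - 0.05), 0.01)
  # speckle variance scales with intensity: dark pixels stay closer
  dark <- uniform_frame(64, 64, 20L); bright <- uniform_frame(64, 64, 200L)
  cfg <- filter_config("SN", seed = 5)
  sd_dark <- sd(add_noise(dark, all_mask(dark), cfg,
                          filter_state_init(cfg))$frame - 20)
  sd_bright <- sd(add_noise(bright, all_mask(bright), cfg,
                            filter_state_init(cfg))$frame - 200)
  expect_gt(sd_bright, 5 * sd_dark)
  # Poisson resampling keeps the mean and adds shot noise
  cfg <- filter_config("PoN", seed = 5)
  out <- add_noise(f, all_mask(f), cfg, filter_state_init(cfg))$frame
  expect_lt(abs(mean(out) - 128), 0.5)
  expect_gt(sd(as.numeric(out)), 1)
  # noise respects the caller's RNG stream
  set.seed(123); before <- runif(1)
  cfg <- filter_config("AGN", seed = 5)
  set.seed(123)
  invisible(add_noise(f, all_mask(f), cfg, filter_state_init(cfg)))
  expect_identical(runif(1), before)
})

test_that("overlay composites exactly per pixel", {
  a <- random_frame(8, 8, seed = 1)
  b <- random_frame(8, 8, seed = 2)
  zero <- structure(list(mask = matrix(0L, 8, 8), roi_kind = "facial_skin"),
                    class = "roi_mask")
  ones <- full_frame_mask(a)
  expect_identical(overlay_roi(a, b, zero), a)
  expect_identical(overlay_roi(a, b, ones), b)
  set.seed(3)
  m <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
  rnd <- structure(list(mask = m, roi_kind = "facial_skin"),
                   class = "roi_mask")
  out <- overlay_roi(a, b, rnd)
  for (ch in 1:3) for (i in 1:8) for (j in 1:8)
    expect_identical(out[i, j, ch],
                     if (m[i, j] == 1L) b[i, j, ch] else a[i, j, ch])
  expect_error(overlay_roi(a, random_frame(9, 8), ones),
               class = "dimension_error")
})

test_that("modify_video: NE is bit-identical and operators stay inside the ROI", {
  sc <- cached_scene(duration = 2, width = 32, height = 32, seed = 5)
  prov <- scene_landmark_provider(sc)
  ne <- modify_video(sc$video, "facial_skin", filter_config("NE"),
                     provider = prov)
  expect_identical(ne$frames, sc$video$frames)
  expect_equal(frame_mse(sc$video, ne), 0)

  mask <- facial_skin_mask(sc$landmarks[[1]], c(32, 32))
  outside <- array(mask$mask == 0L, dim = c(32, 32, 3))
  for (method in c("MB", "TA-S", "AGN")) {
    mod <- modify_video(sc$video, "facial_skin", filter_config(method),
                        provider = prov)
    for (i in seq_along(mod$frames))
      expect_identical(mod$frames[[i]][outside], sc$video$frames[[i]][outside])
    expect_gt(frame_mse(sc$video, mod), 0)
  }
  expect_error(modify_video(sc$video, "facial_skin", filter_config("MB")),
               class = "config_error")
})
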