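# Beat segmentation, ensemble averaging, spatial smoothing, normalization.

test_that("segmentation yields one stimulus-aligned window per complete cycle", {
  # 1000 frames at 1 ms with stimuli every 100 ms from 50 ms: the last
  # stimulus (950 ms) has no complete cycle -> 9 windows
  frames <- array(0, c(2, 2, 1000))
  frames[, , ] <- 1
  mv <- voltage_movie(frames, 1, 0.05, seq(50, 950, by = 100))
  w <- segment_beats(mv, ensemble_config(n_beats_to_average = 8L))
  expect_equal(length(w$starts), 9)
  expect_equal(w$length, 100)
  expect_equal(w$starts, round(seq(50, 850, by = 100)) + 1L)  # aligned to stimuli

  # fewer complete windows than required
  mv5 <- voltage_movie(frames[, , 1:550, drop = FALSE], 1, 0.05, seq(50, 450, by = 100))
  expect_error(segment_beats(mv5, ensemble_config(n_beats_to_average = 8L)),
               class = "atriakit_insufficient_beats")
})

test_that("stimulus recovery from the global mean trace matches annotations", {
  # detected windows are aligned to the mean-trace upstroke rather than the
  # stimulus, so starts sit a few ms late but keep the pacing period
  sim <- generate_optical_movie(small_optical("CON", n_beats = 9L), seed = 3)
  mv <- sim$movie
  unannotated <- voltage_movie(mv$frames, mv$frame_interval, mv$pixel_pitch,
                               numeric(0), mv$polarity, mv$roi)
  w0 <- segment_beats(mv)
  w1 <- segment_beats(unannotated)
  expect_equal(w1$length, w0$length)
  expect_gte(length(w1$starts), 8)
  expect_lt(max(abs(diff(w1$starts) - w1$length)), 2)       # strictly periodic
  expect_lt(max(abs(w1$starts[1:8] - w0$starts[1:8])), 10)  # near the stimuli
})

test_that("ensemble averaging is exact for identical beats and reduces noise by sqrt(8)", {
  clean <- generate_optical_movie(small_optical("CON", noise_sd = 0), seed = 4)
  w <- segment_beats(clean$movie)
  avg <- ensemble_average(clean$movie, w)
  one <- clean$movie$frames[, , w$starts[1]:(w$starts[1] + w$length - 1)]
  expect_equal(as.numeric(avg), as.numeric(one))   # identical beats: mean == any beat

  cfg1 <- ensemble_config(n_beats_to_average = 1L)
  avg1 <- ensemble_average(clean$movie, w, cfg1)
  expect_equal(as.numeric(avg1), as.numeric(one))  # n = 1 is the identity

  p <- small_optical("CON")
  noisy <- generate_optical_movie(p, seed = 4)
  avg_n <- ensemble_average(noisy$movie, segment_beats(noisy$movie))
  resid <- as.numeric(avg_n) - as.numeric(avg)
  expect_gte(length(resid), 1e4)
  # CLT: averaging 8 independent noise realizations shrinks the SD by sqrt(8)
  expect_lt(abs(sd(resid) - p$noise_sd / sqrt(8)) / (p$noise_sd / sqrt(8)), 0.10)
})

test_that("spatial smoothing implements a NaN-aware reflect-padded uniform kernel", {
  cfg <- ensemble_config()
  const <- array(3.7, c(10, 10, 4))
  expect_equal(spatial_smooth(const, cfg), const, ignore_attr = TRUE)

  # interior impulse of 25 spreads to a 5x5 block of exactly 25/25 = 1
  imp <- array(0, c(11, 11, 1))
  imp[6, 6, 1] <- 25
  sm <- spatial_smooth(imp, cfg)
  expect_equal(sm[4:8, 4:8, 1], matrix(1, 5, 5))
  expect_equal(sum(sm[, , 1] != 0), 25)

  x <- array(rnorm(10 * 10 * 3), c(10, 10, 3))
  expect_equal(spatial_smooth(x, ensemble_config(smoothing_kernel = 1L)), x,
               ignore_attr = TRUE)                  # kernel 1 is the identity
  expect_error(spatial_smooth(x, ensemble_config(smoothing_kernel = 11L)),
               class = "atriakit_config_error")

  # non-ROI pixels are excluded from input and output
  roi <- matrix(TRUE, 11, 11); roi[6, 6] <- FALSE
  sm2 <- spatial_smooth(imp, cfg, roi = roi)
  expect_true(all(is.nan(sm2[6, 6, ])))
  expect_equal(sm2[4, 4, 1], 0)                     # impulse pixel never contributes
})

test_that("normalization yields unit-peak zero-baseline traces and prunes flat pixels", {
  sim <- generate_optical_movie(small_optical("CON", noise_sd = 0), seed = 9)
  beat <- prepare_beat(sim$movie, ensemble_config(smoothing_kernel = 1L))
  tr <- matrix(beat$traces, prod(dim(beat$traces)[1:2]), dim(beat$traces)[3])
  expect_equal(max(tr, na.rm = TRUE), 1)
  expect_equal(unname(apply(tr, 1, max)), rep(1, nrow(tr)))  # per-pixel peak 1
  base_cols <- (ncol(tr) - 9):ncol(tr)
  expect_lt(max(abs(tr[, base_cols])), 1e-3)                 # rests at 0

  # a flat pixel is dropped from the ROI
  mv <- sim$movie
  mv$frames[3, 3, ] <- 30000
  beat2 <- prepare_beat(mv, ensemble_config(smoothing_kernel = 1L))
  expect_false(beat2$roi[3, 3])
  expect_true(all(is.nan(beat2$traces[3, 3, ])))

  # polarity "increases": no inversion, upstroke remains positive-going
  inc <- small_optical("CON", noise_sd = 0,
                       polarity = "fluorescence_increases_on_depolarization")
  simi <- generate_optical_movie(inc, seed = 9)
  expect_gt(max(simi$movie$frames), inc$baseline_level)      # deflection is upward
  beati <- prepare_beat(simi$movie, ensemble_config(smoothing_kernel = 1L))
  expect_equal(max(beati$traces, na.rm = TRUE), 1)
  expect_equal(as.numeric(beati$traces[6, 6, ]), as.numeric(beat$traces[6, 6, ]),
               tolerance = 1e-2)                             # same normalized shape

  # all pixels flat -> no-signal error
  flat <- voltage_movie(array(1000, c(6, 6, 400)), 1, 0.05, c(10, 110, 210))
  expect_error(prepare_beat(flat, ensemble_config(n_beats_to_average = 2L)),
               class = "atriakit_no_signal")
})

test_that("the full chain reproduces the generator template to interpolation error", {
  # uniform (simultaneous) wavefront: spatial smoothing mixes identical
  # traces, so the chain must return the template itself
  p <- small_optical("CON", noise_sd = 0, simultaneous = TRUE, quantize = FALSE)
  sim <- generate_optical_movie(p, seed = 2)
  beat <- prepare_beat(sim$movie)
  phases <- (seq_len(dim(beat$traces)[3]) - 1) * p$frame_interval
  template <- atriakit:::ap_template(phases - sim$truth$t_act[1, 1], p$upstroke_rise_time,
                                     sim$truth$tau, p$full_repol_time)
  for (px in list(c(1, 1), c(6, 10), c(12, 20))) {
    expect_lt(max(abs(beat$traces[px[1], px[2], ] - template)), 0.01)
  }

  # smoothing a spatially constant wavefront commutes with normalization
  cfg <- ensemble_config()
  w <- segment_beats(sim$movie)
  avg <- ensemble_average(sim$movie, w, cfg)
  a <- normalize_invert(spatial_smooth(avg, cfg), sim$movie$polarity, cfg)
  b <- spatial_smooth(normalize_invert(avg, sim$movie$polarity, cfg)$traces, cfg)
  expect_equal(as.numeric(a$traces), as.numeric(b), tolerance = 1e-9)
})
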