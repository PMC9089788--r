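# Activation, upstroke-velocity and APD map oracles.

test_that("APD75 matches closed-form values on analytic traces", {
  fi <- 0.1
  t <- seq(0, 99.9, by = fi)

  # triangle: instant rise to 1 at t = 10, linear fall to 0 at t = 50;
  # the 0.25 crossing sits at t = 40, so APD75 = 40 - 10 = 30 ms
  tri <- ifelse(t < 10, 0, ifelse(t <= 50, 1 - (t - 10) / 40, 0))
  apd <- apd_map(beat_from_trace(tri, fi))
  expect_equal(apd$apd[1, 1], 30, tolerance = 0.1 / 30)

  # square pulse of duration d has APD75 = d
  d <- 25
  sq <- ifelse(t >= 10 & t < 10 + d, 1, 0)
  apd_sq <- apd_map(beat_from_trace(sq, fi))
  expect_equal(apd_sq$apd[1, 1], d, tolerance = 2 * fi / d)

  # instant rise then exponential recovery: solve exp(-t/tau) = 0.25
  # -> APD75 = tau * ln 4
  tau <- 12
  ex <- ifelse(t < 10, 0, exp(-(t - 10) / tau))
  apd_ex <- apd_map(beat_from_trace(ex, fi))
  expect_lt(abs(apd_ex$apd[1, 1] - tau * log(4)), 1)  # within one (coarse) frame

  # APD level is configurable: square pulse at level 0.5 still = d
  expect_equal(apd_map(beat_from_trace(sq, fi), level = 0.5)$apd[1, 1], d,
               tolerance = 2 * fi / d)
  expect_error(apd_map(beat_from_trace(sq, fi), level = 1.2),
               class = "atriakit_config_error")

  # a trace that never recovers below 1 - level is flagged NaN
  stuck <- ifelse(t < 10, 0, 1 - 0.3 * (1 - exp(-(t - 10) / 5)))
  apd_st <- apd_map(beat_from_trace(stuck, fi))
  expect_true(is.nan(apd_st$apd[1, 1]))
  expect_equal(apd_st$n_bad_pixels, 1)
})

test_that("upstroke velocity equals the construction slope of linear rises", {
  t <- seq(0, 99, by = 1)
  # linear 0 -> 1 over 2 ms: slope 0.50 / ms
  lin <- approx(c(0, 10, 12, 40, 100), c(0, 0, 1, 0, 0), xout = t)$y
  ups <- upstroke_velocity_map(beat_from_trace(lin, 1))
  expect_equal(ups$roi_mean, 0.50, tolerance = 1e-6)

  # rise completed within one 1 ms frame: derivative capped by sampling at 1 / ms
  fast <- ifelse(t < 10, 0, ifelse(t < 30, 1, 0)) # 0 at 9, 1 at 10
  ups_f <- upstroke_velocity_map(beat_from_trace(fast, 1))
  expect_equal(ups_f$roi_mean, 1.0, tolerance = 1e-6)
})

test_that("activation span recovers planar-wave geometry", {
  # hand value: (80 - 1) pixels * 0.05 mm / 0.5 mm/ms = 7.9 ms across the
  # field; small row count and fine frames keep estimator error far below
  # the band
  p <- optical_preset("CON", grid_size = c(8L, 80L), frame_interval = 0.25,
                      n_beats = 8L, noise_sd = 0, quantize = FALSE)
  sim <- generate_optical_movie(p, seed = 3)
  beat <- prepare_beat(sim$movie, ensemble_config(smoothing_kernel = 1L))
  am <- activation_map(beat, span = "minmax")
  expect_equal(am$activation_span, 7.9, tolerance = 0.1 / 7.9)
  expect_lt(max(abs(am$t_act - sim$truth$t_act), na.rm = TRUE), p$frame_interval)

  # simultaneous activation: span collapses to interpolation error
  sim0 <- generate_optical_movie(small_optical("CON", noise_sd = 0, simultaneous = TRUE),
                                 seed = 4)
  am0 <- activation_map(prepare_beat(sim0$movie), span = "minmax")
  expect_lt(am0$activation_span, 0.1)
})

test_that("per-pixel recovery on noiseless movies is within one frame interval", {
  for (name in c("CON", "dKO")) {
    sim <- generate_optical_movie(small_optical(name, noise_sd = 0), seed = 5)
    beat <- prepare_beat(sim$movie)
    act <- activation_map(beat)
    apd <- apd_map(beat)
    fi <- sim$movie$frame_interval
    expect_gte(mean(abs(act$t_act - sim$truth$t_act) < fi, na.rm = TRUE), 0.99)
    expect_gte(mean(abs(apd$apd - sim$truth$apd75) < fi, na.rm = TRUE), 0.99)
  }
})

test_that("activation is stimulus-referenced and APD is amplitude-invariant", {
  p <- small_optical("CON", noise_sd = 0)
  a <- generate_optical_movie(p, seed = 6)
  b <- generate_optical_movie(small_optical("CON", noise_sd = 0, lead_in = 25), seed = 6)
  ta <- activation_map(prepare_beat(a$movie))$t_act
  tb <- activation_map(prepare_beat(b$movie))$t_act
  expect_equal(ta, tb, tolerance = 1e-8)   # shifting the pacing train shifts nothing

  # declaring stimuli Delta earlier shifts all activation times by +Delta
  a9 <- generate_optical_movie(small_optical("CON", noise_sd = 0, n_beats = 9L), seed = 6)
  mv <- a9$movie
  shifted <- voltage_movie(mv$frames, mv$frame_interval, mv$pixel_pitch,
                           mv$stimulus_times - 5, mv$polarity, mv$roi)
  t9 <- activation_map(prepare_beat(mv))$t_act
  ts <- activation_map(prepare_beat(shifted))$t_act
  expect_equal(as.numeric(ts), as.numeric(t9 + 5), tolerance = 1e-6)

  # doubling one pixel's amplitude must not change its APD (normalization contract)
  mv2 <- a$movie
  mv2$frames[5, 7, ] <- 2 * (mv2$frames[5, 7, ] - 30000) + 30000
  apd1 <- apd_map(prepare_beat(a$movie, ensemble_config(smoothing_kernel = 1L)))
  apd2 <- apd_map(prepare_beat(mv2, ensemble_config(smoothing_kernel = 1L)))
  expect_equal(apd2$apd[5, 7], apd1$apd[5, 7], tolerance = 1e-9)
})

test_that("point-stimulus fixture yields concentric fronts with monotone radius", {
  p <- optical_preset("CON", grid_size = c(40L, 40L), n_beats = 8L,
                      pacing_site = c(19.5, 19.5), wave_geometry = "point")
  sim <- generate_optical_movie(p, seed = 8)
  am <- activation_map(prepare_beat(sim$movie))
  r <- sqrt(outer((0:39 - 19.5)^2, (0:39 - 19.5)^2, `+`))
  bins <- cut(as.vector(r), breaks = seq(0, 28, by = 4))
  mean_t <- as.numeric(tapply(as.vector(am$t_act), bins, mean, na.rm = TRUE))
  mean_t <- mean_t[is.finite(mean_t)]
  expect_true(all(diff(mean_t) > 0))            # isochrones are concentric rings
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(am); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})

test_that("ROI summaries average exactly the finite pixels", {
  sim <- generate_optical_movie(small_optical("CON", noise_sd = 0), seed = 10)
  beat <- prepare_beat(sim$movie)
  act <- activation_map(beat); apd <- apd_map(beat); ups <- upstroke_velocity_map(beat)
  s <- roi_summary(act, apd, ups, region_label = "LA")
  expect_equal(s$mean_apd75, mean(apd$apd[is.finite(apd$apd)]))
  expect_equal(unname(s$n_roi_pixels["apd"]), sum(is.finite(apd$apd)))

  # single-pixel region equals that pixel
  one <- apd
  one$apd[-1] <- NaN
  s1 <- roi_summary(apd = one, region_label = "custom")
  expect_equal(s1$mean_apd75, apd$apd[1, 1])

  # two disjoint regions give independent summaries
  left <- apd; left$apd[, 11:20] <- NaN
  right <- apd; right$apd[, 1:10] <- NaN
  sl <- roi_summary(apd = left, region_label = "LA")
  sr <- roi_summary(apd = right, region_label = "LV")
  expect_equal(sl$n_roi_pixels[["apd"]] + sr$n_roi_pixels[["apd"]],
               s$n_roi_pixels[["apd"]])
  expect_error(roi_summary(), class = "atriakit_config_error")
})
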