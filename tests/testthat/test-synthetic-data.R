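# Generators: preset arithmetic, determinism, ground-truth recovery of the
# stated construction properties.

test_that("knockout presets encode the phenotype ratios exactly by construction", {
  co <- optical_preset("CON"); ko <- optical_preset("dKO")
  expect_equal(co$conduction_velocity / ko$conduction_velocity, 1.40)
  expect_equal(ko$upstroke_rise_time / co$upstroke_rise_time, 2)
  expect_equal((1 / ko$upstroke_rise_time) / (1 / co$upstroke_rise_time), 0.50)
  expect_equal(ko$apd75_true / co$apd75_true, 1.50)

  ce <- ecg_preset("CON"); ke <- ecg_preset("dKO_wk1")
  expect_equal(ke$p_duration / ce$p_duration, 2.0)
  expect_equal(ke$pr_interval / ce$pr_interval, 1.10)
  expect_equal(ke$qrs_duration / ce$qrs_duration, 1.00)
  expect_identical(ke$p_morphology, "double_peak")
  expect_gt(ecg_preset("dKO_wk2_4")$pac_per_min, 0)
})

test_that("preset invariants are enforced", {
  expect_error(optical_preset("CON", n_beats = 5L), class = "atriakit_config_error")
  expect_error(optical_preset("CON", apd75_true = 60), class = "atriakit_config_error")
  expect_error(optical_preset("CON", upstroke_rise_time = -1), class = "atriakit_config_error")
  expect_error(optical_preset("CON", frame_interval = 0.3), class = "atriakit_config_error")
  expect_error(ecg_preset("CON", pr_interval = 10), class = "atriakit_config_error")
  expect_error(ecg_preset("CON", qrs_duration = 0), class = "atriakit_config_error")
  expect_error(ecg_preset("CON", sampling_rate = 500), class = "atriakit_config_error")
  expect_error(optical_preset("CON", nonsense = 1), class = "atriakit_config_error")
})

test_that("optical ground truth follows the planar-wave geometry", {
  p <- optical_preset("CON", n_beats = 8L, noise_sd = 0)
  sim <- generate_optical_movie(p, seed = 1)
  # pixel at exactly 4 mm from the electrode activates at 4 / 0.5 = 8 ms
  j_4mm <- 4 / p$pixel_pitch + p$pacing_site[2]      # 0-based column
  expect_lt(j_4mm, p$grid_size[2])
  expect_equal(sim$truth$t_act[1, j_4mm + 1], 8)
  # planar: no row dependence
  expect_equal(sim$truth$t_act[1, ], sim$truth$t_act[80, ])

  # simultaneous flag: all activation times equal
  sim0 <- generate_optical_movie(small_optical("CON", noise_sd = 0, simultaneous = TRUE), seed = 1)
  expect_equal(length(unique(as.numeric(sim0$truth$t_act))), 1L)
})

test_that("identical preset and seed give bit-identical synthetic data", {
  p <- small_optical("CON")
  a <- generate_optical_movie(p, seed = 42)
  b <- generate_optical_movie(p, seed = 42)
  expect_identical(a$movie$frames, b$movie$frames)
  c2 <- generate_optical_movie(p, seed = 43)
  expect_false(identical(a$movie$frames, c2$movie$frames))

  e1 <- generate_ecg(ecg_preset("dKO_wk2_4"), 10, seed = 7)
  e2 <- generate_ecg(ecg_preset("dKO_wk2_4"), 10, seed = 7)
  expect_identical(e1$ecg$samples, e2$ecg$samples)
  expect_identical(e1$truth$beats, e2$truth$beats)

  t1 <- generate_ct_table(qpcr_preset(), 4, seed = 3)
  t2 <- generate_ct_table(qpcr_preset(), 4, seed = 3)
  expect_identical(t1, t2)

  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_optical_movie(p, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("camera noise realizations match the configured SD", {
  p <- small_optical("CON")
  noisy <- generate_optical_movie(p, seed = 5)$movie$frames
  clean <- generate_optical_movie(small_optical("CON", noise_sd = 0), seed = 5)$movie$frames
  resid <- as.numeric(noisy - clean)
  expect_gte(length(resid), 1e4)
  expect_lt(abs(sd(resid) - p$noise_sd) / p$noise_sd, 0.05)
})

test_that("ECG schedule matches the preset rate and labels", {
  sim <- generate_ecg(ecg_preset("CON", noise_sd = 0), 60, seed = 1)
  expect_equal(nrow(sim$truth$beats), 500, tolerance = 0.004)  # 500 bpm x 1 min, +/-2
  expect_true(all(sim$truth$beats$label == "sinus"))           # no PACs, no AF

  pac <- generate_ecg(ecg_preset("dKO_wk2_4"), 60, seed = 2)
  expect_equal(sum(pac$truth$beats$label == "PAC"), 3)

  af <- generate_ecg(ecg_preset("dKO_af"), 60, seed = 3)      # one 40 s episode
  expect_equal(mean(af$truth$af_sample_mask), 40 / 60, tolerance = 1e-3)
  expect_true(all(af$truth$beats$label[af$truth$beats$time_s >= 10 &
                                         af$truth$beats$time_s < 50] == "in_AF"))
  expect_error(generate_ecg(ecg_preset("dKO_af", af_episodes = list(c(50, 40))), 60, seed = 1),
               class = "atriakit_config_error")
  expect_error(generate_ecg(ecg_preset("CON"), 0.5, seed = 1),
               class = "atriakit_config_error")
})

test_that("Ct tables encode the preset fold changes", {
  ct <- generate_ct_table(qpcr_preset(), n_replicates = 3, seed = 1, noise_sd = 0)
  # ddCt for a 160-fold difference is -log2(160) = -7.3219
  fc <- fold_change(ct, "Pitx2c", "Gapdh", "CON_LA", "CON_RA")
  expect_equal(fc$ddct, -log2(160))
  expect_equal(fc$ddct, -7.3219, tolerance = 1e-4)
  # fold-1 design gives ddCt = 0
  fc0 <- fold_change(ct, "Mef2c", "Gapdh", "dKO_LA", "CON_RA")
  expect_equal(fc0$ddct, 0)
  expect_equal(fc0$fold, 1)
  expect_error(generate_ct_table(qpcr_preset(), n_replicates = 1, seed = 1),
               class = "atriakit_config_error")
})
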