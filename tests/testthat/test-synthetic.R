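test_that("gen_stimulus draws seeded syllable-modulated waveforms", {
  cfg <- tiny_cfg()
  w1 <- gen_stimulus(cfg, 1)
  w2 <- gen_stimulus(cfg, 1)
  expect_identical(w1$samples, w2$samples)
  dur <- length(w1$samples) / w1$rate_hz
  expect_gte(dur, 5.5)
  expect_lte(dur, 6.5)

  # the modulation spectrum peaks near the syllable rate
  env <- hilbert_envelope(w1)
  e50 <- resample(env$samples, env$rate_hz, 50)
  e50 <- e50 - mean(e50)
  sp <- Mod(stats::fft(e50))[2:40]
  freqs <- (1:39) * 50 / length(e50)
  expect_lt(abs(freqs[which.max(sp)] - cfg$syllable_rate_hz), 1)

  expect_error(gen_stimulus(cfg, 99), class = "envtrack_parameter")
})

test_that("gen_eeg produces study-shaped seeded epochs", {
  cfg <- tiny_cfg(n_channels = 128L, frontocentral_subset = 1:12)
  stim <- gen_stimulus(cfg, 2)
  eps <- gen_eeg(cfg, stim, 2, participants = 1, repetitions = 1:2)
  ep <- eps[[1]][[1]]
  expect_equal(dim(ep$data), c(128, round(8.5 * 250)))
  expect_equal(ep$rate_hz, 250)
  expect_equal(ep$window_ms, c(-700, 7800))

  eps2 <- gen_eeg(cfg, stim, 2, participants = 1, repetitions = 1:2)
  expect_identical(eps[[1]][[2]]$data, eps2[[1]][[2]]$data)

  # channel-subset generation is consistent with full generation
  sub <- gen_eeg(cfg, stim, 2, participants = 1, repetitions = 1,
                 channels = c(3L, 7L))
  expect_identical(sub[[1]][[1]]$data, ep$data[c(3, 7), ])

  # zero kernel amplitude: pure noise, unit-RMS-scaled
  cfg0 <- tiny_cfg(kernel_neg_amp = 0, kernel_pos_amp = 0)
  e0 <- gen_eeg(cfg0, stim, 2, participants = 1, repetitions = 1,
                channels = 1L)[[1]][[1]]
  expect_lt(abs(sqrt(mean(e0$data^2)) - 1), 0.1)
})

test_that("gen_eeg plants a recoverable envelope-following response", {
  cfg <- tiny_cfg(snr_db = 60, participant_latency_sd_ms = 0,
                  n_channels = 1L, frontocentral_subset = 1L)
  stim <- gen_stimulus(cfg, 1)
  ep <- gen_eeg(cfg, stim, 1, participants = 1, repetitions = 1)[[1]][[1]]
  series <- post_onset_series(ep$data[1, ], ep$rate_hz, ep$window_ms, 5.5)
  resp50 <- resample(series, 250, 50)
  env <- stimulus_envelope(stim, 50)
  cg <- cross_correlate(env, resp50, max_lag_ms = 500)
  trough <- cg$lags_ms[which.min(cg$values)]
  expect_lte(abs(trough - 140), 20 + 1000 / 50)
})

test_that("trained network responses encode the envelope with layer gains", {
  cfg <- tiny_cfg()
  stim <- gen_stimulus(cfg, 3)
  acts <- gen_network_responses(cfg, stim, 3, mode = "trained")
  expect_length(acts, 5)
  expect_true(all(vapply(acts, function(a) a$trained, logical(1))))
  expect_equal(vapply(acts, function(a) nrow(a$data), integer(1)),
               rep(cfg$n_units, 5))
  acts2 <- gen_network_responses(cfg, stim, 3, mode = "trained")
  expect_identical(acts[[4]]$data, acts2[[4]]$data)

  un1 <- gen_network_responses(cfg, stim, 3, mode = "untrained", instance = 2)
  un2 <- gen_network_responses(cfg, stim, 3, mode = "untrained", instance = 2)
  expect_identical(un1[[1]]$data, un2[[1]]$data)
  expect_false(isTRUE(all.equal(
    un1[[1]]$data,
    gen_network_responses(cfg, stim, 3, mode = "untrained", instance = 1)[[1]]$data)))
  expect_error(gen_network_responses(cfg, stim, 3, mode = "untrained",
                                     instance = 99),
               class = "envtrack_parameter")
})
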