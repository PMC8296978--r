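test_that("surrogate_forward is deterministic and respects the architecture", {
  spec <- surrogate_spec(layer_sizes = rep(8L, 5), input_feature_count = 6L,
                         seed = 123L)
  feats <- matrix(rnorm(6 * 40), 6, 40)
  a1 <- surrogate_forward(spec, feats)
  a2 <- surrogate_forward(spec, feats)
  for (l in 1:5) expect_identical(a1[[l]]$data, a2[[l]]$data)
  expect_equal(vapply(a1, `[[`, integer(1), "layer_index"), 1:5)

  # clipped ReLU layers live in [0, clip]; LSTM output in (-1, 1)
  for (l in c(1, 2, 3, 5)) {
    expect_true(all(a1[[l]]$data >= 0 & a1[[l]]$data <= spec$relu_clip))
  }
  expect_true(all(abs(a1[[4]]$data) < 1))

  # zero input: feed-forward layers are time-constant
  z <- surrogate_forward(spec, matrix(0, 6, 15))
  for (l in 1:3) {
    expect_equal(z[[l]]$data, z[[l]]$data[, c(1, 1:14)], tolerance = 1e-12)
  }

  expect_error(surrogate_forward(spec, matrix(NA_real_, 6, 4)),
               class = "envtrack_nonfinite")
  expect_error(surrogate_forward(spec, matrix(0, 5, 4)),
               class = "envtrack_alignment")
})

test_that("planted weights reproduce a hand computation", {
  # single unit per layer, identity-ish weights, no effective clipping
  spec <- surrogate_spec(layer_sizes = rep(1L, 5), input_feature_count = 1L,
                         relu_clip = 1e6, seed = 1L)
  W <- list(W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0,
            W3 = matrix(1), b3 = 0,
            Wx = matrix(0, 4, 1), Wh = matrix(0, 4, 1), bl = rep(0, 4),
            W5 = matrix(1), b5 = 0)
  ramp <- matrix(seq(-3, 3, length.out = 13), 1)
  out <- surrogate_forward(spec, ramp, weights = W)
  expect_equal(out[[1]]$data[1, ], pmax(seq(-3, 3, length.out = 13), 0),
               tolerance = 1e-12)
  # zero LSTM weights: gates at sigmoid(0)=0.5, g=tanh(0)=0 -> state stays 0
  expect_equal(out[[4]]$data[1, ], rep(0, 13), tolerance = 1e-12)
})

test_that("make_untrained_ensemble derives distinct reproducible seeds", {
  tmpl <- surrogate_spec(layer_sizes = rep(4L, 5), input_feature_count = 3L)
  ens <- make_untrained_ensemble(tmpl, 100, master_seed = 7L)
  seeds <- vapply(ens, `[[`, integer(1), "seed")
  expect_length(unique(seeds), 100)
  ens2 <- make_untrained_ensemble(tmpl, 100, master_seed = 7L)
  expect_identical(seeds, vapply(ens2, `[[`, integer(1), "seed"))
  one <- make_untrained_ensemble(tmpl, 1, master_seed = 7L)
  expect_identical(one[[1]]$seed, derive_seed(7L, "untrained", 0L))
  expect_error(make_untrained_ensemble(tmpl, 0, 1L), class = "envtrack_parameter")
})

test_that("activation container round trips losslessly", {
  set.seed(5)
  sets <- list()
  for (s in 1:25) {
    for (l in 1:5) {
      sets[[length(sets) + 1]] <- layer_activation_set(
        matrix(rnorm(6), 2, 3), l, 50, "netA", trained = (s %% 2 == 0),
        stimulus_id = sprintf("s%02d", s), shuffle_seed = s)
    }
  }
  path <- file.path(tempdir(), "acts")
  unlink(path, recursive = TRUE)
  write_activation_container(sets, path)
  back <- read_activation_container(path)
  expect_length(back, 125)
  # match on (stimulus, layer) and compare bit-for-bit
  key <- function(x) paste(x$stimulus_id, x$layer_index)
  back_by <- stats::setNames(back, vapply(back, key, character(1)))
  for (s in sets) {
    b <- back_by[[key(s)]]
    expect_identical(b$data, s$data)
    expect_identical(b$frame_rate_hz, s$frame_rate_hz)
    expect_identical(b$trained, s$trained)
  }

  # missing attribute -> schema error
  one <- file.path(tempdir(), "acts_bad")
  unlink(one, recursive = TRUE)
  write_activation_container(sets[1], one)
  mf <- list.files(one, pattern = "json$", recursive = TRUE, full.names = TRUE)
  meta <- jsonlite::read_json(mf[1])
  meta$frame_rate_hz <- NULL
  jsonlite::write_json(meta, mf[1], auto_unbox = TRUE)
  expect_error(read_activation_container(one), class = "envtrack_schema")
})

test_that("spectrogram features are frame-aligned to the stimulus", {
  cfg <- tiny_cfg()
  w <- gen_stimulus(cfg, 1)
  f <- spectrogram_features(w, frame_rate_hz = 50)
  expect_equal(nrow(f), 26)
  dur <- length(w$samples) / w$rate_hz
  expect_lt(abs(ncol(f) - dur * 50), 3)
  expect_true(all(is.finite(f)))
})
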