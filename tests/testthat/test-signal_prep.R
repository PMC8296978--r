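test_that("hilbert_envelope recovers tone amplitudes", {
  rate <- 500
  t <- (0:2047) / rate
  # constant-amplitude tone: envelope ~ A away from the edges
  A <- 1.7
  w <- waveform(A * sin(2 * pi * 40 * t), rate)
  env <- hilbert_envelope(w)
  interior <- env$samples[200:1800]
  expect_lt(max(abs(interior - A)), 0.02 * A)

  # 5 Hz AM tone: envelope against an independent DFT analytic-signal oracle
  m <- 0.6
  x <- (1 + m * sin(2 * pi * 5 * t)) * sin(2 * pi * 60 * t)
  w2 <- waveform(x, rate)
  env2 <- hilbert_envelope(w2)
  n <- length(x)
  X <- stats::fft(x)
  mult <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  oracle_env <- Mod(stats::fft(X * mult, inverse = TRUE) / n)
  # compare modulation depth at 5 Hz on a 3 s window (integer bin, no leakage)
  i <- 251:1750
  amp_pkg <- spectrum_amp(env2$samples[i] - mean(env2$samples[i]), rate, 5)
  amp_ora <- spectrum_amp(oracle_env[i] - mean(oracle_env[i]), rate, 5)
  expect_lt(abs(amp_pkg - amp_ora) / amp_ora, 0.05)
  expect_lt(abs(amp_pkg - m) / m, 0.1)

  # all-zero input stays zero
  expect_equal(hilbert_envelope(waveform(numeric(100), rate))$samples,
               numeric(100))

  expect_error(hilbert_envelope(waveform(1, rate)), class = "envtrack_length")
  expect_error(hilbert_envelope(waveform(rnorm(100), 40)),
               class = "envtrack_filter_design")
})

test_that("preprocess_envelope rectifies, differences and normalises", {
  # strictly increasing ramp: N-1 equal increments
  N <- 60
  env <- waveform(seq(0, 1, length.out = N), 50)
  me <- preprocess_envelope(env, 50)
  expect_length(me$samples, N - 1)
  expect_equal(me$samples, rep(1 / (N - 1), N - 1), tolerance = 1e-12)
  expect_equal(sum(me$samples), 1, tolerance = 1e-9)

  # strictly decreasing: degenerate
  expect_error(preprocess_envelope(waveform(seq(1, 0, length.out = N), 50), 50),
               class = "envtrack_degenerate_envelope")

  # 5 Hz AM envelope downsampled to 50 Hz matches the brute-force chain
  rate <- 250
  t <- (0:999) / rate
  x <- 1 + 0.5 * sin(2 * pi * 5 * t)
  me2 <- preprocess_envelope(waveform(x, rate), 50)
  xr <- resample(x, rate, 50)
  d <- numeric(length(xr) - 1)
  for (i in seq_along(d)) d[i] <- max((xr[i + 1] - xr[i]) * 50, 0)
  expect_equal(me2$samples, d / sum(d), tolerance = 1e-12)
  expect_true(all(me2$samples >= 0))

  expect_error(preprocess_envelope(waveform(x, rate), 500),
               class = "envtrack_parameter")
})

test_that("fir_bandpass separates bands for both designs", {
  rate <- 250
  t <- (0:4095) / rate
  x <- sin(2 * pi * 3 * t) + sin(2 * pi * 30 * t)
  for (kind in c("least_squares", "gaussian")) {
    # for the Gaussian kernel unit gain holds at the band centre (3 Hz)
    band <- if (kind == "gaussian") c(1, 5) else c(1, 20)
    y <- fir_bandpass(x, rate, band[1], band[2], kind = kind)
    a3 <- spectrum_amp(y, rate, 3)
    a30 <- spectrum_amp(y, rate, 30)
    expect_gt(20 * log10(a3 / a30), 20) # stop-band down >= 20 dB
    expect_gt(a3, 0.95) # pass-band tone retained
  }
  # DC through a band-pass vanishes (away from the kernel-length edges)
  y0 <- fir_bandpass(rep(2, 6000), rate, 1, 20)
  expect_lt(max(abs(y0[2500:3500])), 0.05)

  expect_error(fir_bandpass(x, rate, 20, 1), class = "envtrack_parameter")
  expect_error(fir_bandpass(x, rate, 1, 200), class = "envtrack_parameter")
})

test_that("filters are linear", {
  set.seed(7)
  rate <- 250
  x <- rnorm(500); y <- rnorm(500)
  a <- 2.5; b <- -1.25
  f <- function(z) fir_bandpass(z, rate, 1, 20)
  lhs <- f(a * x + b * y)
  rhs <- a * f(x) + b * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)
})

test_that("resample is anti-aliased and rate-consistent", {
  expect_equal(resample(rep(3.2, 100), 250, 50), rep(3.2, 20), tolerance = 1e-6)
  x <- rnorm(100)
  expect_identical(resample(x, 250, 250), x)

  t <- (0:999) / 250
  tone <- sin(2 * pi * 5 * t)
  y <- resample(tone, 250, 50)
  expect_equal(length(y), 200)
  expect_lt(abs(spectrum_amp(y, 50, 5) - 1), 0.02)

  # round trip preserves band-limited signals (interior)
  z <- resample(y, 50, 250)
  n <- length(z)
  i <- 100:(n - 100)
  expect_lt(sqrt(mean((z[i] - tone[i])^2)) / sqrt(mean(tone[i]^2)), 0.02)

  expect_error(resample(x, -1, 50), class = "envtrack_parameter")
})

test_that("average_epochs averages repetitions then channels", {
  mk <- function(data) eeg_epoch(data, 250, c(-100, 500))
  d <- matrix(rnorm(4 * 10), 4, 10)
  e <- mk(d)
  expect_equal(average_epochs(list(e, e, e), 2:4), colMeans(d[2:4, ]))
  expect_equal(average_epochs(list(mk(d), mk(-d)), 1:4), rep(0, 10))

  # brute-force double mean over 4 random epochs, 3-channel subset
  set.seed(11)
  eps <- lapply(1:4, function(i) mk(matrix(rnorm(40), 4, 10)))
  sub <- c(1, 3, 4)
  brute <- numeric(10)
  for (tt in 1:10) {
    acc <- 0
    for (ch in sub) for (e in eps) acc <- acc + e$data[ch, tt]
    brute[tt] <- acc / (length(sub) * 4)
  }
  expect_equal(average_epochs(eps, sub), brute, tolerance = 1e-12)

  bad <- eeg_epoch(d, 500, c(-100, 500))
  expect_error(average_epochs(list(e, bad), 1:2), class = "envtrack_alignment")
  expect_error(average_epochs(list(e), integer(0)), class = "envtrack_parameter")
})

test_that("WAV round trip preserves 16-bit audio", {
  set.seed(3)
  w <- waveform(runif(2000, -0.9, 0.9), 16000, id = "rt")
  path <- file.path(tempdir(), "rt.wav")
  write_wav(w, path)
  w2 <- read_wav(path)
  expect_equal(w2$rate_hz, 16000)
  expect_equal(w2$samples, round(w$samples * 32768) / 32768, tolerance = 1e-12)
})

test_that("EEG epoch container round trips losslessly", {
  set.seed(9)
  epochs <- list()
  for (p in 1:2) for (s in 1:2) for (r in 1:2) {
    epochs[[length(epochs) + 1]] <- eeg_epoch(
      matrix(rnorm(3 * 10), 3, 10), 250, c(-100, 500),
      participant_id = sprintf("P%02d", p),
      stimulus_id = sprintf("s%02d", s), repetition_index = r)
  }
  path <- file.path(tempdir(), "eegc")
  unlink(path, recursive = TRUE)
  write_eeg_container(epochs, path)
  back <- read_eeg_container(path)
  expect_length(back, 8)
  key <- function(e) paste(e$participant_id, e$stimulus_id, e$repetition_index)
  back_by <- stats::setNames(back, vapply(back, key, character(1)))
  for (e in epochs) {
    b <- back_by[[key(e)]]
    expect_identical(b$data, e$data)
    expect_identical(b$rate_hz, e$rate_hz)
    expect_identical(b$window_ms, e$window_ms)
  }
  mf <- list.files(path, pattern = "json$", recursive = TRUE, full.names = TRUE)
  meta <- jsonlite::read_json(mf[1]); meta$rate_hz <- NULL
  jsonlite::write_json(meta, mf[1], auto_unbox = TRUE)
  expect_error(read_eeg_container(path), class = "envtrack_schema")
})

test_that("post_onset_series cuts from stimulus onset", {
  s <- 1:100
  # window -100..300 ms at 250 Hz: onset at sample 26
  cut <- post_onset_series(s, 250, c(-100, 300), 0.2)
  expect_equal(cut, 26:75)
  expect_error(post_onset_series(s, 250, c(-100, 300), 10),
               class = "envtrack_parameter")
})
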