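test_that("cross_correlate matches impulse algebra and the loop oracle", {
  rate <- 50
  e <- numeric(40); e[10] <- 1
  r <- numeric(40); r[17] <- 1
  cg <- cross_correlate(e, r, max_lag_ms = 500, rate_hz = rate)
  nz <- which(cg$values != 0)
  expect_length(nz, 1)
  expect_equal(cg$lags_ms[nz], 7 / rate * 1000)
  expect_equal(cg$values[nz], 1)

  expect_equal(cross_correlate(e, numeric(40), 500, rate)$values,
               rep(0, 2 * 25 + 1))

  set.seed(21)
  e2 <- rnorm(80); r2 <- rnorm(80)
  cg2 <- cross_correlate(e2, r2, max_lag_ms = 200, rate_hz = rate)
  expect_equal(cg2$values, oracle_xcorr(e2, r2, 10), tolerance = 1e-10)
})

test_that("cross_correlate is bilinear and shift-equivariant", {
  set.seed(2)
  rate <- 50
  e <- abs(rnorm(60)); r <- rnorm(60)
  a <- 3.7
  c1 <- cross_correlate(e, a * r, 300, rate)$values
  c2 <- a * cross_correlate(e, r, 300, rate)$values
  expect_equal(c1, c2, tolerance = 1e-12)
  # shifting the response by +k samples shifts the correlogram by +k
  # (response padded so the shift loses no samples off the end)
  k <- 4
  r[(60 - k + 1):60] <- 0
  r_shift <- c(rep(0, k), r)[1:60]
  cs <- cross_correlate(e, r_shift, 300, rate)$values
  c0 <- cross_correlate(e, r, 300, rate)$values
  max_lag <- 15
  interior <- (k + 1):(2 * max_lag + 1)
  expect_equal(cs[interior], c0[interior - k], tolerance = 1e-8)
})

test_that("make_null_pairing avoids self pairs and is seeded", {
  p2 <- make_null_pairing(c("a", "b"), 1)
  expect_equal(unname(p2[c("a", "b")]), c("b", "a"))

  ids <- sprintf("s%02d", 1:25)
  m1 <- make_null_pairing(ids, 99)
  m2 <- make_null_pairing(ids, 99)
  expect_identical(m1, m2)
  expect_true(all(m1 != names(m1)))
  expect_true(all(m1 %in% ids))
  expect_error(make_null_pairing("only", 1), class = "envtrack_pairing")
})

test_that("select_top_nodes keeps strict-percentile winners", {
  base <- mk_cg(sin(seq(-pi, pi, length.out = 21)))
  # identical nodes / a single node go through the documented tie fallback
  expect_equal(suppressWarnings(select_top_nodes(list(base, base, base))$values),
               base$values)
  expect_equal(suppressWarnings(select_top_nodes(list(base))$values),
               base$values)

  # statistics 1..10: percentile 20 keeps the 8 nodes above 2.8
  nodes <- lapply(1:10, function(s) mk_cg(c(rep(0, 10), s, rep(0, 10))))
  out <- select_top_nodes(nodes, 20)
  expect_equal(out$provenance$n_kept, 8)
  rows <- do.call(rbind, lapply(nodes, `[[`, "values"))
  expect_equal(out$values, oracle_select(rows, 20), tolerance = 1e-12)

  # degenerate ties: nothing strictly above the threshold -> warn, keep all
  same <- lapply(1:4, function(i) mk_cg(rep(1, 21)))
  expect_warning(res <- select_top_nodes(same, 20),
                 class = "envtrack_empty_selection")
  expect_equal(res$values, rep(1, 21))
})

test_that("extract_peak finds planted lobes and flags edges", {
  lags <- seq(-1000, 1000, by = 20)
  v <- -exp(-(lags - 140)^2 / (2 * 30^2))
  cg <- mk_cg(v)
  pk <- extract_peak(cg, 140, 60, "min")
  expect_equal(pk$latency_ms, 140)
  expect_false(pk$at_edge)
  expect_true(pk$latency_ms >= pk$search_window_ms[1] &&
              pk$latency_ms <= pk$search_window_ms[2])

  mono <- mk_cg(seq_along(lags) * 1.0)
  pk2 <- extract_peak(mono, 140, 60, "max")
  expect_true(pk2$at_edge)
  expect_error(extract_peak(cg, 5000, 50, "min"), class = "envtrack_parameter")
})

test_that("paired_peak_test matches closed forms and flags degeneracy", {
  x <- c(5, 6, 7)
  expect_equal(paired_peak_test(x, x)$t_statistic, 0)
  expect_equal(paired_peak_test(x, x)$p_value, 1)

  # differences {1,2,3}: t = 2 / (1/sqrt(3)) = 2*sqrt(3)
  m <- c(2, 4, 6); u <- c(1, 2, 3)
  tt <- paired_peak_test(m, u)
  expect_equal(tt$t_statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(tt$df, 2)

  d <- paired_peak_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(d$degenerate)
  expect_equal(d$t_statistic, Inf)
  expect_equal(d$p_value, 0)

  ts <- paired_peak_test(rnorm(15) + 1, rnorm(15), mode = "two_sample")
  expect_equal(ts$df, 28)

  expect_error(paired_peak_test(1:3, 1:4), class = "envtrack_alignment")
  expect_error(paired_peak_test(1:2, 1:2), class = "envtrack_parameter")
})

test_that("planted response kernels are recovered at the planted lag", {
  # noiseless planted trough: argmin at the configured network lag
  cfg <- tiny_cfg(net_noise_rel = 0, layer_lag_ms = 140)
  stim <- gen_stimulus(cfg, 1)
  acts <- gen_network_responses(cfg, stim, 1, mode = "trained")
  env <- stimulus_envelope(stim, cfg$net_frame_rate_hz)
  cg <- layer_correlogram(env, acts[[4]], max_lag_ms = 400)
  expect_lt(abs(cg$lags_ms[which.min(cg$values)] - 140), 21)

  # null pairing has no systematic extremum: mean over seeds ~ 0 at the lag
  at_lag <- vapply(1:12, function(s) {
    cfgs <- tiny_cfg(net_noise_rel = 0, master_seed = 100L + s)
    st1 <- gen_stimulus(cfgs, 1); st2 <- gen_stimulus(cfgs, 2)
    a <- gen_network_responses(cfgs, st2, 2, mode = "trained")
    e <- stimulus_envelope(st1, cfgs$net_frame_rate_hz)
    cgk <- layer_correlogram(e, a[[4]], max_lag_ms = 400)
    cgk$values[which.min(abs(cgk$lags_ms - 140))]
  }, numeric(1))
  matched_val <- min(cg$values)
  expect_lt(abs(mean(at_lag)), abs(matched_val) * 0.35)
})
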