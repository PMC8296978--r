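test_that("response_vector pools channels in channel-major order", {
  d <- matrix(1:12, 2, 6, byrow = TRUE) # ch1: 1..6, ch2: 7..12
  ep <- eeg_epoch(d, 10, c(-100, 500))
  # onset at sample 2; window 0.4 s -> 4 samples
  v <- response_vector(ep, 1:2, 0.4)
  expect_equal(v, c(2:5, 8:11))
  expect_equal(response_vector(ep, 2, 0.4), 8:11)
  expect_error(response_vector(ep, 1:3, 0.4), class = "envtrack_alignment")
  expect_error(response_vector(ep, 1, 5), class = "envtrack_parameter")
})

test_that("compute_rdm matches the loop oracle", {
  v <- lapply(1:4, function(i) rep(1.5, 7))
  r0 <- compute_rdm(v)
  expect_equal(r0$matrix, matrix(0, 4, 4))

  a <- c(1, 2, 3); b <- c(1, 2, 7)
  r1 <- compute_rdm(list(a, b))
  expect_equal(r1$matrix[1, 2], 4)

  set.seed(13)
  vecs <- lapply(1:5, function(i) rnorm(7))
  r2 <- compute_rdm(vecs)
  expect_equal(r2$matrix, oracle_rdm(vecs), tolerance = 1e-10)
  expect_equal(r2$matrix, t(r2$matrix))
  expect_equal(diag(r2$matrix), rep(0, 5))

  expect_error(compute_rdm(list(1:3, 1:4)), class = "envtrack_alignment")
})

test_that("average_rdms is the elementwise mean", {
  set.seed(17)
  r <- compute_rdm(lapply(1:4, function(i) rnorm(6)))
  r3 <- r; r3$matrix <- 3 * r$matrix
  avg <- average_rdms(list(r, r3))
  expect_equal(avg$matrix, 2 * r$matrix, tolerance = 1e-12)
  expect_equal(average_rdms(list(r))$matrix, r$matrix)

  rs <- lapply(1:4, function(i) compute_rdm(lapply(1:5, function(j) rnorm(6))))
  m <- average_rdms(rs)$matrix
  brute <- (rs[[1]]$matrix + rs[[2]]$matrix + rs[[3]]$matrix + rs[[4]]$matrix) / 4
  expect_equal(m, brute, tolerance = 1e-12)

  bad <- rs[[1]]; bad$stimulus_order <- rev(bad$stimulus_order)
  expect_error(average_rdms(list(rs[[1]], bad)), class = "envtrack_alignment")
})

test_that("compare_rdms is Spearman on the lower triangle", {
  set.seed(19)
  a <- compute_rdm(lapply(1:6, function(i) rnorm(8)))
  expect_equal(compare_rdms(a, a), 1)
  sq <- a; sq$matrix <- a$matrix^2
  expect_equal(compare_rdms(a, sq), 1) # monotone invariance

  b <- compute_rdm(lapply(1:6, function(i) rnorm(8)))
  expect_equal(compare_rdms(a, b),
               oracle_spearman(a$matrix[lower.tri(a$matrix)],
                               b$matrix[lower.tri(b$matrix)]),
               tolerance = 1e-12)

  const <- a; const$matrix[] <- 1; diag(const$matrix) <- 0
  expect_error(compare_rdms(a, const), class = "envtrack_degenerate_rdm")
})

test_that("rank_transform scales average-tie ranks into [0,1]", {
  m <- matrix(0, 3, 3)
  m[lower.tri(m)] <- c(1, 5, 9)
  m <- m + t(m)
  r <- rank_transform(new_rdm_for_test(m))
  expect_equal(sort(r$matrix[lower.tri(r$matrix)]), c(0, 0.5, 1))

  m2 <- matrix(2, 4, 4); diag(m2) <- 0
  r2 <- rank_transform(new_rdm_for_test(m2))
  expect_true(all(r2$matrix[lower.tri(r2$matrix)] == 0.5))
  expect_equal(diag(r2$matrix), rep(0, 4))

  set.seed(23)
  r3in <- compute_rdm(lapply(1:7, function(i) rnorm(5)))
  r3 <- rank_transform(r3in)
  expect_equal(oracle_spearman(r3in$matrix[lower.tri(r3in$matrix)],
                               r3$matrix[lower.tri(r3$matrix)]), 1,
               tolerance = 1e-12)
  expect_equal(r3$matrix, t(r3$matrix))
})

test_that("noise_ceiling brackets participant consistency", {
  set.seed(29)
  shared <- lapply(1:6, function(i) rnorm(10))
  identical_rdms <- lapply(1:5, function(p) compute_rdm(shared))
  nc <- noise_ceiling(identical_rdms)
  expect_equal(nc$lower, 1)
  expect_equal(nc$upper, 1)

  noisy <- lapply(1:5, function(p)
    compute_rdm(lapply(shared, function(v) v + rnorm(10, sd = 0.7))))
  nc2 <- noise_ceiling(noisy)
  expect_lte(nc2$lower, nc2$upper)
  expect_error(noise_ceiling(noisy[1]), class = "envtrack_parameter")
})

test_that("layer_profile compares trained against the ensemble", {
  set.seed(31)
  eeg <- lapply(1:15, function(p) compute_rdm(lapply(1:8, function(i) rnorm(12))))
  trained <- lapply(1:5, function(l) compute_rdm(lapply(1:8, function(i) rnorm(12))))
  # ensemble identical to the trained network: all differences are zero
  prof <- layer_profile(eeg, trained, list(trained, trained))
  expect_true(all(abs(prof$t_statistic) < 1e-10))
  expect_true(all(prof$p_value > 0.99))
  expect_equal(prof$df, rep(28, 5)) # two-sample mode, 15 participants
  expect_error(layer_profile(eeg[1], trained, list(trained)),
               class = "envtrack_parameter")
})

test_that("band_rsa localises a band-limited representation", {
  # EEG signal confined to 4-6 Hz; the layer RDM is built from the same
  # band-limited signatures, so |rho| must peak in the 4-6 Hz band
  set.seed(37)
  rate <- 250
  n <- 500
  nS <- 6
  t <- (0:(n - 1)) / rate
  sig <- lapply(1:nS, function(i)
    sin(2 * pi * runif(1, 4.2, 5.8) * t + runif(1, 0, 2 * pi)) * runif(1, 0.5, 2))
  mk_part <- function(noise_sd) {
    lapply(1:nS, function(i) {
      lapply(1:2, function(r) {
        d <- rbind(sig[[i]] + rnorm(n, sd = noise_sd),
                   sig[[i]] + rnorm(n, sd = noise_sd))
        eeg_epoch(cbind(matrix(0, 2, 25), d), rate, c(-100, 1900),
                  participant_id = "P", stimulus_id = i, repetition_index = r)
      })
    })
  }
  parts <- list(mk_part(0.2), mk_part(0.2))
  layer <- compute_rdm(lapply(sig, function(s) rep(s, 2)))
  tab <- band_rsa(parts, 1:2, n / rate, list(layer),
                  band_edges_hz = seq(0, 12, by = 2))
  best <- tab$band_lo[which.max(abs(tab$rho))]
  expect_equal(best, 4)
})

test_that("electrode_rsa masks non-significant electrodes to exactly zero", {
  set.seed(41)
  rate <- 50; n <- 100; nS <- 5; nE <- 6
  sig <- lapply(1:nS, function(i) rnorm(n))
  # electrodes 1-2 carry the signal, 3-6 pure noise
  mk_part <- function() {
    lapply(1:nS, function(i) {
      lapply(1:2, function(r) {
        d <- rbind(sig[[i]] + rnorm(n, sd = 0.2), sig[[i]] + rnorm(n, sd = 0.2),
                   matrix(rnorm(4 * n), 4, n))
        eeg_epoch(cbind(matrix(0, nE, 5), d), rate, c(-100, 2000),
                  participant_id = "P", stimulus_id = i, repetition_index = r)
      })
    })
  }
  parts <- lapply(1:4, function(p) mk_part())
  trained <- list(compute_rdm(sig))
  untr <- lapply(1:2, function(k)
    list(compute_rdm(lapply(1:nS, function(i) rnorm(n)))))
  em <- electrode_rsa(parts, n / rate, trained, untr, alpha = 0.05)
  expect_true(all(em$masked_rho[!em$mask] == 0))
  expect_true(all(em$mask[1:2, 1]))
  expect_equal(dim(em$rho), c(nE, 1))
})
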