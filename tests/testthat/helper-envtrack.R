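# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (double loops, closed forms) and never call the code
# paths they check.

# --- oracles -----------------------------------------------------------

# raw cross-correlation, double loop
oracle_xcorr <- function(e, r, max_lag) {
  n <- min(length(e), length(r))
  vals <- numeric(2 * max_lag + 1)
  for (j in seq_along(vals)) {
    k <- j - max_lag - 1
    s <- 0
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) s <- s + e[t] * r[t + k]
    }
    vals[j] <- s
  }
  vals
}

# Euclidean RDM, double loop
oracle_rdm <- function(vecs) {
  n <- length(vecs)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sqrt(sum((vecs[[i]] - vecs[[j]])^2))
    }
  }
  m
}

# average-tie ranks by counting, then Pearson from first principles
oracle_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# percentile-selection + pointwise mean, loops
oracle_select <- function(value_rows, percentile) {
  stat <- apply(abs(value_rows), 1, max)
  thr <- stats::quantile(stat, percentile / 100, names = FALSE)
  keep <- which(stat > thr)
  if (length(keep) == 0) keep <- seq_len(nrow(value_rows))
  colMeans(value_rows[keep, , drop = FALSE])
}

# amplitude of the DFT bin nearest f_hz
spectrum_amp <- function(x, rate_hz, f_hz) {
  n <- length(x)
  bin <- round(f_hz * n / rate_hz)
  2 * Mod(stats::fft(x)[bin + 1]) / n
}

# --- fixtures ----------------------------------------------------------

tiny_cfg <- function(...) {
  defaults <- list(n_stimuli = 3L, n_participants = 2L, n_repetitions = 2L,
                   n_channels = 4L, frontocentral_subset = 1:3,
                   n_units = 6L, n_untrained = 2L, master_seed = 42L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# small random correlogram object on a given lag axis
mk_cg <- function(values, rate_hz = 50, pairing = "matched") {
  max_lag <- (length(values) - 1) / 2
  structure(list(lags_ms = (-max_lag:max_lag) / rate_hz * 1000,
                 values = values, rate_hz = rate_hz, pairing = pairing,
                 provenance = list()),
            class = "cross_correlogram")
}

mk_rdm_from_vecs <- function(vecs) compute_rdm(vecs)

# wrap a raw symmetric matrix as an rdm object
new_rdm_for_test <- function(m) {
  structure(list(matrix = m, metric = "euclidean", source = "test",
                 stimulus_order = seq_len(nrow(m))),
            class = "rdm")
}
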