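# FIR design and zero-phase filtering primitives.
#
# No signal-processing package ships with the analysis environment, so the
# three kernels the pipeline needs are designed here on top of stats::fft:
#   * least-squares linear-phase FIR (type I) for the 25 Hz envelope
#     low-pass and the 1-20 Hz EEG band-pass,
#   * Gaussian-frequency-response FIR for the 2 Hz band decomposition,
#   * Hamming-windowed sinc for anti-alias filtering inside resample().
# All kernels are symmetric (exactly linear phase); application compensates
# the group delay so filtering is zero-phase by construction.

# cache: LS designs are O(M^3) to solve; key on the design parameters.
.fir_cache <- new.env(parent = emptyenv())

# integral of cos(2*pi*nu*m) over [a, b] (normalized frequency nu, cycles
# per sample, Nyquist = 0.5)
.cos_int <- function(m, a, b) {
  if (m == 0) return(b - a)
  (sin(2 * pi * b * m) - sin(2 * pi * a * m)) / (2 * pi * m)
}

# Least-squares type-I FIR over a set of bands with constant desired
# amplitude per band; frequencies in normalized units, don't-care gaps
# between bands are excluded from the error integral.
fir_design_ls <- function(order, bands, desired, weights = NULL) {
  stopifnot(order %% 2 == 0, nrow(bands) == length(desired))
  # weight each band by 1/width by default so narrow stop/pass bands are
  # not sacrificed to wide ones in the integrated squared error
  weights <- weights %||% (1 / (bands[, 2] - bands[, 1]))
  key <- paste("ls", order,
               paste(signif(c(t(bands), desired, weights), 10), collapse = ","),
               sep = "|")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  M <- order / 2
  k <- 0:M
  Q <- matrix(0, M + 1, M + 1)
  d <- numeric(M + 1)
  for (b in seq_len(nrow(bands))) {
    lo <- bands[b, 1]; hi <- bands[b, 2]
    Ivals <- vapply(0:(2 * M), .cos_int, numeric(1), a = lo, b = hi)
    # Q_{ij} = 1/2 * (I(|i-j|) + I(i+j))
    idx_diff <- abs(outer(k, k, "-")) + 1
    idx_sum <- outer(k, k, "+") + 1
    Q <- Q + weights[b] *
      0.5 * (matrix(Ivals[idx_diff], M + 1) + matrix(Ivals[idx_sum], M + 1))
    d <- d + weights[b] * desired[b] * Ivals[k + 1]
  }
  a <- solve(Q, d)
  h <- c(rev(a[-1] / 2), a[1], a[-1] / 2)
  .fir_cache[[key]] <- h
  h
}

# Order rule: 4 * (rate / transition width), rounded to even, capped so the
# normal-equation solve stays tractable (the transition widens at high
# sampling rates; see the methods vignette).
.fir_ls_order <- function(rate_hz, transition_hz, cap = 4000L) {
  n <- round(4 * rate_hz / transition_hz)
  n <- min(n, cap)
  n <- max(n, 16)
  if (n %% 2 == 1) n <- n + 1
  as.integer(n)
}

# Least-squares low-pass: passband [0, cutoff], transition, stopband to
# Nyquist. cutoff/transition in Hz.
fir_lowpass_ls <- function(rate_hz, cutoff_hz, transition_hz = 5) {
  if (cutoff_hz >= rate_hz / 2) {
    stop_envtrack("envtrack_filter_design",
      sprintf("cutoff %g Hz not below Nyquist (%g Hz)", cutoff_hz, rate_hz / 2))
  }
  order <- .fir_ls_order(rate_hz, transition_hz)
  trans <- 4 * rate_hz / order # effective transition after cap
  f_stop <- min((cutoff_hz + trans) / rate_hz, 0.5)
  bands <- rbind(c(0, cutoff_hz / rate_hz), c(f_stop, 0.5))
  if (f_stop >= 0.5) bands <- bands[1, , drop = FALSE]
  fir_design_ls(order, bands, if (nrow(bands) == 2) c(1, 0) else 1)
}

fir_bandpass_ls <- function(rate_hz, lo_hz, hi_hz, transition_hz = NULL) {
  trans <- transition_hz %||% min(max(lo_hz / 2, 0.25), 5)
  order <- .fir_ls_order(rate_hz, trans)
  trans_eff <- min(4 * rate_hz / order, trans)
  f1s <- max((lo_hz - trans_eff) / rate_hz, 0)
  f2s <- min((hi_hz + trans_eff) / rate_hz, 0.5)
  bands <- rbind(c(0, f1s), c(lo_hz / rate_hz, hi_hz / rate_hz), c(f2s, 0.5))
  desired <- c(0, 1, 0)
  keep <- bands[, 2] > bands[, 1]
  fir_design_ls(order, bands[keep, , drop = FALSE], desired[keep])
}

# Gaussian band filter: FIR kernel whose frequency response is a Gaussian
# centred on the band, sigma = half band-width, truncated at 4 sigma (in
# time). Used for the 2 Hz band decomposition.
fir_gaussian <- function(rate_hz, lo_hz, hi_hz) {
  f0 <- (lo_hz + hi_hz) / 2
  sigma_f <- (hi_hz - lo_hz) / 2
  if (sigma_f <= 0) stop_envtrack("envtrack_filter_design", "empty Gaussian band")
  sigma_t <- 1 / (2 * pi * sigma_f) # seconds
  half <- ceiling(4 * sigma_t * rate_hz)
  t <- (-half:half) / rate_hz
  h <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
  # normalise to unit gain at the band centre
  gain <- sum(h * cos(2 * pi * f0 * t))
  h / gain
}

# Hamming-windowed sinc low-pass with given half-width in taps; closed-form
# design used for anti-alias filtering in resample().
fir_sinc_hamming <- function(cutoff_norm, half_width) {
  n <- (-half_width):half_width
  h <- 2 * cutoff_norm * sinc_fn(2 * cutoff_norm * n)
  w <- 0.54 + 0.46 * cos(pi * n / half_width)
  h <- h * w
  h / sum(h)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase application of a symmetric odd-length FIR kernel via FFT
# convolution; group delay (len-1)/2 is removed so output aligns with input.
# pad = "edge" replicates boundary samples (keeps constants constant);
# pad = "zero" zero-pads.
apply_fir <- function(x, h, pad = c("edge", "zero")) {
  pad <- match.arg(pad)
  n <- length(x)
  m <- length(h)
  half <- (m - 1) / 2
  xp <- if (pad == "edge") c(rep(x[1], half), x, rep(x[n], half)) else c(rep(0, half), x, rep(0, half))
  L <- length(xp) + m - 1
  nfft <- 2^ceiling(log2(L))
  X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
  H <- stats::fft(c(h, rep(0, nfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  # full convolution starts at index 1; remove kernel delay + padding
  y[(2 * half + 1):(2 * half + n)]
}

# Columnwise zero-phase filtering of a matrix (time along rows).
apply_fir_mat <- function(X, h, pad = c("edge", "zero")) {
  pad <- match.arg(pad)
  n <- nrow(X)
  m <- length(h)
  half <- (m - 1) / 2
  top <- if (pad == "edge") X[rep(1, half), , drop = FALSE] else matrix(0, half, ncol(X))
  bot <- if (pad == "edge") X[rep(n, half), , drop = FALSE] else matrix(0, half, ncol(X))
  Xp <- rbind(top, X, bot)
  L <- nrow(Xp) + m - 1
  nfft <- 2^ceiling(log2(L))
  Xf <- stats::mvfft(rbind(Xp, matrix(0, nfft - nrow(Xp), ncol(Xp))))
  H <- stats::fft(c(h, rep(0, nfft - m)))
  Y <- Re(stats::mvfft(Xf * H, inverse = TRUE)) / nfft
  Y[(2 * half + 1):(2 * half + n), , drop = FALSE]
}

# Analytic signal via the frequency-domain method. For long inputs the
# signal is zero-padded to the next power of two (arbitrary lengths can hit
# near-worst-case mixed-radix FFT sizes) and the result truncated; short
# inputs use the exact DFT length.
analytic_signal <- function(x) {
  n0 <- length(x)
  if (n0 > 8192) {
    nfft <- 2^ceiling(log2(n0))
    if (nfft > n0) return(analytic_signal(c(x, rep(0, nfft - n0)))[seq_len(n0)])
  }
  n <- length(x)
  X <- stats::fft(x)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[1] <- 1
    mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * mult, inverse = TRUE) / n
}
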