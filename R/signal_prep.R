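#' Construct a waveform object
#'
#' A waveform is the basic time-series container for stimuli and derived
#' envelopes: a numeric sample vector with its sampling rate and the sample
#' index of stimulus onset (1-based; 1 means the recording starts at onset).
#'
#' @param samples numeric vector, finite.
#' @param rate_hz sampling rate in Hz, > 0.
#' @param onset_index sample index of stimulus onset (default 1).
#' @param id optional identifier carried through processing.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, rate_hz, onset_index = 1L, id = NULL) {
  if (!is.numeric(samples)) stop_envtrack("envtrack_type", "samples must be numeric")
  assert_finite(samples, "waveform samples")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop_envtrack("envtrack_parameter", "rate_hz must be a positive scalar")
  }
  structure(list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
                 onset_index = as.integer(onset_index), id = id),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform%s: %d samples @ %g Hz (%.3f s)>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz))
  invisible(x)
}

#' Amplitude envelope via the Hilbert transform
#'
#' Computes the magnitude of the analytic signal and low-pass filters it at
#' `cutoff_hz` with a least-squares linear-phase FIR filter applied with
#' zero phase. This is the first stage of the stimulus modulation-envelope
#' chain.
#'
#' @param w a [waveform()].
#' @param cutoff_hz low-pass cutoff in Hz (default 25).
#' @return a [waveform()] of the same length and rate, nonnegative up to
#'   small filter ripple (clamped at zero).
#' @export
hilbert_envelope <- function(w, cutoff_hz = 25) {
  stopifnot(inherits(w, "waveform"))
  if (length(w$samples) < 2) {
    stop_envtrack("envtrack_length", "waveform too short for an envelope (need >= 2 samples)")
  }
  if (w$rate_hz <= 2 * cutoff_hz) {
    stop_envtrack("envtrack_filter_design",
      sprintf("sampling rate %g Hz too low for a %g Hz low-pass", w$rate_hz, cutoff_hz))
  }
  env <- Mod(analytic_signal(w$samples))
  h <- fir_lowpass_ls(w$rate_hz, cutoff_hz, transition_hz = 5)
  out <- apply_fir(env, h, pad = "edge")
  out[out < 0] <- 0
  waveform(out, w$rate_hz, w$onset_index, id = w$id)
}

#' Preprocess an amplitude envelope into a modulation envelope
#'
#' Downsamples the (already low-passed) envelope to the target rate, takes
#' the first derivative (first difference scaled by the rate, units 1/s),
#' half-wave rectifies it, and normalises the result to unit area so the
#' sum of samples is exactly 1. The resulting modulation envelope is the
#' drive signal cross-correlated against EEG and network responses.
#'
#' @param env a nonnegative [waveform()] (output of [hilbert_envelope()]).
#' @param target_rate_hz target sampling rate; must not exceed `env$rate_hz`.
#' @return a `modulation_envelope`: fields `samples` (nonnegative, sum 1),
#'   `rate_hz`, `source_stimulus_id`.
#' @export
preprocess_envelope <- function(env, target_rate_hz) {
  stopifnot(inherits(env, "waveform"))
  if (target_rate_hz > env$rate_hz) {
    stop_envtrack("envtrack_parameter", "target rate exceeds envelope rate")
  }
  x <- if (target_rate_hz == env$rate_hz) env$samples else
    resample(env$samples, env$rate_hz, target_rate_hz)
  d <- diff(x) * target_rate_hz
  d[d < 0] <- 0
  total <- sum(d)
  if (!is.finite(total) || total <= 1e-12) {
    stop_envtrack("envtrack_degenerate_envelope",
      "rectified envelope derivative sums to zero; unit-area normalisation undefined")
  }
  structure(list(samples = d / total, rate_hz = as.numeric(target_rate_hz),
                 source_stimulus_id = env$id),
            class = "modulation_envelope")
}

#' Zero-phase FIR band filtering
#'
#' Filters a sequence with either a least-squares linear-phase FIR design
#' (the 1-20 Hz EEG band-pass) or a Gaussian-frequency-response FIR (the
#' 2 Hz band decomposition). `lo_hz = 0` requests a low-pass. Application
#' is zero-phase (symmetric kernel, compensated delay) and length-preserving.
#'
#' @param x numeric sequence.
#' @param rate_hz sampling rate in Hz.
#' @param lo_hz,hi_hz band edges, 0 <= lo < hi < rate/2.
#' @param kind "least_squares" or "gaussian".
#' @return filtered numeric sequence, same length as `x`.
#' @export
fir_bandpass <- function(x, rate_hz, lo_hz, hi_hz, kind = c("least_squares", "gaussian")) {
  kind <- match.arg(kind)
  if (!(lo_hz >= 0 && lo_hz < hi_hz && hi_hz < rate_hz / 2)) {
    stop_envtrack("envtrack_parameter",
      sprintf("invalid band edges: need 0 <= lo < hi < rate/2, got [%g, %g] at %g Hz",
              lo_hz, hi_hz, rate_hz))
  }
  h <- fir_band_kernel(rate_hz, lo_hz, hi_hz, kind)
  pad <- if (lo_hz > 0) "zero" else "edge"
  if (is.matrix(x)) apply_fir_mat(x, h, pad = pad) else apply_fir(x, h, pad = pad)
}

# kernel shared by vector/matrix paths
fir_band_kernel <- function(rate_hz, lo_hz, hi_hz, kind) {
  if (kind == "gaussian") {
    fir_gaussian(rate_hz, lo_hz, hi_hz)
  } else if (lo_hz == 0) {
    fir_lowpass_ls(rate_hz, hi_hz)
  } else {
    fir_bandpass_ls(rate_hz, lo_hz, hi_hz)
  }
}

#' Anti-aliased rational-ratio resampling
#'
#' Resamples `x` from `rate_from` to `rate_to` by zero-stuffing with the
#' reduced upsampling factor, filtering with a Hamming-windowed-sinc
#' low-pass at half the lower of the two rates, and decimating. Output
#' length is `ceiling(length(x) * p / q)` for the reduced ratio p/q.
#'
#' @param x numeric sequence.
#' @param rate_from,rate_to sampling rates in Hz (> 0).
#' @return resampled numeric sequence.
#' @export
resample <- function(x, rate_from, rate_to) {
  if (rate_from <= 0 || rate_to <= 0) {
    stop_envtrack("envtrack_parameter", "sampling rates must be positive")
  }
  if (rate_from == rate_to) return(x)
  # reduce to a rational ratio (rates scaled to integers first)
  scale <- 1
  while (abs(rate_from * scale - round(rate_from * scale)) > 1e-9 ||
         abs(rate_to * scale - round(rate_to * scale)) > 1e-9) {
    scale <- scale * 10
    if (scale > 1e6) stop_envtrack("envtrack_parameter", "rates not rationally related")
  }
  a <- round(rate_to * scale); b <- round(rate_from * scale)
  g <- gcd_int(a, b)
  p <- a / g; q <- b / g
  n <- length(x)
  up <- if (p > 1) {
    u <- numeric(n * p)
    u[seq(1, n * p, by = p)] <- x
    u
  } else x
  half <- 10 * max(p, q)
  cutoff <- 0.5 / max(p, q) # normalised at the upsampled rate
  h <- fir_sinc_hamming(cutoff, half) * p
  y <- apply_fir(up, h, pad = "edge")
  y[seq(1, length(y), by = q)]
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Construct an EEG epoch
#'
#' One participant x stimulus x repetition epoch: a channel x time matrix
#' with its sampling rate and epoch window relative to stimulus onset.
#'
#' @param data channel x time numeric matrix (microvolts).
#' @param rate_hz sampling rate in Hz.
#' @param window_ms length-2 numeric, (start, end) ms relative to onset;
#'   start < 0 < end.
#' @param participant_id,stimulus_id,repetition_index provenance labels.
#' @return an object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, rate_hz, window_ms, participant_id = NA,
                      stimulus_id = NA, repetition_index = NA_integer_) {
  if (!is.matrix(data)) stop_envtrack("envtrack_type", "epoch data must be a channel x time matrix")
  if (!(window_ms[1] < 0 && window_ms[2] > 0)) {
    stop_envtrack("envtrack_parameter", "epoch window must straddle onset (start < 0 < end)")
  }
  structure(list(data = data, rate_hz = as.numeric(rate_hz),
                 window_ms = as.numeric(window_ms),
                 participant_id = participant_id, stimulus_id = stimulus_id,
                 repetition_index = repetition_index),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch p=%s s=%s rep=%s: %d ch x %d samples @ %g Hz, window [%g, %g] ms>\n",
              x$participant_id, x$stimulus_id, x$repetition_index,
              nrow(x$data), ncol(x$data), x$rate_hz, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

# sample index of onset within the epoch (1-based)
epoch_onset_index <- function(epoch) {
  as.integer(round(-epoch$window_ms[1] / 1000 * epoch$rate_hz)) + 1L
}

#' Average EEG epochs over repetitions and a channel subset
#'
#' Averages a list of epochs elementwise (reducing repetition noise), then
#' averages across the given channel subset, yielding a single time series.
#'
#' @param epochs list of [eeg_epoch()] sharing rate, window and channel count.
#' @param channel_subset integer channel indices (nonempty).
#' @return numeric time series (same length as the epoch time axis).
#' @export
average_epochs <- function(epochs, channel_subset) {
  if (length(epochs) == 0) stop_envtrack("envtrack_parameter", "no epochs to average")
  if (length(channel_subset) == 0) stop_envtrack("envtrack_parameter", "empty channel subset")
  ref <- epochs[[1]]
  for (e in epochs) {
    if (e$rate_hz != ref$rate_hz || !isTRUE(all.equal(e$window_ms, ref$window_ms)) ||
        nrow(e$data) != nrow(ref$data) || ncol(e$data) != ncol(ref$data)) {
      stop_envtrack("envtrack_alignment", "epochs differ in rate, window or dimensions")
    }
  }
  acc <- Reduce(`+`, lapply(epochs, `[[`, "data")) / length(epochs)
  colMeans(acc[channel_subset, , drop = FALSE])
}

#' Extract the post-onset response series from an epoch average
#'
#' Helper used by the tracking stage: cuts the averaged series from stimulus
#' onset for `duration_s` seconds.
#' @param series numeric time series on the epoch time axis.
#' @param rate_hz sampling rate.
#' @param window_ms epoch window (start, end) in ms.
#' @param duration_s length of the cut in seconds.
#' @return numeric vector of `round(duration_s * rate_hz)` samples.
#' @export
post_onset_series <- function(series, rate_hz, window_ms, duration_s) {
  i0 <- as.integer(round(-window_ms[1] / 1000 * rate_hz)) + 1L
  n <- as.integer(round(duration_s * rate_hz))
  if (i0 + n - 1L > length(series)) {
    stop_envtrack("envtrack_parameter", "requested window extends past the epoch end")
  }
  series[i0:(i0 + n - 1L)]
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE reader for the stimulus format used throughout
#' (16 kHz, 16-bit PCM, mono). Samples are scaled to [-1, 1).
#'
#' @param path file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_envtrack("envtrack_io", "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_envtrack("envtrack_io", "not a WAVE file")
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]; rate <- fmt[3] + fmt[4] * 65536; bits <- fmt[8]
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples) || is.null(rate)) stop_envtrack("envtrack_io", "missing fmt/data chunk")
  if (channels != 1 || bits != 16) {
    stop_envtrack("envtrack_io", "only 16-bit PCM mono WAV is supported")
  }
  waveform(samples / 32768, rate, id = sub("\\.wav$", "", basename(path)))
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' Samples are clipped to [-1, 1) and quantised to 16 bits.
#' @param w a [waveform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  s <- pmax(pmin(w$samples, 32767 / 32768), -1)
  pcm <- as.integer(round(s * 32768))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little") # PCM, mono
  writeBin(as.integer(w$rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate_hz * 2), con, size = 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Write EEG epochs to a hierarchical on-disk container
#'
#' Plain-text container mirroring the activation container: one directory
#' per participant / stimulus, one TSV per repetition (channel x time) with
#' a JSON sidecar holding `rate_hz`, `window_ms` and the identifiers. The
#' round trip is lossless at full double precision.
#'
#' @param epochs list of [eeg_epoch()].
#' @param path container root directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_eeg_container <- function(epochs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (e in epochs) {
    d <- file.path(path, as.character(e$participant_id), as.character(e$stimulus_id))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(d, sprintf("rep_%d.tsv", e$repetition_index))
    utils::write.table(format(e$data, digits = 17, scientific = TRUE, trim = TRUE),
                       f, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    meta <- list(rate_hz = e$rate_hz, window_ms = e$window_ms,
                 participant_id = e$participant_id, stimulus_id = e$stimulus_id,
                 repetition_index = e$repetition_index)
    jsonlite::write_json(meta, sub("\\.tsv$", ".json", f),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an EEG-epoch container written by [write_eeg_container()]
#'
#' @param path container root directory.
#' @return list of [eeg_epoch()] objects.
#' @export
read_eeg_container <- function(path) {
  metas <- list.files(path, pattern = "^rep_\\d+\\.json$", recursive = TRUE,
                      full.names = TRUE)
  if (length(metas) == 0) stop_envtrack("envtrack_io", "no EEG epochs found in container")
  lapply(sort(metas), function(mf) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    required <- c("rate_hz", "window_ms")
    missing <- setdiff(required, names(meta))
    if (length(missing) > 0) {
      stop_envtrack("envtrack_schema",
        sprintf("EEG container missing attributes: %s", paste(missing, collapse = ", ")))
    }
    dat <- as.matrix(utils::read.table(sub("\\.json$", ".tsv", mf), sep = "\t"))
    dimnames(dat) <- NULL
    eeg_epoch(dat, meta$rate_hz, meta$window_ms, meta$participant_id %||% NA,
              meta$stimulus_id %||% NA, meta$repetition_index %||% NA_integer_)
  })
}

#' Full stimulus-to-modulation-envelope chain
#'
#' Convenience wrapper: Hilbert envelope, 25 Hz least-squares low-pass,
#' downsample to `target_rate_hz`, rectified derivative, unit-area
#' normalisation.
#' @param w stimulus [waveform()].
#' @param target_rate_hz output rate (default 50 Hz, the network frame rate).
#' @return a `modulation_envelope`.
#' @export
stimulus_envelope <- function(w, target_rate_hz = 50) {
  preprocess_envelope(hilbert_envelope(w), target_rate_hz)
}
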