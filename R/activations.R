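#' Construct a layer activation set
#'
#' Unit x frame activations of one network layer for one stimulus, with the
#' metadata needed to align them to the stimulus and to group trained vs
#' untrained instances. Layers 1-5 are the analysed hidden layers (the
#' softmax output layer is excluded from all analyses); layer 4 is the
#' recurrent (LSTM) layer.
#'
#' @param data unit x frame numeric matrix.
#' @param layer_index integer in 1..5.
#' @param frame_rate_hz frame rate in Hz.
#' @param network_id identifier of the network instance.
#' @param trained logical flag.
#' @param stimulus_id stimulus identifier.
#' @param shuffle_seed integer seed of an untrained instance, or NA.
#' @return an object of class `layer_activation_set`.
#' @export
layer_activation_set <- function(data, layer_index, frame_rate_hz, network_id,
                                 trained, stimulus_id, shuffle_seed = NA_integer_) {
  if (!is.matrix(data)) stop_envtrack("envtrack_type", "activations must be a unit x frame matrix")
  if (!(layer_index >= 1 && layer_index <= 5)) {
    stop_envtrack("envtrack_parameter", "layer_index must be in 1..5")
  }
  structure(list(data = data, layer_index = as.integer(layer_index),
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 network_id = network_id, trained = isTRUE(trained),
                 stimulus_id = stimulus_id,
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "layer_activation_set")
}

#' Specify a surrogate (architecture-matched, random-weight) network
#'
#' The surrogate mirrors the analysed architecture: three feed-forward
#' layers with clipped ReLU activation, a unidirectional LSTM layer, and a
#' fifth clipped-ReLU layer. "Untrained" means randomly initialised:
#' weights are drawn uniformly in [-init_scale, init_scale] from `seed`.
#'
#' @param layer_sizes integer vector of 5 layer widths (layer 4 recurrent).
#' @param input_feature_count feature dimension fed to layer 1.
#' @param frame_rate_hz frame rate of the activations (default 50).
#' @param relu_clip clipping ceiling for the ReLU layers (default 20).
#' @param init_scale half-width of the uniform weight initialisation.
#' @param seed integer seed the weights are drawn from.
#' @return an object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(layer_sizes = rep(64L, 5), input_feature_count = 26L,
                           frame_rate_hz = 50, relu_clip = 20,
                           init_scale = 0.5, seed = 0L) {
  if (length(layer_sizes) != 5 || any(layer_sizes < 1)) {
    stop_envtrack("envtrack_parameter", "layer_sizes must be 5 positive integers")
  }
  if (relu_clip <= 0 || init_scale <= 0) {
    stop_envtrack("envtrack_parameter", "relu_clip and init_scale must be positive")
  }
  structure(list(layer_sizes = as.integer(layer_sizes),
                 input_feature_count = as.integer(input_feature_count),
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 relu_clip = as.numeric(relu_clip),
                 init_scale = as.numeric(init_scale), seed = as.integer(seed)),
            class = "surrogate_spec")
}

# draw all weights for a surrogate from its seed
.surrogate_weights <- function(spec) {
  with_seed(spec$seed, {
    sz <- spec$layer_sizes
    d <- spec$input_feature_count
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -spec$init_scale, spec$init_scale), nr, nc)
    list(
      W1 = u(sz[1], d),     b1 = stats::runif(sz[1], -spec$init_scale, spec$init_scale),
      W2 = u(sz[2], sz[1]), b2 = stats::runif(sz[2], -spec$init_scale, spec$init_scale),
      W3 = u(sz[3], sz[2]), b3 = stats::runif(sz[3], -spec$init_scale, spec$init_scale),
      # LSTM: input and recurrent weights for the 4 gates (i, f, g, o)
      Wx = u(4 * sz[4], sz[3]), Wh = u(4 * sz[4], sz[4]),
      bl = stats::runif(4 * sz[4], -spec$init_scale, spec$init_scale),
      W5 = u(sz[5], sz[4]), b5 = stats::runif(sz[5], -spec$init_scale, spec$init_scale)
    )
  })
}

clipped_relu <- function(x, clip) pmin(pmax(x, 0), clip)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Run a surrogate network forward over feature frames
#'
#' Layers 1-3: affine map + clipped ReLU on each frame. Layer 4: a standard
#' unidirectional LSTM recurrence over frames (zero initial state). Layer 5:
#' affine map of the LSTM hidden state + clipped ReLU. Weights are a pure
#' function of `spec$seed`, so identical specs and features give
#' bit-identical activations.
#'
#' @param spec a [surrogate_spec()].
#' @param features feature x frame numeric matrix, frame-aligned to onset.
#' @param network_id,stimulus_id labels carried into the outputs.
#' @param weights optional explicit weight list (as produced internally
#'   from the seed); intended for controlled tests.
#' @return list of 5 [layer_activation_set()] objects.
#' @export
surrogate_forward <- function(spec, features, network_id = "surrogate",
                              stimulus_id = NA, weights = NULL) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (!is.matrix(features)) stop_envtrack("envtrack_type", "features must be a matrix")
  if (!all(is.finite(features))) stop_envtrack("envtrack_nonfinite", "features contain non-finite values")
  if (nrow(features) != spec$input_feature_count) {
    stop_envtrack("envtrack_alignment",
      sprintf("feature dimension %d does not match spec (%d)", nrow(features), spec$input_feature_count))
  }
  W <- weights %||% .surrogate_weights(spec)
  Tn <- ncol(features)
  h1 <- clipped_relu(W$W1 %*% features + W$b1, spec$relu_clip)
  h2 <- clipped_relu(W$W2 %*% h1 + W$b2, spec$relu_clip)
  h3 <- clipped_relu(W$W3 %*% h2 + W$b3, spec$relu_clip)
  n4 <- spec$layer_sizes[4]
  # precompute the input contribution for all frames; recur over time
  Zx <- W$Wx %*% h3 + W$bl
  h <- numeric(n4); cst <- numeric(n4)
  H4 <- matrix(0, n4, Tn)
  i_idx <- 1:n4; f_idx <- n4 + 1:n4; g_idx <- 2 * n4 + 1:n4; o_idx <- 3 * n4 + 1:n4
  for (t in seq_len(Tn)) {
    z <- Zx[, t] + W$Wh %*% h
    i <- sigmoid(z[i_idx]); f <- sigmoid(z[f_idx])
    g <- tanh(z[g_idx]); o <- sigmoid(z[o_idx])
    cst <- f * cst + i * g
    h <- o * tanh(cst)
    H4[, t] <- h
  }
  h5 <- clipped_relu(W$W5 %*% H4 + W$b5, spec$relu_clip)
  layers <- list(h1, h2, h3, H4, h5)
  lapply(seq_along(layers), function(l) {
    layer_activation_set(layers[[l]], l, spec$frame_rate_hz, network_id,
                         trained = FALSE, stimulus_id = stimulus_id,
                         shuffle_seed = spec$seed)
  })
}

#' Generate an ensemble of untrained surrogate specs
#'
#' Produces `n` copies of a template spec with distinct seeds derived from
#' `master_seed`; the ensemble is a pure function of the master seed.
#'
#' @param spec_template a [surrogate_spec()] whose seed field is ignored.
#' @param n ensemble size (the study convention is 100 shuffles).
#' @param master_seed integer.
#' @return list of `n` [surrogate_spec()] objects.
#' @export
make_untrained_ensemble <- function(spec_template, n, master_seed) {
  stopifnot(inherits(spec_template, "surrogate_spec"))
  if (n < 1) stop_envtrack("envtrack_parameter", "ensemble size must be >= 1")
  lapply(seq_len(n), function(k) {
    s <- spec_template
    s$seed <- derive_seed(master_seed, "untrained", k - 1L)
    s
  })
}

#' Log-mel-style spectrogram features for the surrogate networks
#'
#' A simple acoustic frontend: framed power spectra (Hamming window, hop =
#' rate / frame_rate) projected on a triangular mel-spaced filterbank and
#' log-compressed. The exact frontend is configurable scaffolding for the
#' surrogate; it is not itself an analysis target.
#'
#' @param w stimulus [waveform()].
#' @param frame_rate_hz frame rate (default 50, i.e. 20 ms hop).
#' @param n_mels number of filterbank channels (default 26).
#' @param win_s analysis window length in seconds (default 0.032).
#' @return n_mels x n_frames matrix.
#' @export
spectrogram_features <- function(w, frame_rate_hz = 50, n_mels = 26, win_s = 0.032) {
  stopifnot(inherits(w, "waveform"))
  hop <- as.integer(round(w$rate_hz / frame_rate_hz))
  win <- as.integer(round(win_s * w$rate_hz))
  x <- w$samples
  if (length(x) < win) stop_envtrack("envtrack_length", "waveform shorter than one analysis window")
  starts <- seq(1, length(x) - win + 1, by = hop)
  hw <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  nfft <- 2^ceiling(log2(win))
  frames <- vapply(starts, function(s) {
    seg <- x[s:(s + win - 1)] * hw
    Mod(stats::fft(c(seg, rep(0, nfft - win)))[1:(nfft / 2 + 1)])^2
  }, numeric(nfft / 2 + 1))
  fb <- .mel_filterbank(n_mels, nfft, w$rate_hz)
  log(fb %*% frames + 1e-10)
}

.mel_filterbank <- function(n_mels, nfft, rate_hz) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(0), mel(rate_hz / 2), length.out = n_mels + 2))
  freqs <- seq(0, rate_hz / 2, length.out = nfft / 2 + 1)
  fb <- matrix(0, n_mels, nfft / 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Write layer activation sets to a hierarchical on-disk container
#'
#' Plain-text container: one directory per network instance / stimulus,
#' one TSV per layer (unit x frame), and a `meta.json` sidecar holding the
#' attributes (`layer_index`, `frame_rate_hz`, `trained`, `shuffle_seed`).
#' The round trip is lossless at full double precision.
#'
#' @param sets list of [layer_activation_set()].
#' @param path container root directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_activation_container <- function(sets, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in sets) {
    d <- file.path(path, as.character(s$network_id), as.character(s$stimulus_id))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(d, sprintf("layer_%d.tsv", s$layer_index))
    utils::write.table(format(s$data, digits = 17, scientific = TRUE, trim = TRUE),
                       f, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    meta <- list(layer_index = s$layer_index, frame_rate_hz = s$frame_rate_hz,
                 trained = s$trained, shuffle_seed = s$shuffle_seed,
                 network_id = s$network_id, stimulus_id = s$stimulus_id)
    jsonlite::write_json(meta, file.path(d, sprintf("layer_%d.json", s$layer_index)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a layer-activation container written by [write_activation_container()]
#'
#' @param path container root directory.
#' @return list of [layer_activation_set()] objects, one per stored layer.
#' @export
read_activation_container <- function(path) {
  metas <- list.files(path, pattern = "^layer_\\d+\\.json$", recursive = TRUE,
                      full.names = TRUE)
  if (length(metas) == 0) stop_envtrack("envtrack_io", "no activation sets found in container")
  lapply(sort(metas), function(mf) {
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    required <- c("layer_index", "frame_rate_hz", "trained")
    missing <- setdiff(required, names(meta))
    if (length(missing) > 0) {
      stop_envtrack("envtrack_schema",
        sprintf("activation container missing attributes: %s", paste(missing, collapse = ", ")))
    }
    dat <- as.matrix(utils::read.table(sub("\\.json$", ".tsv", mf), sep = "\t"))
    dimnames(dat) <- NULL
    layer_activation_set(dat, meta$layer_index, meta$frame_rate_hz,
                         meta$network_id %||% NA, meta$trained,
                         meta$stimulus_id %||% NA,
                         meta$shuffle_seed %||% NA_integer_)
  })
}
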