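# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes -- syllable-rate amplitude-modulated stimuli, EEG with a
# lagged envelope-following response (negative lobe near 140 ms, positive
# near 220 ms) over 1/f noise, and five layers of network activations with
# configurable per-layer envelope-tracking gain and lag -- so every stage of
# the pipeline is testable without any external recordings. Every generator
# is a pure function of (config, master seed, indices).

#' Synthetic study configuration
#'
#' Defaults mirror the emulated study design: 25 stimuli of 5.5-6.5 s with
#' ~5 Hz syllable-rate modulation, 15 participants x 4 repetitions,
#' 128-channel EEG epochs from -700 to +7800 ms at 250 Hz with a
#' 12-channel frontocentral subset, network activations at 50 Hz in five
#' layers, an envelope-following EEG kernel with lobes at 140/220 ms, and a
#' 100-instance untrained ensemble.
#'
#' @param n_stimuli,n_participants,n_repetitions,n_channels study counts.
#' @param frontocentral_subset channel indices pooled in the main analyses.
#' @param stim_duration_s length-2 range stimuli are drawn from (s).
#' @param syllable_rate_hz nominal syllable rate (Hz).
#' @param syllable_jitter relative jitter of inter-syllable intervals.
#' @param audio_rate_hz stimulus sampling rate (Hz).
#' @param eeg_rate_hz EEG sampling rate after preprocessing (Hz).
#' @param net_frame_rate_hz network activation frame rate (Hz).
#' @param epoch_window_ms EEG epoch window relative to onset (ms).
#' @param kernel_neg_ms,kernel_pos_ms latencies of the negative/positive
#'   response lobes (ms).
#' @param kernel_neg_amp,kernel_pos_amp lobe amplitudes (the negative lobe
#'   is slightly stronger, as in auditory N1-P2-like responses).
#' @param kernel_sigma_ms Gaussian lobe width (ms).
#' @param snr_db per-channel signal-to-noise ratio of the planted response
#'   at frontocentral channels (dB RMS).
#' @param other_channel_gain response gain at non-frontocentral channels.
#' @param participant_latency_sd_ms standard deviation of the
#'   per-participant response-latency shift (ms, clamped at 2 sd); models
#'   between-participant variability and keeps the noise ceiling below 1.
#' @param response_gain_jitter half-width of the uniform per-repetition
#'   response gain (attentional fluctuation); the participant x stimulus
#'   interaction it induces is what separates participant RDMs.
#' @param layer_mixing 5 envelope-tracking gains, maximal at the recurrent
#'   layer 4.
#' @param layer_lag_ms lag of the network envelope response (ms).
#' @param net_noise_rel unit-noise standard deviation relative to the
#'   layer-4 envelope component.
#' @param n_units units per layer in the synthetic trained network and the
#'   surrogate ensemble ("full" study-scale analyses would use wider layers;
#'   64 keeps the desk-scale pipeline fast).
#' @param n_untrained untrained ensemble size (study convention: 100).
#' @param relu_clip,init_scale surrogate-network parameters.
#' @param master_seed integer master seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_stimuli = 25L, n_participants = 15L,
                         n_repetitions = 4L, n_channels = 128L,
                         frontocentral_subset = 1:12,
                         stim_duration_s = c(5.5, 6.5),
                         syllable_rate_hz = 5, syllable_jitter = 0.2,
                         audio_rate_hz = 16000, eeg_rate_hz = 250,
                         net_frame_rate_hz = 50,
                         epoch_window_ms = c(-700, 7800),
                         kernel_neg_ms = 140, kernel_pos_ms = 220,
                         kernel_neg_amp = 1, kernel_pos_amp = 0.8,
                         kernel_sigma_ms = 20,
                         snr_db = 0, other_channel_gain = 0.3,
                         participant_latency_sd_ms = 8,
                         layer_mixing = c(0.1, 0.2, 0.3, 0.8, 0.5),
                         response_gain_jitter = 0.3,
                         layer_lag_ms = 140, net_noise_rel = 1.5,
                         n_units = 64L, n_untrained = 100L,
                         relu_clip = 20, init_scale = 0.5,
                         master_seed = 1L) {
  cfg <- list(n_stimuli = as.integer(n_stimuli),
              n_participants = as.integer(n_participants),
              n_repetitions = as.integer(n_repetitions),
              n_channels = as.integer(n_channels),
              frontocentral_subset = as.integer(frontocentral_subset),
              stim_duration_s = stim_duration_s,
              syllable_rate_hz = syllable_rate_hz,
              syllable_jitter = syllable_jitter,
              audio_rate_hz = audio_rate_hz, eeg_rate_hz = eeg_rate_hz,
              net_frame_rate_hz = net_frame_rate_hz,
              epoch_window_ms = epoch_window_ms,
              kernel_neg_ms = kernel_neg_ms, kernel_pos_ms = kernel_pos_ms,
              kernel_neg_amp = kernel_neg_amp, kernel_pos_amp = kernel_pos_amp,
              kernel_sigma_ms = kernel_sigma_ms, snr_db = snr_db,
              other_channel_gain = other_channel_gain,
              participant_latency_sd_ms = participant_latency_sd_ms,
              response_gain_jitter = response_gain_jitter,
              layer_mixing = layer_mixing, layer_lag_ms = layer_lag_ms,
              net_noise_rel = net_noise_rel, n_units = as.integer(n_units),
              n_untrained = as.integer(n_untrained), relu_clip = relu_clip,
              init_scale = init_scale, master_seed = as.integer(master_seed))
  if (any(c(cfg$n_stimuli, cfg$n_participants, cfg$n_repetitions, cfg$n_channels) < 1)) {
    stop_envtrack("envtrack_parameter", "all study counts must be >= 1")
  }
  if (max(cfg$frontocentral_subset) > cfg$n_channels) {
    stop_envtrack("envtrack_parameter", "frontocentral subset exceeds channel count")
  }
  if (cfg$kernel_pos_ms >= cfg$epoch_window_ms[2]) {
    stop_envtrack("envtrack_parameter", "response latencies must lie inside the epoch")
  }
  structure(cfg, class = "synth_config")
}

# 1/f ("pink") noise, unit RMS, one column per channel.
pink_noise <- function(n, n_channels = 1) {
  nfft <- 2^ceiling(log2(n))
  W <- matrix(stats::rnorm(nfft * n_channels), nfft, n_channels)
  F <- stats::mvfft(W)
  freqs <- c(1, seq_len(nfft - 1)) # guard DC
  shape <- 1 / sqrt(pmin(freqs, nfft - (freqs - 1)))
  shape[1] <- 0
  X <- Re(stats::mvfft(F * shape, inverse = TRUE)) / nfft
  X <- X[seq_len(n), , drop = FALSE]
  sweep(X, 2, sqrt(colMeans(X^2)), "/")
}

# single pink-noise trace drawn from its own seed; the per-channel seeding
# makes gen_eeg a pure function of (cfg, indices) under any channel subset
.pink_noise_seeded <- function(n, seed) {
  with_seed(seed, pink_noise(n, 1))[, 1]
}

#' Generate a synthetic stimulus waveform
#'
#' A noise carrier amplitude-modulated by a positive quasi-periodic
#' "syllable" envelope: raised-cosine bumps at the configured rate with
#' seeded jitter, over a small baseline. RMS-normalised. Duration is drawn
#' from the configured range. Pure function of (cfg, index).
#'
#' @param cfg a [synth_config()].
#' @param index stimulus index in 1..n_stimuli.
#' @return a [waveform()] with id `stim<index>`.
#' @export
gen_stimulus <- function(cfg, index) {
  stopifnot(inherits(cfg, "synth_config"))
  if (index < 1 || index > cfg$n_stimuli) {
    stop_envtrack("envtrack_parameter", "stimulus index out of range")
  }
  seed <- derive_seed(cfg$master_seed, "stimulus", index)
  with_seed(seed, {
    dur <- stats::runif(1, cfg$stim_duration_s[1], cfg$stim_duration_s[2])
    n <- as.integer(round(dur * cfg$audio_rate_hz))
    t <- (seq_len(n) - 1) / cfg$audio_rate_hz
    # quasi-periodic syllable onsets with jittered inter-onset intervals
    mean_ioi <- 1 / cfg$syllable_rate_hz
    onsets <- c()
    pos <- stats::runif(1, 0, mean_ioi / 2)
    while (pos < dur) {
      onsets <- c(onsets, pos)
      pos <- pos + mean_ioi * (1 + cfg$syllable_jitter * stats::runif(1, -1, 1))
    }
    env <- rep(0.15, n) # baseline so the carrier never fully gates off
    width <- mean_ioi * 0.6
    for (o in onsets) {
      idx <- which(t >= o & t < o + width)
      env[idx] <- env[idx] + 0.5 * (1 - cos(2 * pi * (t[idx] - o) / width))
    }
    # carrier: noise with a stimulus-specific formant-like spectral profile,
    # so stimuli differ in spectral content (as utterances do), not only in
    # envelope timing
    n_formants <- 3
    fc <- stats::runif(n_formants, 300, 3200)
    bw <- stats::runif(n_formants, 150, 500)
    fg <- stats::runif(n_formants, 0.5, 1)
    nfft <- 2^ceiling(log2(n)) # power of two keeps the FFT fast
    freqs <- seq(0, cfg$audio_rate_hz / 2, length.out = nfft / 2 + 1)
    profile <- 0.05 + Reduce(`+`, lapply(seq_len(n_formants), function(j)
      fg[j] * exp(-(freqs - fc[j])^2 / (2 * bw[j]^2))))
    shape <- c(profile, rev(profile[2:(nfft / 2)]))
    carrier <- Re(stats::fft(stats::fft(stats::rnorm(nfft)) * shape,
                             inverse = TRUE))[seq_len(n)] / nfft
    x <- carrier * env
    x <- x / sqrt(mean(x^2))
    waveform(x, cfg$audio_rate_hz, id = sprintf("stim%02d", index))
  })
}

# envelope drive at an arbitrary rate: the rectified-derivative unit-area
# modulation envelope of a stimulus (cached per (cfg, index, rate) within a
# call chain by the pipeline, not here).
stimulus_drive <- function(cfg, stimulus, rate_hz) {
  preprocess_envelope(hilbert_envelope(stimulus), rate_hz)
}

# Stimulus-independent reference response RMS used to anchor the noise
# level: a perfectly periodic syllable drive (6 s, unit area) convolved
# with the response kernel. Tying noise to each stimulus's own signal RMS
# would leak stimulus identity into noise-only channels, so the SNR is
# defined against this fixed reference instead. Cached per parameter set.
.ref_rms_cache <- new.env(parent = emptyenv())
.reference_response_rms <- function(cfg, rate_hz) {
  key <- paste(signif(c(rate_hz, cfg$syllable_rate_hz, cfg$kernel_neg_ms,
                        cfg$kernel_pos_ms, cfg$kernel_neg_amp,
                        cfg$kernel_pos_amp, cfg$kernel_sigma_ms), 10),
               collapse = ",")
  if (!is.null(.ref_rms_cache[[key]])) return(.ref_rms_cache[[key]])
  dur <- 6
  n <- as.integer(round(dur * rate_hz))
  t <- (seq_len(n) - 1) / rate_hz
  mean_ioi <- 1 / cfg$syllable_rate_hz
  width <- mean_ioi * 0.6
  env <- rep(0.15, n)
  for (o in seq(0, dur - width, by = mean_ioi)) {
    idx <- which(t >= o & t < o + width)
    env[idx] <- env[idx] + 0.5 * (1 - cos(2 * pi * (t[idx] - o) / width))
  }
  d <- diff(env) * rate_hz
  d[d < 0] <- 0
  if (sum(d) <= 0) return(0)
  d <- d / sum(d)
  k <- response_kernel(cfg, rate_hz)
  resp <- stats::convolve(d, rev(k), type = "open")[seq_along(d)]
  out <- sqrt(mean(resp^2))
  .ref_rms_cache[[key]] <- out
  out
}

# biphasic response kernel on the EEG time axis: difference of two
# Gaussians, negative lobe first; shift_ms models per-participant latency
# variability
response_kernel <- function(cfg, rate_hz, shift_ms = 0) {
  t_ms <- seq(0, cfg$kernel_pos_ms + 6 * cfg$kernel_sigma_ms + abs(shift_ms),
              by = 1000 / rate_hz)
  neg <- cfg$kernel_neg_ms + shift_ms
  pos <- cfg$kernel_pos_ms + shift_ms
  -cfg$kernel_neg_amp * exp(-(t_ms - neg)^2 / (2 * cfg$kernel_sigma_ms^2)) +
    cfg$kernel_pos_amp * exp(-(t_ms - pos)^2 / (2 * cfg$kernel_sigma_ms^2))
}

#' Generate synthetic EEG epochs for one stimulus
#'
#' Each channel carries (channel gain) x conv(modulation envelope, biphasic
#' kernel) plus independent pink noise scaled to the configured per-channel
#' SNR. Frontocentral channels get gain 1 (times a per-participant gain in
#' [0.8, 1.2]); all other channels are attenuated by `other_channel_gain`.
#' The epoch spans the configured window (default -700..+7800 ms at
#' 250 Hz). Pure function of (cfg, stimulus index, participant, repetition).
#'
#' @param cfg a [synth_config()].
#' @param stimulus a [waveform()] from [gen_stimulus()].
#' @param stimulus_index its index (seeds the noise draws).
#' @param participants,repetitions optional index subsets (defaults: all).
#' @param channels channel subset to generate (defaults: all). Noise is
#'   seeded per channel, so a channel's data are identical whichever subset
#'   it is requested in; analyses may generate only the channels they use.
#' @param drive optional precomputed modulation envelope of `stimulus` at
#'   the EEG rate (avoids re-deriving it when looping over noise seeds).
#' @return nested list `[[participant]][[repetition]]` of [eeg_epoch()]
#'   whose rows correspond to `channels` in order.
#' @export
gen_eeg <- function(cfg, stimulus, stimulus_index,
                    participants = seq_len(cfg$n_participants),
                    repetitions = seq_len(cfg$n_repetitions),
                    channels = seq_len(cfg$n_channels), drive = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  rate <- cfg$eeg_rate_hz
  n_ep <- as.integer(round(diff(cfg$epoch_window_ms) / 1000 * rate))
  onset <- as.integer(round(-cfg$epoch_window_ms[1] / 1000 * rate)) + 1L
  drive <- drive %||% stimulus_drive(cfg, stimulus, rate)
  embed_response <- function(shift_ms) {
    k <- response_kernel(cfg, rate, shift_ms)
    resp <- stats::convolve(drive$samples, rev(k), type = "open")[seq_along(drive$samples)]
    signal <- numeric(n_ep)
    n_fit <- min(length(resp), n_ep - onset + 1L)
    signal[onset:(onset + n_fit - 1L)] <- resp[seq_len(n_fit)]
    signal
  }
  ref_signal <- embed_response(0)
  sig_rms <- sqrt(mean(ref_signal^2) * n_ep / (n_ep - onset + 1L))
  # noise anchored to a stimulus-independent reference so noise-only
  # channels carry no stimulus information
  ref_rms <- .reference_response_rms(cfg, rate)
  noise_rms <- if (ref_rms > 0) ref_rms / 10^(cfg$snr_db / 20) else 1
  ch_gain <- rep(cfg$other_channel_gain, cfg$n_channels)
  ch_gain[cfg$frontocentral_subset] <- 1
  out <- lapply(participants, function(p) {
    traits <- with_seed(derive_seed(cfg$master_seed, "participant_traits", p), {
      list(gain = stats::runif(1, 0.8, 1.2),
           latency_shift_ms = max(-2, min(2, stats::rnorm(1))) *
             cfg$participant_latency_sd_ms)
    })
    p_gain <- traits$gain
    signal <- if (cfg$participant_latency_sd_ms > 0 && sig_rms > 0) {
      embed_response(traits$latency_shift_ms)
    } else ref_signal
    lapply(repetitions, function(r) {
      rep_gain <- with_seed(derive_seed(cfg$master_seed, "rep_gain", stimulus_index, p, r),
        stats::runif(1, 1 - cfg$response_gain_jitter, 1 + cfg$response_gain_jitter))
      dat <- matrix(0, length(channels), n_ep)
      for (j in seq_along(channels)) {
        ch <- channels[j]
        noise <- .pink_noise_seeded(n_ep,
          derive_seed(cfg$master_seed, "eeg", stimulus_index, p, r, ch))
        dat[j, ] <- noise * noise_rms + ch_gain[ch] * p_gain * rep_gain * signal
      }
      eeg_epoch(dat, rate, cfg$epoch_window_ms,
                participant_id = sprintf("P%02d", p),
                stimulus_id = stimulus$id, repetition_index = r)
    })
  })
  names(out) <- sprintf("P%02d", participants)
  out
}

#' Generate synthetic network activations for one stimulus
#'
#' Trained mode plants an envelope-tracking code: each unit of layer l is
#' `-w_u * layer_mixing[l] * envelope(t - layer_lag_ms) + noise`,
#' with per-unit weights w_u ~ U(0.5, 1.5) and white unit noise, so the raw
#' cross-correlation with the modulation envelope has a trough at the
#' configured lag and the RDM correlation with EEG grows with the mixing
#' gain (maximal at the recurrent layer 4 by default). Untrained mode runs
#' an architecture-matched random-weight surrogate network on log-mel
#' features of the stimulus.
#'
#' @param cfg a [synth_config()].
#' @param stimulus a [waveform()].
#' @param stimulus_index its index.
#' @param mode "trained" or "untrained".
#' @param instance untrained-ensemble instance index (1-based; ignored for
#'   trained mode).
#' @param drive optional precomputed modulation envelope of `stimulus` at
#'   the network frame rate (trained mode only).
#' @return list of 5 [layer_activation_set()].
#' @export
gen_network_responses <- function(cfg, stimulus, stimulus_index,
                                  mode = c("trained", "untrained"),
                                  instance = 1L, drive = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  mode <- match.arg(mode)
  rate <- cfg$net_frame_rate_hz
  if (mode == "untrained") {
    template <- surrogate_spec(layer_sizes = rep(cfg$n_units, 5),
                               input_feature_count = 26L,
                               frame_rate_hz = rate,
                               relu_clip = cfg$relu_clip,
                               init_scale = cfg$init_scale)
    specs <- make_untrained_ensemble(template, cfg$n_untrained, cfg$master_seed)
    if (instance > length(specs)) {
      stop_envtrack("envtrack_parameter", "untrained instance index out of range")
    }
    feats <- spectrogram_features(stimulus, frame_rate_hz = rate)
    return(surrogate_forward(specs[[instance]], feats,
                             network_id = sprintf("untrained%03d", instance),
                             stimulus_id = stimulus$id))
  }
  env <- drive %||% stimulus_drive(cfg, stimulus, rate)
  Tn <- length(env$samples)
  lag <- as.integer(round(cfg$layer_lag_ms / 1000 * rate))
  shifted <- c(rep(0, lag), env$samples)[seq_len(Tn)]
  ref_sd <- stats::sd(shifted) * max(cfg$layer_mixing)
  lapply(1:5, function(l) {
    seed <- derive_seed(cfg$master_seed, "trained_net", stimulus_index, l)
    dat <- with_seed(seed, {
      w <- stats::runif(cfg$n_units, 0.5, 1.5)
      noise <- matrix(stats::rnorm(cfg$n_units * Tn), cfg$n_units, Tn) *
        cfg$net_noise_rel * ref_sd
      # negative sign: the envelope-following code enters with the trough
      # polarity seen in raw cross-correlograms of the recurrent layer
      -outer(w * cfg$layer_mixing[l], shifted) + noise
    })
    layer_activation_set(dat, l, rate, network_id = "trained",
                         trained = TRUE, stimulus_id = stimulus$id)
  })
}
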