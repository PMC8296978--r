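# Representational similarity analysis: RDM construction and comparison,
# layer profiles against untrained ensembles, band-resolved and
# per-electrode maps, noise ceilings, display transforms.

#' Pool an epoch's channels into one response vector
#'
#' Concatenates the selected channels' post-onset time series (truncated to
#' a common window) into a single vector, channel-major: channel 1's
#' series, then channel 2's, and so on. All stimuli must be reduced to the
#' same window so vectors are comparable.
#'
#' @param epoch an [eeg_epoch()].
#' @param channel_subset integer channel indices.
#' @param window_s length of the post-onset window in seconds (stimuli of
#'   5.5-6.5 s are truncated to the common 5.5 s by default upstream).
#' @return numeric vector of length `length(channel_subset) * round(window_s * rate)`.
#' @export
response_vector <- function(epoch, channel_subset, window_s) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (any(channel_subset > nrow(epoch$data))) {
    stop_envtrack("envtrack_alignment", "channel subset exceeds channel count")
  }
  i0 <- epoch_onset_index(epoch)
  n <- as.integer(round(window_s * epoch$rate_hz))
  if (i0 + n - 1L > ncol(epoch$data)) {
    stop_envtrack("envtrack_parameter", "window extends past the epoch end")
  }
  as.numeric(t(epoch$data[channel_subset, i0:(i0 + n - 1L), drop = FALSE]))
}

#' Compute a Euclidean representational dissimilarity matrix
#'
#' Pairwise Euclidean distances between equal-length response vectors, one
#' per stimulus; symmetric with a zero diagonal.
#'
#' @param vectors list (or columns of a matrix) of equal-length numeric
#'   vectors, one per stimulus, or a stimulus x feature matrix.
#' @param stimulus_order optional stimulus id vector.
#' @param source free-form provenance label (e.g. "eeg_pooled",
#'   "network_layer 4").
#' @return an `rdm` object: `matrix`, `metric`, `source`, `stimulus_order`.
#' @export
compute_rdm <- function(vectors, stimulus_order = NULL, source = "unspecified") {
  X <- if (is.list(vectors)) {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1) {
      stop_envtrack("envtrack_alignment", "response vectors have unequal lengths")
    }
    do.call(rbind, vectors)
  } else as.matrix(vectors)
  if (nrow(X) < 2) stop_envtrack("envtrack_parameter", "need >= 2 stimuli for an RDM")
  m <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(m) <- NULL
  new_rdm(m, stimulus_order %||% seq_len(nrow(X)), source)
}

new_rdm <- function(m, stimulus_order, source, metric = "euclidean") {
  structure(list(matrix = m, metric = metric, source = source,
                 stimulus_order = stimulus_order),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm [%s, %s]: %d x %d, mean off-diagonal %.4g>\n",
              x$metric, paste(x$source, collapse = " "), nrow(x$matrix), ncol(x$matrix),
              mean(x$matrix[lower.tri(x$matrix)])))
  invisible(x)
}

#' Elementwise mean of RDMs
#'
#' @param rdms list of `rdm` objects with identical stimulus order.
#' @param source provenance label of the average.
#' @return an `rdm`.
#' @export
average_rdms <- function(rdms, source = "average") {
  ref <- rdms[[1]]
  for (r in rdms) {
    if (!identical(r$stimulus_order, ref$stimulus_order) ||
        !all(dim(r$matrix) == dim(ref$matrix))) {
      stop_envtrack("envtrack_alignment", "RDMs differ in stimulus order or size")
    }
  }
  m <- Reduce(`+`, lapply(rdms, `[[`, "matrix")) / length(rdms)
  new_rdm(m, ref$stimulus_order, source, ref$metric)
}

rdm_lower <- function(r) r$matrix[lower.tri(r$matrix)]

#' Spearman comparison of two RDMs
#'
#' Spearman rank correlation over the strictly-lower-triangle entries
#' (n(n-1)/2 values), average ranks for ties.
#'
#' @param a,b `rdm` objects with matching stimulus order.
#' @return Spearman rho in [-1, 1].
#' @export
compare_rdms <- function(a, b) {
  if (!identical(a$stimulus_order, b$stimulus_order) ||
      !all(dim(a$matrix) == dim(b$matrix))) {
    stop_envtrack("envtrack_alignment", "RDMs differ in stimulus order or size")
  }
  x <- rdm_lower(a); y <- rdm_lower(b)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_envtrack("envtrack_degenerate_rdm",
      "an RDM has a constant lower triangle; Spearman correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}

#' Rank-transform an RDM for display
#'
#' Replaces the lower-triangle distances by their average-tie ranks scaled
#' into [0, 1] (smallest distance -> 0, largest -> 1; all-equal entries map
#' to 0.5), mirrors to the upper triangle and zeroes the diagonal.
#' Spearman comparisons are invariant under this transform.
#'
#' @param rdm an `rdm`.
#' @return an `rdm` with metric "rank".
#' @export
rank_transform <- function(rdm) {
  v <- rdm_lower(rdm)
  m <- length(v)
  scaled <- if (m == 1) 0.5 else (rank(v, ties.method = "average") - 1) / (m - 1)
  out <- matrix(0, nrow(rdm$matrix), ncol(rdm$matrix))
  out[lower.tri(out)] <- scaled
  out <- out + t(out)
  new_rdm(out, rdm$stimulus_order, c(rdm$source, "rank_transformed"), metric = "rank")
}

#' Layer profile: trained vs untrained-ensemble RDM similarity
#'
#' For each participant and layer, computes rho(EEG RDM, trained layer RDM)
#' and the ensemble mean of rho(EEG RDM, untrained layer RDM); then, per
#' layer, a two-tailed t-test across participants comparing the trained
#' coefficients against the ensemble-averaged untrained ones. With the
#' default two-sample mode and pooled variance the degrees of freedom are
#' 2 * n_participants - 2 (t(28) at 15 participants); a paired mode is
#' available.
#'
#' @param eeg_rdms list over participants of `rdm`.
#' @param trained_rdms list over 5 layers of `rdm` (trained network).
#' @param untrained_rdm_sets list over ensemble instances, each a list over
#'   5 layers of `rdm`.
#' @param mode "two_sample" (default) or "paired".
#' @return a data.frame with one row per layer: mean rho per group, t, df, p,
#'   plus attribute `per_participant` (participant x layer x group array).
#' @export
layer_profile <- function(eeg_rdms, trained_rdms, untrained_rdm_sets,
                          mode = c("two_sample", "paired")) {
  mode <- match.arg(mode)
  nP <- length(eeg_rdms)
  if (nP < 2) stop_envtrack("envtrack_parameter", "need >= 2 participants")
  nL <- length(trained_rdms)
  rho_tr <- matrix(NA_real_, nP, nL)
  rho_un <- matrix(NA_real_, nP, nL)
  for (p in seq_len(nP)) {
    for (l in seq_len(nL)) {
      rho_tr[p, l] <- compare_rdms(eeg_rdms[[p]], trained_rdms[[l]])
      rho_un[p, l] <- mean(vapply(untrained_rdm_sets, function(inst) {
        compare_rdms(eeg_rdms[[p]], inst[[l]])
      }, numeric(1)))
    }
  }
  rows <- lapply(seq_len(nL), function(l) {
    tt <- if (mode == "paired") {
      paired_peak_test(rho_tr[, l], rho_un[, l], mode = "paired")
    } else {
      paired_peak_test(rho_tr[, l], rho_un[, l], mode = "two_sample")
    }
    data.frame(layer = l, rho_trained = mean(rho_tr[, l]),
               rho_untrained = mean(rho_un[, l]),
               t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_participant") <- list(trained = rho_tr, untrained = rho_un)
  out
}

#' Band-resolved RSA
#'
#' Filters the pooled EEG channel data in successive frequency bands
#' (Gaussian FIR, zero phase), rebuilds the EEG RDM per band (per
#' repetition, then averaged over repetitions and participants), and
#' compares it with each layer RDM.
#'
#' @param epochs_by_participant list over participants; each a list over
#'   stimuli; each a list over repetitions of [eeg_epoch()].
#' @param channel_subset pooled channel indices.
#' @param window_s common post-onset window (s).
#' @param layer_rdms list over layers of `rdm`.
#' @param band_edges_hz numeric vector of band edges (default
#'   `seq(0, 20, by = 2)`: ten 2 Hz bands).
#' @return data.frame with columns band_lo, band_hi, layer, rho.
#' @export
band_rsa <- function(epochs_by_participant, channel_subset, window_s,
                     layer_rdms, band_edges_hz = seq(0, 20, by = 2)) {
  nB <- length(band_edges_hz) - 1
  res <- list()
  for (b in seq_len(nB)) {
    lo <- band_edges_hz[b]; hi <- band_edges_hz[b + 1]
    part_rdms <- lapply(epochs_by_participant, function(stim_list) {
      rep_count <- length(stim_list[[1]])
      rep_rdms <- lapply(seq_len(rep_count), function(r) {
        vecs <- lapply(stim_list, function(reps) {
          ep <- reps[[r]]
          filt <- t(fir_bandpass(t(ep$data[channel_subset, , drop = FALSE]),
                                 ep$rate_hz, lo, hi, kind = "gaussian"))
          ep2 <- eeg_epoch(filt, ep$rate_hz, ep$window_ms, ep$participant_id,
                           ep$stimulus_id, ep$repetition_index)
          response_vector(ep2, seq_along(channel_subset), window_s)
        })
        compute_rdm(vecs, source = sprintf("eeg_band %g-%g", lo, hi))
      })
      average_rdms(rep_rdms, source = sprintf("eeg_band %g-%g", lo, hi))
    })
    grand <- average_rdms(part_rdms, source = sprintf("eeg_band %g-%g grand", lo, hi))
    for (l in seq_along(layer_rdms)) {
      res[[length(res) + 1]] <- data.frame(
        band_lo = lo, band_hi = hi, layer = l,
        rho = compare_rdms(grand, layer_rdms[[l]]))
    }
  }
  do.call(rbind, res)
}

#' Per-electrode RSA with significance masking
#'
#' Builds an RDM per electrode and participant (per repetition, then
#' repetition-averaged), correlates it with trained and ensemble-averaged
#' untrained layer RDMs, tests trained vs untrained per electrode x layer
#' across participants (two-tailed, two-sample), and returns the mean
#' trained rho masked to significant electrodes: non-significant
#' coefficients are set to exactly 0.
#'
#' @param epochs_by_participant nested list as in [band_rsa()].
#' @param window_s common post-onset window (s).
#' @param trained_rdms list over layers of `rdm`.
#' @param untrained_rdm_sets list over instances of lists over layers.
#' @param alpha significance level (default 0.05, uncorrected).
#' @param bh logical; apply Benjamini-Hochberg correction across electrodes
#'   within each layer (default FALSE, mirroring the uncorrected map).
#' @return an `electrode_map`: `rho` (electrode x layer), `p_value`, `mask`,
#'   `masked_rho` (rho where significant, exactly 0 elsewhere).
#' @export
electrode_rsa <- function(epochs_by_participant, window_s, trained_rdms,
                          untrained_rdm_sets, alpha = 0.05, bh = FALSE) {
  nP <- length(epochs_by_participant)
  if (nP < 2) stop_envtrack("envtrack_parameter", "need >= 2 participants")
  nE <- nrow(epochs_by_participant[[1]][[1]][[1]]$data)
  nL <- length(trained_rdms)
  rho_tr <- array(NA_real_, c(nP, nE, nL))
  rho_un <- array(NA_real_, c(nP, nE, nL))
  for (p in seq_len(nP)) {
    r <- .electrode_participant_rho(epochs_by_participant[[p]], window_s,
                                    trained_rdms, untrained_rdm_sets)
    rho_tr[p, , ] <- r$trained
    rho_un[p, , ] <- r$untrained
  }
  .electrode_map_from_rho(rho_tr, rho_un, alpha, bh)
}

#' Noise ceiling for RDM correlations
#'
#' Upper bound: mean over participants of rho(participant RDM, mean RDM of
#' all participants). Lower bound: the same with the leave-one-out mean.
#' Spearman throughout. The ceiling bounds the RDM correlation any model
#' could achieve given between-participant variability.
#'
#' @param participant_rdms list of >= 2 `rdm` objects.
#' @return a `noise_ceiling`: `lower`, `upper`.
#' @export
noise_ceiling <- function(participant_rdms) {
  n <- length(participant_rdms)
  if (n < 2) stop_envtrack("envtrack_parameter", "need >= 2 participant RDMs")
  grand <- average_rdms(participant_rdms, source = "grand")
  upper <- mean(vapply(participant_rdms, function(r) compare_rdms(r, grand), numeric(1)))
  lower <- mean(vapply(seq_len(n), function(i) {
    loo <- average_rdms(participant_rdms[-i], source = "loo")
    compare_rdms(participant_rdms[[i]], loo)
  }, numeric(1)))
  structure(list(lower = lower, upper = upper), class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("<noise ceiling: lower %.3f, upper %.3f>\n", x$lower, x$upper))
  invisible(x)
}

#' Participant-level pooled EEG RDM
#'
#' Builds the per-repetition pooled-channel RDM and averages over
#' repetitions, the standard EEG entry point for RSA.
#'
#' @param stim_list list over stimuli of lists over repetitions of
#'   [eeg_epoch()].
#' @param channel_subset pooled channel indices.
#' @param window_s common post-onset window (s).
#' @param source provenance label.
#' @return an `rdm`.
#' @export
participant_rdm <- function(stim_list, channel_subset, window_s,
                            source = "eeg_pooled") {
  rep_count <- length(stim_list[[1]])
  rep_rdms <- lapply(seq_len(rep_count), function(r) {
    vecs <- lapply(stim_list, function(reps) {
      response_vector(reps[[r]], channel_subset, window_s)
    })
    compute_rdm(vecs, source = source)
  })
  average_rdms(rep_rdms, source = source)
}

#' RDM of a layer activation set
#'
#' Vectorises each stimulus's unit x frame activations (all units,
#' truncated to a common frame count) and computes the Euclidean RDM.
#'
#' @param acts list over stimuli of [layer_activation_set()] for one layer.
#' @param n_frames common frame count (default: minimum over stimuli).
#' @return an `rdm`.
#' @export
layer_rdm <- function(acts, n_frames = NULL) {
  n_frames <- n_frames %||% min(vapply(acts, function(a) ncol(a$data), integer(1)))
  vecs <- lapply(acts, function(a) as.numeric(a$data[, seq_len(n_frames), drop = FALSE]))
  compute_rdm(vecs, source = sprintf("network_layer %d", acts[[1]]$layer_index))
}
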