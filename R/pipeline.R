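# Orchestration: configuration, the synth/tracking/rsa stages, CSV/JSON
# outputs, and end-to-end determinism (identical config + seed => byte
# identical outputs).

#' Build a pipeline run configuration
#'
#' Bundles the synthetic-data configuration with the analysis parameters
#' and output paths. Two profiles are provided: "test" (small layers, few
#' untrained instances; minutes on one CPU) and "full" (study-scale counts:
#' 100 untrained instances, 128 electrodes).
#'
#' @param out_dir output directory (created on demand).
#' @param profile "test" or "full".
#' @param synth a [synth_config()]; defaults depend on the profile.
#' @param lag_window_ms cross-correlation lag window half-width (ms).
#' @param percentile node-selection percentile.
#' @param peak_centers_ms,peak_half_width_ms a-priori peak windows (ms).
#' @param peak_polarities extremum polarity per peak window.
#' @param band_edges_hz band decomposition edges (Hz).
#' @param alpha significance level for electrode masking.
#' @param n_untrained_analysis untrained instances actually analysed
#'   (defaults: 5 for "test", the full ensemble for "full").
#' @param rsa_window_s common post-onset RSA window (s); defaults to the
#'   minimum stimulus duration.
#' @param write_wav write stimulus WAV files during [cmd_synth()].
#' @param test_mode peak-test mode, "paired" or "two_sample".
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, profile = c("test", "full"), synth = NULL,
                       lag_window_ms = 1000, percentile = 20,
                       peak_centers_ms = c(140, 220), peak_half_width_ms = 50,
                       peak_polarities = c("min", "max"),
                       band_edges_hz = seq(0, 20, by = 2), alpha = 0.05,
                       n_untrained_analysis = NULL, rsa_window_s = NULL,
                       write_wav = FALSE, test_mode = "paired") {
  profile <- match.arg(profile)
  if (is.null(synth)) {
    synth <- if (profile == "test") {
      synth_config(n_stimuli = 6L, n_participants = 4L, n_repetitions = 2L,
                   n_channels = 16L, frontocentral_subset = 1:12,
                   n_units = 16L, n_untrained = 5L)
    } else {
      synth_config()
    }
  }
  n_un <- n_untrained_analysis %||% if (profile == "test") min(5L, synth$n_untrained) else synth$n_untrained
  cfg <- list(out_dir = out_dir, profile = profile, synth = synth,
              lag_window_ms = lag_window_ms, percentile = percentile,
              peak_centers_ms = peak_centers_ms,
              peak_half_width_ms = peak_half_width_ms,
              peak_polarities = peak_polarities,
              band_edges_hz = band_edges_hz, alpha = alpha,
              n_untrained_analysis = as.integer(n_un),
              rsa_window_s = rsa_window_s %||% synth$stim_duration_s[1],
              write_wav = isTRUE(write_wav), test_mode = test_mode)
  cfg$config_hash <- hash_object(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

.ensure_outdir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    ok <- dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(config$out_dir)) {
      stop_envtrack("envtrack_io", sprintf("cannot create output directory %s", config$out_dir))
    }
  }
  invisible(config$out_dir)
}

.stamp <- function(config) {
  list(config_hash = config$config_hash, master_seed = config$synth$master_seed,
       profile = config$profile)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.log_stage <- function(stage, msg, verbose = TRUE) {
  if (verbose) message(sprintf("[envtrack %s] %s", stage, msg))
}

#' Synthesise the study data and write the seed manifest
#'
#' Every generator in the package is a pure function of (config, seed), so
#' the manifest of derived seeds plus the configuration fully determines
#' the data set; downstream stages regenerate what they need from it
#' rather than materialising the multi-gigabyte EEG tensor. Stimulus
#' waveforms are optionally written as 16-bit PCM WAV.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisible list with the manifest.
#' @export
cmd_synth <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  .ensure_outdir(config)
  t0 <- Sys.time()
  scfg <- config$synth
  stim_rows <- lapply(seq_len(scfg$n_stimuli), function(i) {
    w <- gen_stimulus(scfg, i)
    if (config$write_wav) {
      wav_dir <- file.path(config$out_dir, "stimuli")
      dir.create(wav_dir, showWarnings = FALSE)
      write_wav(w, file.path(wav_dir, paste0(w$id, ".wav")))
    }
    data.frame(stimulus_id = w$id, index = i,
               seed = derive_seed(scfg$master_seed, "stimulus", i),
               duration_s = length(w$samples) / w$rate_hz,
               n_samples = length(w$samples))
  })
  stim_df <- do.call(rbind, stim_rows)
  manifest <- list(
    stamp = .stamp(config),
    counts = list(n_stimuli = scfg$n_stimuli, n_participants = scfg$n_participants,
                  n_repetitions = scfg$n_repetitions, n_channels = scfg$n_channels),
    seeds = list(
      master = scfg$master_seed,
      null_pairing = derive_seed(scfg$master_seed, "null_pairing"),
      stimuli = stim_df$seed,
      untrained = vapply(seq_len(scfg$n_untrained), function(k)
        derive_seed(scfg$master_seed, "untrained", k - 1L), integer(1))))
  .write_csv(stim_df, file.path(config$out_dir, "stimuli.csv"))
  .write_json(manifest, file.path(config$out_dir, "manifest.json"))
  .log_stage("synth", sprintf("%d stimuli, %d participants x %d repetitions (%.1f s)",
                              scfg$n_stimuli, scfg$n_participants, scfg$n_repetitions,
                              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
             verbose)
  invisible(manifest)
}

# EEG response series for tracking: average repetitions, average the
# frontocentral subset, band-pass 1-20 Hz (zero phase), cut the post-onset
# window, resample to the envelope rate. Filtering after averaging is
# exact because all operations are linear.
.eeg_tracking_series <- function(cfg, stimulus, stimulus_index, duration_s) {
  epochs <- gen_eeg(cfg, stimulus, stimulus_index,
                    channels = cfg$frontocentral_subset)
  lapply(epochs, function(reps) {
    avg <- average_epochs(reps, seq_along(cfg$frontocentral_subset))
    filt <- fir_bandpass(avg, cfg$eeg_rate_hz, 1, 20, kind = "least_squares")
    cut <- post_onset_series(filt, cfg$eeg_rate_hz, cfg$epoch_window_ms, duration_s)
    resample(cut, cfg$eeg_rate_hz, cfg$net_frame_rate_hz)
  })
}

#' Envelope-tracking analysis of the EEG branch only
#'
#' Generates (or regenerates) the synthetic EEG, reduces it to one series
#' per participant x stimulus (repetition average, frontocentral channel
#' average, 1-20 Hz zero-phase band-pass, post-onset cut, resampled to the
#' envelope rate), cross-correlates matched and null pairings, and runs the
#' a-priori peak tests on per-stimulus participant-averaged peak values.
#'
#' @param config a [run_config()].
#' @return list with per-stimulus and grand-average matched/null
#'   correlograms and the peak test results.
#' @export
tracking_eeg <- function(config) {
  scfg <- config$synth
  nS <- scfg$n_stimuli
  rate <- scfg$net_frame_rate_hz
  stimuli <- lapply(seq_len(nS), function(i) gen_stimulus(scfg, i))
  ids <- vapply(stimuli, `[[`, character(1), "id")
  envs <- lapply(stimuli, function(w) stimulus_drive(scfg, w, rate))
  null_map <- make_null_pairing(ids, derive_seed(scfg$master_seed, "null_pairing"))
  null_idx <- match(null_map[ids], ids)
  dur <- scfg$stim_duration_s[1]
  eeg_series <- lapply(seq_len(nS), function(i)
    .eeg_tracking_series(scfg, stimuli[[i]], i, dur))
  per_stim <- function(i, j) {
    cgs <- lapply(eeg_series[[j]], function(series)
      cross_correlate(envs[[i]], series, config$lag_window_ms,
                      pairing = if (i == j) "matched" else "null"))
    average_correlograms(cgs)
  }
  matched <- lapply(seq_len(nS), function(i) per_stim(i, i))
  null <- lapply(seq_len(nS), function(i) {
    cg <- per_stim(i, null_idx[i]); cg$pairing <- "null"; cg
  })
  tests <- list()
  for (j in seq_along(config$peak_centers_ms)) {
    mv <- vapply(matched, function(cg)
      extract_peak(cg, config$peak_centers_ms[j], config$peak_half_width_ms,
                   config$peak_polarities[j])$value, numeric(1))
    uv <- vapply(null, function(cg)
      extract_peak(cg, config$peak_centers_ms[j], config$peak_half_width_ms,
                   config$peak_polarities[j])$value, numeric(1))
    tt <- paired_peak_test(mv, uv, mode = config$test_mode)
    tests[[sprintf("peak%g", config$peak_centers_ms[j])]] <- tt
  }
  list(matched = matched, null = null,
       grand_matched = average_correlograms(matched),
       grand_null = average_correlograms(null, pairing = "null"),
       null_pairing = null_map, tests = tests,
       stimuli = stimuli, envelopes = envs, null_idx = null_idx)
}

#' Run the envelope-tracking cross-correlation analysis
#'
#' For every stimulus: the modulation envelope is cross-correlated with the
#' matched EEG response (repetition- and channel-averaged, 1-20 Hz, at the
#' envelope rate) and with the response to a randomly chosen non-matching
#' stimulus (the null pairing); likewise for each layer of the trained
#' network and of the untrained surrogate ensemble (percentile node
#' selection within each layer). Grand-average correlograms, peak tables
#' and matched-vs-null peak tests are written as CSV/JSON.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisible list with correlograms, peaks and tests.
#' @export
cmd_tracking <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  .ensure_outdir(config)
  t0 <- Sys.time()
  scfg <- config$synth
  nS <- scfg$n_stimuli
  rate <- scfg$net_frame_rate_hz
  .log_stage("tracking", "EEG branch", verbose)
  eeg <- tracking_eeg(config)
  stimuli <- eeg$stimuli
  ids <- vapply(stimuli, `[[`, character(1), "id")
  envs <- eeg$envelopes
  null_map <- eeg$null_pairing
  null_idx <- eeg$null_idx
  eeg_matched <- eeg$matched
  eeg_null <- eeg$null

  .log_stage("tracking", "network branch (trained)", verbose)
  trained_acts <- lapply(seq_len(nS), function(i)
    gen_network_responses(scfg, stimuli[[i]], i, mode = "trained"))
  layer_cgs <- function(acts_by_stim, pairing_idx, label) {
    lapply(1:5, function(l) {
      per <- lapply(seq_len(nS), function(i) {
        cg <- layer_correlogram(envs[[i]], acts_by_stim[[pairing_idx[i]]][[l]],
                                config$lag_window_ms, config$percentile)
        cg
      })
      g <- average_correlograms(per)
      g$pairing <- label
      list(grand = g, per_stim = per)
    })
  }
  net_tr_matched <- layer_cgs(trained_acts, seq_len(nS), "matched")
  net_tr_null <- layer_cgs(trained_acts, null_idx, "null")

  .log_stage("tracking",
             sprintf("network branch (untrained ensemble, %d instances)",
                     config$n_untrained_analysis), verbose)
  template <- surrogate_spec(layer_sizes = rep(scfg$n_units, 5),
                             input_feature_count = 26L, frame_rate_hz = rate,
                             relu_clip = scfg$relu_clip, init_scale = scfg$init_scale)
  specs <- make_untrained_ensemble(template, scfg$n_untrained, scfg$master_seed)
  feats <- lapply(stimuli, spectrogram_features, frame_rate_hz = rate)
  un_matched_acc <- NULL; un_null_acc <- NULL
  for (k in seq_len(config$n_untrained_analysis)) {
    acts <- lapply(seq_len(nS), function(i)
      surrogate_forward(specs[[k]], feats[[i]],
                        network_id = sprintf("untrained%03d", k),
                        stimulus_id = ids[i]))
    m <- layer_cgs(acts, seq_len(nS), "matched")
    u <- layer_cgs(acts, null_idx, "null")
    gm <- lapply(m, function(x) x$grand$values)
    gu <- lapply(u, function(x) x$grand$values)
    un_matched_acc <- if (is.null(un_matched_acc)) gm else Map(`+`, un_matched_acc, gm)
    un_null_acc <- if (is.null(un_null_acc)) gu else Map(`+`, un_null_acc, gu)
  }
  lag_axis <- eeg_matched[[1]]$lags_ms
  mk_cg <- function(values, pairing) {
    structure(list(lags_ms = lag_axis, values = values, rate_hz = rate,
                   pairing = pairing, provenance = list()),
              class = "cross_correlogram")
  }
  nU <- config$n_untrained_analysis
  net_un_matched <- lapply(un_matched_acc, function(v) mk_cg(v / nU, "matched"))
  net_un_null <- lapply(un_null_acc, function(v) mk_cg(v / nU, "null"))

  # assemble grand averages and peak tables
  sources <- c(list(eeg = list(matched = average_correlograms(eeg_matched),
                               null = average_correlograms(eeg_null, pairing = "null"))),
               stats::setNames(lapply(1:5, function(l) {
                 list(matched = net_tr_matched[[l]]$grand, null = net_tr_null[[l]]$grand)
               }), paste0("trained_layer", 1:5)),
               stats::setNames(lapply(1:5, function(l) {
                 list(matched = net_un_matched[[l]], null = net_un_null[[l]])
               }), paste0("untrained_layer", 1:5)))

  cg_rows <- list(); peak_rows <- list(); tests <- list()
  for (nm in names(sources)) {
    for (pr in c("matched", "null")) {
      cg <- sources[[nm]][[pr]]
      cg_rows[[length(cg_rows) + 1]] <- data.frame(
        source = nm, pairing = pr, lag_ms = cg$lags_ms, value = cg$values)
      for (j in seq_along(config$peak_centers_ms)) {
        pk <- extract_peak(cg, config$peak_centers_ms[j],
                           config$peak_half_width_ms, config$peak_polarities[j])
        peak_rows[[length(peak_rows) + 1]] <- data.frame(
          source = nm, pairing = pr, center_ms = config$peak_centers_ms[j],
          polarity = pk$polarity, latency_ms = pk$latency_ms, value = pk$value,
          at_edge = pk$at_edge)
      }
    }
  }
  # matched-vs-null peak tests on per-stimulus peak values (EEG and trained
  # layers; per-stimulus untrained curves are not retained in the ensemble
  # average above)
  per_stim_sets <- c(list(eeg = list(matched = eeg_matched, null = eeg_null)),
                     stats::setNames(lapply(1:5, function(l) {
                       list(matched = net_tr_matched[[l]]$per_stim,
                            null = net_tr_null[[l]]$per_stim)
                     }), paste0("trained_layer", 1:5)))
  for (nm in names(per_stim_sets)) {
    for (j in seq_along(config$peak_centers_ms)) {
      mv <- vapply(per_stim_sets[[nm]]$matched, function(cg)
        extract_peak(cg, config$peak_centers_ms[j], config$peak_half_width_ms,
                     config$peak_polarities[j])$value, numeric(1))
      uv <- vapply(per_stim_sets[[nm]]$null, function(cg)
        extract_peak(cg, config$peak_centers_ms[j], config$peak_half_width_ms,
                     config$peak_polarities[j])$value, numeric(1))
      tt <- paired_peak_test(mv, uv, mode = config$test_mode)
      tests[[sprintf("%s_peak%g", nm, config$peak_centers_ms[j])]] <- list(
        source = nm, center_ms = config$peak_centers_ms[j],
        polarity = config$peak_polarities[j], t = tt$t_statistic, df = tt$df,
        p = tt$p_value, mode = tt$mode, n = tt$n_pairs)
    }
  }
  out <- list(stamp = .stamp(config), null_pairing = as.list(null_map), tests = tests)
  .write_csv(do.call(rbind, cg_rows), file.path(config$out_dir, "correlograms.csv"))
  .write_csv(do.call(rbind, peak_rows), file.path(config$out_dir, "peaks.csv"))
  .write_json(out, file.path(config$out_dir, "peak_tests.json"))
  .log_stage("tracking", sprintf("done (%.1f s)",
                                 as.numeric(difftime(Sys.time(), t0, units = "secs"))),
             verbose)
  invisible(list(sources = sources, tests = tests,
                 eeg_per_stim = list(matched = eeg_matched, null = eeg_null)))
}

# per-participant pooled epochs, generated lazily per stimulus, keeping
# only the pooled channel subset
.pooled_epochs <- function(scfg, stimuli, participant) {
  lapply(seq_along(stimuli), function(i) {
    eps <- gen_eeg(scfg, stimuli[[i]], i, participants = participant,
                   channels = scfg$frontocentral_subset)[[1]]
    lapply(eps, function(ep) {
      filt <- t(fir_bandpass(t(ep$data), ep$rate_hz, 1, 20,
                             kind = "least_squares"))
      eeg_epoch(filt, ep$rate_hz, ep$window_ms, ep$participant_id,
                ep$stimulus_id, ep$repetition_index)
    })
  })
}

# trained and untrained layer RDM sets for a stimulus list
.network_rdms <- function(config, stimuli) {
  scfg <- config$synth
  nS <- length(stimuli)
  trained_acts <- lapply(seq_len(nS), function(i)
    gen_network_responses(scfg, stimuli[[i]], i, mode = "trained"))
  trained_rdms <- lapply(1:5, function(l)
    layer_rdm(lapply(trained_acts, `[[`, l)))
  template <- surrogate_spec(layer_sizes = rep(scfg$n_units, 5),
                             input_feature_count = 26L,
                             frame_rate_hz = scfg$net_frame_rate_hz,
                             relu_clip = scfg$relu_clip, init_scale = scfg$init_scale)
  specs <- make_untrained_ensemble(template, scfg$n_untrained, scfg$master_seed)
  feats <- lapply(stimuli, spectrogram_features,
                  frame_rate_hz = scfg$net_frame_rate_hz)
  untrained_sets <- lapply(seq_len(config$n_untrained_analysis), function(k) {
    acts <- lapply(seq_len(nS), function(i)
      surrogate_forward(specs[[k]], feats[[i]],
                        network_id = sprintf("untrained%03d", k),
                        stimulus_id = stimuli[[i]]$id))
    lapply(1:5, function(l) layer_rdm(lapply(acts, `[[`, l)))
  })
  list(trained = trained_rdms, untrained = untrained_sets)
}

#' Run the representational similarity analysis
#'
#' Computes per-participant pooled-channel EEG RDMs (per repetition, then
#' averaged), trained and untrained-ensemble layer RDMs, the per-layer
#' trained-vs-untrained profile, the 2 Hz band x layer table, the
#' per-electrode significance-masked map, and the noise ceiling; writes
#' CSV tables and a summary JSON.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisible list with all result tables.
#' @export
cmd_rsa <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  .ensure_outdir(config)
  t0 <- Sys.time()
  scfg <- config$synth
  nS <- scfg$n_stimuli
  nP <- scfg$n_participants
  win <- config$rsa_window_s
  stimuli <- lapply(seq_len(nS), function(i) gen_stimulus(scfg, i))

  .log_stage("rsa", "network RDMs", verbose)
  net <- .network_rdms(config, stimuli)

  .log_stage("rsa", "EEG pooled RDMs + layer profile", verbose)
  pooled <- lapply(seq_len(nP), function(p) .pooled_epochs(scfg, stimuli, p))
  eeg_rdms <- lapply(pooled, function(stim_list)
    participant_rdm(stim_list, seq_along(scfg$frontocentral_subset), win))
  profile <- layer_profile(eeg_rdms, net$trained, net$untrained)
  nc <- noise_ceiling(eeg_rdms)

  .log_stage("rsa", "band x layer RSA", verbose)
  band_tab <- band_rsa(pooled, seq_along(scfg$frontocentral_subset), win,
                       net$trained, config$band_edges_hz)

  .log_stage("rsa", "per-electrode RSA", verbose)
  emap <- .streamed_electrode_rsa(config, stimuli, net, win)

  elec_rows <- do.call(rbind, lapply(1:5, function(l) data.frame(
    electrode = seq_len(nrow(emap$rho)), layer = l, rho = emap$rho[, l],
    p_value = emap$p_value[, l], significant = emap$mask[, l],
    masked_rho = emap$masked_rho[, l])))
  prof_pp <- attr(profile, "per_participant")
  pp_rows <- do.call(rbind, lapply(seq_len(nP), function(p) {
    do.call(rbind, lapply(1:5, function(l) data.frame(
      participant = p, layer = l,
      rho_trained = prof_pp$trained[p, l], rho_untrained = prof_pp$untrained[p, l])))
  }))
  summary <- list(stamp = .stamp(config),
                  noise_ceiling = list(lower = nc$lower, upper = nc$upper),
                  layer_tests = lapply(seq_len(nrow(profile)), function(i)
                    as.list(profile[i, ])))
  .write_csv(profile, file.path(config$out_dir, "layer_profile.csv"))
  .write_csv(pp_rows, file.path(config$out_dir, "layer_rho_per_participant.csv"))
  .write_csv(band_tab, file.path(config$out_dir, "band_rsa.csv"))
  .write_csv(elec_rows, file.path(config$out_dir, "electrode_map.csv"))
  .write_json(summary, file.path(config$out_dir, "rsa_summary.json"))
  .log_stage("rsa", sprintf("done (%.1f s)",
                            as.numeric(difftime(Sys.time(), t0, units = "secs"))),
             verbose)
  invisible(list(profile = profile, band = band_tab, electrode_map = emap,
                 noise_ceiling = nc, eeg_rdms = eeg_rdms, network = net))
}

# electrode RSA with per-participant lazy generation (the full 128-channel
# epoch tensor never lives in memory at once)
.streamed_electrode_rsa <- function(config, stimuli, net, win) {
  scfg <- config$synth
  nP <- scfg$n_participants
  rho_tr <- NULL; rho_un <- NULL
  for (p in seq_len(nP)) {
    stim_list <- lapply(seq_along(stimuli), function(i)
      gen_eeg(scfg, stimuli[[i]], i, participants = p)[[1]])
    r <- .electrode_participant_rho(stim_list, win, net$trained, net$untrained)
    if (is.null(rho_tr)) {
      nE <- nrow(r$trained); nL <- ncol(r$trained)
      rho_tr <- array(NA_real_, c(nP, nE, nL))
      rho_un <- array(NA_real_, c(nP, nE, nL))
    }
    rho_tr[p, , ] <- r$trained
    rho_un[p, , ] <- r$untrained
  }
  .electrode_map_from_rho(rho_tr, rho_un, config$alpha, bh = FALSE)
}

# shared core: per-participant electrode x layer rho for trained and
# ensemble-averaged untrained RDMs
.electrode_participant_rho <- function(stim_list, window_s, trained_rdms,
                                       untrained_rdm_sets) {
  nE <- nrow(stim_list[[1]][[1]]$data)
  nL <- length(trained_rdms)
  rep_count <- length(stim_list[[1]])
  tr <- matrix(NA_real_, nE, nL)
  un <- matrix(NA_real_, nE, nL)
  for (e in seq_len(nE)) {
    rep_rdms <- lapply(seq_len(rep_count), function(r) {
      vecs <- lapply(stim_list, function(reps) response_vector(reps[[r]], e, window_s))
      compute_rdm(vecs, source = sprintf("eeg_electrode %d", e))
    })
    erdm <- average_rdms(rep_rdms, source = sprintf("eeg_electrode %d", e))
    for (l in seq_len(nL)) {
      tr[e, l] <- compare_rdms(erdm, trained_rdms[[l]])
      un[e, l] <- mean(vapply(untrained_rdm_sets, function(inst)
        compare_rdms(erdm, inst[[l]]), numeric(1)))
    }
  }
  list(trained = tr, untrained = un)
}

.electrode_map_from_rho <- function(rho_tr, rho_un, alpha, bh = FALSE) {
  nE <- dim(rho_tr)[2]; nL <- dim(rho_tr)[3]
  rho <- matrix(NA_real_, nE, nL); pval <- matrix(NA_real_, nE, nL)
  for (e in seq_len(nE)) {
    for (l in seq_len(nL)) {
      tt <- paired_peak_test(rho_tr[, e, l], rho_un[, e, l], mode = "two_sample")
      rho[e, l] <- mean(rho_tr[, e, l])
      pval[e, l] <- tt$p_value
    }
  }
  padj <- if (bh) apply(pval, 2, stats::p.adjust, method = "BH") else pval
  mask <- padj < alpha
  structure(list(rho = rho, p_value = pval, mask = mask,
                 masked_rho = ifelse(mask, rho, 0), alpha = alpha, bh = bh),
            class = "electrode_map")
}

#' Run the full pipeline (synth, tracking, RSA)
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return invisible list with the stage results.
#' @export
cmd_all <- function(config, verbose = TRUE) {
  manifest <- cmd_synth(config, verbose)
  tracking <- cmd_tracking(config, verbose)
  rsa <- cmd_rsa(config, verbose)
  invisible(list(manifest = manifest, tracking = tracking, rsa = rsa))
}
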