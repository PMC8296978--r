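# Envelope-response cross-correlation analysis: matched and null pairings,
# node selection, peak extraction, peak statistics.

#' Raw lagged cross-correlation between a modulation envelope and a response
#'
#' Computes the raw (unnormalised, not mean-centred) cross-correlation
#' c(tau) = sum_t env(t) * response(t + tau) for all lags |tau| <=
#' `max_lag_ms`, with zero padding outside the overlap. Positive lags mean
#' the response follows the stimulus; negative lags would reflect
#' prediction of upcoming input. Because the envelope has unit area, the
#' magnitudes are comparable across stimuli of slightly different lengths.
#'
#' @param env a `modulation_envelope` (see [preprocess_envelope()]), or a
#'   plain numeric vector at `rate_hz`.
#' @param response numeric response series at the same sampling rate.
#' @param max_lag_ms maximum absolute lag in ms (default 1000).
#' @param rate_hz required if `env` is a bare numeric vector.
#' @param pairing "matched" or "null" provenance label.
#' @return a `cross_correlogram`: `lags_ms`, `values`, `rate_hz`, `pairing`.
#' @export
cross_correlate <- function(env, response, max_lag_ms = 1000, rate_hz = NULL,
                            pairing = "matched") {
  if (inherits(env, "modulation_envelope")) {
    rate_hz <- env$rate_hz
    e <- env$samples
  } else {
    if (is.null(rate_hz)) stop_envtrack("envtrack_parameter", "rate_hz required for a bare envelope vector")
    e <- as.numeric(env)
  }
  r <- as.numeric(response)
  if (abs(length(e) - length(r)) > 1) {
    n <- min(length(e), length(r))
    e <- e[seq_len(n)]
    r <- r[seq_len(n)]
  }
  n <- min(length(e), length(r))
  e <- e[seq_len(n)]; r <- r[seq_len(n)]
  max_lag <- as.integer(round(max_lag_ms / 1000 * rate_hz))
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(k) {
    if (k >= 0) {
      idx <- seq_len(n - k)
      sum(e[idx] * r[idx + k])
    } else {
      idx <- seq_len(n + k)
      sum(e[idx - k] * r[idx])
    }
  }, numeric(1))
  structure(list(lags_ms = lags / rate_hz * 1000, values = vals,
                 rate_hz = rate_hz, pairing = pairing, provenance = list()),
            class = "cross_correlogram")
}

#' @export
print.cross_correlogram <- function(x, ...) {
  cat(sprintf("<cross_correlogram (%s): %d lags in [%g, %g] ms, range [%.4g, %.4g]>\n",
              x$pairing, length(x$lags_ms), min(x$lags_ms), max(x$lags_ms),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Pointwise mean of correlograms on a common lag axis
#'
#' @param cgs list of `cross_correlogram` objects sharing a lag axis.
#' @param pairing provenance label of the average.
#' @return a `cross_correlogram`.
#' @export
average_correlograms <- function(cgs, pairing = cgs[[1]]$pairing) {
  ref <- cgs[[1]]
  for (cg in cgs) {
    if (length(cg$lags_ms) != length(ref$lags_ms) ||
        max(abs(cg$lags_ms - ref$lags_ms)) > 1e-9) {
      stop_envtrack("envtrack_alignment", "correlograms are on different lag axes")
    }
  }
  vals <- Reduce(`+`, lapply(cgs, `[[`, "values")) / length(cgs)
  structure(list(lags_ms = ref$lags_ms, values = vals, rate_hz = ref$rate_hz,
                 pairing = pairing, provenance = list(n_averaged = length(cgs))),
            class = "cross_correlogram")
}

#' Random non-matching stimulus pairing (the null hypothesis)
#'
#' For each stimulus, draws a uniformly random *different* stimulus whose
#' response is used in place of the matching one. Reproducible from `seed`;
#' a full derangement is not enforced beyond the no-self-pair rule.
#'
#' @param stimulus_ids vector of >= 2 stimulus identifiers.
#' @param seed integer.
#' @return named character vector mapping each stimulus to its null partner.
#' @export
make_null_pairing <- function(stimulus_ids, seed) {
  ids <- as.character(stimulus_ids)
  if (length(ids) < 2) stop_envtrack("envtrack_pairing", "need at least 2 stimuli for a null pairing")
  with_seed(seed, {
    out <- vapply(ids, function(s) sample(setdiff(ids, s), 1), character(1))
  })
  out
}

#' Average per-node correlograms above a percentile of tracking strength
#'
#' Ranks nodes by a selection statistic (default: maximum absolute
#' correlogram value over lags), keeps nodes strictly above the given
#' percentile of that statistic, and averages the kept correlograms
#' pointwise. This retains the nodes contributing most to the layer's
#' dynamics (the "highest 80 percentile" convention at percentile = 20).
#' Degenerate ties that empty the selection fall back to all nodes with a
#' warning.
#'
#' @param per_node list of `cross_correlogram` on a common lag axis.
#' @param percentile percentile (0-100) below which nodes are dropped.
#' @return averaged `cross_correlogram` with `provenance$n_kept`.
#' @export
select_top_nodes <- function(per_node, percentile = 20) {
  if (length(per_node) == 0) stop_envtrack("envtrack_parameter", "no node correlograms supplied")
  stat <- vapply(per_node, function(cg) max(abs(cg$values)), numeric(1))
  thr <- stats::quantile(stat, percentile / 100, names = FALSE)
  keep <- which(stat > thr)
  if (length(keep) == 0) {
    warn_envtrack("envtrack_empty_selection",
                  "node selection empty after percentile threshold; falling back to all nodes")
    keep <- seq_along(per_node)
  }
  out <- average_correlograms(per_node[keep])
  out$provenance$n_kept <- length(keep)
  out$provenance$n_nodes <- length(per_node)
  out
}

#' Extract an extremum from a correlogram in an a-priori latency window
#'
#' Finds the minimum or maximum value within `center_ms +/- half_width_ms`.
#' If the extremum sits on a window edge (monotone correlogram within the
#' window) the result is flagged with `at_edge = TRUE`.
#'
#' @param cg a `cross_correlogram`.
#' @param center_ms window centre in ms (the a-priori peak latencies are
#'   ~140 and ~220 ms).
#' @param half_width_ms window half width in ms.
#' @param polarity "min" (negative lobe) or "max" (positive lobe).
#' @return a `peak_result`: `latency_ms`, `value`, `search_window_ms`,
#'   `polarity`, `at_edge`.
#' @export
extract_peak <- function(cg, center_ms, half_width_ms, polarity = c("min", "max")) {
  polarity <- match.arg(polarity)
  lo <- center_ms - half_width_ms
  hi <- center_ms + half_width_ms
  sel <- which(cg$lags_ms >= lo - 1e-9 & cg$lags_ms <= hi + 1e-9)
  if (length(sel) == 0) {
    stop_envtrack("envtrack_parameter", "peak search window lies outside the lag axis")
  }
  v <- cg$values[sel]
  i <- if (polarity == "min") which.min(v) else which.max(v)
  structure(list(latency_ms = cg$lags_ms[sel[i]], value = v[i],
                 search_window_ms = c(lo, hi), polarity = polarity,
                 at_edge = i == 1L || i == length(v)),
            class = "peak_result")
}

#' Peak statistics: matched vs null-pairing comparison
#'
#' Two-tailed t-test on per-stimulus peak values. `mode = "paired"` tests
#' the per-stimulus differences (df = n - 1); `mode = "two_sample"` treats
#' matched and null values as independent groups with pooled variance
#' (df = 2n - 2). Zero variance of the differences yields a degenerate
#' result reported as t = +/-Inf, p = 0 (or t = 0, p = 1 when the
#' differences are all exactly zero).
#'
#' @param matched_values,null_values per-stimulus numeric vectors, equal
#'   length >= 3.
#' @param mode "paired" or "two_sample".
#' @return a `paired_test_result`: `t_statistic`, `p_value`, `df`,
#'   `n_pairs`, `mean_difference`, `mode`, `degenerate`.
#' @export
paired_peak_test <- function(matched_values, null_values,
                             mode = c("paired", "two_sample")) {
  mode <- match.arg(mode)
  m <- as.numeric(matched_values); u <- as.numeric(null_values)
  if (length(m) != length(u)) stop_envtrack("envtrack_alignment", "matched/null lengths differ")
  if (length(m) < 3) stop_envtrack("envtrack_parameter", "need >= 3 pairs for a peak test")
  n <- length(m)
  if (mode == "paired") {
    d <- m - u
    if (stats::sd(d) < 1e-300) {
      md <- mean(d)
      res <- list(t_statistic = if (md == 0) 0 else sign(md) * Inf,
                  p_value = if (md == 0) 1 else 0, df = n - 1L, n_pairs = n,
                  mean_difference = md, mode = mode, degenerate = md != 0)
      return(structure(res, class = "paired_test_result"))
    }
    tt <- stats::t.test(m, u, paired = TRUE)
  } else {
    if (stats::sd(c(m - mean(m), u - mean(u))) < 1e-300) {
      md <- mean(m) - mean(u)
      res <- list(t_statistic = if (md == 0) 0 else sign(md) * Inf,
                  p_value = if (md == 0) 1 else 0, df = 2L * n - 2L, n_pairs = n,
                  mean_difference = md, mode = mode, degenerate = md != 0)
      return(structure(res, class = "paired_test_result"))
    }
    tt <- stats::t.test(m, u, var.equal = TRUE)
  }
  structure(list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), n_pairs = n,
                 mean_difference = mean(m) - mean(u), mode = mode,
                 degenerate = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<%s t-test: t(%g) = %.3f, p = %.4g, n = %d>\n",
              x$mode, x$df, x$t_statistic, x$p_value, x$n_pairs))
  invisible(x)
}

# Vectorised raw cross-correlation of one envelope against many response
# rows at once (units x time matrix): one matrix-vector product per lag.
cross_correlate_matrix <- function(e, R, max_lag, rate_hz) {
  n <- min(length(e), ncol(R))
  e <- e[seq_len(n)]
  R <- R[, seq_len(n), drop = FALSE]
  lags <- -max_lag:max_lag
  out <- matrix(0, nrow(R), length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    if (k >= 0) {
      idx <- seq_len(n - k)
      out[, j] <- R[, idx + k, drop = FALSE] %*% e[idx]
    } else {
      idx <- seq_len(n + k)
      out[, j] <- R[, idx, drop = FALSE] %*% e[idx - k]
    }
  }
  list(lags_ms = lags / rate_hz * 1000, values = out)
}

#' Per-node correlograms for a layer activation set
#'
#' Cross-correlates each unit's activation series with the modulation
#' envelope, then applies the percentile node selection.
#'
#' @param env `modulation_envelope` at the layer frame rate.
#' @param act a [layer_activation_set()].
#' @param max_lag_ms lag window (default 1000 ms).
#' @param percentile node-selection percentile (default 20).
#' @param pairing provenance label.
#' @return averaged `cross_correlogram` over selected nodes.
#' @export
layer_correlogram <- function(env, act, max_lag_ms = 1000, percentile = 20,
                              pairing = "matched") {
  stopifnot(inherits(act, "layer_activation_set"))
  if (abs(env$rate_hz - act$frame_rate_hz) > 1e-9) {
    stop_envtrack("envtrack_alignment", "envelope and activation rates differ")
  }
  max_lag <- as.integer(round(max_lag_ms / 1000 * env$rate_hz))
  cm <- cross_correlate_matrix(env$samples, act$data, max_lag, env$rate_hz)
  per_node <- lapply(seq_len(nrow(cm$values)), function(u) {
    structure(list(lags_ms = cm$lags_ms, values = cm$values[u, ],
                   rate_hz = env$rate_hz, pairing = pairing,
                   provenance = list()),
              class = "cross_correlogram")
  })
  select_top_nodes(per_node, percentile)
}
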