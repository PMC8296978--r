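#' @keywords internal
"_PACKAGE"

# Classed error helper: every package error carries "envtrackError" plus a
# specific class so tests can target failure modes precisely.
stop_envtrack <- function(class, message, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "envtrackError")))
}

warn_envtrack <- function(class, message) {
  warning(warningCondition(message, class = c(class, "envtrackWarning")))
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop_envtrack("envtrack_nonfinite", sprintf("%s contains non-finite values", what))
  }
  invisible(x)
}

#' Derive a child seed from a master seed and a key path
#'
#' All randomness in the package flows through seeds derived from a single
#' master seed, so that every generated object is a pure function of
#' (configuration, master seed, indices). The derivation is a small
#' multiplicative hash over the integer-coded key path, kept below 2^31.
#'
#' @param master_seed integer master seed.
#' @param ... integers or strings identifying the consumer (e.g. "eeg",
#'   participant index, stimulus index).
#' @return a single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, ...) {
  p <- 2147483629 # prime < 2^31
  h <- as.numeric(master_seed) %% p
  for (k in list(...)) {
    codes <- if (is.character(k)) utf8ToInt(paste(k, collapse = "/")) else as.numeric(k)
    for (v in codes) {
      # h, v < 2^31 would overflow doubles at h*31 + v only past 2^53; safe.
      h <- (h * 69069 + (v %% p) + 1) %% p
    }
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# FNV-1a style hash of a deparsed R object; used to stamp outputs with a
# configuration fingerprint (no digest package in the runtime environment).
hash_object <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
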