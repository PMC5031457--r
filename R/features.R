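#' Biased autocorrelation of a signal
#'
#' Computes the biased autocorrelation estimate
#' `r[k] = sum_t x[t] * x[t+k] / N` for lags `0..max_lag`. The biased
#' normalization (divide by `N`, not `N - k`) guarantees a positive
#' semi-definite sequence, which keeps the Levinson-Durbin recursion stable.
#'
#' @param samples Numeric amplitude vector.
#' @param max_lag Largest lag to compute; must be `< length(samples)`.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorrelation <- function(samples, max_lag) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n <= max_lag) {
    stop("signal too short: need length > max_lag (", n, " <= ", max_lag, ")",
         call. = FALSE)
  }
  vapply(0:max_lag, function(k) {
    sum(samples[1:(n - k)] * samples[(1 + k):n]) / n
  }, numeric(1))
}

#' Levinson-Durbin recursion for linear prediction coefficients
#'
#' Solves the autocorrelation normal equations order-recursively, returning
#' the predictor coefficients `a_1..a_p` of the linear model
#' `x_hat[t] = sum_k a_k * x[t-k]` together with the final prediction-error
#' power. Error power is non-increasing in the order.
#'
#' @param autocorr Autocorrelation sequence `r[0..m]` with `m >= order`.
#' @param order Prediction order `p`.
#' @return A list with `coeffs` (length `order`, predictor sign convention),
#'   `error` (prediction-error power) and `reflection` (the PARCOR
#'   coefficients `k_1..k_p`).
#' @export
levinson_durbin <- function(autocorr, order) {
  r <- as.numeric(autocorr)
  if (length(r) < order + 1L) {
    stop("need at least order + 1 autocorrelation values", call. = FALSE)
  }
  if (!is.finite(r[1]) || r[1] <= 0) {
    stop("degenerate signal: autocorrelation at lag 0 must be positive",
         call. = FALSE)
  }
  a <- numeric(order)        # predictor coefficients a_1..a_p
  k <- numeric(order)
  err <- r[1]
  for (p in seq_len(order)) {
    acc <- r[p + 1]
    if (p > 1L) acc <- acc - sum(a[1:(p - 1)] * r[p:2])
    k[p] <- acc / err
    a_new <- a
    a_new[p] <- k[p]
    if (p > 1L) a_new[1:(p - 1)] <- a[1:(p - 1)] - k[p] * a[(p - 1):1]
    a <- a_new
    err <- err * (1 - k[p]^2)
  }
  list(coeffs = a, error = err, reflection = k)
}

#' Extract the LPC feature vector of one call
#'
#' The classifier input for one vocalization: the call is Hann-windowed as a
#' whole (suppressing segmentation edge artifacts), its biased
#' autocorrelation is taken to lag `order`, and the Levinson-Durbin
#' recursion yields the `order` prediction coefficients. The default order
#' of 20 gives one 20-dimensional feature vector per call. LPC features are
#' amplitude-scale invariant, so recording gain does not leak into the
#' classifier.
#'
#' Two standard stabilizers from speech coding are applied to the
#' autocorrelation before the recursion: a Gaussian lag window
#' (`lag_window_hz`, default 60 Hz) that broadens spectral peaks so the
#' normal equations stay well-conditioned even for near-pure tonal calls,
#' and a white-noise correction (`r[0]` inflated by `noise_floor`, default
#' 1e-4) bounding the spectral dynamic range.
#'
#' @param recording A [call_recording()] (or bare numeric samples).
#' @param order LPC order; default 20.
#' @param rate Sample rate, used only to scale the lag window; taken from
#'   the recording when available.
#' @param lag_window_hz Gaussian lag-window bandwidth in Hz (0 disables).
#' @param noise_floor Relative white-noise correction added to `r[0]`.
#' @return Numeric vector of the `order` LPC coefficients.
#' @export
extract_features <- function(recording, order = 20, rate = 44100,
                             lag_window_hz = 60, noise_floor = 1e-4) {
  if (is_call_recording(recording)) {
    samples <- recording$samples
    rate <- recording$rate
  } else {
    samples <- as.numeric(recording)
  }
  n <- length(samples)
  if (n <= order + 1L) {
    stop("call too short for LPC order ", order, " (", n, " samples)",
         call. = FALSE)
  }
  # Hann window over the whole call
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  r <- autocorrelation(samples * w, order)
  if (lag_window_hz > 0) {
    r <- r * exp(-0.5 * (2 * pi * lag_window_hz * (0:order) / rate)^2)
  }
  r[1] <- r[1] * (1 + noise_floor)
  levinson_durbin(r, order)$coeffs
}

#' Featurize a table of calls
#'
#' Data-frame-first wrapper: takes a dataset tibble with a `recording`
#' list-column (as from [load_dataset()] or [synth_dataset()]) and returns
#' the feature table used by every classifier in the package.
#'
#' @param calls A tibble with columns `label` and `recording`.
#' @param order LPC order; default 20.
#' @return A tibble with `label` and feature columns `c1..c<order>`.
#' @export
featurize_calls <- function(calls, order = 20) {
  stopifnot(is.data.frame(calls), "recording" %in% names(calls))
  feats <- purrr::map(calls$recording, extract_features, order = order)
  mat <- do.call(rbind, feats)
  colnames(mat) <- paste0("c", seq_len(order))
  dplyr::bind_cols(
    tibble::tibble(label = calls$label),
    tibble::as_tibble(mat)
  )
}

#' Split a feature table into label vector and feature matrix
#'
#' @param features A feature tibble with a `label` column (all remaining
#'   numeric columns are features), or a bare numeric matrix.
#' @return A list with `x` (matrix) and `label` (vector or NULL).
#' @keywords internal
feature_matrix <- function(features) {
  if (is.matrix(features)) return(list(x = features, label = NULL))
  stopifnot(is.data.frame(features))
  lab <- if ("label" %in% names(features)) features$label else NULL
  x <- as.matrix(features[setdiff(names(features), "label")])
  storage.mode(x) <- "double"
  list(x = x, label = lab)
}
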