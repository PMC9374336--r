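#' Deconvolution and event-calling parameters
#'
#' @param gamma Per-frame AR(1) decay in (0, 1). If `NULL`, derived from the
#'   kernel time constant as `exp(-1 / (tau * sampling_rate))`.
#' @param tau Calcium kernel decay constant in seconds (GCaMP6m-scale
#'   default 1.0 s); used only when `gamma` is `NULL`.
#' @param sampling_rate Hz, used only when `gamma` is `NULL`.
#' @param sparsity_penalty Nonnegative L1 penalty on inferred activity.
#'   Default 0: thresholded event calling does the sparsification and the
#'   solver stays an exact projection.
#' @param event_threshold_k Event threshold in multiples of the estimated
#'   trace noise SD.
#' @param min_separation Minimum event separation in frames; closer events
#'   are merged keeping the larger.
#' @return A list of class `deconv_params`.
#' @export
deconv_params <- function(gamma = NULL, tau = 1.0, sampling_rate = 10,
                          sparsity_penalty = 0, event_threshold_k = 3,
                          min_separation = 2) {
  if (is.null(gamma)) gamma <- exp(-1 / (tau * sampling_rate))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0 || gamma >= 1)
    stop("gamma must lie in (0, 1)", call. = FALSE)
  if (sparsity_penalty < 0) stop("sparsity_penalty must be >= 0", call. = FALSE)
  if (event_threshold_k <= 0) stop("event_threshold_k must be > 0", call. = FALSE)
  if (min_separation < 1) stop("min_separation must be >= 1 frame", call. = FALSE)
  structure(list(gamma = gamma, sparsity_penalty = sparsity_penalty,
                 event_threshold_k = event_threshold_k,
                 min_separation = as.integer(min_separation)),
            class = "deconv_params")
}

#' Z-score a fluorescence trace
#'
#' Centers and scales by the population SD, computed either on the whole
#' trace or on a reference time window.
#'
#' @param trace A `fluor_trace`.
#' @param reference_window Optional half-open `c(a, b)` in seconds inside
#'   the trace span; mean and SD are computed there but the whole trace is
#'   transformed.
#' @return A `fluor_trace` with standardized values.
#' @export
zscore_trace <- function(trace, reference_window = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  v <- trace$values
  ref <- v
  if (!is.null(reference_window)) {
    check_window(reference_window, "reference_window")
    tt <- trace_times(trace)
    sel <- tt >= reference_window[1] & tt < reference_window[2]
    if (!any(sel))
      stop("reference_window does not overlap the trace", call. = FALSE)
    ref <- v[sel]
  }
  mu <- mean(ref)
  sdev <- sqrt(mean((ref - mu)^2))
  if (sdev == 0)
    stop("degenerate input: zero variance in reference segment", call. = FALSE)
  fluor_trace(trace$neuron_id, (v - mu) / sdev,
              sampling_rate = trace$sampling_rate,
              start_time = trace$start_time)
}

#' Robust noise estimate of a trace
#'
#' Median absolute deviation of the first difference, scaled by
#' `1 / (sqrt(2) * 0.6745)` so that for white Gaussian noise it estimates
#' the per-sample SD.
#'
#' @param values Numeric trace values (or a `fluor_trace`).
#' @return Estimated noise SD.
#' @export
estimate_noise_sd <- function(values) {
  if (inherits(values, "fluor_trace")) values <- values$values
  d <- diff(values)
  if (length(d) == 0) return(0)
  stats::median(abs(d - stats::median(d))) / (sqrt(2) * 0.6745)
}

#' Sparse non-negative AR(1) deconvolution (online active set)
#'
#' Solves `min 0.5 * ||y - c||^2 + lambda * sum(s)` subject to
#' `c_t = gamma * c_[t-1] + s_t`, `s >= 0`, `c >= 0`, by the online
#' active-set / pool-adjacent-violators scheme for the AR(1) model.
#' Equivalent to weighted isotonic regression of `y_t / gamma^t`, so the
#' returned solution is the exact global optimum.
#'
#' @param trace A `fluor_trace`, or a bare numeric vector of samples.
#' @param params A `deconv_params`.
#' @return A list with `spikes` (nonnegative activity `s`, one entry per
#'   frame) and `fit` (the denoised calcium `c`).
#' @export
deconvolve_trace <- function(trace, params = deconv_params()) {
  y <- if (inherits(trace, "fluor_trace")) trace$values else as.numeric(trace)
  stopifnot(inherits(params, "deconv_params"))
  if (length(y) < 10)
    stop("trace must have at least 10 frames", call. = FALSE)
  g <- params$gamma
  lam <- params$sparsity_penalty
  n <- length(y)
  # absorb the L1 term: 1's = (1-gamma)*sum(c[1:(n-1)]) + c[n]
  ytil <- y - lam * (1 - g)
  ytil[n] <- y[n] - lam

  # pools: value v, weight w, start t, length l
  v <- numeric(n); w <- numeric(n); tp <- integer(n); l <- integer(n)
  m <- 0L
  for (t in seq_len(n)) {
    m <- m + 1L
    v[m] <- ytil[t]; w[m] <- 1; tp[m] <- t; l[m] <- 1L
    while (m > 1L && v[m] < g^l[m - 1L] * v[m - 1L]) {
      gl <- g^l[m - 1L]
      wnew <- w[m - 1L] + gl^2 * w[m]
      v[m - 1L] <- (w[m - 1L] * v[m - 1L] + gl * w[m] * v[m]) / wnew
      w[m - 1L] <- wnew
      l[m - 1L] <- l[m - 1L] + l[m]
      m <- m - 1L
    }
  }
  cfit <- numeric(n)
  for (i in seq_len(m)) {
    vi <- max(v[i], 0)  # c >= 0: clip the pooled value (exact for isotonic)
    cfit[tp[i]:(tp[i] + l[i] - 1L)] <- vi * g^(0:(l[i] - 1L))
  }
  s <- c(cfit[1], cfit[-1] - g * cfit[-n])
  s[s < 0 & s > -1e-12] <- 0  # rounding at pool boundaries
  list(spikes = s, fit = cfit)
}

#' Call transient events from deconvolved activity
#'
#' Positive activity frames closer than `min_separation` frames are grouped
#' into one candidate event (so activity that the solver splits across
#' neighboring frames is treated as a single transient, and supra-threshold
#' peaks closer than `min_separation` merge keeping the larger). A candidate
#' becomes an event when its total activity mass exceeds
#' `event_threshold_k` times the trace noise SD ([estimate_noise_sd()]);
#' the event is placed at the candidate's largest activity frame.
#'
#' @param activity Nonnegative activity vector from [deconvolve_trace()].
#' @param trace The `fluor_trace` the activity was derived from (supplies
#'   the time grid and the noise estimate).
#' @param params A `deconv_params`.
#' @param noise_sd Optional noise SD override.
#' @return An `event_train` on the trace's span (possibly empty).
#' @export
detect_transients <- function(activity, trace, params = deconv_params(),
                              noise_sd = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  n <- length(activity)
  if (n != length(trace$values))
    stop("activity must be aligned to the trace frames", call. = FALSE)
  span <- c(trace$start_time, trace$start_time + n / trace$sampling_rate)
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(trace)
  thr <- params$event_threshold_k * noise_sd

  pos <- which(activity > 0)
  if (!length(pos))
    return(event_train(trace$neuron_id, numeric(0), span))
  cluster <- cumsum(c(1L, diff(pos) >= params$min_separation))
  idx <- unlist(lapply(split(pos, cluster), function(g) {
    if (sum(activity[g]) > thr) g[which.max(activity[g])] else integer(0)
  }), use.names = FALSE)
  tms <- trace$start_time + (sort(idx) - 1L) / trace$sampling_rate
  event_train(trace$neuron_id, tms, span)
}

#' Detect events in a trace (deconvolve + threshold)
#'
#' Convenience wrapper: [deconvolve_trace()] followed by
#' [detect_transients()].
#'
#' @inheritParams deconvolve_trace
#' @return An `event_train`.
#' @export
detect_events <- function(trace, params = deconv_params()) {
  d <- deconvolve_trace(trace, params)
  detect_transients(d$spikes, trace, params)
}

#' Count events in a half-open time window
#'
#' @param train An `event_train`.
#' @param window Half-open `c(a, b)` in seconds.
#' @return Integer count of events with `a <= t < b`.
#' @export
count_events <- function(train, window) {
  stopifnot(inherits(train, "event_train"))
  check_window(window)
  sum(train$times >= window[1] & train$times < window[2])
}

#' Transient frequency in a window, events per minute
#'
#' @inheritParams count_events
#' @return Events per minute over the window.
#' @export
transient_frequency <- function(train, window) {
  count_events(train, window) / (window[2] - window[1]) * 60
}
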