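#' Construct a fluorescence trace
#'
#' A single neuron's delta-F-over-noise values on a uniform time grid.
#'
#' @param neuron_id Character or integer identifier.
#' @param values Numeric vector of delta-F-over-noise samples.
#' @param sampling_rate Sampling rate in Hz (default 10, the usual miniscope
#'   frame rate).
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `fluor_trace` with fields `neuron_id`,
#'   `start_time`, `sampling_rate`, `values`.
#' @export
fluor_trace <- function(neuron_id, values, sampling_rate = 10, start_time = 0) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate must be a positive number", call. = FALSE)
  structure(
    list(neuron_id = as.character(neuron_id)[1],
         start_time = as.numeric(start_time)[1],
         sampling_rate = as.numeric(sampling_rate)[1],
         values = values),
    class = "fluor_trace"
  )
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> neuron %s: %d frames @ %g Hz, t0 = %g s\n",
              x$neuron_id, length(x$values), x$sampling_rate, x$start_time))
  invisible(x)
}

#' Time stamps of the frames of a trace
#' @param trace A `fluor_trace`.
#' @return Numeric vector of frame times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1L) / trace$sampling_rate
}

#' Construct an event (transient) train
#'
#' Calcium transient timestamps for one neuron within a session.
#'
#' @param neuron_id Identifier.
#' @param times Event times in seconds, strictly increasing (sorted here).
#' @param span Length-2 numeric `(t0, t1)`; every event must satisfy
#'   `t0 <= t < t1`.
#' @return An object of class `event_train`.
#' @export
event_train <- function(neuron_id, times, span) {
  times <- sort(as.numeric(times))
  span <- as.numeric(span)
  if (length(span) != 2 || !all(is.finite(span)) || span[1] >= span[2])
    stop("span must be (t0, t1) with t0 < t1", call. = FALSE)
  if (length(times) && (times[1] < span[1] || times[length(times)] >= span[2]))
    stop("event times must lie in [span[1], span[2])", call. = FALSE)
  if (anyDuplicated(times))
    times <- unique(times)
  structure(
    list(neuron_id = as.character(neuron_id)[1], times = times, span = span),
    class = "event_train"
  )
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> neuron %s: %d events in [%g, %g) s\n",
              x$neuron_id, length(x$times), x$span[1], x$span[2]))
  invisible(x)
}

#' Construct an occupancy track
#'
#' Time-stamped chamber labels for a two-chamber CPP session.
#'
#' @param time_s Strictly increasing sample times in seconds.
#' @param chamber Character vector of chamber labels (conventionally
#'   `"saline"` / `"cocaine"`); exactly one or two distinct labels allowed.
#' @return A data frame of class `occupancy_track` with columns
#'   `time_s`, `chamber`.
#' @export
occupancy_track <- function(time_s, chamber) {
  time_s <- as.numeric(time_s)
  chamber <- as.character(chamber)
  if (length(time_s) != length(chamber) || length(time_s) == 0)
    stop("time_s and chamber must be nonempty and equal length", call. = FALSE)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (length(unique(chamber)) > 2)
    stop("occupancy track must use at most two chamber labels", call. = FALSE)
  structure(data.frame(time_s = time_s, chamber = chamber,
                       stringsAsFactors = FALSE),
            class = c("occupancy_track", "data.frame"))
}

#' Sampling interval of an occupancy track
#' @param track An `occupancy_track`.
#' @return Median spacing between samples, in seconds.
#' @keywords internal
track_dt <- function(track) {
  if (nrow(track) < 2) return(NA_real_)
  stats::median(diff(track$time_s))
}

# --- internal helpers -------------------------------------------------------

# validate a half-open time window c(a, b)
check_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2 || !all(is.finite(window)) ||
      window[1] >= window[2])
    stop(sprintf("%s must be numeric c(a, b) with a < b", what), call. = FALSE)
  invisible(window)
}

# deterministic 31-bit seed for a named substream, independent of iteration
# order: polynomial hash of the id string mixed with the master seed
substream_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + h + 1) %% 2147483647)
}

# run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
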