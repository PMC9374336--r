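# CSV schemas shared by the simulator and the pipeline:
#   traces:    wide, column 1 `time_s`, one column per neuron id
#   events:    long, `neuron_id,time_s`
#   occupancy: `time_s,chamber` with chamber in {saline, cocaine}
#   truth:     `neuron_id,true_class,baseline_rate,multiplier`
# plus a JSON sidecar holding the generating parameters and seed.

#' Write traces to a wide CSV
#' @param traces Named list of `fluor_trace` on a common grid.
#' @param path Output file.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(length(traces) > 0)
  tt <- trace_times(traces[[1]])
  df <- data.frame(time_s = tt)
  for (tr in traces) {
    if (length(tr$values) != length(tt))
      stop("traces must share one time grid", call. = FALSE)
    df[[tr$neuron_id]] <- tr$values
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from a wide CSV
#' @param path CSV with `time_s` first column, one column per neuron.
#' @return Named list of `fluor_trace`.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2)
    stop("malformed traces CSV (need time_s + neuron columns): ", path,
         call. = FALSE)
  dt <- diff(df$time_s)
  if (any(!is.finite(dt)) || any(abs(dt - dt[1]) > 1e-6))
    stop("malformed traces CSV: non-uniform time grid in ", path,
         call. = FALSE)
  fs <- 1 / dt[1]
  ids <- setdiff(names(df), "time_s")
  out <- lapply(ids, function(id)
    fluor_trace(id, df[[id]], sampling_rate = fs, start_time = df$time_s[1]))
  names(out) <- ids
  out
}

#' Write event trains to a long CSV
#' @param events Named list of `event_train`.
#' @param path Output file.
#' @export
write_events_csv <- function(events, path) {
  rows <- lapply(events, function(e)
    if (length(e$times))
      data.frame(neuron_id = e$neuron_id, time_s = e$times,
                 stringsAsFactors = FALSE)
    else NULL)
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(neuron_id = character(0), time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read event trains from a long CSV
#' @param path CSV with columns `neuron_id,time_s`.
#' @param span Session span `(t0, t1)`; defaults to the range of the data
#'   (floor/ceiling to the second).
#' @param neuron_ids Optional id set, so neurons with zero events are kept.
#' @return Named list of `event_train`.
#' @export
read_events_csv <- function(path, span = NULL, neuron_ids = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("neuron_id", "time_s") %in% names(df)))
    stop("malformed events CSV (need neuron_id,time_s): ", path, call. = FALSE)
  df$neuron_id <- as.character(df$neuron_id)
  df$time_s <- as.numeric(df$time_s)
  if (nrow(df) && any(!is.finite(df$time_s)))
    stop("malformed events CSV: non-finite time_s at row ",
         which(!is.finite(df$time_s))[1], " of ", path, call. = FALSE)
  if (is.null(span)) {
    if (!nrow(df)) stop("cannot infer span from an empty events CSV",
                        call. = FALSE)
    span <- c(floor(min(df$time_s)), ceiling(max(df$time_s)) + 1)
  }
  ids <- if (is.null(neuron_ids)) unique(df$neuron_id) else neuron_ids
  out <- lapply(ids, function(id)
    event_train(id, df$time_s[df$neuron_id == id], span))
  names(out) <- ids
  out
}

#' Write an occupancy track to CSV
#' @param track An `occupancy_track`.
#' @param path Output file.
#' @export
write_occupancy_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Read an occupancy track from CSV
#' @param path CSV with columns `time_s,chamber`.
#' @return An `occupancy_track`.
#' @export
read_occupancy_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "chamber") %in% names(df)))
    stop("malformed occupancy CSV (need time_s,chamber): ", path,
         call. = FALSE)
  occupancy_track(as.numeric(df$time_s), as.character(df$chamber))
}

#' Write a simulated session to a directory
#'
#' Traces (if present), events, occupancy (if present), and ground truth as
#' CSV, plus a `params.json` sidecar with the generating parameters.
#'
#' @param session Output of [simulate_injection_session()] or
#'   [simulate_cpp_session()].
#' @param dir Output directory (created if needed).
#' @param params The generating parameter object, stored in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, params = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_events_csv(session$events, file.path(dir, "events.csv"))
  if (!is.null(session$traces))
    write_traces_csv(session$traces, file.path(dir, "traces.csv"))
  if (!is.null(session$track))
    write_occupancy_csv(session$track, file.path(dir, "occupancy.csv"))
  utils::write.csv(session$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(unclass(params), file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
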