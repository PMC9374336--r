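#' Run configuration for the end-to-end pipelines
#'
#' Collects inputs (in-memory objects or CSV paths), analysis windows and
#' test configurations, the master seed, and an optional output directory.
#'
#' @param events Named list of `event_train`, or path to an events CSV.
#' @param traces Named list of `fluor_trace`, or path to a traces CSV
#'   (optional; required for the trace-comparison methods, and used to
#'   detect events when `events` is absent).
#' @param track,pre_track,post_track `occupancy_track`s or CSV paths (CPP
#'   pipeline; `track` is the recording session being classified).
#' @param windows A `phase_windows` (injection pipeline).
#' @param perm_cfg A `permutation_config`.
#' @param trace_cfg A `trace_test_config`.
#' @param episode_cfg An `episode_config`.
#' @param deconv A `deconv_params` for event detection from traces.
#' @param seed Master seed; overrides `perm_cfg$seed`.
#' @param outdir Optional directory for label CSVs and the JSON report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(events = NULL, traces = NULL, track = NULL,
                       pre_track = NULL, post_track = NULL,
                       windows = phase_windows(),
                       perm_cfg = permutation_config(),
                       trace_cfg = trace_test_config(),
                       episode_cfg = episode_config(),
                       deconv = deconv_params(),
                       seed = 1L, outdir = NULL) {
  for (p in list(events, traces, track, pre_track, post_track))
    if (is.character(p) && !file.exists(p))
      stop("input file does not exist: ", p, call. = FALSE)
  perm_cfg$seed <- as.integer(seed)
  structure(list(events = events, traces = traces, track = track,
                 pre_track = pre_track, post_track = post_track,
                 windows = windows, perm_cfg = perm_cfg,
                 trace_cfg = trace_cfg, episode_cfg = episode_cfg,
                 deconv = deconv, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

resolve_events <- function(cfg, span = NULL) {
  if (is.character(cfg$events)) read_events_csv(cfg$events, span = span)
  else cfg$events
}

resolve_traces <- function(cfg) {
  if (is.character(cfg$traces)) read_traces_csv(cfg$traces) else cfg$traces
}

resolve_track <- function(x) {
  if (is.character(x)) read_occupancy_csv(x) else x
}

# deterministic provenance fingerprint of the configuration (small additive
# hash over the deparsed non-input fields; not cryptographic)
config_hash <- function(cfg) {
  keep <- cfg[c("windows", "perm_cfg", "trace_cfg", "episode_cfg", "deconv",
                "seed")]
  txt <- paste(deparse(keep), collapse = "")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", h)
}

report_provenance <- function(cfg) {
  list(config_hash = config_hash(cfg), seed = cfg$seed,
       package_version = as.character(utils::packageVersion("catrans")))
}

# recursively drop S3 classes (keeping data frames) so jsonlite can
# serialize report components such as behavior_summary
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

write_report <- function(report, labels, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  utils::write.csv(labels, file.path(outdir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(strip_classes(report[setdiff(names(report), "labels")]),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
}

#' Run the injection-session analysis end to end
#'
#' Detects events from traces when only traces are given, classifies every
#' neuron for the initial (and, when defined, decay) phase with the
#' interval-shuffling permutation test — and with the binned-trace
#' signed-rank test when traces are available — then summarizes population
#' fractions, fold change, and initial/decay persistence. Deterministic
#' given the configuration seed.
#'
#' @param cfg A `run_config` with `events` and/or `traces` and injection
#'   `windows`.
#' @return A list of class `analysis_report`: `labels` (long data frame
#'   over methods and phases), `summary` (per method/phase population
#'   summaries), `overlap` (persistence tables per method, when a decay
#'   window exists), `group_frequency`, and `provenance`. Written to
#'   `cfg$outdir` when set.
#' @export
run_injection_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  w <- cfg$windows
  span <- c(w$pre[1], if (!is.null(w$decay)) w$decay[2] else w$initial[2])
  traces <- resolve_traces(cfg)
  events <- resolve_events(cfg, span = span)
  if (is.null(events)) {
    if (is.null(traces))
      stop("need events or traces in the configuration", call. = FALSE)
    events <- lapply(traces, detect_events, params = cfg$deconv)
  }

  phases <- list(initial = w$initial)
  if (!is.null(w$decay)) phases$decay <- w$decay

  labels <- list(); summaries <- list()
  for (ph in names(phases)) {
    res <- classify_population(events, w$pre, phases[[ph]], cfg$perm_cfg,
                               method = "transients")
    res$phase <- ph
    labels[[paste0("transients_", ph)]] <- res
    summaries[[paste0("transients_", ph)]] <- summarize_population(res)
    if (!is.null(traces)) {
      res_t <- classify_population(traces, w$pre, phases[[ph]], cfg$trace_cfg,
                                   method = "traces")
      res_t$phase <- ph
      labels[[paste0("traces_", ph)]] <- res_t
      summaries[[paste0("traces_", ph)]] <- summarize_population(res_t)
    }
  }

  overlap <- NULL
  if (!is.null(w$decay)) {
    overlap <- list(transients = overlap_analysis(
      labels$transients_initial, labels$transients_decay))
    if (!is.null(traces))
      overlap$traces <- overlap_analysis(labels$traces_initial,
                                         labels$traces_decay)
  }

  gf <- group_frequency_change(events, labels$transients_initial,
                               w$pre, w$initial)
  lab_df <- do.call(rbind, labels)
  rownames(lab_df) <- NULL
  report <- structure(list(labels = lab_df, summary = summaries,
                           overlap = overlap, group_frequency = gf,
                           provenance = report_provenance(cfg)),
                      class = "analysis_report")
  if (!is.null(cfg$outdir)) write_report(report, lab_df, cfg$outdir)
  report
}

#' Run the CPP-session analysis end to end
#'
#' Extracts chamber-staying episodes from the occupancy track, classifies
#' CACE neurons by per-episode transient frequency (and by per-episode
#' trace means when traces are available), aligns event rates around
#' cocaine-chamber entries, and scores place preference when pre- and
#' post-conditioning tracks are both given.
#'
#' @param cfg A `run_config` with `events` (or `traces`), `track`, and
#'   optionally `pre_track`/`post_track`.
#' @return A list of class `analysis_report`: `labels`, `summary`,
#'   `peri_entry`, `behavior` (a `behavior_summary` or `NULL`),
#'   `provenance`.
#' @export
run_cpp_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  track <- resolve_track(cfg$track)
  if (is.null(track))
    stop("CPP pipeline needs an occupancy track", call. = FALSE)
  span <- c(track$time_s[1],
            track$time_s[nrow(track)] + max(track_dt(track), 0, na.rm = TRUE))
  traces <- resolve_traces(cfg)
  events <- resolve_events(cfg, span = span)
  if (is.null(events)) {
    if (is.null(traces))
      stop("need events or traces in the configuration", call. = FALSE)
    events <- lapply(traces, detect_events, params = cfg$deconv)
  }

  labels <- list()
  res <- classify_cace_population(events, track, cfg$episode_cfg,
                                  method = "transients")
  res$phase <- "recording"
  labels$transients <- res
  summaries <- list(transients = summarize_population(
    res[res$label != "nonclassifiable", , drop = FALSE]))
  if (!is.null(traces)) {
    res_t <- classify_cace_population(traces, track, cfg$episode_cfg,
                                      method = "traces")
    res_t$phase <- "recording"
    labels$traces <- res_t
    summaries$traces <- summarize_population(
      res_t[res_t$label != "nonclassifiable", , drop = FALSE])
  }

  peri <- peri_entry_summary(events, track, "cocaine", cfg$episode_cfg)

  behavior <- NULL
  if (!is.null(cfg$pre_track) && !is.null(cfg$post_track))
    behavior <- cpp_score(resolve_track(cfg$pre_track),
                          resolve_track(cfg$post_track))

  lab_df <- do.call(rbind, labels)
  rownames(lab_df) <- NULL
  report <- structure(list(labels = lab_df, summary = summaries,
                           peri_entry = peri, behavior = behavior,
                           provenance = report_provenance(cfg)),
                      class = "analysis_report")
  if (!is.null(cfg$outdir)) write_report(report, lab_df, cfg$outdir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %s: %d neurons — %.1f%% excited, %.1f%% inhibited",
                nm, s$n_total, s$pct_excited, s$pct_inhibited))
    if (!is.na(s$fold_inhibited_over_excited))
      cat(sprintf(" (%.1f-fold inhibited/excited)",
                  s$fold_inhibited_over_excited))
    cat("\n")
  }
  cat(sprintf("  seed %d, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}
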