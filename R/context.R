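#' Episode and peri-entry analysis configuration
#'
#' @param min_dwell Minimum chamber dwell in seconds; only episodes strictly
#'   longer are analyzed (default 5 s).
#' @param min_episodes_per_chamber Minimum episodes per chamber for the
#'   rank test; neurons below it are nonclassifiable.
#' @param alpha Two-sided significance level.
#' @param peri_window Half-width of the peri-entry window, seconds.
#' @param peri_bin Peri-entry bin width, seconds.
#' @return A list of class `episode_config`.
#' @export
episode_config <- function(min_dwell = 5, min_episodes_per_chamber = 3,
                           alpha = 0.05, peri_window = 5, peri_bin = 1) {
  if (min_dwell <= 0) stop("min_dwell must be > 0", call. = FALSE)
  if (min_episodes_per_chamber < 2)
    stop("min_episodes_per_chamber must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (peri_window <= 0 || peri_bin <= 0 || peri_window %% peri_bin > 1e-9)
    stop("peri_window must be a positive multiple of peri_bin", call. = FALSE)
  structure(list(min_dwell = min_dwell,
                 min_episodes_per_chamber = as.integer(min_episodes_per_chamber),
                 alpha = alpha, peri_window = peri_window, peri_bin = peri_bin),
            class = "episode_config")
}

#' Extract chamber-staying episodes from an occupancy track
#'
#' Maximal constant-chamber runs of the track, as half-open `[start, end)`
#' intervals; the last run is closed one sampling interval after the last
#' sample. Runs with duration at most `min_dwell` are excluded from the
#' episode list (entries into them still count for peri-entry alignment,
#' which works on the raw track).
#'
#' @param track An `occupancy_track` with labels from
#'   `{"saline", "cocaine"}`.
#' @param cfg An `episode_config`.
#' @return Data frame with `chamber`, `start_s`, `end_s`, `duration_s`,
#'   ordered in time.
#' @export
extract_episodes <- function(track, cfg = episode_config()) {
  stopifnot(inherits(track, "occupancy_track"))
  bad <- setdiff(unique(track$chamber), c("saline", "cocaine"))
  if (length(bad))
    stop("unknown chamber label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  r <- rle(track$chamber)
  idx_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  start_s <- track$time_s[idx_start]
  dt <- track_dt(track)
  end_s <- c(start_s[-1], track$time_s[nrow(track)] + (if (is.na(dt)) 0 else dt))
  ep <- data.frame(chamber = r$values, start_s = start_s, end_s = end_s,
                   duration_s = end_s - start_s, stringsAsFactors = FALSE)
  ep <- ep[ep$duration_s > cfg$min_dwell, , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

#' Per-episode transient frequencies
#'
#' Event count in each episode divided by the episode duration, in events
#' per minute, grouped by chamber.
#'
#' @param train An `event_train`.
#' @param episodes Episode data frame from [extract_episodes()].
#' @return The episode data frame with `n_events` and `freq_per_min` added.
#' @export
episode_frequencies <- function(train, episodes) {
  stopifnot(inherits(train, "event_train"))
  if (!nrow(episodes)) {
    out <- episodes
    out$n_events <- integer(0); out$freq_per_min <- numeric(0)
    return(out)
  }
  n <- vapply(seq_len(nrow(episodes)), function(i)
    count_events(train, c(episodes$start_s[i], episodes$end_s[i])), numeric(1))
  out <- episodes
  out$n_events <- as.integer(n)
  out$freq_per_min <- n / episodes$duration_s * 60
  out
}

# per-episode mean trace values, same layout as episode_frequencies
episode_trace_means <- function(trace, episodes) {
  tt <- trace_times(trace)
  vapply(seq_len(nrow(episodes)), function(i) {
    sel <- tt >= episodes$start_s[i] & tt < episodes$end_s[i]
    if (!any(sel)) return(NA_real_)
    mean(trace$values[sel])
  }, numeric(1))
}

#' Classify a context-encoding (CACE) neuron
#'
#' Compares neuronal activity between cocaine-chamber and saline-chamber
#' staying episodes with a two-sided Mann-Whitney U test (exact for
#' combined episode counts up to 20, tie-corrected normal approximation
#' beyond). Activity is the per-episode transient frequency (method
#' `"transients"`) or the per-episode mean trace value (method `"traces"`).
#' Significantly higher cocaine-chamber activity gives
#' "excited" (cocaine-chamber-excited), lower gives "inhibited"; neurons
#' with fewer than `min_episodes_per_chamber` episodes in either chamber
#' are "nonclassifiable".
#'
#' @param x An `event_train` (transients) or `fluor_trace` (traces).
#' @param episodes Episode data frame from [extract_episodes()].
#' @param cfg An `episode_config`.
#' @param method `"transients"` or `"traces"`.
#' @return One-row data frame: `neuron_id`, `label`, `statistic` (U),
#'   `p_value`, `n_cocaine`, `n_saline`, `method`.
#' @export
classify_cace <- function(x, episodes, cfg = episode_config(),
                          method = c("transients", "traces")) {
  method <- match.arg(method)
  vals <- if (method == "transients") {
    stopifnot(inherits(x, "event_train"))
    episode_frequencies(x, episodes)$freq_per_min
  } else {
    stopifnot(inherits(x, "fluor_trace"))
    episode_trace_means(x, episodes)
  }
  id <- x$neuron_id
  coc <- vals[episodes$chamber == "cocaine"]
  sal <- vals[episodes$chamber == "saline"]
  coc <- coc[!is.na(coc)]; sal <- sal[!is.na(sal)]
  if (length(coc) < cfg$min_episodes_per_chamber ||
      length(sal) < cfg$min_episodes_per_chamber) {
    return(data.frame(neuron_id = id, label = "nonclassifiable",
                      statistic = NA_real_, p_value = NA_real_,
                      n_cocaine = length(coc), n_saline = length(sal),
                      method = method, stringsAsFactors = FALSE))
  }
  ts <- mann_whitney_test(coc, sal)
  label <- if (ts$p_value < cfg$alpha && ts$direction > 0) "excited"
           else if (ts$p_value < cfg$alpha && ts$direction < 0) "inhibited"
           else "nonresponsive"
  data.frame(neuron_id = id, label = label, statistic = ts$statistic,
             p_value = ts$p_value, n_cocaine = length(coc),
             n_saline = length(sal), method = method, stringsAsFactors = FALSE)
}

#' Classify a population of CACE neurons
#'
#' @param xs Named list of `event_train` or `fluor_trace`.
#' @param track An `occupancy_track` shared by the population.
#' @param cfg An `episode_config`.
#' @param method `"transients"` or `"traces"`.
#' @return Data frame with one row per neuron.
#' @export
classify_cace_population <- function(xs, track, cfg = episode_config(),
                                     method = c("transients", "traces")) {
  method <- match.arg(method)
  if (!length(xs)) stop("empty population", call. = FALSE)
  episodes <- extract_episodes(track, cfg)
  out <- do.call(rbind, lapply(xs, classify_cace, episodes = episodes,
                               cfg = cfg, method = method))
  rownames(out) <- NULL
  out
}

#' Peri-entry event-rate matrix for one neuron
#'
#' Aligns the event train on transitions into a chamber: for each entry,
#' event counts in `peri_bin`-wide bins over `[-peri_window, +peri_window)`
#' seconds around the entry (entry at 0). Entries closer than `peri_window`
#' to the session edges are dropped.
#'
#' @param train An `event_train`.
#' @param track An `occupancy_track`.
#' @param target_chamber Chamber whose entries define time zero.
#' @param cfg An `episode_config`.
#' @param require_dwell Minimum dwell (s) in the departed chamber before,
#'   and in the target chamber after, a transition for it to count as an
#'   entry. Default 0: every transition counts.
#' @return List with `counts` (entries x bins matrix), `bin_left` (left bin
#'   edges, s), `entry_times`, `pre_rate` and `post_rate` (mean event rate
#'   over `[-peri_window, 0)` and `[0, +peri_window)` across entries, in
#'   events/min), and `curve` (per-bin mean rate across entries,
#'   events/min). Empty (zero-row) matrix with a warning when no entry
#'   survives the edge rule.
#' @export
peri_entry_matrix <- function(train, track, target_chamber = "cocaine",
                              cfg = episode_config(), require_dwell = 0) {
  stopifnot(inherits(train, "event_train"), inherits(track, "occupancy_track"))
  if (!target_chamber %in% track$chamber)
    stop("target_chamber not present in track", call. = FALSE)
  w <- cfg$peri_window
  nb <- as.integer(round(2 * w / cfg$peri_bin))
  bin_left <- -w + (seq_len(nb) - 1) * cfg$peri_bin

  is_target <- track$chamber == target_chamber
  entry_idx <- which(is_target & !c(TRUE, is_target[-nrow(track)]))
  entries <- track$time_s[entry_idx]
  dt <- track_dt(track)
  t0 <- track$time_s[1]
  t1 <- track$time_s[nrow(track)] + (if (is.na(dt)) 0 else dt)
  if (require_dwell > 0 && length(entries)) {
    r <- rle(track$chamber)
    run_start <- track$time_s[cumsum(c(1L, r$lengths[-length(r$lengths)]))]
    run_end <- c(run_start[-1], t1)
    run_of_entry <- findInterval(entries, run_start)
    ok <- vapply(run_of_entry, function(k) {
      k > 1 &&
        (run_end[k - 1] - run_start[k - 1]) >= require_dwell &&
        (run_end[k] - run_start[k]) >= require_dwell
    }, logical(1))
    entries <- entries[ok]
  }
  entries <- entries[entries - w >= t0 & entries + w <= t1]

  if (!length(entries)) {
    warning("no valid entries into ", target_chamber, call. = FALSE)
    m <- matrix(numeric(0), nrow = 0, ncol = nb)
    return(list(counts = m, bin_left = bin_left, entry_times = numeric(0),
                pre_rate = NA_real_, post_rate = NA_real_,
                curve = rep(NA_real_, nb)))
  }
  counts <- t(vapply(entries, function(te) {
    vapply(bin_left, function(a)
      sum(train$times >= te + a & train$times < te + a + cfg$peri_bin),
      numeric(1))
  }, numeric(nb)))
  pre_cols <- bin_left < 0
  list(counts = counts, bin_left = bin_left, entry_times = entries,
       pre_rate = mean(rowSums(counts[, pre_cols, drop = FALSE])) / w * 60,
       post_rate = mean(rowSums(counts[, !pre_cols, drop = FALSE])) / w * 60,
       curve = colMeans(counts) / cfg$peri_bin * 60)
}

#' Peri-entry group summary across neurons
#'
#' @param trains Named list of `event_train`.
#' @param track Shared `occupancy_track`.
#' @param target_chamber Chamber whose entries define time zero.
#' @param cfg An `episode_config`.
#' @return List with `per_neuron` (data frame of per-neuron pre/post entry
#'   rates, events/min) and `curve` (bin-wise mean rate over entries then
#'   neurons).
#' @export
peri_entry_summary <- function(trains, track, target_chamber = "cocaine",
                               cfg = episode_config()) {
  per <- lapply(trains, peri_entry_matrix, track = track,
                target_chamber = target_chamber, cfg = cfg)
  df <- data.frame(
    neuron_id = vapply(trains, `[[`, character(1), "neuron_id"),
    pre_rate = vapply(per, `[[`, numeric(1), "pre_rate"),
    post_rate = vapply(per, `[[`, numeric(1), "post_rate"),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  curves <- do.call(rbind, lapply(per, `[[`, "curve"))
  list(per_neuron = df, curve = colMeans(curves, na.rm = TRUE),
       bin_left = per[[1]]$bin_left)
}

# total time per chamber label from a track (run lengths; last sample
# closed one sampling interval later)
chamber_times <- function(track) {
  r <- rle(track$chamber)
  idx_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  start_s <- track$time_s[idx_start]
  dt <- track_dt(track)
  end_s <- c(start_s[-1], track$time_s[nrow(track)] + (if (is.na(dt)) 0 else dt))
  tapply(end_s - start_s, r$values, sum)
}

#' CPP score and baseline-preference exclusion
#'
#' The cocaine-paired chamber defaults to the less-preferred chamber of the
#' preconditioning track (the conditioning assignment rule); the CPP score
#' is the time spent there post-conditioning minus pre-conditioning.
#' Animals whose baseline preference for either chamber falls below 25% are
#' flagged excluded.
#'
#' @param pre_track,post_track Preconditioning / postconditioning
#'   `occupancy_track`s with matching chamber labels.
#' @param cocaine_chamber Optional explicit cocaine-chamber label; default
#'   assigns the less-preferred chamber of `pre_track`.
#' @param exclusion_threshold Baseline minority-preference fraction below
#'   which the animal is excluded (default 0.25).
#' @return A list of class `behavior_summary`: `cocaine_chamber`,
#'   `pre_time_cocaine_s`, `post_time_cocaine_s`, `cpp_score_s`,
#'   `baseline_preference_fraction`, `excluded`.
#' @export
cpp_score <- function(pre_track, post_track, cocaine_chamber = NULL,
                      exclusion_threshold = 0.25) {
  stopifnot(inherits(pre_track, "occupancy_track"),
            inherits(post_track, "occupancy_track"))
  pre_t <- chamber_times(pre_track)
  post_t <- chamber_times(post_track)
  labs <- union(names(pre_t), names(post_t))
  pre_full <- setNames(rep(0, length(labs)), labs)
  pre_full[names(pre_t)] <- pre_t
  post_full <- setNames(rep(0, length(labs)), labs)
  post_full[names(post_t)] <- post_t
  if (is.null(cocaine_chamber)) {
    # less-preferred pre-conditioning chamber; alphabetical tie-break
    o <- order(pre_full, names(pre_full))
    cocaine_chamber <- names(pre_full)[o[1]]
  } else if (!cocaine_chamber %in% labs) {
    stop("cocaine_chamber not present in tracks", call. = FALSE)
  }
  pref <- min(pre_full) / sum(pre_full)
  structure(list(
    cocaine_chamber = cocaine_chamber,
    pre_time_cocaine_s = unname(pre_full[cocaine_chamber]),
    post_time_cocaine_s = unname(post_full[cocaine_chamber]),
    cpp_score_s = unname(post_full[cocaine_chamber] - pre_full[cocaine_chamber]),
    baseline_preference_fraction = unname(pref),
    excluded = unname(pref < exclusion_threshold)
  ), class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(paste0("<behavior_summary> cocaine chamber: %s\n",
                     "  time pre %.1f s, post %.1f s, CPP score %+.1f s\n",
                     "  baseline preference %.1f%%%s\n"),
              x$cocaine_chamber, x$pre_time_cocaine_s, x$post_time_cocaine_s,
              x$cpp_score_s, 100 * x$baseline_preference_fraction,
              if (x$excluded) " (excluded: strong baseline bias)" else ""))
  invisible(x)
}
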