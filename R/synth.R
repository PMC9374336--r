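#' Phase windows for an injection session
#'
#' Recording layout relative to the injection at t = 0: a 10-min
#' preinjection baseline, a 10-min postinjection initial phase, and a
#' 10-min decay phase starting 50 min after injection.
#'
#' @param pre,initial,decay Length-2 numeric half-open windows in seconds.
#' @return A list of class `phase_windows`.
#' @export
phase_windows <- function(pre = c(-600, 0), initial = c(0, 600),
                          decay = c(3000, 3600)) {
  check_window(pre, "pre"); check_window(initial, "initial")
  w <- list(pre = as.numeric(pre), initial = as.numeric(initial))
  if (!is.null(decay)) {
    check_window(decay, "decay")
    w$decay <- as.numeric(decay)
  }
  starts <- vapply(w, `[`, numeric(1), 1)
  ends <- vapply(w, `[`, numeric(1), 2)
  o <- order(starts)
  if (any(starts[o][-1] < ends[o][-length(o)]))
    stop("phase windows must not overlap", call. = FALSE)
  structure(w, class = "phase_windows")
}

#' Parameters for a synthetic injection session
#'
#' Neurons fire as inhomogeneous Poisson processes: at their baseline rate
#' in the preinjection window and between windows, and at baseline times a
#' class-specific multiplier inside the postinjection windows. Baseline
#' rates are heterogeneous across the population (log-normal around
#' `baseline_rate`); fluorescence traces are built by convolving unit
#' events with an exponential-decay kernel and adding Gaussian noise.
#'
#' @param n_neurons Number of neurons.
#' @param baseline_rate Median baseline event rate, events per minute.
#' @param rate_sdlog Log-scale SD of per-neuron baseline rates (0 = fixed).
#' @param frac_excited,frac_inhibited Population fractions of
#'   injection-excited / injection-inhibited neurons; must sum to at most 1.
#' @param multiplier_excited Rate multiplier (>= 1) applied to excited
#'   neurons in postinjection windows.
#' @param multiplier_inhibited Rate multiplier in (0, 1] for inhibited
#'   neurons.
#' @param kernel_decay_tau Calcium kernel decay constant, seconds.
#' @param noise_sd Additive Gaussian noise SD, delta-F-over-noise units.
#' @param sampling_rate Trace sampling rate, Hz.
#' @param seed Master seed; all randomness derives from it.
#' @return A validated list of class `synth_session_params`.
#' @export
synth_session_params <- function(n_neurons = 100, baseline_rate = 4,
                                 rate_sdlog = 0.5,
                                 frac_excited = 0.15, frac_inhibited = 0.30,
                                 multiplier_excited = 2.5,
                                 multiplier_inhibited = 0.4,
                                 kernel_decay_tau = 1.0, noise_sd = 0.2,
                                 sampling_rate = 10, seed = 1L) {
  p <- list(n_neurons = as.integer(n_neurons), baseline_rate = baseline_rate,
            rate_sdlog = rate_sdlog, frac_excited = frac_excited,
            frac_inhibited = frac_inhibited,
            multiplier_excited = multiplier_excited,
            multiplier_inhibited = multiplier_inhibited,
            kernel_decay_tau = kernel_decay_tau, noise_sd = noise_sd,
            sampling_rate = sampling_rate, seed = as.integer(seed))
  if (p$n_neurons < 1) stop("n_neurons must be >= 1", call. = FALSE)
  if (!is.finite(p$baseline_rate) || p$baseline_rate <= 0)
    stop("baseline_rate must be a positive finite rate", call. = FALSE)
  if (p$rate_sdlog < 0) stop("rate_sdlog must be >= 0", call. = FALSE)
  if (p$frac_excited < 0 || p$frac_inhibited < 0 ||
      p$frac_excited + p$frac_inhibited > 1)
    stop("frac_excited + frac_inhibited must lie in [0, 1]", call. = FALSE)
  if (p$multiplier_excited < 1)
    stop("multiplier_excited must be >= 1", call. = FALSE)
  if (p$multiplier_inhibited <= 0 || p$multiplier_inhibited > 1)
    stop("multiplier_inhibited must be in (0, 1]", call. = FALSE)
  if (p$kernel_decay_tau <= 0 || p$noise_sd < 0 || p$sampling_rate <= 0)
    stop("kernel_decay_tau and sampling_rate must be positive, noise_sd >= 0",
         call. = FALSE)
  structure(p, class = "synth_session_params")
}

# deterministic class layout: first round(fe*n) excited, next round(fi*n)
# inhibited, remainder nonresponsive
assign_classes <- function(n, frac_excited, frac_inhibited) {
  ne <- round(frac_excited * n)
  ni <- round(frac_inhibited * n)
  cls <- rep("none", n)
  if (ne > 0) cls[seq_len(ne)] <- "excited"
  if (ni > 0) cls[ne + seq_len(ni)] <- "inhibited"
  cls
}

# homogeneous Poisson events on [a, b) at `rate` events/min
rpois_events <- function(rate_per_min, a, b) {
  n <- stats::rpois(1, rate_per_min / 60 * (b - a))
  if (n == 0) return(numeric(0))
  sort(stats::runif(n, a, b))
}

# piecewise-constant-rate event train over contiguous segments
rsegmented_events <- function(seg_start, seg_end, seg_rate) {
  ev <- mapply(rpois_events, seg_rate, seg_start, seg_end, SIMPLIFY = FALSE)
  sort(unlist(ev, use.names = FALSE))
}

# sample an exponential-kernel trace from event times: unit impulse placed on
# the first frame at/after each event (scaled for the sub-frame offset), then
# an AR(1) recursive filter with per-frame decay gamma = exp(-1/(tau*fs))
events_to_trace_values <- function(times, span, tau, fs, noise_sd = 0) {
  n_frames <- max(1L, as.integer(round((span[2] - span[1]) * fs)))
  gamma <- exp(-1 / (tau * fs))
  x <- numeric(n_frames)
  if (length(times)) {
    idx <- ceiling((times - span[1]) * fs - 1e-9) + 1L
    tf <- span[1] + (idx - 1L) / fs
    amp <- exp(-(tf - times) / tau)
    keep <- idx >= 1L & idx <= n_frames
    for (k in which(keep)) x[idx[k]] <- x[idx[k]] + amp[k]
  }
  v <- as.numeric(stats::filter(x, gamma, method = "recursive"))
  if (noise_sd > 0) v <- v + stats::rnorm(n_frames, 0, noise_sd)
  v
}

#' Simulate a synthetic injection session with known ground truth
#'
#' @param params A `synth_session_params` object.
#' @param windows A `phase_windows` object; events span the whole recording
#'   from the start of the earliest window to the end of the latest, with
#'   rate multipliers active only inside the postinjection windows.
#' @param make_traces If `TRUE` also synthesize fluorescence traces (set
#'   `FALSE` for large event-only simulations).
#' @return A list with `events` (named list of `event_train`), `traces`
#'   (named list of `fluor_trace` or `NULL`), and `truth` (data frame with
#'   `neuron_id`, `true_class`, `baseline_rate`, `multiplier`).
#' @export
simulate_injection_session <- function(params,
                                       windows = phase_windows(),
                                       make_traces = TRUE) {
  stopifnot(inherits(params, "synth_session_params"),
            inherits(windows, "phase_windows"))
  cls <- assign_classes(params$n_neurons, params$frac_excited,
                        params$frac_inhibited)
  ids <- sprintf("n%04d", seq_len(params$n_neurons))
  mult <- ifelse(cls == "excited", params$multiplier_excited,
                 ifelse(cls == "inhibited", params$multiplier_inhibited, 1))

  # contiguous segmentation of the session span; post windows carry the
  # multiplier, baseline elsewhere (gaps included)
  w <- windows[order(vapply(windows, `[`, numeric(1), 1))]
  span <- c(w[[1]][1], w[[length(w)]][2])
  post_names <- setdiff(names(w), "pre")
  bounds <- sort(unique(c(span, unlist(w, use.names = FALSE))))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  in_post <- vapply(seq_along(seg_start), function(i) {
    any(vapply(post_names, function(nm)
      seg_start[i] >= w[[nm]][1] && seg_end[i] <= w[[nm]][2], logical(1)))
  }, logical(1))

  events <- vector("list", params$n_neurons)
  traces <- if (make_traces) vector("list", params$n_neurons) else NULL
  base_rate <- numeric(params$n_neurons)
  for (i in seq_len(params$n_neurons)) {
    with_seed(substream_seed(params$seed, paste0("spk:", ids[i])), {
      r0 <- if (params$rate_sdlog > 0)
        stats::rlnorm(1, log(params$baseline_rate), params$rate_sdlog)
      else params$baseline_rate
      base_rate[i] <- r0
      rates <- ifelse(in_post, r0 * mult[i], r0)
      tms <- rsegmented_events(seg_start, seg_end, rates)
      events[[i]] <- event_train(ids[i], tms, span)
      if (make_traces)
        traces[[i]] <- fluor_trace(
          ids[i],
          events_to_trace_values(tms, span, params$kernel_decay_tau,
                                 params$sampling_rate, params$noise_sd),
          sampling_rate = params$sampling_rate, start_time = span[1])
    })
  }
  names(events) <- ids
  if (make_traces) names(traces) <- ids
  list(events = events, traces = traces,
       truth = data.frame(neuron_id = ids, true_class = cls,
                          baseline_rate = base_rate, multiplier = mult,
                          stringsAsFactors = FALSE))
}

#' Synthesize a fluorescence trace from known event times
#'
#' Unit events are convolved with the exponential kernel `exp(-t/tau)`
#' (sampled on the frame grid via an AR(1) recursive filter) and Gaussian
#' noise is added. With `noise_sd = 0` and an event on a frame boundary the
#' trace is exactly the shifted kernel.
#'
#' @param neuron_id Identifier for the resulting trace.
#' @param times Event times in seconds.
#' @param span Half-open session span `c(t0, t1)`.
#' @param tau Kernel decay constant, seconds.
#' @param sampling_rate Hz.
#' @param noise_sd Additive Gaussian noise SD (uses the caller's RNG
#'   stream).
#' @return A `fluor_trace`.
#' @export
synthesize_trace <- function(neuron_id, times, span, tau = 1.0,
                             sampling_rate = 10, noise_sd = 0) {
  check_window(span, "span")
  fluor_trace(neuron_id,
              events_to_trace_values(sort(as.numeric(times)), span, tau,
                                     sampling_rate, noise_sd),
              sampling_rate = sampling_rate, start_time = span[1])
}

#' Parameters for a synthetic CPP session
#'
#' The animal alternates between the saline- and cocaine-paired chambers
#' with shifted-exponential dwell times (floor `min_dwell_floor`, mean
#' `mean_dwell`), so episodes both above and below the 5-s analysis
#' threshold occur. Each neuron fires at its baseline rate in the saline
#' chamber; chamber-excited / chamber-inhibited neurons scale their rate in
#' the cocaine chamber by the corresponding multiplier. The behavior and
#' spike random streams are split from one seed so the trajectory does not
#' depend on `n_neurons`.
#'
#' @param n_neurons Number of neurons.
#' @param baseline_rate Median baseline rate, events/min.
#' @param rate_sdlog Log-scale SD of per-neuron baseline rates.
#' @param frac_chamber_excited,frac_chamber_inhibited Fractions of neurons
#'   whose cocaine-chamber rate is scaled up / down.
#' @param multiplier_excited Cocaine-chamber rate multiplier (>= 1) for
#'   chamber-excited neurons.
#' @param multiplier_inhibited Cocaine-chamber multiplier in (0, 1].
#' @param session_length Session duration, seconds.
#' @param mean_dwell Mean chamber dwell time, seconds.
#' @param min_dwell_floor Minimum dwell time, seconds (must be below
#'   `mean_dwell`).
#' @param kernel_decay_tau,noise_sd,sampling_rate Trace synthesis settings
#'   as in [synth_session_params()].
#' @param seed Master seed.
#' @return A validated list of class `synth_cpp_params`.
#' @export
synth_cpp_params <- function(n_neurons = 100, baseline_rate = 4,
                             rate_sdlog = 0.5,
                             frac_chamber_excited = 0.05,
                             frac_chamber_inhibited = 0.17,
                             multiplier_excited = 2.5,
                             multiplier_inhibited = 0.3,
                             session_length = 900, mean_dwell = 20,
                             min_dwell_floor = 2,
                             kernel_decay_tau = 1.0, noise_sd = 0.2,
                             sampling_rate = 10, seed = 1L) {
  p <- list(n_neurons = as.integer(n_neurons), baseline_rate = baseline_rate,
            rate_sdlog = rate_sdlog,
            frac_chamber_excited = frac_chamber_excited,
            frac_chamber_inhibited = frac_chamber_inhibited,
            multiplier_excited = multiplier_excited,
            multiplier_inhibited = multiplier_inhibited,
            session_length = session_length, mean_dwell = mean_dwell,
            min_dwell_floor = min_dwell_floor,
            kernel_decay_tau = kernel_decay_tau, noise_sd = noise_sd,
            sampling_rate = sampling_rate, seed = as.integer(seed))
  if (p$n_neurons < 1) stop("n_neurons must be >= 1", call. = FALSE)
  if (p$baseline_rate <= 0) stop("baseline_rate must be positive", call. = FALSE)
  if (p$frac_chamber_excited < 0 || p$frac_chamber_inhibited < 0 ||
      p$frac_chamber_excited + p$frac_chamber_inhibited > 1)
    stop("chamber fractions must lie in [0, 1] and sum to <= 1", call. = FALSE)
  if (p$multiplier_excited < 1) stop("multiplier_excited must be >= 1", call. = FALSE)
  if (p$multiplier_inhibited <= 0 || p$multiplier_inhibited > 1)
    stop("multiplier_inhibited must be in (0, 1]", call. = FALSE)
  if (p$min_dwell_floor <= 0 || p$mean_dwell <= p$min_dwell_floor)
    stop("need 0 < min_dwell_floor < mean_dwell", call. = FALSE)
  if (p$session_length < 2 * p$min_dwell_floor)
    stop("session_length too short for two dwell episodes", call. = FALSE)
  structure(p, class = "synth_cpp_params")
}

#' Simulate a synthetic CPP session with known ground truth
#'
#' @param params A `synth_cpp_params` object.
#' @param make_traces If `TRUE` also synthesize fluorescence traces.
#' @return A list with `track` (an `occupancy_track` sampled at
#'   `sampling_rate`), `events`, `traces`, `truth` (as in
#'   [simulate_injection_session()], classes relative to the cocaine
#'   chamber), and `episodes_true` (the generating dwell segments).
#' @export
simulate_cpp_session <- function(params, make_traces = FALSE) {
  stopifnot(inherits(params, "synth_cpp_params"))
  fs <- params$sampling_rate

  # behavior stream: alternating dwells, shifted-exponential durations
  beh <- with_seed(substream_seed(params$seed, "behavior"), {
    first <- sample(c("saline", "cocaine"), 1)
    starts <- numeric(0); durs <- numeric(0)
    t <- 0
    while (t < params$session_length) {
      d <- params$min_dwell_floor +
        stats::rexp(1, 1 / (params$mean_dwell - params$min_dwell_floor))
      starts <- c(starts, t); durs <- c(durs, d)
      t <- t + d
    }
    durs[length(durs)] <- params$session_length - starts[length(durs)]
    ch <- rep(c(first, setdiff(c("saline", "cocaine"), first)),
              length.out = length(starts))
    data.frame(chamber = ch, start_s = starts, end_s = starts + durs,
               stringsAsFactors = FALSE)
  })
  if (nrow(beh) < 2)
    stop("session_length too short for two dwell episodes", call. = FALSE)

  tt <- seq(0, params$session_length - 1 / fs, by = 1 / fs)
  seg_of <- findInterval(tt, beh$start_s)
  track <- occupancy_track(tt, beh$chamber[seg_of])

  cls <- assign_classes(params$n_neurons, params$frac_chamber_excited,
                        params$frac_chamber_inhibited)
  ids <- sprintf("n%04d", seq_len(params$n_neurons))
  mult <- ifelse(cls == "excited", params$multiplier_excited,
                 ifelse(cls == "inhibited", params$multiplier_inhibited, 1))
  span <- c(0, params$session_length)
  is_coc <- beh$chamber == "cocaine"

  events <- vector("list", params$n_neurons)
  traces <- if (make_traces) vector("list", params$n_neurons) else NULL
  base_rate <- numeric(params$n_neurons)
  for (i in seq_len(params$n_neurons)) {
    with_seed(substream_seed(params$seed, paste0("spk:", ids[i])), {
      r0 <- if (params$rate_sdlog > 0)
        stats::rlnorm(1, log(params$baseline_rate), params$rate_sdlog)
      else params$baseline_rate
      base_rate[i] <- r0
      rates <- ifelse(is_coc, r0 * mult[i], r0)
      tms <- rsegmented_events(beh$start_s, beh$end_s, rates)
      events[[i]] <- event_train(ids[i], tms, span)
      if (make_traces)
        traces[[i]] <- fluor_trace(
          ids[i],
          events_to_trace_values(tms, span, params$kernel_decay_tau, fs,
                                 params$noise_sd),
          sampling_rate = fs, start_time = 0)
    })
  }
  names(events) <- ids
  if (make_traces) names(traces) <- ids
  list(track = track, events = events, traces = traces,
       truth = data.frame(neuron_id = ids, true_class = cls,
                          baseline_rate = base_rate, multiplier = mult,
                          stringsAsFactors = FALSE),
       episodes_true = beh)
}
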