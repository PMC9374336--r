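#' Permutation-test configuration for injection responses
#'
#' Settings for the intertransient-interval shuffling null: number of
#' shuffles, the percentile thresholds of the shuffled transient-change
#' distribution, and the smallest combined event count that is considered
#' classifiable (at least two intervals are needed to permute).
#'
#' @param n_permutations Number of shuffled replicates (default 10000).
#' @param lower_percentile,upper_percentile Percentiles of the shuffled
#'   change distribution used as inhibited/excited thresholds (1 and 99).
#' @param seed Seed for the shuffles.
#' @param min_events Minimum combined event count across the two windows;
#'   neurons below it are labeled nonresponsive.
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 10000, lower_percentile = 1,
                               upper_percentile = 99, seed = 1L,
                               min_events = 3) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (!(lower_percentile > 0 && lower_percentile < upper_percentile &&
        upper_percentile < 100))
    stop("need 0 < lower_percentile < upper_percentile < 100", call. = FALSE)
  if (min_events < 3)
    stop("min_events must be >= 3 (two intervals to permute)", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations),
                 lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 seed = as.integer(seed), min_events = as.integer(min_events)),
            class = "permutation_config")
}

#' Trace-comparison configuration
#'
#' @param n_bins Number of bins per window (default ten 1-min bins).
#' @param bin_length Bin length in seconds; `n_bins * bin_length` must equal
#'   the window duration.
#' @param alpha Two-sided significance level for the signed-rank test.
#' @return A list of class `trace_test_config`.
#' @export
trace_test_config <- function(n_bins = 10, bin_length = 60, alpha = 0.05) {
  if (n_bins < 2 || bin_length <= 0 || alpha <= 0 || alpha >= 1)
    stop("invalid trace test configuration", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), bin_length = bin_length,
                 alpha = alpha),
            class = "trace_test_config")
}

#' Actual transient change between two equal windows
#'
#' Signed difference in event counts: post-window count minus pre-window
#' count.
#'
#' @param train An `event_train`.
#' @param pre,post Half-open windows `c(a, b)` of equal duration.
#' @return Integer count difference.
#' @export
actual_transient_change <- function(train, pre, post) {
  check_window(pre, "pre"); check_window(post, "post")
  if (abs(diff(pre) - diff(post)) > 1e-9)
    stop("pre and post windows must have equal duration", call. = FALSE)
  count_events(train, post) - count_events(train, pre)
}

# map events of the two windows onto one concatenated pseudo-timeline.  The
# chronologically earlier window always comes first, so the timeline (and
# hence the shuffles under a fixed seed) is invariant under swapping the
# pre/post roles — which makes the classifier exactly antisymmetric.  For
# the non-contiguous decay comparison this abuts the windows, preserving
# the interval structure within each.  `post_second` records where the
# post window sits.
combined_timeline <- function(train, pre, post) {
  post_second <- post[1] >= pre[1]
  w1 <- if (post_second) pre else post
  w2 <- if (post_second) post else pre
  d1 <- diff(w1)
  t1 <- train$times[train$times >= w1[1] & train$times < w1[2]] - w1[1]
  t2 <- train$times[train$times >= w2[1] & train$times < w2[2]] - w2[1] + d1
  list(times = sort(c(t1, t2)), boundary = d1, total = d1 + diff(w2),
       post_second = post_second)
}

#' Shuffled transient-change distribution
#'
#' Builds the permutation null for one neuron: events of both windows are
#' placed on a concatenated pseudo-timeline, their intertransient intervals
#' are permuted uniformly at random, event times are rebuilt starting from
#' the first original event's offset, and the post-minus-pre count change
#' is recorded per replicate. Events reconstructed past the timeline end
#' (possible only through floating-point rounding) are dropped.
#'
#' @param train An `event_train`.
#' @param pre,post Equal-duration half-open windows.
#' @param cfg A `permutation_config`.
#' @return Integer vector of `n_permutations` shuffled changes, or `NULL`
#'   when the combined event count is below `cfg$min_events`
#'   (nonclassifiable, distinct from an error).
#' @export
shuffled_change_distribution <- function(train, pre, post,
                                         cfg = permutation_config()) {
  stopifnot(inherits(cfg, "permutation_config"))
  check_window(pre, "pre"); check_window(post, "post")
  if (abs(diff(pre) - diff(post)) > 1e-9)
    stop("pre and post windows must have equal duration", call. = FALSE)
  tl <- combined_timeline(train, pre, post)
  n <- length(tl$times)
  if (n < cfg$min_events) return(NULL)
  d <- diff(tl$times)
  t1 <- tl$times[1]
  sgn <- if (tl$post_second) 1L else -1L
  with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(b) {
      tms <- t1 + cumsum(c(0, sample(d)))
      tms <- tms[tms < tl$total]
      sgn * as.integer(sum(tms >= tl$boundary) - sum(tms < tl$boundary))
    }, integer(1))
  })
}

#' Classify one neuron by the interval-shuffling permutation test
#'
#' The neuron is injection-excited when its actual transient change exceeds
#' the upper percentile of the shuffled change distribution, injection-
#' inhibited when it falls below the lower percentile (strict inequalities,
#' linear-interpolation percentiles), and nonresponsive otherwise. Neurons
#' with fewer than `cfg$min_events` combined events are nonresponsive by
#' definition.
#'
#' @inheritParams shuffled_change_distribution
#' @return One-row data frame: `neuron_id`, `label`, `statistic` (the
#'   actual change), `null_low`, `null_high`, `p_value` (`NA` for this
#'   method), `method`.
#' @export
classify_by_transients <- function(train, pre, post,
                                   cfg = permutation_config()) {
  delta <- actual_transient_change(train, pre, post)
  dist <- shuffled_change_distribution(train, pre, post, cfg)
  if (is.null(dist)) {
    return(data.frame(neuron_id = train$neuron_id, label = "nonresponsive",
                      statistic = delta, null_low = NA_real_,
                      null_high = NA_real_, p_value = NA_real_,
                      method = "transients", stringsAsFactors = FALSE))
  }
  q <- stats::quantile(dist, c(cfg$lower_percentile, cfg$upper_percentile) / 100,
                       names = FALSE, type = 7)
  label <- if (delta > q[2]) "excited" else if (delta < q[1]) "inhibited"
           else "nonresponsive"
  data.frame(neuron_id = train$neuron_id, label = label, statistic = delta,
             null_low = q[1], null_high = q[2], p_value = NA_real_,
             method = "transients", stringsAsFactors = FALSE)
}

# mean of trace values inside consecutive bins of a window
window_bin_means <- function(trace, window, n_bins, bin_length) {
  tt <- trace_times(trace)
  vapply(seq_len(n_bins), function(j) {
    a <- window[1] + (j - 1) * bin_length
    sel <- tt >= a & tt < a + bin_length
    if (!any(sel)) stop("trace does not cover the comparison windows",
                        call. = FALSE)
    mean(trace$values[sel])
  }, numeric(1))
}

#' Classify one neuron by binned z-scored trace comparison
#'
#' The trace segments of the two windows are z-scored (jointly by default),
#' averaged into `n_bins` bins per window, and compared with the exact
#' two-sided Wilcoxon signed-rank test. `p < alpha` with a positive mean
#' paired difference (post minus pre) gives "excited", negative gives
#' "inhibited"; otherwise (or when all paired differences are zero)
#' "nonresponsive".
#'
#' @param trace A `fluor_trace` covering both windows.
#' @param pre,post Equal-duration half-open windows.
#' @param cfg A `trace_test_config` with `n_bins * bin_length` equal to the
#'   window duration.
#' @param zscore `"joint"` (one mean/SD across the concatenated pre+post
#'   segment; default) or `"per_window"` (each window standardized
#'   separately — kept as an option because it forces both window means to
#'   zero and weakens the test).
#' @return One-row data frame as in [classify_by_transients()], with
#'   `statistic` the signed-rank p-value carrier: `p_value` holds the test
#'   p-value and `statistic` the mean paired bin difference.
#' @export
classify_by_traces <- function(trace, pre, post, cfg = trace_test_config(),
                               zscore = c("joint", "per_window")) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(cfg, "trace_test_config"))
  zscore <- match.arg(zscore)
  check_window(pre, "pre"); check_window(post, "post")
  if (abs(diff(pre) - diff(post)) > 1e-9)
    stop("pre and post windows must have equal duration", call. = FALSE)
  if (abs(cfg$n_bins * cfg$bin_length - diff(pre)) > 1e-9)
    stop("n_bins * bin_length must equal the window duration", call. = FALSE)

  tt <- trace_times(trace)
  sel_pre <- tt >= pre[1] & tt < pre[2]
  sel_post <- tt >= post[1] & tt < post[2]
  if (!any(sel_pre) || !any(sel_post))
    stop("trace does not cover the comparison windows", call. = FALSE)
  z <- trace
  if (zscore == "joint") {
    seg <- c(trace$values[sel_pre], trace$values[sel_post])
    mu <- mean(seg); sdev <- sqrt(mean((seg - mu)^2))
    if (sdev == 0)
      stop("degenerate input: zero variance across comparison windows",
           call. = FALSE)
    z$values <- (trace$values - mu) / sdev
  } else {
    z$values <- trace$values
    for (sel in list(sel_pre, sel_post)) {
      seg <- trace$values[sel]
      mu <- mean(seg); sdev <- sqrt(mean((seg - mu)^2))
      if (sdev == 0)
        stop("degenerate input: zero variance in a comparison window",
             call. = FALSE)
      z$values[sel] <- (seg - mu) / sdev
    }
  }
  pre_bins <- window_bin_means(z, pre, cfg$n_bins, cfg$bin_length)
  post_bins <- window_bin_means(z, post, cfg$n_bins, cfg$bin_length)
  ts <- signed_rank_test(post_bins, pre_bins)
  md <- mean(post_bins - pre_bins)
  label <- if (is.na(ts$p_value) || ts$p_value >= cfg$alpha) "nonresponsive"
           else if (md > 0) "excited" else if (md < 0) "inhibited"
           else "nonresponsive"
  data.frame(neuron_id = trace$neuron_id, label = label, statistic = md,
             null_low = NA_real_, null_high = NA_real_,
             p_value = ts$p_value, method = "traces",
             stringsAsFactors = FALSE)
}

#' Classify a population of neurons against an injection
#'
#' Driver over a list of event trains (permutation method) or traces
#' (signed-rank method). For the permutation method the master seed is
#' expanded into one substream per neuron id, so results do not depend on
#' iteration order.
#'
#' @param x Named list of `event_train` (method `"transients"`) or
#'   `fluor_trace` (method `"traces"`).
#' @param pre,post Equal-duration comparison windows.
#' @param cfg A `permutation_config` or `trace_test_config` matching the
#'   method.
#' @param method `"transients"` or `"traces"`.
#' @return Data frame with one classification row per neuron.
#' @export
classify_population <- function(x, pre, post, cfg,
                                method = c("transients", "traces")) {
  method <- match.arg(method)
  if (!length(x)) stop("empty population", call. = FALSE)
  rows <- lapply(x, function(xi) {
    if (method == "transients") {
      cfg_i <- cfg
      cfg_i$seed <- substream_seed(cfg$seed, paste0("perm:", xi$neuron_id))
      classify_by_transients(xi, pre, post, cfg_i)
    } else {
      classify_by_traces(xi, pre, post, cfg)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population summary: responsive fractions and fold change
#'
#' @param results Classification data frame (needs a `label` column), or a
#'   character vector of labels.
#' @return List with counts, percentages (one decimal, as conventionally
#'   printed), and the inhibited/excited fold change (one decimal; `NA`
#'   when no neuron is excited).
#' @export
summarize_population <- function(results) {
  labels <- if (is.data.frame(results)) results$label else as.character(results)
  if (!length(labels)) stop("empty classification set", call. = FALSE)
  n <- length(labels)
  ne <- sum(labels == "excited")
  ni <- sum(labels == "inhibited")
  list(n_total = n, n_excited = ne, n_inhibited = ni,
       n_nonresponsive = n - ne - ni,
       pct_excited = round(100 * ne / n, 1),
       pct_inhibited = round(100 * ni / n, 1),
       pct_nonresponsive = round(100 * (n - ne - ni) / n, 1),
       fold_inhibited_over_excited = if (ne > 0) round(ni / ne, 1) else NA_real_)
}

#' Phase-overlap (persistence) analysis
#'
#' For each response direction, the count and percentage of neurons labeled
#' in the initial phase that carry the same label in the decay phase.
#'
#' @param initial,decay Classification data frames over the same neuron ids.
#' @return Data frame with `direction`, `n_initial`, `n_persistent`,
#'   `pct_persistent` (one decimal); directions with no initially labeled
#'   neuron are omitted, so two empty inputs give an empty table.
#' @export
overlap_analysis <- function(initial, decay) {
  if (!setequal(initial$neuron_id, decay$neuron_id) ||
      nrow(initial) != nrow(decay))
    stop("initial and decay results must cover the same neurons", call. = FALSE)
  dec <- decay$label[match(initial$neuron_id, decay$neuron_id)]
  rows <- lapply(c("excited", "inhibited"), function(dir) {
    sel <- initial$label == dir
    n0 <- sum(sel)
    if (n0 == 0) return(NULL)
    np <- sum(dec[sel] == dir)
    data.frame(direction = dir, n_initial = n0, n_persistent = np,
               pct_persistent = round(100 * np / n0, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(direction = character(0), n_initial = integer(0),
                      n_persistent = integer(0), pct_persistent = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

#' Per-group transient frequency before and after injection
#'
#' Mean and standard error of per-neuron transient frequency in each window,
#' grouped by classification label.
#'
#' @param trains Named list of `event_train`.
#' @param labels Classification data frame (`neuron_id`, `label`).
#' @param pre,post Comparison windows.
#' @return Data frame with `group`, `window`, `n`, `mean_freq`, `sem_freq`
#'   (events/min). Labels with no neurons are omitted with a warning.
#' @export
group_frequency_change <- function(trains, labels, pre, post) {
  ids <- vapply(trains, `[[`, character(1), "neuron_id")
  lab <- labels$label[match(ids, labels$neuron_id)]
  if (anyNA(lab)) stop("labels missing for some neurons", call. = FALSE)
  groups <- c("excited", "inhibited", "nonresponsive")
  missing <- setdiff(groups, unique(lab))
  if (length(missing))
    warning("empty group(s) omitted: ", paste(missing, collapse = ", "),
            call. = FALSE)
  rows <- lapply(intersect(groups, unique(lab)), function(gr) {
    tr <- trains[lab == gr]
    out <- lapply(c("pre", "post"), function(wn) {
      w <- if (wn == "pre") pre else post
      f <- vapply(tr, transient_frequency, numeric(1), window = w)
      data.frame(group = gr, window = wn, n = length(f), mean_freq = mean(f),
                 sem_freq = if (length(f) > 1) stats::sd(f) / sqrt(length(f))
                            else 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
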