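pre10 <- c(-600, 0)
post10 <- c(0, 600)

test_that("actual transient change is a signed count difference", {
  tr <- event_train("a", c(seq(-550, -150, by = 100), seq(50, 450, by = 100)),
                    span = c(-600, 600))
  expect_equal(actual_transient_change(tr, pre10, post10), 0)
  tr2 <- event_train("b", c(-500, -100, seq(10, 590, length.out = 9)),
                     span = c(-600, 600))
  expect_equal(actual_transient_change(tr2, pre10, post10), 7)
  expect_equal(actual_transient_change(tr2, post10, pre10), -7)
  expect_error(actual_transient_change(tr2, c(-600, 0), c(0, 300)),
               "equal duration")
})

test_that("a periodic train yields a degenerate permutation null", {
  tr <- event_train("p", seq(-570, 570, by = 60), span = c(-600, 600))
  cfg <- permutation_config(n_permutations = 200, seed = 8)
  dist <- shuffled_change_distribution(tr, pre10, post10, cfg)
  delta <- actual_transient_change(tr, pre10, post10)
  expect_true(all(dist == delta))
})

test_that("Monte-Carlo shuffles match exhaustive interval enumeration", {
  set.seed(9)
  for (n_ev in 4:6) {
    times <- sort(runif(n_ev, -600, 600))
    tr <- event_train("e", times, span = c(-600, 600))
    cfg <- permutation_config(n_permutations = 10000, seed = 100 + n_ev)
    mc <- shuffled_change_distribution(tr, pre10, post10, cfg)
    tl_times <- c(times[times < 0] + 600, times[times >= 0] + 600)
    exact <- enumerate_shuffled_changes(tl_times, boundary = 600, total = 1200)
    expect_lt(tv_distance(mc, exact), 0.02)
  }
})

test_that("shuffling is deterministic given the seed and guards min_events", {
  tr <- event_train("d", c(-300, -100, 50, 200, 400), span = c(-600, 600))
  cfg <- permutation_config(n_permutations = 300, seed = 77)
  expect_identical(shuffled_change_distribution(tr, pre10, post10, cfg),
                   shuffled_change_distribution(tr, pre10, post10, cfg))
  sparse <- event_train("s", c(-300, 100), span = c(-600, 600))
  expect_null(shuffled_change_distribution(sparse, pre10, post10, cfg))
  res <- classify_by_transients(sparse, pre10, post10, cfg)
  expect_equal(res$label, "nonresponsive")
})

test_that("a strongly suppressed neuron is classified inhibited", {
  # baseline 8/min, post multiplier 0.3: expected change ~ -56, far beyond
  # any permuted percentile of the combined train
  p <- synth_session_params(n_neurons = 1, baseline_rate = 8, rate_sdlog = 0,
                            frac_excited = 0, frac_inhibited = 1,
                            multiplier_inhibited = 0.3, seed = 13)
  s <- simulate_injection_session(p, phase_windows(decay = NULL),
                                  make_traces = FALSE)
  res <- classify_by_transients(s$events[[1]], pre10, post10,
                                permutation_config(n_permutations = 1000,
                                                   seed = 14))
  expect_equal(res$label, "inhibited")
  expect_lt(res$statistic, res$null_low)
})

test_that("swapping the compared windows maps excited to inhibited", {
  p <- synth_session_params(n_neurons = 20, baseline_rate = 6, rate_sdlog = 0,
                            frac_excited = 0.5, frac_inhibited = 0.5,
                            seed = 15)
  s <- simulate_injection_session(p, phase_windows(decay = NULL),
                                  make_traces = FALSE)
  cfg <- permutation_config(n_permutations = 500, seed = 16)
  fwd <- classify_population(s$events, pre10, post10, cfg)
  rev <- classify_population(s$events, post10, pre10, cfg)
  swap <- c(excited = "inhibited", inhibited = "excited",
            nonresponsive = "nonresponsive")
  expect_equal(unname(swap[fwd$label]), rev$label)
})

test_that("binned trace comparison classifies direction and degenerates", {
  # flat pre, elevated post: exact signed-rank p = 2/1024 < 0.05
  set.seed(17)
  vals <- c(rnorm(6000, 0, 0.1), rnorm(6000, 1, 0.1))
  tr <- fluor_trace("t", vals, sampling_rate = 10, start_time = -600)
  res <- classify_by_traces(tr, pre10, post10)
  expect_equal(res$label, "excited")
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)

  vals_inh <- c(rnorm(6000, 1, 0.1), rnorm(6000, 0, 0.1))
  tr_inh <- fluor_trace("t2", vals_inh, sampling_rate = 10, start_time = -600)
  expect_equal(classify_by_traces(tr_inh, pre10, post10)$label, "inhibited")

  # identical pre and post segments: all paired differences zero
  seg <- rnorm(6000, 0, 0.5)
  tr_eq <- fluor_trace("t3", c(seg, seg), sampling_rate = 10,
                       start_time = -600)
  expect_equal(classify_by_traces(tr_eq, pre10, post10)$label, "nonresponsive")

  expect_error(classify_by_traces(
    fluor_trace("t4", rep(1, 12000), sampling_rate = 10, start_time = -600),
    pre10, post10), "zero variance")
  expect_error(classify_by_traces(tr, pre10, post10,
                                  cfg = trace_test_config(n_bins = 7)),
               "window duration")
})

test_that("population summaries reproduce worked-example arithmetic", {
  s <- summarize_population(rep(c("excited", "inhibited", "nonresponsive"),
                                c(49, 117, 190)))
  expect_equal(s$pct_excited, 13.8)
  expect_equal(s$pct_inhibited, 32.9)
  expect_equal(s$fold_inhibited_over_excited, 2.4)
  s0 <- summarize_population(rep("nonresponsive", 10))
  expect_equal(s0$pct_excited, 0)
  expect_true(is.na(s0$fold_inhibited_over_excited))
  expect_error(summarize_population(character(0)), "empty")
})

test_that("overlap analysis counts persisting labels per direction", {
  ids <- sprintf("n%03d", 1:200)
  ini <- data.frame(neuron_id = ids,
                    label = rep(c("excited", "inhibited", "nonresponsive"),
                                c(49, 117, 34)))
  dec <- data.frame(neuron_id = ids,
                    label = c(rep("excited", 29), rep("nonresponsive", 20),
                              rep("inhibited", 30), rep("nonresponsive", 121)))
  ov <- overlap_analysis(ini, dec)
  expect_equal(ov$pct_persistent[ov$direction == "excited"], 59.2)
  expect_equal(ov$pct_persistent[ov$direction == "inhibited"], 25.6)

  none <- data.frame(neuron_id = ids, label = "nonresponsive")
  expect_equal(nrow(overlap_analysis(none, dec)), 0)
  expect_error(overlap_analysis(ini[1:10, ], dec), "same neurons")
})

test_that("group frequency change reports per-group means and sems", {
  tr1 <- event_train("a", c(seq(-590, -10, length.out = 12),
                            seq(10, 590, length.out = 6)),
                     span = c(-600, 600))
  labels <- data.frame(neuron_id = "a", label = "inhibited")
  expect_warning(gf <- group_frequency_change(list(tr1), labels, pre10, post10),
                 "omitted")
  expect_equal(gf$mean_freq[gf$window == "pre"], 1.2)
  expect_equal(gf$mean_freq[gf$window == "post"], 0.6)
  expect_equal(gf$sem_freq, c(0, 0))
})
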