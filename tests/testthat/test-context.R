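# 10 Hz track built from dwell segments
track_from_segments <- function(durations, chambers, fs = 10) {
  start <- cumsum(c(0, durations[-length(durations)]))
  tt <- seq(0, sum(durations) - 1 / fs, by = 1 / fs)
  occupancy_track(tt, chambers[findInterval(tt, start)])
}

test_that("episode extraction applies the strict 5-s dwell rule", {
  tk <- track_from_segments(rep(10, 10), rep(c("saline", "cocaine"), 5))
  ep <- extract_episodes(tk)
  expect_equal(nrow(ep), 10)
  expect_equal(sum(ep$chamber == "saline"), 5)
  expect_equal(sum(ep$chamber == "cocaine"), 5)
  expect_equal(unique(ep$duration_s), 10)

  # a 4-s visit between two long stays is dropped (4 <= 5)
  tk2 <- track_from_segments(c(30, 4, 30), c("saline", "cocaine", "saline"))
  ep2 <- extract_episodes(tk2)
  expect_equal(ep2$chamber, c("saline", "saline"))

  # single-chamber track
  tk3 <- track_from_segments(60, "cocaine")
  ep3 <- extract_episodes(tk3)
  expect_equal(ep3$chamber, "cocaine")

  bad <- occupancy_track(0:5, rep("lobby", 6))
  expect_error(extract_episodes(bad), "unknown chamber")
})

test_that("episode frequencies divide event counts by staying time", {
  tk <- track_from_segments(c(30, 30), c("cocaine", "saline"))
  ep <- extract_episodes(tk)
  tr <- event_train("a", c(5, 15, 25), span = c(0, 60))
  ef <- episode_frequencies(tr, ep)
  expect_equal(ef$freq_per_min, c(6, 0))
  empty <- episode_frequencies(tr, ep[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("CACE classification follows the exact U test and its guards", {
  segs <- rep(20, 8)
  tk <- track_from_segments(segs, rep(c("saline", "cocaine"), 4))
  ep <- extract_episodes(tk)
  # saline episodes empty; cocaine episodes hold 2,3,4,5 events
  coc_starts <- ep$start_s[ep$chamber == "cocaine"]
  times <- unlist(lapply(seq_along(coc_starts), function(i)
    coc_starts[i] + seq(2, 18, length.out = i + 1)))
  tr <- event_train("c", times, span = c(0, 160))
  res <- classify_cace(tr, ep, episode_config(min_episodes_per_chamber = 4))
  expect_equal(res$label, "excited")
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)

  # identical activity in both chambers: nonresponsive
  tr_null <- event_train("n", seq(1, 159, by = 2), span = c(0, 160))
  expect_equal(classify_cace(tr_null, ep)$label, "nonresponsive")

  # too few episodes: nonclassifiable, distinct from nonresponsive
  short <- extract_episodes(track_from_segments(c(20, 20),
                                                c("saline", "cocaine")))
  expect_equal(classify_cace(tr_null, short)$label, "nonclassifiable")
})

test_that("relabeling the chambers swaps CACE directions", {
  p <- synth_cpp_params(n_neurons = 30, frac_chamber_excited = 0.3,
                        frac_chamber_inhibited = 0.3, seed = 23)
  s <- simulate_cpp_session(p)
  res <- classify_cace_population(s$events, s$track)
  flip <- s$track
  flip$chamber <- ifelse(flip$chamber == "saline", "cocaine", "saline")
  res_f <- classify_cace_population(s$events, flip)
  swap <- c(excited = "inhibited", inhibited = "excited",
            nonresponsive = "nonresponsive",
            nonclassifiable = "nonclassifiable")
  expect_equal(unname(swap[res$label]), res_f$label)
})

test_that("null CPP sessions keep the responsive fraction near alpha", {
  p <- synth_cpp_params(n_neurons = 200, frac_chamber_excited = 0,
                        frac_chamber_inhibited = 0, seed = 29)
  s <- simulate_cpp_session(p)
  res <- classify_cace_population(s$events, s$track)
  cls <- res[res$label != "nonclassifiable", ]
  frac <- mean(cls$label != "nonresponsive")
  expect_lte(frac, 2 * 0.05)
})

test_that("peri-entry alignment bins events and drops edge entries", {
  tk <- track_from_segments(c(30, 30, 30, 30),
                            c("saline", "cocaine", "saline", "cocaine"))
  # events 1 s after each cocaine entry (entries at 30 and 90)
  tr <- event_train("a", c(31, 91), span = c(0, 120))
  pm <- peri_entry_matrix(tr, tk, "cocaine")
  expect_equal(nrow(pm$counts), 2)
  expect_equal(pm$bin_left, -5:4)
  expect_equal(unname(colSums(pm$counts)), c(rep(0, 6), 2, rep(0, 3)))
  expect_equal(pm$post_rate, 12)  # one event per 5-s post window
  expect_equal(pm$pre_rate, 0)

  # an entry 2 s after session start is dropped
  tk2 <- track_from_segments(c(2, 30, 30), c("saline", "cocaine", "saline"))
  expect_warning(pm2 <- peri_entry_matrix(tr, tk2, "cocaine"), "no valid")
  expect_equal(nrow(pm2$counts), 0)
})

test_that("chamber-excited populations raise the post-entry rate", {
  p <- synth_cpp_params(n_neurons = 50, baseline_rate = 10, rate_sdlog = 0,
                        frac_chamber_excited = 1, frac_chamber_inhibited = 0,
                        multiplier_excited = 2, session_length = 900,
                        seed = 31)
  s <- simulate_cpp_session(p)
  peri <- peri_entry_summary(s$events, s$track, "cocaine")
  d <- peri$per_neuron$post_rate - peri$per_neuron$pre_rate
  expect_gt(mean(d), 0)
  expect_lt(stats::wilcox.test(d, exact = FALSE)$p.value, 0.05)
})

test_that("CPP scoring assigns the less-preferred chamber and excludes bias", {
  tkA <- track_from_segments(c(600, 300), c("saline", "cocaine"))
  tkB <- track_from_segments(c(400, 500), c("saline", "cocaine"))
  bs <- cpp_score(tkA, tkB)
  expect_equal(bs$cocaine_chamber, "cocaine")
  expect_equal(bs$pre_time_cocaine_s, 300)
  expect_equal(bs$cpp_score_s, 200)
  expect_false(bs$excluded)

  # balanced pre/post: score 0
  expect_equal(cpp_score(tkA, tkA)$cpp_score_s, 0)

  # 800/100 of 900: baseline preference 11% < 25%, excluded
  tkC <- track_from_segments(c(800, 100), c("saline", "cocaine"))
  expect_true(cpp_score(tkC, tkB)$excluded)
  expect_equal(cpp_score(tkC, tkB)$baseline_preference_fraction, 1 / 9,
               tolerance = 1e-12)

  # relabeling with an explicit cocaine chamber negates the score
  swapA <- tkA; swapA$chamber <- ifelse(tkA$chamber == "saline",
                                        "cocaine", "saline")
  swapB <- tkB; swapB$chamber <- ifelse(tkB$chamber == "saline",
                                        "cocaine", "saline")
  s1 <- cpp_score(tkA, tkB, cocaine_chamber = "cocaine")
  s2 <- cpp_score(swapA, swapB, cocaine_chamber = "cocaine")
  expect_equal(s2$cpp_score_s, -s1$cpp_score_s)
})

test_that("entry detection can require a minimum dwell on both sides", {
  tk <- track_from_segments(c(30, 2, 30, 30),
                            c("cocaine", "saline", "cocaine", "saline"))
  tr <- event_train("a", 50, span = c(0, 92))
  # transition at t = 32 follows a 2-s saline visit: dropped when a 5-s
  # dwell is required on both sides
  pm_all <- peri_entry_matrix(tr, tk, "cocaine")
  expect_equal(pm_all$entry_times, 32)
  expect_warning(
    pm_strict <- peri_entry_matrix(tr, tk, "cocaine", require_dwell = 5),
    "no valid")
  expect_length(pm_strict$entry_times, 0)
})
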