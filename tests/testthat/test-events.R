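test_that("z-scoring matches the direct population formula", {
  tr <- fluor_trace("a", c(1, 2, 3), sampling_rate = 1)
  z <- zscore_trace(tr)
  expect_equal(z$values, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  set.seed(1)
  tr2 <- fluor_trace("b", 5 + 2 * rnorm(5000))
  z2 <- zscore_trace(tr2)
  expect_lt(abs(mean(z2$values)), 0.05)
  expect_lt(abs(sqrt(mean(z2$values^2)) - 1), 1e-12)

  expect_error(zscore_trace(fluor_trace("c", rep(2, 100))), "zero variance")
})

test_that("z-scoring with a reference window uses that window's moments", {
  tr <- fluor_trace("a", c(0, 0, 2, 2, 10, 10), sampling_rate = 1)
  z <- zscore_trace(tr, reference_window = c(0, 4))  # first four samples
  expect_equal(mean(z$values[1:4]), 0)
  expect_equal(z$values[1:4], c(-1, -1, 1, 1))
})

test_that("deconvolution inverts single- and double-event kernels exactly", {
  prm <- deconv_params(gamma = 0.9)
  g <- 0.9
  y <- c(rep(0, 99), g^(0:100))  # unit event at frame 100
  d <- deconvolve_trace(y, prm)
  expect_equal(which(d$spikes > 1e-8), 100)
  expect_equal(d$spikes[100], 1, tolerance = 1e-10)
  expect_equal(d$fit, y, tolerance = 1e-10)

  # two well-separated events, amplitudes 1 and 0.7
  y2 <- numeric(50)
  y2[10:50] <- g^(0:40)
  y2[35:50] <- y2[35:50] + 0.7 * g^(0:15)
  d2 <- deconvolve_trace(y2, prm)
  expect_equal(which(d2$spikes > 1e-8), c(10, 35))
  expect_equal(d2$spikes[c(10, 35)], c(1, 0.7), tolerance = 1e-6)

  expect_equal(deconvolve_trace(numeric(20), prm)$spikes, numeric(20))
})

test_that("pool-adjacent-violators solution attains the brute-force optimum", {
  set.seed(7)
  # exhaustive active-set enumeration on tiny instances, with and without L1
  for (lam in c(0, 0.3)) {
    for (rep in 1:6) {
      n <- sample(10:12, 1)
      g <- runif(1, 0.6, 0.95)
      y <- as.numeric(stats::filter(rbinom(n, 1, 0.3) * runif(n, 0.5, 2),
                                    g, method = "recursive")) + rnorm(n, 0, 0.3)
      prm <- deconv_params(gamma = g, sparsity_penalty = lam)
      mine <- deconvolve_trace(y, prm)
      obj_mine <- deconv_objective(y, mine$spikes, g, lam)
      oracle <- brute_force_deconv_exhaustive(y, g, lam)
      expect_lte(obj_mine, oracle$obj + 1e-8)
      expect_gte(obj_mine, oracle$obj - 1e-8)
    }
  }
  # bound-constrained quasi-Newton reference on 50-frame instances
  for (rep in 1:4) {
    n <- 50
    g <- 0.9
    y <- as.numeric(stats::filter(rbinom(n, 1, 0.15) * runif(n, 0.5, 2),
                                  g, method = "recursive")) + rnorm(n, 0, 0.2)
    prm <- deconv_params(gamma = g)
    obj_mine <- deconv_objective(y, deconvolve_trace(y, prm)$spikes, g, 0)
    oracle <- brute_force_deconv_lbfgsb(y, g, 0)
    expect_lte(obj_mine, oracle$obj + 1e-8)
  }
})

test_that("event calling thresholds, merges, and handles empty activity", {
  tr <- fluor_trace("a", rnorm(100, 0, 0.1))
  ev0 <- detect_transients(numeric(100), tr)
  expect_length(ev0$times, 0)

  # two supra-threshold peaks one frame apart merge to the larger
  act <- numeric(100)
  act[c(50, 51)] <- c(2, 3)
  prm <- deconv_params(min_separation = 3)
  ev <- detect_transients(act, tr, prm, noise_sd = 0.1)
  expect_equal(ev$times, tr$start_time + 50 / 10)  # frame 51 kept

  # sub-threshold activity is ignored
  ev2 <- detect_transients(act * 0.01, tr, prm, noise_sd = 0.1)
  expect_length(ev2$times, 0)
})

test_that("detection is shift-equivariant and amplitude-invariant", {
  times <- c(5, 12, 20.5, 28)
  tr <- synthesize_trace("a", times, span = c(0, 40))
  ev <- detect_events(tr)
  shifted <- fluor_trace("a", tr$values, sampling_rate = 10, start_time = 100)
  ev_s <- detect_events(shifted)
  expect_equal(ev_s$times, ev$times + 100, tolerance = 1e-9)
  scaled <- fluor_trace("a", 7 * tr$values, sampling_rate = 10)
  expect_equal(detect_events(scaled)$times, ev$times, tolerance = 1e-9)
})

test_that("noiseless round-trip recovers nearly all well-separated events", {
  set.seed(5)
  missed <- 0L; total <- 0L
  for (rep in 1:20) {
    gaps <- runif(15, 3, 10)  # >= 3 tau apart (tau = 1 s)
    times <- 2 + cumsum(gaps)
    span <- c(0, max(times) + 10)
    tr <- synthesize_trace("r", times, span)
    det <- detect_events(tr)
    hits <- match_events(times, det$times, tol = 0.1 + 1e-9)
    total <- total + length(times)
    missed <- missed + (length(times) - hits)
  }
  expect_gte(1 - missed / total, 0.99)
})

test_that("window counting is half-open and converts units", {
  tr <- event_train("a", c(1, 2, 3), span = c(0, 10))
  expect_equal(count_events(tr, c(1, 3)), 2)
  expect_equal(count_events(tr, c(0, 1)), 0)
  tr2 <- event_train("b", seq(5, 115, by = 10), span = c(0, 120))
  expect_equal(transient_frequency(tr2, c(0, 120)), 6)
  empty <- event_train("c", numeric(0), span = c(0, 10))
  expect_equal(count_events(empty, c(0, 10)), 0)
  expect_equal(transient_frequency(empty, c(0, 10)), 0)
  expect_error(count_events(tr, c(3, 3)), "a < b")
})
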