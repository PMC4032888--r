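toy_raster <- function(times, ids, N, t_total, t_transient = 0) {
  structure(list(times = times, ids = as.integer(ids), n_neurons = N,
                 t_total = t_total, t_transient = t_transient,
                 config = list(), stsd = NULL), class = "spike_raster")
}

test_that("rate binning converts counts to Hz per neuron and conserves spikes", {
  r <- toy_raster(c(0.2, 0.5, 0.9), c(1, 2, 3), 3000, 10)
  rs <- bin_rates(r, 1, from = 0, to = 10)
  expect_equal(rs$rates[1], 1)              # 3 spikes / (3000 * 1 ms)
  expect_equal(sum(rs$counts), 3)
  # conservation on a random raster at several bin widths
  set.seed(3)
  rr <- toy_raster(sort(runif(5000, 0, 1000)), sample(50, 5000, TRUE), 50, 1000)
  for (bw in c(0.5, 1, 2, 7)) {
    rs <- bin_rates(rr, bw, from = 0, to = 1000)
    expect_equal(sum(rs$counts), sum(rr$times <= rs$bin_ms * length(rs$counts)))
  }
  # empty window: all-zero rates
  expect_true(all(bin_rates(toy_raster(numeric(0), integer(0), 10, 100),
                            from = 0, to = 100)$rates == 0))
  expect_error(bin_rates(r, 0), "bin_ms")
})

test_that("regime classification separates the three rate distributions", {
  n <- 2e4
  set.seed(9)
  # exponential: counts concentrated at zero (mean rate ~1 Hz at N=1000)
  exp_rates <- rate_series(rpois(n, 1), 1000)
  expect_identical(classify_regime(exp_rates)$label, "exponential")
  # gaussian: single high-rate mode at ~20 Hz
  gau_rates <- rate_series(pmax(0, round(rnorm(n, 20, 3))), 1000)
  expect_identical(classify_regime(gau_rates)$label, "gaussian")
  # bimodal: mixture of the two with a clear valley
  mix <- ifelse(runif(n) < 0.5, rpois(n, 1), pmax(0, round(rnorm(n, 20, 3))))
  lab <- classify_regime(rate_series(mix, 1000))
  expect_identical(lab$label, "bimodal")
  expect_true(lab$valley > 2 && lab$valley < 20)
  expect_error(classify_regime(rate_series(rpois(100, 1), 1000)), "bins")
})

test_that("avalanche detection concatenates strict super-threshold runs", {
  rs <- rate_series(c(0, 10, 20, 0, 8, 0), 1000)
  av <- detect_avalanches(rs, 7)
  expect_equal(nrow(av), 2)
  expect_equal(av$duration_ms, c(2, 1))
  expect_equal(av$size, c(30, 8))
  expect_equal(av$start_ms, c(1, 4))
  # a bin exactly at the threshold terminates (strict inequality)
  rs2 <- rate_series(c(10, 7, 10), 1000)
  expect_equal(nrow(detect_avalanches(rs2, 7)), 2)
  # nothing above threshold: empty result
  expect_equal(nrow(detect_avalanches(rate_series(rep(5, 10), 1000), 7)), 0)
  expect_error(detect_avalanches(rs, 0), "r_min")
})

test_that("avalanche detection and segmentation agree with naive oracles", {
  set.seed(11)
  for (k in 1:1000) {
    n <- sample(30:120, 1)
    counts <- rpois(n, lambda = sample(c(2, 6, 12), 1))
    rs <- rate_series(counts, n_neurons = 1000)
    av <- detect_avalanches(rs, 7)
    ref <- naive_avalanches(rs$rates, rs$counts, 1, 7)
    expect_equal(av, ref)
    if (nrow(av) >= 1) {
      win <- c(0, n)
      expect_equal(segment_up_down(av, 10, window = win),
                   naive_segments(av, 10, win))
    }
  }
})

test_that("waiting times are end-to-start gaps", {
  av <- data.frame(start_ms = c(5, 14, 100), duration_ms = c(5, 2, 3),
                   size = c(1, 1, 1))
  expect_equal(waiting_times(av), c(4, 84))
  rs <- rate_series(c(0, 10, 20, 0, 8, 0), 1000)
  expect_equal(waiting_times(detect_avalanches(rs, 7)), 1)
  expect_error(waiting_times(av[1, ]), "2 avalanches")
  # K avalanches give exactly K - 1 waiting times
  set.seed(2)
  starts <- cumsum(runif(20, 2, 50))
  av20 <- data.frame(start_ms = starts, duration_ms = 1, size = 1)
  expect_length(waiting_times(av20), 19)
})

test_that("log-measure density is the linear density times dt, bin by bin", {
  set.seed(13)
  dts <- rpareto_trunc(2e4, 3, 5, 80)
  dl <- waiting_time_density(dts, "per_linear_bin", n_bins = 25)
  dg <- waiting_time_density(dts, "per_log_bin", n_bins = 25)
  expect_equal(dg$density, dl$density * dl$mid, tolerance = 1e-12)
  # each normalized in its own measure
  expect_equal(sum(dl$density * (dl$hi - dl$lo)), 1, tolerance = 1e-12)
  expect_equal(sum(dg$density * log(dg$hi / dg$lo)), 1, tolerance = 1e-12)
  # degenerate input: single occupied bin carrying all mass
  dd <- waiting_time_density(rep(4, 10), "per_linear_bin")
  expect_equal(sum(dd$count), 10)
  expect_equal(sum(dd$density * (dd$hi - dd$lo)), 1)
})

test_that("fitted exponents under the two measures differ by exactly one", {
  set.seed(14)
  dts <- rpareto_trunc(5e4, 3, 10, 50)
  s_lin <- replaynet:::density_slope(dts, 10, 50, "per_linear_bin")
  s_log <- replaynet:::density_slope(dts, 10, 50, "per_log_bin")
  expect_equal(s_lin$exponent - s_log$exponent, 1, tolerance = 1e-10)
  expect_equal(s_lin$exponent, 3, tolerance = 0.15)
})

test_that("up/down segmentation follows the concatenation rules", {
  # gaps [20, 60, 30, 10]: avalanches 1-2 form an up state, 3-5 another,
  # with a down state holding the 60 ms gap
  starts <- c(0, 30, 100, 140, 160)
  av <- data.frame(start_ms = starts, duration_ms = 10, size = 1)
  segs <- segment_up_down(av, 50, window = c(0, 200))
  expect_equal(segs$kind, c("up", "down", "up", "down"))
  expect_equal(segs$start_ms, c(0, 40, 100, 170))
  expect_equal(segs$duration_ms, c(40, 60, 70, 30))
  # an isolated avalanche does not interrupt the down state
  one <- data.frame(start_ms = 50, duration_ms = 5, size = 1)
  segs1 <- segment_up_down(one, 50, window = c(0, 200))
  expect_equal(segs1$kind, "down")
  expect_equal(segs1$duration_ms, 200)
  # all gaps below threshold: a single up state
  av3 <- data.frame(start_ms = c(0, 20, 40), duration_ms = 10, size = 1)
  segs3 <- segment_up_down(av3, 50, window = c(0, 50))
  expect_equal(segs3$kind, "up")
  # durations always partition the window
  expect_equal(sum(segs$duration_ms), 200)
})

test_that("power-law estimator recovers planted exponents", {
  set.seed(15)
  for (g in c(1.5, 2, 3)) {
    x <- rpareto_trunc(1e5, g, 4, 1e4)
    fit <- fit_power_law(x, 4, 1e4)
    expect_equal(fit$exponent, g, tolerance = 0.05)
  }
  # discrete variant
  z <- rzipf_trunc(1e5, 1.5, 4, 1e4)
  expect_equal(fit_power_law(z, 4, 1e4)$exponent, 1.5, tolerance = 0.05)
  # the two fit methods agree on the same sample
  x <- rpareto_trunc(1e5, 2.5, 5, 500)
  f_mle <- fit_power_law(x, 5, 500, method = "mle")
  f_lsq <- fit_power_law(x, 5, 500, method = "lsq")
  expect_equal(f_mle$exponent, f_lsq$exponent, tolerance = 0.1)
  # insufficient or degenerate data
  expect_error(fit_power_law(c(5, 6), 1, 10), "samples")
  expect_error(fit_power_law(rep(c(5, 6), 100), 1, 10), "distinct")
})

test_that("waiting-time density fit recovers a planted Pareto exponent", {
  set.seed(16)
  dts <- rpareto_trunc(1e5, 3, 10, 50)
  expect_equal(fit_power_law(dts, 10, 50)$exponent, 3, tolerance = 0.1)
})

test_that("exponential fit recovers the mean and flags degenerate input", {
  set.seed(17)
  x <- rexp(1e4, 1 / 200)
  fit <- fit_exponential(x, t_min = 0)
  expect_equal(fit$mean_ms, 200, tolerance = 0.02 * 200)
  expect_gt(fit$ks_p, 0.001)
  const <- fit_exponential(rep(100, 200), t_min = 50)
  expect_lt(const$ks_p, 0.01)
  expect_error(fit_exponential(c(1, 2, 3)), "durations")
})

test_that("replay score is high for the pattern, null for permuted labels", {
  r <- make_fixture("toy-raster", list(N = 1000, bg_hz = 0), seed = 18)
  expect_gt(replay_similarity(r, r$pattern, 0, 100), 0.95)
  # permuting neuron identities destroys the correlation
  set.seed(19)
  r_perm <- r
  r_perm$ids <- sample(1000)[r$ids]
  expect_lt(abs(replay_similarity(r_perm, r$pattern, 0, 100)), 0.1)
  few <- toy_raster(1:5, 1:5, 10, 10)
  expect_error(replay_similarity(few, r$pattern, 0, 10), "10")
})

test_that("avalanche sizes never exceed the spike count of the window", {
  set.seed(20)
  counts <- rpois(2000, 4)
  rs <- rate_series(counts, 500)
  av <- detect_avalanches(rs, 7)
  expect_lte(sum(av$size), sum(counts))
})
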