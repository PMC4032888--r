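test_that("config constructors validate their invariants", {
  expect_error(sim_config(alpha = 0.1, dt = 1), "dt")
  expect_error(sim_config(alpha = 0.1, t_total = 100, t_transient = 200))
  expect_error(sim_config(alpha = -1))
  expect_error(stsd_config(TRUE, tau_r = -1))
  expect_error(stsd_config(TRUE, f_stsd = 0))
  cfg <- sim_config(alpha = 0.1)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$noise_convention, "sqrt_alpha")
})

test_that("noise sigma follows the configured convention", {
  W <- matrix(c(0, 3, 4, 0), 2, 2, byrow = TRUE)  # row energies 9+? rows: (0,3),(4,0)
  e <- rowSums(W^2)
  c1 <- sim_config(alpha = 0.16, rho = 4, noise_convention = "sqrt_alpha")
  expect_equal(noise_sigma(W, c1), sqrt(0.16 / 4 * e))
  c2 <- sim_config(alpha = 0.16, rho = 4, noise_convention = "alpha_sqrt")
  expect_equal(noise_sigma(W, c2), 0.16 * sqrt(4 * e))
  # zero energy gives zero sigma, not NaN
  expect_equal(noise_sigma(matrix(0, 2, 2), c1), c(0, 0))
})

test_that("noise sampler has the configured moments", {
  set.seed(5)
  n <- 1e6
  sigma <- rep(2, n)
  amp <- draw_noise(sigma, rho = 1, dt = 1)
  # mean 0 within 4 sd(mean); per-draw variance = sigma^2 * E[count] = 4
  expect_lt(abs(mean(amp)), 4 * 2 / sqrt(n))
  expect_equal(sd(amp), 2, tolerance = 0.01)
  expect_true(all(draw_noise(rep(0, 100), 1, 1) == 0))
})

test_that("integrator reproduces the analytic PSP superposition exactly", {
  imp <- data.frame(time = c(0, 7.5, 20), neuron = 1, amp = c(2, -1.5, 3))
  cfg <- sim_config(alpha = 0, theta = 100, dt = 0.1, t_total = 60,
                    t_transient = 0)
  r <- simulate_network(matrix(0, 1, 1), cfg, external = imp, record_v = TRUE)
  tt <- seq(0, 60, by = 0.1)
  analytic <- rowSums(vapply(seq_len(3), function(k) {
    dtk <- tt - imp$time[k]
    out <- numeric(length(tt))
    out[dtk >= 0] <- imp$amp[k] * epsilon_kernel(dtk[dtk >= 0])
    out
  }, numeric(length(tt))))
  expect_lt(max(abs(r$v_trace[, 1] - analytic)), 1e-9)
})

test_that("zero input produces zero spikes; threshold gates single impulses", {
  cfg <- sim_config(alpha = 0, t_total = 500, t_transient = 0)
  r0 <- simulate_network(matrix(0, 5, 5), cfg)
  expect_length(r0$times, 0)
  # peak response to impulse J is J/4: J = 4.2 crosses, J = 3.9 does not
  hit <- simulate_network(matrix(0, 1, 1), cfg,
                          external = data.frame(time = 0, neuron = 1, amp = 4.2))
  miss <- simulate_network(matrix(0, 1, 1), cfg,
                           external = data.frame(time = 0, neuron = 1, amp = 3.9))
  expect_length(hit$times, 1)
  expect_length(miss$times, 0)
  expect_lt(hit$times[1], 10 * log(2) + 0.2)  # crossing happens before the peak
})

test_that("reset clears membrane and trace; prior input is forgotten", {
  # big impulse triggers a spike; a second small impulse lands before the
  # spike and must leave no trace afterwards
  imp <- data.frame(time = c(0, 1), neuron = 1, amp = c(8, 0.5))
  cfg <- sim_config(alpha = 0, t_total = 50, t_transient = 0)
  r <- simulate_network(matrix(0, 1, 1), cfg, external = imp, record_v = TRUE)
  expect_length(r$times, 1)
  after <- r$v_trace[seq(round(r$times[1] / 0.1) + 2, nrow(r$v_trace)), 1]
  expect_true(all(after == 0))
})

test_that("simultaneous crossings are all emitted and recurrences start next step", {
  W <- matrix(1, 3, 3); diag(W) <- 0
  imp <- data.frame(time = c(0, 0, 0), neuron = 1:3, amp = 5)
  cfg <- sim_config(alpha = 0, t_total = 30, t_transient = 0)
  r <- simulate_network(W, cfg, external = imp)
  first <- min(r$times)
  expect_equal(sum(r$times == first), 3)  # all three cross in the same step
})

test_that("simulation is deterministic under a fixed seed", {
  net <- make_fixture("toy-weights", list(N = 100), seed = 3)
  cfg <- sim_config(alpha = 3, t_total = 2000, t_transient = 0, seed = 17)
  r1 <- simulate_network(net$W, cfg)
  r2 <- simulate_network(net$W, cfg)
  expect_identical(r1$times, r2$times)
  expect_identical(r1$ids, r2$ids)
  expect_gt(length(r1$times), 0)
})

test_that("the spike cap stops the run early", {
  net <- make_fixture("toy-weights", list(N = 100), seed = 3)
  cfg <- sim_config(alpha = 15, t_total = 5000, t_transient = 100,
                    max_spikes = 50, seed = 17)
  r <- simulate_network(net$W, cfg)
  expect_lt(r$t_total, 5000)
  expect_gte(sum(r$times > 100), 50)
})

test_that("mean rate halving dt is stable (integration-scheme robustness)", {
  net <- make_fixture("toy-weights", list(N = 300), seed = 8)
  rates <- vapply(c(0.1, 0.05), function(dt) {
    mean(vapply(1:3, function(s) {
      cfg <- sim_config(alpha = 6, dt = dt, t_total = 6000, t_transient = 1000,
                        seed = 100 + s)
      mean_rate(simulate_network(net$W, cfg))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(rates[1], 0.5)  # the probe regime is actually active
  expect_lt(abs(rates[1] - rates[2]) / rates[1], 0.05)
})

test_that("depression reference: relaxation, single-spike solution, bound", {
  st <- stsd_config(TRUE, tau_r = 10, f_stsd = 0.5)
  J0 <- matrix(c(0, 1, 2, 0), 2, 2)
  # no spikes: exponential relaxation toward J0
  J <- J0 * 0.3
  for (k in 1:40) J <- depress_and_recover(J, J0, integer(0), 1, st)
  expect_equal(J, J0 + (J0 * 0.3 - J0) * exp(-40 / 10), tolerance = 1e-12)
  # one spike of presynaptic neuron 2 at t = 0: J(t) = J0 (1 - 0.5 e^(-t/10))
  J <- depress_and_recover(J0, J0, spiked = 2, dt = 0, stsd = st)
  tt <- seq(0.5, 30, by = 0.5)
  for (t in tt) {
    Jt <- depress_and_recover(J, J0, integer(0), t, st)
    expect_equal(Jt[, 2], J0[, 2] * (1 - 0.5 * exp(-t / 10)), tolerance = 1e-12)
  }
  # |J_dyn| never exceeds |J0| when started at rest
  set.seed(2)
  J <- J0
  for (k in 1:200) {
    spiked <- which(runif(2) < 0.2)
    J <- depress_and_recover(J, J0, spiked, 0.5, st)
    expect_true(all(abs(J) <= abs(J0) + 1e-12))
  }
})

test_that("compiled depression matches the discrete-event oracle", {
  # neuron 1 is driven to spike at known times; its synapse onto neuron 2
  # transmits J0 * r with r depressed at each spike and recovering with tau_r
  J0 <- 0.3
  W <- matrix(c(0, 0, J0, 0), 2, 2, byrow = TRUE)
  drive <- data.frame(time = c(5, 15, 25, 60), neuron = 1, amp = 10)
  cfg <- sim_config(alpha = 0, t_total = 100, t_transient = 0, dt = 0.1)
  r <- simulate_network(W, cfg, stsd = stsd_config(TRUE, 10, 0.5),
                        external = drive, record_v = TRUE)
  sp <- r$times[r$ids == 1]
  expect_length(sp, 4)
  # transmission factors from the event-driven oracle (value just before
  # each spike's own depression)
  fac <- stsd_oracle(sp, sp - 1e-9, J0 = 1, tau_r = 10, f = 0.5)
  tt <- seq(0, 100, by = 0.1)
  expected <- rowSums(vapply(seq_along(sp), function(k) {
    dtk <- tt - sp[k]
    out <- numeric(length(tt))
    out[dtk >= 0] <- J0 * fac[k] * epsilon_kernel(dtk[dtk >= 0])
    out
  }, numeric(length(tt))))
  expect_lt(max(abs(r$v_trace[, 2] - expected)), 1e-9)
})

test_that("depressed synapses lower sustained activity", {
  net <- make_fixture("toy-weights", list(N = 150), seed = 12)
  cfg <- sim_config(alpha = 12, t_total = 3000, t_transient = 500, seed = 4)
  r_plain <- simulate_network(net$W, cfg)
  r_stsd <- simulate_network(net$W, cfg, stsd = stsd_config(TRUE, 10, 0.5))
  expect_lt(mean_rate(r_stsd), mean_rate(r_plain) + 0.5)
})
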