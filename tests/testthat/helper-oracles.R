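# Independent reference implementations and samplers used across the suite.
# These are deliberately naive (loops, closed forms, discrete-event logic) so
# they share no code path with the package.

# brute-force imprinting: triple loop over (i, j, n)
brute_learn <- function(patterns, config) {
  N <- length(patterns[[1]]$phases)
  J <- matrix(0, N, N)
  for (pat in patterns) {
    t <- pat$phases / (2 * pi) * pat$period
    lead <- order(pat$phases, seq_len(N))[seq_len(ceiling(config$leader_fraction * N))]
    for (i in seq_len(N)) {
      H <- if (i %in% lead) config$H0 * config$leader_multiplier else config$H0
      for (j in seq_len(N)) {
        if (i == j) next
        acc <- 0
        for (n in -config$n_window:config$n_window)
          acc <- acc + stdp_kernel(t[j] - t[i] + n * pat$period)
        J[i, j] <- J[i, j] + H * acc
      }
    }
  }
  J
}

# naive avalanche detector: explicit scan
naive_avalanches <- function(rates, counts, bin_ms, r_min, t_start = 0) {
  out <- data.frame(start_ms = numeric(0), duration_ms = numeric(0), size = numeric(0))
  k <- 1; n <- length(rates)
  while (k <= n) {
    if (rates[k] > r_min) {
      st <- k
      while (k <= n && rates[k] > r_min) k <- k + 1
      out <- rbind(out, data.frame(
        start_ms = t_start + (st - 1) * bin_ms,
        duration_ms = (k - st) * bin_ms,
        size = sum(counts[st:(k - 1)])))
    } else k <- k + 1
  }
  out
}

# naive up/down segmentation: walk the avalanche list, apply the rules directly
naive_segments <- function(av, t_max, window) {
  K <- nrow(av)
  ends <- av$start_ms + av$duration_ms
  # group avalanches: new group when gap >= t_max
  grp <- integer(K)
  g <- 1
  if (K > 0) grp[1] <- 1
  for (k in seq_len(K)[-1]) {
    if (av$start_ms[k] - ends[k - 1] >= t_max) g <- g + 1
    grp[k] <- g
  }
  ups <- data.frame(start = numeric(0), end = numeric(0))
  for (gg in unique(grp)) {
    members <- which(grp == gg)
    if (length(members) >= 2)
      ups <- rbind(ups, data.frame(start = av$start_ms[members[1]],
                                   end = ends[members[length(members)]]))
  }
  segs <- data.frame(kind = character(0), start_ms = numeric(0), duration_ms = numeric(0))
  cur <- window[1]
  for (k in seq_len(nrow(ups))) {
    if (ups$start[k] > cur)
      segs <- rbind(segs, data.frame(kind = "down", start_ms = cur,
                                     duration_ms = ups$start[k] - cur))
    segs <- rbind(segs, data.frame(kind = "up", start_ms = ups$start[k],
                                   duration_ms = ups$end[k] - ups$start[k]))
    cur <- ups$end[k]
  }
  if (window[2] > cur)
    segs <- rbind(segs, data.frame(kind = "down", start_ms = cur,
                                   duration_ms = window[2] - cur))
  segs
}

# truncated Pareto sampler by inverse CDF (continuous)
rpareto_trunc <- function(n, gamma, xmin, xmax) {
  u <- runif(n)
  if (abs(gamma - 1) < 1e-12) return(xmin * (xmax / xmin)^u)
  a <- 1 - gamma
  (u * (xmax^a - xmin^a) + xmin^a)^(1 / a)
}

# truncated Zipf sampler (discrete) by direct table sampling
rzipf_trunc <- function(n, gamma, xmin, xmax) {
  support <- xmin:xmax
  p <- support^(-gamma)
  sample(support, n, replace = TRUE, prob = p / sum(p))
}

# event-driven single-synapse depression oracle: exact piecewise solution of
# dJ/dt = (J0 - J)/tau_r with J *= f at each presynaptic spike time;
# t_eval must be sorted increasing
stsd_oracle <- function(spike_times, t_eval, J0 = 1, tau_r = 10, f = 0.5) {
  stopifnot(!is.unsorted(t_eval))
  events <- sort(spike_times)
  J <- J0; t_last <- 0; ei <- 1
  vapply(t_eval, function(tq) {
    while (ei <= length(events) && events[ei] <= tq) {
      J <<- (J0 + (J - J0) * exp(-(events[ei] - t_last) / tau_r)) * f
      t_last <<- events[ei]
      ei <<- ei + 1
    }
    J0 + (J - J0) * exp(-(tq - t_last) / tau_r)
  }, numeric(1))
}
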