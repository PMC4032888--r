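#' Bin a spike raster into a population rate series
#'
#' Time is divided into bins of `bin_ms`; the population rate of a bin is the
#' spike count divided by `N * bin_ms * 1e-3`, i.e. Hz per neuron.
#'
#' @param raster a `spike_raster`.
#' @param bin_ms bin width in ms (default 1).
#' @param from,to analysis window (ms); defaults to the post-transient part.
#' @return An object of class `rate_series`: `rates` (Hz per neuron),
#'   `counts`, `bin_ms`, `t_start`, `n_neurons`.
#' @export
bin_rates <- function(raster, bin_ms = 1,
                      from = raster$t_transient, to = raster$t_total) {
  stopifnot(inherits(raster, "spike_raster"))
  if (bin_ms <= 0) stop("`bin_ms` must be positive")
  stopifnot(to > from)
  n_bins <- floor((to - from) / bin_ms)
  if (n_bins < 1) stop("window shorter than one bin")
  sel <- raster$times > from & raster$times <= from + n_bins * bin_ms
  idx <- ceiling((raster$times[sel] - from) / bin_ms)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(rates = counts / (raster$n_neurons * bin_ms * 1e-3),
         counts = counts, bin_ms = bin_ms, t_start = from,
         n_neurons = raster$n_neurons),
    class = "rate_series"
  )
}

#' Build a rate series directly from counts (for fixtures and tests)
#'
#' @param counts spike counts per bin.
#' @param n_neurons neuron count used for the Hz-per-neuron conversion.
#' @param bin_ms bin width, ms.
#' @param t_start window start, ms.
#' @return A `rate_series`.
#' @export
rate_series <- function(counts, n_neurons, bin_ms = 1, t_start = 0) {
  stopifnot(all(counts >= 0), n_neurons >= 1, bin_ms > 0)
  structure(
    list(rates = counts / (n_neurons * bin_ms * 1e-3),
         counts = as.integer(counts), bin_ms = bin_ms, t_start = t_start,
         n_neurons = as.integer(n_neurons)),
    class = "rate_series"
  )
}

gaussian_smooth <- function(y, sd_bins) {
  half <- ceiling(4 * sd_bins)
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
}

peak_prominences <- function(y) {
  n <- length(y)
  is_peak <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > l && y[i] >= r
  }, logical(1)))
  prom <- vapply(is_peak, function(p) {
    h <- y[p]
    col_side <- function(idx) {
      if (length(idx) == 0) return(min(h, 0))
      run_min <- Inf
      for (q in idx) {
        if (y[q] > h) break
        run_min <- min(run_min, y[q])
      }
      if (is.infinite(run_min)) min(h, 0) else run_min
    }
    left <- col_side(rev(seq_len(p - 1)))
    right <- col_side(if (p < n) (p + 1):n else integer(0))
    h - max(left, right)
  }, numeric(1))
  list(peaks = is_peak, prominences = prom)
}

#' Classify the dynamical regime from the rate distribution
#'
#' The per-bin rate histogram distinguishes three regimes of the network:
#' nearly exponential with its only mode at zero rate (noise-dominated
#' quiescence), nearly Gaussian with a single high-rate mode (permanent
#' pattern replay), and bimodal with one mode in each band separated by a
#' local minimum (intermittent up/down alternation).
#'
#' Rule: histogram of per-bin rates at 1-Hz resolution, Gaussian smoothing
#' with 2-bin SD; modes are local maxima with prominence at least 5% of the
#' histogram maximum. `exponential` iff the only mode lies in the 0-2 Hz
#' band, `gaussian` iff the only mode is at 10 Hz or above, `bimodal` iff
#' modes occur in both bands with an interior minimum. A unique mode in the
#' intermediate band is assigned to the nearer band edge (below 6 Hz counts
#' as low); with several modes confined to one band the most prominent mode
#' decides the same way.
#'
#' @param rates a `rate_series` with at least `min_bins` bins.
#' @param min_bins minimum number of bins required (default 1e4).
#' @return An object of class `regime_label`: `label` (one of
#'   `"exponential"`, `"bimodal"`, `"gaussian"`), `modes` (data frame of
#'   mode rate, height, prominence), `valley` (rate of the interior minimum,
#'   NA unless bimodal).
#' @export
classify_regime <- function(rates, min_bins = 1e4) {
  stopifnot(inherits(rates, "rate_series"))
  if (length(rates$rates) < min_bins)
    stop(sprintf("need at least %g bins to classify a regime", min_bins))
  r <- rates$rates
  breaks <- seq(0, ceiling(max(r, 12)) + 1, by = 1)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  sm <- gaussian_smooth(h$counts, sd_bins = 2)
  pp <- peak_prominences(sm)
  keep <- pp$prominences >= 0.05 * max(sm)
  peaks <- pp$peaks[keep]
  centers <- h$mids[peaks]
  modes <- data.frame(rate = centers, height = sm[peaks],
                      prominence = pp$prominences[keep])
  low <- centers <= 2
  high <- centers >= 10
  valley <- NA_real_
  if (nrow(modes) == 0) {
    label <- "exponential"   # flat histogram collapses to the low band
  } else if (any(low) && any(high)) {
    lo_peak <- pp$peaks[keep][which(low)[1]]
    hi_peak <- pp$peaks[keep][which(high)[length(which(high))]]
    between <- seq(lo_peak, hi_peak)
    valley <- h$mids[between[which.min(sm[between])]]
    label <- "bimodal"
  } else {
    main <- modes$rate[which.max(modes$prominence)]
    label <- if (main < 6) "exponential" else "gaussian"
  }
  structure(list(label = label, modes = modes, valley = valley),
            class = "regime_label")
}

#' @exportS3Method base::print
print.regime_label <- function(x, ...) {
  cat(sprintf("regime: %s (modes at %s Hz)\n", x$label,
              paste(signif(x$modes$rate, 3), collapse = ", ")))
  invisible(x)
}

#' Detect neuronal avalanches in a rate series
#'
#' An avalanche is a maximal run of consecutive bins with population rate
#' strictly above `r_min_hz`; a bin at or below the threshold terminates it.
#' Size is the total spike count over the run, duration the run length times
#' the bin width.
#'
#' @param rates a `rate_series`.
#' @param r_min_hz rate threshold in Hz per neuron (default 7).
#' @return Data frame with columns `start_ms`, `duration_ms`, `size`
#'   (spikes), ordered in time. Zero rows if no bin exceeds the threshold.
#' @export
detect_avalanches <- function(rates, r_min_hz = 7) {
  stopifnot(inherits(rates, "rate_series"))
  if (r_min_hz <= 0) stop("`r_min_hz` must be positive")
  active <- rates$rates > r_min_hz
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- which(runs$values)
  if (length(on) == 0)
    return(data.frame(start_ms = numeric(0), duration_ms = numeric(0),
                      size = numeric(0)))
  sizes <- vapply(on, function(k) sum(rates$counts[starts[k]:ends[k]]),
                  numeric(1))
  data.frame(
    start_ms = rates$t_start + (starts[on] - 1) * rates$bin_ms,
    duration_ms = runs$lengths[on] * rates$bin_ms,
    size = sizes
  )
}

#' Waiting times between successive avalanches
#'
#' The waiting time is the quiescent gap from the end of one avalanche to
#' the start of the next. Gaps before the first and after the last avalanche
#' are not included.
#'
#' @param avalanches data frame from [detect_avalanches()].
#' @return Numeric vector of K-1 waiting times (ms) for K avalanches.
#' @export
waiting_times <- function(avalanches) {
  if (nrow(avalanches) < 2) stop("need at least 2 avalanches")
  ends <- avalanches$start_ms + avalanches$duration_ms
  avalanches$start_ms[-1] - ends[-nrow(avalanches)]
}

#' Waiting-time density under linear or logarithmic measure
#'
#' With logarithmically spaced bins, the per-linear-bin density P assigns
#' each bin `count / (n * (hi - lo))` — probability per ms. The per-log-bin
#' density, the probability of a waiting time between \eqn{\Delta t} and
#' \eqn{\Delta t (1 + \delta\lambda)} per unit \eqn{\delta\lambda}, is
#' `count / (n * log(hi/lo))`. Representing each bin by the logarithmic mean
#' of its edges makes the two densities satisfy
#' \eqn{\tilde P(\Delta t) = P(\Delta t)\,\Delta t} exactly bin-by-bin while
#' both integrate to 1 in their own measure; an exact power law with density
#' exponent \eqn{-\gamma} therefore appears with exponent \eqn{-(\gamma-1)}
#' under the log measure.
#'
#' @param dts waiting times (ms).
#' @param convention `"per_linear_bin"` for P or `"per_log_bin"` for
#'   \eqn{\tilde P}.
#' @param n_bins number of logarithmically spaced bins (default 40).
#' @return Data frame with columns `lo`, `hi`, `mid` (logarithmic mean),
#'   `count`, `density`; attribute `convention`.
#' @export
waiting_time_density <- function(dts,
                                 convention = c("per_linear_bin", "per_log_bin"),
                                 n_bins = 40) {
  convention <- match.arg(convention)
  if (length(dts) == 0) stop("`dts` is empty")
  stopifnot(all(dts > 0))
  lo_all <- min(dts); hi_all <- max(dts)
  if (lo_all == hi_all) {
    # degenerate support: one bin carrying all mass
    edges <- c(lo_all * 0.99, lo_all * 1.01)
  } else {
    edges <- exp(seq(log(lo_all), log(hi_all), length.out = n_bins + 1))
    edges[length(edges)] <- hi_all
  }
  idx <- findInterval(dts, edges, rightmost.closed = TRUE, all.inside = TRUE)
  count <- tabulate(idx, nbins = length(edges) - 1)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  n <- length(dts)
  width_lin <- hi - lo
  width_log <- log(hi / lo)
  density <- if (convention == "per_linear_bin") count / (n * width_lin)
             else count / (n * width_log)
  out <- data.frame(lo = lo, hi = hi, mid = width_lin / width_log,
                    count = count, density = density)
  attr(out, "convention") <- convention
  out
}

#' Segment the recording into up and down states
#'
#' Up states are maximal concatenations of at least two avalanches whose
#' internal waiting times are all below `t_max_ms`; they span from the start
#' of their first avalanche to the end of their last. An isolated avalanche
#' — preceded and followed by waiting times of `t_max_ms` or more — does not
#' interrupt the surrounding down state. Down states cover the remainder of
#' the analysis window, so up and down durations sum to the window length.
#'
#' @param avalanches time-ordered data frame from [detect_avalanches()].
#' @param t_max_ms maximum intra-up-state waiting time (default 50).
#' @param window length-2 numeric, the analysis window in ms.
#' @return Data frame with columns `kind` ("up"/"down"), `start_ms`,
#'   `duration_ms`, in temporal order.
#' @export
segment_up_down <- function(avalanches, t_max_ms = 50,
                            window = c(min(avalanches$start_ms),
                                       max(avalanches$start_ms + avalanches$duration_ms))) {
  stopifnot(t_max_ms > 0, length(window) == 2, window[2] > window[1])
  K <- nrow(avalanches)
  ups <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  if (K >= 2) {
    if (is.unsorted(avalanches$start_ms)) stop("avalanches must be time-sorted")
    gaps <- waiting_times(avalanches)
    grp <- cumsum(c(1, gaps >= t_max_ms))
    for (g in unique(grp)) {
      members <- which(grp == g)
      if (length(members) >= 2) {
        ups <- rbind(ups, data.frame(
          start_ms = avalanches$start_ms[members[1]],
          end_ms = avalanches$start_ms[members[length(members)]] +
            avalanches$duration_ms[members[length(members)]]))
      }
    }
  }
  segs <- data.frame(kind = character(0), start_ms = numeric(0),
                     duration_ms = numeric(0))
  cursor <- window[1]
  if (nrow(ups) > 0) {
    for (k in seq_len(nrow(ups))) {
      if (ups$start_ms[k] > cursor)
        segs <- rbind(segs, data.frame(kind = "down", start_ms = cursor,
                                       duration_ms = ups$start_ms[k] - cursor))
      segs <- rbind(segs, data.frame(kind = "up", start_ms = ups$start_ms[k],
                                     duration_ms = ups$end_ms[k] - ups$start_ms[k]))
      cursor <- ups$end_ms[k]
    }
  }
  if (window[2] > cursor)
    segs <- rbind(segs, data.frame(kind = "down", start_ms = cursor,
                                   duration_ms = window[2] - cursor))
  segs
}

#' Fit a truncated power law
#'
#' Estimates the density exponent \eqn{\gamma} of \eqn{P(x) \propto
#' x^{-\gamma}} on the window `[x_min, x_max]`. The default method is
#' maximum likelihood for the truncated law (discrete support summed
#' exactly, continuous support integrated in closed form), with the exponent
#' found by one-dimensional likelihood optimization; the alternative is
#' least squares on the log-binned density. A Kolmogorov-Smirnov distance
#' between the data and the fitted law is reported as a goodness summary.
#'
#' @param x samples (sizes, durations, waiting times, ...).
#' @param x_min,x_max fit range; samples outside are discarded.
#' @param method `"mle"` or `"lsq"`.
#' @param discrete treat support as integer-valued; default: guessed from
#'   whether all in-range samples are whole numbers.
#' @param min_n minimum number of in-range samples (default 100).
#' @return An object of class `power_law_fit`: `exponent` (positive
#'   convention, density \eqn{\propto x^{-\gamma}}), `x_min`, `x_max`,
#'   `method`, `n`, `ks_distance`.
#' @export
fit_power_law <- function(x, x_min, x_max, method = c("mle", "lsq"),
                          discrete = NULL, min_n = 100) {
  method <- match.arg(method)
  stopifnot(x_max > x_min, x_min > 0)
  x <- x[x >= x_min & x <= x_max]
  if (length(x) < min_n)
    stop(sprintf("only %d samples in [%g, %g]; need >= %d",
                 length(x), x_min, x_max, min_n))
  if (length(unique(x)) < 3) stop("fewer than 3 distinct values in range")
  if (is.null(discrete)) discrete <- all(x == round(x))
  if (method == "mle") {
    slx <- sum(log(x)); n <- length(x)
    if (discrete) {
      support <- seq(ceiling(x_min), floor(x_max))
      nll <- function(g) g * slx / n + log(sum(support^(-g)))
    } else {
      nll <- function(g) {
        logZ <- if (abs(g - 1) < 1e-8) log(log(x_max / x_min))
                else log(abs((x_max^(1 - g) - x_min^(1 - g)) / (1 - g)))
        g * slx / n + logZ
      }
    }
    gamma <- stats::optimize(nll, c(-2, 10))$minimum
  } else {
    d <- waiting_time_density(x, "per_linear_bin",
                              n_bins = max(10, min(30, length(unique(x)))))
    d <- d[d$count > 0, ]
    if (nrow(d) < 3) stop("too few occupied bins for least squares")
    fitlm <- stats::lm(log(d$density) ~ log(d$mid))
    gamma <- -unname(stats::coef(fitlm)[2])
  }
  # KS distance against the fitted truncated law
  if (discrete) {
    support <- seq(ceiling(x_min), floor(x_max))
    p <- support^(-gamma); p <- p / sum(p)
    cdf_fit <- stats::stepfun(support, c(0, cumsum(p)))
  } else {
    cdf_fit <- function(q) {
      if (abs(gamma - 1) < 1e-8) log(q / x_min) / log(x_max / x_min)
      else (q^(1 - gamma) - x_min^(1 - gamma)) /
        (x_max^(1 - gamma) - x_min^(1 - gamma))
    }
  }
  xs <- sort(unique(x))
  ecdf_x <- stats::ecdf(x)
  ks <- max(abs(ecdf_x(xs) - cdf_fit(xs)))
  structure(
    list(exponent = gamma, x_min = x_min, x_max = x_max, method = method,
         n = length(x), discrete = discrete, ks_distance = ks),
    class = "power_law_fit"
  )
}

#' @exportS3Method base::print
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law P(x) ~ x^-%.3f on [%g, %g] (%s, n = %d, KS = %.3f)\n",
              x$exponent, x$x_min, x$x_max, x$method, x$n, x$ks_distance))
  invisible(x)
}

#' Fit an exponential to durations
#'
#' Maximum-likelihood fit with left truncation at the smallest observable
#' duration: rate = 1 / (mean(x) - t_min). Goodness is a Kolmogorov-Smirnov
#' test of the truncated samples against the fitted exponential.
#'
#' @param x durations (ms), at least `min_n` of them.
#' @param t_min left-truncation point; defaults to `min(x)`.
#' @param min_n minimum sample size (default 50).
#' @return List with `rate` (1/ms), `mean_ms` (fitted mean above `t_min`),
#'   `ks_p` (KS p-value), `n`.
#' @export
fit_exponential <- function(x, t_min = min(x), min_n = 50) {
  if (length(x) < min_n)
    stop(sprintf("need >= %d durations, got %d", min_n, length(x)))
  excess <- x - t_min
  m <- mean(excess)
  if (m <= 0) return(list(rate = Inf, mean_ms = 0, ks_p = 0, n = length(x)))
  rate <- 1 / m
  ks <- suppressWarnings(stats::ks.test(excess, "pexp", rate))
  list(rate = rate, mean_ms = m, ks_p = ks$p.value, n = length(x))
}

#' Score replay of a stored pattern in a raster window
#'
#' Measures whether neurons fire in the order prescribed by a phase-coded
#' pattern: the first spike time of each neuron active in the window and its
#' stored phase are both converted to circular ranks, and the Fisher-Lee
#' circular correlation between the two angle sets is returned. A window
#' replaying the pattern scores near 1 (the score is invariant to where in
#' the cycle the window starts); unrelated activity scores near 0.
#'
#' @param raster a `spike_raster`.
#' @param pattern a `phase_pattern`.
#' @param from,to window (ms).
#' @param max_neurons cap on neurons entering the O(n^2) correlation;
#'   a deterministic evenly spaced subset is used beyond it.
#' @return Correlation score in \[-1, 1\].
#' @export
replay_similarity <- function(raster, pattern, from, to, max_neurons = 1500) {
  stopifnot(inherits(raster, "spike_raster"), inherits(pattern, "phase_pattern"))
  stopifnot(to > from)
  sel <- raster$times >= from & raster$times <= to
  t_first <- tapply(raster$times[sel], raster$ids[sel], min)
  ids <- as.integer(names(t_first))
  if (length(ids) < 10) stop("window contains fewer than 10 spiking neurons")
  t_first <- as.numeric(t_first)
  if (length(ids) > max_neurons) {
    keep <- round(seq(1, length(ids), length.out = max_neurons))
    ids <- ids[keep]; t_first <- t_first[keep]
  }
  n <- length(ids)
  a <- 2 * pi * rank(t_first, ties.method = "first") / n
  b <- 2 * pi * rank(pattern$phases[ids], ties.method = "first") / n
  sa <- outer(a, a, "-"); sb <- outer(b, b, "-")
  num <- sum(sin(sa) * sin(sb)) / 2
  den <- sqrt(sum(sin(sa)^2) / 2 * sum(sin(sb)^2) / 2)
  if (den == 0) return(0)
  num / den
}
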