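#' Full experiment configuration
#'
#' Bundles the learning, simulation, depression and analysis parameters of
#' one experiment, plus the master seed. The master seed deterministically
#' spawns the pattern seed and the simulation seed, so a single integer
#' reproduces the whole pipeline. Round-trips losslessly through YAML via
#' [write_experiment_config()] / [read_experiment_config()].
#'
#' @param learning a [learning_config()].
#' @param sim a [sim_config()].
#' @param stsd an [stsd_config()].
#' @param analysis list of analysis parameters: `bin_ms`, `r_min_hz`,
#'   `t_max_ms`, `size_xmin`, `dur_xmin_ms`, `wt_range_ms` (length 2).
#' @param seed master seed (integer).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(learning = learning_config(),
                              sim = sim_config(alpha = 0.14),
                              stsd = stsd_config(),
                              analysis = list(),
                              seed = 1) {
  defaults <- list(bin_ms = 1, r_min_hz = 7, t_max_ms = 50,
                   size_xmin = 10, dur_xmin_ms = 2, wt_range_ms = c(10, 50))
  unknown <- setdiff(names(analysis), names(defaults))
  if (length(unknown) > 0)
    stop("unknown analysis parameter(s): ", paste(unknown, collapse = ", "))
  analysis <- utils::modifyList(defaults, analysis)
  stopifnot(inherits(learning, "learning_config"), inherits(sim, "sim_config"),
            inherits(stsd, "stsd_config"), length(analysis$wt_range_ms) == 2)
  structure(
    list(learning = learning, sim = sim, stsd = stsd, analysis = analysis,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# deterministic sub-seeds (patterns / simulation / fixtures) from one master
# seed, kept below 2^31
spawn_seeds <- function(seed) {
  s <- as.integer(seed)
  list(patterns = (s * 7919L + 1L) %% 2147483629L,
       sim = (s * 104729L + 2L) %% 2147483629L,
       fixture = (s * 1299709L + 3L) %% 2147483629L)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `path` (write) or the reconstructed `experiment_config` (read).
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  obj <- list(learning = strip(config$learning[setdiff(names(config$learning), "kernel")]),
              kernel = strip(config$learning$kernel),
              sim = strip(config$sim), stsd = strip(config$stsd),
              analysis = config$analysis, seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- c("learning", "kernel", "sim", "stsd", "analysis", "seed")
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  kern <- do.call(stdp_params, obj$kernel[c("T_p", "T_D", "eta")])
  lc <- obj$learning
  lc$kernel <- kern
  experiment_config(
    learning = do.call(learning_config, lc),
    sim = do.call(sim_config, obj$sim),
    stsd = do.call(stsd_config, obj$stsd),
    analysis = obj$analysis %||% list(),
    seed = obj$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze a spike raster: rates, regime, avalanches, waiting times, states
#'
#' Runs the whole analysis stack on the post-transient window of a raster:
#' 1-ms rate binning, regime classification, avalanche detection, power-law
#' fits of sizes and durations, waiting-time densities and fits under both
#' measures, up/down segmentation, and an exponential fit of the down-state
#' durations. Components that lack sufficient data (e.g. no avalanches in
#' the quiescent regime) are returned as `NULL` rather than failing.
#'
#' @param raster a `spike_raster`.
#' @param analysis list of analysis parameters as in [experiment_config()].
#' @return A list of class `raster_stats` with elements `rates`, `regime`,
#'   `mean_rate_hz`, `avalanches`, `size_fit`, `duration_fit`, `wt`,
#'   `wt_fit_lsq`, `wt_log_fit_lsq`, `wt_fit_mle`, `segments`, `down_fit`.
#' @export
analyze_raster <- function(raster, analysis = list()) {
  cfg <- experiment_config(analysis = analysis)$analysis
  rates <- bin_rates(raster, cfg$bin_ms)
  reg <- tryCatch(classify_regime(rates), error = function(e) NULL)
  av <- detect_avalanches(rates, cfg$r_min_hz)
  out <- list(rates = rates, regime = reg,
              mean_rate_hz = mean_rate(raster),
              avalanches = av,
              size_fit = NULL, duration_fit = NULL, wt = NULL,
              wt_fit_lsq = NULL, wt_log_fit_lsq = NULL, wt_fit_mle = NULL,
              segments = NULL, down_fit = NULL)
  if (nrow(av) >= 2) {
    out$size_fit <- tryCatch(
      fit_power_law(av$size, cfg$size_xmin, max(av$size)),
      error = function(e) NULL)
    out$duration_fit <- tryCatch(
      fit_power_law(av$duration_ms, cfg$dur_xmin_ms, max(av$duration_ms)),
      error = function(e) NULL)
    wt <- waiting_times(av)
    out$wt <- wt
    lo <- cfg$wt_range_ms[1]; hi <- cfg$wt_range_ms[2]
    out$wt_fit_mle <- tryCatch(fit_power_law(wt, lo, hi),
                               error = function(e) NULL)
    out$wt_fit_lsq <- tryCatch(density_slope(wt, lo, hi, "per_linear_bin"),
                               error = function(e) NULL)
    out$wt_log_fit_lsq <- tryCatch(density_slope(wt, lo, hi, "per_log_bin"),
                                   error = function(e) NULL)
    win <- c(raster$t_transient, raster$t_total)
    out$segments <- segment_up_down(av, cfg$t_max_ms, window = win)
    downs <- out$segments$duration_ms[out$segments$kind == "down"]
    out$down_fit <- tryCatch(fit_exponential(downs), error = function(e) NULL)
  }
  class(out) <- "raster_stats"
  out
}

# least-squares slope of a log-binned waiting-time density on [lo, hi];
# returns the density exponent gamma (density ~ x^-gamma)
density_slope <- function(dts, lo, hi, convention, n_bins = 12, min_n = 50) {
  sel <- dts[dts >= lo & dts <= hi]
  if (length(sel) < min_n)
    stop(sprintf("only %d waiting times in [%g, %g]", length(sel), lo, hi))
  d <- waiting_time_density(sel, convention, n_bins = n_bins)
  d <- d[d$count > 0, ]
  if (nrow(d) < 3) stop("too few occupied bins")
  fit <- stats::lm(log(density) ~ log(mid), data = d)
  list(exponent = -unname(stats::coef(fit)[2]), n = length(sel),
       convention = convention, range_ms = c(lo, hi))
}

#' @exportS3Method base::print
print.raster_stats <- function(x, ...) {
  cat(sprintf("raster_stats: mean rate %.3f Hz, %d avalanches\n",
              x$mean_rate_hz, nrow(x$avalanches)))
  if (!is.null(x$regime)) cat("  regime:", x$regime$label, "\n")
  if (!is.null(x$size_fit))
    cat(sprintf("  size exponent %.2f, duration exponent %.2f\n",
                x$size_fit$exponent,
                if (is.null(x$duration_fit)) NA else x$duration_fit$exponent))
  if (!is.null(x$wt_fit_lsq))
    cat(sprintf("  waiting-time exponents: linear %.2f, log-measure %.2f\n",
                x$wt_fit_lsq$exponent, x$wt_log_fit_lsq$exponent))
  invisible(x)
}

#' Run one full experiment: learn, prune, simulate, analyze
#'
#' Executes the pipeline with all potentials starting at zero, discards the
#' configured transient, and (optionally) writes the artifacts — weights,
#' raster, avalanche/segment tables (CSV), fits and regime label (JSON),
#' resolved config (YAML) — into `out_dir`. Deterministic for a fixed
#' master seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory; created if missing.
#' @return List of class `experiment_result`: `net` ([learn_network()]
#'   output), `raster`, `stats` ([analyze_raster()] output), `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- spawn_seeds(config$seed)
  lc <- config$learning
  lc$seed <- lc$seed %||% seeds$patterns
  sc <- config$sim
  sc$seed <- sc$seed %||% seeds$sim
  net <- learn_network(lc)
  raster <- simulate_network(net$W, sc, config$stsd)
  stats <- analyze_raster(raster, config$analysis)
  res <- structure(list(net = net, raster = raster, stats = stats,
                        config = config), class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
    write_weights(net$W, file.path(out_dir, "weights.rds"))
    write_raster(raster, file.path(out_dir, "raster.rds"))
    utils::write.csv(stats$avalanches, file.path(out_dir, "avalanches.csv"),
                     row.names = FALSE)
    if (!is.null(stats$segments))
      utils::write.csv(stats$segments, file.path(out_dir, "segments.csv"),
                       row.names = FALSE)
    if (!is.null(stats$wt))
      utils::write.csv(data.frame(dt_ms = stats$wt),
                       file.path(out_dir, "waiting_times.csv"),
                       row.names = FALSE)
    fits <- list(
      mean_rate_hz = stats$mean_rate_hz,
      regime = if (is.null(stats$regime)) NA else stats$regime$label,
      size_exponent = if (is.null(stats$size_fit)) NA else stats$size_fit$exponent,
      duration_exponent = if (is.null(stats$duration_fit)) NA else stats$duration_fit$exponent,
      wt_exponent_linear = if (is.null(stats$wt_fit_lsq)) NA else stats$wt_fit_lsq$exponent,
      wt_exponent_log = if (is.null(stats$wt_log_fit_lsq)) NA else stats$wt_log_fit_lsq$exponent,
      pos_fraction = net$pos_fraction, neg_fraction = net$neg_fraction,
      seed = config$seed)
    jsonlite::write_json(fits, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Sweep the phase diagram over a grid of (H0, alpha)
#'
#' For each grid cell and pattern realization: build the network, simulate,
#' and record the mean rate and regime label. Weights are learned once per
#' realization at H0 = 1 and rescaled — the imprinting rule is linear in H0
#' and the pruning procedure is scale-invariant row-wise, so the rescaled
#' matrix is exactly the matrix that would have been learned at that H0.
#' A sweep writing to `out_dir` is restartable: completed cells are skipped.
#'
#' @param h0_values,alpha_values grid coordinates (threshold units; 1/ms).
#' @param n_realizations pattern realizations per cell.
#' @param sim a [sim_config()] used for every cell (its `alpha` is
#'   overridden per cell).
#' @param learning a [learning_config()] (its `H0` is overridden per cell).
#' @param seed master seed.
#' @param out_dir optional directory for the per-cell CSV (restart support).
#' @return Data frame of class `phase_diagram`: one row per cell x
#'   realization with `h0`, `alpha`, `realization`, `mean_rate_hz`,
#'   `regime`, `duty_cycle` (fraction of 1-ms bins above 7 Hz).
#' @export
sweep_phase_diagram <- function(h0_values, alpha_values, n_realizations = 1,
                                sim = sim_config(alpha = 0.1, t_total = 30000,
                                                 t_transient = 5000),
                                learning = learning_config(),
                                seed = 1, out_dir = NULL) {
  stopifnot(length(h0_values) >= 1, length(alpha_values) >= 1)
  csv <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(out_dir, "phase_diagram.csv")
  } else NULL
  done <- if (!is.null(csv) && file.exists(csv)) utils::read.csv(csv)
          else data.frame()
  rows <- list()
  for (re in seq_len(n_realizations)) {
    seeds <- spawn_seeds(seed + 1000L * re)
    lc <- learning
    lc$H0 <- 1
    lc$seed <- seeds$patterns
    W1 <- NULL   # built lazily: skip learning if all cells are done
    for (h0 in h0_values) for (al in alpha_values) {
      if (nrow(done) > 0 &&
          any(done$h0 == h0 & done$alpha == al & done$realization == re)) next
      if (is.null(W1))
        W1 <- suppressWarnings(learn_network(lc))$W
      sc <- sim
      sc$alpha <- al
      sc$seed <- seeds$sim + round(1e6 * h0) + round(1e4 * al)
      raster <- simulate_network(W1 * h0, sc)
      rates <- bin_rates(raster)
      reg <- tryCatch(classify_regime(rates)$label, error = function(e) NA)
      av <- detect_avalanches(rates)
      n_up <- 0L; n_down <- 0L; med_up <- NA_real_
      if (nrow(av) >= 2) {
        segs <- segment_up_down(av, 50, window = c(raster$t_transient,
                                                   raster$t_total))
        n_up <- sum(segs$kind == "up")
        n_down <- sum(segs$kind == "down")
        if (n_up > 0)
          med_up <- stats::median(segs$duration_ms[segs$kind == "up"])
      }
      row <- data.frame(h0 = h0, alpha = al, realization = re,
                        mean_rate_hz = mean_rate(raster),
                        regime = reg,
                        duty_cycle = mean(rates$rates > 7),
                        n_up = n_up, n_down = n_down, med_up_ms = med_up)
      rows[[length(rows) + 1]] <- row
      if (!is.null(csv))
        utils::write.table(row, csv, sep = ",", row.names = FALSE,
                           col.names = !file.exists(csv), append = file.exists(csv))
    }
  }
  out <- rbind(done, do.call(rbind, c(list(data.frame()), rows)))
  class(out) <- c("phase_diagram", class(out))
  out
}

#' Locate the up/down alternation (bimodal) operating point
#'
#' The alternation band is narrow and its position depends on the quenched
#' pattern realization, so it must be located for the very network under
#' study. This routine holds the noise level fixed at a moderate value
#' (where threshold crossings from noise alone stay far below the avalanche
#' threshold) and bisects on the connection strength, along which the
#' dynamics pass monotonically from quiescence through alternation to
#' permanent replay. Each probe simulation is classified from its up/down
#' timeline: *alternating* requires at least `min_switches` up states and
#' as many down states (noise both ignites and terminates replay) plus a
#' minimum up-state duty cycle; *saturated* means activity occupies most of
#' the window; anything else is *quiet*. Quiet probes raise the strength,
#' saturated probes lower it; the search stops at the first alternating
#' probe. The classification looks only at the up/down timeline, never at
#' avalanche exponents, so downstream exponent measurements at the returned
#' point are not conditioned on their own outcome.
#'
#' Because switching slows down as the noise level drops, the search starts
#' at the largest candidate noise level and walks down the list, keeping the
#' lowest level at which alternation is still observed within the probe
#' window — the closest desk-scale approximation to the low-noise regime in
#' which up/down statistics are defined. The first level that fails after a
#' success ends the descent.
#'
#' @param W the network's weight matrix at `H0` = 1 (from a
#'   [learn_network()] call with `H0 = 1`); it is scaled by the probe
#'   strength internally.
#' @param alphas candidate noise levels (1/ms), tried from largest to
#'   smallest.
#' @param h0_range search interval for the connection strength (threshold
#'   units).
#' @param sim a [sim_config()] template for the probe runs (its `alpha` is
#'   overridden).
#' @param min_switches up/down switches required to call a probe
#'   alternating (default 3).
#' @param min_duty minimum fraction of super-threshold bins for an
#'   alternating probe (default 0.01), guarding against sparse
#'   noise-crossing excursions masquerading as up states.
#' @param max_probes bisection budget per noise level (default 6).
#' @param seed seed for the probe simulations.
#' @return List: `h0`, `alpha` (the alternating point), `probes` (data
#'   frame of all probes with their classification).
#' @export
find_bimodal_point <- function(W, alphas = c(0.20, 0.18, 0.16, 0.14, 0.12),
                               h0_range = c(0.16, 0.30),
                               sim = sim_config(alpha = 0.1, t_total = 30000,
                                                t_transient = 5000),
                               min_switches = 3, min_duty = 0.01,
                               max_probes = 6, seed = 1) {
  stopifnot(nrow(W) == ncol(W), length(h0_range) == 2,
            h0_range[2] > h0_range[1])
  probes <- data.frame()
  best <- NULL
  for (alpha in sort(alphas, decreasing = TRUE)) {
    lo <- h0_range[1]; hi <- h0_range[2]
    found <- NULL
    for (k in seq_len(max_probes)) {
      h0 <- (lo + hi) / 2
      sc <- sim
      sc$alpha <- alpha
      sc$seed <- seed + k + round(1e4 * alpha)
      raster <- simulate_network(W * h0, sc)
      rates <- bin_rates(raster)
      av <- detect_avalanches(rates)
      n_up <- 0L; n_down <- 0L
      if (nrow(av) >= 2) {
        segs <- segment_up_down(av, 50, window = c(raster$t_transient,
                                                   raster$t_total))
        n_up <- sum(segs$kind == "up")
        n_down <- sum(segs$kind == "down")
      }
      duty <- mean(rates$rates > 7)
      state <- if (n_up >= min_switches && n_down >= min_switches &&
                   duty >= min_duty) "alternating"
               else if (duty > 0.3) "saturated"
               else "quiet"
      probes <- rbind(probes, data.frame(alpha = alpha, h0 = h0,
                                         state = state, n_up = n_up,
                                         n_down = n_down, duty_cycle = duty,
                                         mean_rate_hz = mean_rate(raster)))
      if (state == "alternating") { found <- h0; break }
      if (state == "quiet") lo <- h0 else hi <- h0
    }
    if (!is.null(found)) {
      best <- list(h0 = found, alpha = alpha)
    } else if (!is.null(best)) {
      break   # switching became too rare to observe; keep the last success
    }
  }
  if (is.null(best))
    stop("no alternating point found over the candidate noise levels")
  c(best, list(probes = probes))
}

#' Deterministic toy fixtures for the analysis stack
#'
#' Small synthetic objects with planted, known structure, used to test the
#' analysis operations without running a full simulation:
#' \describe{
#'   \item{`toy-rates`}{a `rate_series` with avalanches planted at known
#'     positions (`params$avalanches`: data frame `start_bin`, `duration`,
#'     `rate_hz`) on a silent background.}
#'   \item{`toy-raster`}{a `spike_raster` replaying `params$pattern` for
#'     `params$n_cycles` cycles (cycle length `params$cycle_ms`), plus
#'     Poisson background spikes at `params$bg_hz` per neuron.}
#'   \item{`toy-weights`}{a small learned-and-pruned network
#'     ([learn_network()]) with `params$N` neurons, `params$P` patterns.}
#' }
#'
#' @param kind one of `"toy-rates"`, `"toy-raster"`, `"toy-weights"`.
#' @param params named list of kind-specific parameters (see Details).
#' @param seed RNG seed; fixtures are reproducible.
#' @param path optional file path; the fixture is also written there
#'   (RDS for weights/raster, CSV of counts for rates).
#' @return The fixture object.
#' @export
make_fixture <- function(kind, params = list(), seed = 1, path = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fx <- switch(kind,
    "toy-rates" = {
      p <- utils::modifyList(list(n_bins = 1000, n_neurons = 1000,
        avalanches = data.frame(start_bin = c(100, 300), duration = c(5, 12),
                                rate_hz = c(20, 15))), params)
      counts <- integer(p$n_bins)
      for (k in seq_len(nrow(p$avalanches))) {
        a <- p$avalanches[k, ]
        idx <- a$start_bin:(a$start_bin + a$duration - 1)
        counts[idx] <- round(a$rate_hz * p$n_neurons * 1e-3)
      }
      rate_series(counts, p$n_neurons)
    },
    "toy-raster" = {
      p <- utils::modifyList(list(N = 200, cycle_ms = 100, n_cycles = 3,
                                  bg_hz = 0.5, pattern = NULL), params)
      pat <- p$pattern %||% make_patterns(p$N, 1, p$cycle_ms)[[1]]
      N <- length(pat$phases)
      t_rep <- as.vector(outer(pat$phases / (2 * pi) * p$cycle_ms,
                               (0:(p$n_cycles - 1)) * p$cycle_ms, "+"))
      id_rep <- rep(seq_len(N), p$n_cycles)
      t_total <- p$n_cycles * p$cycle_ms
      n_bg <- stats::rpois(1, p$bg_hz * N * t_total / 1000)
      t_bg <- stats::runif(n_bg, 0, t_total)
      id_bg <- sample.int(N, n_bg, replace = TRUE)
      o <- order(c(t_rep, t_bg))
      structure(
        list(times = c(t_rep, t_bg)[o], ids = c(id_rep, id_bg)[o],
             n_neurons = N, t_total = t_total, t_transient = 0,
             config = list(seed = seed), stsd = NULL, pattern = pat),
        class = "spike_raster")
    },
    "toy-weights" = {
      p <- utils::modifyList(list(N = 120, P = 1, H0 = 0.221), params)
      suppressWarnings(learn_network(
        learning_config(N = p$N, P = p$P, H0 = p$H0, seed = seed)))
    },
    stop("unknown fixture kind: ", kind)
  )
  if (!is.null(path)) {
    if (kind == "toy-rates")
      utils::write.csv(data.frame(count = fx$counts), path, row.names = FALSE)
    else saveRDS(fx, path)
  }
  fx
}
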