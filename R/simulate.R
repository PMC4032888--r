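#' Simulation configuration
#'
#' Parameters of the noisy leaky integrate-and-fire dynamics. Each neuron
#' receives, besides recurrent input, a Poisson stream (rate `rho` per ms) of
#' noise impulses whose Gaussian amplitudes scale with `alpha`, the noise
#' level of the network. The membrane responds to every impulse with the
#' double-exponential kernel of [epsilon_kernel()]; crossing the threshold
#' `theta` emits a spike and resets both membrane and synaptic trace to zero,
#' discarding all input received before the spike.
#'
#' The noise amplitude for neuron i is, under the default
#' `noise_convention = "sqrt_alpha"`,
#' \eqn{\sigma_i = \sqrt{(\alpha/\rho) \sum_j J_{ij}^2}} with `alpha` and
#' `rho` in 1/ms; at the standard event rate \eqn{\rho = 1} ms\eqn{^{-1}}
#' this coincides with \eqn{\sqrt{\alpha\rho\sum_j J_{ij}^2}} and is the
#' calibration under which the network's quiescent/replay phase boundary
#' falls nearest the reference coordinates used throughout. The variant
#' `"alpha_sqrt"` uses \eqn{\sigma_i = \alpha \sqrt{\rho \sum_j J_{ij}^2}}
#' (noise linear in `alpha`) instead.
#'
#' @param alpha noise level, 1/ms.
#' @param tau_m membrane time constant, ms.
#' @param tau_s synaptic time constant, ms.
#' @param theta spiking threshold (weights are expressed in its units).
#' @param rho per-neuron noise event rate, 1/ms.
#' @param dt integration step, ms; must satisfy `dt <= tau_s / 10`.
#' @param t_total simulated duration, ms.
#' @param t_transient initial duration discarded from analysis, ms.
#' @param max_spikes stop once this many spikes occurred after the
#'   transient (0 = no cap).
#' @param noise_convention `"alpha_sqrt"` or `"sqrt_alpha"` (see Details).
#' @param seed optional integer RNG seed for the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(alpha, tau_m = 10, tau_s = 5, theta = 1, rho = 1,
                       dt = 0.1, t_total = 40000, t_transient = 10000,
                       max_spikes = 0,
                       noise_convention = c("sqrt_alpha", "alpha_sqrt"),
                       seed = NULL) {
  noise_convention <- match.arg(noise_convention)
  stopifnot(tau_m > tau_s, tau_s > 0, dt > 0, dt <= tau_s / 10,
            alpha >= 0, rho >= 0, theta > 0,
            t_total > t_transient, t_transient >= 0, max_spikes >= 0)
  structure(
    list(alpha = alpha, tau_m = tau_m, tau_s = tau_s, theta = theta,
         rho = rho, dt = dt, t_total = t_total, t_transient = t_transient,
         max_spikes = max_spikes, noise_convention = noise_convention,
         seed = seed),
    class = "sim_config"
  )
}

#' Short-term synaptic depression configuration
#'
#' When enabled, every synapse carries a dynamic value that relaxes to its
#' learned resting value with time constant `tau_r` and is multiplied by
#' `f_stsd` each time its presynaptic neuron fires.
#'
#' @param enabled logical.
#' @param tau_r recovery time constant, ms.
#' @param f_stsd multiplicative depression factor per presynaptic spike.
#' @return An object of class `stsd_config`.
#' @export
stsd_config <- function(enabled = FALSE, tau_r = 10, f_stsd = 0.5) {
  stopifnot(is.logical(enabled), tau_r > 0, f_stsd > 0, f_stsd <= 1)
  structure(list(enabled = enabled, tau_r = tau_r, f_stsd = f_stsd),
            class = "stsd_config")
}

#' Per-neuron noise amplitude
#'
#' @param W weight matrix (dense or sparse), rows = postsynaptic neurons.
#' @param config a [sim_config()].
#' @return Numeric vector of per-neuron Gaussian amplitude SDs
#'   \eqn{\sigma_i}, units of the threshold.
#' @export
noise_sigma <- function(W, config) {
  stopifnot(inherits(config, "sim_config"))
  row_energy <- Matrix::rowSums(W * W)
  if (config$noise_convention == "alpha_sqrt") {
    config$alpha * sqrt(config$rho * row_energy)
  } else {
    sqrt((config$alpha / config$rho) * row_energy)
  }
}

#' Draw one step of noise impulses (reference sampler)
#'
#' Reference implementation of the noise process used inside the compiled
#' simulator: per neuron and step, a Poisson(`rho * dt`) count of impulses,
#' each with an independent zero-mean Gaussian amplitude of that neuron's
#' sigma. Exposed for testing the sampler's moments; the simulator draws the
#' identical process (network-total Poisson count thinned uniformly over
#' neurons).
#'
#' @param sigma per-neuron amplitude SDs (from [noise_sigma()]).
#' @param rho noise event rate, 1/ms.
#' @param dt step, ms.
#' @return Numeric vector: summed impulse amplitude per neuron for one step.
#' @export
draw_noise <- function(sigma, rho, dt) {
  stopifnot(all(sigma >= 0))
  counts <- stats::rpois(length(sigma), rho * dt)
  amp <- numeric(length(sigma))
  hit <- counts > 0
  # sum of k iid N(0, sigma^2) is N(0, k sigma^2)
  amp[hit] <- sigma[hit] * sqrt(counts[hit]) * stats::rnorm(sum(hit))
  amp
}

#' Simulate the noisy LIF network
#'
#' Clock-driven integration with exact exponential propagators: between
#' events the pair (v, s) obeys \eqn{dv/dt = -v/\tau_m + (1/\tau_s -
#' 1/\tau_m) s}, \eqn{ds/dt = -s/\tau_s}, reproducing
#' \eqn{V(t) = \sum J\,\epsilon(t - t_{event})} exactly at step boundaries.
#' Spikes of presynaptic neuron j add column j of `W` to the targets' traces
#' starting the following step; noise impulses enter the trace the same way.
#' A threshold crossing resets v and s of the spiking neuron to zero.
#'
#' @param W N x N weight matrix (dense matrix or `Matrix` sparse), row i =
#'   incoming connections of neuron i.
#' @param config a [sim_config()].
#' @param stsd an [stsd_config()]; depression disabled by default.
#' @param external optional data frame of test impulses with columns
#'   `time` (ms), `neuron` (1-based id), `amp`; delivered at the step
#'   boundary `floor(time / dt)`.
#' @param record_v if `TRUE`, also return the membrane trajectory of every
#'   neuron at each step boundary (only sensible for tiny N).
#' @return An object of class `spike_raster`: list with `times` (ms,
#'   sorted), `ids` (1-based neuron ids), `n_neurons`, `t_total` (actual
#'   simulated end time), `t_transient`, `config`, and optionally `v_trace`.
#' @export
simulate_network <- function(W, config, stsd = stsd_config(),
                             external = NULL, record_v = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(stsd, "stsd_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  # coerce before taking dimensions: a matrix restored from RDS may carry an
  # S4 class whose package namespace is not loaded yet
  Wc <- methods::as(methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                            "dMatrix"), "generalMatrix"), "CsparseMatrix")
  N <- nrow(Wc)
  stopifnot(is.numeric(N), length(N) == 1, ncol(Wc) == N)
  sigma <- noise_sigma(Wc, config)
  if (is.null(external)) {
    ev_step <- integer(0); ev_neuron <- integer(0); ev_amp <- numeric(0)
  } else {
    stopifnot(all(c("time", "neuron", "amp") %in% names(external)))
    o <- order(external$time)
    ev_step <- as.integer(floor(external$time[o] / config$dt))
    ev_neuron <- as.integer(external$neuron[o]) - 1L
    ev_amp <- as.numeric(external$amp[o])
    stopifnot(all(ev_neuron >= 0), all(ev_neuron < N))
  }
  res <- sim_lif_cpp(Wc@p, Wc@i, Wc@x, N, sigma,
                     config$tau_m, config$tau_s, config$theta, config$rho,
                     config$dt, config$t_total, config$t_transient,
                     config$max_spikes,
                     stsd$enabled, stsd$tau_r, stsd$f_stsd,
                     ev_step, ev_neuron, ev_amp, record_v)
  out <- structure(
    list(times = res$times, ids = res$ids + 1L, n_neurons = N,
         t_total = res$t_end, t_transient = config$t_transient,
         config = config, stsd = stsd),
    class = "spike_raster"
  )
  if (record_v) out$v_trace <- res$v_trace
  out
}

#' @exportS3Method base::print
print.spike_raster <- function(x, ...) {
  dur_s <- x$t_total / 1000
  cat(sprintf("spike_raster: %d spikes, %d neurons, %.1f s simulated\n",
              length(x$times), x$n_neurons, dur_s))
  win <- x$t_total - x$t_transient
  n_post <- sum(x$times > x$t_transient)
  if (win > 0)
    cat(sprintf("  mean rate after transient: %.3f Hz/neuron\n",
                n_post / (x$n_neurons * win / 1000)))
  invisible(x)
}

#' Mean firing rate per neuron
#'
#' @param raster a `spike_raster`.
#' @param from,to analysis window in ms; defaults to the post-transient
#'   window.
#' @return Mean rate in Hz per neuron over the window.
#' @export
mean_rate <- function(raster, from = raster$t_transient, to = raster$t_total) {
  stopifnot(inherits(raster, "spike_raster"), to > from)
  n <- sum(raster$times > from & raster$times <= to)
  n / (raster$n_neurons * (to - from) / 1000)
}

#' One step of short-term synaptic depression (reference implementation)
#'
#' Matrix-level reference for the depression dynamics used by the compiled
#' simulator: the dynamic matrix relaxes elementwise toward the resting
#' matrix `J0` with time constant `tau_r` over one step of length `dt`, and
#' every column whose presynaptic neuron fired in this step is then
#' multiplied by `f_stsd`.
#'
#' @param J_dyn current dynamic weight matrix.
#' @param J0 resting (learned) weight matrix.
#' @param spiked integer vector of presynaptic neurons that fired this step.
#' @param dt step, ms.
#' @param stsd an [stsd_config()].
#' @return Updated dynamic matrix.
#' @export
depress_and_recover <- function(J_dyn, J0, spiked, dt, stsd = stsd_config(TRUE)) {
  stopifnot(inherits(stsd, "stsd_config"), stsd$enabled)
  J_dyn <- J0 + (J_dyn - J0) * exp(-dt / stsd$tau_r)
  if (length(spiked) > 0)
    J_dyn[, spiked] <- J_dyn[, spiked, drop = FALSE] * stsd$f_stsd
  J_dyn
}
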