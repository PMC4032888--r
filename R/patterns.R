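#' Generate random phase-coded spatiotemporal patterns
#'
#' A phase-coded pattern assigns each neuron a phase \eqn{\phi_i \in [0, 2\pi)};
#' during one cycle of period `T` the neuron fires once, at
#' \eqn{t_i = (\phi_i / 2\pi) T}. Phases are drawn i.i.d. uniform on
#' \eqn{[0, 2\pi)} and then quenched; they define both the training spike
#' trains used to build the synaptic matrix and the reference order against
#' which replay is scored.
#'
#' @param N number of neurons (> 1).
#' @param P number of patterns (>= 1).
#' @param T_ms pattern period in ms.
#' @param seed optional integer seed; if supplied the RNG state is set
#'   locally so the call is reproducible and does not disturb the caller's
#'   RNG stream.
#' @return A list of `P` objects of class `phase_pattern`, each with fields
#'   `phases` (length `N`), `period` (ms) and `pattern_id`.
#' @examples
#' pats <- make_patterns(N = 100, P = 2, T_ms = 333, seed = 1)
#' spike_times(pats[[1]])[1:5]
#' @export
make_patterns <- function(N, P, T_ms = 333, seed = NULL) {
  if (!is.numeric(N) || N <= 1) stop("`N` must be > 1")
  if (!is.numeric(P) || P < 1) stop("`P` must be >= 1")
  if (!is.numeric(T_ms) || T_ms <= 0) stop("`T_ms` must be > 0")
  N <- as.integer(N); P <- as.integer(P)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lapply(seq_len(P), function(mu) {
    structure(
      list(phases = stats::runif(N, 0, 2 * pi), period = T_ms, pattern_id = mu),
      class = "phase_pattern"
    )
  })
}

#' @exportS3Method base::print
print.phase_pattern <- function(x, ...) {
  cat(sprintf("phase_pattern %d: %d neurons, period %g ms\n",
              x$pattern_id, length(x$phases), x$period))
  invisible(x)
}

#' Spike times of one cycle of a phase-coded pattern
#'
#' @param pattern a `phase_pattern`.
#' @return Numeric vector of within-cycle spike times in ms,
#'   \eqn{t_i = (\phi_i/2\pi) T}, one entry per neuron.
#' @export
spike_times <- function(pattern) {
  stopifnot(inherits(pattern, "phase_pattern"))
  pattern$phases / (2 * pi) * pattern$period
}

#' Select the leader neurons of a pattern
#'
#' Leaders are a small consecutive-phase block of neurons — the ones with the
#' lowest phases — whose incoming connections are amplified during learning
#' (strength \eqn{H_1 = 3 H_0} by default). Their role is to collect and
#' amplify noise-initiated activity into a cue that can start a collective
#' replay of the pattern.
#'
#' @param pattern a `phase_pattern`.
#' @param fraction fraction of neurons designated as leaders (default 0.03).
#' @return Integer vector of neuron indices: the `ceiling(fraction * N)`
#'   neurons with the smallest phases (ties broken by neuron index).
#' @export
select_leaders <- function(pattern, fraction = 0.03) {
  stopifnot(inherits(pattern, "phase_pattern"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)")
  N <- length(pattern$phases)
  if (N == 0L) stop("pattern has no neurons")
  k <- ceiling(fraction * N)
  order(pattern$phases, seq_len(N))[seq_len(k)]
}
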