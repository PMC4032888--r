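#' Learning configuration
#'
#' Bundles every parameter of the connectivity-design stage: pattern
#' generation, STDP imprinting with leader amplification, and competitive
#' pruning. `H0` is the baseline connection strength in units of the spiking
#' threshold; leaders of each pattern get `H1 = leader_multiplier * H0` on
#' their incoming connections for that pattern's contribution.
#'
#' `n_window` controls how many pattern cycles on each side enter the wrap
#' sum of the imprinting rule. The default 0 evaluates the kernel at the bare
#' within-cycle lag; this is the calibration that reproduces the published
#' connectivity statistics of the model (about 12% positive and 27% negative
#' survivors after pruning at the default parameters). With `n_window >= 1`
#' the periodic wrap sum is applied instead; the kernel's zero integral then
#' cancels the slow tails and drives pre-pruning row sums to O(1/N), at the
#' price of a smaller positive fraction (about 32% instead of 41%). Terms
#' beyond three periods are below 1e-9 of the kernel peak at the default
#' window parameters, so `n_window = 3` is effectively the infinite sum.
#'
#' @param N neuron count (> 1).
#' @param P pattern count (>= 1).
#' @param T_ms pattern period (ms).
#' @param H0 baseline connection strength, units of the threshold.
#' @param leader_multiplier ratio H1/H0 applied to leader neurons (default 3).
#' @param leader_fraction fraction of neurons per pattern that are leaders
#'   (default 0.03).
#' @param n_window wrap-sum truncation, in periods on each side (default 0:
#'   bare within-cycle lag).
#' @param f_plus_prune fraction of each neuron's positive incoming
#'   connections deleted during pruning (default 0.70).
#' @param kernel an [stdp_params()] object.
#' @param seed optional RNG seed used when the config is handed to
#'   [learn_network()].
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(N = 3000, P = 2, T_ms = 333, H0 = 0.221,
                            leader_multiplier = 3, leader_fraction = 0.03,
                            n_window = 0, f_plus_prune = 0.70,
                            kernel = stdp_params(), seed = NULL) {
  stopifnot(N > 1, P >= 1, T_ms > 0,
            leader_fraction > 0, leader_fraction < 1,
            f_plus_prune >= 0, f_plus_prune < 1,
            n_window >= 0, inherits(kernel, "stdp_params"))
  structure(
    list(N = as.integer(N), P = as.integer(P), T_ms = T_ms, H0 = H0,
         leader_multiplier = leader_multiplier,
         leader_fraction = leader_fraction,
         n_window = as.integer(n_window), f_plus_prune = f_plus_prune,
         kernel = kernel, seed = seed),
    class = "learning_config"
  )
}

kernel_wrap_sum <- function(D, T_ms, n_window, params) {
  K <- stdp_kernel(as.vector(D), params)
  if (n_window > 0) {
    for (n in seq_len(n_window)) {
      K <- K + stdp_kernel(as.vector(D) + n * T_ms, params) +
        stdp_kernel(as.vector(D) - n * T_ms, params)
    }
  }
  dim(K) <- dim(D)
  K
}

#' Imprint phase-coded patterns on the synaptic matrix
#'
#' Each stored pattern contributes
#' \deqn{\delta J_{ij}^{\mu} = H_i \sum_{n} A(t_j^{\mu} - t_i^{\mu} + n T^{\mu})}
#' where \eqn{A} is the balanced STDP window, \eqn{t_i^{\mu}} the within-cycle
#' spike time of neuron \eqn{i}, and \eqn{H_i} equals `H1` for that pattern's
#' leader neurons and `H0` otherwise. The stored matrix is the plain sum of
#' the per-pattern contributions; self-connections are structurally zero.
#' Under the wrap-summed variant (`n_window >= 1`) the window's zero integral
#' together with uniform phases makes row sums O(1/N) relative to typical
#' weights — excitation and inhibition arrive balanced even before pruning;
#' under the bare-lag default the balance is instead enforced by [prune()].
#'
#' @param patterns list of `phase_pattern` objects sharing the same `N`.
#' @param config a [learning_config()].
#' @return An N x N dense matrix of weights `J[i, j]` (postsynaptic row `i`,
#'   presynaptic column `j`) in units of the threshold, with attribute
#'   `leaders` (list of per-pattern leader index vectors).
#' @export
learn_weights <- function(patterns, config) {
  stopifnot(inherits(config, "learning_config"))
  stopifnot(length(patterns) >= 1)
  Ns <- vapply(patterns, function(p) length(p$phases), integer(1))
  if (length(unique(Ns)) != 1L) stop("patterns disagree on neuron count N")
  N <- Ns[[1]]
  J <- matrix(0, N, N)
  leaders <- vector("list", length(patterns))
  for (k in seq_along(patterns)) {
    pat <- patterns[[k]]
    t_mu <- spike_times(pat)
    # D[i, j] = t_j - t_i (post-minus-pre lag within one cycle)
    D <- matrix(t_mu, N, N, byrow = TRUE) - t_mu
    K <- kernel_wrap_sum(D, pat$period, config$n_window, config$kernel)
    lead <- select_leaders(pat, config$leader_fraction)
    leaders[[k]] <- lead
    H <- rep(config$H0, N)
    H[lead] <- config$H0 * config$leader_multiplier
    J <- J + H * K   # H recycles down columns: scales row i by H_i
  }
  diag(J) <- 0
  attr(J, "leaders") <- leaders
  J
}

#' Prune the learned matrix, balancing excitation and inhibition per neuron
#'
#' For every postsynaptic neuron the weakest `f_plus_prune` fraction of its
#' positive incoming connections is deleted outright; negative incoming
#' connections are then deleted in increasing order of absolute value,
#' stopping at the deletion count that brings the neuron's total incoming
#' weight as close as possible to zero. The result is a sparse matrix in
#' which roughly the strongest third of excitation survives, matched by just
#' enough inhibition to cancel it.
#'
#' When two deletion counts give equally small |row sum| the larger number of
#' surviving negatives is kept. Rows lacking positive or negative entries are
#' passed through unchanged with a warning (they cannot be balanced).
#'
#' @param J dense square weight matrix with zero diagonal (from
#'   [learn_weights()]).
#' @param f_plus_prune fraction of positive incoming weights deleted
#'   (default 0.70).
#' @return A `Matrix::dgCMatrix` of surviving weights with attributes
#'   `pos_survivors` and `neg_survivors` (per-row counts).
#' @export
prune <- function(J, f_plus_prune = 0.70) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  if (any(diag(J) != 0)) stop("diagonal of J must be zero")
  stopifnot(f_plus_prune >= 0, f_plus_prune < 1)
  N <- nrow(J)
  out <- matrix(0, N, N)
  pos_surv <- integer(N)
  neg_surv <- integer(N)
  degenerate <- integer(0)
  for (i in seq_len(N)) {
    row <- J[i, ]
    pos <- which(row > 0)
    neg <- which(row < 0)
    if (length(pos) == 0L || length(neg) == 0L) {
      # cannot balance: prune positives if any, keep the rest, warn
      degenerate <- c(degenerate, i)
      if (length(pos) > 0L) {
        n_del <- round(f_plus_prune * length(pos))
        keep_pos <- pos[order(row[pos], decreasing = TRUE)][seq_len(length(pos) - n_del)]
        out[i, keep_pos] <- row[keep_pos]
        pos_surv[i] <- length(keep_pos)
      }
      if (length(neg) > 0L) {
        out[i, neg] <- row[neg]
        neg_surv[i] <- length(neg)
      }
      next
    }
    n_del <- round(f_plus_prune * length(pos))
    keep_pos <- pos[order(row[pos], decreasing = TRUE)][seq_len(length(pos) - n_del)]
    pos_sum <- sum(row[keep_pos])
    # negatives ordered by |value| ascending: candidates for deletion first
    neg_ord <- neg[order(-row[neg])]          # -row ascending == |value| ascending
    vals <- row[neg_ord]
    total_neg <- sum(vals)
    # deleting the k smallest-|value| negatives retains total_neg - prefix(k)
    prefix <- c(0, cumsum(vals))              # prefix[k+1] = sum of k smallest |value|
    retained <- total_neg - prefix
    k_best <- which.min(abs(pos_sum + retained)) - 1L  # ties -> smallest k
    keep_neg <- if (k_best < length(neg_ord)) neg_ord[(k_best + 1L):length(neg_ord)] else integer(0)
    out[i, keep_pos] <- row[keep_pos]
    out[i, keep_neg] <- row[keep_neg]
    pos_surv[i] <- length(keep_pos)
    neg_surv[i] <- length(keep_neg)
  }
  if (length(degenerate) > 0)
    warning(sprintf("%d row(s) had no positive or no negative weights; passed through unbalanced (first: %d)",
                    length(degenerate), degenerate[1]))
  W <- methods::as(methods::as(Matrix::Matrix(out, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  attr(W, "pos_survivors") <- pos_surv
  attr(W, "neg_survivors") <- neg_surv
  W
}

#' Full connectivity-design pipeline
#'
#' Convenience wrapper: generate patterns, imprint them, prune. Returns the
#' pruned sparse matrix together with the patterns and survivor statistics.
#'
#' @param config a [learning_config()].
#' @return A list of class `learned_network`: `W` (sparse pruned matrix),
#'   `patterns`, `config`, `pos_fraction`, `neg_fraction` (survivors as
#'   fractions of the N(N-1) ordered pairs).
#' @export
learn_network <- function(config) {
  stopifnot(inherits(config, "learning_config"))
  patterns <- make_patterns(config$N, config$P, config$T_ms, seed = config$seed)
  J <- learn_weights(patterns, config)
  W <- prune(J, config$f_plus_prune)
  n_pairs <- config$N * (config$N - 1)
  structure(
    list(W = W, patterns = patterns, config = config,
         pos_fraction = sum(attr(W, "pos_survivors")) / n_pairs,
         neg_fraction = sum(attr(W, "neg_survivors")) / n_pairs),
    class = "learned_network"
  )
}

#' @exportS3Method base::print
print.learned_network <- function(x, ...) {
  cat(sprintf("learned_network: N = %d, P = %d, H0 = %g\n",
              x$config$N, x$config$P, x$config$H0))
  cat(sprintf("  survivors: %.1f%% positive, %.1f%% negative of N(N-1)\n",
              100 * x$pos_fraction, 100 * x$neg_fraction))
  invisible(x)
}
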