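#' STDP learning-window parameters
#'
#' Builds the parameter set of the asymmetric, balanced STDP learning window
#' \eqn{A(\tau)} used to imprint phase-coded patterns on the synaptic matrix.
#' The window is
#' \deqn{A(\tau) = a_p e^{-\tau/T_p} - a_D e^{-\eta\tau/T_p}, \quad \tau > 0}
#' \deqn{A(\tau) = a_p e^{\eta\tau/T_D} - a_D e^{\tau/T_D}, \quad \tau < 0}
#' with amplitudes fixed by the time constants,
#' \eqn{a_p = [1 + \eta T_p/T_D]^{-1}} and \eqn{a_D = [\eta + T_p/T_D]^{-1}},
#' which makes the window balanced: \eqn{\int_{-\infty}^{\infty} A(\tau)\,d\tau = 0}.
#' Balance is what keeps total excitation and inhibition of each neuron close
#' to zero after learning patterns with uniformly distributed phases.
#'
#' @param T_p potentiation time constant (ms).
#' @param T_D depression time constant (ms).
#' @param eta asymmetry exponent (dimensionless).
#' @return An object of class `stdp_params` with fields `T_p`, `T_D`, `eta`
#'   and the derived amplitudes `a_p`, `a_D`.
#' @examples
#' p <- stdp_params()
#' # closed-form balance: a_p (T_p + T_D/eta) == a_D (T_p/eta + T_D)
#' p$a_p * (p$T_p + p$T_D / p$eta) - p$a_D * (p$T_p / p$eta + p$T_D)
#' @export
stdp_params <- function(T_p = 10.2, T_D = 28.6, eta = 4) {
  stopifnot(is.numeric(T_p), T_p > 0, is.numeric(T_D), T_D > 0,
            is.numeric(eta), eta > 0)
  structure(
    list(T_p = T_p, T_D = T_D, eta = eta,
         a_p = 1 / (1 + eta * T_p / T_D),
         a_D = 1 / (eta + T_p / T_D)),
    class = "stdp_params"
  )
}

#' @exportS3Method base::print
print.stdp_params <- function(x, ...) {
  cat("STDP learning window A(tau)\n")
  cat(sprintf("  T_p = %g ms, T_D = %g ms, eta = %g\n", x$T_p, x$T_D, x$eta))
  cat(sprintf("  a_p = %.6f, a_D = %.6f (balanced: integral A = 0)\n",
              x$a_p, x$a_D))
  invisible(x)
}

#' Evaluate the STDP learning window
#'
#' Signed synaptic-change kernel as a function of the post-minus-pre spike lag
#' `tau` (ms). Vectorized over `tau`. Both one-sided branches meet at
#' \eqn{A(0) = a_p - a_D}, so the window is continuous.
#'
#' @param tau time lag(s) in ms (post-synaptic minus pre-synaptic spike time).
#' @param params an [stdp_params()] object.
#' @return Kernel value(s), dimensionless.
#' @examples
#' stdp_kernel(0)                     # a_p - a_D
#' stdp_kernel(c(-20, -5, 0, 5, 20))
#' @export
stdp_kernel <- function(tau, params = stdp_params()) {
  if (!inherits(params, "stdp_params")) stop("`params` must be an stdp_params object")
  if (!is.numeric(tau) || anyNA(tau) || any(!is.finite(tau)))
    stop("`tau` must be finite numeric")
  a_p <- params$a_p; a_D <- params$a_D
  T_p <- params$T_p; T_D <- params$T_D; eta <- params$eta
  out <- numeric(length(tau))
  pos <- tau >= 0
  out[pos] <- a_p * exp(-tau[pos] / T_p) - a_D * exp(-eta * tau[pos] / T_p)
  out[!pos] <- a_p * exp(eta * tau[!pos] / T_D) - a_D * exp(tau[!pos] / T_D)
  out
}

#' Double-exponential postsynaptic potential kernel
#'
#' The membrane response to a unit synaptic impulse,
#' \eqn{\epsilon(t) = e^{-t/\tau_m} - e^{-t/\tau_s}} for \eqn{t \ge 0}.
#' It vanishes at \eqn{t = 0}, peaks at
#' \eqn{t^* = \frac{\tau_m \tau_s}{\tau_m - \tau_s}\ln(\tau_m/\tau_s)}
#' (\eqn{10\ln 2 \approx 6.93} ms at the defaults, where the peak value is
#' exactly 1/4), and decays with the membrane time constant.
#'
#' @param t time(s) since the impulse, ms; must be non-negative.
#' @param tau_m membrane time constant (ms).
#' @param tau_s synaptic time constant (ms).
#' @return Kernel value(s), dimensionless.
#' @examples
#' epsilon_kernel(10 * log(2))  # 0.25 at the default time constants
#' @export
epsilon_kernel <- function(t, tau_m = 10, tau_s = 5) {
  stopifnot(tau_m > tau_s, tau_s > 0)
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) stop("`t` must be non-negative numeric")
  exp(-t / tau_m) - exp(-t / tau_s)
}
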