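#' Simulate source activity of the somatosensory network
#'
#' Integrates the three-node evoked-response neural mass model with
#' fixed-step RK4 at an internal step of `dt` ms (default 0.5 ms) and
#' samples the result onto the requested (uniform) grid.  Conduction delays
#' are handled by linear interpolation of the stored firing-rate history.
#' The returned trace per node is the pyramidal depolarization, in arbitrary
#' units.  Deterministic given model and grid.
#'
#' @param model A [network_model()].
#' @param times Strictly increasing, uniformly spaced time grid in ms.
#' @param dt Internal integration step, ms.  Must not exceed the grid step.
#' @param return_states If `TRUE`, return all 8 states per node
#'   (rows blocked per node: PSPs x1..x3, x7 and their derivatives) instead
#'   of pyramidal depolarization only.
#' @return Object of class `source_timeseries` with fields `times` (ms) and
#'   `values` (`[nodes x samples]`, rows named by node).
#' @export
simulate_sources <- function(model, times, dt = 0.5, return_states = FALSE) {
  stopifnot(inherits(model, "network_model"), is.numeric(times),
            length(times) >= 2)
  steps <- diff(times)
  if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-8 * steps[1])
    stop("times must be a strictly increasing uniform grid")
  if (dt > steps[1] + 1e-12) dt <- steps[1]

  p <- model$params
  n <- length(model$node_ids)
  comps <- model$inputs
  ncomp <- length(comps)
  Cmat <- matrix(0, n, ncomp)
  mu <- sig <- numeric(ncomp)
  for (k in seq_len(ncomp)) {
    comp <- comps[[k]]$component
    mu[k] <- comp$onset_mean
    sig[k] <- comp$onset_sd
    g <- comps[[k]]$gains
    Cmat[match(names(g), model$node_ids), k] <- comp$amplitude * g
  }

  # integrate in seconds: the conventional couplings of this model family
  # assume rate constants 1000/tau_ms (s^-1), i.e. DC synaptic gain H*tau/1000
  vals <- .nmm_integrate(as.numeric(times) / 1000, dt / 1000,
                         model$forward, model$backward,
                         p$gamma, model$self, p$H_e, p$H_i,
                         p$tau_e / 1000, p$tau_i / 1000,
                         p$sigmoid_slope, p$extrinsic_delay / 1000,
                         p$intrinsic_delay / 1000,
                         Cmat, mu / 1000, sig / 1000, return_states)
  if (!all(is.finite(vals)))
    stop("divergent integration: non-finite source activity")
  if (!return_states) rownames(vals) <- model$node_ids
  structure(list(times = as.numeric(times), values = vals),
            class = "source_timeseries")
}

#' Analytic small-signal synaptic kernel
#'
#' Impulse response of one second-order excitatory synapse,
#' `h(t) = (H_e/tau_e) t exp(-t/tau_e)` for `t >= 0`: peaks at `t = tau_e`
#' with height `H_e / e`.  Used as an independent closed-form oracle for the
#' integrator in the linear (decoupled) regime: a drive `u(t)` produces the
#' response `(h * u)(t)` where the convolution integral runs over time in
#' seconds (equivalently, sum `h * u * dt_ms / 1000` on a ms grid); an
#' impulse of unit area in seconds produces `h` itself, peaking at
#' `t = tau_e` with height `H_e/e` times the input scale.
#'
#' @param t Times, ms.
#' @param H_e Synaptic gain, mV.
#' @param tau_e Time constant, ms.
#' @return Kernel values.
#' @export
synaptic_kernel <- function(t, H_e = 3.25, tau_e = 10) {
  ifelse(t >= 0, (H_e / tau_e) * t * exp(-t / tau_e), 0)
}

#' @export
print.source_timeseries <- function(x, ...) {
  cat(sprintf("<source_timeseries> %d nodes x %d samples, %g..%g ms\n",
              nrow(x$values), ncol(x$values), min(x$times), max(x$times)))
  invisible(x)
}
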