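#' LIF neuron parameters in physical units
#'
#' Bundle of the continuous-domain leaky integrate-and-fire parameters. The
#' membrane resistance `R` is always derived as `tau_v / C` (GOhm, since
#' ms / pF = GOhm) and can never be set independently.
#'
#' @param C Membrane capacitance (pF). Must be positive.
#' @param tau_v Membrane time constant (ms). Must be positive.
#' @param EL Resting potential (mV).
#' @param Vr Reset potential (mV).
#' @param theta Firing threshold (mV). Must exceed `Vr`; use `Inf` to
#'   disable spiking.
#'
#' @return An object of class `"lif_params"`: a list with fields `C`,
#'   `tau_v`, `EL`, `Vr`, `theta` and the derived `R`.
#'
#' @details The defaults describe the base neuron used throughout the
#'   package: a 170 pF, 22.2 ms cortical point neuron resting at -70 mV with
#'   reset equal to rest and a -50 mV firing threshold.
#'
#' @examples
#' p <- lif_params()
#' p$R * p$C  # equals tau_v
#' @export
lif_params <- function(C = 170, tau_v = 22.2, EL = -70, Vr = -70,
                       theta = -50) {
  stopifnot(is.numeric(C), length(C) == 1L, is.finite(C),
            is.numeric(tau_v), length(tau_v) == 1L, is.finite(tau_v),
            is.numeric(EL), length(EL) == 1L, is.finite(EL),
            is.numeric(Vr), length(Vr) == 1L, is.finite(Vr),
            is.numeric(theta), length(theta) == 1L, !is.na(theta))
  if (C <= 0) stop("'C' must be positive (pF)")
  if (tau_v <= 0) stop("'tau_v' must be positive (ms)")
  if (theta <= Vr) stop("'theta' must exceed 'Vr'")
  structure(
    list(C = C, tau_v = tau_v, EL = EL, Vr = Vr, theta = theta,
         R = tau_v / C),
    class = "lif_params"
  )
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF parameters (physical units)\n")
  cat(sprintf("  C     = %g pF\n", x$C))
  cat(sprintf("  tau_v = %g ms\n", x$tau_v))
  cat(sprintf("  EL    = %g mV\n", x$EL))
  cat(sprintf("  Vr    = %g mV\n", x$Vr))
  cat(sprintf("  theta = %g mV\n", x$theta))
  cat(sprintf("  R     = %g GOhm (derived tau_v/C)\n", x$R))
  invisible(x)
}

#' Constant bias-current stimulus
#'
#' @param Ie Constant trans-membrane current (pA).
#' @return An object of class `"lif_stimulus"` with `mode = "bias"`.
#' @seealso [stim_spikes()] for spike-train drive.
#' @examples
#' stim_bias(200)
#' @export
stim_bias <- function(Ie = 200) {
  stopifnot(is.numeric(Ie), length(Ie) == 1L, is.finite(Ie))
  structure(list(mode = "bias", Ie = Ie), class = "lif_stimulus")
}

#' External spike-train stimulus
#'
#' Spikes are delivered through a delta kernel by default: each presynaptic
#' spike instantaneously increments the membrane potential by its source
#' weight (mV). An exponential current kernel with time constant `tau_syn`
#' is available as an alternative.
#'
#' @param trains A [spike_train_set()].
#' @param weight Synaptic weight per source, in mV per spike. Either a
#'   scalar applied to all sources or a vector of length `n_sources`.
#' @param kernel `"delta"` (default) or `"exp"`.
#' @param tau_syn Synaptic time constant (ms) for the exponential kernel.
#' @return An object of class `"lif_stimulus"` with `mode = "spikes"`.
#' @examples
#' stim_spikes(stimulus_table1())
#' @export
stim_spikes <- function(trains, weight = 0.5, kernel = c("delta", "exp"),
                        tau_syn = 5) {
  stopifnot(inherits(trains, "spike_train_set"),
            is.numeric(weight), all(is.finite(weight)))
  kernel <- match.arg(kernel)
  if (!length(weight) %in% c(1L, trains$n_sources))
    stop("'weight' must be a scalar or one value per source")
  structure(
    list(mode = "spikes", trains = trains, weight = weight,
         kernel = kernel, tau_syn = tau_syn),
    class = "lif_stimulus"
  )
}

#' @export
print.lif_stimulus <- function(x, ...) {
  if (x$mode == "bias") {
    cat(sprintf("Stimulus: constant bias current Ie = %g pA\n", x$Ie))
  } else {
    cat(sprintf("Stimulus: %d spike source(s), %d spikes, %s kernel\n",
                x$trains$n_sources, nrow(x$trains$spikes), x$kernel))
  }
  invisible(x)
}

## Per-step increment applied during the update from sample i to i + 1
## (1-based step index i in 1..n): a spike at time t lands in step
## trunc(t/dt) + 1. Used identically by both backends so the two domains
## stay aligned sample-for-sample.
spike_step_increments <- function(trains, weight, dt, n_steps) {
  inc <- numeric(n_steps)
  if (nrow(trains$spikes) == 0L) return(inc)
  w <- if (length(weight) == 1L) rep(weight, trains$n_sources) else weight
  step <- trunc(trains$spikes$time_ms / dt) + 1L
  keep <- step >= 1L & step <= n_steps
  src <- trains$spikes$source_id[keep] + 1L
  for (k in seq_along(src)) {
    inc[step[keep][k]] <- inc[step[keep][k]] + w[src[k]]
  }
  inc
}
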