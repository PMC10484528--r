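#' Truncation toward zero with a floating-point guard
#'
#' All conversions from the continuous to the integer domain round by
#' truncation toward zero, the convention of the emulated hardware. A small
#' absolute guard (1e-9) is added toward the truncation boundary so that
#' quotients that are integers in exact arithmetic (for instance the
#' calibrated bias 1175, or thresholds that are exact multiples of the
#' voltage scale) are not pushed below the boundary by double rounding.
#'
#' @param x Numeric vector.
#' @return `x` truncated toward zero, as a double holding integer values.
#' @examples
#' int_trunc(c(1.9, -1.9, 2 - 1e-12))
#' @export
int_trunc <- function(x) {
  trunc(x + sign(x) * 1e-9)
}

#' Calibrated voltage scale
#'
#' The voltage scale `Vs` (mV per integer unit) is calibrated so that the
#' base bias current maps to a chosen integer bias:
#' `Vs = (dt * Ie / C) / target_bias`. With the defaults (200 pA, 170 pF,
#' dt = 1 ms, target 1175) this gives about 1.00125e-3 mV per unit.
#'
#' @param Ie Anchor bias current (pA).
#' @param C Anchor membrane capacitance (pF).
#' @param dt Timestep (ms).
#' @param target_bias Integer bias the anchor current should map to.
#' @return The voltage scale (mV per integer unit).
#' @examples
#' calibrated_vs()
#' @export
calibrated_vs <- function(Ie = 200, C = 170, dt = 1, target_bias = 1175) {
  stopifnot(Ie > 0, C > 0, dt > 0, target_bias > 0)
  (dt * Ie / C) / target_bias
}

#' Cross-platform mapping configuration
#'
#' Describes the transform between the physical-unit and integer domains:
#' the voltage scale `Vs` (mV per integer unit), the shared timestep `dt`
#' (ms), the precision of the decay parameter (12 bits), and the rounding
#' mode (truncation toward zero).
#'
#' @param Vs Voltage scale (mV per integer unit); default the
#'   [calibrated_vs()] anchor value.
#' @param dt Timestep (ms).
#' @param precision_bits Bit width of the decay parameter (default 12).
#' @param rounding Rounding mode identifier; only `"truncate"` is
#'   implemented.
#' @return An object of class `"mapping_config"`.
#' @examples
#' mapping_config()
#' @export
mapping_config <- function(Vs = calibrated_vs(), dt = 1,
                           precision_bits = 12,
                           rounding = "truncate") {
  stopifnot(is.numeric(Vs), length(Vs) == 1L, Vs > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            precision_bits >= 1)
  rounding <- match.arg(rounding, "truncate")
  structure(
    list(Vs = Vs, dt = dt, precision_bits = as.integer(precision_bits),
         rounding = rounding),
    class = "mapping_config"
  )
}

#' @export
print.mapping_config <- function(x, ...) {
  cat(sprintf(
    "Mapping: Vs = %g mV/unit, dt = %g ms, %d-bit decay, rounding = %s\n",
    x$Vs, x$dt, x$precision_bits, x$rounding))
  invisible(x)
}

#' Rescale a membrane potential into integer units
#'
#' `rescale_state()` applies `trunc((V - Vr) / Vs)`; [inverse_rescale()]
#' maps integer state back as `Vr + v_int * Vs` and round-trips exactly on
#' integer multiples of `Vs`.
#'
#' @param V Membrane potential(s), mV.
#' @param Vr Reset potential (mV), the zero of the integer domain.
#' @param mapping A [mapping_config()].
#' @return Integer-valued state (double).
#' @examples
#' m <- mapping_config()
#' rescale_state(-50, -70, m)
#' inverse_rescale(rescale_state(-50, -70, m), -70, m)
#' @export
rescale_state <- function(V, Vr, mapping) {
  stopifnot(inherits(mapping, "mapping_config"), all(is.finite(V)))
  int_trunc((V - Vr) / mapping$Vs)
}

#' @rdname rescale_state
#' @param v_int Integer-domain state.
#' @export
inverse_rescale <- function(v_int, Vr, mapping) {
  stopifnot(inherits(mapping, "mapping_config"))
  Vr + v_int * mapping$Vs
}

#' Convert a membrane time constant to the integer decay parameter
#'
#' The integer voltage-decay parameter is
#' `delta_v = trunc((dt / tau_v) * 2^precision_bits)`; with 12 bits and
#' dt = 1 ms a 22.2 ms time constant gives 184.
#'
#' @param tau_v Membrane time constant (ms); must be >= `dt`.
#' @param dt Timestep (ms).
#' @param precision_bits Precision of the decay parameter (default 12).
#' @return Integer decay parameter in `[1, 2^precision_bits]`.
#' @examples
#' compute_decay(22.2)
#' invert_decay(193)
#' @export
compute_decay <- function(tau_v, dt = 1, precision_bits = 12) {
  stopifnot(tau_v > 0, dt > 0)
  if (tau_v < dt)
    stop("'tau_v' < 'dt': decay parameter would exceed 2^precision_bits")
  int_trunc((dt / tau_v) * 2^precision_bits)
}

#' @rdname compute_decay
#' @param delta_v Integer decay parameter (>= 1).
#' @return `invert_decay()` returns the recovered time constant
#'   `dt * 2^precision_bits / delta_v` (ms) at full precision; round to one
#'   decimal for display.
#' @export
invert_decay <- function(delta_v, dt = 1, precision_bits = 12) {
  stopifnot(dt > 0)
  if (delta_v < 1) stop("'delta_v' must be >= 1 to invert the decay")
  dt * 2^precision_bits / delta_v
}

#' Map physical-unit LIF parameters onto the integer emulator domain
#'
#' Produces the emulator neuron configuration and the integer-domain
#' stimulus for a run of `duration` ms:
#'
#' * decay via [compute_decay()];
#' * integer bias `trunc(dt * Ie / (C * Vs))` (pA * ms / pF = mV, divided
#'   by `Vs`), stored mantissa/exponent via [encode_bias()] using the
#'   smallest exponent whose mantissa fits in `[-4096, 4096]`;
#' * a per-step increment `trunc(dt * (EL - Vr) / (tau_v * Vs))` restoring
#'   the resting-potential drive whenever `EL != Vr`;
#' * integer threshold via [rescale_state()] and spike weights scaled by
#'   `1 / Vs`.
#'
#' @param params A [lif_params()].
#' @param stim A [stim_bias()] or [stim_spikes()] stimulus (delta kernel
#'   only).
#' @param mapping A [mapping_config()].
#' @param duration Run duration (ms) for which the per-step integer
#'   stimulus vector is materialized.
#' @return A list of class `"loihi_mapping"` with elements `config` (a
#'   [loihi_config()]), `u` (integer per-step synaptic/offset input of
#'   length `floor(duration/dt)`), `bias` (the [encode_bias()] result),
#'   `el_increment`, `n_steps`, and the `mapping` used.
#' @examples
#' mp <- map_lif_to_loihi(lif_params(), stim_bias(200), mapping_config())
#' mp$config$bias_mantissa
#' @export
map_lif_to_loihi <- function(params, stim, mapping,
                             duration = 500) {
  stopifnot(inherits(params, "lif_params"),
            inherits(stim, "lif_stimulus"),
            inherits(mapping, "mapping_config"),
            duration >= mapping$dt)
  dt <- mapping$dt
  Vs <- mapping$Vs
  n_steps <- floor(duration / dt)
  delta_v <- compute_decay(params$tau_v, dt, mapping$precision_bits)

  Ie <- if (stim$mode == "bias") stim$Ie else 0
  bias_int <- int_trunc(dt * Ie / (params$C * Vs))
  exponent <- 0L
  while (abs(int_trunc(bias_int / 2^exponent)) > 4096 && exponent < 7L)
    exponent <- exponent + 1L
  if (abs(int_trunc(bias_int / 2^exponent)) > 4096)
    stop(sprintf(
      "integer bias %g not encodable with mantissa in [-4096, 4096]: Vs = %g is too fine",
      bias_int, Vs))
  bias <- encode_bias(bias_int, exponent)

  el_increment <- int_trunc(dt * (params$EL - params$Vr) /
                              (params$tau_v * Vs))
  u <- rep(el_increment, n_steps)
  weight_int <- 0
  if (stim$mode == "spikes") {
    if (stim$kernel != "delta")
      stop("only the delta synaptic kernel maps to the integer domain")
    weight_int <- int_trunc(stim$weight / Vs)
    u <- u + spike_step_increments(stim$trains, weight_int, dt, n_steps)
  }

  theta_int <- if (is.finite(params$theta))
    rescale_state(params$theta, params$Vr, mapping) else Inf
  cfg <- loihi_config(delta_v = delta_v,
                      bias_mantissa = bias$mantissa,
                      bias_exponent = bias$exponent,
                      theta_int = theta_int,
                      weight_int = weight_int)
  structure(
    list(config = cfg, u = u, bias = bias, el_increment = el_increment,
         n_steps = n_steps, mapping = mapping, Vr = params$Vr),
    class = "loihi_mapping"
  )
}

#' @export
print.loihi_mapping <- function(x, ...) {
  cat(sprintf(
    "Integer-domain mapping: delta_v = %d, bias = %d x 2^%d = %d, theta_int = %s\n",
    x$config$delta_v, x$config$bias_mantissa, x$config$bias_exponent,
    x$bias$reconstructed,
    if (is.finite(x$config$theta_int)) format(x$config$theta_int) else "Inf"))
  invisible(x)
}
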