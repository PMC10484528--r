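#' Integer-domain neuron configuration
#'
#' Parameters of the fixed-point emulator compartment: the 12-bit voltage
#' decay `delta_v`, the bias current as mantissa x 2^exponent, the integer
#' firing threshold, and per-source integer synaptic weight. The reset
#' value is fixed at 0 by the hardware update rule.
#'
#' @param delta_v Integer voltage decay in `[0, 4096]`.
#' @param bias_mantissa Integer in `[-4096, 4096]`.
#' @param bias_exponent Integer in `[0, 7]`.
#' @param theta_int Integer firing threshold (`Inf` disables spiking).
#' @param reset_int Reset value; must be 0.
#' @param weight_int Integer synaptic weight per source.
#' @return An object of class `"loihi_config"`.
#' @examples
#' loihi_config(delta_v = 184, bias_mantissa = 1175, theta_int = 19975)
#' @export
loihi_config <- function(delta_v, bias_mantissa = 0, bias_exponent = 0,
                         theta_int = Inf, reset_int = 0, weight_int = 0) {
  stopifnot(length(delta_v) == 1L, length(bias_mantissa) == 1L,
            length(bias_exponent) == 1L)
  if (delta_v < 0 || delta_v > 4096)
    stop("'delta_v' must lie in [0, 4096]")
  if (abs(bias_mantissa) > 4096)
    stop("'bias_mantissa' must lie in [-4096, 4096]")
  if (bias_exponent < 0 || bias_exponent > 7)
    stop("'bias_exponent' must lie in [0, 7]")
  if (reset_int != 0)
    stop("'reset_int' is fixed at 0 by the hardware update rule")
  structure(
    list(delta_v = as.integer(delta_v),
         bias_mantissa = as.integer(bias_mantissa),
         bias_exponent = as.integer(bias_exponent),
         theta_int = theta_int, reset_int = 0L,
         weight_int = weight_int),
    class = "loihi_config"
  )
}

#' @export
print.loihi_config <- function(x, ...) {
  cat(sprintf(
    "Emulator neuron: delta_v = %d, bias = %d x 2^%d, theta_int = %s\n",
    x$delta_v, x$bias_mantissa, x$bias_exponent,
    if (is.finite(x$theta_int)) format(x$theta_int) else "Inf"))
  invisible(x)
}

#' Fixed-point LIF emulator
#'
#' Iterates the integer compartment update rule
#' `v(t+1) = v(t) - trunc(v(t) * delta_v / 2^12) + b + u(t)`
#' where `b = bias_mantissa * 2^bias_exponent`; whenever the updated state
#' exceeds `theta_int` a spike is recorded at that step and the state at
#' the following step is the reset value 0. With the default
#' `exact = FALSE` every state is an integer at every step (integer
#' closure). `exact = TRUE` drops the decay truncation and is intended for
#' fine-limit equivalence checks against the reference integrator, where
#' the recursion becomes the exact scaled Euler update.
#'
#' @param cfg A [loihi_config()].
#' @param u Integer-domain per-step synaptic/offset input: scalar or vector
#'   of length `n_steps` (the increment applied during the update from step
#'   `i - 1` to `i`).
#' @param n_steps Number of update steps (>= 1).
#' @param v0 Initial integer state.
#' @param exact Skip the decay truncation (real-valued decay); used by
#'   equivalence oracles only.
#' @param overflow_limit Magnitude at which the state is declared
#'   mis-scaled (default `2^23`); exceeding it raises an error naming the
#'   voltage scale as the likely culprit.
#' @param delta_v_real Optional real-valued decay parameter overriding
#'   `cfg$delta_v` (for unquantized-decay oracles).
#' @return An object of class `"loihi_trace"`: list with `steps`, `values`
#'   (length `n_steps + 1`) and `spike_steps` (0-based step indices; the
#'   value at `spike_step + 1` is 0).
#' @examples
#' cfg <- loihi_config(delta_v = 0, bias_mantissa = 1)
#' simulate_emulator(cfg, u = 0, n_steps = 5)$values  # 0 1 2 3 4 5
#' @export
simulate_emulator <- function(cfg, u = 0, n_steps, v0 = 0, exact = FALSE,
                              overflow_limit = 2^23,
                              delta_v_real = NULL) {
  stopifnot(inherits(cfg, "loihi_config"), n_steps >= 1)
  if (length(u) == 1L) u <- rep(u, n_steps)
  if (length(u) != n_steps)
    stop("'u' must be a scalar or have length n_steps")
  delta <- if (is.null(delta_v_real)) cfg$delta_v else delta_v_real
  b <- cfg$bias_mantissa * 2^cfg$bias_exponent
  scale <- 2^12

  v <- numeric(n_steps + 1)
  v[1] <- v0
  spike_steps <- integer(0)
  last_spike <- -2L
  for (i in seq_len(n_steps)) {
    if (last_spike == i - 1L) {
      v[i + 1] <- 0
    } else {
      decay <- v[i] * delta / scale
      if (!exact) decay <- int_trunc(decay)
      v[i + 1] <- v[i] - decay + b + u[i]
    }
    if (abs(v[i + 1]) > overflow_limit)
      stop(sprintf(
        "integer state overflow at step %d (|v| > %g): voltage scale Vs is mis-scaled for this drive",
        i, overflow_limit))
    if (v[i + 1] > cfg$theta_int) {
      spike_steps <- c(spike_steps, i)
      last_spike <- i
    }
  }
  structure(
    list(steps = as.integer(n_steps), values = v,
         spike_steps = spike_steps),
    class = "loihi_trace"
  )
}

#' @export
print.loihi_trace <- function(x, ...) {
  cat(sprintf("Integer trace: %d steps, %d spike(s)\n",
              x$steps, length(x$spike_steps)))
  invisible(x)
}

#' Map an integer trace back to physical units
#'
#' Applies [inverse_rescale()] sample-wise and converts spike steps to
#' times, yielding a [lif_trace()] directly comparable to the reference.
#'
#' @param int_trace A `"loihi_trace"` from [simulate_emulator()].
#' @param Vr Reset potential (mV), the zero of the integer domain.
#' @param mapping A [mapping_config()].
#' @return A [lif_trace()] in mV.
#' @export
as_lif_trace <- function(int_trace, Vr, mapping) {
  stopifnot(inherits(int_trace, "loihi_trace"),
            inherits(mapping, "mapping_config"))
  lif_trace(dt = mapping$dt, duration = int_trace$steps * mapping$dt,
            values = inverse_rescale(int_trace$values, Vr, mapping),
            spike_times = int_trace$spike_steps * mapping$dt)
}

#' Mantissa/exponent encoding of an integer bias current
#'
#' The hardware stores the bias as `mantissa * 2^exponent` with the
#' mantissa an integer in `[-4096, 4096]` and the exponent in `[0, 7]`.
#' Encoding at exponent `e` truncates the mantissa toward zero:
#' `mantissa = trunc(base_bias / 2^e)`, so precision degrades as the
#' exponent grows while the representable range widens.
#'
#' @param base_bias Integer bias value to encode.
#' @param exponent Bias exponent in `[0, 7]`.
#' @return An object of class `"bias_encoding"`: list with `mantissa`,
#'   `exponent` and `reconstructed = mantissa * 2^exponent`.
#' @examples
#' encode_bias(1175, 3)  # mantissa 146, reconstructed 1168
#' @export
encode_bias <- function(base_bias, exponent) {
  stopifnot(length(base_bias) == 1L, length(exponent) == 1L)
  if (exponent < 0 || exponent > 7)
    stop("'exponent' must lie in [0, 7]")
  mantissa <- int_trunc(base_bias / 2^exponent)
  if (abs(mantissa) > 4096)
    stop(sprintf("mantissa %g out of range [-4096, 4096]", mantissa))
  structure(
    list(mantissa = mantissa, exponent = as.integer(exponent),
         reconstructed = mantissa * 2^exponent),
    class = "bias_encoding"
  )
}

#' @export
print.bias_encoding <- function(x, ...) {
  cat(sprintf("Bias encoding: %d x 2^%d = %d\n",
              x$mantissa, x$exponent, x$reconstructed))
  invisible(x)
}

#' Bias precision table across the exponent range
#'
#' Encodes a base bias at every exponent in `exponents` and tabulates the
#' mantissa and the reconstructed value, exposing the precision loss of
#' coarser encodings.
#'
#' @param base_bias Integer base bias (default 1175, the calibrated image
#'   of a 200 pA current).
#' @param exponents Integer exponents to sweep (default `0:7`).
#' @return A data frame with columns `mantissa`, `exponent`,
#'   `reconstructed`.
#' @examples
#' bias_precision_table()
#' @export
bias_precision_table <- function(base_bias = 1175, exponents = 0:7) {
  rows <- lapply(exponents, function(e) {
    enc <- encode_bias(base_bias, e)
    data.frame(mantissa = enc$mantissa, exponent = enc$exponent,
               reconstructed = enc$reconstructed)
  })
  do.call(rbind, rows)
}

#' RMSE sweep over the integer decay parameter
#'
#' Runs the emulator for every integer `delta_v` in
#' `[base_delta - half_width, base_delta + half_width]`, maps each integer
#' trace back to physical units, and records the masked derivative RMSE
#' against a fixed reference trace.
#'
#' @param cfg A [loihi_config()] providing everything but the decay.
#' @param base_delta Center of the sweep (integer decay units).
#' @param half_width Half width of the sweep; the grid is
#'   `base_delta + (-half_width:half_width)`.
#' @param reference A [lif_trace()] to compare against.
#' @param mapping A [mapping_config()].
#' @param u Integer-domain per-step input passed to the emulator.
#' @param Vr Reset potential (mV) for the inverse mapping.
#' @param guard Mask guard width (steps) around spikes/resets.
#' @return A 1-D [sensitivity_grid()] over parameter `"delta_v"`.
#' @examples
#' ref <- simulate_reference(lif_params(theta = Inf), stim_bias(200))
#' mp <- map_lif_to_loihi(lif_params(theta = Inf), stim_bias(200),
#'                        mapping_config())
#' sweep <- decay_sweep(mp$config, 184, 5, ref, mapping_config())
#' locate_minimum(sweep)
#' @export
decay_sweep <- function(cfg, base_delta, half_width, reference, mapping,
                        u = 0, Vr = -70, guard = 1) {
  stopifnot(inherits(cfg, "loihi_config"),
            inherits(reference, "lif_trace"),
            inherits(mapping, "mapping_config"),
            half_width >= 0)
  if (base_delta - half_width < 0)
    stop("sweep extends below delta_v = 0")
  deltas <- seq(base_delta - half_width, base_delta + half_width)
  n_steps <- length(reference$values) - 1L
  rmse_values <- vapply(deltas, function(d) {
    tryCatch({
      cfg_d <- loihi_config(delta_v = d,
                            bias_mantissa = cfg$bias_mantissa,
                            bias_exponent = cfg$bias_exponent,
                            theta_int = cfg$theta_int,
                            weight_int = cfg$weight_int)
      emu <- simulate_emulator(cfg_d, u = u, n_steps = n_steps)
      emu_mv <- as_lif_trace(emu, Vr, mapping)
      mask <- subthreshold_mask(reference, emu_mv, guard = guard)
      rmse(derivative_trace(emu_mv), derivative_trace(reference), mask)
    }, error = function(e) {
      warning(sprintf("delta_v = %d failed: %s", d, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  sensitivity_grid(
    axes = list(param_grid("delta_v", values = deltas,
                           base = base_delta)),
    direction = "emulator", rmse_values = rmse_values
  )
}
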