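#' Reference LIF simulation (floating point, physical units)
#'
#' Integrates the continuous LIF equation
#' `dV/dt = (Ie - (V - EL)/R) / C` by forward Euler with step `dt`,
#' applying threshold/reset dynamics: whenever the freshly computed state
#' exceeds `theta`, a spike is recorded at that sample's time and the state
#' at the following sample is set to `Vr`. Forward Euler with the shared
#' `dt` is deliberate: the integer emulator's update rule is itself a
#' forward-Euler-form recursion, so any higher-order scheme would break
#' cross-backend equivalence in the fine-quantization limit.
#'
#' @param params A [lif_params()].
#' @param stim A [stim_bias()] or [stim_spikes()] stimulus. Delta-kernel
#'   spikes increment the state by their weight (mV) at the spike's step;
#'   the optional exponential kernel low-pass filters the increment with
#'   `tau_syn`.
#' @param dt Sampling step (ms), > 0.
#' @param duration Run duration (ms), >= `dt`.
#' @param V0 Initial membrane potential (mV); defaults to `params$EL`.
#' @return An object of class `"lif_trace"`: list with `dt`, `duration`,
#'   `values` (mV, length `floor(duration/dt) + 1`), and `spike_times`
#'   (ms, multiples of `dt`).
#' @examples
#' tr <- simulate_reference(lif_params(theta = Inf), stim_bias(200))
#' tail(tr$values, 1)  # approaches EL + Ie * tau_v / C = -43.88 mV
#' @export
simulate_reference <- function(params, stim, dt = 1, duration = 500,
                               V0 = NULL) {
  stopifnot(inherits(params, "lif_params"),
            inherits(stim, "lif_stimulus"),
            dt > 0, duration >= dt)
  if (is.null(V0)) V0 <- params$EL
  n <- floor(duration / dt)
  Ie <- if (stim$mode == "bias") stim$Ie else 0

  delta_inc <- numeric(n)
  exp_kernel <- FALSE
  if (stim$mode == "spikes") {
    if (stim$kernel == "delta") {
      delta_inc <- spike_step_increments(stim$trains, stim$weight, dt, n)
    } else {
      exp_kernel <- TRUE
      arrivals <- spike_step_increments(stim$trains, stim$weight, dt, n)
    }
  }

  V <- numeric(n + 1)
  V[1] <- V0
  syn <- 0  # exponential-kernel synaptic state (mV)
  spike_steps <- integer(0)
  last_spike <- -2L
  for (i in seq_len(n)) {
    if (last_spike == i - 1L) {
      V[i + 1] <- params$Vr
    } else {
      drive <- (dt / params$C) * (Ie - (V[i] - params$EL) / params$R)
      if (exp_kernel) {
        syn <- syn * exp(-dt / stim$tau_syn) + arrivals[i]
        drive <- drive + (dt / stim$tau_syn) * syn
        V[i + 1] <- V[i] + drive
      } else {
        V[i + 1] <- V[i] + drive + delta_inc[i]
      }
    }
    if (!is.finite(V[i + 1]))
      stop(sprintf(
        "non-finite membrane potential at step %d: check parameters and dt",
        i))
    if (V[i + 1] > params$theta) {
      spike_steps <- c(spike_steps, i)
      last_spike <- i
    }
  }
  lif_trace(dt = dt, duration = duration, values = V,
            spike_times = spike_steps * dt)
}

#' Membrane-potential trace container
#'
#' @param dt Sampling step (ms).
#' @param duration Duration (ms).
#' @param values Membrane potentials (mV), length `floor(duration/dt) + 1`.
#' @param spike_times Spike times (ms); each must be a multiple of `dt`
#'   within the duration.
#' @return An object of class `"lif_trace"`.
#' @export
lif_trace <- function(dt, duration, values, spike_times = numeric(0)) {
  stopifnot(dt > 0, duration >= 0,
            length(values) == floor(duration / dt) + 1L)
  if (length(spike_times)) {
    steps <- spike_times / dt
    if (any(abs(steps - round(steps)) > 1e-9) ||
        any(spike_times < 0 | spike_times > duration))
      stop("spike times must be multiples of dt within the duration")
  }
  structure(
    list(dt = dt, duration = duration, values = as.numeric(values),
         spike_times = as.numeric(spike_times)),
    class = "lif_trace"
  )
}

#' @export
print.lif_trace <- function(x, ...) {
  cat(sprintf(
    "LIF trace: %d samples at dt = %g ms (%g ms), %d spike(s)\n",
    length(x$values), x$dt, x$duration, length(x$spike_times)))
  invisible(x)
}

## 0-based step indices at which spikes were recorded (sample index
## step + 1 holds the suprathreshold value, step + 2 the reset value)
spike_steps_of <- function(trace) {
  round(trace$spike_times / trace$dt)
}

#' Forward-difference derivative of a trace
#'
#' Returns `(values[i+1] - values[i]) / dt`, of length
#' `length(values) - 1`, in mV/ms. Derivative samples whose interval
#' straddles a spike/reset are *not* removed here; they are flagged
#' downstream by [subthreshold_mask()].
#'
#' @param trace A [lif_trace()] with at least 2 samples.
#' @return Numeric vector of derivatives (mV/ms).
#' @examples
#' tr <- simulate_reference(lif_params(theta = Inf), stim_bias(0))
#' all(derivative_trace(tr) == 0)
#' @export
derivative_trace <- function(trace) {
  stopifnot(inherits(trace, "lif_trace"))
  if (length(trace$values) < 2L)
    stop("trace has a single sample: cannot differentiate")
  diff(trace$values) / trace$dt
}

#' Read and write voltage traces as CSV (`time_ms,value`)
#'
#' Spike times are stored in a `# spikes:` comment line so that the trace
#' round-trips losslessly through plain CSV.
#'
#' @param trace A [lif_trace()].
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   [read_trace_csv()] returns a [lif_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "lif_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spikes: %s",
                     paste(trace$spike_times, collapse = " ")), con)
  writeLines("time_ms,value", con)
  t <- seq(0, by = trace$dt, length.out = length(trace$values))
  writeLines(sprintf("%.10g,%.10g", t, trace$values), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  spike_times <- numeric(0)
  if (startsWith(lines[1], "# spikes:")) {
    raw <- trimws(sub("# spikes:", "", lines[1], fixed = TRUE))
    if (nzchar(raw))
      spike_times <- as.numeric(strsplit(raw, " ", fixed = TRUE)[[1]])
    lines <- lines[-1]
  }
  df <- read.csv(text = paste(lines, collapse = "\n"))
  dt <- if (nrow(df) > 1L) df$time_ms[2] - df$time_ms[1] else 1
  lif_trace(dt = dt, duration = df$time_ms[nrow(df)],
            values = df$value, spike_times = spike_times)
}
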