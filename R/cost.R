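#' Subthreshold mask for derivative comparisons
#'
#' Marks `FALSE` every forward-difference sample whose interval straddles a
#' spike/reset in either trace, plus a guard window (default one step on
#' each side): for a spike recorded at step `k`, derivative samples
#' `k - 1`, `k`, `k + 1` are excluded (1-based, guard 1). The mask of a
#' pair of traces is the AND of the two individual masks.
#'
#' @param trace_ref,trace_emu Two [lif_trace()] objects with equal `dt` and
#'   length.
#' @param guard Extra derivative samples masked on each side of a
#'   spike/reset.
#' @return Logical vector of length `length(values) - 1`.
#' @examples
#' tr <- simulate_reference(lif_params(), stim_bias(200))
#' mean(subthreshold_mask(tr, tr))
#' @export
subthreshold_mask <- function(trace_ref, trace_emu, guard = 1) {
  stopifnot(inherits(trace_ref, "lif_trace"),
            inherits(trace_emu, "lif_trace"))
  if (length(trace_ref$values) != length(trace_emu$values) ||
      abs(trace_ref$dt - trace_emu$dt) > 1e-12)
    stop("misaligned traces: lengths and dt must match")
  n <- length(trace_ref$values) - 1L
  mask <- rep(TRUE, n)
  for (s in c(spike_steps_of(trace_ref), spike_steps_of(trace_emu))) {
    ## derivative sample s + 1 spans the reset interval (samples s+1 -> s+2)
    idx <- seq.int(s + 1L - guard, s + 1L + guard)
    idx <- idx[idx >= 1L & idx <= n]
    mask[idx] <- FALSE
  }
  mask
}

## Sample-level (voltage) analogue of subthreshold_mask: excludes the
## suprathreshold and reset samples of each spike plus the guard.
sample_mask <- function(trace_a, trace_b, guard = 1) {
  n <- length(trace_a$values)
  mask <- rep(TRUE, n)
  for (s in c(spike_steps_of(trace_a), spike_steps_of(trace_b))) {
    ## 1-based samples: s + 1 is suprathreshold, s + 2 is the reset value
    idx <- seq.int(s + 1L - guard, s + 2L + guard)
    idx <- idx[idx >= 1L & idx <= n]
    mask[idx] <- FALSE
  }
  mask
}

#' Root-mean-square error between two derivative sequences
#'
#' `sqrt(mean((y_L - y_B)^2))` over unmasked samples (mV/ms). The RMSE is
#' symmetric in its arguments; in directional sensitivity scans the
#' "direction" lives in which backend's trace was perturbed, not in the
#' argument order.
#'
#' @param y_L,y_B Derivative sequences (mV/ms) of equal length.
#' @param mask Optional logical mask (default: all samples included).
#' @return The RMSE (mV/ms).
#' @examples
#' rmse(c(0, 0, 0), c(3, 4, 0))  # sqrt(25/3)
#' @export
rmse <- function(y_L, y_B, mask = NULL) {
  if (length(y_L) != length(y_B))
    stop("sequences must have equal length")
  if (is.null(mask)) mask <- rep(TRUE, length(y_L))
  if (length(mask) != length(y_L))
    stop("'mask' length must match the sequences")
  if (!any(mask))
    stop("no unmasked samples: comparison is over-masked")
  d <- y_L[mask] - y_B[mask]
  sqrt(mean(d^2))
}

#' Pearson correlation between two voltage traces
#'
#' Standard product-moment correlation over unmasked voltage samples
#' (suprathreshold/reset samples of either trace excluded with a guard
#' window).
#'
#' @param trace_a,trace_b Two aligned [lif_trace()] objects.
#' @param guard Guard width (samples) around spikes/resets.
#' @return Pearson r.
#' @examples
#' tr <- simulate_reference(lif_params(), stim_bias(200))
#' trace_correlation(tr, tr)
#' @export
trace_correlation <- function(trace_a, trace_b, guard = 1) {
  stopifnot(inherits(trace_a, "lif_trace"),
            inherits(trace_b, "lif_trace"))
  if (length(trace_a$values) != length(trace_b$values))
    stop("misaligned traces: lengths must match")
  mask <- sample_mask(trace_a, trace_b, guard = guard)
  a <- trace_a$values[mask]
  b <- trace_b$values[mask]
  if (length(a) < 2L)
    stop("fewer than two unmasked samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate (constant) trace: correlation undefined")
  cor(a, b)
}

#' Cross-backend cost report
#'
#' Convenience wrapper computing the package's validation metrics for a
#' reference trace and an emulator trace mapped back to mV: the masked
#' derivative RMSE (the primary cost, mV/ms), the raw-voltage RMSE
#' (secondary, mV), the Pearson correlation of the voltage traces, and the
#' masked fraction.
#'
#' @param trace_ref Reference [lif_trace()].
#' @param trace_emu Emulator trace mapped to mV ([as_lif_trace()]).
#' @param guard Mask guard width.
#' @return An object of class `"cost_report"`.
#' @export
cost_report <- function(trace_ref, trace_emu, guard = 1) {
  mask <- subthreshold_mask(trace_ref, trace_emu, guard = guard)
  smask <- sample_mask(trace_ref, trace_emu, guard = guard)
  structure(
    list(
      rmse_mv_per_ms = rmse(derivative_trace(trace_emu),
                            derivative_trace(trace_ref), mask),
      voltage_rmse_mv = rmse(trace_emu$values[smask],
                             trace_ref$values[smask]),
      correlation = trace_correlation(trace_ref, trace_emu,
                                      guard = guard),
      n_samples = sum(mask),
      masked_fraction = 1 - mean(mask)
    ),
    class = "cost_report"
  )
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Cross-backend cost report\n")
  cat(sprintf("  derivative RMSE : %.6g mV/ms (primary cost)\n",
              x$rmse_mv_per_ms))
  cat(sprintf("  voltage RMSE    : %.6g mV (secondary)\n",
              x$voltage_rmse_mv))
  cat(sprintf("  correlation     : %.6f\n", x$correlation))
  cat(sprintf("  samples         : %d (%.1f%% masked)\n",
              x$n_samples, 100 * x$masked_fraction))
  invisible(x)
}

#' Serialize a cost report to JSON
#'
#' @param x A [cost_report()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cost_report <- function(x, path) {
  stopifnot(inherits(x, "cost_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Closed-form parameterized RMSE of the cross-backend residual
#'
#' Evaluates, for each voltage sample, the bracket term
#' `e_i = (V_i - EL)^2 / tau_v^2 + Ie^2 / C^2
#'        - 2 (V_i - EL) Ie / (tau_v C)`
#' of the analytic residual decomposition, and the resulting RMSE
#' `sqrt(mean(e_i)) / |Vs - 1|`, together with the closed-form partial
#' derivatives of the bracket with respect to `C`, `tau_v` and `EL`
#' (see [analytic_partials()]).
#'
#' @param params A [lif_params()].
#' @param Vs The (dimensionless) voltage-scale factor of the residual
#'   derivation; must differ from 1.
#' @param V_samples Voltage samples (mV), non-empty.
#' @param Ie Constant current (pA).
#' @return An object of class `"analytic_sensitivity"`: list with
#'   `e_values`, `rmse_analytic`, and per-sample partials `dE_dC`,
#'   `dE_dtau`, `dE_dEL`.
#' @examples
#' a <- analytic_rmse(lif_params(), Vs = 1e-3, V_samples = c(-70, -60), Ie = 200)
#' a$rmse_analytic
#' @export
analytic_rmse <- function(params, Vs, V_samples, Ie) {
  stopifnot(inherits(params, "lif_params"), length(V_samples) >= 1)
  if (Vs == 1)
    stop("Vs = 1 is the degenerate no-discrepancy scale")
  dv <- V_samples - params$EL
  tau <- params$tau_v
  C <- params$C
  e <- dv^2 / tau^2 + Ie^2 / C^2 - 2 * dv * Ie / (tau * C)
  partials <- analytic_partials(params, V_samples, Ie)
  structure(
    list(e_values = e,
         rmse_analytic = sqrt(mean(e)) / abs(Vs - 1),
         dE_dC = partials$dE_dC,
         dE_dtau = partials$dE_dtau,
         dE_dEL = partials$dE_dEL),
    class = "analytic_sensitivity"
  )
}

#' Closed-form partial derivatives of the residual bracket
#'
#' Partial derivatives of
#' `e = (V - EL)^2 / tau_v^2 + Ie^2 / C^2 - 2 (V - EL) Ie / (tau_v C)`
#' with respect to the three scanned parameters:
#' \deqn{\partial e/\partial C = -2 I_e^2/C^3 + 2 (V - E_L) I_e/(\tau_v C^2)}
#' \deqn{\partial e/\partial \tau_v = -2 (V-E_L)^2/\tau_v^3
#'        + 2 (V - E_L) I_e/(\tau_v^2 C)}
#' \deqn{\partial e/\partial E_L = -2 (V - E_L)/\tau_v^2 + 2 I_e/(\tau_v C)}
#' The EL partial is affine in `EL` (the basis of the parameter-impact
#' ranking), while the C and tau_v partials are nonlinear in their own
#' parameters.
#'
#' @param params A [lif_params()].
#' @param V Voltage sample(s), mV.
#' @param Ie Constant current (pA).
#' @return List with vectors `dE_dC`, `dE_dtau`, `dE_dEL`.
#' @examples
#' analytic_partials(lif_params(), V = -60, Ie = 200)
#' @export
analytic_partials <- function(params, V, Ie) {
  stopifnot(inherits(params, "lif_params"))
  dv <- V - params$EL
  tau <- params$tau_v
  C <- params$C
  list(
    dE_dC = -2 * Ie^2 / C^3 + 2 * dv * Ie / (tau * C^2),
    dE_dtau = -2 * dv^2 / tau^3 + 2 * dv * Ie / (tau^2 * C),
    dE_dEL = -2 * dv / tau^2 + 2 * Ie / (tau * C)
  )
}

#' Rank parameters by sensitivity
#'
#' Orders parameters by decreasing sensitivity measure (for instance the
#' first-step relative RMSE change of their scans, computed on comparable
#' relative perturbation scales). Ties preserve the declared input order.
#'
#' @param changes Named numeric vector, one sensitivity value per
#'   parameter.
#' @return Character vector of parameter names, most impactful first.
#' @examples
#' rank_parameters(c(EL = 0.42, tau_v = 0.002, C = 0.002))
#' @export
rank_parameters <- function(changes) {
  stopifnot(is.numeric(changes), !is.null(names(changes)),
            all(nzchar(names(changes))))
  if (any(!is.finite(changes)))
    stop("sensitivity measures must be finite and on comparable scales")
  names(changes)[order(-changes)]
}

#' Analytic bound on the per-step quantization error of the emulator
#'
#' Conservative bound on the cross-backend derivative RMSE for a validated
#' (unperturbed) configuration: each emulator step truncates the decay
#' product and the bias (at most one integer unit each) and carries the
#' decay-quantization defect `v * (dt/tau_v - delta_v / 2^bits)`; mapped to
#' mV/ms this is `(Vs/dt) * (2 + v_max * (dt/tau_v - delta_v / 2^bits))`
#' per step, and the factor 2 accounts for the geometric accumulation of
#' state error (the accumulated state error contributes at most one more
#' per-step equivalent to the derivative residual).
#'
#' @param mapping A [mapping_config()].
#' @param delta_v Integer decay parameter in use.
#' @param tau_v True membrane time constant (ms).
#' @param v_max Maximum integer state magnitude reached subthreshold.
#' @return Upper bound on the derivative RMSE (mV/ms).
#' @export
quantization_bound <- function(mapping, delta_v, tau_v, v_max) {
  stopifnot(inherits(mapping, "mapping_config"))
  defect <- mapping$dt / tau_v - delta_v / 2^mapping$precision_bits
  2 * (mapping$Vs / mapping$dt) * (2 + v_max * max(defect, 0))
}
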