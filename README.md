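# lifmap

Dual-backend simulation of leaky integrate-and-fire (LIF) point neurons:
a floating-point reference integrator in physical units, side by side
with a software emulator of the fixed-point integer update rule used by
digital neuromorphic hardware, plus the machinery to map between the two
domains, to measure their disagreement, and to ask which model
parameters that disagreement is sensitive to.

## Who this is for

Anyone porting conventional spiking-neuron simulations onto
integer-arithmetic neuromorphic substrates and needing to know, before
trusting the hardware, (a) how faithfully a quantized compartment
reproduces the continuous dynamics and (b) which parameters must be
specified carefully because the cross-platform error is steep in them.

## The model and the mapping

The reference neuron integrates, by forward Euler at step `dt`,

    V'(t) = (1/C) [ Ie(t) - (V(t) - EL)/R ],    V <- Vr  if V > Theta

with `C` (pF), `R = tau_v / C` (GOhm), `EL`, `Vr`, `Theta` (mV) and
`Ie` (pA). The emulator iterates the integer recursion

    v(t+1) = v(t) - trunc(v(t) * delta_v / 2^12) + b + u(t),   v <- 0  if v > theta_int

where `delta_v = trunc((dt/tau_v) * 2^12)` is the 12-bit voltage decay,
`b = mantissa * 2^exponent` the encoded bias (mantissa in [-4096, 4096],
exponent in [0, 7]), and states map between domains through the voltage
scale `Vs`: `v = trunc((V - Vr)/Vs)`. The default `Vs` is calibrated so
that the base stimulus (200 pA, 170 pF, dt = 1 ms) lands on integer bias
1175.

Agreement is scored on subthreshold derivative traces — forward
differences with spike/reset-straddling samples masked — as an RMSE in
mV/ms, alongside the Pearson correlation of the voltage traces.
One-at-a-time (OAT) and two-at-a-time (TAT) scans perturb `C`, `tau_v`
or `EL` in either backend over preset grids and profile the RMSE
surface; closed-form partial derivatives of the analytic residual
explain the observed ranking (the resting potential dominates, because
its gradient term is affine while the `C` and `tau_v` terms are not).

## Worked example

```r
library(lifmap)

params  <- lif_params()        # 170 pF, 22.2 ms, EL = Vr = -70 mV, Theta = -50 mV
mapping <- mapping_config()    # calibrated Vs, dt = 1 ms, 12-bit decay

mp <- map_lif_to_loihi(params, stim_bias(200), mapping)
mp
#> Integer-domain mapping: delta_v = 184, bias = 1175 x 2^0 = 1175, theta_int = 19975

ref <- simulate_reference(params, stim_bias(200))
emu <- as_lif_trace(
  simulate_emulator(mp$config, u = mp$u, n_steps = mp$n_steps),
  params$Vr, mapping)
cost_report(ref, emu)
#> Cross-backend cost report
#>   derivative RMSE : 0.0013002 mV/ms (primary cost)
#>   voltage RMSE    : 0.0199884 mV (secondary)
#>   correlation     : 1.000000
#>   samples         : 455 (9.0% masked)
```

The 200 pA drive maps to decay 184 and integer bias 1175; both backends
spike 15 times at the same steps, and on the subthreshold samples the
traces correlate to better than 0.99999 with a derivative RMSE of about
1.3e-3 mV/ms — inside the analytic single-step quantization bound for
this mapping (`quantization_bound()`).

A sensitivity scan of the resting potential under the frozen five-source
spike stimulus:

```r
scan <- oat_scan(params, stim_spikes(stimulus_table1()), mapping,
                 preset_grid("EL", "spike"))
locate_minimum(scan)
#> $coordinates
#>  EL
#> -70
#> $value
#> [1] 0.0003000322
attr(relative_change_profile(scan), "first_step")
#> [1] 1.492707
```

The RMSE minimum sits at the unperturbed base value, and the first 0.1 mV
step away from it already raises the cost by ~149% — two orders of
magnitude more than the corresponding first-step change for `C` or
`tau_v`, which is the parameter ranking the analytic derivatives predict.

A thin command-line wrapper ships under `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lifmap.R",package="lifmap"))')" \
  simulate --stimulus table1 --out out/ --seed 1
```

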