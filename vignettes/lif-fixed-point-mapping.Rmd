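---
title: "Mapping leaky integrate-and-fire neurons onto fixed-point hardware arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping leaky integrate-and-fire neurons onto fixed-point hardware arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifmap)
```

## The problem

Digital neuromorphic chips implement spiking neurons as integer state
machines: the membrane potential lives in a bounded integer register, the
leak is a 12-bit multiplicative decay, and constant input currents are
stored as a mantissa times a power of two. Simulations written against a
conventional floating-point simulator therefore cannot be moved onto such
hardware without a change of representation, and the change of
representation is itself a source of error that must be quantified before
the hardware results can be trusted.

`lifmap` provides both sides of that comparison in one package: a
floating-point reference integrator for the leaky integrate-and-fire (LIF)
model in physical units, a software emulator of the fixed-point update
rule, the unit/integer mapping connecting them, a subthreshold cost
function measuring their disagreement, and perturbation scanners that
probe how fragile the agreement is to each model parameter.

## The two backends

### Reference model

The continuous LIF neuron is

$$ V'(t) = \frac{1}{C}\left[I_e(t) - \frac{1}{R}\big(V(t) - E_L\big)\right],
\qquad V(t) \leftarrow V_r \ \text{ if } V(t) > \Theta, $$

with capacitance $C$ (pF), resistance $R$ (G$\Omega$), resting potential
$E_L$ (mV), reset $V_r$, threshold $\Theta$, and membrane time constant
$\tau_v = RC$ (ms). The unit system pF/ms/mV/pA is closed: pA times
G$\Omega$ is mV, so no hidden conversion factors appear anywhere.
`simulate_reference()` integrates this equation by forward Euler.
Forward Euler is a deliberate choice, not a shortcut: the fixed-point
update rule below is itself a forward-Euler-form recursion, so using any
higher-order scheme on the reference side would make the two backends
disagree even in the limit of infinitely fine quantization. With
`exact = TRUE` and an unquantized decay the emulator recursion is
algebraically identical to the scaled Euler recursion, and the test suite
verifies agreement within one integer unit.

### Fixed-point emulator

The emulator state $v$ is an integer evolving as

$$ v(t+1) = v(t) - \operatorname{trunc}\!\left(\frac{v(t)\,\delta_v}{2^{12}}\right)
   + b + u(t), \qquad v \leftarrow 0 \ \text{ if } v > \theta_{\mathrm{int}}, $$

where $\delta_v \in [0, 4096]$ is the integer voltage decay,
$b = \text{mantissa} \times 2^{\text{exponent}}$ the encoded bias, and
$u(t)$ the per-step integer synaptic input. The decay is applied as
$v - \operatorname{trunc}(v\,\delta_v/2^{12})$ rather than
$\operatorname{trunc}(v\,(1 - \delta_v/2^{12}))$: the two are equivalent
in exact arithmetic, but the first form keeps every intermediate product
integral, which is what the integer-closure tests pin down. The reset
value is fixed at 0 — the integer domain measures voltage relative to
$V_r$.

### The mapping

States and parameters translate between the domains via

* voltage scale: $v = \operatorname{trunc}\big((V - V_r)/V_s\big)$
  (`rescale_state()`), inverted by $V = V_r + v\,V_s$;
* decay: $\delta_v = \operatorname{trunc}\big((dt/\tau_v)\,2^{12}\big)$
  (`compute_decay()`), inverted by $\tau_v = dt\,2^{12}/\delta_v$;
* bias: $b = \operatorname{trunc}\big(dt\,I_e/(C\,V_s)\big)$ — the
  continuous equation is a rate, so the per-step increment carries a
  factor of $dt$;
* resting-potential offset: when $E_L \neq V_r$ the term
  $(E_L - V_r)/(\tau_v V_s)$ becomes a constant per-step integer
  increment;
* spike weights (mV) scale by $1/V_s$.

**Rounding.** Truncation toward zero is used everywhere an integer is
produced from a ratio; it is the unique rounding mode consistent with
both the bias-encoding degradation table (1175 becomes 587 at exponent 1)
and the base decay value $\operatorname{trunc}(4096/22.2) = 184$. One
numerical guard is layered on top: `int_trunc()` adds $10^{-9}$ toward
the truncation boundary so that quotients which are integers in exact
arithmetic (the calibrated bias 1175, the integer threshold 19975) are
not dropped to the adjacent integer by double rounding. Quantities that
are genuinely fractional in this problem domain sit far more than
$10^{-9}$ from an integer, so the guard never changes a true truncation.

**Calibration of $V_s$.** The voltage scale is a free parameter of the
mapping. The package default is anchored so that the base stimulus
(200 pA into 170 pF at $dt = 1$ ms) maps to the integer bias 1175:
$V_s = (dt\,I_e/C)/1175 \approx 1.00125 \times 10^{-3}$ mV per unit
(`calibrated_vs()`). The naive choice $V_s = 10^{-3}$ would give 1176
instead; the anchor is the only printed constraint available, so the
calibrated value is the default and $V_s$ remains fully configurable.

## The cost function

Backends are compared on *subthreshold derivative traces*: forward
differences of the two voltage traces (the emulator's mapped back to mV),
with every derivative sample whose interval straddles a spike or reset in
either trace masked out, plus a one-step guard window on each side
(`subthreshold_mask()`). The primary cost is the RMSE of the unmasked
derivative samples, in mV/ms; a raw-voltage RMSE (mV) and the Pearson
correlation of the unmasked voltage samples are reported alongside
(`cost_report()`). Derivatives rather than raw voltages are the primary
metric because the analytic error decomposition below is exact for the
derivative residual, and because a constant voltage offset between
backends (pure quantization of the operating point) should not dominate
the cost.

For a validated configuration the derivative RMSE is bounded by the
single-step quantization error: each emulator step truncates the decay
product and the bias by at most one unit each and carries the decay
quantization defect $v\,(dt/\tau_v - \delta_v/2^{12})$, giving
$(V_s/dt)\,(2 + v_{\max}\,(dt/\tau_v - \delta_v/2^{12}))$ per step, and a
factor 2 covers the geometrically accumulated state error
(`quantization_bound()`). The acceptance tests check the measured RMSE
against this bound rather than against any particular printed value,
because the bound is derivable from the mapping alone.

### Analytic sensitivity

Subtracting the two backends' derivative equations collapses the residual
to a factored form whose per-sample bracket is

$$ e_i = \frac{(V_i - E_L)^2}{\tau_v^2} + \frac{I_e^2}{C^2}
       - \frac{2 (V_i - E_L) I_e}{\tau_v C}, $$

with RMSE $\sqrt{\overline{e}}\,/\,|V_s - 1|$ (`analytic_rmse()`). The
absolute value is ours: the derivation's scalar is $(V_s - 1)$, but
$V_s \approx 10^{-3} < 1$ in practice and a negative RMSE is meaningless.
The closed-form partials of $e$ (`analytic_partials()`) are the basis of
the parameter ranking: $\partial e/\partial E_L$ is *affine* in $E_L$,
while the $C$ and $\tau_v$ partials are nonlinear in their own
parameters, with inverse-cube leading terms. Because every cost value in
the operating regime is far below 1, the linear-rate parameter moves the
cost much faster than the nonlinear ones near the minimum — so the
resting potential is predicted, and observed, to dominate. The dichotomy
is asserted in the tests as second finite differences of the partials
(zero for $E_L$ to $10^{-9}$, nonzero for $C$ and $\tau_v$), which is the
exact content of the linearity claim; the bracket itself is quadratic in
$E_L$, so a second difference of $e$ would not vanish and would be the
wrong thing to test. The test suite also verifies, on 1000 randomized
inputs, that the analytic expression equals the direct RMSE applied to
the factored residual construction to $10^{-12}$ — the two routes are
implemented independently.

## Sensitivity scans

`oat_scan()` perturbs one parameter in one backend (the other backend
stays at the validated base), re-simulates, and records the masked
derivative RMSE per grid point; `tat_scan()` does the same over the
Cartesian product of two grids. Points are evaluated independently, so
results cannot depend on evaluation order, and per-point failures are
recorded as `NA` without aborting the scan.

Three conventions deserve explanation because the design was genuinely
open:

* **Initial condition.** Every scan run starts at the *base* resting
  potential rather than the perturbed one. Deviation dynamics of a
  linear neuron are translation invariant, so if $V(0)$ tracked the
  perturbed $E_L$ the perturbation would be dynamically invisible; the
  scan would measure nothing. Pinning $V(0)$ means an $E_L$ perturbation
  changes the drive toward rest, which is the effect the scan is meant to
  quantify.
* **Capacitance perturbations.** Perturbing $C$ alone holds the derived
  resistance $R$ fixed at its base value, so the effective time constant
  $\tau_v = RC$ scales with $C$. Without this convention $C$ would cancel
  out of the spike-driven dynamics entirely (the leak depends only on
  $\tau_v$, and delta-kernel spikes bypass the capacitor). When $C$ and
  $\tau_v$ are perturbed *together* in a TAT scan both are set directly
  and $R$ is recomputed. A consequence worth knowing: a TAT slice along
  $C$ at base $\tau_v$ is not the same computation as the OAT $C$ scan;
  slices that do not re-derive $C$'s effect (e.g. the $\tau_v$ slice at
  base $C$) match their OAT curves to $10^{-12}$ and are tested as such.
* **Emulator-side perturbations.** When the emulator is the perturbed
  backend, the physical parameters are re-mapped — and hence re-quantized
  — at every grid point. Emulator-side curves are therefore slightly
  step-like (several neighbouring $\tau_v$ values share one integer
  $\delta_v$); this is intended behaviour, not noise.

The preset grids are local ranges around the base neuron: $C$
$[160, 180]$ pF step 1 and $\tau_v$ $[21.0, 23.6]$ ms step 0.2 for the
spike regime, narrower $C$ $[169, 171.5]$ step 0.2 and shifted $\tau_v$
$[24.0, 26.2]$ step 0.2 for the bias regime, $E_L$ $[-71, -69]$ mV step
0.1 for both. The bias-regime anchors (170.21 pF, 25.1 ms, −70.04 mV)
are retained as declared grid annotations from a differently calibrated
voltage scale; under this package's calibration the bias-regime minima
for $C$ and $E_L$ fall within one grid step of the base values, and the
shifted $\tau_v$ range
deliberately excludes the base value, so no recovery property is claimed
for it.

`locate_minimum()` breaks exact ties toward the declared base value and
then lexicographically; `relative_change_profile()` reports
$(\mathrm{RMSE} - \mathrm{RMSE}_{\min})/\mathrm{RMSE}_{\min}$ per grid
step, falling back to absolute increases when the minimum is exactly
zero.

## Stimuli and the synthetic generator

Two stimulus regimes drive all validation and scan work:

* a constant bias current, default 200.0 pA, and
* a frozen table of eleven external spikes from five sources over
  500 ms (`stimulus_table1()`), shipped both as code and as a CSV
  fixture.

`poisson_spikes()` regenerates stimuli of the frozen table's kind:
homogeneous Poisson trains at 5 Hz per source (interpreting the 5 Hz
figure as the common rate; per-source rate draws in $(0, 5]$ Hz are
available behind `heterogeneous_rates = TRUE`), times snapped to the
sampling grid by truncation, reproducible under a seed. The generator
emulates rate and independence, not any structure the frozen table may
carry by accident of its single draw; passing tests therefore certify
the mapping and cost machinery under low-rate uncorrelated drive, and
say nothing about bursty or correlated inputs. The synaptic weight of an
external spike is not dictated by the model and defaults to 0.5 mV, a
typical unitary cortical EPSP amplitude; weights are per-source
configurable. `random_ei_network()` builds small Bernoulli(0.1)
excitatory/inhibitory networks (1:1 ratio) as a demo of network-scale
stimulus construction; network-level cost functions are out of scope.

## Defaults and tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| $C$ | 170 | pF | base neuron of the validation study |
| $\tau_v$ | 22.2 | ms | base neuron |
| $E_L = V_r$ | −70 | mV | reset at rest makes the offset drive vanish |
| $\Theta$ | −50 | mV | standard cortical threshold; not printed in the source study, configurable |
| $dt$ | 1 | ms | decay analysis is defined at this step |
| duration | 500 | ms | matches the stimulus table window |
| $V_s$ | $1.00125\times10^{-3}$ | mV/unit | calibrated: 200 pA $\to$ bias 1175 |
| spike weight | 0.5 | mV | typical unitary EPSP; not printed in the source study |
| guard | 1 | step | one Euler step of post-reset transient |
| overflow check | $2^{23}$ | units | surfaces a mis-scaled $V_s$; register width is configurable |

## Problem sizes

The shipped tests and the acceptance script run single neurons for 500
steps; the full preset scan suite (24 scans, roughly 3,600 grid points,
each a fresh 500-step simulation of the perturbed backend) completes in
well under a minute. These sizes were chosen to match the stimulus
window the frozen table defines; nothing in the implementation is
specific to them.

## Known limitations

* The emulator reproduces the arithmetic of the fixed-point update rule,
  not any particular silicon: no noise sources, synaptic delays,
  learning rules, dendritic compartments, or cycle-level behaviour.
* Only the voltage decay is modelled; a synaptic current decay parameter
  exists on real hardware but is not exercised by the delta-kernel
  stimulus and is not implemented.
* The exponential synaptic kernel is available on the reference side
  only; mapping it to the integer domain would require that current
  decay.
* Spike-timing-based cost functions are out of scope; the cost is
  defined on subthreshold segments precisely to exclude timing effects.
* Printed error minima from the study this package's regime follows
  (e.g. $4.208\times10^{-5}$ mV/ms) depend on an unpublished voltage
  scale and hardware rounding path; they are treated as reference
  annotations, never as targets, and the package's own acceptance
  properties are the quantization bound and the sub-1 mV/ms ceiling that
  are derivable from its own mapping.

## A worked validation

```{r validate}
params <- lif_params()
mapping <- mapping_config()
mp <- map_lif_to_loihi(params, stim_bias(200), mapping)
mp

ref <- simulate_reference(params, stim_bias(200))
emu <- as_lif_trace(
  simulate_emulator(mp$config, u = mp$u, n_steps = mp$n_steps),
  params$Vr, mapping)
cost_report(ref, emu)
```

```{r scan}
scan <- oat_scan(params, stim_spikes(stimulus_table1()), mapping,
                 preset_grid("EL", "spike"))
locate_minimum(scan)
```
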