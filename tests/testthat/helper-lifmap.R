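## Shared fixtures: the base neuron and mapping used across tests.

base_neuron <- function(...) lif_params(...)

base_mapping <- function(...) mapping_config(...)

table1_stim <- function(weight = 0.5) {
  stim_spikes(stimulus_table1(), weight = weight)
}

## Closed-form subthreshold solution for constant current:
## V(t) = V_inf + (V0 - V_inf) * exp(-t / tau), V_inf = EL + Ie * tau / C.
closed_form_voltage <- function(params, Ie, V0, times) {
  v_inf <- params$EL + Ie * params$tau_v / params$C
  v_inf + (V0 - v_inf) * exp(-times / params$tau_v)
}

## Run both backends under the default mapping and return mV traces.
run_both <- function(params = base_neuron(), stim = stim_bias(200),
                     mapping = base_mapping(), duration = 500,
                     V0 = NULL) {
  ref <- simulate_reference(params, stim, dt = mapping$dt,
                            duration = duration, V0 = V0)
  mp <- map_lif_to_loihi(params, stim, mapping, duration)
  emu_int <- simulate_emulator(mp$config, u = mp$u, n_steps = mp$n_steps)
  list(ref = ref, emu = as_lif_trace(emu_int, params$Vr, mapping),
       emu_int = emu_int, mapped = mp)
}
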