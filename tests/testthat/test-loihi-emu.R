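test_that("emulator reproduces hand-computable integer dynamics", {
  ## zero input: flat at zero, no spikes
  z <- simulate_emulator(loihi_config(delta_v = 100), u = 0, n_steps = 10)
  expect_true(all(z$values == 0))
  expect_length(z$spike_steps, 0)
  ## pure accumulation with no decay
  acc <- simulate_emulator(loihi_config(delta_v = 0, bias_mantissa = 1),
                           u = 0, n_steps = 5)
  expect_equal(acc$values, 0:5)
  ## full decay in one step: trunc(1000 * 4096 / 4096) = 1000
  full <- simulate_emulator(loihi_config(delta_v = 4096), u = 0,
                            n_steps = 3, v0 = 1000)
  expect_equal(full$values, c(1000, 0, 0, 0))
})

test_that("every emulator state is an integer for randomized configurations", {
  set.seed(71)
  for (k in 1:25) {
    cfg <- loihi_config(delta_v = sample(0:4096, 1),
                        bias_mantissa = sample(-300:300, 1),
                        bias_exponent = sample(0:3, 1),
                        theta_int = sample(c(Inf, 5000), 1))
    u <- sample(-50:50, 40, replace = TRUE)
    tr <- simulate_emulator(cfg, u = u, n_steps = 40,
                            v0 = sample(0:2000, 1))
    expect_true(all(tr$values == round(tr$values)))
  }
})

test_that("threshold crossing resets the integer state to zero", {
  cfg <- loihi_config(delta_v = 0, bias_mantissa = 10, theta_int = 25)
  tr <- simulate_emulator(cfg, u = 0, n_steps = 10)
  expect_gt(length(tr$spike_steps), 0)
  for (s in tr$spike_steps) {
    expect_gt(tr$values[s + 1], 25)       # suprathreshold at the spike step
    expect_identical(tr$values[s + 2], 0) # reset at the next step
  }
})

test_that("state overflow raises an error naming the voltage scale", {
  cfg <- loihi_config(delta_v = 0, bias_mantissa = 4096,
                      bias_exponent = 7)
  expect_error(simulate_emulator(cfg, u = 0, n_steps = 100), "Vs")
})

test_that("bias encoding reproduces the mantissa/exponent arithmetic", {
  e0 <- encode_bias(1175, 0)
  expect_identical(e0$mantissa, 1175)
  expect_identical(e0$reconstructed, 1175)
  e3 <- encode_bias(1175, 3)
  expect_identical(e3$mantissa, 146)
  expect_identical(e3$reconstructed, 1168)
  expect_identical(encode_bias(0, 7)$reconstructed, 0)
  expect_error(encode_bias(1175, 8), "exponent")
  expect_error(encode_bias(1e7, 0), "mantissa")
})

test_that("encoding error is non-decreasing in the exponent and bounded by the input", {
  for (bias in c(1175, 333, 4095, 2048, -1175)) {
    err <- vapply(0:7, function(e) {
      enc <- encode_bias(bias, e)
      expect_lte(abs(enc$reconstructed), abs(bias))  # never overshoots
      abs(bias - enc$reconstructed)
    }, numeric(1))
    expect_true(all(diff(err) >= 0))
    expect_identical(err[1], 0)  # exponent 0 is the identity
  }
})

test_that("emulator in the exact fine-Vs limit matches the reference Euler trace", {
  p <- base_neuron(theta = Inf)
  m <- mapping_config(Vs = 1e-4)  # 1 unit = 1e-4 mV
  ref <- simulate_reference(p, stim_bias(200), dt = 1, duration = 500)
  ## unquantized decay and unencoded (real) bias: the recursion is the
  ## scaled Euler update, so agreement must be within one integer unit
  delta_real <- (m$dt / p$tau_v) * 2^12
  b_real <- m$dt * 200 / (p$C * m$Vs)
  emu <- simulate_emulator(
    loihi_config(delta_v = 0, theta_int = Inf), u = rep(b_real, 500),
    n_steps = 500, exact = TRUE, delta_v_real = delta_real,
    overflow_limit = Inf)
  mapped <- p$Vr + emu$values * m$Vs
  expect_lt(max(abs(mapped - ref$values)), m$Vs)
})

test_that("decay sweeps locate the decay matching the reference time constant", {
  p <- base_neuron(theta = Inf)
  m <- base_mapping()
  stim <- stim_bias(200)
  mp <- map_lif_to_loihi(p, stim, m)
  ref <- simulate_reference(p, stim, dt = m$dt, duration = 500)
  ## single-point sweep
  s0 <- decay_sweep(mp$config, 184, 0, ref, m, u = 0)
  expect_length(s0$rmse_values, 1)
  ## self-consistency: a reference whose time constant is exactly the
  ## inverse image of delta_v = 184 is best matched by that grid point
  ref_sc <- simulate_reference(
    base_neuron(tau_v = invert_decay(184), theta = Inf), stim,
    dt = m$dt, duration = 500)
  s1 <- decay_sweep(mp$config, 184, 5, ref_sc, m, u = 0)
  expect_equal(unname(locate_minimum(s1)$coordinates), 184)
  ## a reference built at tau = 21.2 ms is best matched by delta_v = 193
  ref2 <- simulate_reference(base_neuron(tau_v = 21.2, theta = Inf),
                             stim, dt = m$dt, duration = 500)
  s2 <- decay_sweep(mp$config, 184, 30, ref2, m, u = 0)
  expect_equal(unname(locate_minimum(s2)$coordinates), 193)
})
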