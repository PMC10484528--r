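test_that("rmse matches hand arithmetic and is symmetric", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(5, 5, 5), c(3, 3, 3)), 2)          # constant offset
  expect_equal(rmse(c(0, 0, 0), c(3, 4, 0)), sqrt(25 / 3),
               tolerance = 1e-12)
  x <- rnorm(50); y <- rnorm(50)
  expect_identical(rmse(x, y), rmse(y, x))
  expect_error(rmse(1:3, 1:4), "equal length")
  expect_error(rmse(1:3, 4:6, mask = c(FALSE, FALSE, FALSE)),
               "over-masked")
})

test_that("subthreshold mask excludes spike-straddling derivative samples", {
  quiet <- simulate_reference(base_neuron(theta = Inf), stim_bias(0))
  expect_true(all(subthreshold_mask(quiet, quiet)))
  ## single spike at a known step
  spiky <- lif_trace(dt = 1, duration = 10, values = rep(-70, 11),
                     spike_times = 5)
  m <- subthreshold_mask(spiky, quiet_trace <- lif_trace(
    dt = 1, duration = 10, values = rep(-70, 11)))
  expect_identical(which(!m), 5:7)   # k-1, k, k+1 with guard 1 (k = 6)
  ## union property: the pair mask is the AND of the individual masks
  other <- lif_trace(dt = 1, duration = 10, values = rep(-70, 11),
                     spike_times = 2)
  m_pair <- subthreshold_mask(spiky, other)
  m_a <- subthreshold_mask(spiky, quiet_trace)
  m_b <- subthreshold_mask(other, quiet_trace)
  expect_identical(m_pair, m_a & m_b)
  expect_error(subthreshold_mask(quiet, spiky), "misaligned")
})

test_that("trace correlation behaves like Pearson r on unmasked samples", {
  tr <- simulate_reference(base_neuron(), stim_bias(200))
  expect_equal(trace_correlation(tr, tr), 1.0)
  neg <- lif_trace(dt = tr$dt, duration = tr$duration,
                   values = 2 * mean(tr$values) - tr$values,
                   spike_times = tr$spike_times)
  expect_equal(trace_correlation(tr, neg), -1.0)
  set.seed(42)
  noisy <- lif_trace(dt = tr$dt, duration = tr$duration,
                     values = tr$values +
                       rnorm(length(tr$values),
                             sd = 1e-4 * diff(range(tr$values))),
                     spike_times = tr$spike_times)
  expect_gt(trace_correlation(tr, noisy), 0.999)
  flat <- lif_trace(dt = 1, duration = 10, values = rep(-70, 11))
  expect_error(trace_correlation(flat, flat), "degenerate")
})

test_that("analytic RMSE matches its algebraic special cases", {
  p <- base_neuron()
  ## all samples at rest, no current: zero cost
  a0 <- analytic_rmse(p, Vs = 1e-3, V_samples = rep(-70, 10), Ie = 0)
  expect_true(all(a0$e_values == 0))
  expect_identical(a0$rmse_analytic, 0)
  ## single sample: the bracket is a perfect square
  V <- -61.3; Ie <- 140; Vs <- 2e-3
  a1 <- analytic_rmse(p, Vs, V, Ie)
  expect_equal(a1$rmse_analytic,
               abs((V - p$EL) / p$tau_v - Ie / p$C) / abs(Vs - 1),
               tolerance = 1e-12)
  expect_error(analytic_rmse(p, Vs = 1, V_samples = -70, Ie = 0),
               "degenerate")
})

test_that("closed-form partials agree with central finite differences", {
  p <- base_neuron()
  expect_equal(analytic_partials(p, V = -70, Ie = 0),
               list(dE_dC = 0, dE_dtau = 0, dE_dEL = 0))
  ## root of the affine EL partial: V - EL = tau * Ie / C
  Ie <- 200
  V_root <- p$EL + p$tau_v * Ie / p$C
  expect_equal(analytic_partials(p, V_root, Ie)$dE_dEL, 0,
               tolerance = 1e-15)
  ## randomized finite-difference agreement
  set.seed(9)
  bracket <- function(C, tau, EL, V, Ie) {
    (V - EL)^2 / tau^2 + Ie^2 / C^2 - 2 * (V - EL) * Ie / (tau * C)
  }
  for (k in 1:20) {
    C <- runif(1, 100, 250); tau <- runif(1, 10, 40)
    EL <- runif(1, -80, -60); V <- runif(1, -75, -40)
    Ie <- runif(1, 0, 400)
    pp <- lif_params(C = C, tau_v = tau, EL = EL, Vr = EL,
                     theta = EL + 20)
    got <- analytic_partials(pp, V, Ie)
    h <- 1e-4
    fd <- list(
      dE_dC = (bracket(C + h, tau, EL, V, Ie) -
                 bracket(C - h, tau, EL, V, Ie)) / (2 * h),
      dE_dtau = (bracket(C, tau + h, EL, V, Ie) -
                   bracket(C, tau - h, EL, V, Ie)) / (2 * h),
      dE_dEL = (bracket(C, tau, EL + h, V, Ie) -
                  bracket(C, tau, EL - h, V, Ie)) / (2 * h)
    )
    for (nm in names(fd))
      expect_equal(got[[nm]], fd[[nm]], tolerance = 1e-6)
  }
})

test_that("parameters rank by descending sensitivity with stable ties", {
  expect_identical(
    rank_parameters(c(EL = 0.42, tau_v = 0.002, C = 0.002)),
    c("EL", "tau_v", "C"))
  expect_identical(rank_parameters(c(EL = 1)), "EL")
  expect_error(rank_parameters(c(EL = NA, C = 1)), "comparable")
})

test_that("cost report summarizes a validated run and serializes to JSON", {
  res <- run_both()
  rep <- cost_report(res$ref, res$emu)
  expect_gte(rep$rmse_mv_per_ms, 0)
  expect_lt(rep$masked_fraction, 1)
  expect_gt(rep$correlation, 0.999)
  path <- withr::local_tempfile(fileext = ".json")
  write_cost_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$rmse_mv_per_ms, rep$rmse_mv_per_ms,
               tolerance = 1e-12)
  expect_named(parsed, c("rmse_mv_per_ms", "voltage_rmse_mv",
                         "correlation", "n_samples", "masked_fraction"))
})
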