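test_that("grids validate their construction", {
  g <- param_grid("EL", -71, -69, 0.1, base = -70)
  expect_length(g$values, 21)
  expect_error(param_grid("EL", values = c(1, 1, 2)), "increasing")
  expect_error(param_grid("EL", values = 1:3, base = 9), "base")
  expect_error(
    tat_scan(base_neuron(), stim_bias(200), base_mapping(),
             param_grid("C", values = 169:171),
             param_grid("C", values = 169:171)),
    "distinct")
})

test_that("a single-point grid reproduces the base validation RMSE", {
  res <- run_both(stim = table1_stim())
  mask <- subthreshold_mask(res$ref, res$emu)
  base_rmse <- rmse(derivative_trace(res$emu), derivative_trace(res$ref),
                    mask)
  g <- param_grid("EL", values = -70, base = -70)
  s <- oat_scan(base_neuron(), table1_stim(), base_mapping(), g)
  expect_equal(unname(s$rmse_values), base_rmse, tolerance = 1e-12)
})

test_that("TAT has Cartesian-product shape and its slices match OAT curves", {
  p <- base_neuron(); m <- base_mapping(); stim <- table1_stim()
  ga <- param_grid("C", values = c(168, 170, 172), base = 170)
  gb <- param_grid("tau_v", values = c(21.8, 22.2, 22.6, 23.0),
                   base = 22.2)
  tt <- tat_scan(p, stim, m, ga, gb, duration = 200)
  expect_identical(dim(tt$rmse_values), c(3L, 4L))
  ## slicing at C = base reproduces the OAT tau curve point for point
  oat_tau <- oat_scan(p, stim, m, gb, duration = 200)
  expect_equal(unname(tt$rmse_values[2, ]), unname(oat_tau$rmse_values),
               tolerance = 1e-12)
  ## slicing {tau, EL} at tau = base reproduces the OAT EL curve
  gel <- param_grid("EL", values = c(-70.2, -70, -69.8), base = -70)
  tt2 <- tat_scan(p, stim, m, param_grid("tau_v", values = 22.2,
                                         base = 22.2),
                  gel, duration = 200)
  oat_el <- oat_scan(p, stim, m, gel, duration = 200)
  expect_equal(unname(tt2$rmse_values[1, ]), unname(oat_el$rmse_values),
               tolerance = 1e-12)
})

test_that("scan results are independent of grid evaluation order", {
  p <- base_neuron(); m <- base_mapping(); stim <- table1_stim()
  vals <- c(-70.4, -70.2, -70, -69.8, -69.6)
  fwd <- oat_scan(p, stim, m, param_grid("EL", values = vals, base = -70),
                  duration = 200)
  ## evaluating each point as its own single-point grid = shuffled order
  set.seed(3)
  shuffled <- sample(seq_along(vals))
  one_by_one <- vapply(vals[shuffled], function(v) {
    s <- oat_scan(p, stim, m, param_grid("EL", values = v, base = v),
                  duration = 200)
    unname(s$rmse_values)
  }, numeric(1))
  expect_equal(one_by_one[order(shuffled)], unname(fwd$rmse_values),
               tolerance = 1e-14)
})

test_that("minimum location breaks ties toward the base value", {
  flat <- sensitivity_grid(
    axes = list(param_grid("EL", values = c(-71, -70, -69), base = -70)),
    direction = "reference", rmse_values = c(1, 1, 1))
  m <- locate_minimum(flat)
  expect_equal(unname(m$coordinates), -70)
  convex <- sensitivity_grid(
    axes = list(param_grid("C", values = 160:180, base = 170)),
    direction = "reference", rmse_values = (160:180 - 173)^2 + 2)
  expect_equal(unname(locate_minimum(convex)$coordinates), 173)
  expect_equal(locate_minimum(convex)$value, 2)
})

test_that("relative change profiles report fractional increases from the minimum", {
  g <- param_grid("EL", values = c(-70.1, -70, -69.9), base = -70)
  s3 <- sensitivity_grid(axes = list(g), direction = "reference",
                         rmse_values = c(1.42, 1, 2))
  prof <- relative_change_profile(s3)
  expect_equal(as.numeric(prof), c(0.42, 0, 1.0), tolerance = 1e-12)
  expect_equal(attr(prof, "first_step"), 1.0)
  flat <- sensitivity_grid(axes = list(g), direction = "reference",
                           rmse_values = c(2, 2, 2))
  expect_true(all(relative_change_profile(flat) == 0))
  edge <- sensitivity_grid(axes = list(g), direction = "reference",
                           rmse_values = c(1, 2, 3))
  expect_error(relative_change_profile(edge), "boundary")
})

test_that("spike-input OAT scans recover base parameters in both directions", {
  p <- base_neuron(); m <- base_mapping(); stim <- table1_stim()
  for (dir in c("reference", "emulator")) {
    for (prm in c("C", "tau_v", "EL")) {
      g <- preset_grid(prm, "spike")
      s <- oat_scan(p, stim, m, g, direction = dir)
      arg <- unname(locate_minimum(s)$coordinates)
      step <- g$values[2] - g$values[1]
      expect_lte(abs(arg - g$base), step + 1e-9,
                 label = sprintf("%s-side %s argmin", dir, prm))
    }
  }
})

test_that("perturbation directions locate the same minimum for EL", {
  p <- base_neuron(); m <- base_mapping(); stim <- table1_stim()
  g <- preset_grid("EL", "spike")
  ref_side <- oat_scan(p, stim, m, g, direction = "reference")
  emu_side <- oat_scan(p, stim, m, g, direction = "emulator")
  expect_equal(locate_minimum(ref_side)$coordinates,
               locate_minimum(emu_side)$coordinates)
})

test_that("RMSE grows monotonically away from the spike-input EL minimum", {
  s <- oat_scan(base_neuron(), table1_stim(), base_mapping(),
                preset_grid("EL", "spike"))
  i <- locate_minimum(s)$index[1]
  v <- as.numeric(s$rmse_values)
  expect_true(all(diff(v[i:length(v)]) >= -1e-12))
  expect_true(all(diff(rev(v[1:i])) >= -1e-12))
})

test_that("scan exports round-trip through CSV and JSON", {
  g <- param_grid("EL", values = c(-70.2, -70, -69.8), base = -70)
  s <- oat_scan(base_neuron(), table1_stim(), base_mapping(), g,
                duration = 200)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_scan_csv(s, csv)
  df <- read.csv(csv)
  expect_named(df, c("param_1", "value_1", "direction", "rmse"))
  expect_equal(df$rmse, unname(s$rmse_values), tolerance = 1e-9)
  write_scan_summary(s, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$argmin$EL, -70)
})
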