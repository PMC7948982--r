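test_that("noise-free exponential phases are recovered to high accuracy", {
  t <- log_grid(0.002, 1, 200)
  y <- 1 - exp(-16.52 * t)
  fit <- fit_exponentials(data.frame(time = t, value = y), 1)
  expect_lt(rel_err(fit$phases$kobs, 16.52), 1e-3)
  expect_equal(fit$phases$amplitude, -1, tolerance = 1e-4)
  expect_equal(fit$offset, 1, tolerance = 1e-4)

  # biexponential with the fluorescent-intermediate rates
  t2 <- log_grid(0.002, 100, 400)
  y2 <- 0.2 + 0.8 * exp(-1.5 * t2) - 1.1 * exp(-0.073 * t2)
  fit2 <- fit_exponentials(data.frame(time = t2, value = y2), 2)
  expect_lt(rel_err(fit2$phases$kobs[1], 1.5), 0.005)
  expect_lt(rel_err(fit2$phases$kobs[2], 0.073), 0.005)
  # phases ordered by decreasing kobs
  expect_true(all(diff(fit2$phases$kobs) < 0))
})

test_that("degenerate traces are rejected and near-equal rates flagged", {
  t <- seq(0.01, 10, length.out = 60)
  expect_error(fit_exponentials(data.frame(time = t, value = rep(2, 60)), 1),
               class = "halokin_fit_error")
  y <- exp(-1.00 * t) + exp(-1.02 * t)
  fit <- fit_exponentials(data.frame(time = t, value = y), 2)
  expect_true(fit$ill_conditioned)
})

test_that("phase-count selection matches the known phase structure", {
  t <- log_grid(0.002, 1, 120)
  y1 <- 1 - exp(-16.52 * t)
  expect_identical(select_phase_count(data.frame(t, y1), 3), 1L)

  tt <- thal_truths()
  a380 <- generate_trace(tt$halide_free_trace, "A380", noise = noise_model(0))
  expect_identical(select_phase_count(a380, 3), 2L)

  a450 <- generate_trace(tt$chloride_flux_trace, "A450", noise = noise_model(0))
  expect_identical(select_phase_count(a450, 4), 3L)

  expect_error(select_phase_count(a380, 5), class = "halokin_validation_error")
})

test_that("predict_kobs satisfies its identities", {
  expect_equal(predict_kobs(0.064, 4.51, 0.064), 4.51 / 2)
  expect_equal(predict_kobs(0.78, 1.83, 0), 0)
  expect_equal(predict_kobs(0.78, 1.83, 10), 1.70, tolerance = 0.002)
  expect_error(predict_kobs(-1, 2, 1), class = "halokin_validation_error")
})

test_that("saturation fit recovers noise-free truths exactly", {
  sat <- truths$saturation
  for (h in names(sat)) {
    tr <- sat[[h]]
    ds <- generate_saturation_dataset(h, tr$Kd, tr$k, tr$concs,
                                      noise = noise_model(0))
    fit <- fit_saturation(ds)
    expect_lt(rel_err(fit$Kd, tr$Kd), 1e-3)
    expect_lt(rel_err(fit$k, tr$k), 1e-3)
  }
})

test_that("saturation fit is scale-equivariant in concentration", {
  tr <- truths$saturation$Br
  ds <- generate_saturation_dataset("Br", tr$Kd, tr$k, tr$concs,
                                    noise = noise_model(0.02, seed = 8))
  f1 <- fit_saturation(ds)
  ds2 <- saturation_dataset("Br", ds$conc_mM * 7, ds$kobs_s1, se = ds$se)
  f2 <- fit_saturation(ds2)
  expect_equal(f2$Kd, 7 * f1$Kd, tolerance = 1e-6)
  expect_equal(f2$k, f1$k, tolerance = 1e-6)
})

test_that("saturation optimum matches the brute-force grid search", {
  tr <- truths$saturation$I
  ds <- generate_saturation_dataset("I", tr$Kd, tr$k, tr$concs,
                                    noise = noise_model(0.02, seed = 21))
  ds$se <- NULL  # unweighted, same objective as the grid oracle
  fit <- fit_saturation(ds)
  gs <- grid_search_saturation(ds$conc_mM, ds$kobs_s1)
  expect_lt(abs(log(fit$Kd) - log(gs$Kd)), gs$cell_Kd)
  expect_lt(abs(log(fit$k) - log(gs$k)), gs$cell_k)
})

test_that("uninformative saturation designs raise unidentifiability errors", {
  # straight line through the origin: concentrations far below Kd
  conc <- seq(0.01, 0.05, length.out = 6)
  ds_lin <- saturation_dataset("Cl", conc, predict_kobs(50, 2, conc))
  expect_error(fit_saturation(ds_lin), class = "halokin_unidentifiable_error")

  # all concentrations far above Kd: every point already saturated
  conc2 <- c(50, 120, 300, 700, 1500)
  ds_sat <- saturation_dataset("I", conc2, predict_kobs(0.064, 4.51, conc2))
  expect_error(fit_saturation(ds_sat), class = "halokin_unidentifiable_error")
})

test_that("fitted halide order reproduces the measured reactivity series", {
  fits <- lapply(names(truths$saturation), function(h) {
    tr <- truths$saturation[[h]]
    fit_saturation(generate_saturation_dataset(h, tr$Kd, tr$k, tr$concs,
                                               noise = noise_model(0)))
  })
  names(fits) <- names(truths$saturation)
  expect_gt(fits$I$k, fits$Br$k)
  expect_gt(fits$Br$k, fits$Cl$k)
  expect_lt(fits$I$Kd, fits$Br$Kd)
  expect_lt(fits$Br$Kd, fits$Cl$Kd)
})

test_that("inactivation series fit recovers the isomerization rate", {
  tr <- truths$inactivation
  ser <- generate_inactivation_series(tr$k_inact, tr$ages, A0 = tr$A0,
                                      noise = noise_model(0))
  fit <- fit_inactivation(ser)
  expect_lt(rel_err(fit$k_inact, 0.41), 1e-3)
  expect_equal(fit$A0, tr$A0, tolerance = 1e-4)
  # the shortest preincubation keeps nearly the full amplitude
  expect_equal(ser$amplitude[1], tr$A0, tolerance = 0.005)

  flat <- inactivation_series(c(0.01, 1, 5, 30), rep(0.13, 4))
  expect_error(fit_inactivation(flat), class = "halokin_fit_error")
})

test_that("fitted 2-SE intervals are calibrated under 2% noise", {
  # 200 seeded replicates per fitter; coverage of a +/-2 SE interval is
  # pooled across parameters. The nominal rate of a +/-2 SE interval is
  # 95.45%, so the pooled observation is checked against nominal minus its
  # one-sided 99% binomial sampling allowance at this replicate count.
  n_rep <- 200L
  hits <- 0L
  total <- 0L

  # single-exponential trace fits, 500 points
  t <- log_grid(0.002, 1, 500)
  mu <- 1 - exp(-16.52 * t)
  for (r in seq_len(n_rep)) {
    y <- mu + withr::with_seed(30000 + r, rnorm(500, 0, 0.02))
    fit <- fit_exponentials(data.frame(time = t, value = y), 1)
    hits <- hits + (abs(fit$phases$kobs - 16.52) <= 2 * fit$phases$se_kobs) +
      (abs(fit$phases$amplitude + 1) <= 2 * fit$phases$se_amplitude) +
      (abs(fit$offset - 1) <= 2 * fit$se_offset)
    total <- total + 3L
  }

  # inactivation fits, 500 age points
  ages <- seq(0.01, 15, length.out = 500)
  mu2 <- 0.13 * exp(-0.41 * ages)
  for (r in seq_len(n_rep)) {
    amp <- mu2 + withr::with_seed(40000 + r, rnorm(500, 0, 0.02 * 0.13))
    fit <- fit_inactivation(inactivation_series(ages, amp))
    hits <- hits + (abs(fit$k_inact - 0.41) <= 2 * fit$se_k_inact)
    total <- total + 1L
  }

  nominal <- 2 * stats::pnorm(2) - 1
  allowance <- stats::qnorm(0.99) * sqrt(nominal * (1 - nominal) / total)
  expect_gte(hits / total, nominal - allowance)
})
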