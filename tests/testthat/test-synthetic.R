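test_that("generators are seed-reproducible and noiseless at sigma 0", {
  tt <- truths$halide_free_trace
  grid <- log_grid(n = 120)
  det <- generate_trace(tt, "A380", grid, noise = noise_model(0))
  tc <- simulate_scheme(tt$params, tt$init, tt$halide, grid)
  expect_equal(det$value, species_to_trace(tc, optical_model(), "A380")$value)

  n1 <- generate_trace(tt, "A380", grid, noise = noise_model(0.02, seed = 5))
  n2 <- generate_trace(tt, "A380", grid, noise = noise_model(0.02, seed = 5))
  n3 <- generate_trace(tt, "A380", grid, noise = noise_model(0.02, seed = 6))
  expect_identical(n1$value, n2$value)
  expect_false(identical(n1$value, n3$value))
  # different seeds share the same underlying mean
  expect_equal(mean(n1$value - n3$value), 0,
               tolerance = 5 * 0.02 * diff(range(det$value)) / sqrt(120))
  # generators do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_trace(tt, "A380", grid,
                                        noise = noise_model(0.02, seed = 9)))
  expect_identical(runif(1), a)
})

test_that("the truth sidecar round-trips losslessly", {
  tt <- truths$chloride_pop_trace
  tr <- generate_trace(tt, "F_ex380", log_grid(n = 40),
                       noise = noise_model(0.02, seed = 13))
  truth <- attr(tr, "truth")
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_identical(back$seed, 13L)
  expect_identical(back$sigma_frac, 0.02)
  expect_identical(back$truth$params$k_unc, tt$params$k_unc)
  expect_equal(unlist(back$truth$params$Kd_X)[c("I", "Br", "Cl")],
               tt$params$Kd_X[c("I", "Br", "Cl")])
  expect_identical(back$truth$params$f_unc_pop, 0.55)
  expect_equal(back$truth$init$X_conc, 10)
})

test_that("saturation generator lies on the hyperbola and exposes failure modes", {
  tr <- truths$saturation$I
  ds0 <- generate_saturation_dataset("I", tr$Kd, tr$k, tr$concs,
                                     noise = noise_model(0))
  expect_equal(ds0$kobs_s1, predict_kobs(tr$Kd, tr$k, tr$concs))
  fit <- fit_saturation(ds0)
  expect_equal(fit$Kd, 0.064, tolerance = 1e-4)
  expect_equal(fit$k, 4.51, tolerance = 1e-4)

  # design with every concentration far above Kd is unidentifiable
  ds_bad <- generate_saturation_dataset("I", tr$Kd, tr$k,
                                        c(50, 150, 400, 1000),
                                        noise = noise_model(0))
  expect_error(fit_saturation(ds_bad), class = "halokin_unidentifiable_error")
})

test_that("inactivation and quench generators match their analytic forms", {
  tr <- truths$inactivation
  ser <- generate_inactivation_series(tr$k_inact, tr$ages, A0 = tr$A0,
                                      floor = 0.01, noise = noise_model(0))
  expect_equal(ser$amplitude, 0.01 + tr$A0 * exp(-0.41 * tr$ages))
  expect_equal(ser$amplitude[1], 0.01 + tr$A0, tolerance = 0.005)
  expect_equal(ser$amplitude[length(tr$ages)], 0.01, tolerance = 1e-3)

  st <- truths$single_turnover
  qt <- c(0.001, log_grid(0.02, 100, 25), 400)
  q <- generate_quench_series(st, qt, noise = noise_model(0))
  expect_equal(q$halogenated_fraction[1], 0, tolerance = 1e-5)
  expect_true(all(diff(q$halogenated_fraction) >= -1e-12))
  expect_equal(q$halogenated_fraction[nrow(q)], 0.30, tolerance = 1e-3)
  # noisy fractions stay within [0, 1]
  qn <- generate_quench_series(st, qt, noise = noise_model(0.05, seed = 2))
  expect_true(all(qn$halogenated_fraction >= 0 & qn$halogenated_fraction <= 1))
})

test_that("generate -> fit closes the loop on every truth parameter", {
  # the central round-trip property, at 2% noise with fixed seeds
  tt <- truths$halide_free_trace
  tr <- generate_trace(tt, "A380", noise = noise_model(0.02, seed = 31))
  fit <- fit_exponentials(tr, 2)
  expect_lt(abs(fit$phases$kobs[1] - 16.52), 2.5 * fit$phases$se_kobs[1] + 0.15)
  expect_lt(abs(fit$phases$kobs[2] - 0.41), 2.5 * fit$phases$se_kobs[2] + 0.01)

  sat <- truths$saturation$Br
  ds <- generate_saturation_dataset("Br", sat$Kd, sat$k, sat$concs,
                                    noise = noise_model(0.02, seed = 32))
  sf <- fit_saturation(ds)
  expect_lt(abs(sf$Kd - 0.40), 3 * sf$se_Kd)
  expect_lt(abs(sf$k - 2.54), 3 * sf$se_k)

  ser <- generate_inactivation_series(0.41, truths$inactivation$ages,
                                      noise = noise_model(0.02, seed = 33))
  fi <- fit_inactivation(ser)
  expect_lt(abs(fi$k_inact - 0.41), 3 * fi$se_k_inact + 0.02)
})
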