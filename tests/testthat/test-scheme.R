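test_that("closed-form chain matches its analytic landmarks", {
  # boundary values
  cf0 <- closed_form_chain(16.52, 0.41, 15, 0)
  expect_equal(unlist(cf0[c("A", "B", "C")]), c(A = 15, B = 0, C = 0))

  # intermediate peak: dB/dt = 0 at t = ln(k1/k2)/(k1 - k2)
  t_peak <- log(16.52 / 0.41) / (16.52 - 0.41)
  expect_equal(t_peak, 0.229, tolerance = 5e-3)
  cf <- closed_form_chain(16.52, 0.41, 15, t_peak)
  expect_equal(cf$B, 13.65, tolerance = 1e-3)
  expect_equal(cf$B / 15, 0.910, tolerance = 1e-3)

  # completion
  cf_end <- closed_form_chain(16.52, 0.41, 15, 1000)
  expect_lt(cf_end$A + cf_end$B, 1e-8)
  expect_equal(cf_end$C, 15, tolerance = 1e-8)

  # degenerate k1 = k2 is rejected
  expect_error(closed_form_chain(1, 1, 15, 0.1),
               class = "halokin_degenerate_error")
})

test_that("ODE integration matches the closed-form chain everywhere", {
  grid <- log_grid(0.002, 100, 400)
  tc <- simulate_scheme(chain_params(), chain_init(), "Cl", grid)
  cf <- closed_form_chain(16.52, 0.41, 15, grid)
  expect_lt(max(abs(tc$E_FADH - cf$A)) / 15, 1e-6)
  expect_lt(max(abs(tc$C4aOOH - cf$B)) / 15, 1e-6)
  expect_lt(max(abs(tc$E_FAD - cf$C)) / 15, 1e-6)
})

test_that("total flavin is conserved in every mode", {
  grid <- log_grid(0.002, 50, 120)
  set.seed(99)
  for (i in 1:6) {
    params <- rate_parameters(
      k_bind_flavin = runif(1, 0, 5), k_inact = runif(1, 0, 1),
      k_ox = runif(1, 0.01, 0.2), k_unc = runif(1, 0.05, 2),
      k_dehyd = runif(1, 0.01, 0.5), k_capture = runif(1, 0, 50),
      k_leak = runif(1, 0, 50),
      f_unc_pop = if (i %% 2) NA_real_ else runif(1)
    )
    init <- initial_conditions(E_FADH = 10, FADH_free = 5, E_free = 20,
                               Trp = 30, O2 = 128, X_conc = runif(1, 0, 20))
    mode <- if (i %% 3) "rapid_equilibrium" else "explicit"
    tc <- simulate_scheme(params, init, sample(c("Cl", "Br", "I"), 1),
                          grid, mode = mode)
    ft <- flavin_total(tc)
    expect_lt(diff(range(ft)) / ft[1], 1e-6)
  }
})

test_that("no flux without rates, and no halide branch without halide", {
  grid <- linear_grid(0.01, 10, 50)
  zero <- rate_parameters(k_bind_flavin = 0, k_inact = 0, k_ox = 0,
                          k_unc = 0, k_dehyd = 0, k_capture = 0, k_leak = 0)
  init <- initial_conditions(E_FADH = 15, FADH_free = 3, Trp = 10,
                             O2 = 128, X_conc = 10)
  tc <- simulate_scheme(zero, init, "Cl", grid)
  for (sp in scheme_species()) {
    expect_equal(diff(range(tc[[sp]])), 0)
  }

  # zero halide: HOX branch carries no flux
  tc0 <- simulate_scheme(rate_parameters(), chain_init(), "Cl", grid)
  expect_equal(max(tc0$C4aOH), 0)
  expect_equal(max(tc0$HOX_site + tc0$HOX_free + tc0$TrpX), 0)
})

test_that("fluoride forms no fluorescent intermediate at any concentration", {
  grid <- log_grid(0.002, 100, 100)
  init <- initial_conditions(E_FADH = 15, O2 = 128, X_conc = 50)
  tc <- simulate_scheme(rate_parameters(), init, "F", grid)
  expect_equal(max(tc$C4aOH), 0)
  expect_equal(max(tc$HOX_free), 0)
})

test_that("cumulative HOX flux is monotone in halide concentration", {
  grid <- log_grid(0.002, 100, 80)
  hox_yield <- vapply(c(0, 0.2, 0.8, 2, 10, 100), function(x) {
    init <- initial_conditions(E_FADH = 15, O2 = 128, X_conc = x)
    tc <- simulate_scheme(rate_parameters(k_capture = 0, k_leak = 5),
                          init, "Cl", grid)
    tc$HOX_free[nrow(tc)]
  }, numeric(1))
  expect_true(all(diff(hox_yield) >= 0))
})

test_that("effective HOX rate saturates to the limiting rate", {
  p <- rate_parameters()
  for (h in c("Cl", "Br", "I")) {
    Kd <- p$Kd_X[[h]]
    expect_equal(k_hox_obs(p, h, 100 * Kd), p$k_hox[[h]],
                 tolerance = 0.01)
    expect_equal(k_hox_obs(p, h, 0), 0)
  }
  # tabulated chloride constants at 10 mM
  expect_equal(k_hox_obs(rate_parameters(), "Cl", 10), 1.70,
               tolerance = 0.002)
})

test_that("explicit halide binding reproduces the rapid-equilibrium limit", {
  grid <- log_grid(0.002, 100, 120)
  init <- initial_conditions(E_FADH = 15, O2 = 128, X_conc = 2)
  re <- simulate_scheme(rate_parameters(), init, "Br", grid)
  ex <- simulate_scheme(rate_parameters(), init, "Br", grid,
                        mode = "explicit", kon = 1e4 / 0.40)
  # compare total C4aOOH (free + halide-bound) and downstream product
  expect_lt(max(abs((ex$C4aOOH + ex$C4aOOH_X) - re$C4aOOH)) / 15, 1e-3)
  expect_lt(max(abs(ex$E_FAD - re$E_FAD)) / 15, 1e-3)
})

test_that("invalid inputs are rejected with validation errors", {
  expect_error(rate_parameters(k_unc = -1), class = "halokin_validation_error")
  expect_error(rate_parameters(Kd_X = c(I = 0, Br = 0.4, Cl = 0.78)),
               class = "halokin_validation_error")
  expect_error(rate_parameters(f_unc_pop = 1.2),
               class = "halokin_validation_error")
  expect_error(initial_conditions(E_FADH = -5),
               class = "halokin_validation_error")
  expect_error(initial_conditions(NotASpecies = 1),
               class = "halokin_validation_error")
  expect_error(halide_id("Na"), class = "halokin_validation_error")
  expect_error(simulate_scheme(rate_parameters(), chain_init(), "Cl",
                               c(1, 1, 2)),
               class = "halokin_validation_error")
})
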