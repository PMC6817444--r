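test_that("rhs vanishes at the zero state and is capped at Vm in saturation", {
  p <- ref_params()
  d0 <- tmdd_rhs(data.frame(analyte = c("a", "b"), A1 = c(0, 0), A2 = c(0, 0)), p)
  expect_equal(d0$dA1, c(0, 0))
  expect_equal(d0$dA2, c(0, 0))

  # deep saturation: the Michaelis-Menten term approaches Vm from below
  for (C1 in c(1e3, 1e5, 1e7)) {
    d <- tmdd_rhs(data.frame(analyte = "ADC", A1 = C1 * p$V1, A2 = 123), p)
    expect_lt(d$saturable_rate, p$Vm)
    expect_lt(abs(d$saturable_rate - p$Vm), p$Vm * p$Km / C1 * 1.01)
    # residual after removing linear clearance and distribution terms -> -Vm
    resid <- d$dA1 + (p$CL + p$Cld) / p$V1 * (C1 * p$V1) - p$Cld / p$V2 * 123
    expect_equal(resid, -d$saturable_rate)
  }
})

test_that("saturable elimination runs at Vm/2 when C1 equals Km", {
  p <- ref_params()
  d <- tmdd_rhs(data.frame(analyte = "ADC", A1 = p$Km * p$V1, A2 = 0), p)
  expect_equal(d$saturable_rate, 38.1 / 2, tolerance = 1e-12)
  expect_equal(d$saturable_rate, 19.05)
})

test_that("rhs rejects invalid parameters and non-finite state", {
  expect_error(pk_parameters(55.5, 58.6, 8.97, 105, 38.1, -0.1),
               class = "adcpk_parameter_error")
  expect_error(pk_parameters(-1, 58.6, 8.97, 105, 38.1, 0.142),
               class = "adcpk_parameter_error")
  expect_error(tmdd_rhs(data.frame(analyte = "x", A1 = NaN, A2 = 0),
                        ref_params()),
               class = "adcpk_domain_error")
})

test_that("an IV bolus lands in the central compartment: C1(0+) = dose / V1", {
  sim <- pk_simulate(ref_params(), single_bolus(1000), times = c(0, 1, 7))
  expect_equal(sim$C1[sim$time == 0], 1000 / 55.5, tolerance = 1e-12)
  expect_equal(sim$C1[sim$time == 0], 18.02, tolerance = 1e-3)
})

test_that("with Vm = 0 the solver reproduces the closed-form biexponential", {
  p <- pk_parameters(55.5, 58.6, 8.97, 105, 0, 0.142)
  tt <- c(0, 0.02, 0.1, 0.5, 1, 2, 3.5, 5, 7)
  sim <- pk_simulate(p, single_bolus(1000), times = tt)
  oracle <- biexp_conc(55.5, 58.6, 8.97, 105, 1000, tt)
  expect_lt(max(abs(sim$C1 - oracle) / oracle), 1e-3)
})

test_that("compiled and plain-R right-hand sides agree", {
  p <- ref_params()
  reg <- regimen(dose_event("mAb", -1, 500), dose_event("ADC", 0, 1000))
  tt <- seq(-1, 7, by = 0.5)
  a <- pk_simulate(p, reg, times = tt, compiled = TRUE)
  b <- pk_simulate(p, reg, times = tt, compiled = FALSE)
  expect_equal(a$C1, b$C1, tolerance = 1e-6)
  expect_equal(a$A2, b$A2, tolerance = 1e-6)
})

test_that("a zero-dose regimen yields identically zero trajectories", {
  reg <- regimen(dose_event("ADC", 0, 0))
  sim <- pk_simulate(ref_params(), reg, times = seq(0, 7, 1))
  expect_true(all(sim$A1 == 0 & sim$A2 == 0 & sim$C1 == 0))
})

test_that("two analytes dosed identically under shared coupling are exchangeable", {
  reg <- regimen(dose_event("x", 0, 800), dose_event("y", 0, 800))
  sim <- pk_simulate(ref_params(), reg, times = seq(0, 7, 0.5),
                     coupling = "shared")
  wide <- tidyr::pivot_wider(sim[, c("time", "analyte", "C1")],
                             names_from = "analyte", values_from = "C1")
  expect_equal(wide$x, wide$y, tolerance = 1e-10)
})

test_that("shared and independent coupling coincide for a single analyte", {
  tt <- seq(0, 7, 0.25)
  a <- pk_simulate(ref_params(), single_bolus(342), tt, coupling = "shared")
  b <- pk_simulate(ref_params(), single_bolus(342), tt, coupling = "independent")
  expect_equal(a$C1, b$C1, tolerance = 1e-10)
})

test_that("increasing the dose never decreases C1 anywhere", {
  tt <- seq(0, 7, 0.25)
  doses <- c(50, 342, 1000, 5000, 10500)
  curves <- sapply(doses, function(d) {
    pk_simulate(ref_params(), single_bolus(d), tt)$C1
  })
  for (j in 2:length(doses)) {
    expect_true(all(curves[, j] >= curves[, j - 1] - 1e-9))
  }
})

test_that("mass balance holds along every simulated trajectory", {
  set.seed(7)
  for (k in 1:20) {
    p <- random_params()
    reg <- regimen(dose_event("ADC", 0, runif(1, 10, 10000)))
    sim <- pk_simulate(p, reg, times = seq(0, 7, 0.5))
    mb <- mass_balance(sim)
    expect_lt(max(abs(mb$rel_error), na.rm = TRUE), 1e-3)
  }
})

test_that("superposition holds in the linear limit and fails near Km", {
  p_lin <- pk_parameters(55.5, 58.6, 8.97, 105, 0, 0.142)
  tt <- seq(0, 7, 0.25)
  one <- pk_simulate(p_lin, single_bolus(500), tt)$C1
  two <- pk_simulate(p_lin, single_bolus(1000), tt)$C1
  expect_equal(two, 2 * one, tolerance = 1e-6)

  # with the saturable pathway on and concentrations near Km, doubling the
  # dose more than doubles exposure
  p <- ref_params()
  one_n <- pk_simulate(p, single_bolus(10), tt)$C1
  two_n <- pk_simulate(p, single_bolus(20), tt)$C1
  expect_gt(max(abs(two_n - 2 * one_n) / pmax(2 * one_n, 1e-12)), 0.01)
})

test_that("dose events outside the time grid are a regimen error", {
  expect_error(
    pk_simulate(ref_params(), regimen(dose_event("ADC", -1, 100)),
                times = c(0, 1)),
    class = "adcpk_regimen_error")
  expect_error(
    pk_simulate(ref_params(), single_bolus(100), times = c(0, 1, 1)),
    class = "adcpk_domain_error")
})
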