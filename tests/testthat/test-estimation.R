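make_noise_free <- function(doses = c(342, 750, 1000, 2500, 5000, 7500, 10500),
                            times = c(0.02, 0.25, 1, 2, 4, 7)) {
  cfg <- synthetic_study_config(pk = list(dose_levels = doses,
                                          sample_times = times,
                                          cv = 0, n_per_group = 1L))
  d <- generate_pk(cfg, seed = 1)
  list(data = d, regimens = attr(d, "regimens"))
}

test_that("noise-free data returns the generating parameters", {
  nf <- make_noise_free()
  init <- pk_parameters(55.5 * 1.3, 58.6 * 1.3, 8.97 * 1.3, 105 * 1.3,
                        38.1 * 1.3, 0.142 * 1.3)
  fit <- pk_fit(nf$data, nf$regimens, init = init, n_starts = 1)
  truth <- coef(ref_params())
  expect_true(fit$converged)
  expect_true(all(abs(coef(fit) - truth) / truth < 1e-3))
  expect_lt(fit$objective, 1e-8)
})

test_that("the objective is invariant under data reordering", {
  cfg <- synthetic_study_config(pk = list(cv = 0.1))
  d <- generate_pk(cfg, seed = 3)
  regs <- attr(d, "regimens")
  f1 <- pk_fit(d, regs, init = ref_params(), n_starts = 1)
  set.seed(99)
  f2 <- pk_fit(d[sample(nrow(d)), ], regs, init = ref_params(), n_starts = 1)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("a single dose deep in the saturated regime leaves Km poorly identified", {
  # concentrations stay far above Km over the sampled window, so only the
  # near-zero-order elimination is visible in the (noisy) data
  cfg <- synthetic_study_config(pk = list(
    dose_levels = 342, sample_times = c(0.02, 0.1, 0.25, 0.5, 1, 2),
    cv = 0.10, n_per_group = 3L))
  d <- generate_pk(cfg, seed = 17)
  expect_warning(
    fit <- pk_fit(d, attr(d, "regimens"), init = ref_params(), n_starts = 1),
    "dose levels")
  expect_true("Km" %in% fit$poorly_identified)
})

test_that("estimates are invariant under a consistent change of time unit", {
  nf <- make_noise_free(doses = c(342, 2500, 10500),
                        times = c(0.02, 0.25, 1, 3, 7))
  fit_d <- pk_fit(nf$data, nf$regimens, init = ref_params(), n_starts = 1)

  # same study expressed in hours: rates scale by 1/24, volumes unchanged
  d_h <- nf$data
  d_h$time <- d_h$time * 24
  regs_h <- lapply(nf$regimens, function(r) {
    regimen(dose_event("ADC", r$events$time[1] * 24, r$events$dose[1]))
  })
  init_h <- pk_parameters(55.5, 58.6, 8.97 / 24, 105 / 24, 38.1 / 24, 0.142)
  fit_h <- pk_fit(d_h, regs_h, init = init_h, n_starts = 1)
  est_d <- coef(fit_d)
  est_h <- coef(fit_h)
  scale <- c(V1 = 1, V2 = 1, CL = 24, Cld = 24, Vm = 24, Km = 1)
  expect_equal(est_h * scale, est_d, tolerance = 1e-3)
})

test_that("fit inputs are validated", {
  nf <- make_noise_free(doses = c(342, 10500), times = c(0.25, 1, 7))
  d <- nf$data
  d$concentration <- 0
  expect_error(pk_fit(d, nf$regimens, init = ref_params()),
               class = "adcpk_data_error")
  expect_error(pk_fit(nf$data[, c("time", "concentration")], nf$regimens,
                      init = ref_params()),
               class = "adcpk_data_error")
  expect_error(pk_fit(nf$data, nf$regimens["dose_342"], init = ref_params()),
               class = "adcpk_data_error")
})

test_that("tidy, glance and augment expose the fit in broom shape", {
  nf <- make_noise_free(doses = c(342, 2500, 10500), times = c(0.25, 1, 4, 7))
  fit <- pk_fit(nf$data, nf$regimens, init = ref_params(), n_starts = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "rel.std.error", "unit"))
  expect_equal(td$term, c("V1", "V2", "CL", "Cld", "Vm", "Km"))
  expect_true(all(td$std.error >= 0))
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(abs(ev))))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(nf$data))
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid * pmax(au$.fitted, 1e-12),
               au$concentration, tolerance = 1e-10)
})

test_that("assay curves decompose totals into mAb and ADC contributions", {
  p <- ref_params()
  tt <- seq(-1, 7, 0.25)
  reg_mab <- regimen(dose_event("mAb", -1, 1000))
  sim_mab <- pk_simulate(p, reg_mab, times = tt)
  ac_mab <- predict_assay(sim_mab)
  expect_true(all(ac_mab$concentration[ac_mab$assay == "conjugated_adc"] == 0))

  reg_adc <- regimen(dose_event("ADC", 0, 1000))
  sim_adc <- pk_simulate(p, reg_adc, times = seq(0, 7, 0.25))
  ac_adc <- predict_assay(sim_adc)
  wide <- tidyr::pivot_wider(ac_adc, names_from = "assay",
                             values_from = "concentration")
  expect_equal(wide$total_antibody, wide$conjugated_adc)

  # predose at -1 d + ADC at 0: at 0+ the assays differ by exactly the
  # residual mAb concentration
  reg <- regimen(dose_event("mAb", -1, 1000), dose_event("ADC", 0, 1000))
  sim <- pk_simulate(p, reg, times = tt)
  ac <- predict_assay(sim)
  tot0 <- ac$concentration[ac$assay == "total_antibody" & ac$time == 0]
  adc0 <- ac$concentration[ac$assay == "conjugated_adc" & ac$time == 0]
  mab0 <- sim$C1[sim$analyte == "mAb" & sim$time == 0]
  expect_equal(tot0 - adc0, mab0, tolerance = 1e-10)

  expect_error(predict_assay(pk_simulate(p, regimen(dose_event("drugX", 0, 10)),
                                         times = c(0, 1))),
               class = "adcpk_mapping_error")
})
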