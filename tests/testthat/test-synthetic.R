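test_that("generators are pure functions of config and seed", {
  cfg <- synthetic_study_config()
  expect_identical(generate_pk(cfg, seed = 5), generate_pk(cfg, seed = 5))
  expect_false(isTRUE(all.equal(generate_pk(cfg, seed = 5)$concentration,
                                generate_pk(cfg, seed = 6)$concentration)))
  b1 <- generate_biodist(cfg, seed = 5)
  b2 <- generate_biodist(cfg, seed = 5)
  expect_identical(b1$records, b2$records)
  expect_identical(generate_efficacy(cfg, seed = 5),
                   generate_efficacy(cfg, seed = 5))
})

test_that("zero-noise PK records equal the model predictions", {
  cfg <- synthetic_study_config(pk = list(cv = 0, n_per_group = 1L))
  d <- generate_pk(cfg, seed = 1)
  regs <- attr(d, "regimens")
  for (g in unique(d$group_id)) {
    obs <- d[d$group_id == g, ]
    sim <- pk_simulate(cfg$pk$params, regs[[g]],
                       times = sort(unique(c(0, obs$time))))
    expect_equal(obs$concentration, sim$C1[match(obs$time, sim$time)],
                 tolerance = 1e-12)
  }
})

test_that("proportional noise has the configured coefficient of variation", {
  cfg <- synthetic_study_config(pk = list(cv = 0.10, n_per_group = 30L))
  d <- generate_pk(cfg, seed = 2)
  cv_cell <- dplyr::summarise(
    dplyr::group_by(d, .data$group_id, .data$time),
    cv = sd(.data$concentration) / mean(.data$concentration),
    .groups = "drop")
  expect_gt(mean(cv_cell$cv), 0.05)
  expect_lt(mean(cv_cell$cv), 0.15)
  expect_true(all(d$concentration > 0))
  expect_error(synthetic_study_config(pk = list(cv = -0.1)),
               class = "adcpk_config_error")
})

test_that("gamma-count tables round-trip to the configured %ID/g truth", {
  # near noise-free limit: huge standard counts, no background
  cfg <- synthetic_study_config(biodist = list(standard_counts = 1e9,
                                               background = 0))
  g <- generate_biodist(cfg, seed = 3)
  out <- percent_id_per_gram(g$records, g$standards)
  joined <- dplyr::left_join(out, cfg$biodist$truth,
                             by = c("tissue", "timepoint", "isotope"))
  expect_lt(max(abs(joined$percent_id_g - joined$true_pidg) /
                joined$true_pidg), 0.01)
})

test_that("a zero-uptake truth map recovers background-only values", {
  truth0 <- default_biodist_truth()
  truth0$true_pidg <- 0
  cfg <- synthetic_study_config(biodist = list(truth = truth0))
  g <- generate_biodist(cfg, seed = 4)
  suppressWarnings(out <- percent_id_per_gram(g$records, g$standards))
  # counts are pure background; net %ID/g stays near zero
  expect_lt(max(out$percent_id_g), 0.1)
  expect_true(all(out$percent_id_g >= 0))
})

test_that("efficacy fixture: no kill means no separation from control", {
  arms <- tibble::tibble(group = c("vehicle", "sham"), kill = c(0, 0))
  cfg <- synthetic_study_config(efficacy = list(arms = arms,
                                                n_per_group = 30L))
  s <- summarize_groups(generate_efficacy(cfg, seed = 6), censor_volume = Inf)
  d28 <- s[s$study_day == 28, ]
  gap <- abs(diff(d28$mean_volume)) / mean(d28$mean_volume)
  expect_lt(gap, 0.15)
})

test_that("baseline volumes match the randomization window", {
  arms <- tibble::tibble(group = "vehicle", kill = 0)
  cfg <- synthetic_study_config(efficacy = list(arms = arms,
                                                n_per_group = 500L,
                                                meas_cv = 0, days = 0))
  m <- generate_efficacy(cfg, seed = 7)
  v0 <- tumor_volume(m$length, m$width)
  expect_gt(mean(v0 >= 250 - 90 & v0 <= 250 + 90), 0.99)
  expect_equal(mean(v0), 250, tolerance = 0.05)
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_study_config(efficacy = list(
    arms = tibble::tibble(group = "x", kill = 1.2))),
    class = "adcpk_config_error")
  expect_error(synthetic_study_config(biodist = list(standard_counts = -1)),
               class = "adcpk_config_error")
  expect_error(synthetic_study_config(seed = NULL),
               class = "adcpk_config_error")
})
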