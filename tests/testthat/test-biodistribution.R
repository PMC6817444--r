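std1 <- function(counts = 1e5, background = 0, count_time = 0,
                 isotope = "In-111") {
  tibble::tibble(isotope = isotope, counts = counts, background = background,
                 count_time = count_time)
}

rec1 <- function(counts, mass = 1, background = 0, count_time = 0,
                 isotope = "In-111", tissue = "tumor") {
  tibble::tibble(animal_id = "m1", tissue = tissue, mass = mass,
                 counts = counts, background = background,
                 count_time = count_time, isotope = isotope)
}

test_that("percent_id_per_gram evaluates the counting formula", {
  # sample identical to the standard: 100 %ID/g at 1 g
  expect_equal(percent_id_per_gram(rec1(1e5), std1())$percent_id_g, 100)
  # counted one half-life after the standard: decay correction doubles it
  expect_equal(
    percent_id_per_gram(rec1(1e5, count_time = 2.805), std1())$percent_id_g,
    200)
  # direct evaluation: (5000/100000) / 0.25 g * 100 = 20 %ID/g
  expect_equal(
    percent_id_per_gram(rec1(5000, mass = 0.25), std1())$percent_id_g, 20)
})

test_that("%ID/g is invariant to detector gain and robust to bad counts", {
  r <- rec1(5000, mass = 0.25, background = 100)
  s <- std1(background = 40)
  base <- percent_id_per_gram(r, s)$percent_id_g
  gain <- 3.7
  r2 <- r; r2$counts <- r$counts * gain; r2$background <- r$background * gain
  s2 <- s; s2$counts <- s$counts * gain; s2$background <- s$background * gain
  expect_equal(percent_id_per_gram(r2, s2)$percent_id_g, base)

  expect_warning(out <- percent_id_per_gram(rec1(10, background = 50), std1()),
                 "clipped")
  expect_equal(out$percent_id_g, 0)
  expect_error(percent_id_per_gram(rec1(100), std1(counts = 10, background = 50)),
               class = "adcpk_data_error")
  expect_error(percent_id_per_gram(rec1(100, mass = 0), std1()),
               class = "adcpk_data_error")
})

test_that("decay correction is the identity at zero elapsed time and monotone", {
  expect_identical(decay_correct(123, 0, 2.805), 123)
  tt <- seq(0, 10, 0.5)
  expect_true(all(diff(decay_correct(100, tt, 59.4)) > 0))
  expect_equal(decay_correct(100, 59.4, 59.4), 200)
})

test_that("tissue ratios propagate uncertainty to first order", {
  tbl <- tibble::tibble(tissue = c("tumor", "blood"),
                        mean_pidg = c(27, 13.5), sd_pidg = c(6, 1))
  r <- tissue_ratio(tbl, "tumor", "blood")
  expect_equal(r$ratio, 2)
  expect_equal(tissue_ratio(tbl, "blood", "blood")$ratio, 1)

  # Monte-Carlo oracle for the propagated SD
  set.seed(42)
  draws <- rnorm(1e5, 27, 6) / rnorm(1e5, 13.5, 1)
  expect_equal(r$ratio_sd, sd(draws), tolerance = 0.05)

  expect_error(tissue_ratio(tbl, "spleen", "blood"),
               class = "adcpk_lookup_error")
})

test_that("the residualizing-isotope contrast reports internalization", {
  a <- tibble::tibble(tissue = c("tumor", "blood"), mean_pidg = c(15, 20))
  b <- tibble::tibble(tissue = c("tumor", "blood"), mean_pidg = c(4.9, 20))
  ct <- residualization_contrast(a, b)
  expect_equal(ct$ratio[ct$tissue == "tumor"], 15 / 4.9)
  expect_equal(ct$ratio[ct$tissue == "tumor"], 3.06, tolerance = 1e-2)
  expect_equal(ct$difference[ct$tissue == "blood"], 0)
  expect_equal(ct$ratio[ct$tissue == "blood"], 1)

  same <- residualization_contrast(a, a)
  expect_true(all(same$difference == 0) && all(same$ratio == 1))

  expect_error(
    residualization_contrast(a, b[b$tissue == "tumor", ]),
    class = "adcpk_alignment_error")
})

test_that("summed organ %ID stays within the injected dose on a conserving fixture", {
  # whole-animal fixture: tissue %ID/g * mass sums exactly to 100 %ID
  tissues <- tibble::tibble(
    tissue = c("blood", "liver", "carcass"),
    mass = c(1.5, 1.2, 15),
    frac = c(0.25, 0.15, 0.60))
  recs <- tibble::tibble(
    animal_id = "m1", tissue = tissues$tissue, mass = tissues$mass,
    counts = tissues$frac * 1e6, background = 0, count_time = 0,
    isotope = "In-111")
  out <- percent_id_per_gram(recs, std1(counts = 1e6))
  expect_equal(sum(out$percent_id_g * out$mass), 100, tolerance = 1e-10)
})

test_that("isotope specs carry the physical half-lives", {
  expect_equal(isotope_spec("In-111")$half_life, 2.805)
  expect_equal(isotope_spec("I-125")$half_life, 59.4)
  expect_equal(isotope_spec("Zr-89", half_life = 3.27)$half_life, 3.27)
  expect_error(isotope_spec("Xx-1"), class = "adcpk_domain_error")
})
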