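#' Synthetic study configuration
#'
#' Defaults mirror the animal study design that this package analyses:
#' multi-dose PK at seven ADC dose levels spanning 0.342-10.5 mg/kg with
#' proportional 10% noise and n = 3 per sampled time over 7 days;
#' dual-isotope gamma-counting tables with Poisson counting noise, isotope
#' decay and background; and groups of 7 mice randomised at a baseline
#' tumor volume of 250 +/- 30 mm^3 and followed for 28 days.
#'
#' @param pk List: `params` ([pk_parameters()] ground truth),
#'   `dose_levels` (ug/kg), `sample_times` (days), `cv` (proportional
#'   noise fraction, >= 0), `n_per_group`.
#' @param biodist List: `truth` (tibble `tissue`, `timepoint`, `isotope`,
#'   `true_pidg`), `standard_counts` (decay-corrected counts representing
#'   the full injected dose), `background` (expected background counts),
#'   `standard_count_time` (days), `masses` (named vector, g),
#'   `n_per_group`.
#' @param efficacy List: `baseline_mean`, `baseline_sd` (mm^3),
#'   `growth_rate` (/day), `arms` (tibble `group`, `kill` with the
#'   dose-dependent kill fraction in `[0, 1)`), `days`, `n_per_group`,
#'   `meas_cv` (caliper measurement CV), `aspect_ratio` (length/width used
#'   to back-calculate caliper dimensions from volume).
#' @param seed Integer seed (mandatory; every generator is a pure function
#'   of its config and seed).
#' @return A validated list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(pk = list(), biodist = list(),
                                   efficacy = list(), seed = 1234L) {
  pk_def <- list(
    params = adc_reference_params(),
    dose_levels = c(0.342, 0.75, 1, 2.5, 5, 7.5, 10.5) * 1000,
    sample_times = c(0.02, 0.25, 1, 2, 4, 7),
    cv = 0.10,
    n_per_group = 3L
  )
  bio_def <- list(
    truth = default_biodist_truth(),
    standard_counts = 1e6,
    background = 50,
    standard_count_time = 0,
    masses = c(blood = 0.5, tumor = 0.3, spleen = 0.1, muscle = 0.3),
    n_per_group = 3L
  )
  eff_def <- list(
    baseline_mean = 250,
    baseline_sd = 30,
    growth_rate = 0.09,
    arms = default_efficacy_arms(),
    days = c(0, 4, 7, 11, 14, 18, 21, 25, 28),
    n_per_group = 7L,
    meas_cv = 0.08,
    aspect_ratio = 1.4
  )
  merge_flat <- function(def, usr) {
    bad <- setdiff(names(usr), names(def))
    if (length(bad) > 0) {
      abort(sprintf("Unknown config field(s): %s.", paste(bad, collapse = ", ")),
            class = "adcpk_config_error")
    }
    def[names(usr)] <- usr
    def
  }
  cfg <- list(pk = merge_flat(pk_def, pk),
              biodist = merge_flat(bio_def, biodist),
              efficacy = merge_flat(eff_def, efficacy),
              seed = seed)
  if (is.null(seed) || !is.numeric(seed)) {
    abort("`seed` is mandatory.", class = "adcpk_config_error")
  }
  if (cfg$pk$cv < 0) {
    abort("`pk$cv` must be non-negative.", class = "adcpk_config_error")
  }
  if (any(cfg$pk$dose_levels <= 0) || any(cfg$pk$sample_times < 0)) {
    abort("PK dose levels must be positive and sample times non-negative.",
          class = "adcpk_config_error")
  }
  if (cfg$biodist$standard_counts <= 0) {
    abort("`biodist$standard_counts` must be positive.",
          class = "adcpk_config_error")
  }
  if (any(cfg$efficacy$arms$kill < 0) || any(cfg$efficacy$arms$kill >= 1)) {
    abort("Kill fractions must lie in [0, 1).", class = "adcpk_config_error")
  }
  if (cfg$efficacy$baseline_mean <= 0 || cfg$efficacy$baseline_sd < 0 ||
      cfg$efficacy$growth_rate <= 0) {
    abort("Efficacy baseline and growth rate must be positive.",
          class = "adcpk_config_error")
  }
  structure(cfg, class = "synthetic_study_config")
}

#' @rdname synthetic_study_config
#' @export
default_biodist_truth <- function() {
  tibble(
    tissue = rep(c("blood", "tumor", "spleen", "muscle"), times = 4),
    timepoint = rep(c(1, 1, 3, 3), each = 4),
    isotope = rep(rep(c("I-125", "In-111"), each = 4), times = 2),
    true_pidg = c(20, 4.9, 7, 0.7,
                  20, 15, 8, 0.8,
                  12, 3.4, 3.5, 0.7,
                  13.5, 27, 5, 0.8)
  )
}

#' @rdname synthetic_study_config
#' @export
default_efficacy_arms <- function() {
  tibble(
    group = c("vehicle", "ADC 1 mg/kg", "ADC 3 mg/kg",
              "pre 0.5 + ADC 1 mg/kg", "pre 1 + ADC 1 mg/kg",
              "pre 0.5 + ADC 3 mg/kg", "pre 1 + ADC 3 mg/kg"),
    kill = c(0, 0.55, 0.85, 0.55, 0.55, 0.85, 0.85)
  )
}

#' Generate synthetic multi-dose PK observations
#'
#' Simulate the disposition model at each dose level of the config and
#' perturb the predictions with proportional noise:
#' `conc = pred * (1 + eps)`, `eps ~ Normal(0, cv)`, redrawn where
#' `1 + eps <= 0` so concentrations stay positive. Deterministic given
#' `seed`.
#'
#' @param config A [synthetic_study_config()].
#' @param seed Integer seed; defaults to the config's.
#' @param dense_early_doses Optional number of lowest dose levels that
#'   additionally receive early sample times `dense_early_times`, to
#'   inform the saturable pathway.
#' @param dense_early_times Extra times (days) for those dose levels.
#' @return A tibble of concentration records (`group_id`, `analyte`,
#'   `assay`, `time`, `dose_group` in ug/kg, `concentration` in ug/mL)
#'   with the per-group regimens attached as attribute `"regimens"` and
#'   the generating parameters as `"params"`.
#' @export
generate_pk <- function(config, seed = config$seed,
                        dense_early_doses = 0L,
                        dense_early_times = c(0.05, 0.1)) {
  stopifnot(inherits(config, "synthetic_study_config"))
  pk <- config$pk
  set.seed(seed)
  doses <- sort(pk$dose_levels)
  groups <- sprintf("dose_%g", doses)
  regimens <- list()
  recs <- list()
  for (i in seq_along(doses)) {
    tt <- sort(unique(c(pk$sample_times,
                        if (i <= dense_early_doses) dense_early_times)))
    reg <- regimen(dose_event("ADC", 0, doses[i]),
                   label = groups[i])
    regimens[[groups[i]]] <- reg
    sim <- pk_simulate(pk$params, reg, times = sort(unique(c(0, tt))))
    pred <- sim$C1[match(tt, sim$time)]
    n <- pk$n_per_group
    pred_rep <- rep(pred, each = n)
    eps <- rnorm(length(pred_rep), 0, pk$cv)
    while (any(1 + eps <= 0)) {
      bad <- which(1 + eps <= 0)
      eps[bad] <- rnorm(length(bad), 0, pk$cv)
    }
    recs[[i]] <- tibble(
      group_id = groups[i],
      analyte = "ADC",
      assay = "total_antibody",
      time = rep(tt, each = n),
      dose_group = doses[i],
      concentration = pred_rep * (1 + eps)
    )
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "regimens") <- regimens
  attr(out, "params") <- pk$params
  out
}

#' Generate synthetic gamma-counting tables
#'
#' Expected raw sample counts are
#' `true_pidg/100 * mass * standard_counts * 2^(-count_time/half_life)`,
#' drawn Poisson, plus Poisson background. Standards are generated the
#' same way at the full injected dose. Samples are counted at their
#' harvest timepoint. Round-tripping through [percent_id_per_gram()]
#' recovers the configured truth within Poisson error.
#'
#' @inheritParams generate_pk
#' @return A list with `records` (tissue count records, one per animal,
#'   tissue, isotope and timepoint; `group` encodes the timepoint) and
#'   `standards`.
#' @export
generate_biodist <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_study_config"))
  bio <- config$biodist
  set.seed(seed)
  truth <- as_tibble(bio$truth)
  need <- c("tissue", "timepoint", "isotope", "true_pidg")
  stopifnot(all(need %in% names(truth)))
  hl <- .half_life_lookup(truth$isotope)
  n <- bio$n_per_group
  rows <- truth[rep(seq_len(nrow(truth)), each = n), ]
  rows$animal_id <- sprintf("m%d_t%g", rep(seq_len(n), times = nrow(truth)),
                            rows$timepoint)
  rows$mass <- unname(bio$masses[rows$tissue])
  if (anyNA(rows$mass)) {
    abort("`biodist$masses` must name every tissue in the truth table.",
          class = "adcpk_config_error")
  }
  hl_rows <- .half_life_lookup(rows$isotope)
  expected <- rows$true_pidg / 100 * rows$mass * bio$standard_counts *
    2^(-rows$timepoint / hl_rows)
  rows$counts <- as.numeric(rpois(nrow(rows), expected) +
                              rpois(nrow(rows), bio$background))
  rows$background <- bio$background
  rows$count_time <- rows$timepoint
  rows$group <- sprintf("%gd", rows$timepoint)
  records <- rows[, c("animal_id", "tissue", "mass", "counts", "background",
                      "count_time", "isotope", "group", "timepoint")]
  iso <- unique(truth$isotope)
  t_std <- bio$standard_count_time
  std_expected <- bio$standard_counts * 2^(-t_std / .half_life_lookup(iso))
  standards <- tibble(
    isotope = iso,
    counts = as.numeric(rpois(length(iso), std_expected) +
                          rpois(length(iso), bio$background)),
    background = bio$background,
    count_time = t_std
  )
  list(records = as_tibble(records), standards = standards)
}

#' Generate synthetic tumor-growth trajectories
#'
#' Fixture growth model (not a fitted pharmacodynamic model): per-animal
#' lognormal baseline volume around `(baseline_mean, baseline_sd)`,
#' exponential growth at `growth_rate`, and a dose-dependent
#' multiplicative kill `(1 - kill)` applied to the viable volume after the
#' day-0 dose. Caliper length and width are back-calculated from volume at
#' the fixed `aspect_ratio`, after multiplicative lognormal measurement
#' noise of CV `meas_cv`. Deterministic given `seed`.
#'
#' @inheritParams generate_pk
#' @return A tibble of caliper measurements (`animal_id`, `group`,
#'   `study_day`, `length`, `width` in mm).
#' @export
generate_efficacy <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_study_config"))
  eff <- config$efficacy
  set.seed(seed)
  sdlog <- sqrt(log(1 + (eff$baseline_sd / eff$baseline_mean)^2))
  meanlog <- log(eff$baseline_mean) - sdlog^2 / 2
  rho <- eff$aspect_ratio
  out <- list()
  for (g in seq_len(nrow(eff$arms))) {
    grp <- eff$arms$group[g]
    kill <- eff$arms$kill[g]
    for (a in seq_len(eff$n_per_group)) {
      b <- rlnorm(1, meanlog, sdlog)
      v <- b * exp(eff$growth_rate * eff$days) *
        ifelse(eff$days > 0, 1 - kill, 1)
      if (eff$meas_cv > 0) {
        v <- v * exp(rnorm(length(v), 0, eff$meas_cv))
      }
      w <- (2 * v / rho)^(1 / 3)
      out[[length(out) + 1]] <- tibble(
        animal_id = sprintf("%s_a%d", gsub("[^0-9A-Za-z]+", "_", grp), a),
        group = grp,
        study_day = eff$days,
        length = rho * w,
        width = w
      )
    }
  }
  dplyr::bind_rows(out)
}
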