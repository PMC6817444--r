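#' Study manifest
#'
#' Collect the file paths and settings for an end-to-end pipeline run.
#' Every input is optional, but at least one analysis stage must be
#' runnable; absent stages are skipped with a log message.
#'
#' @param pk_csv Concentration CSV (see [read_concentration_csv()]);
#'   enables the fitting stage. Needs a `dose_group` column (ug/kg) from
#'   which the per-group single-bolus regimens are built.
#' @param regimen_yaml Regimen/parameter YAML (see [read_regimen_yaml()]);
#'   supplies initial parameters for fitting and the coupling mode.
#' @param biodist_csv,standards_csv Tissue count and dosing-standard CSVs;
#'   enable the biodistribution stage.
#' @param caliper_csv Caliper CSV; enables the efficacy stage.
#' @param out_dir Output directory (created if needed; outputs never
#'   overwrite inputs).
#' @param seed Integer seed used by every stochastic step.
#' @param predose_levels,adc_doses Study grid (mg/kg) simulated after
#'   fitting.
#' @return A list of class `study_manifest`.
#' @export
study_manifest <- function(pk_csv = NULL, regimen_yaml = NULL,
                           biodist_csv = NULL, standards_csv = NULL,
                           caliper_csv = NULL, out_dir = tempfile("adcpk_out"),
                           seed = 1234L, predose_levels = c(0, 0.5, 1),
                           adc_doses = 1) {
  m <- list(pk_csv = pk_csv, regimen_yaml = regimen_yaml,
            biodist_csv = biodist_csv, standards_csv = standards_csv,
            caliper_csv = caliper_csv, out_dir = out_dir, seed = seed,
            predose_levels = predose_levels, adc_doses = adc_doses)
  inputs <- purrr::compact(m[c("pk_csv", "regimen_yaml", "biodist_csv",
                               "standards_csv", "caliper_csv")])
  if (length(inputs) == 0) {
    abort("Empty manifest: supply at least one input file.",
          class = "adcpk_usage_error")
  }
  missing <- inputs[!vapply(inputs, file.exists, TRUE)]
  if (length(missing) > 0) {
    abort(sprintf("Manifest input(s) not found: %s.",
                  paste(unlist(missing), collapse = ", ")),
          class = "adcpk_usage_error")
  }
  structure(m, class = "study_manifest")
}

#' Run the analysis pipeline
#'
#' Execute every stage the manifest provides inputs for: (1) fit the
#' disposition model to the concentration data, (2) simulate the predose x
#' ADC study regimens with assay-specific readouts in both ug/mL and
#' %ID/mL, (3) convert gamma counts to %ID/g with group summaries, the
#' tumor/blood ratio and the residualizing-isotope contrast, (4)
#' summarise tumor growth with %TGI against the vehicle arm. Machine
#' readable outputs (CSV/JSON) are written under `out_dir`; results are
#' returned invisibly. Deterministic given the manifest seed.
#'
#' @param manifest A [study_manifest()].
#' @return (Invisibly) a list of class `adcpk_report` with elements `fit`,
#'   `simulations`, `biodist`, `efficacy` (present stages only) and
#'   `outputs` (paths written).
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- normalizePath(unlist(purrr::compact(
    manifest[c("pk_csv", "regimen_yaml", "biodist_csv", "standards_csv",
               "caliper_csv")])), mustWork = TRUE)
  outpath <- function(name) {
    p <- file.path(manifest$out_dir, name)
    if (normalizePath(p, mustWork = FALSE) %in% inputs) {
      abort(sprintf("Refusing to overwrite input file '%s'.", p),
            class = "adcpk_usage_error")
    }
    p
  }
  report <- list()
  outputs <- character()
  add_output <- function(p) outputs <<- c(outputs, p)
  stage <- function(name, expr) {
    inform(sprintf("[%s] running", name))
    force(expr)
  }

  params <- adc_reference_params()
  coupling <- "shared"
  body_weight <- 0.0275
  if (!is.null(manifest$regimen_yaml)) {
    cfgfile <- read_regimen_yaml(manifest$regimen_yaml)
    if (!is.null(cfgfile$params)) params <- cfgfile$params
    if (!is.null(cfgfile$coupling)) coupling <- cfgfile$coupling
    body_weight <- cfgfile$regimen$body_weight
  }
  inform(sprintf(
    "Defaults in effect: body weight %g kg; coupling '%s'; half-lives In-111 2.805 d, I-125 59.4 d; solver rtol 1e-8.",
    body_weight, coupling))

  if (!is.null(manifest$pk_csv)) {
    report$fit <- stage("fit", {
      obs <- read_concentration_csv(manifest$pk_csv)
      if (!"dose_group" %in% names(obs)) {
        abort("Fitting needs a `dose_group` column (ug/kg) in the PK CSV.",
              class = "adcpk_data_error")
      }
      regs <- lapply(split(obs$dose_group, obs$group_id), function(d) {
        regimen(dose_event("ADC", 0, d[1]), body_weight = body_weight)
      })
      fit <- pk_fit(obs, regs, init = params, seed = manifest$seed)
      p <- outpath("fitted_parameters.csv")
      readr::write_csv(tidy(fit), p)
      y <- outpath("fitted_parameters.yaml")
      yaml::write_yaml(list(params = unclass(fit$estimates)), y)
      j <- outpath("fit_summary.json")
      jsonlite::write_json(as.list(glance(fit)), j, auto_unbox = TRUE)
      add_output(p); add_output(y); add_output(j)
      fit
    })
    params <- report$fit$estimates
  }

  report$simulations <- stage("simulate", {
    regs <- build_study_regimens(manifest$predose_levels, manifest$adc_doses,
                                 body_weight = body_weight)
    curves <- purrr::imap_dfr(regs, function(reg, lab) {
      t0 <- min(c(reg$events$time, 0))
      sim <- pk_simulate(params, reg, times = sort(unique(c(
        seq(t0, 7, by = 0.05), reg$events$time))), coupling = coupling)
      ac <- predict_assay(sim)
      ac$regimen <- lab
      ac$percent_id_ml <- percent_id_per_ml(
        ac$concentration, total_injected_dose(reg, analyte = "ADC"))
      ac
    })
    p <- outpath("simulated_assay_curves.csv")
    readr::write_csv(curves, p)
    add_output(p)
    curves
  })

  if (!is.null(manifest$biodist_csv) && !is.null(manifest$standards_csv)) {
    report$biodist <- stage("biodist", {
      recs <- read_tissue_counts_csv(manifest$biodist_csv)
      stds <- read_standards_csv(manifest$standards_csv)
      pidg <- percent_id_per_gram(recs, stds)
      summ <- summarize_biodist(pidg)
      out <- list(per_record = pidg, summary = summ)
      if (all(c("tumor", "blood") %in% summ$tissue)) {
        out$tumor_blood <- tissue_ratio(summ, "tumor", "blood")
      }
      isos <- unique(summ$isotope)
      if (all(c("In-111", "I-125") %in% isos)) {
        out$contrast <- residualization_contrast(
          summ[summ$isotope == "In-111", setdiff(names(summ), "isotope")],
          summ[summ$isotope == "I-125", setdiff(names(summ), "isotope")])
      }
      p <- outpath("biodist_summary.csv")
      readr::write_csv(summ, p)
      add_output(p)
      if (!is.null(out$contrast)) {
        p2 <- outpath("residualization_contrast.csv")
        readr::write_csv(out$contrast, p2)
        add_output(p2)
      }
      out
    })
  } else {
    inform("[biodist] skipped (no tissue count / standards input)")
  }

  if (!is.null(manifest$caliper_csv)) {
    report$efficacy <- stage("efficacy", {
      cal <- read_caliper_csv(manifest$caliper_csv)
      summ <- summarize_groups(cal)
      out <- list(summary = summ)
      if ("vehicle" %in% summ$group) {
        last_day <- max(summ$study_day[summ$group == "vehicle"])
        treated <- setdiff(unique(summ$group), "vehicle")
        out$tgi <- tibble(
          group = treated,
          day = last_day,
          percent_tgi = vapply(treated, function(g) {
            tryCatch(percent_tgi(summ, g, "vehicle", last_day),
                     error = function(e) NA_real_)
          }, 1)
        )
      }
      p <- outpath("efficacy_summary.csv")
      readr::write_csv(summ, p)
      add_output(p)
      if (!is.null(out$tgi)) {
        p2 <- outpath("tgi.csv")
        readr::write_csv(out$tgi, p2)
        add_output(p2)
      }
      out
    })
  } else {
    inform("[efficacy] skipped (no caliper input)")
  }

  report$outputs <- outputs
  class(report) <- "adcpk_report"
  invisible(report)
}
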