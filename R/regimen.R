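#' Dosing events and regimens
#'
#' A regimen is an ordered table of intravenous bolus dose events, each
#' tagged with the analyte it delivers ("ADC", "mAb", ...). Event times are
#' in days and may be negative: a predose of unconjugated antibody given
#' 24 hours before the ADC sits at `time = -1`.
#'
#' @param analyte Character label of the dosed species.
#' @param time Event time in days (may be negative).
#' @param dose Dose in ug/kg body weight (non-negative).
#' @param route Administration route; only `"iv_bolus"` is supported.
#'
#' @return `dose_event()` returns a one-row tibble; `regimen()` an object of
#'   class `regimen` holding the event table (sorted by time), an optional
#'   label and the body weight used for absolute-dose conversions.
#' @examples
#' regimen(dose_event("mAb", -1, 1000), dose_event("ADC", 0, 1000),
#'         label = "1 mg/kg predose + 1 mg/kg ADC")
#' @export
dose_event <- function(analyte, time, dose, route = "iv_bolus") {
  stopifnot(is.character(analyte), length(analyte) == 1L,
            is.numeric(time), length(time) == 1L, is.finite(time),
            is.numeric(dose), length(dose) == 1L, is.finite(dose))
  if (dose < 0) {
    abort("`dose` must be non-negative.", class = "adcpk_regimen_error")
  }
  if (!identical(route, "iv_bolus")) {
    abort("Only intravenous bolus dosing is supported.",
          class = "adcpk_regimen_error")
  }
  tibble(analyte = analyte, time = as.numeric(time),
         dose = as.numeric(dose), route = route)
}

#' @rdname dose_event
#' @param ... For `regimen()`: dose events (one-row tibbles from
#'   [dose_event()]) or data frames of events with columns
#'   `analyte`, `time`, `dose` (and optionally `route`).
#' @param label Optional regimen label.
#' @param body_weight Body weight in kg used to convert per-kg doses into
#'   absolute injected amounts. Defaults to 0.0275 kg, the midpoint of the
#'   25-30 g mice used in these studies.
#' @export
regimen <- function(..., label = NULL, body_weight = 0.0275) {
  parts <- list(...)
  if (length(parts) == 0L) {
    abort("A regimen needs at least one dose event.",
          class = "adcpk_regimen_error")
  }
  ev <- dplyr::bind_rows(parts)
  if (!all(c("analyte", "time", "dose") %in% names(ev))) {
    abort("Events must have columns `analyte`, `time`, `dose`.",
          class = "adcpk_regimen_error")
  }
  if (is.null(ev$route)) ev$route <- "iv_bolus"
  if (any(ev$dose < 0) || !all(ev$route == "iv_bolus")) {
    abort("Doses must be non-negative IV bolus events.",
          class = "adcpk_regimen_error")
  }
  stopifnot(is.numeric(body_weight), body_weight > 0)
  ev <- dplyr::arrange(ev, .data$time, .data$analyte)
  structure(list(events = ev, label = label, body_weight = body_weight),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("<regimen>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  body weight: %g kg\n", x$body_weight))
  print(x$events)
  invisible(x)
}

#' Build the predose x ADC study regimens
#'
#' Construct the cartesian product of antibody predose levels and ADC dose
#' levels used in the biodistribution and tumor-growth-inhibition designs:
#' the unconjugated mAb predose is given at -1 day (24 h before the ADC)
#' and the ADC at day 0. Zero-predose regimens contain only the ADC event.
#'
#' @param predose_levels Numeric vector of mAb predose levels.
#' @param adc_doses Numeric vector of ADC dose levels.
#' @param unit Unit of the two dose vectors, `"mg/kg"` (default) or
#'   `"ug/kg"`; stored internally as ug/kg.
#' @param body_weight Body weight in kg, passed to each [regimen()].
#' @return A named list of `regimen` objects, ordered predose-major.
#' @examples
#' names(build_study_regimens(c(0, 0.5, 1), 1))
#' @export
build_study_regimens <- function(predose_levels, adc_doses, unit = "mg/kg",
                                 body_weight = 0.0275) {
  stopifnot(is.numeric(predose_levels), is.numeric(adc_doses))
  if (any(predose_levels < 0) || any(adc_doses < 0)) {
    abort("Dose levels must be non-negative.", class = "adcpk_regimen_error")
  }
  scale <- switch(unit, "mg/kg" = 1000, "ug/kg" = 1,
                  abort("`unit` must be \"mg/kg\" or \"ug/kg\".",
                        class = "adcpk_unit_error"))
  out <- list()
  for (pre in predose_levels) {
    for (adc in adc_doses) {
      lab <- sprintf("pre%g+ADC%g", pre * scale / 1000, adc * scale / 1000)
      events <- list()
      if (pre > 0) {
        events <- c(events, list(dose_event("mAb", -1, pre * scale)))
      }
      events <- c(events, list(dose_event("ADC", 0, adc * scale)))
      out[[lab]] <- do.call(regimen,
                            c(events, list(label = lab,
                                           body_weight = body_weight)))
    }
  }
  out
}

#' Total injected dose of a regimen
#'
#' @param x A [regimen()].
#' @param analyte Optional analyte label; default sums all analytes.
#' @param body_weight Body weight in kg; defaults to the regimen's.
#' @return Total injected amount in ug.
#' @export
total_injected_dose <- function(x, analyte = NULL, body_weight = NULL) {
  stopifnot(inherits(x, "regimen"))
  bw <- body_weight %||% x$body_weight
  ev <- x$events
  if (!is.null(analyte)) ev <- ev[ev$analyte %in% analyte, , drop = FALSE]
  sum(ev$dose) * bw
}

#' Convert between ug/mL and percent injected dose per mL
#'
#' Dose-normalised blood concentrations: `%ID/mL` expresses a concentration
#' as the percentage of the total injected amount found in one mL. The two
#' conversions are exact inverses.
#'
#' @param concentration Concentration in ug/mL.
#' @param percent_id Concentration in %ID/mL.
#' @param total_injected Total injected amount in ug (> 0); see
#'   [total_injected_dose()].
#' @return `percent_id_per_ml()` returns %ID/mL;
#'   `conc_from_percent_id()` returns ug/mL.
#' @examples
#' percent_id_per_ml(5, total_injected = 25) # 20 %ID/mL
#' @export
percent_id_per_ml <- function(concentration, total_injected) {
  .check_injected(total_injected)
  concentration / total_injected * 100
}

#' @rdname percent_id_per_ml
#' @export
conc_from_percent_id <- function(percent_id, total_injected) {
  .check_injected(total_injected)
  percent_id * total_injected / 100
}

.check_injected <- function(total_injected) {
  if (!is.numeric(total_injected) || any(!is.finite(total_injected)) ||
      any(total_injected <= 0)) {
    abort("`total_injected` must be positive and finite.",
          class = "adcpk_domain_error")
  }
}

#' Read and write regimen configuration files
#'
#' Regimens (and optionally solver settings and model parameters) are
#' stored in a plain-text YAML file with keys `label`, `body_weight_kg`,
#' `events` (list of `analyte` / `time_day` / `dose_ug_per_kg`), and
#' optionally `params` (the six model parameters) and `coupling`.
#'
#' @param path File path.
#' @param x A [regimen()] object.
#' @param params Optional [pk_parameters()] written alongside the regimen.
#' @param coupling Optional coupling mode string stored in the file.
#' @return `read_regimen_yaml()` returns a list with elements `regimen` and
#'   (if present in the file) `params` and `coupling`.
#'   `write_regimen_yaml()` returns `path` invisibly.
#' @export
write_regimen_yaml <- function(x, path, params = NULL, coupling = NULL) {
  stopifnot(inherits(x, "regimen"))
  obj <- list(
    label = x$label %||% "regimen",
    body_weight_kg = x$body_weight,
    events = purrr::pmap(x$events, function(analyte, time, dose, route) {
      list(analyte = analyte, time_day = time, dose_ug_per_kg = dose)
    })
  )
  if (!is.null(params)) obj$params <- unclass(.as_pk_parameters(params))
  if (!is.null(coupling)) obj$coupling <- coupling
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_regimen_yaml
#' @export
read_regimen_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$events)) {
    abort("Regimen file has no `events` key.", class = "adcpk_io_error")
  }
  ev <- purrr::map_dfr(obj$events, function(e) {
    dose_event(e$analyte, e$time_day, e$dose_ug_per_kg)
  })
  reg <- regimen(ev, label = obj$label,
                 body_weight = obj$body_weight_kg %||% 0.0275)
  out <- list(regimen = reg)
  if (!is.null(obj$params)) {
    out$params <- do.call(pk_parameters, obj$params)
  }
  if (!is.null(obj$coupling)) out$coupling <- obj$coupling
  out
}
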