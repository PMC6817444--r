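#' Assay-specific concentration readouts of a simulation
#'
#' Serum exposure in predose studies is measured by two ELISAs with
#' different semantics: the total-antibody assay detects both the
#' unconjugated mAb and the ADC, while the conjugated-ADC assay detects
#' only antibody still carrying at least one drug. Map a multi-analyte
#' simulation onto the two assay curves:
#' `total_antibody = sum of all central concentrations`,
#' `conjugated_adc = central concentration of the ADC analyte only`.
#'
#' @param sim A `pk_sim` from [pk_simulate()].
#' @param adc_analyte,mab_analyte Labels identifying the conjugated and
#'   unconjugated species in `sim`. Any analyte label outside these two is
#'   a mapping error.
#' @return A tibble with columns `time`, `assay`
#'   (`"total_antibody"` / `"conjugated_adc"`) and `concentration` (ug/mL).
#' @examples
#' reg <- regimen(dose_event("mAb", -1, 1000), dose_event("ADC", 0, 1000))
#' sim <- pk_simulate(adc_reference_params(), reg, times = seq(-1, 7, 0.25))
#' predict_assay(sim)
#' @export
predict_assay <- function(sim, adc_analyte = "ADC", mab_analyte = "mAb") {
  stopifnot(inherits(sim, "pk_sim"))
  labs <- unique(sim$analyte)
  unknown <- setdiff(labs, c(adc_analyte, mab_analyte))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown analyte label(s): %s. Set `adc_analyte` / `mab_analyte`.",
                  paste(unknown, collapse = ", ")),
          class = "adcpk_mapping_error")
  }
  total <- dplyr::summarise(dplyr::group_by(as_tibble(sim), .data$time),
                            concentration = sum(.data$C1), .groups = "drop")
  total$assay <- "total_antibody"
  adc <- as_tibble(sim)[sim$analyte == adc_analyte, c("time", "C1")]
  if (nrow(adc) == 0) {
    adc <- tibble(time = total$time, C1 = 0)
  }
  names(adc)[2] <- "concentration"
  adc$assay <- "conjugated_adc"
  out <- dplyr::bind_rows(total, adc)
  out <- out[, c("time", "assay", "concentration")]
  dplyr::arrange(out, .data$assay, .data$time)
}
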