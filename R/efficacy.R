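#' Tumor volume from caliper measurements
#'
#' Ellipsoid approximation used throughout xenograft efficacy studies:
#' `V = l * w^2 / 2` with `l` the longest dimension and `w` the
#' perpendicular width, both in mm.
#'
#' @param l Length (mm), the longest dimension.
#' @param w Width (mm), perpendicular to the length.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 5) # 125
#' @export
tumor_volume <- function(l, w) {
  if (any(!is.finite(l)) || any(!is.finite(w)) || any(l <= 0) || any(w <= 0)) {
    abort("Tumor dimensions must be positive and finite.",
          class = "adcpk_domain_error")
  }
  l * w^2 / 2
}

# Validate caliper records; auto-swap length/width with a warning when
# width exceeds length.
.as_tumor_measurements <- function(x) {
  x <- as_tibble(x)
  need <- c("animal_id", "group", "study_day", "length", "width")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("Caliper data is missing column(s): %s.",
                  paste(miss, collapse = ", ")), class = "adcpk_data_error")
  }
  if (any(x$length <= 0) || any(x$width <= 0)) {
    abort("Caliper dimensions must be positive.", class = "adcpk_data_error")
  }
  swap <- x$width > x$length
  if (any(swap)) {
    warn(sprintf("%d record(s) had width > length; dimensions swapped.",
                 sum(swap)))
    tmp <- x$length[swap]
    x$length[swap] <- x$width[swap]
    x$width[swap] <- tmp
  }
  if (anyDuplicated(x[, c("animal_id", "study_day")]) > 0) {
    abort("Duplicate (animal_id, study_day) records.",
          class = "adcpk_data_error")
  }
  x
}

#' Group tumor-volume summaries
#'
#' Convert caliper records to volumes ([tumor_volume()]) and summarise per
#' group and study day as mean +/- SEM with the number of animals. Animals
#' whose volume reaches `censor_volume` (the maximum allowable volume at
#' which mice are euthanised) are excluded from all later study days; the
#' censoring days are attached as the `"censored"` attribute.
#'
#' @param measurements Data frame with columns `animal_id`, `group`,
#'   `study_day`, `length`, `width` (mm).
#' @param censor_volume Volume (mm^3) triggering removal; default 3000.
#' @return A tibble with `group`, `study_day`, `mean_volume`, `sem`
#'   (`sd/sqrt(n)`; 0 when `n = 1`), and `n`. Attribute `"censored"` is a
#'   tibble of `animal_id`, `censor_day`.
#' @export
summarize_groups <- function(measurements, censor_volume = 3000) {
  x <- .as_tumor_measurements(measurements)
  x$volume <- tumor_volume(x$length, x$width)
  hit <- x[x$volume >= censor_volume, c("animal_id", "study_day")]
  censored <- if (nrow(hit) > 0) {
    dplyr::summarise(dplyr::group_by(hit, .data$animal_id),
                     censor_day = min(.data$study_day), .groups = "drop")
  } else {
    tibble(animal_id = character(), censor_day = numeric())
  }
  if (nrow(censored) > 0) {
    cen_day <- censored$censor_day[match(x$animal_id, censored$animal_id)]
    x <- x[is.na(cen_day) | x$study_day <= cen_day, , drop = FALSE]
  }
  out <- dplyr::summarise(dplyr::group_by(x, .data$group, .data$study_day),
                          mean_volume = mean(.data$volume),
                          sem = if (dplyr::n() > 1) {
                            sd(.data$volume) / sqrt(dplyr::n())
                          } else 0,
                          n = dplyr::n(), .groups = "drop")
  attr(out, "censored") <- censored
  out
}

#' Percent tumor growth inhibition
#'
#' Baseline-anchored delta ratio:
#' `%TGI = 100 * (1 - (V_t(day) - V_t(ref)) / (V_c(day) - V_c(ref)))`,
#' computed on group mean volumes. 0% means the treated arm grew like
#' control, 100% means it stayed at baseline.
#'
#' @param summary A group summary from [summarize_groups()].
#' @param treated,control Group labels.
#' @param day Study day at which to evaluate.
#' @param ref_day Baseline day; defaults to the earliest day shared by the
#'   two groups.
#' @return %TGI (a single number). If the control arm regressed
#'   (`delta V <= 0`) the metric is undefined: returns `NA` with a warning.
#' @examples
#' # treated grew 100 mm^3 while control grew 400 mm^3 -> 75% inhibition
#' @export
percent_tgi <- function(summary, treated, control, day, ref_day = NULL) {
  s <- as_tibble(summary)
  pick <- function(g, d) {
    v <- s$mean_volume[s$group == g & s$study_day == d]
    if (length(v) != 1) {
      abort(sprintf("No unique summary row for group '%s' on day %g.", g, d),
            class = "adcpk_lookup_error")
    }
    v
  }
  if (is.null(ref_day)) {
    days_t <- s$study_day[s$group == treated]
    days_c <- s$study_day[s$group == control]
    common <- intersect(days_t, days_c)
    if (length(common) == 0) {
      abort("Groups share no study day to anchor the baseline.",
            class = "adcpk_lookup_error")
    }
    ref_day <- min(common)
  }
  dv_t <- pick(treated, day) - pick(treated, ref_day)
  dv_c <- pick(control, day) - pick(control, ref_day)
  if (dv_c <= 0) {
    warn("Control arm did not grow; %TGI is undefined (returning NA).")
    return(NA_real_)
  }
  100 * (1 - dv_t / dv_c)
}
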