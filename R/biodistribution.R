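#' Isotope specifications
#'
#' Physical half-lives of the two radiolabels used in dual-isotope ADC
#' biodistribution: residualizing In-111 (DOTA chelate; catabolites stay
#' trapped in cells) and non-residualizing I-125 (tyrosine iodination;
#' reports mainly intact antibody).
#'
#' @param name `"In-111"` or `"I-125"`, or any label when `half_life` is
#'   given explicitly.
#' @param half_life Half-life in days; defaults to the physical constant
#'   for the two known isotopes (In-111: 2.805 d, I-125: 59.4 d).
#' @return A named list of class `isotope_spec`.
#' @export
isotope_spec <- function(name, half_life = NULL) {
  defaults <- c("In-111" = 2.805, "I-125" = 59.4)
  if (is.null(half_life)) {
    if (!name %in% names(defaults)) {
      abort(sprintf("Unknown isotope '%s'; supply `half_life` in days.", name),
            class = "adcpk_domain_error")
    }
    half_life <- defaults[[name]]
  }
  stopifnot(is.numeric(half_life), half_life > 0)
  structure(list(name = name, half_life = half_life), class = "isotope_spec")
}

.half_life_lookup <- function(isotopes, half_lives = NULL) {
  defaults <- c("In-111" = 2.805, "I-125" = 59.4)
  hl <- defaults
  if (!is.null(half_lives)) hl[names(half_lives)] <- half_lives
  miss <- setdiff(unique(isotopes), names(hl))
  if (length(miss) > 0) {
    abort(sprintf("No half-life known for isotope(s): %s.",
                  paste(miss, collapse = ", ")),
          class = "adcpk_domain_error")
  }
  unname(hl[isotopes])
}

#' Decay-correct raw counts
#'
#' Correct a gamma count measured `elapsed` days after the reference
#' instant back to the reference: `counts * 2^(elapsed / half_life)`.
#' Zero elapsed time is the identity; the correction grows monotonically
#' with elapsed time.
#'
#' @param counts Raw counts.
#' @param elapsed Days since the reference instant.
#' @param half_life Isotope half-life in days.
#' @return Corrected counts.
#' @export
decay_correct <- function(counts, elapsed, half_life) {
  stopifnot(is.numeric(half_life), all(half_life > 0))
  counts * 2^(elapsed / half_life)
}

#' Percent injected dose per gram from gamma counts
#'
#' Convert raw gamma-counting records to `%ID/g`: background-subtract,
#' decay-correct both the sample and the dosing-solution standard back to
#' the injection time, divide by the standard (which represents the full
#' injected dose) and by the wet tissue mass:
#'
#' \deqn{\%ID/g = \frac{(counts - background)\,2^{\Delta t / T_{1/2}}}
#'   {(std - std_{bg})\,2^{\Delta t_{std} / T_{1/2}}} \cdot \frac{100}{mass}}
#'
#' @param records Data frame of tissue count records with columns
#'   `animal_id`, `tissue`, `mass` (g), `counts`, `background`,
#'   `count_time` (days since injection), `isotope`, and optionally `group`
#'   and `timepoint` (carried through).
#' @param standards Data frame of dosing-solution standards with columns
#'   `isotope`, `counts`, `background`, `count_time`.
#' @param half_lives Optional named numeric vector overriding the built-in
#'   half-lives (days).
#' @return The records tibble with columns `net_counts` (decay-corrected;
#'   negative values after background subtraction are clipped to zero with
#'   a warning) and `percent_id_g` added.
#' @examples
#' rec <- tibble::tibble(animal_id = "m1", tissue = "tumor", mass = 0.25,
#'                       counts = 5000, background = 0, count_time = 0,
#'                       isotope = "In-111")
#' std <- tibble::tibble(isotope = "In-111", counts = 1e5,
#'                       background = 0, count_time = 0)
#' percent_id_per_gram(rec, std)$percent_id_g # 20
#' @export
percent_id_per_gram <- function(records, standards, half_lives = NULL) {
  records <- as_tibble(records)
  standards <- as_tibble(standards)
  need_r <- c("tissue", "mass", "counts", "background", "count_time", "isotope")
  need_s <- c("isotope", "counts", "background", "count_time")
  miss <- setdiff(need_r, names(records))
  if (length(miss) > 0) {
    abort(sprintf("`records` is missing column(s): %s.",
                  paste(miss, collapse = ", ")), class = "adcpk_data_error")
  }
  miss <- setdiff(need_s, names(standards))
  if (length(miss) > 0) {
    abort(sprintf("`standards` is missing column(s): %s.",
                  paste(miss, collapse = ", ")), class = "adcpk_data_error")
  }
  if (any(records$mass <= 0)) {
    abort("Tissue masses must be positive.", class = "adcpk_data_error")
  }
  std <- standards
  std$half_life <- .half_life_lookup(std$isotope, half_lives)
  std$std_net <- decay_correct(std$counts - std$background,
                               std$count_time, std$half_life)
  if (any(std$std_net <= 0)) {
    abort("Standard net counts must be positive after background subtraction.",
          class = "adcpk_data_error")
  }
  idx <- match(records$isotope, std$isotope)
  if (anyNA(idx)) {
    abort(sprintf("No standard for isotope(s): %s.",
                  paste(unique(records$isotope[is.na(idx)]), collapse = ", ")),
          class = "adcpk_data_error")
  }
  hl <- .half_life_lookup(records$isotope, half_lives)
  net <- records$counts - records$background
  if (any(net < 0)) {
    warn(sprintf("%d record(s) with net counts below zero clipped to 0.",
                 sum(net < 0)))
    net <- pmax(net, 0)
  }
  net <- decay_correct(net, records$count_time, hl)
  records$net_counts <- net
  records$percent_id_g <- net / std$std_net[idx] / records$mass * 100
  records
}

#' Group summaries of %ID/g tables
#'
#' Mean, SD and n of `percent_id_g` per tissue / isotope / group /
#' timepoint (whichever of these columns are present).
#'
#' @param tbl Output of [percent_id_per_gram()].
#' @return A tibble with `mean_pidg`, `sd_pidg`, `n` per stratum.
#' @export
summarize_biodist <- function(tbl) {
  keys <- intersect(c("tissue", "isotope", "group", "timepoint"), names(tbl))
  dplyr::summarise(dplyr::group_by(as_tibble(tbl), dplyr::across(dplyr::all_of(keys))),
                   mean_pidg = mean(.data$percent_id_g),
                   sd_pidg = if (dplyr::n() > 1) sd(.data$percent_id_g) else 0,
                   n = dplyr::n(), .groups = "drop")
}

#' Tissue uptake ratio with first-order error propagation
#'
#' Ratio of mean %ID/g between two tissues (classically tumor/blood), with
#' the ratio's SD propagated to first order from the per-tissue means and
#' SDs assuming independence:
#' `sd(r) = r * sqrt((sd_n/m_n)^2 + (sd_d/m_d)^2)`.
#'
#' @param tbl A summary table from [summarize_biodist()] (or any tibble
#'   with `tissue`, `mean_pidg` and optionally `sd_pidg`).
#' @param num,den Numerator and denominator tissue labels.
#' @return A tibble with the grouping columns (isotope/group/timepoint if
#'   present), `ratio` and `ratio_sd`.
#' @export
tissue_ratio <- function(tbl, num, den) {
  tbl <- as_tibble(tbl)
  if (!"sd_pidg" %in% names(tbl)) tbl$sd_pidg <- 0
  keys <- intersect(c("isotope", "group", "timepoint"), names(tbl))
  wide <- tidyr::pivot_wider(tbl[tbl$tissue %in% c(num, den),
                                 c(keys, "tissue", "mean_pidg", "sd_pidg")],
                             names_from = "tissue",
                             values_from = c("mean_pidg", "sd_pidg"))
  ncol_m <- paste0("mean_pidg_", num); dcol_m <- paste0("mean_pidg_", den)
  ncol_s <- paste0("sd_pidg_", num); dcol_s <- paste0("sd_pidg_", den)
  if (!all(c(ncol_m, dcol_m) %in% names(wide)) ||
      anyNA(wide[[ncol_m]]) || anyNA(wide[[dcol_m]])) {
    abort(sprintf("Tissue '%s' or '%s' missing from the table.", num, den),
          class = "adcpk_lookup_error")
  }
  if (any(wide[[dcol_m]] <= 0)) {
    abort("Denominator tissue mean must be positive.",
          class = "adcpk_domain_error")
  }
  r <- wide[[ncol_m]] / wide[[dcol_m]]
  rsd <- r * sqrt((wide[[ncol_s]] / wide[[ncol_m]])^2 +
                  (wide[[dcol_s]] / wide[[dcol_m]])^2)
  out <- wide[, keys, drop = FALSE]
  out$ratio <- r
  out$ratio_sd <- rsd
  as_tibble(out)
}

#' Residualizing vs non-residualizing isotope contrast
#'
#' Per-tissue difference and ratio of residualizing In-111 uptake over
#' non-residualizing I-125 uptake — an index of cellular internalization
#' and catabolism of the ADC (trapped In-111 catabolites accumulate where
#' the antibody was internalised, while I-125 reports intact antibody).
#'
#' @param tbl_in111,tbl_i125 Summary tables (from [summarize_biodist()] or
#'   with columns `tissue`, `mean_pidg`) for the two isotopes; they must
#'   align on tissue and on any shared `group`/`timepoint` columns.
#' @return A tibble with the alignment keys, `in111`, `i125`, `difference`
#'   (`in111 - i125`, %ID/g) and `ratio` (`in111 / i125`).
#' @export
residualization_contrast <- function(tbl_in111, tbl_i125) {
  a <- as_tibble(tbl_in111); b <- as_tibble(tbl_i125)
  keys <- intersect(intersect(c("tissue", "group", "timepoint"), names(a)),
                    names(b))
  if (!"tissue" %in% keys) {
    abort("Both tables need a `tissue` column.", class = "adcpk_data_error")
  }
  a_k <- do.call(paste, c(a[keys], sep = "\r"))
  b_k <- do.call(paste, c(b[keys], sep = "\r"))
  only_a <- setdiff(a_k, b_k); only_b <- setdiff(b_k, a_k)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(paste0("Tables do not align. Missing pairs: ",
                 paste(gsub("\r", "/", c(only_a, only_b)), collapse = "; ")),
          class = "adcpk_alignment_error")
  }
  j <- match(a_k, b_k)
  out <- a[, keys, drop = FALSE]
  out$in111 <- a$mean_pidg
  out$i125 <- b$mean_pidg[j]
  out$difference <- out$in111 - out$i125
  out$ratio <- out$in111 / out$i125
  as_tibble(out)
}
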