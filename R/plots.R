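#' Plot a simulated concentration-time course
#'
#' Central concentration of every analyte on a log scale, with dose events
#' marked.
#'
#' @param object A `pk_sim` from [pk_simulate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_sim <- function(object, ...) {
  ev <- attr(object, "regimen")$events
  df <- as_tibble(object)
  df <- df[df$C1 > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$C1,
                                   colour = .data$analyte)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = ev$time, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (days)", y = "Central concentration (µg/mL)",
                  colour = "Analyte")
}

#' Plot observations against model fit
#'
#' Observed concentrations (points) and the fitted model curves (lines)
#' per dose group, on a log concentration scale.
#'
#' @param object A `pk_fit` from [pk_fit()].
#' @param times Simulation grid for the fitted curves; defaults to 200
#'   points over the observed time span.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_fit <- function(object, times = NULL, ...) {
  obs <- as_tibble(object$data)
  if (is.null(times)) {
    times <- seq(0, max(obs$time), length.out = 200)
  }
  curves <- purrr::imap_dfr(object$regimens, function(reg, g) {
    tt <- sort(unique(c(times, reg$events$time)))
    sim <- pk_simulate(object$estimates, reg, times = tt)
    tibble(group_id = g, time = sim$time, concentration = sim$C1)
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$concentration,
                                    colour = .data$group_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves[curves$concentration > 0, ]) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (days)", y = "Concentration (µg/mL)",
                  colour = "Dose group")
}

#' Tissue-uptake bar chart
#'
#' Mean %ID/g per tissue with SD error bars, faceted by isotope and
#' timepoint where present, coloured by group (predose level).
#'
#' @param summary A table from [summarize_biodist()].
#' @return A ggplot object.
#' @export
plot_biodist <- function(summary) {
  s <- as_tibble(summary)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$tissue, y = .data$mean_pidg))
  if ("group" %in% names(s)) {
    p <- p + ggplot2::aes(fill = .data$group) +
      ggplot2::geom_col(position = ggplot2::position_dodge()) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean_pidg - .data$sd_pidg,
                     ymax = .data$mean_pidg + .data$sd_pidg),
        position = ggplot2::position_dodge(width = 0.9), width = 0.3)
  } else {
    p <- p + ggplot2::geom_col() +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean_pidg - .data$sd_pidg,
                     ymax = .data$mean_pidg + .data$sd_pidg), width = 0.3)
  }
  facets <- intersect(c("isotope", "timepoint"), names(s))
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_wrap(facets)
  }
  p + ggplot2::labs(x = NULL, y = "%ID/g")
}

#' Tumor-growth curves
#'
#' Group mean tumor volume versus study day with SEM error bars.
#'
#' @param summary A table from [summarize_groups()].
#' @return A ggplot object.
#' @export
plot_tumor_growth <- function(summary) {
  s <- as_tibble(summary)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$study_day, y = .data$mean_volume,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_volume - .data$sem,
                                        ymax = .data$mean_volume + .data$sem),
                           width = 0.5) +
    ggplot2::labs(x = "Study day", y = expression(Tumor~volume~(mm^3)),
                  colour = "Group")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
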