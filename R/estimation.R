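#' Fit the disposition model to multi-dose concentration data
#'
#' Naive-pooled weighted least squares under a proportional (constant-CV)
#' error model: the objective is `sum(((obs - pred) / pred)^2)`, with the
#' model prediction (never the observation) in the denominator. The six
#' parameters are optimised on the log scale by Levenberg-Marquardt with a
#' multi-start strategy (starts jittered multiplicatively around `init`),
#' and asymptotic standard errors are taken from the Jacobian at the
#' optimum. Each dose group is treated as an independent animal set, so
#' each group saturates its own target-mediated pathway.
#'
#' At least two distinct dose levels are recommended: with a single dose
#' level deep in the saturated regime `Vm` and `Km` are only weakly
#' identified, which the fit reports through standard errors exceeding
#' 100% of the estimate (`poorly_identified`).
#'
#' @param data Data frame of concentration records with columns `group_id`,
#'   `time` (days) and `concentration` (ug/mL). Other columns (`analyte`,
#'   `assay`, `dose_group`) are carried along if present.
#' @param regimens Named list of [regimen()] objects, one per `group_id`
#'   appearing in `data`. Each must dose a single analyte.
#' @param init Initial [pk_parameters()] for the optimisation.
#' @param n_starts Number of multi-starts (default 5). The first start is
#'   `init` itself; the rest are jittered by independent factors uniform on
#'   `[1 - jitter, 1 + jitter]` per parameter.
#' @param jitter Multiplicative jitter half-width (default 0.5).
#' @param seed Seed for the start jitter (stochastic routines in this
#'   package always take an explicit seed; default 1234).
#' @param coupling Saturable-pathway coupling passed to the solver; groups
#'   are always independent of each other.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param max_iter Levenberg-Marquardt iteration budget per start.
#' @return An object of class `pk_fit` with elements `estimates`
#'   ([pk_parameters()]), `std_errors` (same units, delta-method from the
#'   log scale), `covariance` (natural scale, symmetric PSD), `objective`
#'   (final weighted residual sum of squares), `converged`, `n_obs`,
#'   `poorly_identified` (parameter names with SE > 100% of the estimate),
#'   `starts` (per-start deviances) and the data/regimens used. Methods:
#'   [tidy()], [glance()], [augment()], `coef()`, `print()`, [autoplot()].
#' @export
pk_fit <- function(data, regimens, init, n_starts = 5, jitter = 0.5,
                   seed = 1234L, coupling = "independent",
                   rtol = 1e-8, atol = 1e-10, max_iter = 100) {
  init <- .as_pk_parameters(init)
  cache <- .make_fit_cache(data, regimens, coupling, rtol, atol)
  n_obs <- nrow(cache$data)

  resid_fun <- function(lp) {
    # solver complaints at absurd trial parameters are part of the
    # objective's domain handling: such points simply get a large residual
    pred <- tryCatch(
      suppressWarnings(.fit_predict(exp(lp), cache)),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(1e6, n_obs))
    }
    (cache$data$concentration - pred) / pmax(pred, 1e-12)
  }

  par0 <- log(unlist(unclass(init)))
  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- par0
  if (n_starts > 1) {
    for (k in 2:n_starts) {
      starts[[k]] <- par0 + log(runif(6, 1 - jitter, 1 + jitter))
    }
  }

  fits <- purrr::map(starts, function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         lower = rep(-25, 6), upper = rep(25, 6),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  })
  dev <- purrr::map_dbl(fits, function(f) {
    if (is.null(f)) Inf else f$deviance
  })
  if (all(!is.finite(dev))) {
    abort("All optimisation starts failed.", class = "adcpk_fit_error")
  }
  best <- fits[[which.min(dev)]]
  lp_hat <- best$par
  theta <- exp(lp_hat)
  names(theta) <- names(par0)

  # asymptotic covariance on the log scale from a forward-difference Jacobian
  r0 <- resid_fun(lp_hat)
  J <- matrix(0, n_obs, 6)
  h <- 1e-6
  for (j in 1:6) {
    lp <- lp_hat
    lp[j] <- lp[j] + h
    J[, j] <- (resid_fun(lp) - r0) / h
  }
  rss <- sum(r0^2)
  dof <- max(n_obs - 6L, 1L)
  sigma2 <- rss / dof
  JtJ <- crossprod(J)
  cov_log <- tryCatch(sigma2 * solve(JtJ),
                      error = function(e) sigma2 * MASS::ginv(JtJ))
  cov_log <- (cov_log + t(cov_log)) / 2
  D <- diag(theta)
  cov_nat <- D %*% cov_log %*% D
  dimnames(cov_nat) <- list(names(theta), names(theta))
  se <- theta * sqrt(pmax(diag(cov_log), 0))

  converged <- !is.null(best$info) && best$info %in% 1:4 && is.finite(rss)
  est <- pk_parameters(theta[["V1"]], theta[["V2"]], theta[["CL"]],
                       theta[["Cld"]], theta[["Vm"]], theta[["Km"]])
  structure(list(
    estimates = est,
    std_errors = se,
    covariance = cov_nat,
    objective = rss,
    converged = converged,
    n_obs = n_obs,
    sigma = sqrt(sigma2),
    # a parameter is poorly identified when its asymptotic SE exceeds the
    # estimate, when the data carry (numerically) no information about it,
    # or when the optimiser pinned it to the log-scale box
    poorly_identified = {
      jnorm <- sqrt(colSums(J^2))
      names(theta)[se > theta | jnorm < 1e-8 * max(jnorm) |
                     abs(lp_hat) > 24]
    },
    starts = tibble(start = seq_len(n_starts), deviance = dev),
    data = cache$data,
    fitted = .fit_predict(theta, cache),
    regimens = regimens,
    init = init,
    seed = seed
  ), class = "pk_fit")
}

# Validate the fit inputs and precompute the solver scaffolding: dose
# groups are stacked as independent analytes of one ODE system so every
# objective evaluation costs a single solver call.
.make_fit_cache <- function(data, regimens, coupling, rtol, atol) {
  data <- as_tibble(data)
  need <- c("group_id", "time", "concentration")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(miss, collapse = ", ")),
          class = "adcpk_data_error")
  }
  if (nrow(data) == 0 || all(data$concentration == 0)) {
    abort("`data` has no non-zero observations.", class = "adcpk_data_error")
  }
  if (any(data$concentration < 0)) {
    abort("Concentrations must be non-negative.", class = "adcpk_data_error")
  }
  groups <- unique(as.character(data$group_id))
  if (!all(groups %in% names(regimens))) {
    abort(sprintf("No regimen supplied for group(s): %s.",
                  paste(setdiff(groups, names(regimens)), collapse = ", ")),
          class = "adcpk_data_error")
  }
  ev <- purrr::map_dfr(groups, function(g) {
    e <- regimens[[g]]$events
    if (length(unique(e$analyte)) > 1) {
      abort(sprintf("Group '%s' doses more than one analyte; fitting supports a single dosed species per group.", g),
            class = "adcpk_data_error")
    }
    tibble(time = e$time, analyte_i = match(g, groups), dose = e$dose)
  })
  doses <- tapply(ev$dose, ev$analyte_i, sum)
  if (length(unique(round(doses, 10))) < 2) {
    warn("Fewer than two distinct dose levels: Vm and Km may be poorly identified.")
  }
  bad <- data$time < tapply(ev$time, ev$analyte_i, min)[match(data$group_id, groups)]
  if (any(bad)) {
    abort("Observations precede the first dose of their group.",
          class = "adcpk_data_error")
  }
  grid <- sort(unique(c(data$time, ev$time)))
  list(data = data,
       groups = groups,
       events = as.data.frame(ev),
       grid = grid,
       row_idx = match(data$time, grid),
       col_idx = 3L * (match(as.character(data$group_id), groups) - 1L) + 1L,
       coupling = coupling, rtol = rtol, atol = atol)
}

.fit_predict <- function(theta, cache) {
  params <- pk_parameters(theta[["V1"]], theta[["V2"]], theta[["CL"]],
                          theta[["Cld"]], theta[["Vm"]], theta[["Km"]])
  Y <- .integrate_tmdd(params, cache$events, length(cache$groups),
                       cache$grid, cache$coupling,
                       rtol = cache$rtol, atol = cache$atol)
  Y[cbind(cache$row_idx, cache$col_idx)] / params$V1
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> proportional-error weighted least squares\n")
  cat(sprintf("  %d observations, objective %.6g, %s\n", x$n_obs,
              x$objective, if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  if (length(x$poorly_identified) > 0) {
    cat("  poorly identified (SE > estimate):",
        paste(x$poorly_identified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  unlist(unclass(object$estimates))
}

#' Tidy methods for fitted PK models
#'
#' `tidy()` returns one row per parameter with its estimate and asymptotic
#' standard error; `glance()` a one-row model summary; `augment()` the
#' observations with fitted values and proportional residuals.
#'
#' @param x,object A `pk_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pk_fit <- function(x, ...) {
  est <- coef(x)
  tibble(term = names(est),
         estimate = unname(est),
         std.error = unname(x$std_errors),
         rel.std.error = unname(x$std_errors / est),
         unit = c("mL/kg", "mL/kg", "mL/kg/day", "mL/kg/day",
                  "ug/day/kg", "ug/mL"))
}

#' @rdname tidy.pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble(objective = x$objective, sigma = x$sigma, converged = x$converged,
         n_obs = x$n_obs, n_params = 6L,
         n_poorly_identified = length(x$poorly_identified))
}

#' @rdname tidy.pk_fit
#' @export
augment.pk_fit <- function(x, ...) {
  out <- as_tibble(x$data)
  out$.fitted <- x$fitted
  out$.resid <- (out$concentration - out$.fitted) / pmax(out$.fitted, 1e-12)
  out
}
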