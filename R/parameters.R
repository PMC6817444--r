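#' Two-compartment TMDD model parameters
#'
#' Bundle the six parameters of the two-compartment antibody disposition
#' model with parallel linear and saturable (Michaelis-Menten) clearance.
#' All volumes and clearances are normalised to body weight so that
#' compartment amounts are carried in ug/kg and central concentration is
#' `A1 / V1` in ug/mL.
#'
#' @param V1 Central volume of distribution (mL/kg).
#' @param V2 Peripheral volume of distribution (mL/kg).
#' @param CL Linear (non-saturable) clearance from the central
#'   compartment (mL/kg/day).
#' @param Cld Distributional (inter-compartmental) clearance (mL/kg/day).
#' @param Vm Maximal rate of the saturable, target-mediated elimination
#'   pathway (ug/day/kg). `Vm = 0` disables the pathway and reduces the
#'   model to the linear two-compartment model.
#' @param Km Central concentration at which the saturable pathway runs at
#'   half its maximal rate (ug/mL).
#'
#' @return An object of class `pk_parameters`: a named list of the six
#'   values, validated (finite, positive; `Vm` may be zero).
#' @seealso [adc_reference_params()] for a ready-made parameter set.
#' @examples
#' pk_parameters(V1 = 55.5, V2 = 58.6, CL = 8.97, Cld = 105,
#'               Vm = 38.1, Km = 0.142)
#' @export
pk_parameters <- function(V1, V2, CL, Cld, Vm, Km) {
  vals <- list(V1 = V1, V2 = V2, CL = CL, Cld = Cld, Vm = Vm, Km = Km)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "adcpk_parameter_error")
    }
  }
  strict <- c("V1", "V2", "CL", "Cld", "Km")
  for (nm in strict) {
    if (vals[[nm]] <= 0) {
      abort(sprintf("`%s` must be strictly positive (got %g).", nm, vals[[nm]]),
            class = "adcpk_parameter_error")
    }
  }
  if (vals$Vm < 0) {
    abort("`Vm` must be non-negative.", class = "adcpk_parameter_error")
  }
  structure(lapply(vals, as.numeric), class = "pk_parameters")
}

#' Reference parameter estimates for an anti-TENB2 ADC in mice
#'
#' The fitted two-compartment nonlinear-clearance parameter set for a
#' humanised anti-TENB2 MMAE antibody-drug conjugate in mice, estimated
#' from multi-dose (0.342-10.5 mg/kg) concentration-time data. Used as the
#' default ground truth of the synthetic PK generator and as a sensible
#' initial value for fitting antibody data of this kind.
#'
#' @return A [pk_parameters()] object.
#' @export
adc_reference_params <- function() {
  pk_parameters(V1 = 55.5, V2 = 58.6, CL = 8.97, Cld = 105,
                Vm = 38.1, Km = 0.142)
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters>\n")
  units <- c(V1 = "mL/kg", V2 = "mL/kg", CL = "mL/kg/day",
             Cld = "mL/kg/day", Vm = "ug/day/kg", Km = "ug/mL")
  for (nm in names(units)) {
    cat(sprintf("  %-3s %10.4g  %s\n", nm, x[[nm]], units[[nm]]))
  }
  invisible(x)
}

#' @export
coef.pk_parameters <- function(object, ...) {
  unlist(unclass(object))
}

#' @export
as_tibble.pk_parameters <- function(x, ...) {
  tibble(parameter = names(unclass(x)),
         value = unlist(unclass(x), use.names = FALSE),
         unit = c("mL/kg", "mL/kg", "mL/kg/day", "mL/kg/day",
                  "ug/day/kg", "ug/mL"))
}

# internal: parameter list -> solver parameter vector
.tmdd_parms <- function(params, n_analytes, coupling) {
  c(n_analytes, as.numeric(coupling == "independent"),
    params$V1, params$V2, params$CL, params$Cld, params$Vm, params$Km)
}

.as_pk_parameters <- function(x) {
  if (inherits(x, "pk_parameters")) return(x)
  if (is.numeric(x) && all(c("V1", "V2", "CL", "Cld", "Vm", "Km") %in% names(x))) {
    return(pk_parameters(x[["V1"]], x[["V2"]], x[["CL"]], x[["Cld"]],
                         x[["Vm"]], x[["Km"]]))
  }
  abort("`params` must be a pk_parameters object or a named numeric vector.",
        class = "adcpk_parameter_error")
}
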