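# Independent closed-form solution of the linear two-compartment model
# after a single IV bolus at t = 0 (textbook biexponential), written here
# from the macro-constant formulas so it does not share code with the
# package's solver path.
biexp_conc <- function(V1, V2, CL, Cld, dose, times) {
  k10 <- CL / V1
  k12 <- Cld / V1
  k21 <- Cld / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  c0 <- dose / V1
  A <- c0 * (alpha - k21) / (alpha - beta)
  B <- c0 * (k21 - beta) / (alpha - beta)
  A * exp(-alpha * times) + B * exp(-beta * times)
}

# Random plausible antibody parameter sets for property tests.
random_params <- function() {
  pk_parameters(
    V1 = runif(1, 30, 100),
    V2 = runif(1, 30, 150),
    CL = runif(1, 3, 20),
    Cld = runif(1, 20, 200),
    Vm = runif(1, 0, 100),
    Km = 10^runif(1, -2, 1)
  )
}

ref_params <- function() adc_reference_params()

single_bolus <- function(dose, analyte = "ADC", t = 0) {
  regimen(dose_event(analyte, t, dose))
}
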