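# Thermodynamic properties of liquid water, 0-100 degC and 1-500 bar.
#
# Density follows the Kell (1975) atmospheric-pressure polynomial with an
# isothermal-compressibility correction for pressure; the dielectric
# constant is the Bradley & Pitzer (1979) formulation; the apparent molar
# Gibbs energy integrates a quadratic heat-capacity polynomial and the
# volumetric pressure term from the SUPCRT reference value at 25 degC,
# 1 bar. Conditions below the liquid-vapor saturation pressure are
# evaluated at saturation (liquid branch), so the 100 degC / 1.01 bar
# grid point is well defined.

T_REF_K <- 298.15
P_REF_BAR <- 1.0
CAL_J <- 4.184
R_GAS <- 8.3145          # J/(mol K)
MW_WATER <- 18.0153e-3   # kg/mol
G_WATER_REF_KJ <- -237.183   # kJ/mol at 25 degC, 1 bar (SUPCRT lineage)
S_WATER_REF_J <- 69.95       # J/(mol K)

# Cp(liquid water, 1 bar) quadratic in Kelvin, J/(mol K); fitted to
# calorimetric values at 0, 50 and 100 degC (max error < 0.15 J/(mol K))
CP_W <- c(a = 104.72283, b = -0.18225700, c = 0.000282)

# isothermal compressibility (1/bar), fitted to reference values
kappa_water <- function(tC) {
  # cubic through (0,50.89) (25,45.25) (50,44.24) (75,45.80) (100,49.10) e-6
  tt <- c(0, 25, 50, 75, 100)
  kk <- c(50.89, 45.25, 44.24, 45.80, 49.10) * 1e-6
  cf <- unname(stats::lm.fit(cbind(1, tt, tt^2, tt^3), kk)$coefficients)
  cf[1] + cf[2] * tC + cf[3] * tC^2 + cf[4] * tC^3
}

#' Saturation vapor pressure of water
#'
#' Antoine equation (1-100 degC range), returned in bar.
#' @param temperature_C Temperature in degrees Celsius.
#' @return Saturation pressure in bar.
#' @export
psat_water <- function(temperature_C) {
  mmHg <- 10^(8.07131 - 1730.63 / (233.426 + temperature_C))
  mmHg * 133.322e-5
}

#' Temperature-pressure condition
#'
#' Validates the engine range: 0-100 degC, 1-500 bar, liquid water. A
#' pressure below saturation is replaced by the saturation pressure
#' (liquid branch) with a message.
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param pressure_bar Pressure in bar.
#' @return A `tp_condition` list with fields `temperature_C`,
#'   `pressure_bar` (possibly raised to saturation) and
#'   `nominal_pressure_bar` (as requested).
#' @export
tp_condition <- function(temperature_C, pressure_bar) {
  if (!is.finite(temperature_C) || temperature_C < 0 || temperature_C > 100)
    stop_ox("temperature %s degC outside validated range [0, 100]",
            format(temperature_C))
  if (!is.finite(pressure_bar) || pressure_bar < 1 || pressure_bar > 500)
    stop_ox("pressure %s bar outside validated range [1, 500]",
            format(pressure_bar))
  ps <- psat_water(temperature_C)
  p_eff <- pressure_bar
  if (pressure_bar < ps) {
    message(sprintf(
      "condition %.5g degC / %.5g bar below saturation; using Psat = %.5g bar (liquid)",
      temperature_C, pressure_bar, ps))
    p_eff <- ps
  }
  structure(list(temperature_C = temperature_C, pressure_bar = p_eff,
                 nominal_pressure_bar = pressure_bar),
            class = "tp_condition")
}

#' Dielectric constant of water (Bradley-Pitzer 1979)
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param pressure_bar Pressure in bar.
#' @return Static dielectric constant (dimensionless).
#' @export
dielectric_water <- function(temperature_C, pressure_bar = 1) {
  TK <- temperature_C + 273.15
  U <- c(3.4279e2, -5.0866e-3, 9.4690e-7, -2.0525, 3.1159e3,
         -1.8289e2, -8.0325e3, 4.2142e6, 2.1417)
  e1000 <- U[1] * exp(U[2] * TK + U[3] * TK^2)
  CC <- U[4] + U[5] / (U[6] + TK)
  B <- U[7] + U[8] / TK + U[9] * TK
  e1000 + CC * log((B + pressure_bar) / (B + 1000))
}

# Born functions from the dielectric surface (numerical derivatives)
born_Q <- function(TK, P) {
  h <- 0.5
  tC <- TK - 273.15
  (dielectric_water(tC, P + h) - dielectric_water(tC, P - h)) / (2 * h) /
    dielectric_water(tC, P)^2
}
born_Y <- function(TK, P) {
  h <- 0.02
  (dielectric_water(TK + h - 273.15, P) -
     dielectric_water(TK - h - 273.15, P)) / (2 * h) /
    dielectric_water(TK - 273.15, P)^2
}
born_X <- function(TK, P) {
  h <- 0.05
  (born_Y(TK + h, P) - born_Y(TK - h, P)) / (2 * h)
}

# reference-state Born functions (constants of the engine)
EPS_REF <- dielectric_water(25, 1)
Y_REF <- born_Y(T_REF_K, P_REF_BAR)
Q_REF <- born_Q(T_REF_K, P_REF_BAR)
X_REF <- born_X(T_REF_K, P_REF_BAR)

#' Density of liquid water
#'
#' Kell (1975) polynomial at atmospheric pressure with an exponential
#' compressibility correction.
#' @param temperature_C Temperature in degrees Celsius.
#' @param pressure_bar Pressure in bar.
#' @return Density in kg/m^3.
#' @export
density_water <- function(temperature_C, pressure_bar = 1) {
  t <- temperature_C
  rho1 <- (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
           46.170461e-6 * t^3 + 105.56302e-9 * t^4 -
           280.54253e-12 * t^5) / (1 + 16.879850e-3 * t)
  rho1 * exp(kappa_water(t) * (pressure_bar - 1))
}

# closed-form temperature integral of the quadratic Cp:
# int_Tr^T int_Tr^T' Cp(T'')/T'' dT'' dT'
cp_double_integral <- function(TK) {
  a <- CP_W[["a"]]; b <- CP_W[["b"]]; cc <- CP_W[["c"]]
  Tr <- T_REF_K
  a * (TK * log(TK / Tr) - TK + Tr) +
    b * (TK - Tr)^2 / 2 +
    cc / 2 * ((TK^3 - Tr^3) / 3 - Tr^2 * (TK - Tr))
}

#' Properties of liquid water at a condition
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param pressure_bar Pressure in bar.
#' @return List with `density` (kg/m^3), `dielectric`, `gibbs_kJ`
#'   (apparent molar Gibbs energy, kJ/mol) and the effective pressure used.
#' @export
water_properties <- function(temperature_C, pressure_bar = 1) {
  cond <- tp_condition(temperature_C, pressure_bar)
  P <- cond$pressure_bar
  TK <- temperature_C + 273.15
  gT <- -(S_WATER_REF_J * (TK - T_REF_K) + cp_double_integral(TK))  # J/mol
  V1 <- MW_WATER / density_water(temperature_C, 1)                  # m^3/mol
  k <- kappa_water(temperature_C)
  dP <- P - P_REF_BAR
  gP <- V1 * (1 - exp(-k * dP)) / k * 1e5                           # J/mol
  list(density = density_water(temperature_C, P),
       dielectric = dielectric_water(temperature_C, P),
       gibbs_kJ = G_WATER_REF_KJ + (gT + gP) / 1000,
       pressure_bar = P)
}
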