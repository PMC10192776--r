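# Revised-HKF apparent standard molal Gibbs energies of aqueous species.
#
# Species parameters are embedded as a citation-tagged CSV (see
# inst/extdata/hkf_species.csv). Reference-state values are stored in kJ/mol
# and J/(mol K); the equation-of-state coefficients use the conventional
# scaled calorie units of the SUPCRT-style compilations:
#   a1 x 10 cal/(mol bar), a2 x 1e-2 cal/mol, a3 cal K/(mol bar),
#   a4 x 1e-4 cal K/mol, c1 cal/(mol K), c2 x 1e-4 cal K/mol,
#   omega x 1e-5 cal/mol.
# The solvation (Born) term uses a constant omega; the high-temperature
# g-function correction is omitted, which is negligible below ~150 degC,
# and the engine range is capped at 100 degC / 500 bar accordingly.

HKF_THETA <- 228   # K
HKF_PSI <- 2600    # bar

#' Load the aqueous species parameter table
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return Data.frame with one row per species; `formula` parsed into a
#'   `formula_list` column (named integer vectors).
#' @export
load_species_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hkf_species.csv",
                        package = "oxalotrace", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "charge", "dG_f_ref_kJ", "S_ref_J",
            "a1", "a2", "a3", "a4", "c1", "c2", "omega")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_ox("species table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$name)) stop_ox("duplicate species names in table")
  df$formula_list <- lapply(df$formula, parse_formula)
  df
}

parse_formula <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  elements <- vapply(kv, `[`, "", 1L)
  counts <- as.integer(vapply(kv, `[`, "", 2L))
  if (anyNA(counts) || any(counts <= 0L) || length(elements) == 0L)
    stop_ox("malformed formula string: %s", s)
  setNames(counts, elements)
}

get_species <- function(name, table) {
  i <- match(name, table$name)
  if (is.na(i)) stop_ox("unknown species: %s", name)
  table[i, , drop = FALSE]
}

#' Apparent standard Gibbs energy of an aqueous species
#'
#' Revised-HKF equation of state with constant omega: the reference value
#' plus entropy, heat-capacity (c1, c2), volumetric (a1..a4) and Born
#' solvation contributions. At 25 degC and 1 bar the reference value is
#' returned exactly. Water is delegated to the dedicated liquid-water
#' model ([water_properties()]).
#'
#' @param name Species name present in the table.
#' @param cond A [tp_condition()] (or temperature in degC when `pressure_bar`
#'   is also given).
#' @param pressure_bar Pressure in bar when `cond` is numeric.
#' @param table Species table from [load_species_table()].
#' @return Apparent standard Gibbs energy in kJ/mol.
#' @export
gibbs_species <- function(name, cond, pressure_bar = NULL,
                          table = load_species_table()) {
  if (is.numeric(cond)) cond <- tp_condition(cond, pressure_bar)
  stopifnot(inherits(cond, "tp_condition"))
  sp <- get_species(name, table)
  if (sp$name == "water")
    return(water_properties(cond$temperature_C, cond$pressure_bar)$gibbs_kJ)

  params <- c("a1", "a2", "a3", "a4", "c1", "c2", "omega")
  bad <- params[!is.finite(unlist(sp[params]))]
  if (length(bad) > 0L)
    stop_ox("species '%s' lacks HKF parameter(s): %s",
            name, paste(bad, collapse = ", "))

  TK <- cond$temperature_C + 273.15
  P <- cond$pressure_bar
  Tr <- T_REF_K; Pr <- P_REF_BAR; th <- HKF_THETA; psi <- HKF_PSI

  # unscale to plain calorie units
  a1 <- sp$a1 * 1e-1; a2 <- sp$a2 * 1e2; a3 <- sp$a3; a4 <- sp$a4 * 1e4
  c1 <- sp$c1; c2 <- sp$c2 * 1e4; om <- sp$omega * 1e5
  G_cal <- sp$dG_f_ref_kJ * 1000 / CAL_J
  S_cal <- sp$S_ref_J / CAL_J

  eps <- dielectric_water(cond$temperature_C, P)
  g <- G_cal - S_cal * (TK - Tr) -
    c1 * (TK * log(TK / Tr) - TK + Tr) -
    c2 * ((1 / (TK - th) - 1 / (Tr - th)) * ((th - TK) / th) -
          TK / th^2 * log(Tr * (TK - th) / (TK * (Tr - th)))) +
    a1 * (P - Pr) + a2 * log((psi + P) / (psi + Pr)) +
    (a3 * (P - Pr) + a4 * log((psi + P) / (psi + Pr))) / (TK - th) +
    om * (1 / eps - 1 / EPS_REF) + om * Y_REF * (TK - Tr)
  g * CAL_J / 1000
}
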