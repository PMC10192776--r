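# Catabolic reaction definitions, balance validation, and reaction Gibbs
# energies at temperature-pressure conditions with optional activity
# corrections.
#
# Sign convention: negative stoichiometric coefficients are reactants,
# positive are products; a negative reaction Gibbs energy is
# energy-yielding.

#' Define a reaction
#'
#' @param stoichiometry Named numeric vector, species name to signed
#'   coefficient (reactants negative, products positive).
#' @param label Short reaction label.
#' @return A `reaction` object.
#' @export
reaction <- function(stoichiometry, label = "reaction") {
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop_ox("stoichiometry must be a named vector")
  if (any(stoichiometry == 0)) stop_ox("zero stoichiometric coefficients not allowed")
  structure(list(stoichiometry = stoichiometry, label = label),
            class = "reaction")
}

#' Oxalotrophy: oxalate + water -> formate + bicarbonate
#'
#' The biologically relevant overall oxalate-degradation reaction at
#' circumneutral pH: C2O4^2- + H2O -> HCOO- + HCO3-.
#' @return A `reaction`.
#' @export
reaction_oxalotrophy <- function() {
  reaction(c(oxalate = -1, water = -1, formate = 1, bicarbonate = 1),
           label = "oxalotrophy (oxalate + H2O -> formate + bicarbonate)")
}

#' Anaerobic methane oxidation coupled to sulfate reduction
#'
#' SO4^2- + CH4 -> HS- + HCO3- + H2O, the "low energy" marine-sediment
#' comparison metabolism.
#' @return A `reaction`.
#' @export
reaction_aom_sr <- function() {
  reaction(c(sulfate = -1, methane = -1,
             bisulfide = 1, bicarbonate = 1, water = 1),
           label = "AOM-SR (sulfate + methane -> bisulfide + bicarbonate + water)")
}

#' Schematic oxalate-to-carbonate reaction (documentation only)
#'
#' The classical schematic of the oxalate-carbonate pathway writes oxalate
#' plus water and a proton going to a generic "CHO" organic product plus
#' bicarbonate. The generic CHO molecule is not a defined aqueous species,
#' so this reaction cannot be validated or evaluated by the engine;
#' [validate_reaction()] rejects it with an explanatory error. It is
#' provided so the rejection is explicit rather than silent.
#' @return A `reaction` referencing the undefined species `CHO`.
#' @export
reaction_ocp_schematic <- function() {
  reaction(c(oxalate = -1, water = -1, `H+` = -1, CHO = 1, bicarbonate = 1),
           label = "schematic OCP (generic CHO product; not evaluable)")
}

#' Validate element and charge balance of a reaction
#'
#' Balance is checked in exact integer arithmetic over the species table's
#' parsed formulas. An imbalance raises an error listing per-element and
#' charge residuals.
#'
#' @param rxn A [reaction()].
#' @param table Species table from [load_species_table()].
#' @return Invisibly, a data.frame of residuals (all zero when balanced).
#' @export
validate_reaction <- function(rxn, table = load_species_table()) {
  stopifnot(inherits(rxn, "reaction"))
  unknown <- setdiff(names(rxn$stoichiometry), table$name)
  if (length(unknown) > 0L)
    stop_ox("reaction '%s' uses species not in the table: %s%s",
            rxn$label, paste(unknown, collapse = ", "),
            if ("CHO" %in% unknown)
              " (the generic CHO product is schematic, not a defined aqueous species)"
            else "")
  elements <- sort(unique(unlist(lapply(
    table$formula_list[match(names(rxn$stoichiometry), table$name)], names))))
  resid <- setNames(rep(0L, length(elements)), elements)
  charge <- 0L
  for (spn in names(rxn$stoichiometry)) {
    nu <- rxn$stoichiometry[[spn]]
    row <- get_species(spn, table)
    f <- row$formula_list[[1L]]
    resid[names(f)] <- resid[names(f)] + as.integer(round(nu)) * f
    charge <- charge + as.integer(round(nu)) * row$charge
  }
  out <- data.frame(component = c(elements, "charge"),
                    residual = c(as.integer(resid), charge))
  if (any(out$residual != 0L)) {
    bad <- out[out$residual != 0L, , drop = FALSE]
    stop_ox("reaction '%s' is unbalanced: %s", rxn$label,
            paste(sprintf("%s %+d", bad$component, bad$residual),
                  collapse = ", "))
  }
  invisible(out)
}

#' Standard-state reaction Gibbs energy
#'
#' Sum of stoichiometry-weighted apparent standard Gibbs energies of the
#' species at the condition; negative values are energy-yielding.
#'
#' @param rxn A [reaction()] (validated before evaluation).
#' @param cond A [tp_condition()], or temperature in degC with
#'   `pressure_bar`.
#' @param pressure_bar Pressure in bar when `cond` is numeric.
#' @param table Species table.
#' @return Reaction Gibbs energy in kJ/mol.
#' @export
delta_g_standard <- function(rxn, cond, pressure_bar = NULL,
                             table = load_species_table()) {
  if (is.numeric(cond)) cond <- tp_condition(cond, pressure_bar)
  validate_reaction(rxn, table)
  contrib <- vapply(names(rxn$stoichiometry), function(spn)
    rxn$stoichiometry[[spn]] * gibbs_species(spn, cond, table = table),
    numeric(1L))
  sum(contrib)
}

#' Activity set
#'
#' @param ... Named activities (dimensionless, molal scale); species not
#'   named default to unit activity.
#' @return An `activity_set` named numeric vector.
#' @export
activity_set <- function(...) {
  a <- c(...)
  if (is.null(a)) a <- setNames(numeric(0), character(0))
  if (length(a) > 0 && (is.null(names(a)) || any(!nzchar(names(a)))))
    stop_ox("activities must be named")
  if (any(a <= 0)) stop_ox("activities must be positive")
  structure(a, class = "activity_set")
}

#' Activity-corrected reaction Gibbs energy
#'
#' dG_r = dG0_r + R T ln Q with Q the product of activities raised to
#' stoichiometric coefficients (R = 8.3145 J/(mol K), T in kelvin).
#'
#' @param rxn A [reaction()].
#' @param cond A [tp_condition()], or temperature in degC with
#'   `pressure_bar`.
#' @param activities An [activity_set()] (unset species have activity 1).
#' @param pressure_bar Pressure in bar when `cond` is numeric.
#' @param table Species table.
#' @return An `energetics_result` list: `dG0_r`, `dG_r`, `lnQ`,
#'   `contributions` (per-species nu * G, kJ/mol), `condition`.
#' @export
delta_g <- function(rxn, cond, activities = activity_set(),
                    pressure_bar = NULL, table = load_species_table()) {
  if (is.numeric(cond)) cond <- tp_condition(cond, pressure_bar)
  validate_reaction(rxn, table)
  extra <- setdiff(names(activities), names(rxn$stoichiometry))
  if (length(extra) > 0L)
    warn_ox("activities for species not in the reaction ignored: %s",
            paste(extra, collapse = ", "))
  contrib <- vapply(names(rxn$stoichiometry), function(spn)
    rxn$stoichiometry[[spn]] * gibbs_species(spn, cond, table = table),
    numeric(1L))
  dg0 <- sum(contrib)
  act <- setNames(rep(1, length(rxn$stoichiometry)), names(rxn$stoichiometry))
  common <- intersect(names(activities), names(act))
  if (length(common) > 0L) act[common] <- unclass(activities)[common]
  lnQ <- sum(rxn$stoichiometry * log(act))
  TK <- cond$temperature_C + 273.15
  dg <- dg0 + R_GAS * TK * lnQ / 1000
  structure(list(dG0_r = dg0, dG_r = dg, lnQ = lnQ,
                 contributions = contrib, condition = cond,
                 label = rxn$label),
            class = "energetics_result")
}

#' @export
print.energetics_result <- function(x, ...) {
  cat(sprintf("%s\n  at %.5g degC, %.5g bar\n", x$label,
              x$condition$temperature_C, x$condition$nominal_pressure_bar))
  cat(sprintf("  dG0_r = %.2f kJ/mol   lnQ = %.4f   dG_r = %.2f kJ/mol\n",
              x$dG0_r, x$lnQ, x$dG_r))
  invisible(x)
}

#' Default marine temperature-pressure grid
#'
#' The survey grid: 2, 20, 50, 100 degC crossed with 1.01 and 250 bar.
#' @return Data.frame with `temperature_C` and `pressure_bar`.
#' @export
default_tp_grid <- function() {
  expand.grid(temperature_C = c(2, 20, 50, 100),
              pressure_bar = c(1.01, 250),
              KEEP.OUT.ATTRS = FALSE)
}

#' Standard-state Gibbs energies over a temperature-pressure grid
#'
#' @param rxn A [reaction()] or named list of reactions (one output column
#'   per reaction).
#' @param conditions Data.frame with `temperature_C` and `pressure_bar`
#'   (default: [default_tp_grid()]).
#' @param table Species table.
#' @return Data.frame: the condition columns plus one `dG0_<label>` column
#'   of kJ/mol values per reaction.
#' @export
tp_grid <- function(rxn, conditions = default_tp_grid(),
                    table = load_species_table()) {
  rxns <- if (inherits(rxn, "reaction")) setNames(list(rxn), rxn$label) else rxn
  stopifnot(all(vapply(rxns, inherits, TRUE, "reaction")))
  out <- conditions
  for (nm in names(rxns)) {
    vals <- mapply(function(tc, pb)
      suppressMessages(delta_g_standard(rxns[[nm]], tp_condition(tc, pb),
                                        table = table)),
      conditions$temperature_C, conditions$pressure_bar)
    out[[paste0("dG0_", nm)]] <- vals
  }
  out
}
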