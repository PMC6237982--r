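#' Stoichiometric constants for MFC electron accounting
#'
#' Single source of truth for every chemical conversion the package
#' performs: Faraday's constant, electron equivalents of the half
#' reactions (acetate oxidation, nitrate reduction), molar masses, and
#' the theoretical COD content of sodium acetate.
#'
#' The COD equivalent of sodium acetate is derived, not stored: complete
#' oxidation of one mole of acetate consumes two moles of O2, so one gram
#' of sodium acetate (82.0 g/mol) corresponds to
#' \code{1000 * 2 * 32.0 / 82.0 = 780.5} mg COD.  Molar masses are kept
#' at the two-significant-figure values that reproduce this printed
#' conversion; using 82.03 or 14.007 shifts derived ratios only in the
#' third decimal.
#'
#' @param faraday Charge per mole of electrons (C/mol).
#' @param e_per_acetate Electrons released per mole of acetate fully
#'   oxidized to CO2.
#' @param e_per_nitrate_to_n2 Electrons consumed per mole of nitrate
#'   reduced to N2.
#' @param e_per_nitrate_to_no2 Electrons consumed per mole of nitrate
#'   reduced only to nitrite.
#' @param e_per_o2 Electrons per mole of O2; the definition of COD as an
#'   electron currency (1 mol O2 = 4 mol e-).
#' @param mw_o2,mw_n,mw_sodium_acetate Molar masses (g/mol).
#' @return An object of class \code{stoich_constants}: a list of the
#'   constants above plus the derived \code{cod_per_g_sodium_acetate}
#'   (mg COD per g).
#' @examples
#' st <- stoich_constants()
#' st$cod_per_g_sodium_acetate  # ~780.5
#' @export
stoich_constants <- function(faraday = 96485,
                             e_per_acetate = 8,
                             e_per_nitrate_to_n2 = 5,
                             e_per_nitrate_to_no2 = 2,
                             e_per_o2 = 4,
                             mw_o2 = 32.0,
                             mw_n = 14.0,
                             mw_sodium_acetate = 82.0) {
  vals <- list(faraday = faraday,
               e_per_acetate = e_per_acetate,
               e_per_nitrate_to_n2 = e_per_nitrate_to_n2,
               e_per_nitrate_to_no2 = e_per_nitrate_to_no2,
               e_per_o2 = e_per_o2,
               mw_o2 = mw_o2,
               mw_n = mw_n,
               mw_sodium_acetate = mw_sodium_acetate)
  bad <- vapply(vals, function(x) !is.numeric(x) || length(x) != 1 ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop("all stoichiometric constants must be single positive numbers; bad: ",
         paste(names(vals)[bad], collapse = ", "))
  vals$cod_per_g_sodium_acetate <- 1000 * (2 * mw_o2) / mw_sodium_acetate
  structure(vals, class = "stoich_constants")
}

#' @export
print.stoich_constants <- function(x, ...) {
  cat("Stoichiometric constants:\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Load stoichiometric constants from a configuration file
#'
#' Reads a flat key-value file (JSON or YAML, by extension) and overrides
#' the defaults of \code{\link{stoich_constants}} with any recognized key.
#' Unknown keys are an error so that typos do not silently fall back to
#' defaults.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{stoich_constants} object.
#' @export
load_stoich_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- setdiff(names(formals(stoich_constants)), "...")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown stoichiometry config keys: ", paste(unknown, collapse = ", "))
  do.call(stoich_constants, cfg)
}

# ---------------------------------------------------------------------------
# Chemical species bookkeeping

#' Parse a chemical species formula into element counts and charge
#'
#' Understands simple ionic formulas as written in wastewater chemistry:
#' element symbols with optional counts, and a trailing charge written as
#' \code{+}, \code{-}, \code{2-}, etc.  \code{"e-"} is the bare electron.
#'
#' @param species A single formula string, e.g. \code{"CH3COO-"},
#'   \code{"C5H7O2N"}, \code{"NO3-"}.
#' @return Named list with \code{elements} (named numeric vector of atom
#'   counts) and \code{charge} (signed number).
#' @examples
#' parse_species("CH3COO-")  # C2 H3 O2, charge -1
#' @export
parse_species <- function(species) {
  if (!is.character(species) || length(species) != 1 || !nzchar(species))
    stop("species must be a single non-empty string")
  s <- gsub("\\s", "", species)
  if (s %in% c("e-", "e"))
    return(list(elements = c(e = 1), charge = -1))
  # a bare trailing sign is a unit charge ("NO3-"); larger charges are
  # written caret-style ("Fe^3+") so digits are never stolen from an
  # element count
  charge <- 0
  m <- regmatches(s, regexpr("(\\^[0-9]+)?([+-])$", s))
  if (length(m) && nzchar(m)) {
    n <- gsub("[^0-9]", "", m)
    mag <- if (nzchar(n)) as.numeric(n) else 1
    charge <- if (grepl("\\+$", m)) mag else -mag
    s <- sub("(\\^[0-9]+)?([+-])$", "", s)
  }
  body <- s
  counts <- c()
  while (nzchar(body)) {
    m <- regmatches(body, regexpr("^([A-Z][a-z]?)([0-9]*)", body))
    if (!length(m) || !nzchar(m))
      stop("cannot parse species '", species, "' at '", body, "'")
    el <- sub("[0-9]*$", "", m)
    num <- sub("^[A-Za-z]+", "", m)
    n <- if (nzchar(num)) as.numeric(num) else 1
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
    body <- substr(body, nchar(m) + 1, nchar(body))
  }
  list(elements = counts, charge = charge)
}

#' Construct a half reaction (or full reaction) for element bookkeeping
#'
#' A reaction is a pair of named coefficient vectors.  Coefficients are
#' moles per formula unit as written; electrons may appear either as an
#' explicit \code{"e-"} species or via the \code{electrons} field.
#'
#' @param reactants,products Named numeric vectors: species formula ->
#'   stoichiometric coefficient (all positive).
#' @param electrons Moles of electrons transferred per formula unit
#'   (positive = released by the reactant side), if not written as an
#'   explicit \code{"e-"} species.
#' @return Object of class \code{half_reaction}.
#' @examples
#' # acetate oxidation: CH3COO- + 2H2O -> 2CO2 + 8e- + 7H+
#' acetate_oxidation()
#' @export
half_reaction <- function(reactants, products, electrons = 0) {
  for (side in list(reactants, products)) {
    if (is.null(names(side)) || any(!nzchar(names(side))))
      stop("reactants and products must be named numeric vectors")
    if (any(!is.finite(side)) || any(side <= 0))
      stop("stoichiometric coefficients must be positive and finite")
  }
  structure(list(reactants = reactants, products = products,
                 electrons = electrons),
            class = "half_reaction")
}

#' @export
print.half_reaction <- function(x, ...) {
  fmt <- function(v) paste(sprintf("%g %s", v, names(v)), collapse = " + ")
  cat(fmt(x$reactants), "=", fmt(x$products), "\n")
  if (x$electrons != 0)
    cat("  (", x$electrons, "e- per formula unit )\n")
  invisible(x)
}

#' Acetate-oxidation half reaction (8 electrons per acetate)
#' @return A \code{half_reaction}.
#' @export
acetate_oxidation <- function() {
  half_reaction(
    reactants = c("CH3COO-" = 1, "H2O" = 2),
    products  = c("CO2" = 2, "e-" = 8, "H+" = 7))
}

#' Nitrate-to-dinitrogen half reaction (5 electrons per nitrate)
#' @return A \code{half_reaction}.
#' @export
nitrate_reduction <- function() {
  half_reaction(
    reactants = c("NO3-" = 1, "e-" = 5, "H+" = 6),
    products  = c("N2" = 0.5, "H2O" = 3))
}

#' Heterotrophic denitrifier stoichiometry with biomass synthesis
#'
#' The biomass-inclusive denitrification reaction used to derive the
#' critical COD/N ratio: 7.03 acetate + 8.58 nitrate yielding 0.58
#' C5H7O2N biomass, CO2, hydroxide, water and N2.  Coefficients are kept
#' exactly as conventionally printed (rounded to two decimals), so the
#' equation balances in C, N and O but not in H or charge; use
#' \code{\link{check_element_balance}} to inspect the discrepancies.
#'
#' @return A \code{half_reaction}.
#' @export
denitrifier_stoichiometry <- function() {
  half_reaction(
    reactants = c("CH3COO-" = 7.03, "NO3-" = 8.58),
    products  = c("C5H7O2N" = 0.58, "CO2" = 11.16, "OH-" = 8.58,
                  "H2O" = 7.74, "N2" = 4))
}

#' Element (and charge) balance check for a reaction
#'
#' Tallies each requested element on both sides, weighted by the
#' stoichiometric coefficients, and reports the signed left-minus-right
#' discrepancy.  \code{"charge"} may be requested like an element.
#' Rounded printed coefficients typically leave discrepancies of a few
#' hundredths of a formula unit; the default tolerance flags anything
#' larger.
#'
#' @param reaction A \code{half_reaction}.
#' @param elements Character vector of element symbols, optionally
#'   including \code{"charge"}.
#' @param tolerance Discrepancy (formula units) below which a tally is
#'   considered balanced.
#' @return A data frame with columns \code{element}, \code{left},
#'   \code{right}, \code{discrepancy}, \code{balanced}.
#' @examples
#' check_element_balance(denitrifier_stoichiometry(),
#'                       c("C", "N", "O", "H", "charge"))
#' @export
check_element_balance <- function(reaction,
                                  elements = c("C", "H", "O", "N", "charge"),
                                  tolerance = 0.05) {
  stopifnot(inherits(reaction, "half_reaction"))
  tally <- function(side) {
    tot <- stats::setNames(numeric(length(elements)), elements)
    for (sp in names(side)) {
      p <- parse_species(sp)
      for (el in elements) {
        add <- if (el == "charge") p$charge
               else if (el %in% names(p$elements)) p$elements[[el]] else 0
        tot[el] <- tot[el] + side[[sp]] * add
      }
    }
    tot
  }
  left <- tally(reaction$reactants)
  right <- tally(reaction$products)
  # explicit electrons count as negative charge on whichever side they sit
  data.frame(element = elements,
             left = unname(left),
             right = unname(right),
             discrepancy = unname(left - right),
             balanced = unname(abs(left - right) <= tolerance),
             row.names = NULL)
}

# ---------------------------------------------------------------------------
# Conversions

#' COD equivalent of a sodium acetate concentration
#'
#' @param mass_concentration_g_l Sodium acetate concentration (g/L), >= 0.
#' @param constants A \code{stoich_constants} object.
#' @return COD concentration in mg/L (one gram of sodium acetate is
#'   780.5 mg COD at the default molar masses).
#' @examples
#' cod_of_sodium_acetate(1)  # 780.5
#' @export
cod_of_sodium_acetate <- function(mass_concentration_g_l,
                                  constants = stoich_constants()) {
  if (any(!is.finite(mass_concentration_g_l)) ||
      any(mass_concentration_g_l < 0))
    stop("mass_concentration_g_l must be non-negative and finite")
  mass_concentration_g_l * constants$cod_per_g_sodium_acetate
}

#' Charge equivalent of consumed COD
#'
#' Converts a COD mass consumed (mg O2) into Coulombs via the electron
#' content of oxygen: 1 mol O2 accepts 4 mol e-.  Equivalent to counting
#' 8 electrons per mole of acetate oxidized.
#'
#' @param delta_cod_mg COD consumed (mg), >= 0.
#' @param constants A \code{stoich_constants} object.
#' @return Charge in Coulombs.
#' @examples
#' electrons_from_cod(11.71)  # ~141.2 C (1 g/L acetate in a 15 mL chamber)
#' @export
electrons_from_cod <- function(delta_cod_mg, constants = stoich_constants()) {
  if (any(!is.finite(delta_cod_mg)) || any(delta_cod_mg < 0))
    stop("delta_cod_mg must be non-negative and finite (COD consumed)")
  (delta_cod_mg / 1000 / constants$mw_o2) * constants$e_per_o2 *
    constants$faraday
}

#' Charge equivalent of denitrified nitrate
#'
#' Converts nitrate-N removed (mg N) into Coulombs assuming reduction to
#' N2 (5 e- per N).  Optionally corrects for nitrate that stalled at
#' nitrite, which consumed only 2 of the 5 electrons: each mole of
#' residual nitrite-N subtracts 3 electron-moles.  The correction is off
#' by default because nitrite intermediates are typically below detection
#' at cycle end.
#'
#' @param delta_no3n_mg Nitrate-N removed (mg N), >= 0.
#' @param residual_no2n_mg Nitrite-N remaining at cycle end (mg N), >= 0,
#'   cannot exceed the nitrate-N removed.
#' @param nitrite_correction Apply the 3 e-/mol deduction for residual
#'   nitrite?
#' @param constants A \code{stoich_constants} object.
#' @return Charge in Coulombs.
#' @examples
#' electrons_from_nitrate(0.75)  # ~25.85 C (50 mg/L N in 15 mL)
#' @export
electrons_from_nitrate <- function(delta_no3n_mg, residual_no2n_mg = 0,
                                   nitrite_correction = FALSE,
                                   constants = stoich_constants()) {
  if (any(!is.finite(delta_no3n_mg)) || any(delta_no3n_mg < 0))
    stop("delta_no3n_mg must be non-negative and finite")
  if (any(!is.finite(residual_no2n_mg)) || any(residual_no2n_mg < 0))
    stop("residual_no2n_mg must be non-negative and finite")
  if (any(residual_no2n_mg > delta_no3n_mg))
    stop("residual nitrite-N exceeds nitrate-N removed: inconsistent data")
  mol_e <- (delta_no3n_mg / 1000 / constants$mw_n) *
    constants$e_per_nitrate_to_n2
  if (nitrite_correction) {
    deficit <- constants$e_per_nitrate_to_n2 - constants$e_per_nitrate_to_no2
    mol_e <- mol_e - (residual_no2n_mg / 1000 / constants$mw_n) * deficit
  }
  mol_e * constants$faraday
}

#' Critical COD/N ratio of a denitrification stoichiometry
#'
#' The stoichiometric minimum mass of COD needed per mass of nitrate-N
#' for complete denitrification, read off a biomass-inclusive reaction:
#' (acetate coefficient x molar mass of sodium acetate x COD per gram) /
#' (nitrate coefficient x molar mass of N).  With the conventional
#' coefficients (7.03 acetate : 8.58 nitrate) this is 3.75 g COD per g N.
#'
#' @param reaction A \code{half_reaction} whose reactants include
#'   \code{"CH3COO-"} and \code{"NO3-"}.
#' @param constants A \code{stoich_constants} object.
#' @return The ratio (g COD per g N), dimensionless.
#' @examples
#' critical_cod_n_ratio(denitrifier_stoichiometry())  # 3.75
#' @export
critical_cod_n_ratio <- function(reaction, constants = stoich_constants()) {
  stopifnot(inherits(reaction, "half_reaction"))
  r <- reaction$reactants
  if (!all(c("CH3COO-", "NO3-") %in% names(r)))
    stop("reaction must contain CH3COO- and NO3- among its reactants")
  ac <- r[["CH3COO-"]]; ni <- r[["NO3-"]]
  (ac * constants$mw_sodium_acetate *
      constants$cod_per_g_sodium_acetate / 1000) / (ni * constants$mw_n)
}

#' COD mass equivalent of a charge
#'
#' Inverse of \code{\link{electrons_from_cod}}: Coulombs back to mg O2.
#' Used to express residual electron fluxes in COD units for COD/N
#' ratios.
#'
#' @param charge_c Charge (C), any sign.
#' @param constants A \code{stoich_constants} object.
#' @return COD mass in mg.
#' @export
cod_equivalent_of_charge <- function(charge_c, constants = stoich_constants()) {
  charge_c / constants$faraday / constants$e_per_o2 * constants$mw_o2 * 1000
}
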