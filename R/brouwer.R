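#' Brouwer coefficients for indirect calorimetry
#'
#' Coefficient set converting daily gas exchange and urinary nitrogen into
#' heat production (kJ/d): `HP = 16.18*O2 + 5.02*CO2 - 2.17*CH4 - 5.99*uN`
#' with gas volumes in litres and urinary N in grams.  The set also carries
#' the nitrogen-to-protein factor (6.25) and the combustion energy of body
#' protein (23.86 kJ/g) used to convert retained nitrogen into energy
#' deposited as protein.
#'
#' @param o2,co2,ch4 kJ per litre of O2 consumed, CO2 produced and CH4
#'   produced.
#' @param urinary_n kJ per gram of urinary nitrogen (negative: energy lost).
#' @param n_to_protein grams of protein per gram of nitrogen.
#' @param protein_energy combustion energy of protein, kJ/g.
#' @return An object of class `brouwer_coefficients` (a named list).
#' @examples
#' heat_production(o2 = 500, co2 = 450, ch4 = 2, urinary_n = 8)
#' @export
brouwer_coefficients <- function(o2 = 16.18, co2 = 5.02, ch4 = -2.17,
                                 urinary_n = -5.99,
                                 n_to_protein = 6.25, protein_energy = 23.86) {
  coef <- list(o2 = o2, co2 = co2, ch4 = ch4, urinary_n = urinary_n,
               n_to_protein = n_to_protein, protein_energy = protein_energy)
  stopifnot(vapply(coef, is.numeric, logical(1)),
            lengths(coef) == 1L)
  structure(coef, class = "brouwer_coefficients")
}

#' @export
print.brouwer_coefficients <- function(x, ...) {
  cat("Heat production coefficients (kJ):\n")
  cat(sprintf("  %+.2f /L O2  %+.2f /L CO2  %+.2f /L CH4  %+.2f /g urinary N\n",
              x$o2, x$co2, x$ch4, x$urinary_n))
  cat(sprintf("  N -> protein: x%.2f; protein energy: %.2f kJ/g\n",
              x$n_to_protein, x$protein_energy))
  invisible(x)
}

#' Heat production from gas exchange
#'
#' Linear combination of daily O2 consumption, CO2 and CH4 production and
#' urinary nitrogen excretion.  Vectorised over all four inputs.
#'
#' @param o2,co2,ch4 daily gas volumes, L/d.  Must be non-negative.
#' @param urinary_n daily urinary nitrogen, g/d.
#' @param coef a [brouwer_coefficients()] set.
#' @return Heat production, kJ/d.
#' @export
heat_production <- function(o2, co2, ch4 = 0, urinary_n = 0,
                            coef = brouwer_coefficients()) {
  stopifnot(is.numeric(o2), is.numeric(co2), is.numeric(ch4),
            is.numeric(urinary_n))
  if (any(o2 < 0, na.rm = TRUE) || any(co2 < 0, na.rm = TRUE) ||
      any(ch4 < 0, na.rm = TRUE)) {
    stop("gas volumes must be non-negative", call. = FALSE)
  }
  coef$o2 * o2 + coef$co2 * co2 + coef$ch4 * ch4 + coef$urinary_n * urinary_n
}
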