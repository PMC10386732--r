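#' Stoichiometric mass-conversion factors of the hydrolysis reactions
#'
#' Computes, from atomic masses, the factors converting the mass of a
#' polymeric anhydro-sugar unit into the mass of the hydrated product:
#' cellulose (anhydroglucose) to cellobiose, cellulose to glucose,
#' cellobiose to glucose, and xylan (anhydroxylose) to xylose. Hydrolysis
#' adds one water per glycosidic bond broken, so each product weighs more
#' than the substrate consumed; the model's mass balances multiply the
#' reaction rates by these factors.
#'
#' @return Named numeric vector with elements `cellulose_to_cellobiose`,
#'   `cellulose_to_glucose`, `cellobiose_to_glucose`, `xylan_to_xylose`.
#' @examples
#' round(stoichiometric_factors(), 3)
#' @export
stoichiometric_factors <- function() {
  C <- 12.011; H <- 1.008; O <- 15.999
  glucose <- 6 * C + 12 * H + 6 * O        # C6H12O6
  anhydroglucose <- 6 * C + 10 * H + 5 * O # C6H10O5, cellulose monomer
  cellobiose <- 12 * C + 22 * H + 11 * O   # C12H22O11
  xylose <- 5 * C + 10 * H + 5 * O         # C5H10O5
  anhydroxylose <- 5 * C + 8 * H + 4 * O   # C5H8O4, xylan monomer
  c(cellulose_to_cellobiose = cellobiose / (2 * anhydroglucose),
    cellulose_to_glucose    = glucose / anhydroglucose,
    cellobiose_to_glucose   = 2 * glucose / cellobiose,
    xylan_to_xylose         = xylose / anhydroxylose)
}

# The mass balances use the factors as printed (3-4 significant digits);
# stoichiometric_factors() verifies them from first principles.
.stoich <- c(c2g2 = 1.056, g2g = 1.053, c2g = 1.111, xn2x = 1.136)
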