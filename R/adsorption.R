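#' Adsorption coefficient set for cellulase Langmuir isotherms
#'
#' The maximum adsorption capacity `Emax` (mg protein/g substrate) and
#' the dissociation constant `Kp` (mL/mg protein) of the cellulase
#' isotherm change as hydrolysis proceeds; both are correlated with the
#' cellulose conversion percentage `X` through `exp(a + b*X + c*X^2)`.
#' Non-productive adsorption on lignin uses a second isotherm with fixed
#' capacity `emaxL` (mg protein/g lignin) and constant `kpL` (mL/mg
#' protein); by default it is disabled (`emaxL = 0`) because those two
#' constants are not part of the fitted parameter set and the
#' surface-decay law already carries the lignin-blocking effect.
#'
#' @param emax_abc Numeric triple `(a, b, c)` for the `Emax` correlation.
#' @param kp_abc Numeric triple `(a, b, c)` for the `Kp` correlation.
#' @param emaxL Maximum cellulase adsorption on lignin (mg/g), `>= 0`.
#' @param kpL Lignin adsorption dissociation constant (mL/mg), `>= 0`.
#' @return An object of class `adsorption_coeffs`.
#' @seealso [load_adsorption()] for the shipped fitted coefficient sets.
#' @export
adsorption_coeffs <- function(emax_abc, kp_abc, emaxL = 0, kpL = 0) {
  stopifnot(length(emax_abc) == 3, length(kp_abc) == 3,
            all(is.finite(c(emax_abc, kp_abc))),
            emaxL >= 0, kpL >= 0)
  structure(list(emax_abc = as.numeric(emax_abc),
                 kp_abc = as.numeric(kp_abc),
                 emaxL = emaxL, kpL = kpL),
            class = "adsorption_coeffs")
}

#' Conversion-dependent Langmuir coefficient
#'
#' Evaluates `exp(a + b*X + c*X^2)` at cellulose conversion `X` percent.
#'
#' @param conversion_pct Cellulose conversion in percent, in `[0, 100]`.
#' @param abc Numeric triple `(a, b, c)`.
#' @return Strictly positive coefficient value. Vectorised over
#'   `conversion_pct`.
#' @examples
#' langmuir_coefficient(0, c(3.607, -0.00719, -0.0000772)) # exp(3.607)
#' @export
langmuir_coefficient <- function(conversion_pct, abc) {
  stopifnot(is.numeric(conversion_pct), length(abc) == 3)
  if (any(conversion_pct < 0 | conversion_pct > 100))
    stop("conversion must be within [0, 100] percent")
  exp(abc[1] + abc[2] * conversion_pct + abc[3] * conversion_pct^2)
}

#' Partition total cellulase among free, bagasse-, lignin- and
#' cellulose-bound pools
#'
#' Solves the closed Langmuir mass balance
#' `E1T = E1f + Emax*Kp*E1f*S / ((1 + Kp*E1f) * 1000)`
#' for the free pool `E1f` via the positive root of the resulting
#' quadratic (the 1/1000 factor bridges per-gram capacities against
#' mg/mL substrate concentrations). The lignin-bound pool is evaluated
#' from the same free pool; the productively (cellulose-) bound pool is
#' the bagasse-bound amount minus the lignin-bound amount, clipped at
#' zero with a warning if the clip is active.
#'
#' @param E1T Total cellulase protein (mg/mL), `>= 0`.
#' @param S Insoluble solids concentration (mg/mL), `>= 0`.
#' @param L Lignin concentration (mg/mL), `>= 0`.
#' @param Emax Adsorption capacity on bagasse (mg protein/g substrate).
#' @param Kp Dissociation constant on bagasse (mL/mg protein).
#' @param emaxL,kpL Lignin isotherm constants (defaults disable lignin
#'   adsorption).
#' @return List with components `E1f`, `E1b`, `E1bL`, `E1bC` (mg/mL).
#' @export
cellulase_partition <- function(E1T, S, L, Emax, Kp, emaxL = 0, kpL = 0) {
  stopifnot(E1T >= 0, S >= 0, L >= 0, Emax >= 0, Kp >= 0,
            emaxL >= 0, kpL >= 0)
  if (E1T == 0)
    return(list(E1f = 0, E1b = 0, E1bL = 0, E1bC = 0))
  A <- Emax * S / 1000
  if (Kp == 0 || A == 0) {
    E1f <- E1T
  } else {
    b <- 1 + Kp * (A - E1T)
    disc <- b^2 + 4 * Kp * E1T
    if (disc < 0)
      stop(sprintf("no real root in cellulase partition (E1T=%g, S=%g, Emax=%g, Kp=%g)",
                   E1T, S, Emax, Kp))
    E1f <- 2 * E1T / (b + sqrt(disc)) # positive root, cancellation-free
  }
  E1b <- E1T - E1f
  E1bL <- if (emaxL > 0 && kpL > 0)
    emaxL * kpL * E1f * L / ((1 + kpL * E1f) * 1000) else 0
  E1bC <- E1b - E1bL
  if (E1bC < 0) {
    warning("lignin-bound cellulase exceeds bagasse-bound; clipping E1bC at 0")
    E1bC <- 0
  }
  list(E1f = E1f, E1b = E1b, E1bL = E1bL, E1bC = E1bC)
}
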