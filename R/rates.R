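#' Construct a model state
#'
#' The ODE state: time plus the five concentrations — cellulose `C`,
#' cellobiose `G2`, glucose `G`, xylan `Xn`, xylose `X`, all in mg/mL.
#'
#' @param t Time (h), `>= 0`.
#' @param C,G2,G,Xn,X Concentrations (mg/mL), `>= 0`.
#' @return Named numeric vector of class `hydro_state`.
#' @export
hydro_state <- function(t = 0, C = 0, G2 = 0, G = 0, Xn = 0, X = 0) {
  s <- c(t = t, C = C, G2 = G2, G = G, Xn = Xn, X = X)
  if (any(!is.finite(s)) || any(s < 0))
    stop("state components must be finite and >= 0")
  structure(s, class = "hydro_state")
}

#' Reaction rates of the hydrolysis network
#'
#' The four rate laws, each in mg/(mL h):
#' * `rate_r1` — heterogeneous cellulose to cellobiose, catalysed by
#'   cellulose-bound cellulase, competitively inhibited by cellobiose,
#'   glucose and xylose, attenuated by the surface decay `exp(-lam*t)`;
#' * `rate_r2` — homogeneous cellobiose to glucose by free
#'   beta-glucosidase, Michaelis-Menten with competitive glucose/xylose
#'   inhibition;
#' * `rate_r3` — heterogeneous cellulose to glucose, same structure as r1
#'   with its own constants;
#' * `rate_r4` — xylan to xylose with xylose inhibition and a
#'   substrate-limitation term `Xn / (kS + Xn)`.
#'
#' @param state A [hydro_state()].
#' @param E1bC Cellulose-bound cellulase (mg protein/mL), `>= 0`.
#' @param E2f Free beta-glucosidase (mg protein/mL), `>= 0`.
#' @param p A [kinetic_params()] object.
#' @param lam Surface-decay rate (1/h), `>= 0`.
#' @param K4 Concentrated xylan hydrolysis constant (1/h), see
#'   [k4_concentrated()].
#' @return Reaction rate in mg/(mL h).
#' @name rates
NULL

#' @rdname rates
#' @export
rate_r1 <- function(state, E1bC, p, lam) {
  stopifnot(E1bC >= 0, lam >= 0)
  s <- unclass(state)
  p$k1r * E1bC * s[["C"]] * exp(-lam * s[["t"]]) /
    (1 + s[["G2"]] / p$K1iG2 + s[["G"]] / p$K1iG + s[["X"]] / p$K1iX)
}

#' @rdname rates
#' @export
rate_r2 <- function(state, E2f, p) {
  stopifnot(E2f >= 0)
  s <- unclass(state)
  G2 <- s[["G2"]]
  if (G2 == 0) return(0)
  p$k2r * E2f * G2 /
    (p$K2m * (1 + s[["G"]] / p$K2iG + s[["X"]] / p$K2iX) + G2)
}

#' @rdname rates
#' @export
rate_r3 <- function(state, E1bC, p, lam) {
  stopifnot(E1bC >= 0, lam >= 0)
  s <- unclass(state)
  p$k3r * E1bC * s[["C"]] * exp(-lam * s[["t"]]) /
    (1 + s[["G2"]] / p$K3iG2 + s[["G"]] / p$K3iG + s[["X"]] / p$K3iX)
}

#' Concentrated xylan-hydrolysis constant from the xylanase dose
#'
#' A Langmuir-type saturation of the xylan rate constant in the reactor
#' xylanase activity: `K4 = k4 * E3 / (Keq + E3)`.
#'
#' @param E3 Xylanase activity in the reactor (U/mL), `>= 0`.
#' @param p A [kinetic_params()] object.
#' @return `K4` in 1/h; 0 at `E3 = 0`, approaching `k4` at large doses.
#' @export
k4_concentrated <- function(E3, p) {
  stopifnot(E3 >= 0)
  p$k4 * E3 / (p$Keq + E3)
}

#' @rdname rates
#' @export
rate_r4 <- function(state, K4, p) {
  stopifnot(K4 >= 0)
  s <- unclass(state)
  Xn <- s[["Xn"]]
  if (Xn == 0) return(0)
  K4 * Xn / (1 + s[["X"]] / p$K4iX) * Xn / (p$kS + Xn)
}
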