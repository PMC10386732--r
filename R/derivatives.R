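# Resolve an (assay, params) pair into the flat coefficient list the
# compiled RHS consumes. lambda is evaluated once per assay from the
# (constant) lignin concentration; beta-glucosidase never adsorbs, so
# E2f = E2T throughout.
.model_list <- function(assay, params) {
  stopifnot(inherits(assay, "hydro_assay"), inherits(params, "hydro_params"))
  lam <- if (params$lambda_spec$mode == "constant") params$lambda_spec$value
         else lambda_of_lignin(assay$L0, params$lambda_spec)
  ad <- assay$adsorption
  list(k1r = params$k1r, k2r = params$k2r, k3r = params$k3r,
       K1iG2 = params$K1iG2, K1iG = params$K1iG, K1iX = params$K1iX,
       K2iG = params$K2iG, K2m = params$K2m, K2iX = params$K2iX,
       K3iG2 = params$K3iG2, K3iG = params$K3iG, K3iX = params$K3iX,
       K4 = k4_concentrated(assay$E3, params), K4iX = params$K4iX,
       kS = params$kS, lam = lam,
       E1T = assay$E1T, E2f = assay$E2T, L0 = assay$L0, C0 = assay$C0,
       ea = ad$emax_abc[1], eb = ad$emax_abc[2], ec = ad$emax_abc[3],
       ka = ad$kp_abc[1], kb = ad$kp_abc[2], kc = ad$kp_abc[3],
       emaxL = ad$emaxL, kpL = ad$kpL,
       dynamicS = identical(assay$S_mode, "dynamic"),
       S0 = assay$C0 + assay$Xn0 + assay$L0)
}

#' Time derivatives of the five-state mass balance
#'
#' Assembles the full right-hand side at one state: evaluates the
#' cellulose conversion, the conversion-dependent Langmuir coefficients,
#' the cellulase partition, the surface-decay rate, and the four reaction
#' rates, and returns
#' `dC/dt = -r1 - r3`, `dG2/dt = 1.056 r1 - r2`,
#' `dG/dt = 1.053 r2 + 1.111 r3`, `dXn/dt = -r4`, `dX/dt = 1.136 r4`.
#'
#' This is the reference R assembly built from the exported rate-law
#' functions; the compiled integrator evaluates the identical expressions.
#'
#' @param state A [hydro_state()].
#' @param assay A [assay_config()].
#' @param params A [kinetic_params()].
#' @return Named numeric vector `(C, G2, G, Xn, X)` of derivatives in
#'   mg/(mL h).
#' @export
hydrolysis_derivatives <- function(state, assay, params) {
  s <- unclass(state)
  conv <- if (assay$C0 > 0) 100 * (assay$C0 - s[["C"]]) / assay$C0 else 0
  conv <- min(max(conv, 0), 100)
  ad <- assay$adsorption
  Emax <- langmuir_coefficient(conv, ad$emax_abc)
  Kp <- langmuir_coefficient(conv, ad$kp_abc)
  S <- if (identical(assay$S_mode, "dynamic")) s[["C"]] + s[["Xn"]] + assay$L0
       else assay$C0 + assay$Xn0 + assay$L0
  part <- cellulase_partition(assay$E1T, S, assay$L0, Emax, Kp,
                              ad$emaxL, ad$kpL)
  lam <- if (params$lambda_spec$mode == "constant") params$lambda_spec$value
         else lambda_of_lignin(assay$L0, params$lambda_spec)
  r1 <- rate_r1(state, part$E1bC, params, lam)
  r2 <- rate_r2(state, assay$E2T, params)
  r3 <- rate_r3(state, part$E1bC, params, lam)
  r4 <- rate_r4(state, k4_concentrated(assay$E3, params), params)
  c(C = -r1 - r3,
    G2 = .stoich[["c2g2"]] * r1 - r2,
    G = .stoich[["g2g"]] * r2 + .stoich[["c2g"]] * r3,
    Xn = -r4,
    X = .stoich[["xn2x"]] * r4)
}
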