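#' Surface-decay rate specifications
#'
#' The heterogeneous rates r1 and r3 are attenuated by `exp(-lambda * t)`,
#' representing the progressive loss of enzyme-accessible cellulose
#' surface. For delignified (organosolv) bagasse lambda is a constant; for
#' hydrothermal bagasse it increases with the residual lignin
#' concentration following a Hill curve, `lambda_max * L^n / (k^n + L^n)`,
#' valid up to 40 mg/mL of lignin.
#'
#' @param value Constant surface-decay rate (1/h), `>= 0`.
#' @param lambda_max Maximal decay rate (1/h), `> 0`.
#' @param n Hill exponent (dimensionless), `> 0`.
#' @param k Half-saturation lignin concentration (mg/mL), `> 0`.
#' @return An object of class `lambda_spec`.
#' @examples
#' lambda_hill(0.1817, 9.45, 18.354)
#' lambda_const(0.2004)
#' @export
lambda_hill <- function(lambda_max, n, k) {
  stopifnot(is.numeric(lambda_max), lambda_max > 0, n > 0, k > 0)
  structure(list(mode = "lignin_hill",
                 hill = list(lambda_max = lambda_max, n = n, k = k)),
            class = "lambda_spec")
}

#' @rdname lambda_hill
#' @export
lambda_const <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  structure(list(mode = "constant", value = value), class = "lambda_spec")
}

#' Evaluate the surface-decay rate at a lignin concentration
#'
#' @param L Lignin concentration (mg/mL), `>= 0`. Vectorised.
#' @param spec A [lambda_hill()] or [lambda_const()] specification.
#' @return Surface-decay rate(s) in 1/h. In Hill mode a warning (not an
#'   error) is issued when `L` exceeds the 40 mg/mL validity limit of the
#'   fitted curve.
#' @examples
#' lambda_of_lignin(18.354, lambda_hill(0.1817, 9.45, 18.354)) # lambda_max/2
#' @export
lambda_of_lignin <- function(L, spec) {
  stopifnot(inherits(spec, "lambda_spec"), is.numeric(L))
  if (any(L < 0)) stop("lignin concentration must be >= 0")
  if (spec$mode == "constant") return(rep(spec$value, length(L)))
  if (any(L > 40))
    warning("lignin concentration above 40 mg/mL: outside the validity ",
            "domain of the fitted surface-decay curve")
  h <- spec$hill
  h$lambda_max * L^h$n / (h$k^h$n + L^h$n)
}

.kinetic_names <- c("k1r", "k2r", "k3r", "K1iG2", "K1iG", "K1iX",
                    "K2iG", "K2m", "K2iX", "K3iG2", "K3iG", "K3iX",
                    "k4", "Keq", "K4iX", "kS")

#' Kinetic parameter set of the hydrolysis model
#'
#' Bundles the 16 positive rate and inhibition constants with the
#' surface-decay specification. Units follow the estimated-parameter
#' table convention: `k1r`, `k3r` in mL/(mg h); `k2r`, `k4` in 1/h;
#' every `K*` inhibition/saturation constant in mg/mL except `Keq`
#' (U/mL, xylanase adsorption saturation).
#'
#' @param k1r Rate constant, cellulose to cellobiose (mL/(mg h)).
#' @param k2r Rate constant, cellobiose to glucose (1/h).
#' @param k3r Rate constant, cellulose to glucose (mL/(mg h)).
#' @param K1iG2,K1iG,K1iX Competitive inhibition constants in r1 (mg/mL).
#' @param K2iG,K2iX Inhibition constants in r2 (mg/mL).
#' @param K2m Cellobiose saturation constant of beta-glucosidase (mg/mL).
#' @param K3iG2,K3iG,K3iX Inhibition constants in r3 (mg/mL).
#' @param k4 Maximum specific xylan hydrolysis rate (1/h).
#' @param Keq Xylanase adsorption saturation constant (U/mL).
#' @param K4iX Xylanase inhibition constant by xylose (mg/mL).
#' @param kS Xylan substrate-limitation saturation constant (mg/mL).
#' @param lambda_spec A [lambda_hill()] or [lambda_const()] object.
#' @return An object of class `hydro_params`.
#' @seealso [load_params()] for the shipped fitted parameter sets.
#' @export
kinetic_params <- function(k1r, k2r, k3r, K1iG2, K1iG, K1iX,
                           K2iG, K2m, K2iX, K3iG2, K3iG, K3iX,
                           k4, Keq, K4iX, kS, lambda_spec) {
  vals <- c(k1r = k1r, k2r = k2r, k3r = k3r, K1iG2 = K1iG2, K1iG = K1iG,
            K1iX = K1iX, K2iG = K2iG, K2m = K2m, K2iX = K2iX,
            K3iG2 = K3iG2, K3iG = K3iG, K3iX = K3iX,
            k4 = k4, Keq = Keq, K4iX = K4iX, kS = kS)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all kinetic constants must be finite and > 0; offending: ",
         paste(names(vals)[!(is.finite(vals) & vals > 0)], collapse = ", "))
  stopifnot(inherits(lambda_spec, "lambda_spec"))
  structure(c(as.list(vals), list(lambda_spec = lambda_spec)),
            class = "hydro_params")
}

#' @export
print.hydro_params <- function(x, ...) {
  cat("Hydrolysis kinetic parameters\n")
  v <- unlist(x[.kinetic_names])
  print(signif(v, 5))
  if (x$lambda_spec$mode == "constant") {
    cat("lambda: constant", x$lambda_spec$value, "1/h\n")
  } else {
    h <- x$lambda_spec$hill
    cat(sprintf("lambda: Hill in lignin (lambda_max=%g 1/h, n=%g, k=%g mg/mL)\n",
                h$lambda_max, h$n, h$k))
  }
  invisible(x)
}

#' Flatten a parameter set to the 17-element named vector
#'
#' Returns the 16 kinetic constants plus a scalar `lambda`. For a
#' Hill-mode specification a lignin concentration `L` must be supplied so
#' lambda can be evaluated (once per assay; lignin is constant over a
#' run).
#'
#' @param params A [kinetic_params()] object.
#' @param L Lignin concentration (mg/mL), required in Hill mode.
#' @return Named numeric vector of length 17.
#' @export
param_vector <- function(params, L = NULL) {
  stopifnot(inherits(params, "hydro_params"))
  v <- unlist(params[.kinetic_names])
  if (params$lambda_spec$mode == "constant") {
    lam <- params$lambda_spec$value
  } else {
    if (is.null(L))
      stop("lambda is lignin-dependent: supply L to evaluate it")
    lam <- lambda_of_lignin(L, params$lambda_spec)
  }
  c(v, lambda = unname(lam))
}

#' Replace named constants in a parameter set
#'
#' Used by the estimation and sensitivity modules to substitute candidate
#' values. A `lambda` entry replaces the surface-decay specification with
#' a constant.
#'
#' @param params A [kinetic_params()] object.
#' @param theta Named numeric vector; names among the 16 constants or
#'   `lambda`.
#' @return A new `hydro_params` object.
#' @export
set_params <- function(params, theta) {
  stopifnot(inherits(params, "hydro_params"), is.numeric(theta),
            !is.null(names(theta)))
  unknown <- setdiff(names(theta), c(.kinetic_names, "lambda"))
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  out <- params
  for (nm in intersect(names(theta), .kinetic_names)) out[[nm]] <- unname(theta[[nm]])
  if ("lambda" %in% names(theta))
    out$lambda_spec <- lambda_const(unname(theta[["lambda"]]))
  v <- unlist(out[.kinetic_names])
  if (any(!is.finite(v) | v <= 0))
    stop("substitution produced non-positive kinetic constants")
  out
}
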