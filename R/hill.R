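#' Fit the lignin-dependent surface-decay law
#'
#' Least-squares fit of the Hill curve
#' `lambda = lambda_max * L^n / (k^n + L^n)` to (lignin, lambda) pairs by
#' Levenberg-Marquardt (via [minpack.lm::nlsLM()]), started from
#' `lambda_max = max(lambda)`, `k = median(L)`, `n = 2`.
#'
#' @param L Lignin concentrations (mg/mL), `>= 0`, at least 4 points.
#' @param lambda Surface-decay rates (1/h) at those concentrations.
#' @return An object of class `hill_fit`: list with `hill` (a
#'   [lambda_hill()] spec), `r_squared`, `fitted`, `residuals`.
#' @examples
#' L <- seq(5, 40, by = 5)
#' fit_hill(L, lambda_of_lignin(L, lambda_hill(0.1817, 9.45, 18.354)))
#' @export
fit_hill <- function(L, lambda) {
  stopifnot(length(L) == length(lambda), length(L) >= 4, all(L >= 0))
  if (diff(range(lambda)) < .Machine$double.eps * max(abs(lambda), 1))
    stop("all lambda values are equal: Hill parameters non-identifiable ",
         "(degenerate, constant decay rate)")
  d <- data.frame(L = L, lam = lambda)
  fit <- minpack.lm::nlsLM(
    lam ~ lambda_max * L^n / (k^n + L^n), data = d,
    start = list(lambda_max = max(lambda), n = 2, k = median(L)),
    lower = c(1e-10, 1e-10, 1e-10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((lambda - mean(lambda))^2)
  structure(list(hill = lambda_hill(est[["lambda_max"]], est[["n"]],
                                    est[["k"]]),
                 r_squared = 1 - ss_res / ss_tot,
                 fitted = as.numeric(fitted(fit)),
                 residuals = as.numeric(resid(fit))),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  h <- x$hill$hill
  cat(sprintf("Hill surface-decay fit: lambda_max=%.5g 1/h, n=%.4g, k=%.5g mg/mL (R^2=%.4f)\n",
              h$lambda_max, h$n, h$k, x$r_squared))
  invisible(x)
}

#' @importFrom stats fitted
NULL
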