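# Shared fixtures and independent oracles used across test files.

hb_params <- load_params("HB")
ob_params <- load_params("OB")
hb_assay10 <- load_assay("HB", 10)
ob_assay10 <- load_assay("OB", 10)
hb_hill <- lambda_hill(0.1817, 9.45, 18.354)

# Independent oracle for the cellulase partition: damped fixed-point
# iteration of E1f <- E1T - Emax*Kp*E1f*S/((1+Kp*E1f)*1000), independent
# of the quadratic-root solution.
fixed_point_E1f <- function(E1T, S, Emax, Kp, alpha = 0.1, tol = 1e-13,
                            maxit = 2e5) {
  if (E1T == 0) return(0)
  A <- Emax * S / 1000
  if (Kp == 0 || A == 0) return(E1T)
  x <- E1T / 2
  for (i in seq_len(maxit)) {
    xn <- (1 - alpha) * x + alpha * max(E1T - A * Kp * x / (1 + Kp * x), 0)
    if (abs(xn - x) < tol) return(xn)
    x <- xn
  }
  stop("fixed-point iteration did not converge")
}

# Log-space oracle for the Hill curve, written independently of the
# direct formula (log-sum-exp for the denominator).
hill_logspace <- function(L, lambda_max, n, k) {
  if (L == 0) return(0)
  a <- n * log(k); b <- n * log(L); m <- max(a, b)
  exp(log(lambda_max) + b - (m + log(exp(a - m) + exp(b - m))))
}

# A trajectory-shaped object for metric tests that do not need the ODE.
fake_traj <- function(time_h, ..., assay = NULL) {
  d <- data.frame(time_h = time_h, ...)
  structure(d, class = c("hydro_traj", "data.frame"), assay = assay)
}

# Coarse integration settings used where speed matters more than the
# last digits (estimation tests).
coarse_ctrl <- list(step = 0.05, startup_step = 5e-4, startup_until = 1)

cellulolytic <- c("k1r", "k2r", "k3r", "K1iG2", "K1iG", "K1iX", "K2iG",
                  "K2m", "K2iX", "K3iG2", "K3iG", "K3iX", "lambda")
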