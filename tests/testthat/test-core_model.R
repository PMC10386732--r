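test_that("surface-decay law: limits, half-saturation, log-space oracle, domain", {
  expect_equal(lambda_of_lignin(0, hb_hill), 0)
  # L = k forces exactly lambda_max/2
  expect_equal(lambda_of_lignin(18.354, hb_hill), 0.1817 / 2)
  # direct evaluation against an independent log-space rewrite
  for (L in c(5, 12.79, 31.97, 38.36))
    expect_equal(lambda_of_lignin(L, hb_hill),
                 hill_logspace(L, 0.1817, 9.45, 18.354), tolerance = 1e-12)
  expect_equal(lambda_of_lignin(c(0, 10), lambda_const(0.2004)),
               c(0.2004, 0.2004))
  expect_warning(lambda_of_lignin(45, hb_hill), "validity")
  expect_error(lambda_of_lignin(-1, hb_hill), ">= 0")
})

test_that("conversion-dependent Langmuir coefficients", {
  expect_equal(langmuir_coefficient(0, c(0, 0, 0)), 1)
  expect_equal(langmuir_coefficient(0, c(3.607, -0.00719, -0.0000772)),
               exp(3.607))
  # term-by-term summation oracle at 50% conversion
  expect_equal(langmuir_coefficient(50, c(0.2501, 0.00134, -0.000146)),
               exp(0.2501 + 0.00134 * 50 + (-0.000146) * 2500))
  expect_true(all(langmuir_coefficient(seq(0, 100, 10),
                                       c(3.607, -0.00719, -0.0000772)) > 0))
  expect_error(langmuir_coefficient(101, c(0, 0, 0)), "\\[0, 100\\]")
  expect_error(langmuir_coefficient(-5, c(0, 0, 0)), "\\[0, 100\\]")
})

test_that("cellulase partition: trivial pools, mass balance, fixed-point oracle", {
  expect_equal(cellulase_partition(0, 95, 32, 30, 1.2),
               list(E1f = 0, E1b = 0, E1bL = 0, E1bC = 0))
  p <- cellulase_partition(1.049, 0, 0, exp(3.607), exp(0.2501))
  expect_equal(p$E1f, 1.049)
  expect_equal(p$E1b, 0)
  # closed mass balance and oracle agreement at the reference conditions
  p <- cellulase_partition(1.049, 95.17, 31.97, exp(3.607), exp(0.2501))
  expect_equal(p$E1f + p$E1b, 1.049, tolerance = 1e-10)
  expect_equal(p$E1f, fixed_point_E1f(1.049, 95.17, exp(3.607), exp(0.2501)),
               tolerance = 1e-10)
  expect_equal(p$E1bC, p$E1b) # lignin adsorption disabled by default
  # lignin-bound pool subtracts from the productive pool
  pl <- cellulase_partition(1.049, 95.17, 31.97, exp(3.607), exp(0.2501),
                            emaxL = 10, kpL = 0.5)
  expect_gt(pl$E1bL, 0)
  expect_equal(pl$E1bC, pl$E1b - pl$E1bL)
  # extreme lignin adsorption triggers the documented clip
  expect_warning(
    pc <- cellulase_partition(1.049, 10, 500, 1, 0.01, emaxL = 5000, kpL = 50),
    "clipping")
  expect_equal(pc$E1bC, 0)
})

test_that("rate laws match hand evaluation and obey their limits", {
  p <- hb_params
  # r1: zero cellulose, hand product, inhibition limit
  expect_equal(rate_r1(hydro_state(0, C = 0), 0.5, p, 0.1), 0)
  expect_equal(rate_r1(hydro_state(0, C = 61.07), 0.5, p, 0.18),
               19.178 * 0.5 * 61.07)
  r_prev <- Inf
  for (G2 in c(0, 1, 10, 100, 1e4)) {
    r <- rate_r1(hydro_state(1, C = 30, G2 = G2), 0.5, p, 0.18)
    expect_lte(r, r_prev); r_prev <- r
  }
  expect_lt(rate_r1(hydro_state(1, C = 30, G2 = 1e9), 0.5, p, 0.18), 1e-5)
  # r2: zero substrate, saturation, half-saturation identity
  expect_equal(rate_r2(hydro_state(0), 0.25, p), 0)
  expect_equal(rate_r2(hydro_state(0, G2 = 1e9), 0.2543, p),
               196.56 * 0.2543, tolerance = 1e-6)
  expect_equal(rate_r2(hydro_state(0, G2 = 22.48), 0.2543, p),
               196.56 * 0.2543 / 2)
  # r3: hand product and surface-decay limit
  expect_equal(rate_r3(hydro_state(0, C = 61.07), 0.5, p, 0.18),
               8.576 * 0.5 * 61.07)
  expect_lt(rate_r3(hydro_state(t = 500, C = 61.07), 0.5, p, 0.18), 1e-30)
  # K4 saturation in the xylanase dose
  expect_equal(k4_concentrated(0, p), 0)
  expect_equal(k4_concentrated(0.0786, p), 18.066 / 2)
  expect_equal(k4_concentrated(14.632, p), 18.066 * 14.632 / 14.7106)
  expect_lt(abs(k4_concentrated(1e9, p) - 18.066), 1e-6)
  # r4: zero substrate, unlimited/uninhibited limit, hand evaluation
  expect_equal(rate_r4(hydro_state(0), 10, p), 0)
  expect_equal(rate_r4(hydro_state(0, Xn = 1000), 10, p), 10 * 1000,
               tolerance = 1e-4)
  expect_equal(rate_r4(hydro_state(0, Xn = 2.1, X = 1), 17.97, p),
               17.97 * 2.1 / (1 + 1 / 0.0111) * 2.1 / (0.0354 + 2.1))
  # monotone in the inhibitor
  expect_gt(rate_r4(hydro_state(0, Xn = 2, X = 0.1), 17.97, p),
            rate_r4(hydro_state(0, Xn = 2, X = 1), 17.97, p))
})

test_that("assembled derivatives: trivial cases and stoichiometric coupling", {
  a <- hb_assay10; p <- hb_params
  expect_equal(unname(hydrolysis_derivatives(hydro_state(0), a, p)),
               rep(0, 5))
  a0 <- assay_config("HB", 10, C0 = 61.07, L0 = 31.97, Xn0 = 2.1,
                     E1T = 0, E2T = 0, E3 = 0, adsorption = a$adsorption)
  expect_equal(unname(hydrolysis_derivatives(
    hydro_state(5, C = 30, G2 = 2, G = 10, Xn = 1, X = 0.5), a0, p)),
    rep(0, 5))
  # single-reaction xylan stoichiometry: dXn/dt + dX/dt / 1.136 = 0 exactly
  set.seed(1)
  for (i in 1:20) {
    st <- hydro_state(runif(1, 0, 72), runif(1, 0, 61), runif(1, 0, 5),
                      runif(1, 0, 40), runif(1, 0, 2.1), runif(1, 0, 2.4))
    d <- hydrolysis_derivatives(st, a, p)
    expect_identical(d[["Xn"]] + d[["X"]] / 1.136, 0)
  }
})

test_that("compiled right-hand side agrees with the R assembly", {
  set.seed(7)
  for (cfg in list(list(a = hb_assay10, p = hb_params),
                   list(a = ob_assay10, p = ob_params))) {
    ml <- hydrolysim:::.model_list(cfg$a, cfg$p)
    for (i in 1:25) {
      t <- runif(1, 0, 72)
      y <- c(runif(1, 0, cfg$a$C0), runif(1, 0, 6), runif(1, 0, 45),
             runif(1, 0, cfg$a$Xn0), runif(1, 0, 5))
      dR <- hydrolysis_derivatives(
        hydro_state(t, y[1], y[2], y[3], y[4], y[5]), cfg$a, cfg$p)
      dC <- hydrolysim:::.rhs_cpp(t, y, ml)
      expect_equal(unname(dR), as.numeric(dC), tolerance = 1e-12)
    }
  }
})

test_that("parameter-set plumbing: validation, flattening, substitution", {
  expect_error(kinetic_params(k1r = -1, k2r = 1, k3r = 1, K1iG2 = 1,
                              K1iG = 1, K1iX = 1, K2iG = 1, K2m = 1,
                              K2iX = 1, K3iG2 = 1, K3iG = 1, K3iX = 1,
                              k4 = 1, Keq = 1, K4iX = 1, kS = 1,
                              lambda_spec = lambda_const(0.1)), "k1r")
  v <- param_vector(hb_params, L = 31.97)
  expect_length(v, 17)
  expect_equal(v[["lambda"]], lambda_of_lignin(31.97, hb_hill))
  expect_error(param_vector(hb_params), "supply L")
  expect_equal(param_vector(ob_params)[["lambda"]], 0.2004)
  p2 <- set_params(hb_params, c(k3r = 9, lambda = 0.15))
  expect_equal(p2$k3r, 9)
  expect_equal(p2$lambda_spec$value, 0.15)
  expect_error(set_params(hb_params, c(bogus = 1)), "bogus")
})
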