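test_that("objective is zero at the generating parameters and matches its closed form", {
  a <- hb_assay10
  lam0 <- lambda_of_lignin(a$L0, hb_hill)
  truth <- set_params(hb_params, c(lambda = lam0))
  prof <- generate_profiles(a, truth, noise_model(0, 0))
  spec <- objective_spec(list(list(assay = a, profile = prof)), hb_params,
                         free = c("k3r", "lambda"))
  th <- c(k3r = hb_params$k3r, lambda = lam0)
  expect_lt(hydrolysis_objective(th, spec), 1e-16)

  # single-point, single-species profile: score is ((sim - exp)/max_exp)^2
  tr <- simulate_assay(a, truth, t_end = 24, report_times = 24)
  simC <- tr$C[tr$time_h == 24]
  prof1 <- data.frame(time_h = 24, C = 55)
  spec1 <- objective_spec(list(list(assay = a, profile = prof1)), truth,
                          free = "k3r")
  expect_equal(hydrolysis_objective(c(k3r = truth$k3r), spec1),
               ((simC - 55) / 55)^2, tolerance = 1e-10)

  # doubling the residuals quadruples the score (weights pinned by the
  # untouched early-time maximum of the cellulose profile)
  tr2 <- simulate_assay(a, truth, t_end = 24, report_times = c(0.5, 24))
  simC2 <- tr2$C[match(c(0.5, 24), tr2$time_h)]
  mk <- function(d) {
    pr <- data.frame(time_h = c(0.5, 24), C = simC2 - c(0, d))
    objective_spec(list(list(assay = a, profile = pr)), truth, free = "k3r")
  }
  th1 <- c(k3r = truth$k3r)
  s1 <- hydrolysis_objective(th1, mk(1))
  s2 <- hydrolysis_objective(th1, mk(2))
  expect_equal(s2 / s1, 4, tolerance = 1e-9)
})

test_that("objective is invariant to profile and time-point ordering", {
  a <- hb_assay10
  prof <- generate_profiles(a, ob_params, noise_model(0, 0),
                            schedule = c(3, 6, 12, 24, 72))
  a2 <- load_assay("HB", 6)
  prof2 <- generate_profiles(a2, ob_params, noise_model(0, 0),
                             schedule = c(3, 6, 12, 24, 72))
  th <- c(k3r = hb_params$k3r)
  mk <- function(ds) objective_spec(ds, hb_params, free = "k3r",
                                    sim_control = coarse_ctrl)
  s12 <- hydrolysis_objective(th, mk(list(list(assay = a, profile = prof),
                                          list(assay = a2, profile = prof2))))
  s21 <- hydrolysis_objective(th, mk(list(list(assay = a2, profile = prof2),
                                          list(assay = a, profile = prof))))
  expect_equal(s12, s21)
  rev_prof <- prof[nrow(prof):1, ]
  srev <- hydrolysis_objective(th, mk(list(list(assay = a,
                                                profile = rev_prof),
                                           list(assay = a2,
                                                profile = prof2))))
  expect_equal(s12, srev)
})

test_that("candidates outside feasibility are penalised, not fatal", {
  a <- hb_assay10
  prof <- data.frame(time_h = c(6, 24), C = c(40, 30))
  spec <- objective_spec(list(list(assay = a, profile = prof)), hb_params,
                         free = "k3r", sim_control = coarse_ctrl)
  # a candidate that breaks parameter validation scores +Inf
  expect_identical(hydrolysis_objective(c(k3r = -1), spec), Inf)
})

test_that("GA engine: seeded reproducibility, elitist monotonicity, nested bounds", {
  sphere <- function(x) sum((x - 0.3)^2)
  lo <- setNames(rep(0, 3), c("a", "b", "c"))
  hi <- setNames(rep(1, 3), c("a", "b", "c"))
  cfg <- ga_config(pop_size = 40, generations = 60, seed = 5)
  r1 <- ga_optimize(sphere, lo, hi, cfg)
  r2 <- ga_optimize(sphere, lo, hi, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$history) <= 0))
  expect_lt(r1$value, 1e-3)
  # widening bounds around an interior optimum cannot systematically
  # worsen the seeded best-of-history (checked over 5 seeds; the slack
  # is a small fraction of the widened search scale)
  deltas <- vapply(1:5, function(s) {
    cfg_s <- ga_config(pop_size = 40, generations = 60, seed = s)
    narrow <- ga_optimize(sphere, lo, hi, cfg_s)$value
    wide <- ga_optimize(sphere, lo - 2, hi + 2, cfg_s)$value
    wide - narrow
  }, numeric(1))
  expect_lt(mean(deltas), 0.02)
})

test_that("GA fit is reproducible and improves on the starting population", {
  a <- hb_assay10
  lam0 <- lambda_of_lignin(a$L0, hb_hill)
  truth <- set_params(hb_params, c(lambda = lam0))
  prof <- generate_profiles(a, truth, noise_model(0, 0),
                            schedule = c(3, 12, 48, 72))
  tv <- c(k3r = hb_params$k3r, K3iG = hb_params$K3iG)
  spec <- objective_spec(list(list(assay = a, profile = prof)), truth,
                         free = c("k3r", "K3iG"),
                         lower = 0.5 * tv, upper = 1.5 * tv,
                         sim_control = coarse_ctrl)
  cfg <- ga_config(pop_size = 14, generations = 6, seed = 99)
  f1 <- fit_ga(spec, cfg)
  f2 <- fit_ga(spec, cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$value, f2$value)
  expect_true(all(diff(f1$history) <= 0))
  expect_s3_class(predict(f1, a, t_end = 24), "hydro_traj")
  expect_length(residuals(f1), 1)
})

test_that("per-assay surface-decay estimation keeps one lambda per profile", {
  a4 <- load_assay("HB", 4); a10 <- hb_assay10
  mkprof <- function(a) {
    lam <- lambda_of_lignin(a$L0, hb_hill)
    generate_profiles(a, set_params(hb_params, c(lambda = lam)),
                      noise_model(0, 0), schedule = c(6, 24, 72),
                      sim_control = coarse_ctrl)
  }
  spec <- objective_spec(list(list(assay = a4, profile = mkprof(a4)),
                              list(assay = a10, profile = mkprof(a10))),
                         hb_params, free = c("k3r", "lambda"),
                         lambda_mode = "per_assay",
                         sim_control = coarse_ctrl)
  expect_setequal(spec$free, c("k3r", "lambda.1", "lambda.2"))
  th <- c(k3r = hb_params$k3r,
          lambda.1 = lambda_of_lignin(a4$L0, hb_hill),
          lambda.2 = lambda_of_lignin(a10$L0, hb_hill))
  expect_lt(hydrolysis_objective(th, spec), 1e-16)
})

test_that("Hill-law fit recovers exact curves and flags degeneracy", {
  L <- seq(5, 40, by = 5)
  lam <- lambda_of_lignin(L, hb_hill)
  f <- fit_hill(L, lam)
  expect_equal(f$hill$hill$lambda_max, 0.1817, tolerance = 1e-4)
  expect_equal(f$hill$hill$n, 9.45, tolerance = 1e-3)
  expect_equal(f$hill$hill$k, 18.354, tolerance = 1e-3)
  expect_gt(f$r_squared, 0.999)
  expect_error(fit_hill(L, rep(0.2, 8)), "non-identifiable")
  expect_error(fit_hill(1:3, c(0.1, 0.2, 0.3)), "length")
})

test_that("Hill-law fit is robust to 1% measurement noise", {
  L <- seq(5, 40, by = 5)
  lam <- lambda_of_lignin(L, hb_hill)
  set.seed(31)
  est <- replicate(50, {
    f <- try(fit_hill(L, lam * (1 + rnorm(length(L), 0, 0.01))),
             silent = TRUE)
    if (inherits(f, "try-error")) NA_real_ else f$hill$hill$lambda_max
  })
  expect_lt(abs(median(est, na.rm = TRUE) - 0.1817) / 0.1817, 0.05)
})

test_that("held-out assay is predicted as well as the training assays", {
  mk <- function(l) {
    a <- load_assay("OB", l)
    list(assay = a, profile = generate_profiles(a, ob_params,
                                                noise_model(0, 0)))
  }
  train <- lapply(c(4, 6, 8, 12), mk)
  tv <- c(k3r = ob_params$k3r, K3iG = ob_params$K3iG)
  spec <- objective_spec(train, ob_params, free = c("k3r", "K3iG"),
                         lower = 0.5 * tv, upper = 1.5 * tv,
                         sim_control = coarse_ctrl)
  fit <- fit_ga(spec, ga_config(pop_size = 30, generations = 30, seed = 11))
  va <- ob_assay10
  vp <- generate_profiles(va, ob_params, noise_model(0, 0))
  tr <- predict(fit, va, t_end = 72, report_times = vp$time_h)
  for (s in c("C", "G2", "G", "X"))
    expect_lt(rsd(tr, vp, s), 5)
})
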