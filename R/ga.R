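#' Genetic-algorithm settings
#'
#' Defaults follow the classic settings of the Pikaia optimiser:
#' population 100, 500 generations, crossover probability 0.85, adaptive
#' mutation rate in `[5e-4, 0.25]`, generational replacement with one
#' elite.
#'
#' @param pop_size Population size, `>= 2`.
#' @param generations Number of generations, `>= 1`.
#' @param p_cross One-point crossover probability.
#' @param mutation `"adaptive"` adjusts the per-gene mutation rate from
#'   the fitness spread between the best and the median individual;
#'   `"constant"` keeps `p_mut` fixed.
#' @param p_mut Initial per-gene mutation rate.
#' @param p_mut_range Bounds of the adaptive mutation rate.
#' @param elitism Keep the best-ever individual in the population.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, generations = 500, p_cross = 0.85,
                      mutation = c("adaptive", "constant"), p_mut = 0.005,
                      p_mut_range = c(5e-4, 0.25), elitism = TRUE,
                      seed = NULL) {
  mutation <- match.arg(mutation)
  stopifnot(pop_size >= 2, generations >= 1,
            p_cross >= 0, p_cross <= 1, p_mut >= 0, p_mut <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_cross = p_cross, mutation = mutation, p_mut = p_mut,
                 p_mut_range = p_mut_range, elitism = elitism, seed = seed),
            class = "ga_config")
}

# Run `expr` under a locally seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Minimise a function with a Pikaia-style real-coded genetic algorithm
#'
#' Real-coded GA on the unit hypercube (candidates are decoded linearly
#' into `[lower, upper]`): rank-proportional selection, one-point
#' crossover, creep plus jump mutation with an optionally adaptive rate,
#' and generational replacement with one elite. Deterministic given
#' `config$seed`.
#'
#' @param fn Objective to minimise; receives a named numeric vector.
#' @param lower,upper Named finite bounds, `lower < upper`.
#' @param config A [ga_config()].
#' @return List with `par` (best-ever candidate), `value`, `history`
#'   (best-ever score per generation; non-increasing when elitism is on)
#'   and `seed`.
#' @export
ga_optimize <- function(fn, lower, upper, config = ga_config()) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower < upper))
  n <- length(lower)
  nm <- names(lower)
  decode <- function(x) setNames(lower + x * (upper - lower), nm)
  .with_seed(config$seed, {
    np <- config$pop_size
    pop <- matrix(runif(np * n), nrow = np)
    score <- apply(pop, 1, function(x) fn(decode(x)))
    if (all(!is.finite(score)))
      stop("all candidates infeasible in the initial generation")
    pm <- config$p_mut
    best_x <- pop[which.min(score), ]
    best_v <- min(score)
    history <- numeric(config$generations)
    # rank-proportional selection weights (best rank gets largest)
    sel_w <- (2 * (np:1)) / (np * (np + 1))
    for (g in seq_len(config$generations)) {
      ord <- order(score)
      prob <- numeric(np); prob[ord] <- sel_w
      parents <- sample.int(np, 2 * np, replace = TRUE, prob = prob)
      children <- matrix(0, np, n)
      for (i in seq_len(np)) {
        p1 <- pop[parents[2 * i - 1], ]
        p2 <- pop[parents[2 * i], ]
        if (runif(1) < config$p_cross && n > 1) {
          cut <- sample.int(n - 1, 1)
          child <- c(p1[seq_len(cut)], p2[(cut + 1):n])
        } else child <- p1
        mut <- runif(n) < pm
        if (any(mut)) {
          jump <- runif(n) < 0.5
          child[mut & jump] <- runif(sum(mut & jump))
          creep <- mut & !jump
          child[creep] <- child[creep] + rnorm(sum(creep), sd = 0.1)
          child <- pmin(pmax(child, 0), 1)
        }
        children[i, ] <- child
      }
      cscore <- apply(children, 1, function(x) fn(decode(x)))
      pop <- children; score <- cscore
      if (config$elitism) {
        worst <- which.max(score)
        if (min(score) > best_v) {
          pop[worst, ] <- best_x
          score[worst] <- best_v
        }
      }
      if (min(score) < best_v) {
        best_v <- min(score)
        best_x <- pop[which.min(score), ]
      }
      if (config$mutation == "adaptive") {
        fin <- score[is.finite(score)]
        if (length(fin) >= 2) {
          spread <- abs(median(fin) - min(fin)) /
            max(abs(median(fin)) + abs(min(fin)), .Machine$double.eps)
          pm <- if (spread < 0.05) min(pm * 1.5, config$p_mut_range[2])
                else if (spread > 0.25) max(pm / 1.5, config$p_mut_range[1])
                else pm
        }
      }
      history[g] <- best_v
    }
    list(par = decode(best_x), value = best_v, history = history,
         seed = config$seed)
  })
}

#' Fit the kinetic model by genetic-algorithm minimisation
#'
#' Minimises [hydrolysis_objective()] over the free parameters of an
#' [objective_spec()] and returns a fitted-model object.
#'
#' @param spec An [objective_spec()].
#' @param ga A [ga_config()].
#' @return An object of class `hydro_fit` with components `params` (the
#'   best parameter set, per-assay lambdas resolved for the first
#'   profile), `theta` (named best candidate), `value`, `history`,
#'   `spec`, `ga`. Supported methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot`, `simulate`.
#' @export
fit_ga <- function(spec, ga = ga_config()) {
  stopifnot(inherits(spec, "objective_spec"), inherits(ga, "ga_config"))
  res <- ga_optimize(function(th) hydrolysis_objective(th, spec),
                     spec$lower, spec$upper, ga)
  structure(list(params = .theta_params(res$par, spec, 1L),
                 theta = res$par, value = res$value,
                 history = res$history, spec = spec, ga = ga,
                 seed = ga$seed),
            class = "hydro_fit")
}

#' @export
print.hydro_fit <- function(x, ...) {
  cat("Genetic-algorithm fit of the hydrolysis kinetic model\n")
  cat(sprintf("  %d profile(s); %d free parameter(s); objective = %.6g\n",
              length(x$spec$dataset), length(x$theta), x$value))
  cat("  best candidate:\n")
  print(signif(x$theta, 5))
  invisible(x)
}

#' @export
summary.hydro_fit <- function(object, ...) {
  rsds <- lapply(seq_along(object$spec$dataset), function(j) {
    d <- object$spec$dataset[[j]]
    pj <- .theta_params(object$theta, object$spec, j)
    tr <- simulate_assay(d$assay, pj, t_end = max(d$profile$time_h),
                         report_times = d$profile$time_h)
    sp <- intersect(c("C", "G2", "G", "X"), names(d$profile))
    vapply(sp, function(s)
      tryCatch(rsd(tr, as_profile(d$profile), s), error = function(e) NA_real_),
      numeric(1))
  })
  out <- list(fit = object, rsd = rsds)
  class(out) <- "summary.hydro_fit"
  out
}

#' @export
print.summary.hydro_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-profile RSD (%):\n")
  for (j in seq_along(x$rsd)) {
    a <- x$fit$spec$dataset[[j]]$assay
    cat(sprintf("   %s %g%%: %s\n", a$pretreatment, a$loading_pct,
                paste(sprintf("%s=%.2f", names(x$rsd[[j]]), x$rsd[[j]]),
                      collapse = " ")))
  }
  invisible(x)
}

#' @export
coef.hydro_fit <- function(object, ...) object$theta

#' @export
predict.hydro_fit <- function(object, assay = NULL, t_end = 72,
                              report_times = sampling_schedule(t_end), ...) {
  if (is.null(assay)) assay <- object$spec$dataset[[1]]$assay
  simulate_assay(assay, object$params, t_end = t_end,
                 report_times = report_times)
}

#' @export
residuals.hydro_fit <- function(object, ...) {
  lapply(seq_along(object$spec$dataset), function(j) {
    d <- object$spec$dataset[[j]]
    pj <- .theta_params(object$theta, object$spec, j)
    tr <- simulate_assay(d$assay, pj, t_end = max(d$profile$time_h),
                         report_times = d$profile$time_h)
    m <- match(round(d$profile$time_h, 8), round(tr$time_h, 8))
    sp <- intersect(c("C", "G2", "G", "X"), names(d$profile))
    res <- data.frame(time_h = d$profile$time_h)
    for (s in sp) res[[s]] <- tr[[s]][m] - d$profile[[s]]
    res
  })
}

#' @export
plot.hydro_fit <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "s", log = "y",
                 xlab = "generation", ylab = "best objective",
                 main = "GA convergence", ...)
  invisible(x)
}

#' @export
simulate.hydro_fit <- function(object, nsim = 1, seed = NULL, rel = 0.05,
                               ...) {
  d1 <- object$spec$dataset[[1]]
  lapply(seq_len(nsim), function(i) {
    nm <- noise_model(rel = rel,
                      seed = if (!is.null(seed)) seed + i - 1L else NULL)
    generate_profiles(d1$assay, object$params, noise = nm,
                      schedule = d1$profile$time_h)
  })
}
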