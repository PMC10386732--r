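#' Specify the least-squares estimation problem
#'
#' Bundles a dataset of (assay, profile) pairs with the free-parameter
#' list and search bounds. The objective simulates every assay and sums,
#' over profiles and sampling times, the squared residuals of C, G2, G
#' and X, each normalised by that profile's maximum measured value of the
#' species (so all species contribute on a comparable scale); species
#' absent from a profile contribute nothing.
#'
#' @param dataset List of `list(assay =, profile =)` pairs.
#' @param base_params A [kinetic_params()] supplying every constant not
#'   being estimated.
#' @param free Character vector of free parameter names (among the 16
#'   kinetic constants and `"lambda"`).
#' @param lower,upper Named bounds for the free parameters (finite,
#'   `lower < upper`). Defaults are 0.1x and 10x the base value.
#' @param lambda_mode `"shared"` estimates a single `lambda` for every
#'   profile; `"per_assay"` gives each profile its own free `lambda`
#'   (names `lambda.1`, `lambda.2`, ... appended to the free vector) —
#'   the two-stage construction used to build the lignin law for
#'   hydrothermal bagasse.
#' @param sim_control List of [simulate_assay()] settings used inside the
#'   objective (`step`, `startup_step`, `startup_until`).
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(dataset, base_params, free,
                           lower = NULL, upper = NULL,
                           lambda_mode = c("shared", "per_assay"),
                           sim_control = list()) {
  lambda_mode <- match.arg(lambda_mode)
  stopifnot(length(dataset) >= 1, inherits(base_params, "hydro_params"))
  for (d in dataset)
    stopifnot(inherits(d$assay, "hydro_assay"), is.data.frame(d$profile))
  ok <- c(.kinetic_names, "lambda")
  if (!all(free %in% ok))
    stop("free parameters must be among: ", paste(ok, collapse = ", "))
  if (lambda_mode == "per_assay") {
    free <- setdiff(free, "lambda")
    free <- c(free, paste0("lambda.", seq_along(dataset)))
  }
  base_of <- function(nm) {
    if (startsWith(nm, "lambda")) {
      if (base_params$lambda_spec$mode == "constant")
        base_params$lambda_spec$value
      else lambda_of_lignin(dataset[[1]]$assay$L0, base_params$lambda_spec)
    } else base_params[[nm]]
  }
  bv <- vapply(free, base_of, numeric(1))
  if (is.null(lower)) lower <- 0.1 * bv else lower <- lower[free]
  if (is.null(upper)) upper <- 10 * bv else upper <- upper[free]
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  ctrl <- modifyList(list(step = 0.01, startup_step = 1e-4, startup_until = 1),
                     sim_control)
  structure(list(dataset = dataset, base_params = base_params, free = free,
                 lower = setNames(as.numeric(lower), free),
                 upper = setNames(as.numeric(upper), free),
                 lambda_mode = lambda_mode, sim_control = ctrl),
            class = "objective_spec")
}

# Parameter set for profile j given a candidate theta.
.theta_params <- function(theta, spec, j) {
  nm <- names(theta)
  sub <- theta[!startsWith(nm, "lambda")]
  p <- if (length(sub)) set_params(spec$base_params, sub) else spec$base_params
  if (spec$lambda_mode == "per_assay") {
    p$lambda_spec <- lambda_const(unname(theta[[paste0("lambda.", j)]]))
  } else if ("lambda" %in% nm) {
    p$lambda_spec <- lambda_const(unname(theta[["lambda"]]))
  }
  p
}

#' Evaluate the estimation objective
#'
#' @param theta Named candidate vector over `spec$free`, within bounds.
#' @param spec An [objective_spec()].
#' @return Non-negative score; `Inf` (with a message) if a simulation
#'   fails for the candidate.
#' @export
hydrolysis_objective <- function(theta, spec) {
  stopifnot(inherits(spec, "objective_spec"))
  if (is.null(names(theta))) names(theta) <- spec$free
  score <- 0
  ctrl <- spec$sim_control
  for (j in seq_along(spec$dataset)) {
    d <- spec$dataset[[j]]
    pj <- tryCatch(.theta_params(theta, spec, j), error = function(e) NULL)
    if (is.null(pj)) return(Inf)
    tr <- tryCatch(
      simulate_assay(d$assay, pj, t_end = max(d$profile$time_h),
                     report_times = d$profile$time_h,
                     step = ctrl$step, startup_step = ctrl$startup_step,
                     startup_until = ctrl$startup_until),
      error = function(e) {
        message("simulation failed for candidate: ", conditionMessage(e))
        NULL
      })
    if (is.null(tr)) return(Inf)
    maxima <- attr(as_profile(d$profile), "maxima")
    m <- match(round(d$profile$time_h, 8), round(tr$time_h, 8))
    for (s in intersect(c("C", "G2", "G", "X"), names(d$profile))) {
      ye <- d$profile[[s]]
      keep <- !is.na(ye)
      if (!any(keep) || !s %in% names(maxima) || maxima[[s]] <= 0) next
      score <- score + sum(((tr[[s]][m[keep]] - ye[keep]) / maxima[[s]])^2)
    }
  }
  score
}
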