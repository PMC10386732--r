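# First rows of the standard cyclic Plackett-Burman generators.
.pb_generators <- list(
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1))

.pb_matrix <- function(runs) {
  g <- .pb_generators[[as.character(runs)]]
  if (is.null(g))
    stop("unsupported run size ", runs, "; supported: ",
         paste(names(.pb_generators), collapse = ", "))
  k <- runs - 1
  rows <- t(vapply(0:(k - 1),
                   function(s) g[((seq_len(k) - 1 - s) %% k) + 1],
                   numeric(k)))
  rbind(rows, rep(-1, k))
}

# Contrast effect of one +/-1 column on a runs x times response matrix:
# (sum of responses at +1 - sum at -1) / (runs/2).
.pb_contrast <- function(levels, y) {
  y <- as.matrix(y)
  half <- length(levels) / 2
  colSums(y[levels == 1, , drop = FALSE]) / half -
    colSums(y[levels == -1, , drop = FALSE]) / half
}

#' Two-level Plackett-Burman screening design over the kinetic parameters
#'
#' Builds the standard cyclic Plackett-Burman design with the smallest
#' supported run count exceeding the factor count, assigns one column per
#' parameter and leaves the remaining columns as dummies (their apparent
#' effects estimate the noise floor). Levels map to
#' `nominal * (1 +/- rel_width)`.
#'
#' For the 17 kinetic parameters this is the 20-run design with 19
#' columns and 2 dummies. The nominal values are the flattened parameter
#' vector; a Hill-mode lambda requires `lignin` so the nominal scalar
#' lambda can be evaluated (lignin is constant over a run).
#'
#' @param params A [kinetic_params()] set of nominal values.
#' @param rel_width Relative half-width of the levels (default 0.10).
#' @param lignin Lignin concentration (mg/mL) used to evaluate lambda in
#'   Hill mode.
#' @return An object of class `pb_design`: list with the `runs x factors`
#'   `matrix` of +/-1 levels (columns named by parameter, dummies
#'   `dummy1`, ...), `nominal`, `rel_width`, `dummy` (dummy column
#'   indices) and `base_params`.
#' @export
pb_design <- function(params, rel_width = 0.10, lignin = NULL) {
  stopifnot(inherits(params, "hydro_params"),
            rel_width >= 0, rel_width < 1)
  nominal <- param_vector(params, L = lignin)
  nf <- length(nominal)
  sizes <- as.integer(names(.pb_generators))
  runs <- sizes[sizes > nf][1]
  if (is.na(runs))
    stop("too many factors (", nf, "); supported run sizes: ",
         paste(sizes, collapse = ", "))
  M <- .pb_matrix(runs)
  nd <- ncol(M) - nf
  colnames(M) <- c(names(nominal),
                   if (nd > 0) paste0("dummy", seq_len(nd)))
  structure(list(matrix = M, nominal = nominal, rel_width = rel_width,
                 dummy = if (nd > 0) nf + seq_len(nd) else integer(0),
                 base_params = set_params(params,
                                          c(lambda = unname(nominal[["lambda"]])))),
            class = "pb_design")
}

#' @export
print.pb_design <- function(x, ...) {
  cat(sprintf("Plackett-Burman design: %d runs, %d factors, %d dummy column(s), level width %.0f%%\n",
              nrow(x$matrix), length(x$nominal), length(x$dummy),
              100 * x$rel_width))
  invisible(x)
}

#' Time-resolved Plackett-Burman contrast effects
#'
#' Simulates every design run (each row substitutes all 17 parameters at
#' `nominal * (1 +/- rel_width)`) and computes, per response species and
#' sampling time, the contrast effect of each factor:
#' `(sum of responses at +1 - sum at -1) / (runs/2)`. Dummy-column
#' contrasts are pooled into a pseudo standard error
#' `sqrt(mean(dummy effects^2))` per species and time.
#'
#' @param design A [pb_design()].
#' @param assay A [assay_config()] giving the reference batch conditions.
#' @param report_times Sampling times (h) at which effects are evaluated.
#' @param t_end Horizon (h).
#' @param sim_control Optional list overriding `step`, `startup_step`,
#'   `startup_until` of [simulate_assay()].
#' @return A data frame of class `pb_effects` with columns `species`,
#'   `time_h`, `factor`, `effect` (mg/mL), `pseudo_se`; the per-species
#'   peak response magnitude is attached as the `peak_response`
#'   attribute. Use [classify_effects()] to add influence classes.
#' @export
pb_effects <- function(design, assay, report_times = sampling_schedule(t_end),
                       t_end = 72, sim_control = list()) {
  stopifnot(inherits(design, "pb_design"), inherits(assay, "hydro_assay"))
  ctrl <- modifyList(list(step = 0.01, startup_step = 1e-4,
                          startup_until = 1), sim_control)
  M <- design$matrix
  runs <- nrow(M)
  species <- c("C", "G2", "G", "Xn", "X")
  nt <- length(report_times)
  resp <- array(NA_real_, dim = c(runs, nt, length(species)),
                dimnames = list(NULL, NULL, species))
  fac <- names(design$nominal)
  for (r in seq_len(runs)) {
    theta <- design$nominal * (1 + design$rel_width * M[r, fac])
    pr <- set_params(design$base_params, theta)
    tr <- tryCatch(
      simulate_assay(assay, pr, t_end = t_end, report_times = report_times,
                     step = ctrl$step, startup_step = ctrl$startup_step,
                     startup_until = ctrl$startup_until),
      error = function(e)
        stop("simulation failed for design run ", r, ": ",
             conditionMessage(e)))
    m <- match(round(report_times, 8), round(tr$time_h, 8))
    for (s in species) resp[r, , s] <- tr[[s]][m]
  }
  eff_of <- function(col, s) .pb_contrast(M[, col], resp[, , s])
  out <- do.call(rbind, lapply(species, function(s) {
    dummy_eff <- if (length(design$dummy))
      sapply(design$dummy, function(ci) eff_of(colnames(M)[ci], s))
    else matrix(0, nt, 1)
    pse <- sqrt(rowMeans(as.matrix(dummy_eff)^2))
    do.call(rbind, lapply(colnames(M), function(f) {
      data.frame(species = s, time_h = report_times, factor = f,
                 effect = as.numeric(eff_of(f, s)), pseudo_se = pse)
    }))
  }))
  peak <- vapply(species,
                 function(s) max(abs(colMeans(resp[, , s, drop = FALSE][, , 1]))),
                 numeric(1))
  structure(out, class = c("pb_effects", "data.frame"),
            peak_response = peak, rel_width = design$rel_width)
}

#' Classify factors by influence per response species
#'
#' Magnitude-based classification mirroring the black/grey/white coding
#' of screening summaries: per species, a factor whose peak absolute
#' effect over time is at least `great_frac` of the peak response
#' magnitude is classed `"great"`, at least `low_frac` is `"low"`, else
#' `"negligible"`.
#'
#' @param effects A [pb_effects()] table.
#' @param great_frac,low_frac Classification thresholds (fractions of the
#'   peak response magnitude), `0 < low_frac < great_frac`.
#' @return The effects table with an added `class` column (constant
#'   within species x factor).
#' @export
classify_effects <- function(effects, great_frac = 0.05, low_frac = 0.01) {
  stopifnot(inherits(effects, "pb_effects"),
            low_frac > 0, great_frac > low_frac)
  peak <- attr(effects, "peak_response")
  eff <- as.data.frame(effects)
  key <- interaction(eff$species, eff$factor, drop = TRUE)
  pk <- tapply(abs(eff$effect), key, max)
  rel <- pk[key] / pmax(peak[eff$species], .Machine$double.eps)
  eff$class <- ifelse(rel >= great_frac, "great",
                      ifelse(rel >= low_frac, "low", "negligible"))
  structure(eff, class = c("pb_effects", "data.frame"),
            peak_response = peak, rel_width = attr(effects, "rel_width"))
}

#' Peak influence summary of a classified effects table
#'
#' @param effects A classified [pb_effects()] table.
#' @return Data frame `species`, `factor`, `peak_effect`, `class`.
#' @export
influence_table <- function(effects) {
  eff <- as.data.frame(effects)
  if (is.null(eff$class)) stop("run classify_effects() first")
  agg <- stats::aggregate(abs(eff$effect),
                          by = list(species = eff$species, factor = eff$factor),
                          FUN = max)
  names(agg)[3] <- "peak_effect"
  cls <- unique(eff[c("species", "factor", "class")])
  merge(agg, cls, by = c("species", "factor"))
}
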