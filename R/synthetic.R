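#' Proportional measurement-noise model
#'
#' Observations are perturbed with independent zero-mean Gaussian noise
#' of standard deviation `max(rel * value, floor)` and truncated at zero.
#' Batch sampling in duplicate justifies a small proportional noise; the
#' default is 5%.
#'
#' @param rel Relative standard deviation (fraction), `>= 0`.
#' @param floor Absolute standard-deviation floor (mg/mL), `>= 0`.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(rel = 0.05, floor = 0, seed = NULL) {
  stopifnot(rel >= 0, floor >= 0)
  structure(list(rel = rel, floor = floor, seed = seed),
            class = "noise_model")
}

#' Generate a pseudo-experimental concentration profile
#'
#' Simulates the assay, samples the requested species at the sampling
#' schedule, and perturbs each observation under the noise model. With
#' `rel = 0` and `floor = 0` the simulated values are returned exactly.
#'
#' @param assay A [assay_config()].
#' @param params A [kinetic_params()].
#' @param noise A [noise_model()].
#' @param schedule Sampling times (h).
#' @param species Which species are "measured" (default the four
#'   HPLC-observable ones: C, G2, G, X).
#' @param sim_control Optional list overriding the integration settings.
#' @return A `hydro_profile` data frame (see [read_profile()]); the
#'   per-species maxima attribute holds the objective weights.
#' @examples
#' \donttest{
#' pr <- generate_profiles(load_assay("HB", 10), load_params("HB"),
#'                         noise_model(0.05, seed = 7))
#' }
#' @export
generate_profiles <- function(assay, params, noise = noise_model(),
                              schedule = sampling_schedule(),
                              species = c("C", "G2", "G", "X"),
                              sim_control = list()) {
  stopifnot(inherits(noise, "noise_model"))
  species <- match.arg(species, c("C", "G2", "G", "Xn", "X"),
                       several.ok = TRUE)
  ctrl <- modifyList(list(step = 0.01, startup_step = 1e-4,
                          startup_until = 1), sim_control)
  tr <- simulate_assay(assay, params, t_end = max(schedule),
                       report_times = schedule, step = ctrl$step,
                       startup_step = ctrl$startup_step,
                       startup_until = ctrl$startup_until)
  m <- match(round(schedule, 8), round(tr$time_h, 8))
  out <- data.frame(time_h = schedule)
  vals <- lapply(species, function(s) tr[[s]][m])
  names(vals) <- species
  noisy <- .with_seed(noise$seed, {
    lapply(vals, function(v) {
      if (noise$rel == 0 && noise$floor == 0) return(v)
      sd <- pmax(noise$rel * v, noise$floor)
      pmax(v + rnorm(length(v), 0, sd), 0)
    })
  })
  for (s in species) out[[s]] <- noisy[[s]]
  as_profile(out)
}
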