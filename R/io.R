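#' Read and write concentration profiles
#'
#' Profiles are plain CSV tables with a `time_h` column and any subset of
#' the species columns `C`, `G2`, `G`, `Xn`, `X` (mg/mL). Empty cells
#' mark missing observations. Times must be strictly increasing and
#' concentrations non-negative; unknown columns are rejected.
#'
#' @param path File path.
#' @return `read_profile` returns a data frame of class `hydro_profile`
#'   with per-species maxima (the objective weights) in the `maxima`
#'   attribute.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.csv(path, check.names = TRUE)
  allowed <- c("time_h", "C", "G2", "G", "Xn", "X")
  unknown <- setdiff(names(d), allowed)
  if (length(unknown))
    stop("unknown column(s) in profile: ", paste(unknown, collapse = ", "))
  if (!"time_h" %in% names(d)) stop("profile must have a time_h column")
  sp <- setdiff(names(d), "time_h")
  if (!length(sp)) stop("profile has no species columns")
  if (any(diff(d$time_h) <= 0))
    stop("times must be strictly increasing; offending row ",
         which(diff(d$time_h) <= 0)[1] + 1)
  for (s in sp) {
    bad <- which(!is.na(d[[s]]) & d[[s]] < 0)
    if (length(bad))
      stop("negative concentration in column ", s, ", row ", bad[1])
  }
  as_profile(d)
}

#' Coerce a data frame to a profile
#'
#' @param d Data frame with `time_h` plus species columns.
#' @return A `hydro_profile` with the `maxima` attribute set to the
#'   per-species maximum observed value.
#' @rdname read_profile
#' @export
as_profile <- function(d) {
  sp <- setdiff(names(d), "time_h")
  maxima <- vapply(sp, function(s) suppressWarnings(max(d[[s]], na.rm = TRUE)),
                   numeric(1))
  maxima <- maxima[is.finite(maxima)]
  structure(d, class = c("hydro_profile", "data.frame"), maxima = maxima)
}

#' @param profile A profile data frame.
#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE, na = "")
  invisible(path)
}

.read_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yaml::read_yaml(path)
}

#' Read a kinetic parameter config
#'
#' Flat YAML key-value file carrying the 16 kinetic constants plus a
#' `lambda` block (`mode: constant, value:` or
#' `mode: lignin_hill, lambda_max:, n:, k:`). Unknown keys are rejected;
#' missing keys are reported by name.
#'
#' @param path File path.
#' @return A [kinetic_params()] object.
#' @seealso [load_params()] for the shipped fitted sets.
#' @export
read_params <- function(path) {
  y <- .read_yaml(path)
  allowed <- c(.kinetic_names, "lambda", "pretreatment")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown key(s) in parameter file: ", paste(unknown, collapse = ", "))
  missing <- setdiff(c(.kinetic_names, "lambda"), names(y))
  if (length(missing))
    stop("missing required key(s): ", paste(missing, collapse = ", "))
  lam <- y$lambda
  spec <- switch(lam$mode,
    constant = lambda_const(lam$value),
    lignin_hill = lambda_hill(lam$lambda_max, lam$n, lam$k),
    stop("lambda mode must be 'constant' or 'lignin_hill'"))
  do.call(kinetic_params, c(y[.kinetic_names], list(lambda_spec = spec)))
}

#' Write a kinetic parameter config
#'
#' @param params A [kinetic_params()] object.
#' @param path File path.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  lam <- if (params$lambda_spec$mode == "constant")
    list(mode = "constant", value = params$lambda_spec$value)
  else c(list(mode = "lignin_hill"), params$lambda_spec$hill)
  yaml::write_yaml(c(params[.kinetic_names], list(lambda = lam)), path)
  invisible(path)
}

#' Read an adsorption coefficient config
#'
#' Keys: `emax_a/b/c`, `kp_a/b/c`, optional `emaxL`, `kpL`.
#'
#' @param path File path.
#' @return An [adsorption_coeffs()] object.
#' @export
read_adsorption <- function(path) {
  y <- .read_yaml(path)
  req <- c("emax_a", "emax_b", "emax_c", "kp_a", "kp_b", "kp_c")
  missing <- setdiff(req, names(y))
  if (length(missing))
    stop("missing required key(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(y), c(req, "emaxL", "kpL", "pretreatment"))
  if (length(unknown))
    stop("unknown key(s) in adsorption file: ", paste(unknown, collapse = ", "))
  adsorption_coeffs(c(y$emax_a, y$emax_b, y$emax_c),
                    c(y$kp_a, y$kp_b, y$kp_c),
                    emaxL = y$emaxL %||% 0, kpL = y$kpL %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an assay config
#'
#' YAML with keys `pretreatment`, `loading_pct`, `C0`, `L0`, `Xn0`,
#' `E1T`, `E2T`, `E3`, an inline `adsorption` block (same keys as
#' [read_adsorption()]) and optional `S_mode`.
#'
#' @param path File path.
#' @return A [assay_config()] object.
#' @seealso [load_assay()] for the shipped batch assays.
#' @export
read_assay <- function(path) {
  y <- .read_yaml(path)
  req <- c("pretreatment", "loading_pct", "C0", "L0", "Xn0",
           "E1T", "E2T", "E3", "adsorption")
  missing <- setdiff(req, names(y))
  if (length(missing))
    stop("missing required key(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(y), c(req, "S_mode"))
  if (length(unknown))
    stop("unknown key(s) in assay file: ", paste(unknown, collapse = ", "))
  ab <- y$adsorption
  ads <- adsorption_coeffs(c(ab$emax_a, ab$emax_b, ab$emax_c),
                           c(ab$kp_a, ab$kp_b, ab$kp_c),
                           emaxL = ab$emaxL %||% 0, kpL = ab$kpL %||% 0)
  assay_config(y$pretreatment, y$loading_pct, y$C0, y$L0, y$Xn0,
               y$E1T, y$E2T, y$E3, ads, S_mode = y$S_mode %||% "dynamic")
}

.fixture <- function(name) {
  p <- system.file("extdata", name, package = "hydrolysim")
  if (p == "") stop("fixture not found: ", name)
  p
}

#' Shipped fitted configurations
#'
#' Loaders for the in-package fixtures: the fitted kinetic parameter sets
#' and Langmuir adsorption coefficient sets for the two pretreatments,
#' and the ten batch assays (five solids loadings per pretreatment).
#'
#' @param pretreatment `"HB"` or `"OB"`.
#' @param loading_pct One of 4, 6, 8, 10, 12 (percent w/v).
#' @return A `hydro_params`, `adsorption_coeffs` or `hydro_assay` object.
#' @examples
#' load_params("HB")
#' load_assay("OB", 10)
#' @export
load_params <- function(pretreatment = c("HB", "OB")) {
  pretreatment <- match.arg(pretreatment)
  read_params(.fixture(sprintf("params_%s.yml", tolower(pretreatment))))
}

#' @rdname load_params
#' @export
load_adsorption <- function(pretreatment = c("HB", "OB")) {
  pretreatment <- match.arg(pretreatment)
  read_adsorption(.fixture(sprintf("adsorption_%s.yml", tolower(pretreatment))))
}

#' @rdname load_params
#' @export
load_assay <- function(pretreatment = c("HB", "OB"), loading_pct) {
  pretreatment <- match.arg(pretreatment)
  stopifnot(loading_pct %in% c(4, 6, 8, 10, 12))
  read_assay(.fixture(sprintf("assay_%s_%02d.yml", tolower(pretreatment),
                              loading_pct)))
}
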