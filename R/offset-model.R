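#' Fixed-effect coefficients of the microclimate temperature offset models
#'
#' Returns the fitted linear mixed-effects fixed-effect coefficients used to
#' predict average daily minimum or maximum below-canopy temperature offsets
#' (microclimate minus macroclimate, degrees C) from five predictors:
#' macroclimate temperature (monthly average of daily minima or maxima,
#' matching `kind`), overstory leaf area index (LAI), northness (cosine of
#' aspect), basal-area-weighted shade tolerance (STol, 1-5) and topographic
#' position index (TPI, m).
#'
#' Predictions are population-level: the random study intercept of the
#' original fit is set to zero and its standard deviation is carried along
#' as metadata only (`study_random_sd`).
#'
#' @param kind `"min"` or `"max"`, selecting the model for daily minimum or
#'   maximum temperature offsets.
#' @param intercept,beta_tmacro,beta_lai,beta_northness,beta_stol,beta_tpi
#'   Optional overrides (degrees C, or degrees C per predictor unit) for
#'   locally refitted models.
#' @param study_random_sd Random intercept standard deviation (degrees C),
#'   informational only.
#' @return An object of class `offset_coefficients`: a list with the six
#'   fixed effects, `kind` and `study_random_sd`.
#' @examples
#' co <- offset_coefficients("min")
#' co$intercept  # offset for a zeroed predictor vector
#' @export
offset_coefficients <- function(kind = c("min", "max"),
                                intercept = NULL, beta_tmacro = NULL,
                                beta_lai = NULL, beta_northness = NULL,
                                beta_stol = NULL, beta_tpi = NULL,
                                study_random_sd = NULL) {
  kind <- match.arg(kind)
  defaults <- if (kind == "min") {
    list(intercept = 1.4570, beta_tmacro = -0.0248, beta_lai = 0.0227,
         beta_northness = 0.2627, beta_stol = -0.2031, beta_tpi = 0.0158,
         study_random_sd = 0.6614)
  } else {
    list(intercept = 0.9767, beta_tmacro = -0.1932, beta_lai = -0.3948,
         beta_northness = -0.5729, beta_stol = 0.4419, beta_tpi = 0.0140,
         study_random_sd = 1.6145)
  }
  override <- list(intercept = intercept, beta_tmacro = beta_tmacro,
                   beta_lai = beta_lai, beta_northness = beta_northness,
                   beta_stol = beta_stol, beta_tpi = beta_tpi,
                   study_random_sd = study_random_sd)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) defaults[[nm]] <- as.numeric(override[[nm]])
  }
  vals <- unlist(defaults)
  if (!all(is.finite(vals))) {
    stop("all offset-model coefficients must be finite", call. = FALSE)
  }
  structure(c(list(kind = kind), defaults), class = "offset_coefficients")
}

#' Zeroed offset coefficients (null model)
#'
#' Convenience constructor for a model whose predictions are identically
#' zero, used to verify that paired macroclimate/microclimate simulations
#' coincide when buffering is switched off.
#'
#' @inheritParams offset_coefficients
#' @return An `offset_coefficients` object with all coefficients 0.
#' @export
null_offset_coefficients <- function(kind = c("min", "max")) {
  offset_coefficients(kind, intercept = 0, beta_tmacro = 0, beta_lai = 0,
                      beta_northness = 0, beta_stol = 0, beta_tpi = 0,
                      study_random_sd = 0)
}

#' @export
print.offset_coefficients <- function(x, ...) {
  cat(sprintf("Offset model (%s): intercept %.4f; t_macro %.4f; lai %.4f; northness %.4f; stol %.4f; tpi %.4f (study sd %.4f)\n",
              x$kind, x$intercept, x$beta_tmacro, x$beta_lai,
              x$beta_northness, x$beta_stol, x$beta_tpi, x$study_random_sd))
  invisible(x)
}

#' Predictor vector for the offset models
#'
#' Bundles the five predictors for one (or several, vectorized) 10 m cells.
#' The vector carries its `kind` so that minimum-offset coefficients can
#' never be applied to a maximum-temperature predictor by accident.
#'
#' @param t_macro Monthly average of daily minimum (`kind = "min"`) or
#'   maximum (`kind = "max"`) macroclimate temperature, degrees C.
#' @param lai Overstory leaf area index, m^2 m^-2, >= 0.
#' @param northness Cosine of aspect, in \[-1, 1\].
#' @param stol Basal-area-weighted shade tolerance, in \[1, 5\].
#' @param tpi Topographic position index, m.
#' @param kind `"min"` or `"max"`.
#' @return A `predictor_vector` object (list of equal-length numeric
#'   vectors plus `kind`).
#' @export
predictor_vector <- function(t_macro, lai, northness, stol, tpi,
                             kind = c("min", "max")) {
  kind <- match.arg(kind)
  fields <- list(t_macro = t_macro, lai = lai, northness = northness,
                 stol = stol, tpi = tpi)
  n <- vapply(fields, length, integer(1))
  len <- max(n)
  if (!all(n == len | n == 1L)) {
    stop("predictor fields must have equal length (or length 1)", call. = FALSE)
  }
  fields <- lapply(fields, function(x) rep_len(as.numeric(x), len))
  for (nm in names(fields)) {
    if (anyNA(fields[[nm]]) || !all(is.finite(fields[[nm]]))) {
      stop(sprintf("non-finite predictor value in field '%s'", nm),
           call. = FALSE)
    }
  }
  structure(c(fields, list(kind = kind)), class = "predictor_vector")
}

#' Truncation bounds for offset-model predictors
#'
#' Predictors are clamped to the range covered by the data used to fit the
#' offset models, so the linear models are never extrapolated. The exact
#' fitting ranges are not published; the defaults approximate the observed
#' predictor densities and are fully configurable.
#'
#' @param t_macro,lai,northness,stol,tpi Length-2 numeric `c(lower, upper)`
#'   per predictor, same units as [predictor_vector()].
#' @return A `truncation_bounds` object.
#' @export
truncation_bounds <- function(t_macro = c(-15, 30), lai = c(0, 8),
                              northness = c(-1, 1), stol = c(1, 5),
                              tpi = c(-150, 150)) {
  b <- list(t_macro = as.numeric(t_macro), lai = as.numeric(lai),
            northness = as.numeric(northness), stol = as.numeric(stol),
            tpi = as.numeric(tpi))
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2L || anyNA(b[[nm]]) || b[[nm]][1] > b[[nm]][2]) {
      stop(sprintf("bounds for '%s' must be c(lower, upper) with lower <= upper", nm),
           call. = FALSE)
    }
  }
  structure(b, class = "truncation_bounds")
}

#' Clamp predictors into their fitting ranges
#'
#' Each predictor field is clamped into `[lower, upper]`; the operation is
#' idempotent and leaves in-range values untouched.
#'
#' @param p A [predictor_vector()].
#' @param bounds A [truncation_bounds()].
#' @return A `predictor_vector` with every field inside its bounds.
#' @export
truncate_predictors <- function(p, bounds = truncation_bounds()) {
  stopifnot(inherits(p, "predictor_vector"), inherits(bounds, "truncation_bounds"))
  out <- p
  for (nm in names(bounds)) {
    out[[nm]] <- pmin(pmax(p[[nm]], bounds[[nm]][1]), bounds[[nm]][2])
  }
  out
}

#' Predict a below-canopy temperature offset
#'
#' Evaluates the linear fixed-effect predictor
#' `intercept + b_t * t_macro + b_lai * lai + b_n * northness +
#'  b_s * stol + b_tpi * tpi` (random study effect zero). Positive values
#' mean the understory is warmer than the open macroclimate, negative
#' cooler.
#'
#' @param p A [predictor_vector()], normally already truncated via
#'   [truncate_predictors()].
#' @param coefs An [offset_coefficients()] object whose `kind` must match
#'   `p$kind`.
#' @return Numeric vector of offsets, degrees C.
#' @examples
#' p <- predictor_vector(t_macro = 25, lai = 6, northness = 0, stol = 4,
#'                       tpi = 0, kind = "max")
#' predict_offset(p, offset_coefficients("max"))  # about -4.45 C
#' @export
predict_offset <- function(p, coefs) {
  stopifnot(inherits(p, "predictor_vector"), inherits(coefs, "offset_coefficients"))
  if (!identical(p$kind, coefs$kind)) {
    stop(sprintf("predictor vector kind '%s' does not match coefficient kind '%s'",
                 p$kind, coefs$kind), call. = FALSE)
  }
  coefs$intercept + coefs$beta_tmacro * p$t_macro + coefs$beta_lai * p$lai +
    coefs$beta_northness * p$northness + coefs$beta_stol * p$stol +
    coefs$beta_tpi * p$tpi
}

#' Mean daily offset from minimum and maximum offsets
#'
#' The mean-temperature offset is defined as the arithmetic mean of the
#' minimum and maximum offsets, exactly.
#'
#' @param offset_min,offset_max Offsets in degrees C (vectorized).
#' @return `(offset_min + offset_max) / 2`.
#' @export
derive_mean_offset <- function(offset_min, offset_max) {
  if (!all(is.finite(offset_min)) || !all(is.finite(offset_max))) {
    stop("offsets must be finite", call. = FALSE)
  }
  (offset_min + offset_max) / 2
}
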