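#' Dead organic matter pools
#'
#' Carbon stocks of the four dead organic matter pools tracked by the
#' decomposition model, Mg C ha^-1.
#'
#' @param standing_deadwood,downed_wood,litter,soil_organic_matter
#'   Non-negative stocks, Mg C ha^-1.
#' @return A `carbon_pools` named numeric vector.
#' @export
carbon_pools <- function(standing_deadwood = 0, downed_wood = 0,
                         litter = 0, soil_organic_matter = 0) {
  x <- c(standing_deadwood = standing_deadwood, downed_wood = downed_wood,
         litter = litter, soil_organic_matter = soil_organic_matter)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("carbon pools must be finite and >= 0", call. = FALSE)
  }
  structure(x, class = "carbon_pools")
}

#' Decomposition parameters
#'
#' First-order decay constants at reference climate, humification fractions
#' routing decayed material from the non-soil pools into soil organic
#' matter, and the constants of the climate modifier. The temperature
#' response is a Lloyd-Taylor-form exponential normalized to 1 at `t_ref`;
#' the moisture response is a saturating logistic in the annual
#' precipitation-to-PET ratio. The default decay rates and humification
#' fractions are plausible temperate-forest values, not fitted constants.
#'
#' @param k_ref Named numeric, reference decay rates per pool, yr^-1
#'   (names as in [carbon_pools()]).
#' @param humification Named numeric in \[0, 1\] for the three non-soil
#'   pools: share of decayed carbon transferred to soil rather than
#'   respired.
#' @param t_ref Reference temperature at which the temperature modifier is
#'   1, degrees C.
#' @param e0 Temperature sensitivity (Lloyd-Taylor activation parameter), K.
#' @param t0 Lower temperature asymptote of the Lloyd-Taylor curve,
#'   degrees C; the response is 0 at or below it.
#' @param moisture_enabled Logical; if `FALSE` the moisture modifier is
#'   identically 1.
#' @param moisture_k,moisture_mid Steepness and midpoint of the logistic
#'   moisture response in precip/PET.
#' @return A `decomposition_params` list.
#' @export
decomposition_params <- function(k_ref = c(standing_deadwood = 0.04,
                                           downed_wood = 0.08,
                                           litter = 0.3,
                                           soil_organic_matter = 0.02),
                                 humification = c(standing_deadwood = 0.3,
                                                  downed_wood = 0.3,
                                                  litter = 0.35),
                                 t_ref = 10, e0 = 308.56, t0 = -46.02,
                                 moisture_enabled = FALSE,
                                 moisture_k = 4, moisture_mid = 0.5) {
  pools <- names(carbon_pools())
  stopifnot(all(pools %in% names(k_ref)), all(k_ref >= 0),
            all(setdiff(pools, "soil_organic_matter") %in% names(humification)),
            all(humification >= 0 & humification <= 1),
            t_ref > t0)
  structure(list(k_ref = k_ref[pools],
                 humification = humification[setdiff(pools, "soil_organic_matter")],
                 t_ref = t_ref, e0 = e0, t0 = t0,
                 moisture_enabled = isTRUE(moisture_enabled),
                 moisture_k = moisture_k, moisture_mid = moisture_mid),
            class = "decomposition_params")
}

#' Temperature modifier of decomposition
#'
#' Mean over the daily series of `f(T) / f(t_ref)`, with `f` the
#' Lloyd-Taylor exponential response. Equals 1 for a constant series at
#' `t_ref` and increases strictly when the whole series is shifted upward.
#' Feeding this modifier the mean *microclimate* instead of macroclimate
#' temperature is how canopy buffering slows (or speeds) decomposition.
#'
#' @param daily_tmean Numeric vector of daily mean temperatures, degrees C.
#' @param params [decomposition_params()].
#' @return Dimensionless scalar >= 0.
#' @export
temperature_modifier <- function(daily_tmean, params = decomposition_params()) {
  if (length(daily_tmean) == 0) stop("empty temperature series", call. = FALSE)
  if (!all(is.finite(daily_tmean))) {
    stop("temperature series contains non-finite values", call. = FALSE)
  }
  # f(t) = exp(e0 * (1/(t_ref - t0) - 1/(t - t0))) is already normalized:
  # f(t_ref) = 1 by construction; below t0 the response is 0.
  f <- ifelse(daily_tmean > params$t0 + 1e-9,
              exp(params$e0 * (1 / (params$t_ref - params$t0) -
                                 1 / (daily_tmean - params$t0))), 0)
  mean(f)
}

#' Moisture modifier of decomposition
#'
#' Saturating logistic in the annual precipitation-to-PET ratio, in (0, 1\];
#' exactly 1 when disabled in the parameters.
#'
#' @param annual_precip Annual precipitation, mm.
#' @param annual_pet Annual potential evapotranspiration, mm (> 0 when the
#'   response is enabled).
#' @param params [decomposition_params()].
#' @return Dimensionless scalar in (0, 1\].
#' @export
moisture_modifier <- function(annual_precip, annual_pet,
                              params = decomposition_params()) {
  if (!params$moisture_enabled) return(1)
  if (annual_precip < 0 || annual_pet <= 0) {
    stop("precipitation must be >= 0 and PET > 0", call. = FALSE)
  }
  ratio <- annual_precip / annual_pet
  stats::plogis(params$moisture_k * (ratio - params$moisture_mid))
}

#' Annual first-order decay step
#'
#' Decays each pool by `C * (1 - exp(-k * modifier))` for one year. The
#' non-soil pools route the humified fraction of their loss into soil
#' organic matter and respire the remainder; soil losses are respired
#' entirely. External inputs (litterfall, disturbance-generated deadwood)
#' are added after decay. Mass balance is exact:
#' `sum(before) + sum(inputs) == sum(after) + rh`.
#'
#' @param pools [carbon_pools()].
#' @param params [decomposition_params()].
#' @param climate_modifier Dimensionless >= 0 (product of temperature and
#'   moisture modifiers).
#' @param inputs Named numeric of external carbon inputs per pool,
#'   Mg C ha^-1 (missing pools default to 0).
#' @return List `pools` (updated [carbon_pools()]), `rh` (heterotrophic
#'   respiration, Mg C ha^-1 yr^-1) and `transfers` (humified flux to soil
#'   per source pool).
#' @export
step_pools <- function(pools, params = decomposition_params(),
                       climate_modifier = 1, inputs = numeric(0)) {
  stopifnot(inherits(pools, "carbon_pools"), climate_modifier >= 0)
  nm <- names(carbon_pools())
  inp <- stats::setNames(rep(0, length(nm)), nm)
  if (length(inputs)) inp[names(inputs)] <- inputs
  if (any(inp < 0)) stop("carbon inputs must be >= 0", call. = FALSE)
  loss <- unclass(pools) * (1 - exp(-params$k_ref * climate_modifier))
  nonsoil <- setdiff(nm, "soil_organic_matter")
  to_soil <- params$humification[nonsoil] * loss[nonsoil]
  rh <- sum((1 - params$humification[nonsoil]) * loss[nonsoil]) +
    loss[["soil_organic_matter"]]
  new <- unclass(pools) - loss
  new[["soil_organic_matter"]] <- new[["soil_organic_matter"]] + sum(to_soil)
  new <- new + inp
  stopifnot(all(new >= -1e-12))
  new <- pmax(new, 0)
  list(pools = do.call(carbon_pools, as.list(new)), rh = unname(rh),
       transfers = to_soil)
}
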