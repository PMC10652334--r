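# Pot soil: Campbell water retention anchored at field capacity, and a
# power-law soil-to-root interface conductance. One soil layer per pot; the
# pot surface is film-covered, so soil evaporation is zero.

#' Pot soil parameters
#'
#' Relative water contents are expressed as percent of pot volume, so the
#' water volume held at relative content `rwc` is `pot_volume * rwc / 100`
#' litres. Retention follows Campbell,
#' `psi = psi_e * theta_eff^(-b_retention)` with effective saturation
#' `theta_eff = (rwc - rwc_res)/(rwc_sat - rwc_res)`; the air-entry potential
#' `psi_e` is solved so that the curve passes through `psi_fc` (default
#' -0.033 MPa) at field capacity.
#'
#' @param pot_volume Pot volume (L).
#' @param rwc_sat Relative water content at saturation (%; default 100).
#' @param rwc_fc Relative water content at field capacity (%; default 37,
#'   sandy clay).
#' @param rwc_res Residual relative water content (%; default 9).
#' @param b_retention Campbell retention exponent (default 6, sandy clay).
#' @param psi_fc Matric potential at field capacity (MPa; default -0.033).
#' @param k_sat_soilroot Soil-to-root interface conductance at saturation
#'   (mmol s-1 MPa-1). The default is large: the interface only limits supply
#'   as the soil approaches residual water content.
#' @return A list of class `soil_params` (includes the solved `psi_e`).
#' @export
soil_params <- function(pot_volume = 80, rwc_sat = 100, rwc_fc = 37,
                        rwc_res = 9, b_retention = 6, psi_fc = -0.033,
                        k_sat_soilroot = 1e10) {
  stopifnot(pot_volume > 0, b_retention > 0, psi_fc < 0, k_sat_soilroot > 0)
  if (!(rwc_res < rwc_fc && rwc_fc < rwc_sat)) {
    stop("need rwc_res < rwc_fc < rwc_sat", call. = FALSE)
  }
  theta_eff_fc <- (rwc_fc - rwc_res) / (rwc_sat - rwc_res)
  psi_e <- psi_fc * theta_eff_fc^b_retention
  structure(
    list(pot_volume = pot_volume, rwc_sat = rwc_sat, rwc_fc = rwc_fc,
         rwc_res = rwc_res, b_retention = b_retention, psi_e = psi_e,
         psi_fc = psi_fc, k_sat_soilroot = k_sat_soilroot),
    class = "soil_params"
  )
}

#' Soil water potential from relative water content
#'
#' Campbell retention, monotone decreasing as the soil dries, clipped at
#' -50 MPa. At or below residual content the clip value is returned with a
#' warning.
#'
#' @param theta_rel Relative soil water content (% of pot volume).
#' @param soil A `soil_params` object.
#' @param psi_clip Lower clip (MPa; default -50).
#' @return Soil matric potential (MPa, < 0).
#' @export
soil_water_potential <- function(theta_rel, soil, psi_clip = -50) {
  if (any(theta_rel > soil$rwc_sat)) {
    stop("theta_rel above saturation", call. = FALSE)
  }
  at_res <- theta_rel <= soil$rwc_res
  if (any(at_res)) warning("soil at or below residual water content")
  theta_eff <- pmax((theta_rel - soil$rwc_res) /
                      (soil$rwc_sat - soil$rwc_res), 0)
  psi <- ifelse(at_res, psi_clip,
                soil$psi_e * theta_eff^(-soil$b_retention))
  pmax(psi, psi_clip) * 1 # ensure numeric
}

#' Soil-to-root interface conductance
#'
#' Power-law reduction with effective saturation,
#' `k = k_sat_soilroot * theta_eff^(2 b + 3)` (the Campbell unsaturated
#' conductivity exponent). Non-negative, monotone increasing in water
#' content.
#'
#' @inheritParams soil_water_potential
#' @return Conductance (mmol s-1 MPa-1).
#' @export
soil_root_conductance <- function(theta_rel, soil) {
  theta_eff <- pmax((theta_rel - soil$rwc_res) /
                      (soil$rwc_sat - soil$rwc_res), 0)
  theta_eff <- pmin(theta_eff, 1)
  soil$k_sat_soilroot * theta_eff^(2 * soil$b_retention + 3)
}

#' Extractable water held by the pot
#'
#' Bookkeeping helper: litres of water between field capacity and residual
#' content, `pot_volume * (rwc_fc - rwc_res) / 100`.
#'
#' @param soil A `soil_params` object.
#' @return Extractable water (L).
#' @export
pot_extractable_water <- function(soil) {
  soil$pot_volume * (soil$rwc_fc - soil$rwc_res) / 100
}
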