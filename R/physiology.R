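# Physiological response curves: symplast water relations (pressure-volume),
# xylem vulnerability, stomatal regulation by turgor, temperature response of
# residual conductance, bark conductance, drought leaf shedding, and VPD.
# All functions are pure and vectorized over their first argument.

#' Symplast water potential from relative water content
#'
#' Two-parameter pressure-volume model of the leaf symplast. The osmotic
#' component follows Boyle-van't Hoff dilution (`pi0 / r`) and the turgor
#' component declines linearly with relative water deficit at bulk modulus
#' `epsilon`, floored at zero beyond the turgor loss point.
#'
#' @param r Relative symplast water content, in (0, 1].
#' @param pi0 Osmotic potential at full turgor (MPa, < 0).
#' @param epsilon Bulk modulus of elasticity (MPa, > 0).
#'
#' @return A list of class `pv_state` with components `psi_total`, `osmotic`,
#'   `turgor` (all MPa, vectorized over `r`) and `r_tlp`, the relative water
#'   content at turgor loss (`1 + pi0/epsilon`).
#' @export
#' @examples
#' symplast_water_potential(1, pi0 = -1.26, epsilon = 9.27)
symplast_water_potential <- function(r, pi0, epsilon) {
  stopifnot(pi0 < 0, epsilon > 0)
  if (any(r <= 0 | r > 1)) {
    stop("relative water content `r` must lie in (0, 1]", call. = FALSE)
  }
  osmotic <- pi0 / r
  turgor <- pmax(0, -pi0 - epsilon * (1 - r))
  structure(
    list(
      psi_total = osmotic + turgor,
      osmotic = osmotic,
      turgor = turgor,
      r_tlp = 1 + pi0 / epsilon
    ),
    class = "pv_state"
  )
}

#' Turgor loss point derived from pressure-volume parameters
#'
#' Water potential at which turgor reaches zero: `pi0 / (1 + pi0/epsilon)`.
#' All simulator computations use this derived value; measured TLP entries in
#' trait tables are carried as observational metadata only.
#'
#' @inheritParams symplast_water_potential
#' @return Turgor loss point (MPa, < 0).
#' @export
turgor_loss_point <- function(pi0, epsilon) {
  stopifnot(pi0 < 0, epsilon > 0)
  r_tlp <- 1 + pi0 / epsilon
  if (r_tlp <= 0) stop("epsilon must exceed -pi0 for a positive turgor-loss content",
                       call. = FALSE)
  pi0 / r_tlp
}

#' Relative symplast water content at a given water potential
#'
#' Analytic inverse of [symplast_water_potential()]. Above the turgor loss
#' point the positive root of the quadratic
#' `epsilon r^2 - (pi0 + epsilon + psi) r + pi0 = 0` is taken; beyond it the
#' purely osmotic branch gives `pi0 / psi`.
#'
#' @param psi Total water potential (MPa, <= 0).
#' @inheritParams symplast_water_potential
#' @return Relative water content in (0, 1].
#' @export
symplast_content_at_psi <- function(psi, pi0, epsilon) {
  stopifnot(pi0 < 0, epsilon > 0)
  if (any(psi > 0)) stop("water potential must be <= 0", call. = FALSE)
  tlp <- turgor_loss_point(pi0, epsilon)
  b <- pi0 + epsilon + psi
  r_turgid <- (b + sqrt(b^2 - 4 * epsilon * pi0)) / (2 * epsilon)
  r <- ifelse(psi <= tlp, pi0 / psi, r_turgid)
  pmin(r, 1)
}

#' Percent loss of xylem conductivity at a water potential
#'
#' Sigmoid vulnerability curve
#' `PLC = 100 / (1 + exp((slope/25) * (psi - p50)))`, parameterized so that
#' the absolute slope of the curve at `p50` equals `vc_slope` in % per MPa
#' (the convention of Cavitron-derived curves).
#'
#' @param psi Xylem water potential (MPa).
#' @param p50 Water potential at 50% conductivity loss (MPa, < 0).
#' @param vc_slope Slope of the curve at `p50` (% per MPa, > 0).
#' @return PLC in \[0, 100\].
#' @export
#' @examples
#' plc_at_psi(-4.67, p50 = -4.67, vc_slope = 78) # 50
plc_at_psi <- function(psi, p50, vc_slope) {
  stopifnot(vc_slope > 0)
  100 / (1 + exp((vc_slope / 25) * (psi - p50)))
}

#' Water potential at a given percent loss of conductivity
#'
#' Analytic inverse of [plc_at_psi()]:
#' `psi = p50 + (25/vc_slope) * log(100/plc - 1)`.
#'
#' @param plc Percent loss of conductivity, in (0, 100).
#' @inheritParams plc_at_psi
#' @return Water potential (MPa).
#' @export
psi_at_plc <- function(plc, p50, vc_slope) {
  stopifnot(vc_slope > 0)
  if (any(plc <= 0 | plc >= 100)) {
    stop("plc must lie strictly between 0 and 100", call. = FALSE)
  }
  p50 + (25 / vc_slope) * log(100 / plc - 1)
}

#' Stomatal conductance regulated by leaf turgor
#'
#' Stomata respond to leaf turgor: conductance declines linearly with relative
#' turgor (turgor at `psi_leaf` over turgor at full hydration, `-pi0`) and
#' reaches zero at the derived turgor loss point. A binary light factor closes
#' stomata in the dark (PAR below `par_threshold`).
#'
#' @param psi_leaf Leaf water potential (MPa, <= 0).
#' @param traits A `species_traits` object (see [load_species_traits()]).
#' @param par Photosynthetically active radiation (umol m-2 s-1, >= 0).
#' @param par_threshold Light level below which stomata are closed
#'   (umol m-2 s-1; default 10).
#' @return Stomatal conductance (mmol m-2 s-1).
#' @export
stomatal_conductance <- function(psi_leaf, traits, par, par_threshold = 10) {
  if (any(psi_leaf > 0)) stop("psi_leaf must be <= 0", call. = FALSE)
  stopifnot(all(par >= 0))
  r <- symplast_content_at_psi(psi_leaf, traits$pi0, traits$epsilon)
  turgor <- pmax(0, -traits$pi0 - traits$epsilon * (1 - r))
  light <- as.numeric(par >= par_threshold)
  traits$gs_max * light * turgor / (-traits$pi0)
}

#' Residual (cuticular) conductance at a given air temperature
#'
#' Piecewise Q10 response about the phase-transition temperature `t_p`:
#' below `t_p` conductance scales as `q10_a^((T - t_ref)/10)` from its value
#' `g_res` at the reference temperature; above `t_p` it continues from
#' `g(t_p)` with the steeper `q10_b`. Continuous at `t_p`, non-decreasing in
#' temperature.
#'
#' @param t_air Air temperature (degrees C), in \[-20, 60\].
#' @param traits A `species_traits` object.
#' @param t_ref Reference temperature at which `g_res` is defined
#'   (degrees C; default 25).
#' @return Residual conductance (mmol m-2 s-1).
#' @export
residual_conductance_at_T <- function(t_air, traits, t_ref = 25) {
  if (any(t_air < -20 | t_air > 60)) {
    stop("t_air outside the supported range [-20, 60] degC", call. = FALSE)
  }
  g_tp <- traits$g_res * traits$q10_a^((traits$t_p - t_ref) / 10)
  ifelse(
    t_air <= traits$t_p,
    traits$g_res * traits$q10_a^((t_air - t_ref) / 10),
    g_tp * traits$q10_b^((t_air - traits$t_p) / 10)
  )
}

#' Bark conductance
#'
#' Minimum conductance to water vapour of the bark surface, taken as double
#' the residual conductance of leaves and shoots.
#'
#' @param traits A `species_traits` object.
#' @return Bark conductance at the reference temperature (mmol m-2 s-1),
#'   applied per unit bark surface area.
#' @export
bark_conductance <- function(traits) {
  2 * traits$g_res
}

#' Percentage of leaves shed at a given leaf water potential
#'
#' Sigmoidal drought-deciduous response
#' `PLF = 100 / (1 + exp(rate * (psi_leaf - psi_half)))`. During a simulation
#' the applied canopy loss is the running maximum of PLF along the trajectory
#' (shedding is irreversible). Non-deciduous species (absent
#' `shedding_params`) shed nothing.
#'
#' @param psi_leaf Leaf water potential (MPa, <= 0).
#' @param shedding_params List with elements `rate` (MPa-1) and `psi_half`
#'   (MPa), or `NULL` for non-deciduous species.
#' @return Percentage of initial leaf area shed, in \[0, 100\].
#' @export
#' @examples
#' leaf_shedding_fraction(-1.8, list(rate = 4, psi_half = -1.8)) # 50
leaf_shedding_fraction <- function(psi_leaf, shedding_params) {
  if (any(psi_leaf > 0)) stop("psi_leaf must be <= 0", call. = FALSE)
  if (is.null(shedding_params)) return(rep(0, length(psi_leaf)))
  100 / (1 + exp(shedding_params$rate * (psi_leaf - shedding_params$psi_half)))
}

#' Vapour pressure deficit of the air
#'
#' Tetens saturation vapour pressure,
#' `es(T) = 0.61078 * exp(17.27 T / (T + 237.3))` kPa, times the relative
#' saturation deficit.
#'
#' @param t_air Air temperature (degrees C).
#' @param rh Relative humidity (%), in \[0, 100\].
#' @return VPD (kPa, >= 0).
#' @export
#' @examples
#' vapour_pressure_deficit(25, 50)
vapour_pressure_deficit <- function(t_air, rh) {
  if (any(rh < 0 | rh > 100)) {
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  }
  es <- 0.61078 * exp(17.27 * t_air / (t_air + 237.3))
  es * (1 - rh / 100)
}
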