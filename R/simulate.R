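# Dry-down simulation driver: options, the single-run wrapper around the
# compiled stepper, and the multi-species (optionally standardized) panel.

#' Simulation options
#'
#' @param dt_max Largest sub-step (s; default 600).
#' @param dt_min Smallest sub-step (s; default 1).
#' @param mass_balance_tol Acceptable cumulative mass-balance error, as a
#'   fraction of initial water per simulated day (default 1e-3).
#' @param stop_plc Leaf PLC (%) at which the run terminates as hydraulic
#'   failure (default 99).
#' @param max_days Maximum simulated days (default 60).
#' @param dpsi_max Largest accepted per-sub-step change in any compartment
#'   water potential (MPa; default 0.05) - the adaptive step controller.
#' @param par_threshold Light threshold for stomatal opening
#'   (umol m-2 s-1; default 10).
#' @param t_ref Reference temperature for `g_res` (degrees C; default 25).
#' @param patm Atmospheric pressure (kPa; default 101.3, site ~350 m).
#' @param psi_soil_clip Lower clip on soil water potential (MPa; default -50).
#' @param theta_init Initial relative soil water content (% of pot volume).
#'   `NULL` (default) starts at field capacity: a freely drained pot cannot
#'   hold water above it, so irrigation-maintained saturation equals pot
#'   capacity once drainage has finished.
#' @return A list of class `sim_options`.
#' @export
sim_options <- function(dt_max = 600, dt_min = 1, mass_balance_tol = 1e-3,
                        stop_plc = 99, max_days = 60, dpsi_max = 0.05,
                        par_threshold = 10, t_ref = 25, patm = 101.3,
                        psi_soil_clip = -50, theta_init = NULL) {
  stopifnot(dt_min <= dt_max, stop_plc > 0, stop_plc < 100, max_days > 0)
  structure(
    list(dt_max = dt_max, dt_min = dt_min,
         mass_balance_tol = mass_balance_tol, stop_plc = stop_plc,
         max_days = max_days, dpsi_max = dpsi_max,
         par_threshold = par_threshold, t_ref = t_ref, patm = patm,
         psi_soil_clip = psi_soil_clip, theta_init = theta_init),
    class = "sim_options"
  )
}

#' Simulate a dry-down from full hydration to hydraulic failure
#'
#' Steps the compartment network (soil - root - trunk - branch - leaf) under
#' hourly climate forcing. Each sub-step: (1) forcing interpolated to the
#' sub-step; (2) stomatal conductance from leaf turgor and light; (3) canopy
#' loss `gs * VPD / Patm` over remaining leaf area plus residual loss
#' `g_res(T)` over leaf area and bark loss `2 g_res(T)` over bark area;
#' (4) internal fluxes `K (psi_i - psi_j)` with xylem conductances scaled by
#' `(1 - PLC_stem/100)`, solved backward-Euler on the linearized chain;
#' (5) symplast pools follow their pressure-volume curve and apoplast pools
#' discharge in proportion to the PLC increment; (6) PLC is the running
#' maximum of the vulnerability curve (no refilling); (7) deciduous canopies
#' shrink by the running maximum of the shedding response. The run stops when
#' leaf PLC reaches `stop_plc` or `max_days` elapses.
#'
#' @param traits A `species_traits` object.
#' @param network A `plant_network`, or `NULL` to build one from the traits.
#' @param soil A `soil_params`, or `NULL` for defaults (80 L pot).
#' @param climate A `climate_series` covering `max_days`.
#' @param options A `sim_options` list.
#' @return A `sim_trajectory`: hourly data frame with water potentials per
#'   compartment (MPa), `gs` (mmol m-2 s-1), canopy and residual loss rates
#'   (mmol s-1), leaf and stem PLC (%), soil relative water content (%),
#'   remaining leaf area (m2) and cumulative loss (mol). Attributes carry the
#'   inputs, the failure flag and the mass-balance error.
#' @export
run_dehydration <- function(traits, network = NULL, soil = NULL, climate,
                            options = sim_options()) {
  stopifnot(inherits(traits, "species_traits"))
  if (is.null(network)) network <- build_fractal_tree(traits)
  if (is.null(soil)) soil <- soil_params()
  if (!inherits(climate, "climate_series")) {
    stop("climate must be a climate_series", call. = FALSE)
  }
  if (max(climate$time) < options$max_days * 24 - 1) {
    stop("climate series shorter than the simulation horizon", call. = FALSE)
  }
  theta_init <- if (is.null(options$theta_init)) soil$rwc_fc else
    options$theta_init
  if (theta_init <= soil$rwc_res || theta_init > soil$rwc_sat) {
    stop("theta_init outside (rwc_res, rwc_sat]", call. = FALSE)
  }

  sp <- traits$shedding_params
  traitv <- c(traits$pi0, traits$epsilon, traits$gs_max, traits$g_res,
              traits$t_p, traits$q10_a, traits$q10_b, traits$p50,
              traits$vc_slope, as.numeric(isTRUE(traits$deciduous)),
              if (is.null(sp)) 0 else sp$rate,
              if (is.null(sp)) 0 else sp$psi_half)
  netv <- c(network$leaf_area, network$bark_area_trunk,
            network$bark_area_branch, network$v_sym, network$v_apo,
            network$k_axial)
  pot_mol <- soil$pot_volume * MOL_PER_L
  soilv <- c(pot_mol, soil$rwc_sat, soil$rwc_fc, soil$rwc_res,
             soil$b_retention, soil$psi_e, soil$k_sat_soilroot, theta_init,
             options$psi_soil_clip)
  optv <- c(options$dt_max, options$dt_min, options$stop_plc,
            options$max_days, options$par_threshold, options$t_ref,
            options$patm, options$dpsi_max)

  res <- .sim_core(traitv, netv, soilv, climate$time, climate$t_air,
                   climate$rh, climate$par, optv)

  traj <- res$trajectory
  mb_rel <- abs(res$mass_balance_error + res$clamp_error) / res$initial_water
  tol <- options$mass_balance_tol * max(res$final_time_days, 1)
  if (is.finite(mb_rel) && mb_rel > tol) {
    warning(sprintf("mass-balance error %.3g exceeds tolerance %.3g",
                    mb_rel, tol))
  }
  structure(
    traj,
    class = c("sim_trajectory", "data.frame"),
    traits = traits, network = network, soil = soil, options = options,
    failed = res$failed,
    final_time_days = res$final_time_days,
    initial_water = res$initial_water,
    mass_balance_error = res$mass_balance_error,
    clamp_error = res$clamp_error
  )
}

#' Simulate a panel of species under a common climate
#'
#' With `standardized = TRUE` every species is given a common plant size
#' (leaf area, height, basal diameter) and pot before the networks are built,
#' so differences between trajectories reflect hydraulic traits only; with
#' `standardized = FALSE` each species keeps its measured allometry and its
#' experimental pot volume.
#'
#' @param trait_set List of `species_traits` (or character vector of built-in
#'   ids).
#' @param standardized Standardize plant size and pot volume? (default TRUE)
#' @param climate A `climate_series`.
#' @param options A `sim_options`.
#' @param leaf_area,height,basal_diameter,pot_volume Common size used when
#'   `standardized = TRUE` (defaults 1.5 m2, 1.5 m, 3 cm, 25 L).
#' @param soil Optional `soil_params` overriding the pot defaults.
#' @return Named list of `sim_trajectory` objects.
#' @export
simulate_species_panel <- function(trait_set, standardized = TRUE, climate,
                                   options = sim_options(), leaf_area = 1.5,
                                   height = 1.5, basal_diameter = 3,
                                   pot_volume = 25, soil = NULL) {
  if (is.character(trait_set)) {
    trait_set <- lapply(trait_set, load_species_traits)
  }
  out <- lapply(trait_set, function(tr) {
    if (standardized) {
      tr$leaf_area <- leaf_area
      tr$height <- height
      tr$basal_diameter <- basal_diameter
      sl <- if (is.null(soil)) soil_params(pot_volume = pot_volume) else soil
    } else {
      sl <- if (is.null(soil)) {
        soil_params(pot_volume = species_pot_volume(tr$species_id))
      } else soil
    }
    run_dehydration(tr, network = build_fractal_tree(tr), soil = sl,
                    climate = climate, options = options)
  })
  names(out) <- vapply(trait_set, function(t) t$species_id, character(1))
  out
}

#' Experimental pot volume for a built-in species
#'
#' 100 L for Pin_hale and Que_ilex, 80 L for Pop_nigr and Ced_atla; 80 L for
#' unknown ids.
#'
#' @param species_id Species identifier.
#' @return Pot volume (L).
#' @export
species_pot_volume <- function(species_id) {
  switch(species_id, Pin_hale = 100, Que_ilex = 100, Pop_nigr = 80,
         Ced_atla = 80, 80)
}

#' Write a simulated trajectory to CSV
#'
#' @param traj A `sim_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.sim_trajectory <- function(x, ...) {
  tr <- attr(x, "traits")
  cat(sprintf("<sim_trajectory> %s: %.1f days, %d hourly records\n",
              if (is.null(tr)) "?" else tr$species_id,
              attr(x, "final_time_days"), nrow(x)))
  cat(sprintf("  final psi_leaf %.2f MPa, leaf PLC %.1f%%, %s\n",
              x$psi_leaf[nrow(x)], x$plc_leaf[nrow(x)],
              if (isTRUE(attr(x, "failed"))) "hydraulic failure reached"
              else "failure not reached"))
  invisible(x)
}
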