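# Synthetic "observed" dry-down datasets with the statistical structure of
# the pot experiment: quantized 5-min balance mass, noisy predawn/midday
# water potentials every few days, and shed-leaf records for deciduous
# species. The noise-free truth is kept alongside for recovery tests.

#' Generate a synthetic observed dry-down dataset
#'
#' Runs a dry-down simulation to obtain the truth, then emits observations
#' the way the pot experiment records them: (a) predawn and midday xylem
#' water potentials every `psi_every_days` days with additive Gaussian noise
#' of `psi_sd` (optionally heteroscedastic: the noise doubles once midday
#' transpiration falls below 12% of its maximum, emulating the higher
#' variability near peak stress); (b) pot mass every `mass_every_min`
#' minutes as tare plus soil and plant water, quantized to the balance
#' resolution `mass_quantum`; (c) for deciduous species, daily shed-leaf dry
#' mass consistent with the canopy-loss trajectory. Fully reproducible given
#' the seed.
#'
#' @param traits A `species_traits` object (or built-in id).
#' @param climate A `climate_series`.
#' @param noise List with `psi_sd` (MPa; default 0.15) and `mass_quantum`
#'   (g; default 50).
#' @param sampling List with `psi_every_days` (default 3) and
#'   `mass_every_min` (default 5).
#' @param seed Integer seed.
#' @param soil,options,network Simulation inputs (defaults as in
#'   [run_dehydration()]).
#' @param tare Constant non-water pot mass (g; default 20000).
#' @param leaf_dry_mass_per_area Canopy dry mass per leaf area used for the
#'   shed-leaf records (g m-2; default 100).
#' @param heteroscedastic Double the water-potential noise after stomatal
#'   closure? (default FALSE)
#' @return A list of class `observation_set`: `psi` (day, tree_id, predawn,
#'   midday), `mass` (timestamp in h, tree_id, mass in g), `shed` (day,
#'   tree_id, dry mass in g; `NULL` for evergreens), `truth` (the noise-free
#'   `sim_trajectory`) and `metadata`.
#' @export
generate_observed_dataset <- function(traits, climate,
                                      noise = list(psi_sd = 0.15,
                                                   mass_quantum = 50),
                                      sampling = list(psi_every_days = 3,
                                                      mass_every_min = 5),
                                      seed = 1, soil = NULL,
                                      options = sim_options(),
                                      network = NULL, tare = 20000,
                                      leaf_dry_mass_per_area = 100,
                                      heteroscedastic = FALSE) {
  if (is.character(traits)) traits <- load_species_traits(traits)
  if (is.null(soil)) soil <- soil_params(
    pot_volume = species_pot_volume(traits$species_id))
  psi_sd <- if (is.null(noise$psi_sd)) 0.15 else noise$psi_sd
  quantum <- if (is.null(noise$mass_quantum)) 50 else noise$mass_quantum
  psi_every <- if (is.null(sampling$psi_every_days)) 3 else
    sampling$psi_every_days
  mass_every <- if (is.null(sampling$mass_every_min)) 5 else
    sampling$mass_every_min

  old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  truth <- run_dehydration(traits, network = network, soil = soil,
                           climate = climate, options = options)
  df <- as.data.frame(truth)
  daily <- daily_extremes(truth)

  # (a) water potentials every psi_every days
  obs_days <- daily$day[daily$day %% psi_every == 0]
  sel <- daily$day %in% obs_days
  n_obs <- sum(sel)
  sd_vec <- rep(psi_sd, n_obs)
  if (heteroscedastic && any(is.finite(daily$midday_e))) {
    closed <- daily$midday_e[sel] < 0.12 * max(daily$midday_e)
    sd_vec[closed] <- 2 * psi_sd
  }
  psi_obs <- data.frame(
    day = daily$day[sel],
    tree_id = 1L,
    predawn = daily$predawn_psi[sel] + stats::rnorm(n_obs, 0, sd_vec),
    midday = daily$midday_psi[sel] + stats::rnorm(n_obs, 0, sd_vec)
  )

  # (b) balance mass at mass_every-minute cadence, 50 g quantization
  t_grid <- seq(0, max(df$time), by = mass_every / 60)
  water_mol <- stats::approx(df$time, df$total_water, t_grid)$y
  mass_g <- tare + water_mol * 18.015
  if (quantum > 0) mass_g <- round(mass_g / quantum) * quantum
  mass_obs <- data.frame(timestamp = t_grid, tree_id = 1L, mass = mass_g)

  # (c) shed-leaf dry mass per day (deciduous only)
  shed_obs <- NULL
  if (isTRUE(traits$deciduous)) {
    day <- floor(df$time / 24)
    la_end <- vapply(split(df$la_remaining, day), min, numeric(1))
    shed_area <- -diff(c(traits$leaf_area, la_end))
    shed_area[shed_area < 0] <- 0
    shed_obs <- data.frame(
      day = as.integer(names(la_end)),
      tree_id = 1L,
      dry_mass = shed_area * leaf_dry_mass_per_area
    )
  }

  structure(
    list(
      psi = psi_obs, mass = mass_obs, shed = shed_obs, truth = truth,
      metadata = list(
        species_id = traits$species_id, leaf_area = traits$leaf_area,
        treatment = "WS", tare = tare, psi_sd = psi_sd,
        mass_quantum = quantum, psi_every_days = psi_every,
        mass_every_min = mass_every, seed = seed,
        heteroscedastic = heteroscedastic
      )
    ),
    class = "observation_set"
  )
}

#' Write an observation set to CSV files
#'
#' Emits `psi.csv`, `mass.csv` and (for deciduous species) `shed.csv` in
#' `dir`, in the dialects the trait-extraction readers expect.
#'
#' @param obs An `observation_set`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_observations_csv <- function(obs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    psi = file.path(dir, "psi.csv"),
    mass = file.path(dir, "mass.csv")
  )
  utils::write.csv(obs$psi, files[["psi"]], row.names = FALSE)
  utils::write.csv(obs$mass, files[["mass"]], row.names = FALSE)
  if (!is.null(obs$shed)) {
    files <- c(files, shed = file.path(dir, "shed.csv"))
    utils::write.csv(obs$shed, files[["shed"]], row.names = FALSE)
  }
  invisible(files)
}

#' @export
print.observation_set <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<observation_set> %s: %d psi days, %d mass samples (%g g quantum)%s\n",
    md$species_id, nrow(x$psi), nrow(x$mass), md$mass_quantum,
    if (!is.null(x$shed)) sprintf(", %d shed-leaf days", nrow(x$shed)) else ""
  ))
  invisible(x)
}
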