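# Dry-down simulator: equilibrium and closed-form oracles, conservation,
# convergence, trajectory invariants and directional trait effects.

test_that("with zero VPD in the dark the plant stays at soil equilibrium", {
  cl <- constant_climate(2, t_air = 20, rh = 100, par = 0)
  traj <- run_dehydration(load_species_traits("Pin_hale"), climate = cl,
                          options = sim_options(max_days = 2))
  df <- as.data.frame(traj)
  last <- df[nrow(df), ]
  for (col in c("psi_root", "psi_trunk", "psi_branch", "psi_leaf")) {
    expect_equal(last[[col]], last$psi_soil, tolerance = 1e-3)
  }
  drift <- abs(df$total_water[nrow(df)] - df$total_water[1])
  expect_lt(drift / df$total_water[1], 1e-6)
  expect_true(all(df$gs == 0))
})

test_that("single-capacitor decay matches the constant-efflux closed form", {
  setup <- capacitor_setup()
  vpd <- vapour_pressure_deficit(25, 50)
  cl <- constant_climate(2, t_air = 25, rh = 50, par = 0)
  traj <- run_dehydration(setup$traits, network = setup$network,
                          soil = setup$soil, climate = cl,
                          options = sim_options(max_days = 2))
  df <- as.data.frame(traj)
  rate <- setup$traits$g_res * vpd / 101.3 * setup$traits$leaf_area / 1000
  expected <- df$total_water[1] - rate * df$time * 3600
  expect_equal(df$total_water, expected,
               tolerance = 1e-3 * max(abs(expected)) / max(abs(df$total_water)))
  rel_err <- max(abs(df$total_water - expected)) /
    (df$total_water[1] - min(expected))
  expect_lt(rel_err, 1e-3)
})

test_that("a full deciduous run terminates at the failure threshold", {
  tr <- load_species_traits("Pop_nigr")
  cl <- synthesize_climate(40)
  traj <- run_dehydration(tr, soil = soil_params(pot_volume = 80),
                          climate = cl, options = sim_options(max_days = 40))
  df <- as.data.frame(traj)
  expect_true(attr(traj, "failed"))
  expect_gte(df$plc_leaf[nrow(df)], 99)
  expect_lte(min(df$psi_leaf), psi_at_plc(99, tr$p50, tr$vc_slope) + 1e-6)
})

test_that("water is conserved over every run", {
  cl <- synthesize_climate(60)
  for (sp in c("Pin_hale", "Pop_nigr")) {
    traj <- run_dehydration(load_species_traits(sp), climate = cl,
                            options = sim_options(max_days = 60))
    df <- as.data.frame(traj)
    err <- abs(attr(traj, "initial_water") -
                 df$total_water[nrow(df)] - df$cum_loss[nrow(df)])
    expect_lt(err / attr(traj, "initial_water"), 1e-3)
  }
})

test_that("halving the maximum step barely changes the solution", {
  tr <- load_species_traits("Pop_nigr")
  cl <- synthesize_climate(5)
  run_at <- function(dt) {
    as.data.frame(run_dehydration(
      tr, soil = soil_params(pot_volume = 25), climate = cl,
      options = sim_options(max_days = 5, dt_max = dt)))
  }
  a <- run_at(600)
  b <- run_at(300)
  n <- min(nrow(a), nrow(b))
  rel <- abs(a$psi_leaf[n] - b$psi_leaf[n]) / abs(a$psi_leaf[n])
  expect_lt(rel, 0.005)
})

test_that("trajectory invariants hold along a default dry-down", {
  cl <- synthesize_climate(60)
  traj <- run_dehydration(load_species_traits("Pin_hale"), climate = cl,
                          options = sim_options(max_days = 60))
  df <- as.data.frame(traj)
  expect_true(all(diff(df$plc_leaf) >= -1e-9))
  expect_true(all(diff(df$plc_stem) >= -1e-9))
  expect_true(all(diff(df$theta_rel) <= 1e-9)) # no rain
  expect_true(all(diff(df$la_remaining) <= 1e-9))
  expect_true(all(df$psi_leaf <= 0 & df$psi_soil <= 0))
  daily <- daily_extremes(traj)
  expect_true(all(diff(daily$predawn_psi) <= 1e-6))
})

test_that("trait perturbations move dehydration times the expected way", {
  cl <- synthesize_climate(60)
  soil <- soil_params(pot_volume = 25)
  opts <- sim_options(max_days = 60)
  run_metrics <- function(tr) {
    tr$leaf_area <- 1.5
    tr$height <- 1.5
    tr$basal_diameter <- 3
    traj <- run_dehydration(tr, network = build_fractal_tree(tr),
                            soil = soil, climate = cl, options = opts)
    dehydration_times(traj, tr)
  }
  base <- run_metrics(load_species_traits("Pop_nigr"))

  leaky <- load_species_traits("Pop_nigr")
  leaky$g_res <- leaky$g_res * 1.3
  expect_lt(run_metrics(leaky)$t_cav, base$t_cav)

  resistant <- load_species_traits("Pop_nigr")
  resistant$p50 <- resistant$p50 * 1.2 # more negative
  expect_gt(run_metrics(resistant)$t_cav, base$t_cav)

  # gs_max acts on the demand-limited early phase; Pin_hale (low gs_max)
  # is demand-limited, unlike the supply-limited Pop_nigr
  base_pin <- run_metrics(load_species_traits("Pin_hale"))
  thirsty <- load_species_traits("Pin_hale")
  thirsty$gs_max <- thirsty$gs_max * 1.5
  expect_lt(run_metrics(thirsty)$t_close, base_pin$t_close)
})

test_that("leaf shedding slows dehydration after closure", {
  cl <- synthesize_climate(60)
  soil <- soil_params(pot_volume = 25)
  opts <- sim_options(max_days = 60)
  shed <- load_species_traits("Pop_nigr")
  no_shed <- shed
  no_shed$deciduous <- FALSE
  no_shed$shedding_params <- NULL
  m_shed <- dehydration_times(
    run_dehydration(shed, soil = soil, climate = cl, options = opts), shed)
  m_none <- dehydration_times(
    run_dehydration(no_shed, soil = soil, climate = cl, options = opts),
    no_shed)
  expect_gt(m_shed$t_cav, m_none$t_cav)
})

test_that("the species panel standardizes allometry but not traits", {
  cl <- synthesize_climate(50)
  opts <- sim_options(max_days = 50)
  panel <- simulate_species_panel(builtin_species(), standardized = TRUE,
                                  climate = cl, options = opts)
  expect_named(panel, builtin_species())
  for (p in panel) {
    expect_s3_class(p, "sim_trajectory")
    expect_equal(attr(p, "network")$leaf_area, 1.5)
    expect_equal(attr(p, "soil")$pot_volume, 25)
  }

  # a one-species panel reproduces a direct run
  single <- simulate_species_panel("Ced_atla", standardized = FALSE,
                                   climate = cl, options = opts)[[1]]
  tr <- load_species_traits("Ced_atla")
  direct <- run_dehydration(tr, soil = soil_params(pot_volume = 80),
                            climate = cl, options = opts)
  expect_equal(as.data.frame(single), as.data.frame(direct),
               ignore_attr = TRUE)

  # standardized and experimental allometry differ only through size inputs
  std <- simulate_species_panel("Ced_atla", standardized = TRUE,
                                climate = cl, options = opts)[[1]]
  expect_false(isTRUE(all.equal(attr(std, "network")$k_total,
                                attr(single, "network")$k_total)))
})

test_that("a too-short climate is rejected", {
  cl <- synthesize_climate(2)
  expect_error(
    run_dehydration(load_species_traits("Pin_hale"), climate = cl,
                    options = sim_options(max_days = 10)),
    "shorter"
  )
})
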