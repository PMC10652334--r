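# Trait-extraction fitters: each must round-trip its own forward model
# noise-free, and meet its noisy-recovery bound under seeded replication.

test_that("midday transpiration converts balance slopes correctly", {
  # 36 g over 2 h on 1 m2: 36 / (18.015 * 7200) * 1000 mmol m-2 s-1
  m <- data.frame(timestamp = c(12, 14), mass = c(10000, 9964))
  out <- midday_transpiration_from_mass(m, leaf_area = 1)
  expect_equal(out$e_midday, 36 / (18.015 * 7200) * 1000, tolerance = 1e-9)
  expect_equal(out$e_midday, 0.27755, tolerance = 1e-4)

  m2 <- data.frame(timestamp = seq(12, 14, by = 1 / 12), mass = 5000)
  expect_equal(midday_transpiration_from_mass(m2, 1)$e_midday, 0)

  # watering mid-window flags the day
  m3 <- data.frame(timestamp = seq(12, 14, by = 0.5),
                   mass = c(5000, 5000, 5400, 5400, 5400))
  out3 <- midday_transpiration_from_mass(m3, 1)
  expect_true(out3$flagged)
  expect_true(is.na(out3$e_midday))
})

test_that("known transpiration survives 50 g balance quantization", {
  e_true <- 1.0 # mmol m-2 s-1 over 1 m2
  t <- seq(0, 24, by = 5 / 60)
  mass <- 150000 - e_true * 18.015 / 1000 * t * 3600
  mass_q <- round(mass / 50) * 50
  out <- midday_transpiration_from_mass(
    data.frame(timestamp = t, mass = mass_q), leaf_area = 1)
  expect_equal(out$e_midday, e_true, tolerance = 0.1)
})

test_that("Weibull closure fit recovers its generating curve exactly", {
  psi <- seq(-0.2, -5, by = -0.2)
  e <- 2 * exp(-((-psi) / 2.5)^4)
  fit <- fit_pgs88(psi, e)
  expect_equal(fit$emax, 2, tolerance = 1e-6)
  expect_equal(fit$b, 2.5, tolerance = 1e-6)
  expect_equal(fit$c, 4, tolerance = 1e-5)
  expect_equal(fit$p_gs88, -2.5 * (-log(0.12))^(1 / 4), tolerance = 1e-6)
  expect_equal(fit$p_gs88, -3.01673, tolerance = 1e-5)
  expect_lt(fit$rmse, 1e-9)

  expect_error(fit_pgs88(psi, rep(1, length(psi))), "degenerate")
  expect_error(fit_pgs88(psi[1:4], e[1:4]), "at least 6")
})

test_that("noisy Weibull recovery stays within 0.15 MPa across seeds", {
  p_true <- -2.5 * (-log(0.12))^(1 / 4)
  errs <- vapply(seq_len(100), function(s) {
    set.seed(s)
    psi <- sort(runif(30, -5, -0.2))
    e <- 2 * exp(-((-psi) / 2.5)^4)
    e_noisy <- e + rnorm(30, 0, 0.05 * max(e))
    fit <- tryCatch(fit_pgs88(psi, e_noisy), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else abs(fit$p_gs88 - p_true)
  }, numeric(1))
  expect_lt(sum(is.na(errs)), 5)
  expect_lt(stats::median(errs, na.rm = TRUE), 0.15)
  expect_lt(stats::quantile(errs, 0.9, na.rm = TRUE), 0.15)
})

test_that("pressure-volume analysis recovers pi0, epsilon and TLP", {
  tr <- load_species_traits("Pop_nigr") # pi0 -1.52, epsilon 15.9
  r <- seq(1, 0.70, by = -0.02)
  psi <- symplast_water_potential(r, tr$pi0, tr$epsilon)$psi_total
  fit <- fit_pressure_volume(r, psi)
  expect_equal(fit$pi0, tr$pi0, tolerance = 0.02)
  expect_equal(fit$epsilon, tr$epsilon, tolerance = 0.02)
  expect_equal(fit$tlp, turgor_loss_point(tr$pi0, tr$epsilon),
               tolerance = 0.02)
  expect_equal(fit$tlp, tr$pi0 / (1 + tr$pi0 / tr$epsilon), tolerance = 0.02)

  # point order must not matter
  set.seed(1)
  shuffle <- sample(length(r))
  fit2 <- fit_pressure_volume(r[shuffle], psi[shuffle])
  expect_identical(fit, fit2)

  expect_error(fit_pressure_volume(r[1:5], psi[1:5]), "at least 8")
})

test_that("residual conductance is recovered from a two-phase decay", {
  g_true <- 1.19 # mmol m-2 s-1
  leaf_area <- 0.02
  stem_area <- 0.003
  area <- leaf_area + stem_area # conifer: projected LA + stem
  vpd <- vapour_pressure_deficit(30, 40)
  t <- seq(0, 24, by = 0.25)
  res_slope <- g_true * (vpd / 101.3) * area * 18.015 * 3600 / 1000 # g h-1
  mass <- 200 - res_slope * t - 3 * (1 - exp(-t / 1)) # fast stomatal pool
  fit <- fit_residual_conductance(t, mass, t_air = 30, rh = 40,
                                  leaf_area = leaf_area,
                                  stem_area = stem_area)
  expect_equal(fit$g_res, g_true, tolerance = 0.05)

  # doubling the normalizing area halves the estimate exactly
  fit2 <- fit_residual_conductance(t, mass, t_air = 30, rh = 40,
                                   leaf_area = 2 * leaf_area,
                                   stem_area = 2 * stem_area)
  expect_equal(fit2$g_res, fit$g_res / 2, tolerance = 1e-12)

  expect_error(
    fit_residual_conductance(t, mass, t_air = 30, rh = 100,
                             leaf_area = leaf_area),
    "VPD")
})

test_that("two-segment Arrhenius fit recovers the phase transition", {
  tr <- load_species_traits("Ced_atla") # Tp 41.3, Q10a 1.22, Q10b 1.83
  t_levels <- c(30, 35, 40, 45, 50, 55)
  g <- residual_conductance_at_T(t_levels, tr)
  fit <- fit_temperature_response(t_levels, g)
  expect_false(fit$indeterminate)
  expect_lt(abs(fit$t_p - tr$t_p), 0.5)
  expect_equal(fit$q10_a, tr$q10_a, tolerance = 0.05)
  expect_equal(fit$q10_b, tr$q10_b, tolerance = 0.05)
})

test_that("a single-slope response is flagged indeterminate", {
  g <- 2 * 1.3^((c(30, 35, 40, 45, 50, 55) - 25) / 10)
  fit <- fit_temperature_response(c(30, 35, 40, 45, 50, 55), g)
  expect_true(fit$indeterminate)
  expect_true(is.na(fit$t_p))
  expect_equal(fit$q10_a, fit$q10_b, tolerance = 0.05)
})

test_that("noisy temperature response keeps the breakpoint unbiased", {
  tr <- load_species_traits("Ced_atla")
  t_levels <- c(30, 35, 40, 45, 50, 55)
  g0 <- residual_conductance_at_T(t_levels, tr)
  tps <- vapply(seq_len(100), function(s) {
    set.seed(1000 + s)
    g <- g0 * exp(rnorm(6, 0, 0.05))
    fit <- fit_temperature_response(t_levels, g)
    if (fit$indeterminate) NA_real_ else fit$t_p
  }, numeric(1))
  expect_lt(abs(stats::median(tps, na.rm = TRUE) - tr$t_p), 1)
})
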