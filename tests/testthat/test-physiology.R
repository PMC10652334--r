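# Response-curve unit tests. Expected values are closed-form hand
# evaluations of the printed formulas, frozen here.

test_that("symplast water potential reproduces the pressure-volume model", {
  # full hydration: zero total potential, turgor equals -pi0
  pv <- symplast_water_potential(1, pi0 = -1.26, epsilon = 9.27)
  expect_equal(pv$psi_total, 0)
  expect_equal(pv$turgor, 1.26)

  # turgor loss content and potential, closed form
  expect_equal(pv$r_tlp, 1 + (-1.26) / 9.27)
  expect_equal(pv$r_tlp, 0.864078, tolerance = 1e-6)
  expect_equal(turgor_loss_point(-1.26, 9.27), -1.26 / 0.8640777,
               tolerance = 1e-6)
  expect_equal(turgor_loss_point(-1.26, 9.27), -1.4582, tolerance = 1e-4)

  # beyond turgor loss the branch is purely osmotic
  pv2 <- symplast_water_potential(0.5, pi0 = -1.26, epsilon = 9.27)
  expect_equal(pv2$turgor, 0)
  expect_equal(pv2$psi_total, -2.52)

  expect_error(symplast_water_potential(0, -1.26, 9.27), "0, 1")
  expect_error(symplast_water_potential(1.2, -1.26, 9.27), "0, 1")
})

test_that("symplast potential is continuous and strictly decreasing in drying", {
  for (sp in builtin_species()) {
    tr <- load_species_traits(sp)
    r_tlp <- 1 + tr$pi0 / tr$epsilon
    r <- sort(unique(c(seq(0.4, 1, by = 0.005), r_tlp,
                       r_tlp + c(-1, 1) * 1e-9)))
    psi <- symplast_water_potential(r, tr$pi0, tr$epsilon)$psi_total
    expect_true(all(diff(psi) > 0)) # psi rises with r, falls as r drops
    jump <- abs(diff(psi[abs(r - r_tlp) < 2e-9]))
    expect_lt(max(jump), 1e-7) # no discontinuity across turgor loss
  }
})

test_that("content inversion round-trips the pressure-volume curve", {
  for (sp in c("Pin_hale", "Que_ilex")) {
    tr <- load_species_traits(sp)
    r <- seq(0.3, 1, by = 0.01)
    psi <- symplast_water_potential(r, tr$pi0, tr$epsilon)$psi_total
    r_back <- symplast_content_at_psi(psi, tr$pi0, tr$epsilon)
    expect_equal(r_back, r, tolerance = 1e-9)
  }
})

test_that("vulnerability curve has its midpoint, saturation and printed shape", {
  expect_equal(plc_at_psi(-4.67, -4.67, 78), 50)
  for (sp in builtin_species()) {
    tr <- load_species_traits(sp)
    expect_equal(plc_at_psi(tr$p50, tr$p50, tr$vc_slope), 50)
  }
  expect_equal(plc_at_psi(-1e3, -4.67, 78), 100, tolerance = 1e-9)
  expect_lt(plc_at_psi(0, -4.67, 78), 0.01)
  # hand evaluation of the logistic: a = 100/25 = 4, x = -0.55
  expect_equal(plc_at_psi(-2.75, -2.2, 100), 100 / (1 + exp(-4 * 0.55)),
               tolerance = 1e-12)
  expect_equal(plc_at_psi(-2.75, -2.2, 100), 90.0250, tolerance = 1e-4)
})

test_that("the curve's defining slope at P50 equals the trait value", {
  h <- 1e-6
  for (sp in builtin_species()) {
    tr <- load_species_traits(sp)
    d <- (plc_at_psi(tr$p50 + h, tr$p50, tr$vc_slope) -
          plc_at_psi(tr$p50 - h, tr$p50, tr$vc_slope)) / (2 * h)
    expect_equal(abs(d), tr$vc_slope, tolerance = 1e-3)
  }
})

test_that("psi_at_plc is the exact analytic inverse", {
  expect_equal(psi_at_plc(50, -4.67, 78), -4.67)
  # p50 + (25/slope) * log(100/99 - 1)
  expect_equal(psi_at_plc(99, -2.2, 100), -2.2 + 0.25 * log(1 / 99),
               tolerance = 1e-9)
  expect_equal(psi_at_plc(99, -2.2, 100), -3.3488, tolerance = 1e-4)
  for (sp in builtin_species()) {
    tr <- load_species_traits(sp)
    plc <- c(0.1, 1, 12.5, 50, 90, 99.9)
    expect_equal(plc_at_psi(psi_at_plc(plc, tr$p50, tr$vc_slope),
                            tr$p50, tr$vc_slope), plc, tolerance = 1e-9)
  }
  expect_error(psi_at_plc(0, -4.67, 78), "between")
  expect_error(psi_at_plc(100, -4.67, 78), "between")
})

test_that("stomata open with light and turgor, close at turgor loss", {
  tr <- load_species_traits("Pin_hale")
  expect_equal(stomatal_conductance(0, tr, par = 1000), tr$gs_max)
  expect_equal(stomatal_conductance(0, tr, par = 0), 0) # night
  tlp <- turgor_loss_point(tr$pi0, tr$epsilon)
  expect_equal(stomatal_conductance(tlp, tr, par = 1000), 0)
  expect_equal(stomatal_conductance(tlp - 1, tr, par = 1000), 0)
  gs_half <- stomatal_conductance(tlp / 2, tr, par = 1000)
  expect_gt(gs_half, 0)
  expect_lt(gs_half, tr$gs_max)
  # non-increasing as the leaf dries, on a fine grid
  psi <- seq(0, -3, by = -0.01)
  gs <- stomatal_conductance(psi, tr, par = 1000)
  expect_true(all(diff(gs) <= 1e-12))
  expect_error(stomatal_conductance(0.5, tr, par = 100), "<= 0")
})

test_that("residual conductance follows the two-phase Q10 response", {
  tr <- load_species_traits("Pop_nigr") # g_res 4.5, Tp 35, Q10a 1.2, Q10b 4.8
  expect_equal(residual_conductance_at_T(25, tr), 4.5)
  expect_equal(residual_conductance_at_T(35, tr), 4.5 * 1.2) # 5.4
  expect_equal(residual_conductance_at_T(45, tr), 5.4 * 4.8) # 25.92
  # continuity at the phase transition
  expect_equal(residual_conductance_at_T(tr$t_p - 1e-9, tr),
               residual_conductance_at_T(tr$t_p + 1e-9, tr),
               tolerance = 1e-9)
  # exact Q10 ratios on either side
  for (sp in builtin_species()) {
    tr <- load_species_traits(sp)
    expect_equal(residual_conductance_at_T(tr$t_p - 2, tr) /
                 residual_conductance_at_T(tr$t_p - 12, tr), tr$q10_a)
    expect_equal(residual_conductance_at_T(tr$t_p + 12, tr) /
                 residual_conductance_at_T(tr$t_p + 2, tr), tr$q10_b)
    t_grid <- seq(-10, 59, by = 0.5)
    expect_true(all(diff(residual_conductance_at_T(t_grid, tr)) >= 0))
  }
  expect_error(residual_conductance_at_T(80, tr), "range")
})

test_that("bark conductance doubles the residual conductance", {
  expect_equal(bark_conductance(load_species_traits("Pin_hale")), 1.16)
  expect_equal(bark_conductance(load_species_traits("Ced_atla")), 2.42)
  expect_equal(bark_conductance(list(g_res = 0)), 0)
})

test_that("leaf shedding follows the printed sigmoid and is bounded", {
  sp <- load_species_traits("Pop_nigr")$shedding_params
  expect_equal(sp$rate, 4)
  expect_equal(sp$psi_half, -1.8)
  expect_equal(leaf_shedding_fraction(-1.8, sp), 50)
  expect_equal(leaf_shedding_fraction(0, sp), 100 / (1 + exp(7.2)))
  expect_equal(leaf_shedding_fraction(0, sp), 0.0746, tolerance = 1e-3)
  expect_equal(leaf_shedding_fraction(-100, sp), 100, tolerance = 1e-9)
  expect_equal(leaf_shedding_fraction(-5, NULL), 0) # non-deciduous
})

test_that("VPD follows Tetens saturation vapour pressure", {
  expect_equal(vapour_pressure_deficit(25, 100), 0)
  es25 <- 0.61078 * exp(17.27 * 25 / 262.3)
  expect_equal(vapour_pressure_deficit(25, 50), es25 / 2)
  expect_equal(vapour_pressure_deficit(25, 50), 1.5838, tolerance = 1e-3)
  expect_equal(vapour_pressure_deficit(35, 30), 3.9360, tolerance = 1e-3)
  expect_error(vapour_pressure_deficit(25, 120), "0, 100")
})
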