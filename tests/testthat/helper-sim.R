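# Shared constructors for simulator tests.

# A constant climate (every hour identical).
constant_climate <- function(days, t_air = 25, rh = 50, par = 0) {
  synthesize_climate(days, t_min = t_air, t_max = t_air, rh_min = rh,
                     rh_max = rh, par_max = par)
}

# Single-capacitor configuration: soil hydraulically decoupled, no bark
# surface, no releasable apoplast, cavitation pushed out of reach. With a
# dark constant climate the only loss is residual leaf conductance, so total
# water declines along a closed-form line.
capacitor_setup <- function(traits = load_species_traits("Pin_hale")) {
  traits$p50 <- -80 # no cavitation in the test range
  net <- build_fractal_tree(traits)
  net$bark_area_trunk <- 0
  net$bark_area_branch <- 0
  net$bark_area <- 0
  net$v_apo <- net$v_apo * 0
  soil <- soil_params(pot_volume = 10, k_sat_soilroot = 1e-12)
  list(traits = traits, network = net, soil = soil)
}
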