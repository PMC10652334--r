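# Discretized plant: a fractal allometric scheme turns height, basal diameter
# and leaf area into compartment dimensions (trunk/branch/root volumes, bark
# surfaces), water pools (symplast and apoplast) and a series conductance
# partition. Compartment chain: soil - root - trunk - branch - leaf.

MOL_PER_L <- 1000 / 18.015 # mol of water per litre

# Fractal allometry constants (declared defaults; see the methods vignette).
.fractal <- list(
  branch_volume_ratio = 0.8,   # total branch volume / trunk volume
  branch_diameter_ratio = 1 / 3, # mean branch diameter / basal diameter
  root_volume_ratio = 1.0,     # total root volume / trunk volume
  # fraction of whole-plant hydraulic RESISTANCE per segment (sums to 1)
  resistance_fraction = c(root = 0.50, trunk = 0.125, branch = 0.125,
                          leaf = 0.25),
  # distribution of symplast water across compartments (sums to 1)
  symplast_fraction = c(root = 0.1, trunk = 0.2, branch = 0.2, leaf = 0.5),
  # distribution of cavitation-releasable apoplast water (sums to 1)
  apoplast_fraction_by_comp = c(root = 0.2, trunk = 0.3, branch = 0.3,
                                leaf = 0.2)
)

#' Build the discretized plant hydraulic network
#'
#' Generates a fractal tree from the trait allometry: the trunk is a cylinder
#' of the measured height and basal diameter; branch and root ensembles scale
#' from it by fixed ratios; bark area is the lateral surface of the trunk and
#' branch cylinders. The whole-plant hydraulic conductance
#' `k_plant * leaf_area` is partitioned in series (50% of resistance in the
#' root, 12.5% trunk, 12.5% branch, 25% leaf). Symplast water scales as
#' `symplast_volume_per_area * leaf_area`; cavitation-releasable apoplast
#' water adds `apoplastic_fraction / (1 - apoplastic_fraction)` times that.
#'
#' @param traits A `species_traits` object.
#' @param k_plant Whole-plant hydraulic conductance per leaf area
#'   (mmol s-1 m-2 MPa-1; default 1.5).
#' @return A list of class `plant_network` with compartment volumes (mol),
#'   conductances (mmol s-1 MPa-1), areas (m2) and dimensions.
#' @export
#' @examples
#' build_fractal_tree(load_species_traits("Pin_hale"))
build_fractal_tree <- function(traits, k_plant = 1.5) {
  stopifnot(k_plant > 0)
  la <- traits$leaf_area
  height <- traits$height
  d_basal <- traits$basal_diameter / 100 # cm -> m
  if (la <= 0 || height <= 0 || d_basal <= 0) {
    stop("non-positive plant dimension", call. = FALSE)
  }

  trunk_volume <- pi * (d_basal / 2)^2 * height * 1000 # L
  branch_volume <- .fractal$branch_volume_ratio * trunk_volume
  root_volume <- .fractal$root_volume_ratio * trunk_volume
  d_branch <- .fractal$branch_diameter_ratio * d_basal

  bark_area_trunk <- pi * d_basal * height
  # cylinder ensemble: lateral area = 4 V / d, with V in m3
  bark_area_branch <- 4 * (branch_volume / 1000) / d_branch

  k_total <- k_plant * la # mmol s-1 MPa-1
  k_comp <- k_total / .fractal$resistance_fraction

  v_sym_total <- traits$symplast_volume_per_area * la * MOL_PER_L
  v_sym <- v_sym_total * .fractal$symplast_fraction
  af <- traits$apoplastic_fraction
  v_apo_total <- v_sym_total * af / (1 - af)
  v_apo <- v_apo_total * .fractal$apoplast_fraction_by_comp

  structure(
    list(
      compartments = c("soil", "root", "trunk", "branch", "leaf"),
      leaf_area = la,
      bark_area_trunk = bark_area_trunk,
      bark_area_branch = bark_area_branch,
      bark_area = bark_area_trunk + bark_area_branch,
      trunk_volume = trunk_volume,
      branch_volume = branch_volume,
      root_volume = root_volume,
      v_sym = v_sym,  # mol, per compartment
      v_apo = v_apo,  # mol, cavitation-releasable
      k_axial = k_comp, # mmol s-1 MPa-1 per segment, in series
      k_plant = k_plant,
      k_total = k_total
    ),
    class = "plant_network"
  )
}

#' @export
print.plant_network <- function(x, ...) {
  cat("<plant_network> 5 compartments (soil-root-trunk-branch-leaf)\n")
  cat(sprintf("  leaf area %.2f m2, bark area %.2f m2, trunk volume %.2f L\n",
              x$leaf_area, x$bark_area, x$trunk_volume))
  cat(sprintf("  whole-plant conductance %.3f mmol s-1 MPa-1 (k_plant %.2f)\n",
              x$k_total, x$k_plant))
  cat(sprintf("  symplast %.1f mol, releasable apoplast %.1f mol\n",
              sum(x$v_sym), sum(x$v_apo)))
  invisible(x)
}
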