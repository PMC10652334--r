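# Species trait parameterizations: built-in fixtures for the four study
# species, user CSV loading, validation, and CSV round-tripping.

# Built-in trait tables. Measured TLP and P_gs88 are observational metadata:
# the simulator derives turgor loss from (pi0, epsilon) and stomatal closure
# from the trajectory itself. apoplastic_fraction and symplast_volume_per_area
# are model parameters, not measured traits; defaults below.
.builtin_traits <- list(
  Pin_hale = list(
    species_id = "Pin_hale", leaf_area = 3.64, height = 2.08,
    basal_diameter = 5.7, p50 = -4.67, vc_slope = 78, pi0 = -1.26,
    epsilon = 9.27, tlp_measured = -2.15, gs_max = 60,
    p_gs88_measured = -2.96, g_res = 0.58, t_p = 42.1, q10_a = 1.13,
    q10_b = 2.99, deciduous = FALSE
  ),
  Pop_nigr = list(
    species_id = "Pop_nigr", leaf_area = 1.94, height = 1.24,
    basal_diameter = 1.9, p50 = -2.2, vc_slope = 100, pi0 = -1.52,
    epsilon = 15.9, tlp_measured = -2.07, gs_max = 220,
    p_gs88_measured = -1.14, g_res = 4.5, t_p = 35.0, q10_a = 1.2,
    q10_b = 4.8, deciduous = TRUE,
    shedding_params = list(rate = 4, psi_half = -1.8)
  ),
  Que_ilex = list(
    species_id = "Que_ilex", leaf_area = 1.77, height = 1.49,
    basal_diameter = 3.6, p50 = -7.13, vc_slope = 23, pi0 = -1.89,
    epsilon = 16.2, tlp_measured = -2.83, gs_max = 100,
    p_gs88_measured = -4.04, g_res = 1.19, t_p = 43.2, q10_a = 1.06,
    q10_b = 1.52, deciduous = FALSE
  ),
  Ced_atla = list(
    species_id = "Ced_atla", leaf_area = 1.24, height = 1.14,
    basal_diameter = 3.8, p50 = -5.14, vc_slope = 69, pi0 = -2.14,
    epsilon = 13.0, tlp_measured = -3.14, gs_max = 120,
    p_gs88_measured = -2.57, g_res = 1.21, t_p = 41.3, q10_a = 1.22,
    q10_b = 1.83, deciduous = FALSE
  )
)

.required_trait_fields <- c(
  "species_id", "leaf_area", "height", "basal_diameter", "p50", "vc_slope",
  "pi0", "epsilon", "gs_max", "g_res", "t_p", "q10_a", "q10_b"
)

.numeric_trait_fields <- c(
  "leaf_area", "height", "basal_diameter", "p50", "vc_slope", "pi0",
  "epsilon", "tlp_measured", "gs_max", "p_gs88_measured", "g_res", "t_p",
  "q10_a", "q10_b", "apoplastic_fraction", "symplast_volume_per_area"
)

#' Built-in species identifiers
#'
#' @return Character vector of the four built-in parameterizations.
#' @export
builtin_species <- function() names(.builtin_traits)

new_species_traits <- function(x) {
  # fill documented defaults for optional fields
  if (is.null(x$deciduous)) x$deciduous <- FALSE
  if (isTRUE(x$deciduous) && is.null(x$shedding_params)) {
    x$shedding_params <- list(rate = 4, psi_half = -1.8)
  }
  if (!isTRUE(x$deciduous)) x$shedding_params <- NULL
  if (is.null(x$apoplastic_fraction)) x$apoplastic_fraction <- 0.4
  if (is.null(x$symplast_volume_per_area)) x$symplast_volume_per_area <- 0.1
  if (is.null(x$tlp_measured)) x$tlp_measured <- NA_real_
  if (is.null(x$p_gs88_measured)) x$p_gs88_measured <- NA_real_
  structure(x, class = "species_traits")
}

#' Load a species trait parameterization
#'
#' Either one of the built-in species (`"Pin_hale"`, `"Pop_nigr"`,
#' `"Que_ilex"`, `"Ced_atla"`) or a path to a traits CSV (one header row,
#' one row per species, columns named after the trait fields; the
#' drought-deciduous shedding parameters appear flattened as
#' `shedding_rate` / `shedding_psi_half`). Missing optional columns are
#' filled with documented defaults (`apoplastic_fraction` 0.4,
#' `symplast_volume_per_area` 0.1 L m-2, non-deciduous, shedding constants
#' rate 4 MPa-1 / half-shedding potential -1.8 MPa).
#'
#' @param source Built-in species id, or path to a CSV file.
#' @param species_id When `source` is a multi-row CSV, which row to return
#'   (default: first).
#' @return A validated `species_traits` object.
#' @export
#' @examples
#' tr <- load_species_traits("Pin_hale")
#' tr$p50
load_species_traits <- function(source, species_id = NULL) {
  if (source %in% builtin_species()) {
    tr <- new_species_traits(.builtin_traits[[source]])
  } else {
    if (!file.exists(source)) {
      stop("unknown species id or missing file: ", source, call. = FALSE)
    }
    df <- utils::read.csv(source, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.required_trait_fields, names(df))
    if (length(missing_cols)) {
      stop("traits CSV is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    row <- if (is.null(species_id)) 1L else match(species_id, df$species_id)
    if (is.na(row)) stop("species_id not found in CSV: ", species_id,
                         call. = FALSE)
    tr <- traits_from_row(df[row, , drop = FALSE])
  }
  violations <- validate_traits(tr)
  if (length(violations)) {
    stop("invalid traits: ", paste(violations, collapse = "; "),
         call. = FALSE)
  }
  tr
}

traits_from_row <- function(row) {
  x <- list()
  for (f in c(.required_trait_fields, "tlp_measured", "p_gs88_measured",
              "apoplastic_fraction", "symplast_volume_per_area")) {
    if (f %in% names(row) && !is.na(row[[f]])) {
      val <- row[[f]]
      if (f != "species_id") {
        if (!is.numeric(val)) {
          stop("non-numeric value for required column: ", f, call. = FALSE)
        }
        val <- as.numeric(val)
      }
      x[[f]] <- val
    } else if (f %in% .required_trait_fields) {
      stop("missing value for required column: ", f, call. = FALSE)
    }
  }
  x$deciduous <- isTRUE(as.logical(row$deciduous))
  if (x$deciduous && !is.null(row$shedding_rate) &&
      !is.na(row$shedding_rate)) {
    x$shedding_params <- list(rate = as.numeric(row$shedding_rate),
                              psi_half = as.numeric(row$shedding_psi_half))
  }
  new_species_traits(x)
}

#' Validate a species trait parameterization
#'
#' Checks the sign, ordering and range invariants of the trait set. This is a
#' reporting operation: it never throws.
#'
#' @param t A `species_traits` object (or bare named list).
#' @return Character vector of violations, empty if all invariants hold. Each
#'   entry names the offending field and the rule it breaks.
#' @export
validate_traits <- function(t) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v[[length(v) + 1]] <<- msg
  num_ok <- function(f) is.numeric(t[[f]]) && length(t[[f]]) == 1 &&
    is.finite(t[[f]])
  for (f in setdiff(.required_trait_fields, "species_id")) {
    if (!num_ok(f)) v[[length(v) + 1]] <- paste0(f, ": missing or non-numeric")
  }
  if (length(v)) return(unlist(v))
  chk(t$p50 < 0, "p50: must be negative")
  chk(t$pi0 < 0, "pi0: must be negative")
  chk(t$epsilon > 0, "epsilon: must be positive")
  chk(t$vc_slope > 0, "vc_slope: must be positive")
  chk(t$g_res > 0, "g_res: must be positive")
  chk(t$gs_max > t$g_res, "gs_max: must exceed g_res")
  chk(t$q10_a >= 1, "q10_a: must be >= 1")
  chk(t$q10_b >= 1, "q10_b: must be >= 1")
  chk(t$t_p > 0, "t_p: must be positive")
  chk(t$leaf_area > 0, "leaf_area: must be positive")
  chk(t$height > 0, "height: must be positive")
  chk(t$basal_diameter > 0, "basal_diameter: must be positive")
  if (t$pi0 < 0 && t$epsilon > 0) {
    r_tlp <- 1 + t$pi0 / t$epsilon
    chk(r_tlp > 0 && r_tlp < 1,
        "epsilon: derived turgor-loss point not strictly between pi0 and 0")
  }
  af <- t$apoplastic_fraction
  if (!is.null(af)) chk(af > 0 && af < 1,
                        "apoplastic_fraction: must lie in (0, 1)")
  sv <- t$symplast_volume_per_area
  if (!is.null(sv)) chk(sv > 0, "symplast_volume_per_area: must be positive")
  if (isTRUE(t$deciduous)) {
    chk(!is.null(t$shedding_params),
        "shedding_params: required for deciduous species")
  }
  unlist(v)
}

#' Write one or more trait sets to CSV
#'
#' Emits the traits CSV dialect read by [load_species_traits()] (one row per
#' species, flattened shedding parameters). Round-trips exactly.
#'
#' @param traits A `species_traits` object or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  if (inherits(traits, "species_traits")) traits <- list(traits)
  rows <- lapply(traits, function(t) {
    data.frame(
      species_id = t$species_id, leaf_area = t$leaf_area, height = t$height,
      basal_diameter = t$basal_diameter, p50 = t$p50, vc_slope = t$vc_slope,
      pi0 = t$pi0, epsilon = t$epsilon, tlp_measured = t$tlp_measured,
      gs_max = t$gs_max, p_gs88_measured = t$p_gs88_measured,
      g_res = t$g_res, t_p = t$t_p, q10_a = t$q10_a, q10_b = t$q10_b,
      deciduous = t$deciduous,
      shedding_rate = if (is.null(t$shedding_params)) NA_real_ else
        t$shedding_params$rate,
      shedding_psi_half = if (is.null(t$shedding_params)) NA_real_ else
        t$shedding_params$psi_half,
      apoplastic_fraction = t$apoplastic_fraction,
      symplast_volume_per_area = t$symplast_volume_per_area
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.species_traits <- function(x, ...) {
  cat("<species_traits> ", x$species_id,
      if (x$deciduous) " (deciduous)" else "", "\n", sep = "")
  cat(sprintf("  leaf area %.2f m2, height %.2f m, basal diam %.1f cm\n",
              x$leaf_area, x$height, x$basal_diameter))
  cat(sprintf("  P50 %.2f MPa (slope %g %%/MPa), pi0 %.2f MPa, eps %.2f MPa\n",
              x$p50, x$vc_slope, x$pi0, x$epsilon))
  cat(sprintf("  gs_max %g, g_res %g mmol m-2 s-1; Tp %.1f C, Q10a %g, Q10b %g\n",
              x$gs_max, x$g_res, x$t_p, x$q10_a, x$q10_b))
  cat(sprintf("  derived TLP %.3f MPa\n",
              turgor_loss_point(x$pi0, x$epsilon)))
  invisible(x)
}
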