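# Variance-based global sensitivity analysis: quasi-random Saltelli design
# over trait perturbation ranges, Jansen total-order estimator with bootstrap
# confidence intervals, and the trait-to-dehydration-time driver.

# Halton low-discrepancy sequence (first `dim` prime bases), with a seeded
# Cranley-Patterson random shift modulo 1 so designs are reproducible yet
# decorrelated across seeds.
.halton <- function(n, dim, seed = NULL) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113,
              127, 131, 137, 139, 149, 151, 157, 163, 167, 173, 179, 181,
              191, 193, 197, 199, 211, 223, 227, 229)
  if (dim > length(primes)) stop("too many dimensions", call. = FALSE)
  radical_inverse <- function(i, base) {
    # vectorized over i
    out <- numeric(length(i))
    f <- 1 / base
    while (any(i > 0)) {
      out <- out + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    out
  }
  m <- vapply(primes[seq_len(dim)],
              function(p) radical_inverse(seq_len(n) + 20L, p),
              numeric(n)) # skip the first points (Halton burn-in)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    shift <- stats::runif(dim)
    m <- sweep(m, 2, shift, "+") %% 1
  }
  m
}

#' Saltelli sampling design for Sobol indices
#'
#' Builds the base matrices `A` and `B` from a seeded, randomly shifted
#' Halton low-discrepancy sequence in `2k` dimensions, plus the `k` hybrid
#' matrices `AB_i` (`A` with column `i` taken from `B`). Parameter `i` of
#' every row lies in `base_i` plus or minus `bounds * |base_i|`. Total model
#' evaluations: `N * (k + 2)`.
#'
#' @param params Character vector of parameter names (length `k`).
#' @param base Named numeric vector of base values (one per parameter).
#' @param bounds Half-width of the sampling range as a fraction of the base
#'   value (default 0.10).
#' @param N Sample size per matrix; a power of 2.
#' @param seed Integer seed; the design is reproducible given the seed.
#' @param lower,upper Optional absolute range limits (named or positional,
#'   one per parameter) overriding the fractional `bounds`.
#' @return A list of class `sobol_design` with `params`, `base`, `bounds`,
#'   `N`, `seed`, matrices `A`, `B`, list `AB`, and the stacked evaluation
#'   matrix `X` (`N*(k+2)` rows in order `A`, `B`, `AB_1 ... AB_k`).
#' @export
#' @examples
#' d <- saltelli_design(c("a", "b", "c"), c(a = 1, b = 2, c = 3), N = 8,
#'                      seed = 1)
#' nrow(d$X) # 8 * (3 + 2)
saltelli_design <- function(params, base, bounds = 0.10, N, seed = 1,
                            lower = NULL, upper = NULL) {
  k <- length(params)
  stopifnot(k >= 1, length(base) == k, bounds > 0)
  if (N < 2 || bitwAnd(as.integer(N), as.integer(N) - 1L) != 0) {
    stop("N must be a power of 2", call. = FALSE)
  }
  base <- stats::setNames(as.numeric(base), params)
  u <- .halton(N, 2 * k, seed = seed)
  lo <- if (is.null(lower)) base - bounds * abs(base) else
    stats::setNames(as.numeric(lower), params)
  hi <- if (is.null(upper)) base + bounds * abs(base) else
    stats::setNames(as.numeric(upper), params)
  if (any(hi <= lo)) stop("upper bounds must exceed lower bounds",
                          call. = FALSE)
  scale_cols <- function(m) {
    sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
  }
  A <- scale_cols(u[, seq_len(k), drop = FALSE])
  B <- scale_cols(u[, k + seq_len(k), drop = FALSE])
  colnames(A) <- colnames(B) <- params
  AB <- lapply(seq_len(k), function(i) {
    m <- A
    m[, i] <- B[, i]
    m
  })
  X <- do.call(rbind, c(list(A, B), AB))
  structure(
    list(params = params, base = base, bounds = bounds, N = N, seed = seed,
         A = A, B = B, AB = AB, X = X),
    class = "sobol_design"
  )
}

#' Sobol total-order indices from model evaluations over a Saltelli design
#'
#' Jansen estimator,
#' `S_Ti = (1/(2N)) * sum_j (f(A_j) - f(AB_i,j))^2 / Var(f)`, with the
#' variance taken over the `A` and `B` evaluations. Non-finite outputs
#' (failed runs) are imputed by the median response, provided they are fewer
#' than `max_failed_frac` of all rows; bootstrap confidence intervals are
#' computed by resampling design rows.
#'
#' @param y Numeric vector of model outputs, length `N*(k+2)`, ordered as
#'   the design's evaluation matrix (`A`, `B`, `AB_1 ... AB_k`).
#' @param design The `sobol_design` the outputs came from.
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param max_failed_frac Largest tolerated fraction of non-finite outputs
#'   (default 0.1).
#' @return A data frame of class `sobol_result`: `parameter`, `s_t`,
#'   `ci_low`, `ci_high`, plus attributes `N`, `n_failed`, `variance`.
#' @export
sobol_total_indices <- function(y, design, n_boot = 200, conf = 0.95,
                                max_failed_frac = 0.1) {
  stopifnot(inherits(design, "sobol_design"))
  k <- length(design$params)
  N <- design$N
  if (length(y) != N * (k + 2)) {
    stop("output length does not match the design", call. = FALSE)
  }
  bad <- !is.finite(y)
  n_failed <- sum(bad)
  if (n_failed > max_failed_frac * length(y)) {
    stop(sprintf(
      "%d of %d runs failed (> %.0f%%): design too wide or model unstable",
      n_failed, length(y), 100 * max_failed_frac), call. = FALSE)
  }
  if (n_failed) y[bad] <- stats::median(y[!bad])
  fA <- y[seq_len(N)]
  fAB <- matrix(y[2 * N + seq_len(N * k)], nrow = N, ncol = k)
  vy <- stats::var(y[seq_len(2 * N)])
  st_of <- function(rows) {
    v <- stats::var(c(fA[rows], y[N + rows]))
    if (v <= 0) return(rep(NA_real_, k))
    colMeans((fA[rows] - fAB[rows, , drop = FALSE])^2) / (2 * v)
  }
  s_t <- st_of(seq_len(N))
  boot <- matrix(NA_real_, n_boot, k)
  for (b in seq_len(n_boot)) {
    boot[b, ] <- st_of(sample.int(N, N, replace = TRUE))
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  structure(
    data.frame(parameter = design$params, s_t = s_t, ci_low = ci[1, ],
               ci_high = ci[2, ], row.names = NULL),
    class = c("sobol_result", "data.frame"),
    N = N, n_failed = n_failed, variance = vy
  )
}

# Default perturbation set: every hydraulic trait that the dehydration
# metrics can respond to at desk scale, plus the two storage parameters and
# whole-plant conductance.
.default_sensitivity_params <- c(
  "pi0", "epsilon", "gs_max", "g_res", "q10_a", "q10_b", "t_p", "p50",
  "vc_slope", "apoplastic_fraction", "symplast_volume_per_area", "k_plant"
)

#' Trait sensitivity of dehydration times
#'
#' Runs one dry-down simulation per Saltelli design row with the selected
#' traits perturbed within `bounds` of their base values, extracts
#' `t_close`, `t_cav` and `thf` from every trajectory, and returns Sobol
#' total-order indices per metric. Plant size (leaf area, height, basal
#' diameter) and pot volume are standardized, and the climate is the
#' constant synthetic summer day, so variance comes from traits alone. Runs
#' that never reach closure or failure yield non-finite metrics and are
#' imputed (with a reported count) by [sobol_total_indices()].
#'
#' @param traits Base `species_traits` (or built-in id).
#' @param params Traits to perturb (default: the 12-parameter set of
#'   `pi0`, `epsilon`, `gs_max`, `g_res`, `q10_a`, `q10_b`, `t_p`, `p50`,
#'   `vc_slope`, `apoplastic_fraction`, `symplast_volume_per_area`,
#'   `k_plant`).
#' @param N Saltelli sample size (power of 2).
#' @param seed Design seed.
#' @param bounds Perturbation half-width (fraction; default 0.10).
#' @param climate A `climate_series`, or `NULL` for the synthetic summer
#'   default covering `options$max_days`.
#' @param options A `sim_options`.
#' @param leaf_area,height,basal_diameter,pot_volume Standardized plant size
#'   and pot (defaults 1.5 m2, 1.5 m, 3 cm, 25 L).
#' @param k_plant Base whole-plant conductance per leaf area
#'   (mmol s-1 m-2 MPa-1; default 1.5).
#' @param n_boot Bootstrap replicates for the index confidence intervals.
#' @return A list of class `sensitivity_result` with one `sobol_result` per
#'   metric (`t_close`, `t_cav`, `thf`), the design, and per-metric failed
#'   counts.
#' @export
run_sensitivity <- function(traits, params = .default_sensitivity_params,
                            N = 128, seed = 1, bounds = 0.10,
                            climate = NULL, options = sim_options(),
                            leaf_area = 1.5, height = 1.5,
                            basal_diameter = 3, pot_volume = 25,
                            k_plant = 1.5, n_boot = 200) {
  if (is.character(traits)) traits <- load_species_traits(traits)
  if (is.null(climate)) climate <- synthesize_climate(options$max_days)
  base_all <- c(
    pi0 = traits$pi0, epsilon = traits$epsilon, gs_max = traits$gs_max,
    g_res = traits$g_res, q10_a = traits$q10_a, q10_b = traits$q10_b,
    t_p = traits$t_p, p50 = traits$p50, vc_slope = traits$vc_slope,
    apoplastic_fraction = traits$apoplastic_fraction,
    symplast_volume_per_area = traits$symplast_volume_per_area,
    k_plant = k_plant
  )
  unknown <- setdiff(params, names(base_all))
  if (length(unknown)) {
    stop("unknown sensitivity parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  design <- saltelli_design(params, base_all[params], bounds = bounds,
                            N = N, seed = seed)
  soil <- soil_params(pot_volume = pot_volume)
  tr <- traits
  tr$leaf_area <- leaf_area
  tr$height <- height
  tr$basal_diameter <- basal_diameter

  n_rows <- nrow(design$X)
  y <- matrix(NA_real_, n_rows, 3,
              dimnames = list(NULL, c("t_close", "t_cav", "thf")))
  for (j in seq_len(n_rows)) {
    row <- design$X[j, ]
    trj <- tr
    for (p in setdiff(params, "k_plant")) trj[[p]] <- unname(row[[p]])
    kp <- if ("k_plant" %in% params) unname(row[["k_plant"]]) else k_plant
    m <- tryCatch(suppressWarnings({
      net <- build_fractal_tree(trj, k_plant = kp)
      traj <- run_dehydration(trj, network = net, soil = soil,
                              climate = climate, options = options)
      dehydration_times(traj, trj)
    }), error = function(e) NULL)
    if (!is.null(m)) {
      y[j, ] <- c(m$t_close, m$t_cav, m$thf)
    }
  }
  res <- lapply(colnames(y), function(metric) {
    sobol_total_indices(y[, metric], design, n_boot = n_boot)
  })
  names(res) <- colnames(y)
  structure(
    list(indices = res, design = design,
         n_failed = vapply(res, attr, numeric(1), "n_failed"),
         species_id = traits$species_id),
    class = "sensitivity_result"
  )
}

#' Parameters ranked by total-order index for one metric
#'
#' @param result A `sensitivity_result`.
#' @param metric One of `"t_close"`, `"t_cav"`, `"thf"`.
#' @return The metric's `sobol_result` rows sorted by decreasing `s_t`.
#' @export
rank_sensitivity <- function(result, metric = "thf") {
  r <- result$indices[[metric]]
  r[order(r$s_t, decreasing = TRUE), ]
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>", x$species_id, "\n")
  for (m in names(x$indices)) {
    top <- rank_sensitivity(x, m)
    cat(sprintf("  %s: top %s (S_T = %.2f), %d failed run(s)\n", m,
                top$parameter[1], top$s_t[1], x$n_failed[[m]]))
  }
  invisible(x)
}

#' Write Sobol indices to CSV
#'
#' One row per metric x parameter: `metric`, `parameter`, `s_t`, `ci_low`,
#' `ci_high`, `N`, `seed`.
#'
#' @param result A `sensitivity_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(result, path) {
  rows <- lapply(names(result$indices), function(m) {
    r <- result$indices[[m]]
    data.frame(metric = m, parameter = r$parameter, s_t = r$s_t,
               ci_low = r$ci_low, ci_high = r$ci_high,
               N = attr(r, "N"), seed = result$design$seed)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
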