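# Trait extraction from raw measurement series: midday transpiration from
# balance mass, Weibull closure-point fit, pressure-volume analysis, residual
# conductance from drought-box decays, and the two-segment Arrhenius
# temperature response.

#' Midday transpiration from a balance mass series
#'
#' Least-squares slope of pot mass over the midday window of each day,
#' normalized by canopy leaf area. The slope over all in-window samples is
#' robust to coarse balance quantization.
#'
#' @param mass Data frame with columns `timestamp` (hours since start) and
#'   `mass` (g).
#' @param leaf_area Canopy leaf area (m2, > 0).
#' @param window Window width (h) centred on 13:00 (default 2, i.e.
#'   12:00-14:00).
#' @param quantum Balance resolution (g; default 50), used to flag days with
#'   apparent mass gain beyond quantization (watering or disturbance).
#' @return Data frame with `day`, `e_midday` (mmol m-2 s-1) and `flagged`.
#' @export
#' @examples
#' m <- data.frame(timestamp = c(12, 14), mass = c(10000, 9964))
#' midday_transpiration_from_mass(m, leaf_area = 1)$e_midday # 0.2775
midday_transpiration_from_mass <- function(mass, leaf_area, window = 2,
                                           quantum = 50) {
  stopifnot(leaf_area > 0, window > 0)
  day <- floor(mass$timestamp / 24)
  hour <- mass$timestamp - day * 24
  lo <- 13 - window / 2
  hi <- 13 + window / 2
  out <- lapply(sort(unique(day)), function(d) {
    sel <- which(day == d & hour >= lo & hour <= hi)
    if (length(sel) < 2) return(NULL)
    t_s <- mass$timestamp[sel] * 3600
    m_g <- mass$mass[sel]
    slope <- unname(stats::coef(stats::lm(m_g ~ t_s))[2]) # g s-1
    flagged <- slope > 0 && (m_g[length(m_g)] - m_g[1]) > quantum
    e <- -slope / 18.015 / leaf_area * 1000 # mmol m-2 s-1
    data.frame(day = d, e_midday = if (flagged) NA_real_ else e,
               flagged = flagged)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Fit the Weibull closure curve to midday E versus water potential
#'
#' Fits `E(psi) = Emax * exp(-((-psi)/b)^c)` (Weibull on tension, so
#' `b > 0`) by nonlinear least squares with a multi-start grid on `(b, c)`,
#' and reports the water potential at an 88% reduction of the fitted `Emax`:
#' `P_gs88 = -b * (-log(0.12))^(1/c)`.
#'
#' @param psi Midday water potentials (MPa, <= 0).
#' @param e Midday transpiration (same length as `psi`).
#' @param reduction Fractional reduction defining the closure point
#'   (default 0.88).
#' @return List of class `pgs88_fit`: `emax`, `b`, `c`, `p_gs88`, `rmse`.
#' @export
fit_pgs88 <- function(psi, e, reduction = 0.88) {
  keep <- is.finite(psi) & is.finite(e)
  psi <- psi[keep]; e <- e[keep]
  if (length(psi) < 6) stop("need at least 6 (psi, E) points", call. = FALSE)
  if (stats::sd(e) < 1e-12 * max(abs(e), 1)) {
    stop("degenerate data: all E equal", call. = FALSE)
  }
  tension <- -psi
  df <- data.frame(tension = tension, e = e)
  emax0 <- max(e)
  starts <- expand.grid(
    b = stats::quantile(tension[tension > 0], c(0.25, 0.5, 0.75),
                        names = FALSE),
    c = c(1, 2, 4, 8)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        e ~ emax * exp(-(tension / b)^c), data = df,
        start = list(emax = emax0, b = starts$b[i], c = starts$c[i]),
        lower = c(emax = 1e-9, b = 1e-6, c = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Weibull fit did not converge from any start",
                          call. = FALSE)
  p <- as.list(stats::coef(best$fit))
  structure(
    list(
      emax = p$emax, b = p$b, c = p$c,
      p_gs88 = -p$b * (-log(1 - reduction))^(1 / p$c),
      rmse = sqrt(best$rss / length(e))
    ),
    class = "pgs88_fit"
  )
}

#' Pressure-volume curve analysis
#'
#' Standard `-1/psi` versus water deficit analysis of a bench-dehydration
#' curve: the post-turgor-loss segment is linear in `1 - RWC` and its
#' extrapolation to full hydration gives the osmotic potential at full
#' turgor; the bulk modulus comes from the slope of turgor against RWC over
#' the pre-turgor-loss points; the turgor loss point is derived as
#' `pi0 / (1 + pi0/epsilon)`. The segment split is chosen by maximizing the
#' linearity (r-squared) of the post-TLP segment. Point order does not
#' matter.
#'
#' @param rwc Relative water contents in (0, 1].
#' @param psi Water potentials (MPa, < 0), same length.
#' @return List of class `pv_fit`: `pi0`, `epsilon`, `tlp`, `split_rwc`,
#'   `r_squared_tail`.
#' @export
fit_pressure_volume <- function(rwc, psi) {
  keep <- is.finite(rwc) & is.finite(psi) & psi < 0
  rwc <- rwc[keep]; psi <- psi[keep]
  if (length(rwc) < 8) stop("need at least 8 pressure-volume points",
                            call. = FALSE)
  ord <- order(rwc, decreasing = TRUE)
  rwc <- rwc[ord]; psi <- psi[ord]
  x <- 1 - rwc
  y <- -1 / psi
  n <- length(x)
  best <- NULL
  for (s in 4:(n - 3)) { # tail s..n, at least 4 points each side
    sel <- s:n
    fit <- stats::lm(y[sel] ~ x[sel])
    sst <- sum((y[sel] - mean(y[sel]))^2)
    r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 0
    if (is.null(best) || r2 > best$r2) best <- list(s = s, r2 = r2, fit = fit)
  }
  if (is.null(best) || best$r2 < 0.8) {
    stop("no linear post-turgor-loss tail detectable", call. = FALSE)
  }
  a <- unname(stats::coef(best$fit)[1])
  pi0 <- -1 / a
  # turgor over the pre-TLP points, against RWC
  pre <- seq_len(best$s - 1)
  osmotic <- pi0 / rwc[pre]
  turgor <- psi[pre] - osmotic
  fit_t <- stats::lm(turgor ~ rwc[pre])
  epsilon <- unname(stats::coef(fit_t)[2])
  if (!is.finite(epsilon) || epsilon <= 0) {
    stop("pre-turgor-loss segment has no positive elastic slope",
         call. = FALSE)
  }
  structure(
    list(pi0 = pi0, epsilon = epsilon,
         tlp = pi0 / (1 + pi0 / epsilon),
         split_rwc = rwc[best$s], r_squared_tail = best$r2),
    class = "pv_fit"
  )
}

#' Residual conductance from a drought-box mass decay
#'
#' Detects the post-stomatal-closure phase as the longest terminal window
#' with a stable mass-loss slope (relative change between the window's two
#' halves below `stability`), then normalizes the loss rate by vapour
#' pressure deficit over atmospheric pressure and by the evaporating surface
#' area (double-sided leaf area plus stem cylinder for broadleaves,
#' projected leaf area plus stem for conifers).
#'
#' @param time Sample times (h).
#' @param mass Branch mass (g), same length.
#' @param t_air,rh Drought-box air temperature (degrees C) and relative
#'   humidity (%): scalars or series aligned with `time`.
#' @param leaf_area Projected leaf area (m2).
#' @param stem_area Stem cylinder surface area (m2).
#' @param double_sided Use double-sided leaf area (broadleaf convention)?
#' @param stability Relative slope-change threshold (default 0.1).
#' @param patm Atmospheric pressure (kPa; default 101.3).
#' @return List of class `gres_fit`: `g_res` (mmol m-2 s-1), `window_start`
#'   (h), `slope` (g h-1), `vpd` (kPa), `area` (m2).
#' @export
fit_residual_conductance <- function(time, mass, t_air, rh, leaf_area,
                                     stem_area = 0, double_sided = FALSE,
                                     stability = 0.1, patm = 101.3) {
  n <- length(time)
  stopifnot(length(mass) == n, n >= 6, leaf_area > 0)
  vpd_series <- vapour_pressure_deficit(t_air, rh)
  if (all(vpd_series <= 0)) {
    stop("VPD is zero: residual conductance undefined", call. = FALSE)
  }
  slope_of <- function(sel) {
    unname(stats::coef(stats::lm(mass[sel] ~ time[sel]))[2])
  }
  window <- NULL
  for (i in seq_len(n - 5)) { # longest terminal window first
    sel <- i:n
    mid <- i + floor(length(sel) / 2)
    s_full <- slope_of(sel)
    s1 <- slope_of(i:mid)
    s2 <- slope_of(mid:n)
    if (is.finite(s_full) && s_full < 0 &&
        abs(s1 - s2) / abs(s_full) < stability) {
      window <- list(start = i, slope = s_full)
      break
    }
  }
  if (is.null(window)) stop("no stable terminal phase found", call. = FALSE)
  sel <- window$start:n
  vpd <- if (length(vpd_series) == 1) vpd_series else mean(vpd_series[sel])
  area <- (if (double_sided) 2 else 1) * leaf_area + stem_area
  loss_mmol_s <- -window$slope / 3600 / 18.015 * 1000
  structure(
    list(g_res = loss_mmol_s / (vpd / patm) / area,
         window_start = time[window$start], slope = window$slope,
         vpd = vpd, area = area),
    class = "gres_fit"
  )
}

#' Two-segment Arrhenius fit of the residual-conductance temperature response
#'
#' Fits `ln(g_res)` against inverse absolute temperature with a breakpoint
#' chosen by exhaustively minimizing the total sum of squares over interior
#' candidate splits (at least two points per side). The phase-transition
#' temperature is the intersection of the two segments; each segment's
#' Arrhenius slope is converted to a Q10 at the segment's mean temperature
#' (`Q10 = exp(-10 m / T_bar^2)` with `m` the slope against 1/T in Kelvin).
#'
#' @param t_c Temperature levels (degrees C, >= 5 values).
#' @param g_res Residual conductance at each level (mmol m-2 s-1, > 0).
#' @param q10_tol Relative tolerance on slope separation below which the
#'   breakpoint is declared indeterminate (default 0.15, sized so that the
#'   curvature of a single-Q10 response on the Arrhenius axis over a
#'   30-55 degC span is not mistaken for a phase transition).
#' @return List of class `tp_fit`: `t_p` (degrees C, `NA` if indeterminate),
#'   `q10_a`, `q10_b`, `indeterminate`.
#' @export
fit_temperature_response <- function(t_c, g_res, q10_tol = 0.15) {
  keep <- is.finite(t_c) & is.finite(g_res) & g_res > 0
  t_c <- t_c[keep]; g_res <- g_res[keep]
  ord <- order(t_c)
  t_c <- t_c[ord]; g_res <- g_res[ord]
  n <- length(t_c)
  if (n < 5) stop("need at least 5 temperature levels", call. = FALSE)
  x <- 1 / (t_c + 273.15)
  y <- log(g_res)
  best <- NULL
  for (k in 2:(n - 2)) { # lower segment 1..k, upper (k+1)..n
    f1 <- stats::lm(y[1:k] ~ x[1:k])
    f2 <- stats::lm(y[(k + 1):n] ~ x[(k + 1):n])
    sse <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
    if (is.null(best) || sse < best$sse) best <- list(k = k, sse = sse,
                                                     f1 = f1, f2 = f2)
  }
  c1 <- stats::coef(best$f1); c2 <- stats::coef(best$f2)
  m1 <- unname(c1[2]); m2 <- unname(c2[2])
  tbar1 <- mean(t_c[1:best$k]) + 273.15
  tbar2 <- mean(t_c[(best$k + 1):n]) + 273.15
  q10_a <- exp(-10 * m1 / tbar1^2)
  q10_b <- exp(-10 * m2 / tbar2^2)
  indeterminate <- abs(m1 - m2) < q10_tol * max(abs(m1), abs(m2), 1)
  t_p <- if (indeterminate) NA_real_ else {
    x_star <- (unname(c2[1]) - unname(c1[1])) / (m1 - m2)
    1 / x_star - 273.15
  }
  if (!indeterminate && (!is.finite(t_p) || t_p < min(t_c) - 10 ||
                         t_p > max(t_c) + 10)) {
    indeterminate <- TRUE
    t_p <- NA_real_
  }
  structure(
    list(t_p = t_p, q10_a = q10_a, q10_b = q10_b,
         indeterminate = indeterminate),
    class = "tp_fit"
  )
}
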