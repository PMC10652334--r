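# Dehydration-time metrics extracted from simulated trajectories, daily
# predawn/midday summaries, and model-vs-observation fit reports.

#' Daily predawn and midday summaries of a trajectory
#'
#' Predawn is the 05:00 sample; midday values are means over 12:00-14:00
#' (the two hours around midday). Midday transpiration is the total loss
#' rate, canopy plus residual, as a balance would record it.
#'
#' @param traj A `sim_trajectory` (hourly).
#' @return Data frame with columns `day`, `predawn_psi`, `midday_psi`
#'   (MPa) and `midday_e` (mmol s-1). Days missing the required hours are
#'   skipped with a warning.
#' @export
daily_extremes <- function(traj) {
  df <- as.data.frame(traj)
  day <- floor(df$time / 24)
  hour <- df$time - day * 24
  out <- lapply(sort(unique(day)), function(d) {
    sel_pd <- which(day == d & hour == 5)
    sel_md <- which(day == d & hour >= 12 & hour <= 14)
    if (!length(sel_pd) || length(sel_md) < 3) return(NULL)
    data.frame(
      day = d,
      predawn_psi = df$psi_leaf[sel_pd[1]],
      midday_psi = mean(df$psi_leaf[sel_md]),
      midday_e = mean(df$e_canopy[sel_md] + df$e_residual[sel_md])
    )
  })
  skipped <- sum(vapply(out, is.null, logical(1)))
  if (skipped > 1) { # last day is usually partial; more than that is notable
    warning(skipped, " day(s) skipped for missing hours")
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Dehydration-time metrics of a dry-down trajectory
#'
#' Stomatal closure is the trajectory-relative water potential at an 88%
#' reduction of midday transpiration from its trajectory maximum (the
#' operational closure-point convention); hydraulic failure is the water
#' potential at 99% loss of leaf hydraulic conductivity on the species
#' vulnerability curve. Crossing times are linearly interpolated.
#'
#' @param traj A `sim_trajectory` starting from full hydration.
#' @param traits The `species_traits` used for the run (default: taken from
#'   the trajectory attributes).
#' @param close_fraction Fractional reduction of midday E defining closure
#'   (default 0.88).
#' @param fail_plc Leaf PLC (%) defining hydraulic failure (default 99).
#' @return A list of class `dehydration_metrics`: `t_close`, `t_cav`, `thf`
#'   (days), `psi_close`, `psi_fail`, `psi_min` (MPa), and the reached flags
#'   `closure_reached`, `failure_reached`. `t_cav` and `thf` are `NA` when
#'   failure is not reached.
#' @export
dehydration_times <- function(traj, traits = attr(traj, "traits"),
                              close_fraction = 0.88, fail_plc = 99) {
  df <- as.data.frame(traj)
  daily <- daily_extremes(traj)
  if (is.null(daily) || nrow(daily) < 2) {
    stop("trajectory too short for dehydration metrics", call. = FALSE)
  }
  e <- daily$midday_e
  thr <- (1 - close_fraction) * max(e)
  t_mid <- daily$day + 13 / 24 # centre of the midday window, days

  idx <- which(e[-1] <= thr & e[-length(e)] > thr)
  closure_reached <- length(idx) > 0
  if (closure_reached) {
    i <- idx[1]
    f <- (e[i] - thr) / (e[i] - e[i + 1])
    t_close <- t_mid[i] + f * (t_mid[i + 1] - t_mid[i])
    psi_close <- daily$midday_psi[i] +
      f * (daily$midday_psi[i + 1] - daily$midday_psi[i])
  } else {
    t_close <- NA_real_
    psi_close <- NA_real_
  }

  psi_fail <- psi_at_plc(fail_plc, traits$p50, traits$vc_slope)
  t_day <- df$time / 24
  j <- which(df$psi_leaf[-1] <= psi_fail & df$psi_leaf[-nrow(df)] > psi_fail)
  failure_reached <- length(j) > 0
  if (failure_reached) {
    i <- j[1]
    f <- (df$psi_leaf[i] - psi_fail) / (df$psi_leaf[i] - df$psi_leaf[i + 1])
    t_fail <- t_day[i] + f * (t_day[i + 1] - t_day[i])
  } else {
    t_fail <- NA_real_
  }

  structure(
    list(
      t_close = t_close,
      t_cav = if (failure_reached && closure_reached) t_fail - t_close
              else NA_real_,
      thf = if (failure_reached) t_fail else NA_real_,
      psi_min = min(df$psi_leaf),
      psi_close = psi_close,
      psi_fail = psi_fail,
      closure_reached = closure_reached,
      failure_reached = failure_reached
    ),
    class = "dehydration_metrics"
  )
}

#' @export
print.dehydration_metrics <- function(x, ...) {
  cat("<dehydration_metrics>\n")
  cat(sprintf("  T_close %.2f d (psi_close %.2f MPa)%s\n", x$t_close,
              x$psi_close,
              if (!x$closure_reached) " [closure not reached]" else ""))
  cat(sprintf("  T_cav %.2f d, THF %.2f d (psi_fail %.2f MPa)%s\n", x$t_cav,
              x$thf, x$psi_fail,
              if (!x$failure_reached) " [failure not reached]" else ""))
  invisible(x)
}

#' Write per-run dehydration metrics to CSV
#'
#' @param metrics A `dehydration_metrics` or named list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  if (inherits(metrics, "dehydration_metrics")) metrics <- list(run = metrics)
  rows <- lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(run = nm, t_close = m$t_close, t_cav = m$t_cav, thf = m$thf,
               psi_min = m$psi_min, psi_close = m$psi_close,
               psi_fail = m$psi_fail, closure_reached = m$closure_reached,
               failure_reached = m$failure_reached)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Compare modelled daily water potentials with observations
#'
#' Matches modelled and observed daily predawn/midday water potentials by
#' day and reports root-mean-square error, mean bias (observed minus
#' modelled) and the concordance slope (regression of modelled on observed),
#' overall and - when a closure time is supplied - per drought phase.
#'
#' @param model Daily series from [daily_extremes()].
#' @param observed An `observation_set` (see [generate_observed_dataset()])
#'   or a data frame with columns `day`, `predawn` and `midday`.
#' @param t_close Optional closure time (days) splitting the pre-closure and
#'   post-closure phases.
#' @return Data frame of class `fit_report` with one row per variable x
#'   phase: `variable`, `phase`, `n`, `rmse`, `bias`, `slope`.
#' @export
compare_to_observations <- function(model, observed, t_close = NULL) {
  obs <- if (inherits(observed, "observation_set")) observed$psi else observed
  merged <- merge(model, obs, by = "day")
  if (!nrow(merged)) stop("no overlapping days", call. = FALSE)
  phases <- list(all = rep(TRUE, nrow(merged)))
  if (!is.null(t_close)) {
    phases$pre_closure <- merged$day <= t_close
    phases$post_closure <- merged$day > t_close
  }
  stats_for <- function(m, o) {
    keep <- is.finite(m) & is.finite(o)
    m <- m[keep]; o <- o[keep]
    n <- length(m)
    if (!n) return(c(n = 0, rmse = NA, bias = NA, slope = NA))
    slope <- if (n >= 2 && stats::sd(o) > 0) {
      unname(stats::coef(stats::lm(m ~ o))[2])
    } else NA_real_
    c(n = n, rmse = sqrt(mean((m - o)^2)), bias = mean(o - m), slope = slope)
  }
  rows <- list()
  for (ph in names(phases)) {
    sel <- phases[[ph]]
    for (v in c("predawn", "midday")) {
      mod_col <- paste0(v, "_psi")
      s <- stats_for(merged[[mod_col]][sel], merged[[v]][sel])
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, phase = ph, n = s["n"], rmse = s["rmse"],
        bias = s["bias"], slope = s["slope"], row.names = NULL
      )
    }
  }
  structure(do.call(rbind, rows), class = c("fit_report", "data.frame"))
}
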