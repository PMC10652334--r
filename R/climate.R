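# Hourly atmospheric forcing: CSV reader (with short-gap interpolation) and a
# synthetic diurnal generator for standardized simulations.

new_climate_series <- function(df) {
  df$vpd <- vapour_pressure_deficit(df$t_air, df$rh)
  structure(df, class = c("climate_series", "data.frame"))
}

#' Read an hourly climate series from CSV
#'
#' Expected columns: `time` (hours since start, strictly increasing),
#' `t_air` (degrees C), `rh` (%), `par` (umol m-2 s-1), `wind` (m s-1).
#' Gaps of up to `max_gap` hours are filled by linear interpolation; longer
#' gaps are rejected. VPD is derived from temperature and humidity.
#'
#' @param path CSV file path.
#' @param max_gap Longest gap (h) to fill by interpolation (default 3).
#' @return A `climate_series` data frame with a derived `vpd` column (kPa).
#' @export
read_climate_csv <- function(path, max_gap = 3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time", "t_air", "rh", "par", "wind")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("climate CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(diff(df$time) <= 0)) {
    stop("climate time column must be strictly increasing", call. = FALSE)
  }
  bad_rh <- which(df$rh < 0 | df$rh > 100)
  if (length(bad_rh)) {
    stop("relative humidity out of [0, 100] at row(s) ",
         paste(bad_rh, collapse = ", "), call. = FALSE)
  }
  gaps <- diff(df$time)
  if (any(gaps > max_gap)) {
    stop("climate gap longer than ", max_gap, " h at time ",
         df$time[which(gaps > max_gap)[1]], call. = FALSE)
  }
  if (any(gaps > 1)) {
    full_time <- seq(min(df$time), max(df$time), by = 1)
    df <- data.frame(
      time = full_time,
      t_air = stats::approx(df$time, df$t_air, full_time)$y,
      rh = stats::approx(df$time, df$rh, full_time)$y,
      par = stats::approx(df$time, df$par, full_time)$y,
      wind = stats::approx(df$time, df$wind, full_time)$y
    )
  }
  new_climate_series(df[, needed])
}

#' Write a climate series to CSV
#'
#' Emits the dialect read by [read_climate_csv()] (derived `vpd` omitted).
#'
#' @param climate A `climate_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  utils::write.csv(
    as.data.frame(climate)[, c("time", "t_air", "rh", "par", "wind")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Synthesize a repeating diurnal climate
#'
#' A standardized "summer's day" repeated identically every day: temperature
#' follows two half-sinusoids with the minimum at 05:00 and maximum at 15:00;
#' relative humidity moves in antiphase between its bounds; PAR is a half
#' sine between 06:00 and 20:00; wind is constant. With `noise_sd = 0`
#' (default) the series is fully deterministic and every day is identical.
#'
#' @param days Number of days.
#' @param t_min,t_max Daily temperature extremes (degrees C; defaults 15, 32).
#' @param rh_min,rh_max Humidity bounds (%; defaults 30, 80). `rh_max` holds
#'   at the temperature minimum.
#' @param par_max Midday PAR peak (umol m-2 s-1; default 1800).
#' @param wind Constant wind speed (m s-1; default 1).
#' @param noise_sd Optional Gaussian temperature noise (degrees C; default 0).
#' @param seed Seed for the optional noise.
#' @return A `climate_series` with `24 * days` hourly records.
#' @export
#' @examples
#' cl <- synthesize_climate(2)
#' max(cl$t_air)
synthesize_climate <- function(days, t_min = 15, t_max = 32, rh_min = 30,
                               rh_max = 80, par_max = 1800, wind = 1,
                               noise_sd = 0, seed = NULL) {
  if (t_min > t_max || rh_min > rh_max || rh_min < 0 || rh_max > 100) {
    stop("invalid climate bounds", call. = FALSE)
  }
  hour <- seq(0, 24 * days - 1)
  h <- hour %% 24
  t_mid <- (t_min + t_max) / 2
  t_amp <- (t_max - t_min) / 2
  # rising limb 05-15 h (10 h), falling limb 15-05 h (14 h)
  t_air <- ifelse(
    h >= 5 & h <= 15,
    t_mid - t_amp * cos(pi * (h - 5) / 10),
    t_mid + t_amp * cos(pi * ((h - 15) %% 24) / 14)
  )
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    t_air <- t_air + stats::rnorm(length(t_air), 0, noise_sd)
  }
  frac <- (t_air - t_min) / max(t_max - t_min, 1e-9)
  rh <- pmin(pmax(rh_max - (rh_max - rh_min) * frac, 0), 100)
  par <- ifelse(h >= 6 & h <= 20, par_max * sin(pi * (h - 6) / 14), 0)
  par <- pmax(par, 0)
  new_climate_series(data.frame(
    time = hour, t_air = t_air, rh = rh, par = par, wind = wind
  ))
}
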