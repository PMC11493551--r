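#' Season of a simulation day
#'
#' Day 1 is 1 January of simulation year 1; years are 365 days (no leap
#' days). Under the tropical savannah calendar rule the wet season runs
#' November through April, i.e. day-of-year 305-365 and 1-120.
#'
#' @param day 1-based simulation day (vectorised).
#' @return character vector, `"wet"` or `"dry"`.
#' @export
season_of_day <- function(day) {
  doy <- day_of_year(day)
  ifelse(doy >= 305 | doy <= 120, "wet", "dry")
}

#' @rdname season_of_day
#' @export
day_of_year <- function(day) {
  stopifnot(all(day >= 1))
  ((as.integer(day) - 1L) %% 365L) + 1L
}

#' Generate a synthetic wet-dry rainfall series
#'
#' Daily rainfall is a seasonal Bernoulli-Gamma mixture: day `d` rains with
#' the season-appropriate probability, and rainy-day amounts are Gamma
#' distributed (shape 2) with the season-appropriate mean, giving the
#' positive skew of tropical daily rainfall. Season labels follow the
#' November-April calendar rule of [season_of_day()], or a cumulative-
#' rainfall trigger if requested.
#'
#' @param n_days number of days (>= 1), day 1 = 1 January of year 1.
#' @param seed integer seed.
#' @param p_rain_wet,p_rain_dry probability of a rain day per season.
#' @param mean_mm_wet,mean_mm_dry mean rainfall on rain days (mm).
#' @param season_rule `"calendar"` (default) labels seasons by date;
#'   `"rainfall"` switches a day to wet once 30-day trailing rainfall
#'   exceeds `wet_trigger_mm`.
#' @param wet_trigger_mm trailing-30-day rainfall threshold for the
#'   `"rainfall"` rule.
#' @return a `rainfall_series` data frame with columns `day`, `rain_mm`,
#'   `cum_mm`, `season`.
#' @export
generate_rainfall <- function(n_days, seed, p_rain_wet = 0.55, p_rain_dry = 0.05,
                              mean_mm_wet = 12, mean_mm_dry = 2,
                              season_rule = c("calendar", "rainfall"),
                              wet_trigger_mm = 50) {
  season_rule <- match.arg(season_rule)
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 1)
    stop_with("n_days must be a single integer >= 1")
  if (missing(seed)) stop_with("generate_rainfall() requires an explicit seed")
  assert_prob(p_rain_wet, "p_rain_wet"); assert_prob(p_rain_dry, "p_rain_dry")
  set.seed(as.integer(seed))
  n_days <- as.integer(n_days)
  day <- seq_len(n_days)
  cal_season <- season_of_day(day)
  p <- ifelse(cal_season == "wet", p_rain_wet, p_rain_dry)
  m <- ifelse(cal_season == "wet", mean_mm_wet, mean_mm_dry)
  rains <- stats::runif(n_days) < p
  shape <- 2
  amount <- ifelse(rains, stats::rgamma(n_days, shape = shape, scale = m / shape), 0)
  cum <- cumsum(amount)
  season <- cal_season
  if (season_rule == "rainfall") {
    trail <- amount
    cs <- c(0, cum)
    trail30 <- cs[pmin(day + 1L, n_days + 1L)] - cs[pmax(day - 29L, 1L)]
    season <- ifelse(trail30 >= wet_trigger_mm, "wet", "dry")
  }
  structure(data.frame(day = day, rain_mm = amount, cum_mm = cum, season = season,
                       stringsAsFactors = FALSE),
            class = c("rainfall_series", "data.frame"))
}

#' Read and write rainfall series
#'
#' CSV with header `day,rain_mm,cum_mm,season`. Reading validates that the
#' day column is 1..n, rainfall is non-negative, and the cumulative column
#' is the non-decreasing running total of `rain_mm`; violations are
#' reported with the offending day.
#'
#' @param rain a `rainfall_series` data frame.
#' @param path file path.
#' @return `read_rainfall()` returns a `rainfall_series`;
#'   `write_rainfall()` returns `path` invisibly.
#' @export
write_rainfall <- function(rain, path) {
  utils::write.csv(as.data.frame(rain)[, c("day", "rain_mm", "cum_mm", "season")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rainfall
#' @export
read_rainfall <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (k in c("day", "rain_mm", "cum_mm", "season"))
    if (!k %in% names(df)) stop_with("rainfall CSV missing column '%s'", k)
  if (!identical(as.integer(df$day), seq_len(nrow(df))))
    stop_with("rainfall day column must run 1..%d with no gaps", nrow(df))
  if (any(df$rain_mm < 0)) {
    k <- df$day[which(df$rain_mm < 0)[1]]
    stop_with("negative rainfall at day %d", k)
  }
  dif <- diff(c(0, df$cum_mm))
  if (any(dif < -1e-9)) {
    k <- df$day[which(dif < -1e-9)[1]]
    stop_with("cumulative rainfall decreases at day %d", k)
  }
  if (max(abs(cumsum(df$rain_mm) - df$cum_mm)) > 1e-6 * max(1, max(df$cum_mm))) {
    k <- df$day[which(abs(cumsum(df$rain_mm) - df$cum_mm) > 1e-6)[1]]
    stop_with("cumulative rainfall inconsistent with daily amounts at day %d", k)
  }
  if (!all(df$season %in% c("wet", "dry")))
    stop_with("season column must be 'wet' or 'dry'")
  structure(df, class = c("rainfall_series", "data.frame"))
}
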