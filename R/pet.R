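#' Daily heat units
#'
#' Growing-degree accumulation: `max(0, (tmin + tmax) / 2 - t_base)`, capped at
#' `t_opt - t_base` so daily means above the optimum accrue no additional heat.
#'
#' @param tmin,tmax daily minimum / maximum air temperature, deg C (`tmax >= tmin`).
#' @param t_base,t_opt cultivar base and optimum temperature, deg C.
#' @return heat units, deg C d, never negative.
#' @export
heat_units <- function(tmin, tmax, t_base, t_opt) {
  stopifnot(all(tmax >= tmin), t_base < t_opt)
  clamp((tmin + tmax) / 2 - t_base, 0, t_opt - t_base)
}

#' Potential heat units for a growing season
#'
#' Sums daily heat units over the mean weather climatology between planting and
#' harvest. Seasons wrapping the year boundary are supported: the window runs
#' from `planting_doy` to `harvest_doy` through day 360 and back into the next
#' calendar year.
#'
#' @param climatology list with numeric vectors `tmin`, `tmax` of length 360
#'   (day-of-year means over all simulated years).
#' @param planting_doy,harvest_doy day-of-year in 1..360.
#' @param t_base,t_opt cultivar temperatures, deg C.
#' @return total heat units, deg C d (> 0 required downstream).
#' @export
compute_phu <- function(climatology, planting_doy, harvest_doy, t_base, t_opt) {
  doys <- season_doys(planting_doy, harvest_doy)
  if (length(doys) == 0L) stop("season of length zero")
  sum(heat_units(climatology$tmin[doys], climatology$tmax[doys], t_base, t_opt))
}

# day-of-year indices of a season, wrapping the 360-day year boundary
season_doys <- function(planting_doy, harvest_doy) {
  p <- as.integer(planting_doy); h <- as.integer(harvest_doy)
  stopifnot(p >= 1L, p <= DAYS_PER_YEAR, h >= 1L, h <= DAYS_PER_YEAR)
  if (p == h) stop("season of length zero")
  if (p < h) p:h else c(p:DAYS_PER_YEAR, 1:h)
}

#' Hargreaves reference evapotranspiration
#'
#' `pet = lin * Ra * (Tmean + 17.8) * (Tmax - Tmin)^exp`, with `Ra` the
#' extraterrestrial radiation from the standard solar-geometry closed form,
#' expressed in equivalent evaporation (mm d^-1). The two coefficients are the
#' setup-domain parameters that differ between ensemble members (e.g.
#' 0.0023/0.5 textbook values versus 0.0023/0.6 and 0.0032/0.5 variants).
#'
#' @param tmin,tmax deg C, `tmax >= tmin`.
#' @param lat latitude in degrees.
#' @param doy day of year (solar geometry uses the standard 365-day angle).
#' @param lin_coeff,exp_coeff Hargreaves linear coefficient and exponent.
#' @return potential evapotranspiration, mm d^-1, >= 0.
#' @export
hargreaves_pet <- function(tmin, tmax, lat, doy, lin_coeff = 0.0023, exp_coeff = 0.5) {
  stopifnot(all(tmax >= tmin))
  ra <- extraterrestrial_radiation(lat, doy)
  tmean <- (tmin + tmax) / 2
  pmax(0, lin_coeff * 0.408 * ra * (tmean + 17.8) * (tmax - tmin)^exp_coeff)
}

#' Extraterrestrial radiation
#'
#' Standard closed-form daily extraterrestrial radiation (MJ m^-2 d^-1) from
#' solar geometry: inverse relative earth-sun distance, solar declination and
#' sunset hour angle.
#'
#' @param lat latitude, degrees.
#' @param doy day of year.
#' @return MJ m^-2 d^-1.
#' @export
extraterrestrial_radiation <- function(lat, doy) {
  phi <- lat * pi / 180
  j <- 2 * pi * doy / 365
  dr <- 1 + 0.033 * cos(j)
  delta <- 0.409 * sin(j - 1.39)
  x <- clamp(-tan(phi) * tan(delta), -1, 1)
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}
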