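#' Assign a climate region from simple climatic thresholds
#'
#' A deliberately lightweight stand-in for a full climate classification:
#' regions are used downstream only as strata. Rules, applied in order:
#' tropical if the coldest-month mean is >= 18 deg C and MAP >= 800 mm;
#' else arid if MAP < 400 mm; else cold if the warmest-month mean is
#' < 15 deg C; else temperate. Values exactly at a threshold follow the
#' stated comparison operators (>= counts as inside, < as outside), which
#' assigns boundary cases to the class listed earlier in the rule order.
#'
#' @param mean_annual_precip mm yr^-1.
#' @param mean_annual_temp deg C.
#' @param seasonal_amplitude deg C; coldest/warmest month means are taken as
#'   `mean_annual_temp -/+ seasonal_amplitude` (default 8).
#' @return one of `"tropical"`, `"arid"`, `"temperate"`, `"cold"` (vectorized).
#' @export
assign_climate_region <- function(mean_annual_precip, mean_annual_temp,
                                  seasonal_amplitude = 8) {
  stopifnot(all(is.finite(mean_annual_precip)), all(is.finite(mean_annual_temp)))
  coldest <- mean_annual_temp - seasonal_amplitude
  warmest <- mean_annual_temp + seasonal_amplitude
  out <- rep("temperate", length(mean_annual_precip))
  out[warmest < 15] <- "cold"
  out[mean_annual_precip < 400] <- "arid"
  out[coldest >= 18 & mean_annual_precip >= 800] <- "tropical"
  out
}

#' Default climate-profile settings for the synthetic world
#'
#' `noise` scales every stochastic weather component; 0 yields weather that is
#' exactly the seasonal sinusoid (and uniform daily drizzle equal to MAP/360).
#'
#' @param noise non-negative noise multiplier.
#' @param map_range numeric length-2; MAP extremes pinned onto the first cells
#'   so the generated world always spans the stated precipitation range.
#' @export
climate_profile <- function(noise = 1, map_range = c(200, 1800)) {
  stopifnot(noise >= 0, length(map_range) == 2L, map_range[1] < map_range[2])
  list(noise = noise, map_range = map_range)
}

#' Generate a synthetic gridded agro-environment
#'
#' Builds the study region every downstream stage runs on: grid cells with
#' daily weather over all years (seasonal sinusoid with latitude-dependent
#' amplitude plus autocorrelated noise), a 10-layer soil profile with texture,
#' organic/mineral nutrient pools and hydraulic parameters, N and P
#' application rates, rainfed/irrigated harvested areas, country and climate
#' region assignment, and a harmonized growing season with its potential heat
#' units (PHU). Years are abstract (1..n_years) with 360-day years of 12 x 30
#' days. The first four cells are pinned to climatic archetypes so that every
#' climate region occurs and MAP and fertilizer rates span their stated ranges
#' even in very small worlds.
#'
#' Deterministic: the same `(arguments, seed)` always produce a bit-identical
#' world; all randomness fans out through [derive_seed()].
#'
#' @param n_cells number of grid cells (>= 1, and >= `n_countries`).
#' @param n_countries number of countries (cells are split into contiguous blocks).
#' @param n_years number of simulated years (>= 12; detrending and the
#'   reference window need length).
#' @param seed integer top-level seed.
#' @param profile a [climate_profile()].
#' @return an object of class `world`: list with `cells` (data.frame),
#'   `countries` (data.frame), `weather` (per-cell list of 360 x n_years
#'   matrices `tmin`, `tmax`, `srad`, `prec`), `soil` (per-cell layer
#'   data.frame), `climatology` (per-cell doy means), `n_years`, `seed`,
#'   `params`.
#' @export
generate_world <- function(n_cells = 150, n_countries = 12, n_years = 20,
                           seed = 1, profile = climate_profile()) {
  if (n_years < 12) stop("configuration error: n_years must be >= 12")
  if (n_cells < 1) stop("configuration error: n_cells must be >= 1")
  if (n_cells < n_countries)
    stop("configuration error: n_cells must be >= n_countries")
  noise <- profile$noise

  ## -- countries ------------------------------------------------------------
  set.seed(derive_seed(seed, "countries"))
  # countries sample the development spectrum evenly (jittered stratification),
  # so the fertilizer gradient is well covered from low- to high-input systems
  dev_index <- clamp((seq_len(n_countries) - 0.5) / n_countries +
                       rnorm(n_countries, 0, 0.06), 0.01, 0.99)
  countries <- data.frame(
    country_id = seq_len(n_countries),
    name = sprintf("country_%02d", seq_len(n_countries)),
    dev_index = dev_index,
    stagnating = dev_index < 0.35
  )
  country_of <- sort(rep_len(seq_len(n_countries), n_cells))

  ## -- per-cell climate scalars --------------------------------------------
  set.seed(derive_seed(seed, "cells"))
  lat <- runif(n_cells, -45, 67)
  u_map <- runif(n_cells)
  mapr <- profile$map_range
  map <- mapr[1] + diff(mapr) * u_map^1.2
  # parameterized via the warmest-month mean (what the growing season sees):
  # floor at 13 deg C keeps potential heat units positive for any cultivar
  warm_mean <- pmax(13, 28 - 0.26 * abs(lat) + rnorm(n_cells, 0, 1.5 * noise))
  amp <- pmax(0.5, (2 + 0.30 * abs(lat)) * runif(n_cells, 0.7, 1.3))
  tavg <- warm_mean - amp
  # archetype pins (tropical, arid, temperate, cold) for coverage at small n
  pins <- list(
    c(lat = 5,  map = mapr[2], tavg = 26.5, amp = 3),
    c(lat = 30, map = mapr[1], tavg = 20,   amp = 11),
    c(lat = 45, map = 800,     tavg = 11,   amp = 16),
    c(lat = 58, map = 600,     tavg = 3,    amp = 11)
  )
  for (i in seq_len(min(4L, n_cells))) {
    lat[i] <- pins[[i]]["lat"]; map[i] <- pins[[i]]["map"]
    tavg[i] <- pins[[i]]["tavg"]; amp[i] <- pins[[i]]["amp"]
  }
  region <- assign_climate_region(map, tavg, amp)

  ## -- management and areas -------------------------------------------------
  set.seed(derive_seed(seed, "management"))
  dev_cell <- countries$dev_index[country_of]
  # fertilizer input tracks development convexly (intensification sets in at
  # high development); spans 0-300 kg N across cells
  n_rate <- clamp(300 * dev_cell^3 + rnorm(n_cells, 0, 15), 0, 300)
  p_rate <- 0.15 * n_rate + 2
  area_rainfed <- round(exp(rnorm(n_cells, log(3000), 0.6)))
  irr_share <- clamp(rgamma(n_cells, 2, 8) + 0.25 * (region == "arid"), 0, 0.95)
  area_irrigated <- round(area_rainfed * irr_share / pmax(1e-9, 1 - irr_share))

  ## -- growing season --------------------------------------------------------
  planting <- ifelse(lat >= 0, 90, 270) + round(rnorm(n_cells, 0, 6 * noise))
  planting <- ((as.integer(planting) - 1L) %% DAYS_PER_YEAR) + 1L
  season_len <- as.integer(clamp(round(150 - 1.0 * (tavg - 10)), 100, 170))
  harvest <- ((planting + season_len - 1L) %% DAYS_PER_YEAR) + 1L

  ## -- daily weather ----------------------------------------------------------
  warm_doy <- ifelse(lat >= 0, 195, 15)
  weather <- vector("list", n_cells)
  climatology <- vector("list", n_cells)
  for (g in seq_len(n_cells)) {
    weather[[g]] <- gen_cell_weather(
      derive_seed(seed, "weather", g), n_years, tavg[g], amp[g], map[g],
      abs(lat[g]), warm_doy[g], noise)
    climatology[[g]] <- list(
      tmin = rowMeans(weather[[g]]$tmin),
      tmax = rowMeans(weather[[g]]$tmax))
  }

  ## -- soils -------------------------------------------------------------------
  soil <- vector("list", n_cells)
  for (g in seq_len(n_cells)) {
    soil[[g]] <- gen_cell_soil(derive_seed(seed, "soil", g), map[g], tavg[g])
  }

  ## -- PHU on the harmonized season (reference cultivar temperatures) ---------
  phu <- vapply(seq_len(n_cells), function(g)
    compute_phu(climatology[[g]], planting[g], harvest[g], 8, 28), numeric(1))

  cells <- data.frame(
    cell_id = seq_len(n_cells), lat = lat, country_id = country_of,
    climate_region = region, mean_annual_precip = map, mean_annual_temp = tavg,
    seasonal_amplitude = amp, n_rate = n_rate, p_rate = p_rate,
    area_rainfed = area_rainfed, area_irrigated = area_irrigated,
    planting_doy = planting, harvest_doy = harvest, phu = phu,
    stringsAsFactors = FALSE
  )
  structure(list(
    cells = cells, countries = countries, weather = weather, soil = soil,
    climatology = climatology, n_years = as.integer(n_years), seed = seed,
    params = list(n_cells = n_cells, n_countries = n_countries,
                  n_years = n_years, seed = seed, profile = profile)
  ), class = "world")
}

# daily weather for one cell over all years; pure function of its seed
gen_cell_weather <- function(cell_seed, n_years, tavg, amp, map, abslat,
                             warm_doy, noise) {
  set.seed(cell_seed)
  nd <- DAYS_PER_YEAR * n_years
  doy <- rep(seq_len(DAYS_PER_YEAR), n_years)
  seas <- cos(2 * pi * (doy - warm_doy) / DAYS_PER_YEAR)
  tmean <- tavg + amp * seas
  if (noise > 0) {
    eps <- as.numeric(stats::filter(rnorm(nd, 0, 2 * noise), 0.7,
                                    method = "recursive"))
    tmean <- tmean + eps
  }
  drange <- 10 + pmax(0, 6 * (1 - map / 1500))
  if (noise > 0) drange <- pmax(1, drange + rnorm(nd, 0, 1 * noise))
  tmax <- tmean + drange / 2
  tmin <- tmean - drange / 2
  srad <- 16 + (4 + 0.12 * abslat) * seas
  if (noise > 0) srad <- srad + rnorm(nd, 0, 2 * noise)
  srad <- pmax(0.5, srad)
  if (noise > 0) {
    p_wet <- clamp((0.12 + 0.28 * map / 1800) * (1 + 0.6 * seas), 0.02, 0.95)
    mu <- map / sum(p_wet[seq_len(DAYS_PER_YEAR)])
    wet <- runif(nd) < p_wet
    prec <- numeric(nd)
    prec[wet] <- rgamma(sum(wet), shape = 0.8, scale = mu / 0.8)
  } else {
    prec <- rep(map / DAYS_PER_YEAR, nd)
  }
  lapply(list(tmin = tmin, tmax = tmax, srad = srad, prec = prec),
         matrix, nrow = DAYS_PER_YEAR, ncol = n_years)
}

# 10-layer soil profile for one cell: texture, pools and baseline hydraulics
gen_cell_soil <- function(cell_seed, map, tavg) {
  set.seed(cell_seed)
  nl <- 10L
  thick <- c(rep(0.10, 5), rep(0.15, 5))                       # m, 1.25 m profile
  clay <- clamp(rnorm(1, 0.25, 0.08) + rnorm(nl, 0, 0.02), 0.05, 0.55)
  sand <- clamp(rnorm(1, 0.40, 0.10) + rnorm(nl, 0, 0.02), 0.05, 0.85)
  # wetter/cooler sites accumulate more organic matter; declines with depth
  om_surf <- clamp(0.01 + 0.02 * map / 1800 + 0.01 * (15 - tavg) / 25 +
                     rnorm(1, 0, 0.004), 0.003, 0.06)
  depth_mid <- cumsum(thick) - thick / 2
  om <- om_surf * exp(-2.2 * depth_mid)
  hyd <- pedotransfer(clay, om, thick, source = "input_pedotransfer_A")
  # 5 % N in OM; soil mass = thickness x 1e4 m2 x 1300 kg m^-3
  organic_n <- 0.05 * om * thick * 1.3e7                       # kg N ha^-1 per layer
  data.frame(
    layer = seq_len(nl), thick = thick, clay = clay, sand = sand, om = om,
    fc = hyd$fc, wp = hyd$wp, ksat = hyd$ksat,
    organic_n = organic_n,
    mineral_n = 20 * thick / sum(thick),
    labile_p = 30 * thick / sum(thick)
  )
}

#' Generate country-level "reported" yield series from an aggregated truth
#'
#' Emulates a national yield statistics benchmark: the Eq-1-aggregated truth is
#' overlaid with a multiplicative technology trend and multiplicative noise,
#' `reported(c, t) = truth(c, t) * (1 + trend_slope * (t - t0)) * (1 + eps)`,
#' `eps ~ N(0, noise_sd)` truncated at -0.9 so yields stay positive. A fraction
#' of countries is flagged as agency-estimated, and a configurable subset gets
#' harvested-area series fluctuating by > 100 % to exercise the country filter.
#' With `trend_slope = 0` and `noise_sd = 0` the generator is the identity on
#' the truth.
#'
#' @param world a `world`.
#' @param truth data.frame with columns `country_id`, `year`, `yield` (t ha^-1),
#'   covering every country of `world`.
#' @param trend_slope relative yield trend per year (default 0.015).
#' @param noise_sd multiplicative noise standard deviation (default 0.08).
#' @param flag_fraction fraction of countries flagged `fao_estimated_flag`.
#' @param fluct_countries integer country ids whose harvested area is made to
#'   fluctuate by more than 100 % (default none).
#' @param seed integer seed.
#' @return data.frame of class `reported_yields`: `country_id`, `year`,
#'   `yield`, `harvested_area`, `production`, `fao_estimated_flag`.
#' @export
generate_reported_yields <- function(world, truth, trend_slope = 0.015,
                                     noise_sd = 0.08, flag_fraction = 0.15,
                                     fluct_countries = integer(), seed = 1) {
  stopifnot(noise_sd >= 0, inherits(world, "world"))
  ids <- world$countries$country_id
  missing_ids <- setdiff(ids, unique(truth$country_id))
  if (length(missing_ids))
    stop("data error: countries missing from truth: ",
         paste(missing_ids, collapse = ", "))
  truth <- truth[truth$country_id %in% ids, c("country_id", "year", "yield")]
  truth <- truth[order(truth$country_id, truth$year), ]
  y0 <- min(truth$year)

  set.seed(derive_seed(seed, "reported"))
  n_flag <- floor(flag_fraction * length(ids))
  flagged <- if (n_flag > 0) sample(ids, n_flag) else integer()
  eps <- pmax(rnorm(nrow(truth), 0, noise_sd), -0.9)
  if (noise_sd == 0) eps <- rep(0, nrow(truth))

  area_by_country <- tapply(
    world$cells$area_rainfed + world$cells$area_irrigated,
    world$cells$country_id, sum)

  out <- truth
  out$yield <- truth$yield * (1 + trend_slope * (truth$year - y0)) * (1 + eps)
  out$harvested_area <- as.numeric(area_by_country[as.character(out$country_id)])
  fl <- out$country_id %in% fluct_countries
  out$harvested_area[fl] <- out$harvested_area[fl] *
    ifelse(out$year[fl] %% 2 == 0, 2.3, 1)          # (max-min)/min = 130 % > 100 %
  out$production <- out$yield * out$harvested_area
  out$fao_estimated_flag <- out$country_id %in% flagged
  class(out) <- c("reported_yields", "data.frame")
  out
}

#' Save / restore a synthetic world as plain text
#'
#' Writes the cell and country tables as CSV and a compact JSON manifest of all
#' generator parameters and the seed; because generation is deterministic the
#' manifest is sufficient to rebuild the full world (daily weather and soils
#' included) with [read_world()].
#'
#' @param world a `world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(world$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(world$countries, file.path(dir, "countries.csv"), row.names = FALSE)
  jsonlite::write_json(world$params, file.path(dir, "world.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_world
#' @export
read_world <- function(dir) {
  p <- jsonlite::read_json(file.path(dir, "world.json"), simplifyVector = TRUE)
  generate_world(p$n_cells, p$n_countries, p$n_years, p$seed,
                 climate_profile(p$profile$noise, p$profile$map_range))
}
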