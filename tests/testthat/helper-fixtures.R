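# shared fixtures (memoized small worlds) and independent oracle codings

.fixture_cache <- new.env(parent = emptyenv())

test_world <- function(n_cells = 12, n_countries = 4, n_years = 12, seed = 42,
                       noise = 1) {
  key <- paste(n_cells, n_countries, n_years, seed, noise, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_world(
      n_cells, n_countries, n_years, seed,
      profile = climate_profile(noise = noise))
  .fixture_cache[[key]]
}

test_cube <- function(configs = c("eIIASA", "gGEPIC"), scenario_set = "fullharm",
                      water_set = c("rainfed", "irrigated"), ...) {
  w <- test_world(...)
  key <- paste("cube", paste(configs, collapse = ""),
               paste(scenario_set, collapse = ""),
               paste(water_set, collapse = ""),
               paste(c(...), collapse = "_"), sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- run_ensemble(
      w, lapply(configs, preset_config), scenario_set, water_set)
  .fixture_cache[[key]]
}

# a synthetic standalone season forcing (bypasses world generation)
make_forcing <- function(seed, n_days = 90, lat = 40, cultivar_id = 1,
                         n_budget = 120, p_rate = 20, tmean = 20, srad = 16,
                         prec_mean = 3) {
  set.seed(seed)
  cu <- default_cultivars()[cultivar_id, ]
  tmin <- tmean - 5 + rnorm(n_days, 0, 2)
  tmax <- tmin + 8 + abs(rnorm(n_days, 2, 1))
  soil_df <- data.frame(
    layer = 1:4, thick = c(0.1, 0.2, 0.3, 0.4),
    clay = runif(4, 0.15, 0.35), sand = runif(4, 0.2, 0.5),
    om = c(0.03, 0.02, 0.01, 0.005),
    fc = NA, wp = NA, ksat = NA,
    organic_n = c(1500, 900, 400, 150),
    mineral_n = c(10, 5, 3, 2), labile_p = c(15, 8, 5, 2))
  structure(list(
    cell_id = 1L, year = 1L, lat = lat,
    doys = ((100 + seq_len(n_days) - 2L) %% 360L) + 1L,
    tmin = tmin, tmax = tmax,
    srad = pmax(0.5, srad + rnorm(n_days, 0, 3)),
    prec = ifelse(runif(n_days) < 0.4, rgamma(n_days, 0.8, 0.8 / prec_mean), 0),
    planting_doy = 100L, harvest_doy = 100L + n_days - 1L,
    phu = n_days * 10, cultivar = cu, n_budget = n_budget, p_rate = p_rate,
    soil_init = prepare_cell_soil(soil_df,
                                  list(hydraulic_source = "input_pedotransfer_A",
                                       n_layers = 4L))
  ), class = "season_cell")
}

## -- independent oracles -----------------------------------------------------

# textbook Hargreaves with explicit FAO-56 solar geometry, coded independently
oracle_hargreaves <- function(tmin, tmax, lat, doy, lin = 0.0023, ex = 0.5) {
  phi <- pi * lat / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(min(1, max(-1, -tan(phi) * tan(dec))))
  ra_mj <- (1440 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  ra_mm <- 0.408 * ra_mj                      # textbook mm-equivalent factor
  max(0, lin * ra_mm * ((tmin + tmax) / 2 + 17.8) * (tmax - tmin)^ex)
}

# brute-force area-weighted mean over long-format records
oracle_eq1 <- function(yi, hai, yr, har) {
  sum(yi * hai + yr * har) / sum(hai + har)
}

oracle_cv <- function(x) 100 * sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)

oracle_me <- function(est, ref) sum(est - ref) / length(est)

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_movmean <- function(y, window = 5) {
  h <- (window - 1) %/% 2
  n <- length(y)
  sapply(seq_len(n), function(i) {
    idx <- seq(max(1, i - h), min(n, i + h))
    sum(y[idx]) / length(idx)
  })
}

# a permutation parent equal to eIIASA except a planted cultivar effect
preset_cult_effect <- function(hi_scale = 0.8) {
  g <- preset_config("eIIASA")
  g$label <- "gCULT"
  # scaling both HI bounds scales every realized harvest index, hence every
  # yield, by exactly hi_scale
  g$cult$params$hi_max <- g$cult$params$hi_max * hi_scale
  g$cult$params$hi_min <- g$cult$params$hi_min * hi_scale
  validate_setup_config(g)
}
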