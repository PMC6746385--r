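#' Assemble the daily forcing for one cell, year and scenario
#'
#' Builds the `cell` input consumed by [simulate_season()]: the season's daily
#' weather (seasons wrapping the year boundary draw their pre-January days
#' from the previous calendar year; yields are assigned to the harvest year),
#' the scenario's growing-season dates (the member-specific "default" scenario
#' shifts the harmonized dates by the configuration's
#' `default_season_shift`), the potential heat units recomputed on the
#' climatology for those dates and the cultivar's temperatures, the effective
#' annual N budget, and the prepared soil profile.
#'
#' @param world a `world`.
#' @param config a `setup_config`.
#' @param scenario `"default"`, `"fullharm"` or `"harm-suffN"`.
#' @param cell_id cell id.
#' @param year harvest year in 1..n_years.
#' @return a `season_cell` list, or `NULL` when the season is incomplete (a
#'   wrapping season in year 1 has no previous-year weather).
#' @export
season_inputs <- function(world, config, scenario, cell_id, year) {
  row <- world$cells[world$cells$cell_id == cell_id, ]
  stopifnot(nrow(row) == 1L, year >= 1L, year <= world$n_years)
  shift <- if (scenario == "default") config$manage$default_season_shift else 0L
  planting <- ((row$planting_doy + shift - 1L) %% DAYS_PER_YEAR) + 1L
  harvest <- ((row$harvest_doy + shift - 1L) %% DAYS_PER_YEAR) + 1L
  doys <- season_doys(planting, harvest)
  wraps <- planting > harvest
  if (wraps && year == 1L) return(NULL)

  w <- world$weather[[cell_id]]
  yr <- if (wraps) ifelse(doys >= planting, year - 1L, year) else rep(year, length(doys))
  idx <- cbind(doys, yr)
  cult_id <- cultivar_map(config, world)[[as.character(row$country_id)]]
  cult <- config$cult$params[config$cult$params$cultivar_id == cult_id, ]
  phu <- compute_phu(world$climatology[[cell_id]], planting, harvest,
                     cult$t_base, cult$t_opt)
  n_budget <- switch(scenario,
    "default" = row$n_rate * config$manage$default_nrate_factor,
    "fullharm" = row$n_rate,
    "harm-suffN" = Inf)
  structure(list(
    cell_id = cell_id, year = year, lat = row$lat, doys = doys,
    tmin = w$tmin[idx], tmax = w$tmax[idx], srad = w$srad[idx],
    prec = w$prec[idx],
    planting_doy = planting, harvest_doy = harvest, phu = phu,
    cultivar = cult, n_budget = n_budget, p_rate = row$p_rate,
    soil_init = prepare_cell_soil(world$soil[[cell_id]], config$soil_d)
  ), class = "season_cell")
}

#' Simulate one growing season (reference R engine)
#'
#' The daily crop-soil loop: heat-unit phenology, light interception from a
#' logistic-in-heat-unit-time S-curve, radiation-use-efficiency potential
#' growth scaled by the row-spacing factor, and the minimum-stress rule --
#' on each day only the single most limiting factor (water, nitrogen,
#' phosphorus or temperature) reduces the potential biomass increment. The
#' actual harvest index is `hi_max - (hi_max - hi_min) * WSI`, where WSI is
#' the mean water-stress deficit (1 - stress factor) over the days after the
#' configured fraction of the season. The season ends when accumulated heat
#' units reach the potential heat units or at the harvest date.
#'
#' This pure-R engine composes the exported step functions and serves as the
#' reference coding of the daily loop; [run_ensemble()] uses a transcribed
#' compiled engine that must agree with it to 1e-9.
#'
#' @param cell a `season_cell` from [season_inputs()].
#' @param config a `setup_config`.
#' @param scenario,water_regime management scenario and water regime.
#' @param carryover_state a `soil_state` carried over from the previous
#'   season, or `NULL` to start from the cell's initial profile.
#' @param pstress set `FALSE` to disable phosphorus limitation (diagnostic).
#' @return list with `result` (yield t ha^-1, aboveground_biomass, hi_actual,
#'   stress_days counts, applied_irrigation mm, applied_n kg ha^-1) and
#'   `state` (the `soil_state` at season end).
#' @export
simulate_season <- function(cell, config, scenario, water_regime,
                            carryover_state = NULL, pstress = TRUE) {
  stopifnot(inherits(cell, "season_cell"), cell$phu > 0)
  if (anyNA(cell$tmin)) stop("data error: missing weather days")
  cu <- cell$cultivar
  man <- config$manage
  cw <- config$coeff_w
  cn <- config$coeff_n
  suffn <- scenario == "harm-suffN"
  irrigated <- water_regime == "irrigated"
  fixed_fert <- identical(man$fert_trigger, "fixed")
  f_hi <- config$cult$hi_min_season_fraction

  s <- if (is.null(carryover_state)) cell$soil_init else carryover_state
  n_days <- min(length(cell$doys), SIM_CONST$max_season_days)

  # planting-day inputs: P supply, rigid-timing N
  s$labile_p[1] <- s$labile_p[1] +
    if (suffn) SIM_CONST$suffn_p_supply else cell$p_rate
  budget <- cell$n_budget
  applied_n <- 0

  hu_cum <- 0; biomass <- 0; wsi_sum <- 0; wsi_n <- 0L
  prev_ws <- 1
  applied_irr <- 0; n_uptake <- 0
  stress_days <- c(water = 0L, nitrogen = 0L, phosphorus = 0L, temperature = 0L)

  for (d in seq_len(n_days)) {
    tmin <- cell$tmin[d]; tmax <- cell$tmax[d]
    # rigid-timing fertilization: calendar doses at days 1, 31, 61
    if (fixed_fert && d %in% c(1L, 31L, 61L)) {
      dose <- if (suffn) 6 * SIM_CONST$fert_per_event else cell$n_budget / 3
      s$mineral_n[1] <- s$mineral_n[1] + dose
      applied_n <- applied_n + dose
    }
    hu <- heat_units(tmin, tmax, cu$t_base, cu$t_opt)
    hu_cum <- hu_cum + hu
    huf <- min(1, hu_cum / cell$phu)
    f_int <- scurve_from_anchors(huf, SIM_CONST$lai_anchor1,
                                 SIM_CONST$lai_anchor2, y_percent = TRUE)
    pet <- hargreaves_pet(tmin, tmax, cell$lat, cell$doys[d],
                          cw$hargreaves_lin, cw$hargreaves_exp)
    tmean <- (tmin + tmax) / 2
    temp_stress <- clamp((tmean - cu$t_base) / (cu$t_opt - cu$t_base), 0, 1)

    irr <- 0
    if (irrigated) {
      deficit <- sum(pmax(s$fc - s$water, 0))
      irr <- auto_irrigate(prev_ws, deficit, man)
      applied_irr <- applied_irr + irr
    }
    wb <- water_balance_step(s, cell$prec[d], irr, pet, f_int, cw)
    s <- wb$soil
    ws <- wb$water_stress

    db_pot <- 0.01 * cu$rue * man$row_spacing_factor * f_int *
      (SIM_CONST$par_fraction * cell$srad[d])
    demand_n <- SIM_CONST$plant_n_conc * db_pot
    if (!fixed_fert) {
      # anticipatory trigger: stress the crop would face today from the
      # current mineral pool ("applied if production would be limited")
      proj_ns <- if (demand_n > 0)
        min(1, max(sum(s$mineral_n), 0) / demand_n) else 1
      fert <- auto_fertilize(proj_ns, budget, man, scenario)
      if (fert > 0) {
        s$mineral_n[1] <- s$mineral_n[1] + fert
        applied_n <- applied_n + fert
        if (!suffn) budget <- budget - fert
      }
    }
    demand_p <- if (pstress) SIM_CONST$plant_p_conc * db_pot else 0
    tf <- clamp(tmean / SIM_CONST$temp_fac_max, 0, 1)
    mf <- scurve_from_anchors(wb$smi, cn$moisture_fn_anchors[[1]],
                              cn$moisture_fn_anchors[[2]], y_percent = TRUE)
    nut <- nutrient_step(s, tf, mf, demand_n, demand_p, cn)
    s <- nut$soil
    n_uptake <- n_uptake + nut$n_supply
    ns <- nut$n_stress
    ps <- if (pstress) nut$p_stress else 1

    fac <- c(ws, ns, ps, temp_stress)
    stress <- min(fac)
    stress_days[which.min(fac)] <- stress_days[which.min(fac)] + 1L
    biomass <- biomass + db_pot * stress

    if (huf >= f_hi) { wsi_sum <- wsi_sum + (1 - ws); wsi_n <- wsi_n + 1L }
    prev_ws <- ws
    if (hu_cum >= cell$phu) break
  }

  wsi <- if (wsi_n > 0L) wsi_sum / wsi_n else 0
  hi_a <- cu$hi_max - (cu$hi_max - cu$hi_min) * wsi
  yld <- biomass * hi_a
  # non-grain plant N partially returned as surface residue
  s$organic_n[1] <- s$organic_n[1] + SIM_CONST$residue_n_frac *
    (1 - man$residue_removal) * n_uptake * (1 - hi_a)

  list(result = list(yield = yld, aboveground_biomass = biomass,
                     hi_actual = hi_a, stress_days = stress_days,
                     applied_irrigation = applied_irr, applied_n = applied_n),
       state = s)
}

# off-season daily loop: bare-soil water balance plus nutrient turnover with
# no crop demand; weather indexed from the harvest year (stationary-climate
# approximation for wrapped days)
offseason_update <- function(world, cell_id, year, config, from_doy, to_doy,
                             soil_state) {
  if (from_doy == to_doy) return(soil_state)
  doys <- season_doys(from_doy, to_doy)
  w <- world$weather[[cell_id]]
  lat <- world$cells$lat[world$cells$cell_id == cell_id]
  cw <- config$coeff_w; cn <- config$coeff_n
  s <- soil_state
  for (d in doys) {
    tmin <- w$tmin[d, year]; tmax <- w$tmax[d, year]
    pet <- hargreaves_pet(tmin, tmax, lat, d, cw$hargreaves_lin,
                          cw$hargreaves_exp)
    wb <- water_balance_step(s, w$prec[d, year], 0, pet, 0, cw)
    s <- wb$soil
    tmean <- (tmin + tmax) / 2
    tf <- clamp(tmean / SIM_CONST$temp_fac_max, 0, 1)
    mf <- scurve_from_anchors(wb$smi, cn$moisture_fn_anchors[[1]],
                              cn$moisture_fn_anchors[[2]], y_percent = TRUE)
    s <- nutrient_step(s, tf, mf, 0, 0, cn)$soil
  }
  s
}
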