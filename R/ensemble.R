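#' Yield cube container
#'
#' Yields indexed by (config, scenario, water regime, year, cell), with a
#' validity mask. The first simulation year is always masked as incomplete
#' (seasons wrapping the year boundary have no previous-year weather there),
#' mirroring the protocol of dropping the first year from all means.
#'
#' @param values 5-d array, t ha^-1.
#' @param mask logical array of the same shape; TRUE = valid and scored.
#' @export
yield_cube <- function(values, mask) {
  stopifnot(length(dim(values)) == 5L, identical(dim(values), dim(mask)))
  structure(list(values = values, mask = mask), class = "yield_cube")
}

#' @export
print.yield_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("yield_cube:", d[1], "config(s) x", d[2], "scenario(s) x", d[3],
      "water regime(s) x", d[4], "year(s) x", d[5], "cell(s)\n")
  cat("valid cell-years:", sum(x$mask), "/", length(x$mask), "\n")
  invisible(x)
}

# pack a (config, cell) pair for the compiled engine
pack_cpp_args <- function(world, config, cell_id) {
  soil0 <- unclass(prepare_cell_soil(world$soil[[cell_id]], config$soil_d))
  list(
    soil0 = soil0,
    lai_ab = unname(scurve_coef(SIM_CONST$lai_anchor1, SIM_CONST$lai_anchor2,
                                y_percent = TRUE)),
    mois_ab = unname(scurve_coef(config$coeff_n$moisture_fn_anchors[[1]],
                                 config$coeff_n$moisture_fn_anchors[[2]],
                                 y_percent = TRUE)),
    oxy_ab = unname(scurve_coef(config$coeff_n$oxygen_fn_anchors[[1]],
                                config$coeff_n$oxygen_fn_anchors[[2]],
                                y_percent = TRUE)),
    cns = unname(unlist(SIM_CONST[c(
      "cn_retention_base", "cn_smi_weight", "extract_frac", "evap_smi_gain",
      "base_mineralization", "vol_scale", "plant_n_conc", "plant_p_conc",
      "fert_per_event", "suffn_p_supply", "residue_n_frac", "temp_fac_max",
      "par_fraction")]))
  )
}

# per-year simulation for one cell/config/scenario/water using the compiled
# engine; returns the ny x 6 output matrix
run_cell_cpp <- function(world, config, scenario, water_regime, cell_id,
                         pstress, packed = NULL) {
  if (is.null(packed)) packed <- pack_cpp_args(world, config, cell_id)
  row <- world$cells[cell_id, ]
  shift <- if (scenario == "default") config$manage$default_season_shift else 0L
  planting <- ((row$planting_doy + shift - 1L) %% DAYS_PER_YEAR) + 1L
  harvest <- ((row$harvest_doy + shift - 1L) %% DAYS_PER_YEAR) + 1L
  cult_id <- cultivar_map(config, world)[[as.character(row$country_id)]]
  cu <- config$cult$params[config$cult$params$cultivar_id == cult_id, ]
  phu <- compute_phu(world$climatology[[cell_id]], planting, harvest,
                     cu$t_base, cu$t_opt)
  n_budget <- switch(scenario,
    "default" = row$n_rate * config$manage$default_nrate_factor,
    "fullharm" = row$n_rate, "harm-suffN" = Inf)
  man <- config$manage
  par <- c(config$coeff_w$hargreaves_lin, config$coeff_w$hargreaves_exp,
           config$coeff_w$soil_evap_coeff, config$coeff_w$cn_index_coeff,
           config$coeff_n$microbial_decay, config$coeff_n$n_volatilization,
           config$coeff_n$denit_rate, man$irrigation_trigger,
           man$max_single_irrigation,
           if (identical(man$fert_trigger, "fixed")) -1 else man$fert_trigger,
           man$row_spacing_factor, man$residue_removal,
           config$cult$hi_min_season_fraction)
  w <- world$weather[[cell_id]]
  sim_cell_years_cpp(
    w$tmin, w$tmax, w$srad, w$prec, row$lat, packed$soil0, packed$lai_ab,
    packed$mois_ab, packed$oxy_ab,
    c(cu$t_base, cu$t_opt, cu$rue, cu$hi_min, cu$hi_max), par, packed$cns,
    planting, harvest, phu, n_budget, row$p_rate,
    scenario == "harm-suffN", water_regime == "irrigated", pstress,
    config$soil_p$handling == "static", config$soil_p$topsoil_loss_rate,
    config$soil_p$continuity == "decadal", config$soil_p$spinup_years,
    SIM_CONST$max_season_days)
}

# reference R coding of the same year loop (slow; used for cross-validation)
run_cell_r <- function(world, config, scenario, water_regime, cell_id,
                       pstress = TRUE) {
  init <- prepare_cell_soil(world$soil[[cell_id]], config$soil_d)
  row <- world$cells[cell_id, ]
  shift <- if (scenario == "default") config$manage$default_season_shift else 0L
  planting <- ((row$planting_doy + shift - 1L) %% DAYS_PER_YEAR) + 1L
  harvest <- ((row$harvest_doy + shift - 1L) %% DAYS_PER_YEAR) + 1L
  wraps <- planting > harvest
  off_from <- harvest %% DAYS_PER_YEAR + 1L
  off_to <- ((planting - 2L) %% DAYS_PER_YEAR) + 1L
  have_off <- (harvest %% DAYS_PER_YEAR + 1L) != planting
  decadal <- config$soil_p$continuity == "decadal"
  ny <- world$n_years
  out <- matrix(NA_real_, ny, 6,
                dimnames = list(NULL, c("yield", "biomass", "hi", "irr",
                                        "napp", "valid")))
  s <- init
  for (y in seq_len(ny)) {
    if (decadal && (y - 1L) %% 10L == 0L) {
      s <- init
      cell_y <- season_inputs(world, config, scenario, cell_id, y)
      for (k in seq_len(config$soil_p$spinup_years)) {
        if (!is.null(cell_y))
          s <- simulate_season(cell_y, config, scenario, water_regime, s,
                               pstress)$state
        if (have_off)
          s <- offseason_update(world, cell_id, y, config, off_from, off_to, s)
        s <- end_of_year_soil_update(s, init, config$soil_p, y)
      }
    }
    cell_y <- season_inputs(world, config, scenario, cell_id, y)
    if (!is.null(cell_y)) {
      res <- simulate_season(cell_y, config, scenario, water_regime, s, pstress)
      s <- res$state
      out[y, ] <- c(res$result$yield, res$result$aboveground_biomass,
                    res$result$hi_actual, res$result$applied_irrigation,
                    res$result$applied_n, 1)
    } else {
      out[y, "valid"] <- 0
    }
    if (have_off)
      s <- offseason_update(world, cell_id, y, config, off_from, off_to, s)
    s <- end_of_year_soil_update(s, init, config$soil_p, y)
  }
  out
}

#' Run the simulator over a whole ensemble
#'
#' Simulates every requested configuration, management scenario and water
#' regime over all cells and years of the world and returns the resulting
#' [yield_cube()]. Deterministic for a fixed world (the simulator itself has
#' no randomness); configuration order does not affect the per-configuration
#' content. Year 1 is masked as incomplete.
#'
#' @param world a `world`.
#' @param configs list of `setup_config` objects (unique labels).
#' @param scenario_set subset of `c("default", "fullharm", "harm-suffN")`.
#' @param water_set subset of `c("rainfed", "irrigated")`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference coding).
#' @param pstress set `FALSE` to disable phosphorus limitation everywhere.
#' @return a `yield_cube` with dimnames on all five axes.
#' @export
run_ensemble <- function(world, configs,
                         scenario_set = c("default", "fullharm", "harm-suffN"),
                         water_set = c("rainfed", "irrigated"),
                         engine = c("cpp", "r"), pstress = TRUE) {
  engine <- match.arg(engine)
  if (length(configs) < 1L) stop("configuration error: need >= 1 config")
  if (inherits(configs, "setup_config")) configs <- list(configs)
  labels <- vapply(configs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("configuration error: duplicate config labels")
  stopifnot(all(scenario_set %in% c("default", "fullharm", "harm-suffN")),
            all(water_set %in% c("rainfed", "irrigated")))
  ny <- world$n_years
  nc <- nrow(world$cells)
  dims <- c(length(configs), length(scenario_set), length(water_set), ny, nc)
  dn <- list(config = labels, scenario = scenario_set, water = water_set,
             year = as.character(seq_len(ny)),
             cell = as.character(world$cells$cell_id))
  vals <- array(NA_real_, dims, dimnames = dn)
  mask <- array(FALSE, dims, dimnames = dn)
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (g in seq_len(nc)) {
      packed <- if (engine == "cpp") pack_cpp_args(world, cfg, g) else NULL
      for (si in seq_along(scenario_set)) for (wi in seq_along(water_set)) {
        m <- if (engine == "cpp")
          run_cell_cpp(world, cfg, scenario_set[si], water_set[wi], g,
                       pstress, packed)
        else run_cell_r(world, cfg, scenario_set[si], water_set[wi], g, pstress)
        vals[ci, si, wi, , g] <- m[, "yield"]
        mask[ci, si, wi, , g] <- m[, "valid"] == 1
      }
    }
  }
  mask[, , , 1, ] <- FALSE   # first year incomplete by protocol
  yield_cube(vals, mask)
}
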