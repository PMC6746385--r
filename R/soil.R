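#' Pedotransfer estimates of soil hydraulic parameters
#'
#' Two fixed pedotransfer formulas estimate field capacity, wilting point and
#' saturated conductivity from clay and organic matter content. Source
#' `"input_pedotransfer_A"` (prescribed-input route) yields systematically
#' higher field capacity and lower wilting point than
#' `"online_pedotransfer_B"` (online-estimation route), emulating the
#' documented contrast between prescribed and endogenously estimated soil
#' hydraulics in EPIC-based ensembles.
#'
#' @param clay,om clay and organic-matter mass fractions per layer.
#' @param thick layer thickness, m.
#' @param source pedotransfer route.
#' @return list of per-layer `fc`, `wp` (mm) and `ksat` (mm d^-1).
#' @export
pedotransfer <- function(clay, om, thick,
                         source = c("input_pedotransfer_A",
                                    "online_pedotransfer_B")) {
  source <- match.arg(source)
  if (source == "input_pedotransfer_A") {
    fc_v <- 0.15 + 0.30 * clay + 0.8 * om
    wp_v <- 0.04 + 0.22 * clay
    ks <- 200 * exp(-4 * clay)
  } else {
    fc_v <- 0.12 + 0.28 * clay + 0.6 * om
    wp_v <- 0.06 + 0.26 * clay
    ks <- 300 * exp(-5 * clay)
  }
  list(fc = fc_v * thick * 1000, wp = wp_v * thick * 1000, ksat = ks)
}

#' Materialize a cell's soil state under a configuration's soil-data domain
#'
#' Applies the configuration's pedotransfer route to the cell's texture
#' profile and aggregates the native 10-layer profile to the configured number
#' of layers (thicknesses, capacities and pools are summed; saturated
#' conductivity takes the within-group minimum as the limiting rate). Initial
#' water content is set to 70 % of plant-available capacity.
#'
#' @param soil_df per-layer soil data.frame from a `world`.
#' @param soil_d the configuration's `soil_d` block.
#' @return a `soil_state` list of per-layer vectors: `thick`, `fc`, `wp`,
#'   `ksat`, `organic_n`, `mineral_n`, `labile_p`, `water`, `depth_mid_mm`.
#' @export
prepare_cell_soil <- function(soil_df, soil_d) {
  hyd <- pedotransfer(soil_df$clay, soil_df$om, soil_df$thick,
                      soil_d$hydraulic_source)
  nl0 <- nrow(soil_df)
  nl <- as.integer(soil_d$n_layers)
  stopifnot(nl >= 1L, nl <= nl0)
  grp <- ceiling(seq_len(nl0) / (nl0 / nl))
  agg <- function(x) as.numeric(tapply(x, grp, sum))
  st <- list(
    thick = agg(soil_df$thick),
    fc = agg(hyd$fc), wp = agg(hyd$wp),
    ksat = as.numeric(tapply(hyd$ksat, grp, min)),
    organic_n = agg(soil_df$organic_n),
    mineral_n = agg(soil_df$mineral_n),
    labile_p = agg(soil_df$labile_p)
  )
  st$water <- st$wp + 0.7 * (st$fc - st$wp)
  st$depth_mid_mm <- (cumsum(st$thick) - st$thick / 2) * 1000
  structure(st, class = "soil_state")
}

#' End-of-year soil update
#'
#' Applies the configuration's soil-handling rule between growing seasons:
#' `static` re-initializes the profile (thickness, hydraulic parameters,
#' organic pools) to its initial state while carrying over water content and
#' mineral N/P; `dynamic` carries everything over and removes
#' `topsoil_loss_rate` of the top layer per year, with proportional loss of
#' the top layer's capacities and pools. Decadal continuity (full reset at
#' each decade boundary followed by spin-up) is handled by the year loop of
#' [run_ensemble()], not here.
#'
#' @param soil_state current `soil_state`.
#' @param initial_soil the `soil_state` the run started from.
#' @param soil_p the configuration's `soil_p` block.
#' @param year_index simulation year (1-based); unused by the static/dynamic
#'   rules but part of the update contract.
#' @return updated `soil_state`.
#' @export
end_of_year_soil_update <- function(soil_state, initial_soil, soil_p,
                                    year_index = 1L) {
  s <- soil_state
  if (soil_p$handling == "static") {
    for (f in c("thick", "fc", "wp", "ksat", "organic_n", "depth_mid_mm"))
      s[[f]] <- initial_soil[[f]]
    s$water <- pmin(s$water, s$fc)
  } else {
    r <- soil_p$topsoil_loss_rate
    if (r > 0) {
      for (f in c("thick", "fc", "wp", "water", "organic_n", "mineral_n",
                  "labile_p"))
        s[[f]][1] <- s[[f]][1] * (1 - r)
      s$depth_mid_mm <- (cumsum(s$thick) - s$thick / 2) * 1000
    }
  }
  s
}
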