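#' Area-weighted national yield aggregation
#'
#' National average yield as the harvested-area-weighted mean over the
#' country's grid cells and both water regimes:
#' `YD_av,c = sum_g(YD_i,g HA_i,g + YD_r,g HA_r,g) / sum_g(HA_i,g + HA_r,g)`.
#' Harvested areas are static across years (a fixed cropland mask). Cells
#' with zero total area are excluded; countries with zero total area are
#' dropped with a warning. Masked (invalid) cell-years are excluded with the
#' weights renormalized over the remaining cells.
#'
#' If the cube holds only one water regime (e.g. a rainfed-only permutation
#' run), the weights use that regime's areas only.
#'
#' @param cube a [yield_cube()].
#' @param world the `world` the cube was simulated on.
#' @param config configuration label present in the cube.
#' @param scenario management scenario present in the cube.
#' @return data.frame `country_id`, `year`, `yield` (NA where no valid cells).
#' @export
aggregate_national <- function(cube, world, config, scenario) {
  agg_groups(cube, world, config, scenario, world$cells$country_id)
}

#' Global area-weighted yield series
#'
#' As [aggregate_national()] but over all cells of the world.
#'
#' @inheritParams aggregate_national
#' @return data.frame `year`, `yield`.
#' @export
aggregate_global <- function(cube, world, config, scenario) {
  out <- agg_groups(cube, world, config, scenario,
                    rep(1L, nrow(world$cells)))
  out$country_id <- NULL
  out
}

agg_groups <- function(cube, world, config, scenario, group) {
  dn <- dimnames(cube$values)
  if (!config %in% dn$config) stop("unknown config: ", config)
  if (!scenario %in% dn$scenario) stop("unknown scenario: ", scenario)
  waters <- dn$water
  ny <- length(dn$year)
  area <- cbind(
    irrigated = if ("irrigated" %in% waters) world$cells$area_irrigated else NULL,
    rainfed = if ("rainfed" %in% waters) world$cells$area_rainfed else NULL)
  groups <- sort(unique(group))
  out <- expand.grid(year = seq_len(ny), country_id = groups,
                     KEEP.OUT.ATTRS = FALSE)[, 2:1]
  out$yield <- NA_real_
  for (gi in groups) {
    cells <- which(group == gi)
    tot_area <- sum(area[cells, , drop = FALSE])
    if (tot_area <= 0) {
      warning("country ", gi, " has zero harvested area; dropped")
      next
    }
    for (y in seq_len(ny)) {
      num <- 0; den <- 0
      for (w in waters) {
        v <- cube$values[config, scenario, w, y, cells]
        m <- cube$mask[config, scenario, w, y, cells]
        ha <- area[cells, w]
        keep <- m & ha > 0
        num <- num + sum(v[keep] * ha[keep])
        den <- den + sum(ha[keep])
      }
      if (den > 0)
        out$yield[out$country_id == gi & out$year == y] <- num / den
    }
  }
  out
}

#' Ensemble mean series with a 95 % confidence interval
#'
#' Per-year mean over configurations and the t-based confidence interval of
#' that mean. With a single configuration the interval is undefined and
#' returned as missing.
#'
#' @param series numeric matrix, years x configurations.
#' @param level confidence level (default 0.95).
#' @return data.frame `year`, `mean`, `lo`, `hi`.
#' @export
ensemble_mean_series <- function(series, level = 0.95) {
  series <- as.matrix(series)
  k <- ncol(series)
  m <- rowMeans(series)
  if (k < 2L) {
    return(data.frame(year = seq_len(nrow(series)), mean = m,
                      lo = NA_real_, hi = NA_real_))
  }
  s <- apply(series, 1, sd)
  half <- qt(1 - (1 - level) / 2, df = k - 1) * s / sqrt(k)
  data.frame(year = seq_len(nrow(series)), mean = m, lo = m - half,
             hi = m + half)
}
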