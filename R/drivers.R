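#' Build the per-cell driver table
#'
#' One row per cell and water regime with the ensemble agreement metrics
#' (cross-config CV of long-term means, median pairwise correlation), the
#' cell's N application rate, climate region, and the ensemble's
#' cultivar-agreement class -- the table behind regressions of disagreement
#' on fertilizer input.
#'
#' @param cube a [yield_cube()] over >= 2 configurations.
#' @param world the `world`.
#' @param configs the list of `setup_config`s the cube was run with.
#' @param scenario scenario to evaluate (default `"fullharm"`).
#' @param waters water regimes to include.
#' @param years evaluation window (default: valid years).
#' @return data.frame `cell_id`, `water_regime`, `cv_av`, `median_r`,
#'   `n_rate`, `climate_region`, `cultivar_class`.
#' @export
build_driver_table <- function(cube, world, configs, scenario = "fullharm",
                               waters = c("rainfed", "irrigated"),
                               years = NULL) {
  cls <- vapply(world$cells$cell_id, function(g)
    classify_cultivar_agreement(configs, world, g), character(1))
  out <- list()
  for (w in waters) {
    f_cv <- cv_av(cube, scenario, w, years)
    f_r <- median_r_field(cube, scenario, w, years)
    out[[w]] <- data.frame(
      cell_id = world$cells$cell_id, water_regime = w,
      cv_av = f_cv$value, median_r = f_r$value,
      n_rate = world$cells$n_rate,
      climate_region = world$cells$climate_region,
      cultivar_class = cls)
  }
  do.call(rbind, out)
}

#' Classify ensemble cultivar agreement in one cell
#'
#' `all_high` when every configuration plants one of the high-yielding
#' cultivars 1 or 2; `dominant_low` when at least `n_configs - 1`
#' configurations plant the low-yielding drought-sensitive cultivar 4;
#' otherwise `mixed`.
#'
#' @param configs list of `setup_config`s.
#' @param world the `world`.
#' @param cell cell id.
#' @return one of `"all_high"`, `"dominant_low"`, `"mixed"`.
#' @export
classify_cultivar_agreement <- function(configs, world, cell) {
  country <- world$cells$country_id[world$cells$cell_id == cell]
  planted <- vapply(configs, function(cfg)
    cultivar_map(cfg, world)[[as.character(country)]], integer(1))
  if (all(planted %in% c(1L, 2L))) return("all_high")
  if (sum(planted == 4L) >= length(planted) - 1L) return("dominant_low")
  "mixed"
}

#' Regress an agreement metric on the N application rate
#'
#' Ordinary least squares of the metric on the fertilizer rate over the cells
#' of one climate region and water regime, restricted to rates at or below
#' `cap` (very high rates correspond to saturated N supply and are excluded
#' from the linear fit).
#'
#' @param table driver table from [build_driver_table()].
#' @param metric `"cv_av"` or `"median_r"`.
#' @param region climate region (or `NULL` for all).
#' @param water water regime.
#' @param cap maximum N rate included, kg N ha^-1 (default 200).
#' @return list `slope`, `intercept`, `r_squared`, `p_value`, `n`; all NA
#'   (with a warning) when fewer than 3 cells remain.
#' @export
regress_metric_vs_n <- function(table, metric = c("cv_av", "median_r"),
                                region = NULL, water = "irrigated",
                                cap = 200) {
  metric <- match.arg(metric)
  sub <- table[table$water_regime == water & table$n_rate <= cap, ]
  if (!is.null(region)) sub <- sub[sub$climate_region == region, ]
  sub <- sub[!is.na(sub[[metric]]), ]
  if (nrow(sub) < 3L || sd(sub$n_rate) == 0) {
    warning("degenerate stratum: fewer than 3 usable cells")
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, p_value = NA_real_, n = nrow(sub)))
  }
  if (sd(sub[[metric]]) == 0)
    return(list(slope = 0, intercept = sub[[metric]][1], r_squared = 0,
                p_value = NA_real_, n = nrow(sub)))
  fit <- lm(sub[[metric]] ~ sub$n_rate)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]), n = nrow(sub))
}

#' Bin cells by fertilizer application rate
#'
#' Half-open bins `[k w, (k+1) w)`; per bin the median and interquartile
#' range of the chosen metric.
#'
#' @param table driver table.
#' @param metric `"cv_av"` or `"median_r"`.
#' @param bin_width bin width, kg N ha^-1 (default 50).
#' @return data.frame `bin_lo`, `bin_hi`, `n`, `median`, `q25`, `q75`.
#' @export
bin_by_fertilizer <- function(table, metric = c("cv_av", "median_r"),
                              bin_width = 50) {
  metric <- match.arg(metric)
  stopifnot(bin_width > 0)
  k <- floor(table$n_rate / bin_width)
  out <- do.call(rbind, lapply(sort(unique(k)), function(kk) {
    v <- table[[metric]][k == kk]
    v <- v[!is.na(v)]
    data.frame(bin_lo = kk * bin_width, bin_hi = (kk + 1) * bin_width,
               n = sum(k == kk),
               median = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
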