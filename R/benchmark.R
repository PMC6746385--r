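#' Detrend a reported yield series
#'
#' Removes technology/management trends by subtracting the 5-year centered
#' moving mean (shrunk at the edges) and recombining the anomalies with the
#' series mean over a reference window for which input levels are considered
#' representative. The default recombination is additive
#' (`anomaly + ref-window mean`); a multiplicative mode
#' (`y / movmean * ref-window mean`) is available since the wording of the
#' protocol admits either reading.
#'
#' @param y numeric series (length >= `window`).
#' @param window moving-mean width (default 5, centered).
#' @param ref_window indices of the reference period (default: the central 7
#'   years of the series).
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @return detrended series, same length as `y`.
#' @export
detrend_reported <- function(y, window = 5, ref_window = NULL,
                             mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  n <- length(y)
  if (all(is.na(y))) stop("data error: all-missing series")
  if (n < window) stop("data error: series shorter than the moving window")
  if (is.null(ref_window)) {
    mid <- ceiling(n / 2)
    ref_window <- max(1, mid - 3):min(n, mid + 3)
  }
  half <- (window - 1) %/% 2
  mm <- vapply(seq_len(n), function(t)
    mean(y[max(1, t - half):min(n, t + half)], na.rm = TRUE), numeric(1))
  ref <- mean(y[ref_window], na.rm = TRUE)
  if (mode == "additive") (y - mm) + ref else (y / mm) * ref
}

#' Filter countries for benchmarking
#'
#' Retains countries whose statistics are considered reliable: drops (a)
#' countries whose production/area data were flagged as agency-estimated and
#' (b) countries whose harvested area fluctuates by more than
#' `max_fluctuation` (as `(max - min) / min`) over the study period, which
#' would be inconsistent with the static cropland mask used in aggregation.
#' A minimum area of zero triggers rule (b).
#'
#' @param reported a `reported_yields` data.frame.
#' @param max_fluctuation maximum tolerated relative area fluctuation
#'   (default 1.0, i.e. 100 %).
#' @return list: `retained` (country ids), `dropped_flagged`,
#'   `dropped_fluctuating`.
#' @export
filter_countries <- function(reported, max_fluctuation = 1.0) {
  ids <- unique(reported$country_id)
  flagged <- vapply(ids, function(id)
    any(reported$fao_estimated_flag[reported$country_id == id]), logical(1))
  fluct <- vapply(ids, function(id) {
    a <- reported$harvested_area[reported$country_id == id]
    if (min(a) <= 0) return(TRUE)
    (max(a) - min(a)) / min(a) > max_fluctuation
  }, logical(1))
  list(retained = ids[!flagged & !fluct],
       dropped_flagged = ids[flagged],
       dropped_fluctuating = ids[fluct & !flagged])
}

#' Benchmark simulated national yields against detrended reported yields
#'
#' For every retained country and configuration, computes Pearson's r between
#' the simulated national series and the detrended reported series over the
#' evaluation window, and the mean error. A result is significant when r
#' exceeds the two-sided critical value at `alpha` and is positive. Exactly
#' one configuration per country is flagged best, by highest r with ties
#' broken by lower |ME| and then label order. Simulated series are not
#' detrended (the simulator has no technology trend).
#'
#' @param simulated long data.frame `config`, `country_id`, `year`, `yield`.
#' @param reported a `reported_yields` data.frame (raw; detrending is applied
#'   here per country).
#' @param window year indices of the evaluation period (default: years 2..n).
#' @param alpha significance level (default 0.1).
#' @param max_fluctuation passed to [filter_countries()].
#' @param detrend_mode passed to [detrend_reported()].
#' @return list: `results` (data.frame `country_id`, `config`, `r`, `me`,
#'   `significant`, `best_flag`), `counts` (per-config `best` and `all`
#'   significant counts), `retained` country ids.
#' @export
benchmark_yields <- function(simulated, reported, window = NULL, alpha = 0.1,
                             max_fluctuation = 1.0,
                             detrend_mode = "additive") {
  configs <- sort(unique(simulated$config))
  if (!length(configs)) stop("configuration error: need >= 1 config")
  keep <- filter_countries(reported, max_fluctuation)
  years_all <- sort(unique(reported$year))
  if (is.null(window)) window <- years_all[-1]
  res <- list()
  for (id in keep$retained) {
    rep_c <- reported[reported$country_id == id, ]
    rep_c <- rep_c[order(rep_c$year), ]
    det <- detrend_reported(rep_c$yield, ref_window = NULL,
                            mode = detrend_mode)
    names(det) <- rep_c$year
    for (cfg in configs) {
      sim_c <- simulated[simulated$config == cfg &
                           simulated$country_id == id, ]
      sim_c <- sim_c[order(sim_c$year), ]
      yrs <- intersect(intersect(sim_c$year[!is.na(sim_c$yield)],
                                 rep_c$year), window)
      if (length(yrs) < 3L) next
      est <- sim_c$yield[match(yrs, sim_c$year)]
      ref <- det[as.character(yrs)]
      r <- if (sd(est) > 0 && sd(ref) > 0) cor(est, ref) else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        country_id = id, config = cfg, r = r,
        me = mean_error(est, ref), n_years = length(yrs))
    }
  }
  if (!length(res))
    return(list(results = NULL, counts = NULL, retained = keep$retained))
  results <- do.call(rbind, res)
  results$significant <- !is.na(results$r) &
    results$r > critical_r(results$n_years, alpha) & results$r > 0
  results$best_flag <- FALSE
  for (id in unique(results$country_id)) {
    sel <- which(results$country_id == id)
    sub <- results[sel, ]
    ord <- order(-ifelse(is.na(sub$r), -Inf, sub$r), abs(sub$me), sub$config)
    results$best_flag[sel[ord[1]]] <- TRUE
  }
  counts <- data.frame(
    config = configs,
    best = vapply(configs, function(cfg)
      sum(results$best_flag[results$config == cfg]), integer(1)),
    all = vapply(configs, function(cfg)
      sum(results$significant[results$config == cfg]), integer(1)))
  list(results = results, counts = counts, retained = keep$retained)
}

#' Benchmark the multi-model mean
#'
#' Averages the simulated national series over each configuration subset
#' (unweighted, per year) and benchmarks the mean series as if it were a
#' single model.
#'
#' @param simulated long data.frame as in [benchmark_yields()].
#' @param reported a `reported_yields` data.frame.
#' @param subsets named list of character vectors of config labels.
#' @param ... passed to [benchmark_yields()].
#' @return data.frame `subset`, `country_id`, `r`, `me`, `significant`.
#' @export
multi_model_mean_benchmark <- function(simulated, reported, subsets, ...) {
  if (!length(subsets)) stop("configuration error: empty subset list")
  out <- list()
  for (nm in names(subsets)) {
    cfgs <- subsets[[nm]]
    if (!length(cfgs)) stop("configuration error: empty subset: ", nm)
    sub <- simulated[simulated$config %in% cfgs, ]
    mgm <- stats::aggregate(yield ~ country_id + year, data = sub, FUN = mean)
    mgm$config <- nm
    bm <- benchmark_yields(mgm, reported, ...)
    if (!is.null(bm$results)) {
      res <- bm$results
      res$subset <- nm
      out[[nm]] <- res[, c("subset", "country_id", "r", "me", "significant")]
    }
  }
  do.call(rbind, out)
}

#' Top producing countries
#'
#' @param reported a `reported_yields` data.frame with `production`.
#' @param k number of countries (default 10).
#' @return integer country ids, by decreasing mean production, ties broken by
#'   ascending country id.
#' @export
top_producers <- function(reported, k = 10) {
  prod <- tapply(reported$production, reported$country_id, mean)
  ids <- as.integer(names(prod))
  ord <- order(-prod, ids)
  head(ids[ord], k)
}
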