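SETUP_DOMAINS <- c("cult", "soil_d", "soil_p", "coeff_n", "coeff_w", "manage")

#' Enumerate all 2^6 setup-domain combinations of two presets
#'
#' Materializes every configuration obtainable by splicing whole setup-domain
#' blocks from two parent configurations. Ordering is canonical binary
#' counting with the cultivar domain as the most significant bit; labels are
#' six-letter strings over {e, g} in domain order
#' (cult, soil_d, soil_p, coeff_n, coeff_w, manage), so `"eeeeee"` is the
#' full e-parent and `"gggggg"` the full g-parent.
#'
#' @param preset_e,preset_g complete `setup_config` parents.
#' @return named list of 64 `setup_config`s.
#' @export
enumerate_configs <- function(preset_e, preset_g) {
  validate_setup_config(preset_e)
  validate_setup_config(preset_g)
  out <- vector("list", 64L)
  labels <- character(64L)
  for (i in 0:63) {
    bits <- bitwAnd(bitwShiftR(i, 5:0), 1L)   # cult most significant
    label <- paste(c("e", "g")[bits + 1L], collapse = "")
    blocks <- lapply(seq_along(SETUP_DOMAINS), function(j) {
      src <- if (bits[j] == 1L) preset_g else preset_e
      src[[SETUP_DOMAINS[j]]]
    })
    names(blocks) <- SETUP_DOMAINS
    out[[i + 1L]] <- setup_config(label, blocks$cult, blocks$soil_d,
                                  blocks$soil_p, blocks$coeff_n,
                                  blocks$coeff_w, blocks$manage)
    labels[i + 1L] <- label
  }
  names(out) <- labels
  out
}

#' Run the setup-domain permutation experiment
#'
#' Simulates all provided configurations (normally the 64 from
#' [enumerate_configs()]) under one scenario and water regime, and summarizes
#' each configuration's global area-weighted yield series: long-term mean,
#' normalized inter-annual variability (CV of the mean-scaled series), and
#' the mean error relative to the all-e baseline expressed as a fraction of
#' relative change.
#'
#' @param world a `world`.
#' @param configs list of `setup_config`s (must include the baseline label).
#' @param scenario scenario (default `"fullharm"`, where the permutation is
#'   evaluated).
#' @param water water regime (default `"rainfed"`, which covers the full
#'   range of uncertainty impacts).
#' @param baseline label of the reference configuration (default `"eeeeee"`).
#' @param engine simulator engine.
#' @return list of class `permutation_result`: `cube`, `global` (years x
#'   configs matrix of global yields), `summary` (data.frame `config`,
#'   `mean_yield`, `cv_t`, `me_rel`), `baseline`.
#' @export
run_permutation <- function(world, configs, scenario = "fullharm",
                            water = "rainfed", baseline = "eeeeee",
                            engine = "cpp") {
  cube <- run_ensemble(world, configs, scenario_set = scenario,
                       water_set = water, engine = engine)
  labels <- dimnames(cube$values)$config
  if (!baseline %in% labels)
    stop("configuration error: baseline ", baseline, " not among configs")
  years <- 2:world$n_years
  glob <- vapply(labels, function(lb)
    aggregate_global(cube, world, lb, scenario)$yield[years],
    numeric(length(years)))
  rownames(glob) <- years
  base <- glob[, baseline]
  summ <- data.frame(
    config = labels,
    mean_yield = colMeans(glob),
    cv_t = apply(glob, 2, cv_t),
    me_rel = apply(glob, 2, function(x) mean_error(x, base, relative = TRUE)))
  structure(list(cube = cube, global = glob, summary = summ,
                 baseline = baseline, scenario = scenario, water = water),
            class = "permutation_result")
}

#' Pairwise correlation matrix over permutation configurations
#'
#' Pearson r between the global yield series of every configuration pair.
#'
#' @param global years x configs matrix (>= 3 years), e.g.
#'   `permutation_result$global`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
config_correlation_matrix <- function(global) {
  stopifnot(nrow(global) >= 3L)
  pairwise_r_matrix(global)
}

#' Attribute permutation effects to setup domains
#'
#' For each of the six domains, collects the 32 paired differences
#' `metric(g side) - metric(e side)` obtained by toggling that domain while
#' holding the other five fixed, and summarizes them. Domains whose e and g
#' blocks are identical attribute exactly zero (splicing is exact).
#'
#' @param x a `permutation_result`, or a named numeric vector of one metric
#'   value per configuration label.
#' @param metric which summary metric to attribute when `x` is a
#'   `permutation_result`: `"mean_yield"`, `"cv_t"` or `"me_rel"`.
#' @return list of class `domain_attribution`: per domain a list with
#'   `diffs` (32 values), `mean`, `median`, `iqr`, `n_positive`,
#'   `n_negative`; plus a `summary` data.frame.
#' @export
attribute_domains <- function(x, metric = c("mean_yield", "cv_t", "me_rel")) {
  if (inherits(x, "permutation_result")) {
    metric <- match.arg(metric)
    m <- stats::setNames(x$summary[[metric]], x$summary$config)
  } else {
    m <- x
  }
  if (length(m) != 64L || is.null(names(m)))
    stop("configuration error: need 64 named per-config metric values")
  out <- list()
  for (j in seq_along(SETUP_DOMAINS)) {
    diffs <- numeric(32L)
    k <- 0L
    for (i in 0:63) {
      bits <- bitwAnd(bitwShiftR(i, 5:0), 1L)
      if (bits[j] != 0L) next
      lab_e <- paste(c("e", "g")[bits + 1L], collapse = "")
      bits[j] <- 1L
      lab_g <- paste(c("e", "g")[bits + 1L], collapse = "")
      k <- k + 1L
      diffs[k] <- m[[lab_g]] - m[[lab_e]]
    }
    out[[SETUP_DOMAINS[j]]] <- list(
      diffs = diffs, mean = mean(diffs), median = median(diffs),
      iqr = stats::IQR(diffs), n_positive = sum(diffs > 0),
      n_negative = sum(diffs < 0))
  }
  out$summary <- data.frame(
    domain = SETUP_DOMAINS,
    mean = vapply(SETUP_DOMAINS, function(d) out[[d]]$mean, numeric(1)),
    median = vapply(SETUP_DOMAINS, function(d) out[[d]]$median, numeric(1)),
    iqr = vapply(SETUP_DOMAINS, function(d) out[[d]]$iqr, numeric(1)))
  class(out) <- "domain_attribution"
  out
}
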