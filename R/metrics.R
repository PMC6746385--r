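#' Coefficient of variation
#'
#' `cv = 100 * S / mean`, with `S` the sample (n-1) standard deviation.
#' Undefined (returned as `NA`) when the mean is zero.
#'
#' @param x numeric series, length >= 2 (NAs dropped).
#' @return percent.
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("cv needs n >= 2")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * sd(x) / m
}

#' Coefficient of variation of the mean-normalized series
#'
#' The series is scaled so its mean is 1 before taking the CV, removing bias
#' from changes in yield magnitude. Analytically identical to [cv()] (the CV
#' is scale invariant); kept as a separate operation for protocol fidelity.
#'
#' @inheritParams cv
#' @export
cv_t <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("cv_t needs n >= 2")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  cv(x / m)
}

#' Cross-configuration CV of long-term mean yields, per cell
#'
#' For each grid cell, the long-term mean yield over the evaluation window is
#' computed per configuration, and the CV is taken across configurations --
#' the ensemble's absolute-bias agreement metric.
#'
#' @param cube a [yield_cube()] with >= 2 configurations.
#' @param scenario,water scenario and water regime labels.
#' @param years evaluation window (default: all masked-valid years, i.e.
#'   year 2 onward).
#' @return `metric_field` data.frame: `cell_id`, `value` (percent), with the
#'   metric name, scenario, water regime and window as attributes.
#' @export
cv_av <- function(cube, scenario, water, years = NULL) {
  metric_field_over_cells(cube, scenario, water, years, function(mat) {
    # mat: years x configs of valid yields
    means <- colMeans(mat, na.rm = TRUE)
    if (sum(!is.na(means)) < 2L) return(NA_real_)
    cv(means)
  }, "cv_av")
}

#' Per-cell median pairwise time-series correlation
#'
#' Pearson's r between the yield time series of every pair of configurations
#' in each grid cell over the evaluation window, summarized as the median of
#' the off-diagonal pairs. Pairs with a zero-variance member are excluded.
#'
#' @inheritParams cv_av
#' @return `metric_field` data.frame: `cell_id`, `value` in [-1, 1].
#' @export
median_r_field <- function(cube, scenario, water, years = NULL) {
  metric_field_over_cells(cube, scenario, water, years, function(mat) {
    median_r(pairwise_r_matrix(mat))
  }, "median_r")
}

metric_field_over_cells <- function(cube, scenario, water, years, fn, name) {
  dn <- dimnames(cube$values)
  stopifnot(scenario %in% dn$scenario, water %in% dn$water)
  if (is.null(years)) years <- 2:length(dn$year)
  cells <- as.integer(dn$cell)
  vals <- vapply(seq_along(cells), function(g) {
    v <- cube$values[, scenario, water, years, g, drop = FALSE]
    m <- cube$mask[, scenario, water, years, g, drop = FALSE]
    mat <- matrix(ifelse(m, v, NA_real_), nrow = dim(v)[1])
    fn(t(mat))
  }, numeric(1))
  structure(data.frame(cell_id = cells, value = vals),
            metric = name, scenario = scenario, water = water,
            window = years, class = c("metric_field", "data.frame"))
}

#' Pairwise correlation matrix across configurations in one cell
#'
#' @param cube a [yield_cube()].
#' @param cell cell id.
#' @param window year indices (length >= 3).
#' @param scenario,water scenario and water regime labels.
#' @return symmetric matrix of Pearson r over configurations; entries are NA
#'   where either series has zero variance.
#' @export
pairwise_r <- function(cube, cell, window, scenario, water) {
  stopifnot(length(window) >= 3L)
  dn <- dimnames(cube$values)
  g <- match(as.character(cell), dn$cell)
  v <- cube$values[, scenario, water, window, g, drop = FALSE]
  m <- cube$mask[, scenario, water, window, g, drop = FALSE]
  mat <- t(matrix(ifelse(m, v, NA_real_), nrow = dim(v)[1]))
  colnames(mat) <- dn$config
  pairwise_r_matrix(mat)
}

pairwise_r_matrix <- function(mat) {
  k <- ncol(mat)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  diag(out) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- !is.na(mat[, i]) & !is.na(mat[, j])
    if (sum(ok) >= 3L && sd(mat[ok, i]) > 0 && sd(mat[ok, j]) > 0)
      out[i, j] <- out[j, i] <- cor(mat[ok, i], mat[ok, j])
  }
  out
}

#' Median of the off-diagonal pairwise correlations
#'
#' @param r_matrix symmetric correlation matrix from [pairwise_r()].
#' @return median over the upper-triangle pairs, excluding missing pairs;
#'   `NA` if no valid pair exists.
#' @export
median_r <- function(r_matrix) {
  v <- r_matrix[upper.tri(r_matrix)]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  median(v)
}

#' Mean error between an estimated and a reference series
#'
#' `ME = mean(est - ref)` over aligned years; in relative mode the result is
#' divided by the reference mean (the fraction of relative change used in the
#' setup-domain permutation).
#'
#' @param estimate,reference numeric series of equal length, aligned years.
#' @param relative logical.
#' @return t ha^-1, or a dimensionless fraction when `relative = TRUE`.
#' @export
mean_error <- function(estimate, reference, relative = FALSE) {
  if (length(estimate) != length(reference))
    stop("data error: series are not aligned")
  ok <- !is.na(estimate) & !is.na(reference)
  me <- mean(estimate[ok] - reference[ok])
  if (relative) me / mean(reference[ok]) else me
}

#' Critical Pearson correlation at a two-sided significance level
#'
#' `r* = t* / sqrt(t*^2 + n - 2)` with `t*` the two-sided t quantile on
#' n - 2 degrees of freedom. For n = 30 and alpha = 0.1 this gives 0.306,
#' the conventional "r > 0.31" threshold.
#'
#' @param n sample size (>= 4).
#' @param alpha significance level in (0, 1).
#' @export
critical_r <- function(n, alpha = 0.1) {
  stopifnot(n >= 4, alpha > 0, alpha < 1)
  tstar <- qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}

#' Fraction of grid cells whose median correlation clears significance
#'
#' @param metric_field a `metric_field` of median r values.
#' @param n sample size used in each correlation (window length).
#' @param alpha_levels significance levels.
#' @return data.frame `alpha`, `critical_r`, `fraction_pct`.
#' @export
fraction_significant <- function(metric_field, n, alpha_levels = c(0.1, 0.01)) {
  v <- metric_field$value[!is.na(metric_field$value)]
  if (!length(v)) {
    warning("empty metric field")
    return(data.frame(alpha = numeric(), critical_r = numeric(),
                      fraction_pct = numeric()))
  }
  rc <- vapply(alpha_levels, critical_r, numeric(1), n = n)
  data.frame(alpha = alpha_levels, critical_r = rc,
             fraction_pct = vapply(rc, function(r) 100 * mean(v > r),
                                   numeric(1)))
}

#' Quantile table of a metric field
#'
#' Standard empirical quantiles (type 7) of the per-cell metric values.
#'
#' @param metric_field a `metric_field`.
#' @param probs quantile probabilities.
#' @return data.frame `prob`, `value`.
#' @export
quantile_table <- function(metric_field,
                           probs = c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)) {
  v <- metric_field$value[!is.na(metric_field$value)]
  data.frame(prob = probs,
             value = as.numeric(quantile(v, probs, type = 7)))
}
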