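# hand-built cube: full control over values and areas
build_cube <- function(vals_irr, vals_rain, n_years) {
  nc <- ncol(vals_irr)
  dn <- list(config = "cfg", scenario = "fullharm",
             water = c("rainfed", "irrigated"),
             year = as.character(seq_len(n_years)),
             cell = as.character(seq_len(nc)))
  v <- array(NA_real_, c(1, 1, 2, n_years, nc), dimnames = dn)
  v[1, 1, "irrigated", , ] <- vals_irr
  v[1, 1, "rainfed", , ] <- vals_rain
  m <- array(TRUE, dim(v), dimnames = dn)
  m[, , , 1, ] <- FALSE
  yield_cube(v, m)
}

fake_world <- function(area_r, area_i, country = rep(1L, length(area_r))) {
  structure(list(
    cells = data.frame(cell_id = seq_along(area_r), country_id = country,
                       area_rainfed = area_r, area_irrigated = area_i),
    countries = data.frame(country_id = unique(country)),
    n_years = 3L), class = "world")
}

test_that("national aggregation implements the area-weighted mean", {
  # one cell, no irrigated area: national equals the rainfed yield
  cube <- build_cube(matrix(9, 3, 1), matrix(5, 3, 1), 3)
  w <- fake_world(100, 0)
  out <- aggregate_national(cube, w, "cfg", "fullharm")
  expect_equal(out$yield[out$year > 1], c(5, 5))
  # two cells, equal rainfed areas, yields 2 and 4 -> 3
  cube <- build_cube(matrix(0, 3, 2), matrix(c(2, 4), 3, 2, byrow = TRUE), 3)
  w <- fake_world(c(50, 50), c(0, 0))
  out <- aggregate_national(cube, w, "cfg", "fullharm")
  expect_equal(out$yield[out$year == 2], 3)
  # random 20-cell country against the brute-force oracle
  set.seed(8)
  vi <- matrix(runif(60, 1, 9), 3, 20)
  vr <- matrix(runif(60, 1, 9), 3, 20)
  ai <- runif(20, 0, 500); ar <- runif(20, 10, 500)
  cube <- build_cube(vi, vr, 3)
  w <- fake_world(ar, ai)
  out <- aggregate_national(cube, w, "cfg", "fullharm")
  for (y in 2:3)
    expect_equal(out$yield[out$year == y],
                 oracle_eq1(vi[y, ], ai, vr[y, ], ar), tolerance = 1e-12)
  # area scale invariance and bounds
  w2 <- fake_world(ar * 7, ai * 7)
  expect_equal(aggregate_national(cube, w2, "cfg", "fullharm")$yield,
               out$yield, tolerance = 1e-12)
  expect_true(all(out$yield[-1] >= min(vi, vr) & out$yield[-1] <= max(vi, vr)))
  # zero-area country dropped with a warning
  w3 <- fake_world(rep(0, 20), rep(0, 20))
  expect_warning(aggregate_national(cube, w3, "cfg", "fullharm"), "zero")
})

test_that("global aggregation equals the area-weighted national combination", {
  set.seed(9)
  vi <- matrix(runif(30, 1, 9), 3, 10)
  vr <- matrix(runif(30, 1, 9), 3, 10)
  ai <- runif(10, 0, 300); ar <- runif(10, 10, 300)
  country <- rep(1:2, each = 5)
  cube <- build_cube(vi, vr, 3)
  w <- fake_world(ar, ai, country)
  glob <- aggregate_global(cube, w, "cfg", "fullharm")
  nat <- aggregate_national(cube, w, "cfg", "fullharm")
  wts <- tapply(ar + ai, country, sum)
  for (y in 2:3) {
    ny <- nat$yield[nat$year == y]
    expect_equal(glob$yield[glob$year == y],
                 sum(ny * wts) / sum(wts), tolerance = 1e-12)
  }
})

test_that("ensemble mean series carries a textbook t-interval", {
  m <- cbind(a = c(3, 3), b = c(5, 5))
  out <- ensemble_mean_series(m)
  expect_equal(out$mean, c(4, 4))
  out1 <- ensemble_mean_series(m[, 1, drop = FALSE])
  expect_true(all(is.na(out1$lo)))
  ident <- ensemble_mean_series(cbind(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(ident$hi - ident$lo, c(0, 0))
  set.seed(4)
  m5 <- matrix(rnorm(50, 5), 10, 5)
  out5 <- ensemble_mean_series(m5)
  for (y in c(1, 7)) {
    x <- m5[y, ]
    half <- qt(0.975, 4) * sd(x) / sqrt(5)
    expect_equal(out5$lo[y], mean(x) - half, tolerance = 1e-12)
    expect_equal(out5$hi[y], mean(x) + half, tolerance = 1e-12)
  }
})

test_that("cv family matches its closed forms and identities", {
  expect_equal(cv(c(5, 5, 5, 5)), 0)
  expect_equal(cv(c(2, 4, 6)), 50)
  set.seed(2)
  x <- runif(30, 1, 9)
  expect_equal(cv(3.7 * x), cv(x), tolerance = 1e-12)    # scale invariance
  expect_equal(cv_t(x), cv(x), tolerance = 1e-12)        # documented identity
  expect_equal(cv_t(c(1, 3)), 70.71068, tolerance = 1e-6)
  expect_true(is.na(cv(c(-1, 1))))                       # zero mean undefined
  for (k in 1:50) {
    z <- rnorm(sample(5:30, 1), mean = runif(1, 2, 9))
    expect_equal(cv(z), oracle_cv(z), tolerance = 1e-10)
  }
})

test_that("mean error matches Eq-3 semantics", {
  x <- c(4, 5, 6)
  expect_equal(mean_error(x, x), 0)
  expect_equal(mean_error(x + 1, x), 1)
  set.seed(3)
  a <- runif(20); b <- runif(20)
  expect_equal(mean_error(a, b), oracle_me(a, b), tolerance = 1e-12)
  expect_equal(mean_error(a, b, relative = TRUE),
               oracle_me(a, b) / mean(b), tolerance = 1e-12)
  expect_error(mean_error(1:3, 1:4), "aligned")
})

test_that("pairwise correlation and its median follow Eq 4", {
  dn <- list(config = c("a", "b", "c"), scenario = "fullharm",
             water = "rainfed", year = as.character(1:6),
             cell = "1")
  v <- array(NA_real_, c(3, 1, 1, 6, 1), dimnames = dn)
  v["a", 1, 1, , 1] <- 1:6
  v["b", 1, 1, , 1] <- 1:6          # identical
  v["c", 1, 1, , 1] <- 6:1          # reversed
  cube <- yield_cube(v, array(TRUE, dim(v), dn))
  r <- pairwise_r(cube, 1, 1:6, "fullharm", "rainfed")
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  expect_equal(median_r(r), -1)     # pairs (1, -1, -1) -> median -1
  # zero-variance series excluded from the median
  v["c", 1, 1, , 1] <- 2
  cube <- yield_cube(v, array(TRUE, dim(v), dn))
  r <- pairwise_r(cube, 1, 1:6, "fullharm", "rainfed")
  expect_true(is.na(r["a", "c"]))
  expect_equal(median_r(r), 1)
  # 4 seeded series against the brute-force oracle
  set.seed(6)
  dn$config <- letters[1:4]
  v <- array(rnorm(4 * 6, 5), c(4, 1, 1, 6, 1), dimnames = dn)
  cube <- yield_cube(v, array(TRUE, dim(v), dn))
  r <- pairwise_r(cube, 1, 1:6, "fullharm", "rainfed")
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(r[i, j], oracle_pearson(v[i, 1, 1, , 1], v[j, 1, 1, , 1]),
                 tolerance = 1e-12)
    vals <- c(vals, r[i, j])
  }
  expect_equal(median_r(r), median(vals))
  # invariance to positive affine transforms of each series
  v2 <- v
  for (i in 1:4) v2[i, 1, 1, , 1] <- 2.5 * v[i, 1, 1, , 1] + i
  cube2 <- yield_cube(v2, array(TRUE, dim(v2), dn))
  expect_equal(median_r(pairwise_r(cube2, 1, 1:6, "fullharm", "rainfed")),
               median_r(r), tolerance = 1e-12)
})

test_that("cv_av collapses configs as specified", {
  dn <- list(config = c("a", "b"), scenario = "fullharm", water = "rainfed",
             year = as.character(1:5), cell = c("1", "2"))
  v <- array(NA_real_, c(2, 1, 1, 5, 2), dimnames = dn)
  v["a", 1, 1, , ] <- 4
  v["b", 1, 1, , ] <- 6
  m <- array(TRUE, dim(v), dn); m[, , , 1, ] <- FALSE
  cube <- yield_cube(v, m)
  f <- cv_av(cube, "fullharm", "rainfed")
  expect_equal(f$value, rep(100 * sd(c(4, 6)) / 5, 2), tolerance = 1e-9)
  v["b", 1, 1, , ] <- 4
  f0 <- cv_av(yield_cube(v, m), "fullharm", "rainfed")
  expect_equal(f0$value, c(0, 0))
})

test_that("critical r reproduces the conventional threshold", {
  expect_equal(round(critical_r(30, 0.1), 2), 0.31)
  expect_equal(critical_r(30, 0.1), 0.306057, tolerance = 1e-5)
  expect_lt(critical_r(30, 0.99), 0.01)                   # alpha -> 1 limit
  n <- c(10, 20, 40, 80, 160)
  expect_true(all(diff(vapply(n, critical_r, numeric(1), alpha = 0.1)) < 0))
})

test_that("fraction_significant and quantile_table behave", {
  f <- structure(data.frame(cell_id = 1:4, value = c(0.9, 0.95, 1, 0.99)),
                 class = c("metric_field", "data.frame"))
  out <- fraction_significant(f, n = 30)
  expect_equal(out$fraction_pct, c(100, 100))
  empty <- structure(data.frame(cell_id = integer(), value = numeric()),
                     class = c("metric_field", "data.frame"))
  expect_warning(out0 <- fraction_significant(empty, 30), "empty")
  expect_equal(nrow(out0), 0)
  # monotone non-increasing in the critical value
  set.seed(10)
  f2 <- structure(data.frame(cell_id = 1:200,
                             value = runif(200, -1, 1)),
                  class = c("metric_field", "data.frame"))
  out2 <- fraction_significant(f2, 11, alpha_levels = c(0.2, 0.1, 0.01))
  expect_true(all(diff(out2$fraction_pct) <= 0))
  qt_ <- quantile_table(f2, c(0, 0.5, 1))
  expect_equal(qt_$value, unname(quantile(f2$value, c(0, 0.5, 1), type = 7)))
  cst <- structure(data.frame(cell_id = 1:5, value = rep(3, 5)),
                   class = c("metric_field", "data.frame"))
  expect_equal(unique(quantile_table(cst)$value), 3)
})
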