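test_that("detrending: moving-mean anomalies with reference recombination", {
  # a pure line: interior anomalies exactly zero, output = ref-window mean
  y <- 2 + 0.3 * (1:20)
  out <- detrend_reported(y, ref_window = 8:14)
  expect_equal(out[3:18], rep(mean(y[8:14]), 16), tolerance = 1e-12)
  # constant series maps to itself
  expect_equal(detrend_reported(rep(5, 12)), rep(5, 12))
  # noisy series against the independent moving-mean oracle
  set.seed(12)
  y <- 5 + cumsum(rnorm(25, 0, 0.3))
  mm <- oracle_movmean(y, 5)
  expect_equal(detrend_reported(y, ref_window = 10:16),
               (y - mm) + mean(y[10:16]), tolerance = 1e-12)
  expect_equal(detrend_reported(y, ref_window = 10:16, mode = "multiplicative"),
               y / mm * mean(y[10:16]), tolerance = 1e-12)
  expect_error(detrend_reported(rep(NA_real_, 10)), "all-missing")
  expect_error(detrend_reported(c(1, 2)), "shorter")
})

test_that("country filter drops flagged and area-fluctuating countries", {
  rep_df <- data.frame(
    country_id = rep(1:4, each = 3), year = rep(1:3, 4),
    yield = 4, production = 100,
    harvested_area = c(100, 100, 100,    # 1: stable
                       100, 250, 100,    # 2: 150 % fluctuation
                       100, 190, 100,    # 3: 90 %, retained
                       50, 50, 50),      # 4: flagged
    fao_estimated_flag = rep(c(FALSE, FALSE, FALSE, TRUE), each = 3))
  out <- filter_countries(rep_df)
  expect_equal(sort(out$retained), c(1, 3))
  expect_equal(out$dropped_flagged, 4)
  expect_equal(out$dropped_fluctuating, 2)
  # zero minimum area triggers rule (b)
  rep_df$harvested_area[rep_df$country_id == 1] <- c(0, 10, 10)
  expect_false(1 %in% filter_countries(rep_df)$retained)
})

test_that("benchmarking scores, significance and best flags", {
  set.seed(13)
  years <- 1:15
  countries <- 1:5
  base <- lapply(countries, function(i) 4 + cumsum(rnorm(15, 0, 0.4)))
  rep_df <- do.call(rbind, lapply(countries, function(i)
    data.frame(country_id = i, year = years, yield = base[[i]],
               harvested_area = 100, production = 100 * base[[i]],
               fao_estimated_flag = FALSE)))
  # config A equals the (detrended) reported signal + tiny noise; B is noise
  simA <- do.call(rbind, lapply(countries, function(i)
    data.frame(config = "A", country_id = i, year = years,
               yield = detrend_reported(base[[i]]) + rnorm(15, 0, 0.01))))
  simB <- do.call(rbind, lapply(countries, function(i)
    data.frame(config = "B", country_id = i, year = years,
               yield = 4 + rnorm(15, 0, 0.5))))
  bm <- benchmark_yields(rbind(simA, simB), rep_df, window = years)
  expect_equal(nrow(bm$results), 10)
  expect_true(all(bm$results$r[bm$results$config == "A"] > 0.99))
  expect_equal(bm$counts$best[bm$counts$config == "A"], 5)
  expect_equal(sum(bm$counts$best), length(bm$retained))
  expect_true(all(bm$results$significant[bm$results$config == "A"]))
  # a config benchmarked against itself: r = 1, ME = 0
  simSelf <- do.call(rbind, lapply(countries, function(i)
    data.frame(config = "self", country_id = i, year = years,
               yield = detrend_reported(base[[i]]))))
  bm1 <- benchmark_yields(simSelf, rep_df, window = years)
  expect_equal(bm1$results$r, rep(1, 5), tolerance = 1e-9)
  expect_equal(bm1$results$me, rep(0, 5), tolerance = 1e-9)
  expect_true(all(bm1$results$best_flag))  # single config is best everywhere
})

test_that("multi-model mean benchmarking has the averaging property", {
  set.seed(14)
  years <- 1:15
  signal <- 4 + cumsum(rnorm(15, 0, 0.4))
  rep_df <- data.frame(country_id = 1, year = years, yield = signal,
                       harvested_area = 100, production = 100 * signal,
                       fao_estimated_flag = FALSE)
  det <- detrend_reported(signal)
  sims <- do.call(rbind, lapply(1:4, function(k)
    data.frame(config = paste0("m", k), country_id = 1, year = years,
               yield = det + rnorm(15, 0, 0.6))))
  # singleton subset equals that config's r
  single <- multi_model_mean_benchmark(sims, rep_df,
                                       subsets = list(s1 = "m1"),
                                       window = years)
  bm <- benchmark_yields(sims, rep_df, window = years)
  expect_equal(single$r, bm$results$r[bm$results$config == "m1"],
               tolerance = 1e-9)
  # identical members: MGM r equals the individual r
  twin <- rbind(sims[sims$config == "m1", ],
                transform(sims[sims$config == "m1", ], config = "m1b"))
  mm <- multi_model_mean_benchmark(twin, rep_df,
                                   subsets = list(all = c("m1", "m1b")),
                                   window = years)
  expect_equal(mm$r, single$r, tolerance = 1e-9)
  # noise averaging: MGM r at least the median individual r (20 replicates)
  wins <- 0
  for (rep_i in 1:20) {
    sims_i <- do.call(rbind, lapply(1:4, function(k)
      data.frame(config = paste0("m", k), country_id = 1, year = years,
                 yield = det + rnorm(15, 0, 0.6))))
    mgm_r <- multi_model_mean_benchmark(
      sims_i, rep_df, subsets = list(all = paste0("m", 1:4)),
      window = years)$r
    ind_r <- benchmark_yields(sims_i, rep_df, window = years)$results$r
    if (mgm_r >= median(ind_r)) wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("top producers sort by mean production with id tie-break", {
  rep_df <- data.frame(country_id = rep(1:4, each = 2), year = rep(1:2, 4),
                       production = c(10, 10, 40, 40, 40, 40, 5, 5))
  expect_equal(top_producers(rep_df, 1), 2)       # tie 2/3 -> lower id first
  expect_equal(top_producers(rep_df, 3), c(2, 3, 1))
  same <- data.frame(country_id = rep(1:5, each = 2), year = rep(1:2, 5),
                     production = 7)
  expect_equal(top_producers(same, 3), 1:3)
  set.seed(15)
  rnd <- data.frame(country_id = rep(1:8, each = 3), year = rep(1:3, 8),
                    production = runif(24, 0, 100))
  means <- tapply(rnd$production, rnd$country_id, mean)
  expect_equal(top_producers(rnd, 8),
               as.integer(names(sort(means, decreasing = TRUE))))
})
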