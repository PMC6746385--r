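test_that("heat units follow the capped growing-degree rule", {
  expect_equal(heat_units(10, 14, 12, 25), 0)          # mean at base
  expect_equal(heat_units(18, 30, 8, 30), 16)          # direct evaluation
  expect_equal(heat_units(28, 36, 8, 25), 17)          # capped at t_opt - t_base
  expect_error(heat_units(20, 10, 8, 25))
})

test_that("potential heat units match a brute-force day loop, incl. wrap", {
  clim <- list(tmin = 10 + 8 * sin(2 * pi * (1:360) / 360),
               tmax = 22 + 8 * sin(2 * pi * (1:360) / 360))
  # constant-case closed form
  const <- list(tmin = rep(16, 360), tmax = rep(20, 360))
  expect_equal(compute_phu(const, 1, 100, 8, 30), 100 * 10)
  # sinusoid vs independent loop
  acc <- 0
  for (d in 50:220) acc <- acc + min(max((clim$tmin[d] + clim$tmax[d]) / 2 - 8, 0), 22)
  expect_equal(compute_phu(clim, 50, 220, 8, 30), acc, tolerance = 1e-12)
  # wrapping season equals the sum over the wrapped window
  acc <- 0
  for (d in c(300:360, 1:60)) acc <- acc + min(max((clim$tmin[d] + clim$tmax[d]) / 2 - 8, 0), 22)
  expect_equal(compute_phu(clim, 300, 60, 8, 30), acc, tolerance = 1e-12)
  expect_error(compute_phu(clim, 10, 10, 8, 30), "length zero")
})

test_that("Hargreaves PET matches a textbook oracle and its scaling laws", {
  expect_equal(hargreaves_pet(20, 20, 10, 80, 0.0023, 0.5), 0)  # zero range
  for (case in list(c(20, 30, 0, 80), c(5, 18, 45, 172), c(-2, 9, -30, 300))) {
    got <- hargreaves_pet(case[1], case[2], case[3], case[4], 0.0023, 0.5)
    expect_equal(got, oracle_hargreaves(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-9)
  }
  # linear in the linear coefficient (same exponent)
  a <- hargreaves_pet(15, 28, 35, 150, 0.0023, 0.5)
  b <- hargreaves_pet(15, 28, 35, 150, 0.0032, 0.5)
  expect_equal(b / a, 0.0032 / 0.0023, tolerance = 1e-12)
})

test_that("two-anchor S-curve interpolates its anchors and is monotone", {
  a1 <- c(0.2, 0.1); a2 <- c(0.9, 0.95)
  expect_equal(scurve_from_anchors(0.2, a1, a2), 0.1, tolerance = 1e-6)
  expect_equal(scurve_from_anchors(0.9, a1, a2), 0.95, tolerance = 1e-6)
  mid <- scurve_from_anchors(0.55, a1, a2)
  expect_true(mid > 0.1 && mid < 0.95)
  x <- seq(0.01, 2, length.out = 100)
  expect_true(all(diff(scurve_from_anchors(x, a1, a2)) > 0))
  expect_true(all(scurve_from_anchors(x, a1, a2) > 0 &
                    scurve_from_anchors(x, a1, a2) < 1))
  # percent convention of the parameter tables
  expect_equal(scurve_from_anchors(200, c(200, 5), c(500, 90), y_percent = TRUE),
               0.05, tolerance = 1e-6)
  expect_error(scurve_from_anchors(0.5, c(0.9, 0.1), c(0.2, 0.95)), "anchors")
})

test_that("water balance closes and stress hits its degenerate limits", {
  cw <- preset_config("eIIASA")$coeff_w
  f <- make_forcing(1)
  s <- f$soil_init
  # storage at wilting point, no input: nothing to evaporate or transpire
  s$water <- s$wp
  out <- water_balance_step(s, 0, 0, 5, 0.6, cw)
  expect_equal(out$actual_et, 0)
  expect_equal(out$water_stress, 0)
  # storage at field capacity: demand fully met
  s$water <- s$fc
  out <- water_balance_step(s, 0, 0, 4, 0.8, cw)
  expect_equal(out$water_stress, 1)
  # random 90-day forcing: cumulative mass balance to 1e-6 mm
  s <- f$soil_init
  storage0 <- sum(s$water)
  influx <- 0; outflux <- 0
  for (d in seq_len(90)) {
    out <- water_balance_step(s, f$prec[d], 0, 4, 0.5, cw)
    s <- out$soil
    influx <- influx + f$prec[d]
    outflux <- outflux + out$runoff + out$percolation + out$actual_et
  }
  expect_equal(sum(s$water) - storage0, influx - outflux, tolerance = 1e-6)
})

test_that("nutrient step conserves N and has correct stress limits", {
  cn <- preset_config("gGEPIC")$coeff_n
  s <- make_forcing(2)$soil_init
  # zero demand: no stress
  out <- nutrient_step(s, 0.8, 0.6, 0, 0, cn)
  expect_equal(out$n_stress, 1)
  expect_equal(out$p_stress, 1)
  # empty pools, positive demand: full stress
  s0 <- s
  s0$mineral_n[] <- 0; s0$organic_n[] <- 0
  out <- nutrient_step(s0, 0.8, 0.6, 5, 0, cn)
  expect_equal(out$n_stress, 0)
  # single-step closed form
  out <- nutrient_step(s, 0.5, 0.4, 2, 0.5, cn)
  oxf <- 1 - scurve_from_anchors(s$depth_mid_mm, c(200, 5), c(500, 90),
                                 y_percent = TRUE)
  miner <- 1.0 * 2e-4 * 0.4 * 0.5 * oxf * s$organic_n
  expect_equal(out$mineralized, sum(miner), tolerance = 1e-12)
  expect_equal(out$soil$organic_n, s$organic_n - miner, tolerance = 1e-12)
  # N mass conservation over a random multi-step run
  s1 <- s
  total0 <- sum(s1$organic_n) + sum(s1$mineral_n)
  losses <- 0; uptake <- 0
  set.seed(9)
  for (k in 1:200) {
    out <- nutrient_step(s1, runif(1), runif(1), runif(1, 0, 4), runif(1, 0, 1), cn)
    s1 <- out$soil
    losses <- losses + out$volatilized + out$denitrified
    uptake <- uptake + out$n_supply
  }
  total1 <- sum(s1$organic_n) + sum(s1$mineral_n)
  expect_equal(total0 - total1, losses + uptake, tolerance = 1e-9)
})

test_that("irrigation and fertilizer triggers follow the threshold semantics", {
  man <- preset_config("eBOKU")$manage      # trigger 0.9, max single 50 mm
  expect_equal(auto_irrigate(1, 300, man), 0)
  expect_equal(auto_irrigate(0.5, 300, man), 50)
  expect_equal(auto_irrigate(0.5, 30, list(irrigation_trigger = 0.9,
                                           max_single_irrigation = 500)), 30)
  expect_equal(auto_fertilize(0.95, 100, man, "fullharm"), 0)
  expect_equal(auto_fertilize(0.5, 0, man, "fullharm"), 0)       # budget gone
  expect_gt(auto_fertilize(0.5, Inf, man, "harm-suffN"), 0)      # unbounded
  expect_equal(auto_fertilize(0.1, 100,
                              preset_config("pPEPIC")$manage, "fullharm"), 0)
})
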