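test_that("season limits: stress-free HI and zero-radiation shutdown", {
  cfg <- preset_config("eIIASA")
  f <- make_forcing(3, n_days = 80, prec_mean = 8, n_budget = 400)
  # srad = 0: no interception, no growth
  f0 <- f
  f0$srad[] <- 0
  r0 <- simulate_season(f0, cfg, "fullharm", "rainfed")
  expect_equal(r0$result$aboveground_biomass, 0)
  expect_equal(r0$result$yield, 0)
  # keep soil saturated and nutrients unbounded: HI_a = hi_max
  f1 <- f
  f1$prec[] <- 8
  r1 <- simulate_season(f1, cfg, "harm-suffN", "irrigated")
  expect_equal(r1$result$hi_actual, f$cultivar$hi_max, tolerance = 1e-9)
  expect_equal(r1$result$yield,
               r1$result$aboveground_biomass * f$cultivar$hi_max,
               tolerance = 1e-9)
  expect_error(simulate_season({f$tmin[5] <- NA; f}, cfg, "fullharm",
                               "rainfed"), "missing weather")
})

test_that("season invariants hold over random forcings", {
  cfg <- preset_config("gGEPIC")
  for (k in 1:25) {
    f <- make_forcing(100 + k, n_days = sample(60:120, 1),
                      cultivar_id = sample(1:4, 1),
                      n_budget = runif(1, 0, 300), tmean = runif(1, 12, 28))
    r <- simulate_season(f, cfg, sample(c("default", "fullharm"), 1),
                         sample(c("rainfed", "irrigated"), 1))$result
    expect_gte(r$hi_actual, f$cultivar$hi_min - 1e-12)
    expect_lte(r$hi_actual, f$cultivar$hi_max + 1e-12)
    expect_equal(r$yield, r$aboveground_biomass * r$hi_actual, tolerance = 1e-9)
    expect_lte(sum(r$stress_days), length(f$doys))
    expect_gte(r$yield, 0)
  }
})

test_that("end-of-year update applies the static/dynamic/decadal rules", {
  f <- make_forcing(5)
  init <- f$soil_init
  s <- init
  s$organic_n <- s$organic_n * 0.7
  s$mineral_n <- s$mineral_n + 12
  s$water <- s$wp + 0.3 * (s$fc - s$wp)
  st <- end_of_year_soil_update(s, init, list(handling = "static",
                                              topsoil_loss_rate = 0))
  expect_identical(st$organic_n, init$organic_n)   # OM reset
  expect_identical(st$mineral_n, s$mineral_n)      # mineral pools carried
  expect_identical(st$water, s$water)
  dyn0 <- end_of_year_soil_update(s, init, list(handling = "dynamic",
                                                topsoil_loss_rate = 0))
  expect_identical(dyn0, s)                        # degenerate identity
  # geometric shrinkage of the top layer
  r <- 0.01
  sk <- s
  for (k in 1:5) sk <- end_of_year_soil_update(
    sk, init, list(handling = "dynamic", topsoil_loss_rate = r))
  expect_equal(sk$thick[1], s$thick[1] * (1 - r)^5, tolerance = 1e-12)
  expect_equal(sk$organic_n[1], s$organic_n[1] * (1 - r)^5, tolerance = 1e-12)
  expect_identical(sk$thick[-1], s$thick[-1])
})

test_that("compiled engine agrees with the reference R coding to 1e-9", {
  w <- test_world(n_cells = 5, n_countries = 3, n_years = 12, seed = 21)
  cases <- expand.grid(cfg = c("eIIASA", "gGEPIC", "pPEPIC"),
                       sc = c("default", "fullharm", "harm-suffN"),
                       wr = c("rainfed", "irrigated"),
                       stringsAsFactors = FALSE)
  # a cross-section of config x scenario x water, incl. decadal and rigid fert
  for (i in sample(nrow(cases), 8)) {
    cfg <- preset_config(cases$cfg[i])
    g <- sample(5, 1)
    a <- gridcropens:::run_cell_cpp(w, cfg, cases$sc[i], cases$wr[i], g, TRUE)
    b <- gridcropens:::run_cell_r(w, cfg, cases$sc[i], cases$wr[i], g)
    expect_equal(a, b, tolerance = 1e-9,
                 info = paste(cases$cfg[i], cases$sc[i], cases$wr[i], g))
  }
  cube_r <- run_ensemble(w, list(preset_config("eIIASA")), "fullharm",
                         "rainfed", engine = "r")
  cube_c <- run_ensemble(w, list(preset_config("eIIASA")), "fullharm",
                         "rainfed", engine = "cpp")
  expect_equal(cube_r$values, cube_c$values, tolerance = 1e-9)
  expect_identical(cube_r$mask, cube_c$mask)
})

test_that("run_ensemble composition, masking and order independence", {
  w <- test_world(n_cells = 5, n_countries = 3, n_years = 12, seed = 21)
  cfgs <- list(preset_config("eIIASA"), preset_config("eBOKU"))
  cube <- run_ensemble(w, cfgs, "fullharm", "rainfed")
  expect_false(any(cube$mask[, , , 1, ]))           # first year excluded
  # single value matches a direct season simulation
  g <- 2; y <- 4
  ci <- season_inputs(w, cfgs[[1]], "fullharm", g, 1)
  m <- gridcropens:::run_cell_r(w, cfgs[[1]], "fullharm", "rainfed", g)
  expect_equal(unname(cube$values["eIIASA", "fullharm", "rainfed", y, g]),
               unname(m[y, "yield"]), tolerance = 1e-9)
  # permuting config order leaves per-config content unchanged
  cube2 <- run_ensemble(w, rev(cfgs), "fullharm", "rainfed")
  expect_equal(cube$values["eIIASA", , , , ], cube2$values["eIIASA", , , , ])
  expect_equal(cube$values["eBOKU", , , , ], cube2$values["eBOKU", , , , ])
  expect_error(run_ensemble(w, list()), "config")
})

test_that("monotonicity: more nutrients and water never reduce yields", {
  w <- test_world(n_cells = 6, n_countries = 3, n_years = 12, seed = 31)
  cfg <- preset_config("eIIASA")
  cube <- run_ensemble(w, list(cfg), c("fullharm", "harm-suffN"),
                       c("rainfed", "irrigated"), pstress = FALSE)
  a <- cube$values["eIIASA", "harm-suffN", "irrigated", , ]
  b <- cube$values["eIIASA", "fullharm", "rainfed", , ]
  m <- cube$mask["eIIASA", "harm-suffN", "irrigated", , ] &
    cube$mask["eIIASA", "fullharm", "rainfed", , ]
  expect_true(all(a[m] >= b[m] - 1e-9))
})
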