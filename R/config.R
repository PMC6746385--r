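#' Default cultivar parameter set
#'
#' Four maize cultivars spanning the high-yielding (1, 2) to low-yielding,
#' drought-sensitive (4) range. The values are plausible placeholders on the
#' documented scale (potential harvest index `hi_max` around 0.5 for modern
#' varieties, drought-sensitive types with low `hi_min`), exposed as data so
#' any ensemble member can swap in its own set; they are configuration, not
#' ground truth.
#'
#' @return data.frame with columns `cultivar_id`, `hi_min`, `hi_max`,
#'   `t_base`, `t_opt`, `rue` (radiation-use efficiency, g MJ^-1).
#' @export
default_cultivars <- function() {
  cv <- data.frame(
    cultivar_id = 1:4,
    hi_min = c(0.35, 0.30, 0.30, 0.10),
    hi_max = c(0.55, 0.53, 0.50, 0.40),
    t_base = c(8, 8, 6, 9),
    t_opt  = c(25, 26, 24, 28),
    rue    = c(4.0, 4.0, 4.0, 4.0)   # cultivars differ in HI and temperature
                                     # ranges only; RUE is a crop constant
  )
  validate_cultivars(cv)
  cv
}

validate_cultivars <- function(cv) {
  with(cv, {
    if (!all(hi_min > 0 & hi_min <= hi_max & hi_max < 1))
      stop("cultivar invariant violated: need 0 < hi_min <= hi_max < 1")
    if (!all(t_base < t_opt))
      stop("cultivar invariant violated: need t_base < t_opt")
  })
  invisible(cv)
}

#' Construct a model setup configuration
#'
#' A `setup_config` is one "GGCM": six blocks of parameters and method
#' switches grouped into the aggregated setup domains that are permuted
#' between ensemble members -- cultivars (`cult`), soil data (`soil_d`), soil
#' handling (`soil_p`), nutrient-cycling coefficients (`coeff_n`), hydrologic
#' coefficients (`coeff_w`) and crop management (`manage`).
#'
#' @param label configuration label.
#' @param cult list: `map_rule` (one of `"regional"`, `"hdi"`, `"stagnation"`,
#'   `"all_high"`, or a named integer vector country_id -> cultivar_id),
#'   `params` (cultivar table as [default_cultivars()]),
#'   `hi_min_season_fraction` (fraction of the season after which water stress
#'   affects the harvest index).
#' @param soil_d list: `hydraulic_source` (`"input_pedotransfer_A"` or
#'   `"online_pedotransfer_B"`), `n_layers`.
#' @param soil_p list: `handling` (`"static"`/`"dynamic"`), `continuity`
#'   (`"transient"`/`"decadal"`), `spinup_years`, `topsoil_loss_rate`
#'   (fraction yr^-1 in [0, 0.05]).
#' @param coeff_n list: `microbial_decay`, `n_volatilization`, `denit_rate`,
#'   `moisture_fn_anchors`, `oxygen_fn_anchors` (each a list of two `c(x, y)`
#'   pairs, y in percent).
#' @param coeff_w list: `hargreaves_lin`, `hargreaves_exp`, `soil_evap_coeff`,
#'   `cn_index_coeff`.
#' @param manage list: `irrigation_trigger`, `max_single_irrigation` (mm),
#'   `fert_trigger` (fraction, or `"fixed"` for rigid timing at planting),
#'   `row_spacing_factor`, `residue_removal`, `default_nrate_factor`,
#'   `default_season_shift` (days; the latter two define the member's own
#'   "default"-scenario management assumptions).
#' @return object of class `setup_config`.
#' @export
setup_config <- function(label, cult, soil_d, soil_p, coeff_n, coeff_w, manage) {
  cfg <- structure(list(label = label, cult = cult, soil_d = soil_d,
                        soil_p = soil_p, coeff_n = coeff_n, coeff_w = coeff_w,
                        manage = manage),
                   class = "setup_config")
  validate_setup_config(cfg)
}

#' @rdname setup_config
#' @param cfg a `setup_config`.
#' @export
validate_setup_config <- function(cfg) {
  blocks <- c("cult", "soil_d", "soil_p", "coeff_n", "coeff_w", "manage")
  miss <- blocks[!vapply(blocks, function(b) !is.null(cfg[[b]]), logical(1))]
  if (length(miss))
    stop("configuration error: missing setup domain block(s): ",
         paste(miss, collapse = ", "))
  m <- cfg$manage
  trig <- c(m$irrigation_trigger,
            if (!identical(m$fert_trigger, "fixed")) m$fert_trigger)
  if (!all(trig > 0 & trig <= 1))
    stop("configuration error: triggers must lie in (0, 1]")
  if (!(m$max_single_irrigation > 0))
    stop("configuration error: max_single_irrigation must be > 0")
  sp <- cfg$soil_p
  if (sp$topsoil_loss_rate < 0 || sp$topsoil_loss_rate > 0.05)
    stop("configuration error: topsoil_loss_rate must lie in [0, 0.05]")
  if (!sp$handling %in% c("static", "dynamic"))
    stop("configuration error: unknown soil handling")
  if (!sp$continuity %in% c("transient", "decadal"))
    stop("configuration error: unknown simulation continuity")
  if (!cfg$soil_d$hydraulic_source %in%
        c("input_pedotransfer_A", "online_pedotransfer_B"))
    stop("configuration error: unknown hydraulic source")
  validate_cultivars(cfg$cult$params)
  invisible(cfg)
}

# microbial moisture response shared by all shipped presets (not tabulated
# per member); x is the profile soil moisture index, y in percent
MOISTURE_ANCHORS <- list(c(0.20, 5), c(0.90, 95))

#' Shipped setup presets
#'
#' Five ready-made `setup_config`s emulating the spread of published
#' EPIC-based GGCM setups. `"eIIASA"` and `"gGEPIC"` are the two members used
#' in the setup-domain permutation (static/transient with prescribed soil
#' hydraulics versus dynamic/decadal with online pedotransfer); `"eBOKU"`,
#' `"eTAMU"` and `"pPEPIC"` complete the five-member ensemble. Members whose
#' real-world counterparts use Penman-Monteith PET are given the textbook
#' Hargreaves coefficients (0.0023, 0.5) as a documented stand-in, since only
#' Hargreaves is implemented.
#'
#' @param name one of `"eIIASA"`, `"gGEPIC"`, `"eBOKU"`, `"eTAMU"`, `"pPEPIC"`.
#' @return a `setup_config`.
#' @export
preset_config <- function(name = c("eIIASA", "gGEPIC", "eBOKU", "eTAMU", "pPEPIC")) {
  name <- match.arg(name)
  cv <- default_cultivars()
  base_cult <- function(rule, fhi) list(map_rule = rule, params = cv,
                                        hi_min_season_fraction = fhi)
  switch(name,
    eIIASA = setup_config("eIIASA",
      cult   = base_cult("regional", 0.50),
      soil_d = list(hydraulic_source = "input_pedotransfer_A", n_layers = 10L),
      soil_p = list(handling = "static", continuity = "transient",
                    spinup_years = 0L, topsoil_loss_rate = 0),
      coeff_n = list(microbial_decay = 0.8, n_volatilization = 0.700,
                     denit_rate = 0.002,
                     moisture_fn_anchors = MOISTURE_ANCHORS,
                     oxygen_fn_anchors = list(c(400, 5), c(600, 90))),
      coeff_w = list(hargreaves_lin = 0.0023, hargreaves_exp = 0.6,
                     soil_evap_coeff = 1.5, cn_index_coeff = 1.2),
      manage = list(irrigation_trigger = 0.80, max_single_irrigation = 500,
                    fert_trigger = 0.80, row_spacing_factor = 1.0,
                    residue_removal = 0.3, default_nrate_factor = 1.1,
                    default_season_shift = 0L)),
    gGEPIC = setup_config("gGEPIC",
      cult   = base_cult("hdi", 0.50),
      soil_d = list(hydraulic_source = "online_pedotransfer_B", n_layers = 5L),
      soil_p = list(handling = "dynamic", continuity = "decadal",
                    spinup_years = 5L, topsoil_loss_rate = 0.003),
      coeff_n = list(microbial_decay = 1.0, n_volatilization = 0.005,
                     denit_rate = 0.01,
                     moisture_fn_anchors = MOISTURE_ANCHORS,
                     oxygen_fn_anchors = list(c(200, 5), c(500, 90))),
      coeff_w = list(hargreaves_lin = 0.0032, hargreaves_exp = 0.5,
                     soil_evap_coeff = 2.5, cn_index_coeff = 0.5),
      manage = list(irrigation_trigger = 0.90, max_single_irrigation = 1000,
                    fert_trigger = 0.90, row_spacing_factor = 1.1,
                    residue_removal = 0.6, default_nrate_factor = 0.6,
                    default_season_shift = 8L)),
    eBOKU = setup_config("eBOKU",
      cult   = base_cult("all_high", 0.50),
      soil_d = list(hydraulic_source = "online_pedotransfer_B", n_layers = 10L),
      soil_p = list(handling = "static", continuity = "transient",
                    spinup_years = 0L, topsoil_loss_rate = 0),
      coeff_n = list(microbial_decay = 1.0, n_volatilization = 0.005,
                     denit_rate = 0.005,
                     moisture_fn_anchors = MOISTURE_ANCHORS,
                     oxygen_fn_anchors = list(c(200, 5), c(500, 90))),
      coeff_w = list(hargreaves_lin = 0.0023, hargreaves_exp = 0.5,
                     soil_evap_coeff = 2.5, cn_index_coeff = 1.5),
      manage = list(irrigation_trigger = 0.90, max_single_irrigation = 50,
                    fert_trigger = 0.90, row_spacing_factor = 1.0,
                    residue_removal = 0.3, default_nrate_factor = 1.6,
                    default_season_shift = -10L)),
    eTAMU = setup_config("eTAMU",
      cult   = base_cult("stagnation", 0.45),
      soil_d = list(hydraulic_source = "online_pedotransfer_B", n_layers = 10L),
      soil_p = list(handling = "dynamic", continuity = "transient",
                    spinup_years = 0L, topsoil_loss_rate = 0.001),
      coeff_n = list(microbial_decay = 1.0, n_volatilization = 0.030,
                     denit_rate = 0.01,
                     moisture_fn_anchors = MOISTURE_ANCHORS,
                     oxygen_fn_anchors = list(c(200, 5), c(500, 90))),
      coeff_w = list(hargreaves_lin = 0.0023, hargreaves_exp = 0.5,
                     soil_evap_coeff = 2.5, cn_index_coeff = 1.0),
      manage = list(irrigation_trigger = 0.99, max_single_irrigation = 100,
                    fert_trigger = 0.99, row_spacing_factor = 1.0,
                    residue_removal = 0.3, default_nrate_factor = 1.0,
                    default_season_shift = 0L)),
    pPEPIC = setup_config("pPEPIC",
      cult   = base_cult("hdi", 0.50),
      soil_d = list(hydraulic_source = "online_pedotransfer_B", n_layers = 10L),
      soil_p = list(handling = "dynamic", continuity = "transient",
                    spinup_years = 0L, topsoil_loss_rate = 0.003),
      coeff_n = list(microbial_decay = 1.0, n_volatilization = 0.300,
                     denit_rate = 0.01,
                     moisture_fn_anchors = MOISTURE_ANCHORS,
                     oxygen_fn_anchors = list(c(200, 5), c(500, 90))),
      coeff_w = list(hargreaves_lin = 0.0023, hargreaves_exp = 0.5,
                     soil_evap_coeff = 1.5, cn_index_coeff = 1.0),
      manage = list(irrigation_trigger = 0.90, max_single_irrigation = 500,
                    fert_trigger = "fixed", row_spacing_factor = 1.0,
                    residue_removal = 0.3, default_nrate_factor = 0.9,
                    default_season_shift = -5L))
  )
}

#' All shipped presets as a named list
#' @export
preset_ensemble <- function() {
  nm <- c("eIIASA", "gGEPIC", "eBOKU", "eTAMU", "pPEPIC")
  stats::setNames(lapply(nm, preset_config), nm)
}

#' Crop management scenario table
#'
#' The six management scenarios: three harmonization levels (member-specific
#' "default", harmonized growing seasons and fertilizer rates "fullharm",
#' harmonized with unlimited nutrient supply "harm-suffN") crossed with two
#' water regimes (rainfed, irrigated with automatic scheduling).
#'
#' @return data.frame with columns `scenario`, `water_regime`, `name`.
#' @export
scenarios <- function() {
  grid <- expand.grid(water_regime = c("irrigated", "rainfed"),
                      scenario = c("default", "fullharm", "harm-suffN"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("scenario", "water_regime")]
  grid$name <- paste(grid$scenario, grid$water_regime, sep = "_")
  grid
}

#' Resolve a configuration's cultivar map for a world
#'
#' Applies the configuration's distribution rule to the world's country table:
#' `"all_high"` plants cultivar 1 everywhere; `"stagnation"` plants the
#' low-yielding cultivar 4 where yields have stagnated (here: low development
#' index), cultivar 2 elsewhere; `"hdi"` plants cultivar 2 in highly developed
#' countries (index >= 0.8) and cultivar 4 elsewhere; `"regional"` assigns
#' four cultivars by the country's dominant climate region and development.
#'
#' @param config a `setup_config`.
#' @param world a `world`.
#' @return named integer vector, country_id -> cultivar_id.
#' @export
cultivar_map <- function(config, world) {
  co <- world$countries
  rule <- config$cult$map_rule
  if (is.numeric(rule)) {
    out <- as.integer(rule[as.character(co$country_id)])
    if (anyNA(out)) stop("configuration error: explicit cultivar map is ",
                         "missing countries")
    return(stats::setNames(out, co$country_id))
  }
  dominant_region <- vapply(co$country_id, function(id) {
    reg <- world$cells$climate_region[world$cells$country_id == id]
    names(sort(table(reg), decreasing = TRUE))[1]
  }, character(1))
  out <- switch(rule,
    all_high = rep(1L, nrow(co)),
    hdi = ifelse(co$dev_index >= 0.65, 2L, 4L),
    stagnation = ifelse(co$stagnating, 4L, 2L),
    regional = {
      r <- integer(nrow(co))
      r[dominant_region %in% c("cold", "temperate")] <- 1L
      r[dominant_region == "tropical"] <- ifelse(
        co$dev_index[dominant_region == "tropical"] >= 0.5, 2L, 4L)
      r[dominant_region == "arid"] <- ifelse(
        co$dev_index[dominant_region == "arid"] >= 0.5, 2L, 3L)
      r
    },
    stop("configuration error: unknown cultivar map rule: ", rule))
  stats::setNames(as.integer(out), co$country_id)
}
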