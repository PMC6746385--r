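#' One daily step of the layered soil water balance
#'
#' Curve-number runoff partitioning at the surface, gravity percolation
#' limited by saturated conductivity, plant transpiration extraction and
#' topsoil evaporation. The retention parameter of the curve-number formula is
#' scaled down with a profile soil-moisture index, with the configured
#' `cn_index_coeff` as the exponent of that adjustment (wetter soil, more
#' runoff). Percolation occurs only above field capacity. The water stress
#' factor is actual over potential transpiration in [0, 1] (1 = no stress).
#' Mass balance closes exactly: change in storage equals
#' `precip + irrigation - runoff - actual_et - percolation`.
#'
#' @param soil_state a `soil_state`.
#' @param precip,irrigation mm.
#' @param pet potential evapotranspiration, mm.
#' @param lai_fraction canopy light interception fraction in [0, 1]; splits
#'   PET into potential transpiration and potential soil evaporation.
#' @param coeff_w the configuration's hydrologic coefficient block.
#' @return list: updated `soil`, `runoff`, `percolation` (deep, out of the
#'   profile), `actual_et`, `water_stress`, and `smi` (profile soil-moisture
#'   index, reused by the nutrient step).
#' @export
water_balance_step <- function(soil_state, precip, irrigation, pet,
                               lai_fraction, coeff_w) {
  s <- soil_state
  nl <- length(s$thick)
  stopifnot(precip >= 0, irrigation >= 0, pet >= 0)

  cap <- s$fc - s$wp
  avail <- pmax(s$water - s$wp, 0)
  smi <- min(1, sum(avail) / sum(cap))

  input <- precip + irrigation
  sret <- SIM_CONST$cn_retention_base *
    (1 - SIM_CONST$cn_smi_weight * smi)^coeff_w$cn_index_coeff
  runoff <- if (input > 0.2 * sret)
    (input - 0.2 * sret)^2 / (input + 0.8 * sret) else 0
  s$water[1] <- s$water[1] + input - runoff

  deep <- 0
  for (i in seq_len(nl)) {
    excess <- s$water[i] - s$fc[i]
    if (excess > 0) {
      perc <- min(excess, s$ksat[i])
      s$water[i] <- s$water[i] - perc
      if (i < nl) s$water[i + 1] <- s$water[i + 1] + perc else deep <- perc
    }
  }

  t_pot <- pet * lai_fraction
  avail <- pmax(s$water - s$wp, 0)
  supply <- sum(avail) * SIM_CONST$extract_frac
  t_act <- min(t_pot, supply)
  if (t_act > 0) {
    s$water <- s$water - t_act * avail / sum(avail)
  }
  e_pot <- pet * (1 - lai_fraction)
  avail1 <- max(s$water[1] - s$wp[1], 0)
  smi1 <- avail1 / cap[1]
  e_act <- min(e_pot * min(1, SIM_CONST$evap_smi_gain *
                                coeff_w$soil_evap_coeff * smi1), avail1)
  s$water[1] <- s$water[1] - e_act

  if (any(s$water < -1e-9)) stop("internal invariant violation: negative soil water")
  list(soil = s, runoff = runoff, percolation = deep,
       actual_et = t_act + e_act,
       water_stress = if (t_pot > 0) t_act / t_pot else 1,
       smi = smi)
}

#' One daily step of soil nitrogen and phosphorus cycling
#'
#' First-order mineralization of organic N modulated by the microbial decay
#' coefficient, a two-anchor moisture S-curve, a temperature factor and an
#' oxygen-by-depth factor; daily volatilization of a fraction of surface-layer
#' mineral N; a scalar first-order denitrification loss increasing with soil
#' moisture (stand-in for the method-specific denitrification routines); and
#' crop uptake limited by the available mineral pools. Stress factors are
#' supply over demand capped at 1 (1 = no limitation). Nitrogen mass is
#' conserved across pools, losses and uptake.
#'
#' @param soil_state a `soil_state`.
#' @param temp_factor,moisture_factor microbial activity factors in [0, 1].
#' @param crop_demand_n,crop_demand_p kg ha^-1 d^-1.
#' @param coeff_n the configuration's nutrient coefficient block.
#' @return list: updated `soil`, `n_supply`, `p_supply`, `n_stress`,
#'   `p_stress`, plus diagnostic fluxes `mineralized`, `volatilized`,
#'   `denitrified` (kg N ha^-1).
#' @export
nutrient_step <- function(soil_state, temp_factor, moisture_factor,
                          crop_demand_n, crop_demand_p, coeff_n) {
  s <- soil_state
  stopifnot(temp_factor >= 0, temp_factor <= 1,
            moisture_factor >= 0, moisture_factor <= 1,
            crop_demand_n >= 0, crop_demand_p >= 0)
  oxf <- 1 - scurve_from_anchors(s$depth_mid_mm,
                                 coeff_n$oxygen_fn_anchors[[1]],
                                 coeff_n$oxygen_fn_anchors[[2]],
                                 y_percent = TRUE)
  miner <- coeff_n$microbial_decay * SIM_CONST$base_mineralization *
    moisture_factor * temp_factor * oxf * s$organic_n
  s$organic_n <- s$organic_n - miner
  s$mineral_n <- s$mineral_n + miner

  vol <- coeff_n$n_volatilization * SIM_CONST$vol_scale * s$mineral_n[1]
  s$mineral_n[1] <- s$mineral_n[1] - vol

  # denitrification only under near-saturated (anaerobic) conditions
  anaer <- clamp((moisture_factor - 0.75) / 0.25, 0, 1)
  denit <- coeff_n$denit_rate * anaer^2 * s$mineral_n
  s$mineral_n <- s$mineral_n - denit

  # pools drained to zero can leave O(1e-19) negative residuals; clamp the
  # extractable total so stresses stay in [0, 1]
  tot_n <- sum(s$mineral_n)
  n_supply <- min(crop_demand_n, max(tot_n, 0))
  if (n_supply > 0) s$mineral_n <- s$mineral_n - n_supply * s$mineral_n / tot_n
  tot_p <- sum(s$labile_p)
  p_supply <- min(crop_demand_p, max(tot_p, 0))
  if (p_supply > 0) s$labile_p <- s$labile_p - p_supply * s$labile_p / tot_p

  if (any(s$mineral_n < -1e-9) || any(s$organic_n < -1e-9) ||
      any(s$labile_p < -1e-9))
    stop("internal invariant violation: negative nutrient pool")
  list(soil = s, n_supply = n_supply, p_supply = p_supply,
       n_stress = if (crop_demand_n > 0) min(1, n_supply / crop_demand_n) else 1,
       p_stress = if (crop_demand_p > 0) min(1, p_supply / crop_demand_p) else 1,
       mineralized = sum(miner), volatilized = vol, denitrified = sum(denit))
}

#' Automatic irrigation scheduling
#'
#' Water is applied on days when the previous day's water stress factor falls
#' below the configured trigger, filling the profile deficit to field capacity
#' up to the maximum single application.
#'
#' @param water_stress stress factor in [0, 1] (1 = unstressed).
#' @param soil_deficit_to_fc mm missing to field capacity over the profile.
#' @param manage the configuration's management block.
#' @return applied irrigation, mm.
#' @export
auto_irrigate <- function(water_stress, soil_deficit_to_fc, manage) {
  if (water_stress < manage$irrigation_trigger)
    min(max(soil_deficit_to_fc, 0), manage$max_single_irrigation)
  else 0
}

#' Automatic (or rigid-timing) nitrogen fertilization
#'
#' Same trigger semantics as irrigation: a fixed per-event amount is applied
#' when nitrogen stress falls below the trigger. Under "default"/"fullharm"
#' the annual sum never exceeds the cell's N budget; under "harm-suffN" the
#' budget is unlimited. Configurations with `fert_trigger = "fixed"` apply the
#' whole annual rate at planting instead (handled by [simulate_season()]);
#' this function then returns 0.
#'
#' @param n_stress N stress factor in [0, 1].
#' @param budget_remaining kg N ha^-1 left this year (`Inf` under harm-suffN).
#' @param manage the configuration's management block.
#' @param scenario `"default"`, `"fullharm"` or `"harm-suffN"`.
#' @return applied N, kg ha^-1.
#' @export
auto_fertilize <- function(n_stress, budget_remaining, manage, scenario) {
  if (identical(manage$fert_trigger, "fixed")) return(0)
  if (n_stress >= manage$fert_trigger) return(0)
  if (scenario == "harm-suffN") SIM_CONST$fert_per_event
  else min(SIM_CONST$fert_per_event, max(budget_remaining, 0))
}
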