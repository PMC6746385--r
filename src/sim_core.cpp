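// Compiled engine for the daily crop-soil loop. This is a line-by-line
// transcription of the reference R coding (simulate_season / offseason_update /
// end_of_year_soil_update); the test suite asserts agreement to 1e-9.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int DPY = 360; // days per synthetic year

struct Soil {
  std::vector<double> thick, fc, wp, ksat, organic_n, mineral_n, labile_p,
      water, depth_mid_mm;
  size_t n() const { return thick.size(); }
};

Soil soil_from_list(const List& s) {
  Soil out;
  out.thick = as<std::vector<double>>(s["thick"]);
  out.fc = as<std::vector<double>>(s["fc"]);
  out.wp = as<std::vector<double>>(s["wp"]);
  out.ksat = as<std::vector<double>>(s["ksat"]);
  out.organic_n = as<std::vector<double>>(s["organic_n"]);
  out.mineral_n = as<std::vector<double>>(s["mineral_n"]);
  out.labile_p = as<std::vector<double>>(s["labile_p"]);
  out.water = as<std::vector<double>>(s["water"]);
  out.depth_mid_mm = as<std::vector<double>>(s["depth_mid_mm"]);
  return out;
}

double clampd(double x, double lo, double hi) {
  return std::min(std::max(x, lo), hi);
}

double scurve(double x, double b1, double b2) {
  double xx = std::max(x, 0.0);
  return xx / (xx + std::exp(b1 - b2 * xx));
}

double extraterrestrial_radiation(double lat, int doy) {
  double phi = lat * M_PI / 180.0;
  double j = 2.0 * M_PI * doy / 365.0;
  double dr = 1.0 + 0.033 * std::cos(j);
  double delta = 0.409 * std::sin(j - 1.39);
  double x = clampd(-std::tan(phi) * std::tan(delta), -1.0, 1.0);
  double ws = std::acos(x);
  return (24.0 * 60.0 / M_PI) * 0.0820 * dr *
         (ws * std::sin(phi) * std::sin(delta) +
          std::cos(phi) * std::cos(delta) * std::sin(ws));
}

double hargreaves_pet(double tmin, double tmax, double lat, int doy,
                      double lin, double expo) {
  double ra = extraterrestrial_radiation(lat, doy);
  double tmean = (tmin + tmax) / 2.0;
  double v = lin * 0.408 * ra * (tmean + 17.8) * std::pow(tmax - tmin, expo);
  return std::max(0.0, v);
}

double heat_units(double tmin, double tmax, double tb, double to) {
  return clampd((tmin + tmax) / 2.0 - tb, 0.0, to - tb);
}

// bundled constants and parameters (indices must match the R packer)
struct Par {
  // coeff_w / coeff_n / manage / cult
  double hg_lin, hg_exp, soil_evap, cn_idx;
  double decay, nvol, denit;
  double irr_trig, max_irr, fert_trig; // fert_trig < 0 => fixed timing
  double row_sp, resid_rm, f_hi;
  double t_base, t_opt, rue, hi_min, hi_max;
  // fixed process constants
  double ret_base, smi_w, extract, evap_gain, base_min, vol_scale, n_conc,
      p_conc, fert_event, suffn_p, resid_frac, temp_max, par_frac;
  // S-curves
  double lai_b1, lai_b2, mois_b1, mois_b2, oxy_b1, oxy_b2;
  int max_season_days;
};

struct WBOut { double runoff, deep, aet, wstress, smi; };

WBOut water_balance(Soil& s, double precip, double irr, double pet,
                    double f_int, const Par& p) {
  size_t nl = s.n();
  double sum_avail = 0.0, sum_cap = 0.0;
  for (size_t i = 0; i < nl; ++i) {
    sum_avail += std::max(s.water[i] - s.wp[i], 0.0);
    sum_cap += s.fc[i] - s.wp[i];
  }
  double smi = std::min(1.0, sum_avail / sum_cap);
  double input = precip + irr;
  double sret = p.ret_base * std::pow(1.0 - p.smi_w * smi, p.cn_idx);
  double runoff = 0.0;
  if (input > 0.2 * sret)
    runoff = (input - 0.2 * sret) * (input - 0.2 * sret) /
             (input + 0.8 * sret);
  s.water[0] += input - runoff;
  double deep = 0.0;
  for (size_t i = 0; i < nl; ++i) {
    double excess = s.water[i] - s.fc[i];
    if (excess > 0) {
      double perc = std::min(excess, s.ksat[i]);
      s.water[i] -= perc;
      if (i + 1 < nl) s.water[i + 1] += perc; else deep = perc;
    }
  }
  double t_pot = pet * f_int;
  sum_avail = 0.0;
  for (size_t i = 0; i < nl; ++i)
    sum_avail += std::max(s.water[i] - s.wp[i], 0.0);
  double supply = sum_avail * p.extract;
  double t_act = std::min(t_pot, supply);
  if (t_act > 0) {
    for (size_t i = 0; i < nl; ++i) {
      double avail = std::max(s.water[i] - s.wp[i], 0.0);
      s.water[i] -= t_act * avail / sum_avail;
    }
  }
  double e_pot = pet * (1.0 - f_int);
  double avail1 = std::max(s.water[0] - s.wp[0], 0.0);
  double smi1 = avail1 / (s.fc[0] - s.wp[0]);
  double e_act = std::min(
      e_pot * std::min(1.0, p.evap_gain * p.soil_evap * smi1), avail1);
  s.water[0] -= e_act;
  WBOut out;
  out.runoff = runoff; out.deep = deep; out.aet = t_act + e_act;
  out.wstress = (t_pot > 0) ? t_act / t_pot : 1.0;
  out.smi = smi;
  return out;
}

struct NutOut { double n_supply, p_supply, n_stress, p_stress; };

NutOut nutrient(Soil& s, double tf, double mf, double dem_n, double dem_p,
                const Par& p) {
  size_t nl = s.n();
  for (size_t i = 0; i < nl; ++i) {
    double oxf = 1.0 - scurve(s.depth_mid_mm[i], p.oxy_b1, p.oxy_b2);
    double miner = p.decay * p.base_min * mf * tf * oxf * s.organic_n[i];
    s.organic_n[i] -= miner;
    s.mineral_n[i] += miner;
  }
  double vol = p.nvol * p.vol_scale * s.mineral_n[0];
  s.mineral_n[0] -= vol;
  double anaer = clampd((mf - 0.75) / 0.25, 0.0, 1.0);
  for (size_t i = 0; i < nl; ++i)
    s.mineral_n[i] -= p.denit * anaer * anaer * s.mineral_n[i];
  double tot_n = 0.0, tot_p = 0.0;
  for (size_t i = 0; i < nl; ++i) { tot_n += s.mineral_n[i]; tot_p += s.labile_p[i]; }
  double n_sup = std::min(dem_n, std::max(tot_n, 0.0));
  if (n_sup > 0)
    for (size_t i = 0; i < nl; ++i) s.mineral_n[i] -= n_sup * s.mineral_n[i] / tot_n;
  double p_sup = std::min(dem_p, std::max(tot_p, 0.0));
  if (p_sup > 0)
    for (size_t i = 0; i < nl; ++i) s.labile_p[i] -= p_sup * s.labile_p[i] / tot_p;
  NutOut out;
  out.n_supply = n_sup; out.p_supply = p_sup;
  out.n_stress = (dem_n > 0) ? std::min(1.0, n_sup / dem_n) : 1.0;
  out.p_stress = (dem_p > 0) ? std::min(1.0, p_sup / dem_p) : 1.0;
  return out;
}

struct SeasonOut { double yield, biomass, hi, irr, napp; };

// one growing season; weather columns are 0-based year indices
SeasonOut season(Soil& s, const NumericMatrix& tminM, const NumericMatrix& tmaxM,
                 const NumericMatrix& sradM, const NumericMatrix& precM,
                 double lat, int planting, int harvest, int year0,
                 double phu, double n_budget, double p_rate, bool suffn,
                 bool irrigated, bool pstress, const Par& p) {
  bool wraps = planting > harvest;
  int len = wraps ? (DPY - planting + 1 + harvest) : (harvest - planting + 1);
  int n_days = std::min(len, p.max_season_days);
  bool fixed_fert = p.fert_trig < 0;

  s.labile_p[0] += suffn ? p.suffn_p : p_rate;
  double budget = n_budget, applied_n = 0.0;
  double hu_cum = 0, biomass = 0, wsi_sum = 0;
  int wsi_n = 0;
  double prev_ws = 1.0, applied_irr = 0.0, n_uptake = 0.0;

  for (int d = 0; d < n_days; ++d) {
    int doy = planting + d;       // 1-based
    int yr = year0;
    if (doy > DPY) { doy -= DPY; yr = year0 + 1; }
    double tmin = tminM(doy - 1, yr - 1), tmax = tmaxM(doy - 1, yr - 1);
    if (fixed_fert && (d == 0 || d == 30 || d == 60)) {
      double dose = suffn ? 6.0 * p.fert_event : n_budget / 3.0;
      s.mineral_n[0] += dose;
      applied_n += dose;
    }
    double hu = heat_units(tmin, tmax, p.t_base, p.t_opt);
    hu_cum += hu;
    double huf = std::min(1.0, hu_cum / phu);
    double f_int = scurve(huf, p.lai_b1, p.lai_b2);
    double pet = hargreaves_pet(tmin, tmax, lat, doy, p.hg_lin, p.hg_exp);
    double tmean = (tmin + tmax) / 2.0;
    double temp_stress = clampd((tmean - p.t_base) / (p.t_opt - p.t_base), 0, 1);

    double irr = 0.0;
    if (irrigated) {
      double deficit = 0.0;
      for (size_t i = 0; i < s.n(); ++i)
        deficit += std::max(s.fc[i] - s.water[i], 0.0);
      if (prev_ws < p.irr_trig)
        irr = std::min(std::max(deficit, 0.0), p.max_irr);
      applied_irr += irr;
    }
    WBOut wb = water_balance(s, precM(doy - 1, yr - 1), irr, pet, f_int, p);
    double ws = wb.wstress;

    double db_pot = 0.01 * p.rue * p.row_sp * f_int *
        (p.par_frac * sradM(doy - 1, yr - 1));
    double dem_n = p.n_conc * db_pot;
    if (!fixed_fert) {
      double pool = 0.0;
      for (size_t i = 0; i < s.n(); ++i) pool += s.mineral_n[i];
      double proj_ns = dem_n > 0
        ? std::min(1.0, std::max(pool, 0.0) / dem_n) : 1.0;
      double fert = 0.0;
      if (proj_ns < p.fert_trig)
        fert = suffn ? p.fert_event
                     : std::min(p.fert_event, std::max(budget, 0.0));
      if (fert > 0) {
        s.mineral_n[0] += fert;
        applied_n += fert;
        if (!suffn) budget -= fert;
      }
    }
    double dem_p = pstress ? p.p_conc * db_pot : 0.0;
    double tf = clampd(tmean / p.temp_max, 0, 1);
    double mf = scurve(wb.smi, p.mois_b1, p.mois_b2);
    NutOut nut = nutrient(s, tf, mf, dem_n, dem_p, p);
    n_uptake += nut.n_supply;
    double ns = nut.n_stress;
    double ps = pstress ? nut.p_stress : 1.0;

    double stress = std::min(std::min(ws, ns), std::min(ps, temp_stress));
    biomass += db_pot * stress;

    if (huf >= p.f_hi) { wsi_sum += 1.0 - ws; ++wsi_n; }
    prev_ws = ws;
    if (hu_cum >= phu) break;
  }
  double wsi = wsi_n > 0 ? wsi_sum / wsi_n : 0.0;
  double hi = p.hi_max - (p.hi_max - p.hi_min) * wsi;
  double yld = biomass * hi;
  s.organic_n[0] += p.resid_frac * (1.0 - p.resid_rm) * n_uptake * (1.0 - hi);
  SeasonOut out;
  out.yield = yld; out.biomass = biomass; out.hi = hi;
  out.irr = applied_irr; out.napp = applied_n;
  return out;
}

void offseason(Soil& s, const NumericMatrix& tminM, const NumericMatrix& tmaxM,
               const NumericMatrix& precM, double lat, int from, int to,
               int year, const Par& p) {
  if (from == to) return;
  int len = (to >= from) ? (to - from + 1) : (DPY - from + 1 + to);
  for (int k = 0; k < len; ++k) {
    int doy = from + k;
    if (doy > DPY) doy -= DPY;
    double tmin = tminM(doy - 1, year - 1), tmax = tmaxM(doy - 1, year - 1);
    double pet = hargreaves_pet(tmin, tmax, lat, doy, p.hg_lin, p.hg_exp);
    WBOut wb = water_balance(s, precM(doy - 1, year - 1), 0.0, pet, 0.0, p);
    double tmean = (tmin + tmax) / 2.0;
    double tf = clampd(tmean / p.temp_max, 0, 1);
    double mf = scurve(wb.smi, p.mois_b1, p.mois_b2);
    nutrient(s, tf, mf, 0.0, 0.0, p);
  }
}

void end_of_year(Soil& s, const Soil& init, bool is_static, double loss) {
  if (is_static) {
    s.thick = init.thick; s.fc = init.fc; s.wp = init.wp; s.ksat = init.ksat;
    s.organic_n = init.organic_n; s.depth_mid_mm = init.depth_mid_mm;
    for (size_t i = 0; i < s.n(); ++i)
      s.water[i] = std::min(s.water[i], s.fc[i]);
  } else if (loss > 0) {
    s.thick[0] *= 1 - loss; s.fc[0] *= 1 - loss; s.wp[0] *= 1 - loss;
    s.water[0] *= 1 - loss; s.organic_n[0] *= 1 - loss;
    s.mineral_n[0] *= 1 - loss; s.labile_p[0] *= 1 - loss;
    double cum = 0.0;
    for (size_t i = 0; i < s.n(); ++i) {
      s.depth_mid_mm[i] = (cum + s.thick[i] / 2.0) * 1000.0;
      cum += s.thick[i];
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix sim_cell_years_cpp(
    NumericMatrix tmin, NumericMatrix tmax, NumericMatrix srad,
    NumericMatrix prec, double lat, List soil0, NumericVector lai_ab,
    NumericVector mois_ab, NumericVector oxy_ab, NumericVector cult,
    NumericVector par, NumericVector cns, int planting, int harvest,
    double phu, double n_budget, double p_rate, bool suffn, bool irrigated,
    bool pstress, bool is_static, double loss_rate, bool decadal, int spinup,
    int max_season_days) {
  Par p;
  p.hg_lin = par[0]; p.hg_exp = par[1]; p.soil_evap = par[2]; p.cn_idx = par[3];
  p.decay = par[4]; p.nvol = par[5]; p.denit = par[6];
  p.irr_trig = par[7]; p.max_irr = par[8]; p.fert_trig = par[9];
  p.row_sp = par[10]; p.resid_rm = par[11]; p.f_hi = par[12];
  p.t_base = cult[0]; p.t_opt = cult[1]; p.rue = cult[2];
  p.hi_min = cult[3]; p.hi_max = cult[4];
  p.ret_base = cns[0]; p.smi_w = cns[1]; p.extract = cns[2];
  p.evap_gain = cns[3]; p.base_min = cns[4]; p.vol_scale = cns[5];
  p.n_conc = cns[6]; p.p_conc = cns[7]; p.fert_event = cns[8];
  p.suffn_p = cns[9]; p.resid_frac = cns[10]; p.temp_max = cns[11];
  p.par_frac = cns[12];
  p.lai_b1 = lai_ab[0]; p.lai_b2 = lai_ab[1];
  p.mois_b1 = mois_ab[0]; p.mois_b2 = mois_ab[1];
  p.oxy_b1 = oxy_ab[0]; p.oxy_b2 = oxy_ab[1];
  p.max_season_days = max_season_days;

  Soil init = soil_from_list(soil0);
  Soil s = init;
  int ny = tmin.ncol();
  bool wraps = planting > harvest;
  int off_from = harvest % DPY + 1;
  int off_to = (planting - 2 + DPY) % DPY + 1;
  bool have_off = ((harvest % DPY) + 1) != planting;

  NumericMatrix out(ny, 6);
  colnames(out) = CharacterVector::create("yield", "biomass", "hi", "irr",
                                          "napp", "valid");
  for (int y = 1; y <= ny; ++y) {
    if (decadal && (y - 1) % 10 == 0) {
      s = init;
      for (int k = 0; k < spinup; ++k) {
        if (!(wraps && y == 1))
          season(s, tmin, tmax, srad, prec, lat, planting, harvest,
                 wraps ? y - 1 : y, phu, n_budget, p_rate, suffn, irrigated,
                 pstress, p);
        if (have_off)
          offseason(s, tmin, tmax, prec, lat, off_from, off_to, y, p);
        end_of_year(s, init, is_static, loss_rate);
      }
    }
    bool valid = !(wraps && y == 1);
    if (valid) {
      SeasonOut r = season(s, tmin, tmax, srad, prec, lat, planting, harvest,
                           wraps ? y - 1 : y, phu, n_budget, p_rate, suffn,
                           irrigated, pstress, p);
      out(y - 1, 0) = r.yield; out(y - 1, 1) = r.biomass; out(y - 1, 2) = r.hi;
      out(y - 1, 3) = r.irr; out(y - 1, 4) = r.napp; out(y - 1, 5) = 1.0;
    } else {
      out(y - 1, 0) = NA_REAL; out(y - 1, 1) = NA_REAL; out(y - 1, 2) = NA_REAL;
      out(y - 1, 3) = NA_REAL; out(y - 1, 4) = NA_REAL; out(y - 1, 5) = 0.0;
    }
    if (have_off)
      offseason(s, tmin, tmax, prec, lat, off_from, off_to, y, p);
    end_of_year(s, init, is_static, loss_rate);
  }
  return out;
}
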