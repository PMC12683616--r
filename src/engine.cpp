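// Monthly simulation loop. One tree slot per ground column (at most one
// living tree per 1 m2 voxel), monthly order of operations:
// growth -> stage-1 mortality (background + starvation) -> stage-2 treefall
// -> lightning -> recruitment. Uses R's RNG stream so set.seed() on the R
// side makes runs bit-reproducible.
#include <Rcpp.h>
#include "kernels.h"
#include <set>
using namespace Rcpp;

namespace {

struct Offsets {
  // integer lattice offsets with dx^2+dy^2 <= r^2, sorted by (dx, dy)
  std::vector<int> dx, dy;
  std::vector<double> dist;
};

Offsets make_offsets(double radius) {
  Offsets o;
  int r = (int)std::floor(radius);
  for (int dx = -r; dx <= r; ++dx)
    for (int dy = -r; dy <= r; ++dy) {
      double d2 = (double)dx * dx + (double)dy * dy;
      if (d2 <= radius * radius) {
        o.dx.push_back(dx); o.dy.push_back(dy);
        o.dist.push_back(std::sqrt(d2));
      }
    }
  return o;
}

inline int wrapi(int v, int n) { return ((v % n) + n) % n; }

} // namespace

// [[Rcpp::export]]
List cpp_run_forest(int width, int length, int zmax, bool torus,
                    NumericMatrix sp,        // per-species parameter matrix
                    NumericMatrix ppfd, NumericMatrix temp, NumericMatrix vpd,
                    List phys, List mort, List light,
                    int n_months, int avg_years, bool keep_events) {
  // species columns (kept in step with .sp_matrix() on the R side)
  enum { LMA = 0, WSG, AA, AB, AK, MATURITY, DELTA, VCMAX, JMAX, RD,
         LIFESPAN, PB_MONTH, COMP_PPFD, DBH_THRESH, MAX_DBH, NSPCOL };
  if (sp.ncol() != NSPCOL) stop("species matrix has wrong number of columns");
  const int nsp = sp.nrow();
  const int C = width * length;

  const double phi = phys["phi"], f_wood = phys["f_wood"],
    f_canopy = phys["f_canopy"], k_ext = phys["k_ext"], g1 = phys["g1"],
    rg_frac = phys["rg_frac"], rstem_coef = phys["rstem_coef"],
    rbelow_frac = phys["rbelow_frac"], form_factor = phys["form_factor"],
    cfrac = phys["cfrac"], wood_red = phys["wood_reduction"],
    lai_max = phys["lai_max"], cr_a = phys["cr_a"], cr_b = phys["cr_b"],
    cd_frac = phys["cd_frac"];
  const double pmax_fall = mort["treefall_max_prob"],
    h_mid = mort["treefall_height_scale"], h_exp = mort["treefall_exponent"],
    seedbank_local_weight = mort["seedbank_local_weight"];
  const int mode = light["mode"]; // 0 none, 1 CLLR, 2 SSLR
  const double la = light["a"], p_direct = light["p_direct"],
    r_max = light["r_max"], search_radius = light["search_radius"];
  NumericVector lam_sched = light["lam_schedule"]; // per month
  if ((int)lam_sched.size() < n_months && mode > 0)
    stop("lightning schedule shorter than simulation");

  // tree state, one slot per column
  std::vector<int> spix(C, -1), negm(C, 0), cdlay(C, 1);
  std::vector<char> alive(C, 0);
  std::vector<double> dbh(C, 0), hgt(C, 0), crad(C, 0), larea(C, 0),
    wood(C, 0), canopy(C, 0), afrac(C, 0);

  // per-species crown geometry helpers
  const Offsets tgt_off = make_offsets(search_radius);
  const Offsets flash_off = make_offsets(r_max);

  // precompute mean daytime PPFD per calendar month (recruitment light test)
  std::vector<double> mean_day_ppfd(12, 0.0);
  for (int m = 0; m < 12; ++m) {
    double s = 0; int nd = 0;
    for (int k = 0; k < ppfd.ncol(); ++k)
      if (ppfd(m, k) > 0) { s += ppfd(m, k); nd++; }
    mean_day_ppfd[m] = nd ? s / nd : 0.0;
  }

  auto stem_volume = [&](int c) {
    return wood[c] / (cfrac * 1000.0 * sp(spix[c], WSG));
  };
  auto update_allometry = [&](int c) {
    int s = spix[c];
    hgt[c] = std::min((double)zmax, lg_height(dbh[c], sp(s, AA), sp(s, AB), sp(s, AK)));
    crad[c] = cr_a * std::pow(dbh[c], cr_b);
    cdlay[c] = std::max(1, (int)std::round(cd_frac * hgt[c]));
    larea[c] = canopy[c] / (sp(s, LMA) * cfrac * 1e-3);
    // crown holds at most lai_max over its area; excess canopy is shed
    double lacap = lai_max * std::max(1.0, M_PI * crad[c] * crad[c]);
    if (larea[c] > lacap) {
      larea[c] = lacap;
      canopy[c] = lacap * sp(s, LMA) * cfrac * 1e-3;
    }
  };
  auto dbh_from_volume = [&](int c, double v_target) {
    int s = spix[c];
    double d = dbh[c];
    for (int it = 0; it < 5; ++it) {
      double h = lg_height(d, sp(s, AA), sp(s, AB), sp(s, AK));
      double f = form_factor * M_PI / 4.0 * (d / 100.0) * (d / 100.0) * h - v_target;
      double fp = form_factor * M_PI / 4.0 *
        (2.0 * d / 1e4 * h + (d / 100.0) * (d / 100.0) *
         lg_height_deriv(d, sp(s, AA), sp(s, AB), sp(s, AK)));
      if (fp <= 0) break;
      d -= f / fp;
      if (d < dbh[c]) { d = dbh[c]; break; }
    }
    return std::max(d, dbh[c]); // DBH never decreases
  };
  auto place_recruit = [&](int c, int s) {
    spix[c] = s; alive[c] = 1; negm[c] = 0;
    dbh[c] = 1.0;
    double h1 = lg_height(1.0, sp(s, AA), sp(s, AB), sp(s, AK));
    wood[c] = form_factor * M_PI / 4.0 * 1e-4 * h1 * cfrac * 1000.0 * sp(s, WSG);
    larea[c] = 1.0; // LAI 1 over the home voxel
    canopy[c] = larea[c] * sp(s, LMA) * cfrac * 1e-3;
    update_allometry(c);
  };

  const int n_years = n_months / 12;
  NumericVector yr_agb(n_years), yr_gpp(n_years), yr_n10(n_years),
    yr_n30(n_years), yr_n60(n_years), yr_strikes(n_years), yr_kills(n_years),
    yr_kills60(n_years), yr_recruits(n_years);
  NumericMatrix yr_deaths(n_years, 4); // background, starvation, treefall, lightning
  NumericMatrix yr_spagb(n_years, nsp);
  NumericMatrix kills_by_class(nsp, 4); // dbh <=10, 10-30, 30-60, >60 (cumulative)
  // lightning event log
  std::vector<int> ev_year, ev_month, ev_x, ev_y, ev_target_sp, ev_nkill;
  std::vector<double> ev_target_dbh;

  double gpp_year = 0.0;
  long long recruits_cum = 0, deaths_cum = 0;
  long long strikes_year = 0, kills_year = 0, kills60_year = 0, recruits_year = 0;

  std::vector<double> lad, cum;     // light field work arrays
  std::vector<double> seed_w(nsp);

  for (int m = 0; m < n_months; ++m) {
    const int cm = m % 12, year = m / 12;

    // ---- light field ----------------------------------------------------
    lad.assign((size_t)zmax * C, 0.0);
    int crmax = 0;
    for (int c = 0; c < C; ++c)
      if (alive[c]) crmax = std::max(crmax, (int)std::floor(crad[c]));
    static std::vector<Offsets> cr_off;
    for (int r = (int)cr_off.size(); r <= crmax; ++r)
      cr_off.push_back(make_offsets((double)r));

    std::vector<double> ladt(C, 0.0);
    std::vector<int> ztop(C, 0), zlo(C, 0);
    for (int c = 0; c < C; ++c) {
      if (!alive[c]) continue;
      int top = std::min(zmax - 1, std::max(0, (int)std::ceil(hgt[c]) - 1));
      int nlay = std::min(cdlay[c], top + 1);
      int lo = top - nlay + 1;
      int r = (int)std::floor(crad[c]);
      const Offsets &off = cr_off[r];
      double lar = std::min(larea[c], lai_max * (double)off.dx.size());
      double ld = lar / ((double)off.dx.size() * nlay);
      ztop[c] = top; zlo[c] = lo; ladt[c] = ld;
      int x0 = c % width, y0 = c / width;
      for (size_t j = 0; j < off.dx.size(); ++j) {
        int cx = x0 + off.dx[j], cy = y0 + off.dy[j];
        if (torus) { cx = wrapi(cx, width); cy = wrapi(cy, length); }
        else if (cx < 0 || cx >= width || cy < 0 || cy >= length) continue;
        int col = cx + cy * width;
        for (int z = lo; z <= top; ++z) lad[(size_t)z * C + col] += ld;
      }
    }
    cum.assign((size_t)zmax * C, 0.0);
    std::vector<double> gfrac(C);
    for (int col = 0; col < C; ++col) {
      double acc = 0.0;
      for (int z = zmax - 1; z >= 0; --z) {
        cum[(size_t)z * C + col] = acc;
        acc += lad[(size_t)z * C + col];
      }
      gfrac[col] = std::exp(-k_ext * acc);
    }
    for (int c = 0; c < C; ++c) {
      if (!alive[c]) { afrac[c] = 0; continue; }
      int r = (int)std::floor(crad[c]);
      const Offsets &off = cr_off[r];
      double atot = 0.0;
      int x0 = c % width, y0 = c / width;
      for (size_t j = 0; j < off.dx.size(); ++j) {
        int cx = x0 + off.dx[j], cy = y0 + off.dy[j];
        if (torus) { cx = wrapi(cx, width); cy = wrapi(cy, length); }
        else if (cx < 0 || cx >= width || cy < 0 || cy >= length) continue;
        int col = cx + cy * width;
        for (int z = zlo[c]; z <= ztop[c]; ++z) {
          double tot = lad[(size_t)z * C + col];
          if (tot <= 0.0) continue;
          atot += std::exp(-k_ext * cum[(size_t)z * C + col]) *
            (1.0 - std::exp(-k_ext * tot)) * (ladt[c] / tot);
        }
      }
      afrac[c] = larea[c] > 0 ? atot / larea[c] : 0.0;
    }

    // ---- growth ----------------------------------------------------------
    const double fac = 1800.0 * LG_DAYS_PER_MONTH * 12.011e-9;
    for (int c = 0; c < C; ++c) {
      if (!alive[c]) continue;
      int s = spix[c];
      double gpp = 0.0, rl = 0.0, ftr = 0.0;
      for (int k = 0; k < 48; ++k) {
        gpp += lg_leaf_assim(afrac[c] * ppfd(cm, k), temp(cm, k), vpd(cm, k),
                             sp(s, VCMAX), sp(s, JMAX), phi, g1);
        double fr = lg_ftemp_resp(temp(cm, k));
        rl += sp(s, RD) * fr;
        ftr += fr;
      }
      gpp *= larea[c] * fac;
      rl *= larea[c] * fac;
      double sv = stem_volume(c);
      double sapfrac = std::min(1.0, 0.2 + 2.0 / std::max(dbh[c], 1.0));
      double rs = rstem_coef * sv * sapfrac * (ftr / 48.0) *
        LG_SECONDS_PER_MONTH * 12.011e-9;
      double rm = rl + rs + rbelow_frac * (rl + rs);
      double rg = rg_frac * std::max(0.0, gpp - rm);
      double npp = gpp - rm - rg;
      gpp_year += gpp;

      canopy[c] *= 1.0 - 1.0 / sp(s, LIFESPAN); // leaf turnover
      if (npp <= 0.0) {
        negm[c]++;
      } else {
        negm[c] = 0;
        double fw = f_wood * (dbh[c] > sp(s, DBH_THRESH) ? wood_red : 1.0);
        if (dbh[c] >= sp(s, MAX_DBH)) fw = 0.0; // growth cap; NPP goes below
        wood[c] += fw * npp;
        canopy[c] += f_canopy * npp;
        dbh[c] = dbh_from_volume(c, stem_volume(c));
      }
      update_allometry(c);
    }

    // ---- stage 1: background + carbon starvation -------------------------
    for (int c = 0; c < C; ++c) {
      if (!alive[c]) continue;
      int s = spix[c];
      double p = sp(s, PB_MONTH) + (negm[c] > sp(s, LIFESPAN) ? 1.0 : 0.0);
      if (unif_rand() < p) {
        int cause = negm[c] > sp(s, LIFESPAN) ? 1 : 0;
        alive[c] = 0; deaths_cum++;
        yr_deaths(year, cause) += 1;
      }
    }

    // ---- stage 2: treefall ------------------------------------------------
    for (int c = 0; c < C; ++c) {
      if (!alive[c]) continue;
      double p = lg_treefall_prob(hgt[c], pmax_fall, h_mid, h_exp);
      if (unif_rand() >= p) continue;
      double h0 = hgt[c], cr0 = crad[c];
      int x0 = c % width, y0 = c / width;
      alive[c] = 0; deaths_cum++; yr_deaths(year, 2) += 1;
      double az = unif_rand() * 2.0 * M_PI;
      double ux = std::cos(az), uy = std::sin(az);
      // secondary treefall along the fall corridor
      int reach = (int)std::ceil(h0);
      for (int c2 = 0; c2 < C; ++c2) {
        if (!alive[c2]) continue;
        int dx = (c2 % width) - x0, dy = (c2 / width) - y0;
        if (torus) {
          if (dx > width / 2) dx -= width; else if (dx < -width / 2) dx += width;
          if (dy > length / 2) dy -= length; else if (dy < -length / 2) dy += length;
        }
        if (std::abs(dx) > reach || std::abs(dy) > reach) continue;
        double proj = dx * ux + dy * uy;
        double perp = std::fabs(-dx * uy + dy * ux);
        if (proj > 0.0 && proj <= h0 && perp <= cr0 && hgt[c2] < 0.5 * h0) {
          alive[c2] = 0; deaths_cum++; yr_deaths(year, 2) += 1;
        }
      }
    }

    // ---- stage 3: lightning ----------------------------------------------
    if (mode > 0) {
      double lam = lam_sched[m];
      double pstrike = lam * 1e-6 / 12.0;
      if (pstrike > 1.0) stop("per-voxel strike probability exceeds 1");
      // skip the binomial draw entirely at lam = 0 so a zero-frequency run
      // shares its RNG stream with a lightning-disabled run
      int nstr = pstrike > 0 ? (int)R::rbinom((double)C, pstrike) : 0;
      std::set<int> struck;
      for (int kk = 0; kk < nstr; ++kk) {
        int col;
        do {
          col = (int)std::floor(unif_rand() * C);
          if (col >= C) col = C - 1;
        } while (struck.count(col));
        struck.insert(col);
        strikes_year++;
        // target: tallest living tree within the search radius
        int best = -1; double besth = -1.0;
        int x0 = col % width, y0 = col / width;
        for (size_t j = 0; j < tgt_off.dx.size(); ++j) {
          int cx = x0 + tgt_off.dx[j], cy = y0 + tgt_off.dy[j];
          if (torus) { cx = wrapi(cx, width); cy = wrapi(cy, length); }
          else if (cx < 0 || cx >= width || cy < 0 || cy >= length) continue;
          int cc = cx + cy * width;
          if (!alive[cc]) continue;
          int tx = cc % width, ty = cc / width;
          if (hgt[cc] > besth ||
              (hgt[cc] == besth && best >= 0 &&
               (tx < best % width || (tx == best % width && ty < best / width)))) {
            best = cc; besth = hgt[cc];
          }
        }
        if (best < 0) continue; // treeless neighborhood
        int bx = best % width, by = best / width;
        int nkill = 0;
        for (size_t j = 0; j < flash_off.dx.size(); ++j) {
          int cx = bx + flash_off.dx[j], cy = by + flash_off.dy[j];
          if (torus) { cx = wrapi(cx, width); cy = wrapi(cy, length); }
          else if (cx < 0 || cx >= width || cy < 0 || cy >= length) continue;
          int cc = cx + cy * width;
          if (!alive[cc]) continue;
          double p = lg_cllr(flash_off.dist[j], dbh[cc], la, p_direct);
          if (mode == 2) p = lg_sslr(p, sp(spix[cc], DELTA));
          if (unif_rand() < p) {
            int s2 = spix[cc];
            double d2 = dbh[cc];
            alive[cc] = 0; deaths_cum++; yr_deaths(year, 3) += 1;
            kills_year++; nkill++;
            if (d2 > 60) { kills60_year++; kills_by_class(s2, 3) += 1; }
            else if (d2 > 30) kills_by_class(s2, 2) += 1;
            else if (d2 > 10) kills_by_class(s2, 1) += 1;
            else kills_by_class(s2, 0) += 1;
          }
        }
        if (keep_events) {
          ev_year.push_back(year + 1); ev_month.push_back(cm + 1);
          ev_x.push_back(x0); ev_y.push_back(y0);
          ev_target_sp.push_back(spix[best] + 1);
          ev_target_dbh.push_back(dbh[best]);
          ev_nkill.push_back(nkill);
        }
      }
    }

    // ---- recruitment -------------------------------------------------------
    // seedbank: external seed rain (every species) plus extra weight for
    // species with mature trees in the domain
    double wtot = 0.0;
    for (int s = 0; s < nsp; ++s) seed_w[s] = 1.0;
    // presence of a mature conspecific anywhere in the domain adds a fixed
    // bonus (bounded, so abundant species cannot monopolize the seedbank)
    for (int c = 0; c < C; ++c)
      if (alive[c] && dbh[c] >= sp(spix[c], MATURITY))
        seed_w[spix[c]] = 1.0 + seedbank_local_weight;
    for (int s = 0; s < nsp; ++s) wtot += seed_w[s];
    for (int c = 0; c < C; ++c) {
      if (alive[c]) continue;
      double u = unif_rand() * wtot, acc = 0.0;
      int s = nsp - 1;
      for (int k = 0; k < nsp; ++k) { acc += seed_w[k]; if (u < acc) { s = k; break; } }
      if (gfrac[c] * mean_day_ppfd[cm] > sp(s, COMP_PPFD)) {
        place_recruit(c, s);
        recruits_cum++; recruits_year++;
      }
    }

    // ---- bookkeeping -------------------------------------------------------
    long long nalive = 0;
    for (int c = 0; c < C; ++c) nalive += alive[c] ? 1 : 0;
    if (nalive != recruits_cum - deaths_cum)
      stop("tree bookkeeping invariant violated at month %d", m + 1);

    if (cm == 11) {
      double agb = 0.0; int n10 = 0, n30 = 0, n60 = 0;
      for (int c = 0; c < C; ++c) {
        if (!alive[c]) continue;
        double ab = (wood[c] + canopy[c]) / cfrac; // kg dry mass
        agb += ab;
        yr_spagb(year, spix[c]) += ab;
        if (dbh[c] > 10) n10++;
        if (dbh[c] > 30) n30++;
        if (dbh[c] > 60) n60++;
      }
      double to_mg_ha = 1e-3 / ((double)C * 1e-4); // kg/domain -> Mg/ha
      yr_agb[year] = agb * to_mg_ha;
      for (int s = 0; s < nsp; ++s) yr_spagb(year, s) *= to_mg_ha;
      yr_gpp[year] = gpp_year * to_mg_ha; // Mg C /ha/yr
      yr_n10[year] = n10; yr_n30[year] = n30; yr_n60[year] = n60;
      yr_strikes[year] = (double)strikes_year;
      yr_kills[year] = (double)kills_year;
      yr_kills60[year] = (double)kills60_year;
      yr_recruits[year] = (double)recruits_year;
      gpp_year = 0.0; strikes_year = kills_year = kills60_year = recruits_year = 0;
    }
  }

  // final tree table
  int nfin = 0;
  for (int c = 0; c < C; ++c) nfin += alive[c] ? 1 : 0;
  IntegerVector fx(nfin), fy(nfin), fsp(nfin);
  NumericVector fdbh(nfin), fh(nfin), fla(nfin);
  for (int c = 0, i = 0; c < C; ++c) {
    if (!alive[c]) continue;
    fx[i] = c % width; fy[i] = c / width; fsp[i] = spix[c] + 1;
    fdbh[i] = dbh[c]; fh[i] = hgt[c]; fla[i] = larea[c]; ++i;
  }

  return List::create(
    _["agb"] = yr_agb, _["gpp"] = yr_gpp,
    _["n10"] = yr_n10, _["n30"] = yr_n30, _["n60"] = yr_n60,
    _["strikes"] = yr_strikes, _["kills"] = yr_kills,
    _["kills60"] = yr_kills60, _["recruits"] = yr_recruits,
    _["deaths"] = yr_deaths, _["species_agb"] = yr_spagb,
    _["kills_by_class"] = kills_by_class,
    _["events"] = List::create(
      _["year"] = wrap(ev_year), _["month"] = wrap(ev_month),
      _["x"] = wrap(ev_x), _["y"] = wrap(ev_y),
      _["target_species"] = wrap(ev_target_sp),
      _["target_dbh"] = wrap(ev_target_dbh),
      _["n_killed"] = wrap(ev_nkill)),
    _["final_trees"] = List::create(
      _["x"] = fx, _["y"] = fy, _["species"] = fsp,
      _["dbh"] = fdbh, _["height"] = fh, _["leaf_area"] = fla));
}
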