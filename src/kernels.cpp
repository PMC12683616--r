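// Shared numerical kernels: the lightning risk models, DBH-height allometry,
// the voxel light field, and the monthly leaf-level carbon balance. The
// simulation engine (engine.cpp) calls the same inline functions via
// kernels.h, so the R-level operations and the fast simulation loop cannot
// drift apart.
#include <Rcpp.h>
#include "kernels.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_cllr_prob(NumericVector r, NumericVector dbh,
                            double a, double p_direct) {
  R_xlen_t n = std::max(r.size(), dbh.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double ri = r[i % r.size()], di = dbh[i % dbh.size()];
    if (di <= 0.0) stop("dbh must be positive");
    if (ri < 0.0) stop("distance must be nonnegative");
    out[i] = lg_cllr(ri, di, a, p_direct);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sslr_prob(NumericVector p_com, NumericVector delta) {
  R_xlen_t n = std::max(p_com.size(), delta.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = lg_sslr(p_com[i % p_com.size()], delta[i % delta.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_allom_height(NumericVector dbh, NumericVector a,
                               NumericVector b, NumericVector k) {
  R_xlen_t n = dbh.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (dbh[i] <= 0.0) stop("dbh must be positive");
    out[i] = lg_height(dbh[i], a[i % a.size()], b[i % b.size()],
                       k[i % k.size()]);
  }
  return out;
}

// Voxel light field. Trees are described by parallel vectors; crowns are
// stacks of one-voxel-thick disk layers with uniform leaf area density.
// Returns the fraction of top-of-canopy PPFD arriving above each (z, column)
// voxel, the ground-level fraction per column, and for each tree the
// absorbed flux per unit leaf area (as a fraction of top-of-canopy PPFD).
// [[Rcpp::export]]
List cpp_light_field(int width, int length, int zmax,
                     IntegerVector x, IntegerVector y,
                     NumericVector height, NumericVector crown_radius,
                     IntegerVector crown_layers, NumericVector leaf_area,
                     double k_ext, double lai_max, bool torus) {
  const int C = width * length;
  const int n = x.size();
  std::vector<double> lad((size_t)zmax * C, 0.0);

  // crown column offset cache by integer radius
  int rmax = 0;
  for (int i = 0; i < n; ++i)
    rmax = std::max(rmax, (int)std::floor(crown_radius[i]));
  std::vector<std::vector<std::pair<int,int> > > offs(rmax + 1);
  for (int r = 0; r <= rmax; ++r)
    for (int dx = -r; dx <= r; ++dx)
      for (int dy = -r; dy <= r; ++dy)
        if (dx * dx + dy * dy <= r * r) offs[r].push_back(std::make_pair(dx, dy));

  // per-tree crown geometry
  std::vector<int> zt(n), zl(n), ncol(n);
  std::vector<double> ladt(n);
  for (int i = 0; i < n; ++i) {
    int top = std::min(zmax - 1, std::max(0, (int)std::ceil(height[i]) - 1));
    int nlay = std::max(1, crown_layers[i]);
    int zlo = std::max(0, top - nlay + 1);
    nlay = top - zlo + 1;
    int r = std::min(rmax, (int)std::floor(crown_radius[i]));
    int nc = (int)offs[r].size();
    double la = std::min(leaf_area[i], lai_max * nc);
    zt[i] = top; zl[i] = zlo; ncol[i] = nc;
    ladt[i] = la / ((double)nc * nlay);
    for (size_t j = 0; j < offs[r].size(); ++j) {
      int cx = x[i] + offs[r][j].first, cy = y[i] + offs[r][j].second;
      if (torus) {
        cx = ((cx % width) + width) % width;
        cy = ((cy % length) + length) % length;
      } else if (cx < 0 || cx >= width || cy < 0 || cy >= length) continue;
      int col = cx + cy * width;
      for (int z = zlo; z <= top; ++z) lad[(size_t)z * C + col] += ladt[i];
    }
  }

  // cumulative LAI strictly above each layer, top down
  std::vector<double> cum((size_t)zmax * C, 0.0);
  NumericVector ground(C);
  for (int col = 0; col < C; ++col) {
    double acc = 0.0;
    for (int z = zmax - 1; z >= 0; --z) {
      cum[(size_t)z * C + col] = acc;
      acc += lad[(size_t)z * C + col];
    }
    ground[col] = std::exp(-k_ext * acc);
  }

  // absorbed fraction per unit leaf area for each tree
  NumericVector afrac(n);
  for (int i = 0; i < n; ++i) {
    int r = std::min(rmax, (int)std::floor(crown_radius[i]));
    double atot = 0.0;
    for (size_t j = 0; j < offs[r].size(); ++j) {
      int cx = x[i] + offs[r][j].first, cy = y[i] + offs[r][j].second;
      if (torus) {
        cx = ((cx % width) + width) % width;
        cy = ((cy % length) + length) % length;
      } else if (cx < 0 || cx >= width || cy < 0 || cy >= length) continue;
      int col = cx + cy * width;
      for (int z = zl[i]; z <= zt[i]; ++z) {
        double tot = lad[(size_t)z * C + col];
        if (tot <= 0.0) continue;
        double inc = std::exp(-k_ext * cum[(size_t)z * C + col]);
        atot += inc * (1.0 - std::exp(-k_ext * tot)) * (ladt[i] / tot);
      }
    }
    afrac[i] = leaf_area[i] > 0.0 ? atot / leaf_area[i] : 0.0;
  }

  NumericMatrix fracm(zmax, C), laim(zmax, C);
  for (int col = 0; col < C; ++col)
    for (int z = 0; z < zmax; ++z) {
      fracm(z, col) = std::exp(-k_ext * cum[(size_t)z * C + col]);
      laim(z, col) = lad[(size_t)z * C + col];
    }
  return List::create(_["frac_above"] = fracm, _["lai"] = laim,
                      _["ground_frac"] = ground, _["afrac_leaf"] = afrac);
}

// Monthly carbon balance for a single tree, given the absorbed fraction of
// top-of-canopy PPFD per unit leaf area and one month of half-hourly
// climatology. Returns all terms so tests can audit the decomposition.
// [[Rcpp::export]]
List cpp_npp_month(double afrac_leaf, double leaf_area,
                   double vcmax25, double jmax25, double rd25,
                   double stem_volume, double dbh,
                   NumericVector ppfd, NumericVector temp, NumericVector vpd,
                   double phi, double g1, double rstem_coef,
                   double rbelow_frac, double rg_frac) {
  if (ppfd.size() != temp.size() || ppfd.size() != vpd.size())
    stop("forcing slot vectors must have equal length");
  if (ppfd.size() != 48) stop("expected 48 half-hourly slots");
  double gpp = 0.0, rleaf = 0.0, ftr_sum = 0.0;
  for (R_xlen_t s = 0; s < ppfd.size(); ++s) {
    double A = lg_leaf_assim(afrac_leaf * ppfd[s], temp[s], vpd[s],
                             vcmax25, jmax25, phi, g1);
    gpp += A;
    rleaf += rd25 * lg_ftemp_resp(temp[s]);
    ftr_sum += lg_ftemp_resp(temp[s]);
  }
  const double fac = 1800.0 * LG_DAYS_PER_MONTH * 12.011e-9;
  gpp *= leaf_area * fac;
  rleaf *= leaf_area * fac;
  double sapfrac = std::min(1.0, 0.2 + 2.0 / std::max(dbh, 1.0));
  double rstem = rstem_coef * stem_volume * sapfrac *
    (ftr_sum / ppfd.size()) * LG_SECONDS_PER_MONTH * 12.011e-9;
  double rbelow = rbelow_frac * (rleaf + rstem);
  double rm = rleaf + rstem + rbelow;
  double rg = rg_frac * std::max(0.0, gpp - rm);
  return List::create(_["gpp"] = gpp, _["r_leaf"] = rleaf, _["r_stem"] = rstem,
                      _["r_below"] = rbelow, _["r_growth"] = rg,
                      _["npp"] = gpp - rm - rg);
}
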