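#ifndef LIGHTGAP_KERNELS_H
#define LIGHTGAP_KERNELS_H

#include <cmath>
#include <algorithm>

// month length used to integrate the repeating half-hourly climatology
#define LG_DAYS_PER_MONTH 30.4375
#define LG_SECONDS_PER_MONTH (LG_DAYS_PER_MONTH * 86400.0)

// Community-level lightning mortality probability. Decay exponent a is
// negative; r in metres from the struck tree, dbh in cm. At r = 0 the
// probability equals the direct-hit baseline.
inline double lg_cllr(double r, double dbh, double a, double p_direct) {
  return p_direct * std::pow(10.0, a * (70.0 / dbh) * (r / 45.0));
}

// Species-specific probability: shift the base-10 log-odds of the
// community-level probability by delta. Boundaries map 0 -> 0 and 1 -> 1.
inline double lg_sslr(double p_com, double delta) {
  if (p_com <= 0.0) return 0.0;
  if (p_com >= 1.0) return 1.0;
  double lo = std::log10(p_com / (1.0 - p_com)) + delta;
  return 1.0 / (1.0 + std::pow(10.0, -lo));
}

// Generalized Michaelis-Menten DBH-height allometry; a = asymptote (m).
inline double lg_height(double dbh, double a, double b, double k) {
  double db = std::pow(dbh, b);
  return a * db / (k + db);
}

inline double lg_height_deriv(double dbh, double a, double b, double k) {
  double db = std::pow(dbh, b);
  return a * b * std::pow(dbh, b - 1.0) * k / ((k + db) * (k + db));
}

// Q10 temperature responses, normalized at 25 C.
inline double lg_ftemp_resp(double t) { return std::pow(2.0, (t - 25.0) / 10.0); }
inline double lg_ftemp_photo(double t) {
  return std::min(2.0, std::pow(1.8, (t - 25.0) / 10.0));
}

// Stomatal limitation factor in the spirit of the Medlyn optimization:
// higher vapor pressure deficit closes stomata and reduces the
// Rubisco-limited rate; g1 has units kPa^0.5.
inline double lg_fvpd(double vpd, double g1) {
  return 1.0 / (1.0 + std::sqrt(std::max(vpd, 0.05)) / g1);
}

// Leaf-level gross assimilation (umol C m-2 leaf s-1): minimum of a
// Rubisco-limited rate and an RuBP-regeneration (light) limited rate.
inline double lg_leaf_assim(double i_leaf, double t, double vpd,
                            double vcmax25, double jmax25,
                            double phi, double g1) {
  if (i_leaf <= 0.0) return 0.0;
  double ftv = lg_ftemp_photo(t);
  // lumped CO2-limitation factors: (Ci - Gamma*)/(Ci + Km) ~ 0.25 for the
  // Rubisco-limited rate and ~0.2 Jmax for the RuBP-regeneration ceiling
  double ac = 0.25 * vcmax25 * ftv * lg_fvpd(vpd, g1);
  double aj = std::min(phi * i_leaf, 0.2 * jmax25 * ftv);
  return std::max(0.0, std::min(ac, aj));
}

// Monthly treefall probability: Hill function of height, zero at zero
// height, p_max/2 at the midpoint, saturating at p_max.
inline double lg_treefall_prob(double h, double p_max, double h_mid,
                               double h_exp) {
  if (h <= 0.0) return 0.0;
  double he = std::pow(h, h_exp);
  return p_max * he / (he + std::pow(h_mid, h_exp));
}

// Monthly background mortality, decreasing linearly in wood specific
// gravity; equals m0/12 at the reference (softest) wood.
inline double lg_background_prob(double wsg, double m0, double wsg_ref,
                                 double wsg_max) {
  double p = (m0 / 12.0) * (1.0 - (wsg - wsg_ref) / (wsg_max - wsg_ref));
  return std::max(0.0, std::min(p, m0 / 12.0));
}

#endif
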