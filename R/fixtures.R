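#' Generate a synthetic species community
#'
#' Stands in for a field trait compilation: draws leaf and wood traits,
#' DBH-height allometries, and lightning tolerances for a community with
#' prescribed fractions of lightning-tolerant and -intolerant species. The
#' default shape (27 species, 11 of them non-neutral) mirrors the size of
#' typical measured-tolerance censuses. Two properties are guaranteed so
#' downstream analyses are exercised: at least one tall-statured, strongly
#' tolerant species (large height asymptote, strongly negative `delta_i`)
#' and weak trait covariance placing taller asymptotes with denser wood.
#'
#' @param n_species Number of species.
#' @param fraction_tolerant,fraction_intolerant Fractions of species with
#'   negative / positive `delta_i` (the rest are neutral, `delta_i = 0`).
#' @param delta_scale Spread of the non-zero log-odds shifts.
#' @param seed RNG seed; the table is a pure function of the arguments.
#' @return A [species_traits()] table.
#' @export
gen_species <- function(n_species = 27, fraction_tolerant = 0.2,
                        fraction_intolerant = 0.2, delta_scale = 1,
                        seed = 1) {
  if (n_species < 1) stop("need at least one species", call. = FALSE)
  if (fraction_tolerant + fraction_intolerant > 1) {
    stop("tolerance fractions must sum to at most 1", call. = FALSE)
  }
  set.seed(seed)
  # height asymptote first; other traits covary weakly with stature
  allom_a <- sort(runif(n_species, 20, 48), decreasing = TRUE)
  stature <- (allom_a - 20) / 28   # 0 = short, 1 = tall
  wsg <- pmin(1.1, pmax(0.2, 0.45 + 0.25 * stature +
                          rnorm(n_species, 0, 0.08)))
  lma <- rlnorm(n_species, log(95) + 0.2 * stature, 0.22)
  leaf_n <- pmax(1, rnorm(n_species, 2.2, 0.35))
  leaf_p <- pmax(0.05, rnorm(n_species, 0.12, 0.025))
  # a few species lack leaf %P, as in trait databases
  n_missing_p <- max(0, round(0.1 * n_species) - 1)
  if (n_missing_p > 0) {
    leaf_p[sample.int(n_species, n_missing_p)] <- NA
  }
  allom_b <- runif(n_species, 0.6, 0.9)
  allom_k <- runif(n_species, 15, 30)
  maturity_dbh <- pmax(2, 5 + 25 * stature + rnorm(n_species, 0, 2))
  max_dbh <- pmax(15, 30 + 90 * stature + rnorm(n_species, 0, 8))

  n_tol <- round(fraction_tolerant * n_species)
  n_int <- round(fraction_intolerant * n_species)
  delta <- rep(0, n_species)
  if (n_tol > 0) {
    # tolerant species drawn preferentially from the tall half so the
    # community can acclimate compositionally
    tall_pool <- seq_len(ceiling(n_species / 2))
    tol_idx <- tall_pool[seq_len(min(n_tol, length(tall_pool)))]
    delta[tol_idx] <- -delta_scale * (0.5 + abs(rnorm(length(tol_idx))))
    delta[tol_idx[1]] <- -2 * delta_scale  # strongly tolerant, tall-statured
  }
  if (n_int > 0) {
    free <- which(delta == 0)
    int_idx <- utils::tail(free, n_int)
    delta[int_idx] <- delta_scale * (0.5 + abs(rnorm(n_int)))
  }
  species_traits(data.frame(
    species_id = sprintf("sp%02d", seq_len(n_species)),
    lma = lma, wsg = wsg, leaf_n = leaf_n, leaf_p = leaf_p,
    allom_a = allom_a, allom_b = allom_b, allom_k = allom_k,
    maturity_dbh = maturity_dbh, max_dbh = max_dbh, delta_i = delta
  ))
}

#' Generate synthetic half-hourly climatological forcing
#'
#' Smooth diurnal cycles for a repeating tropical year: PPFD follows a
#' sinusoidal daylight arc (zero at night, maximal at noon) with a mild
#' seasonal amplitude cycle; temperature and VPD follow diurnal cycles that
#' peak in the early afternoon. Strictly repeatable for a given seed.
#'
#' @param seed RNG seed (controls small month-to-month amplitude variation).
#' @param ppfd_max Peak PPFD (umol m-2 s-1); the default reflects a
#'   long-term climatological mean (cloudy slots included) rather than a
#'   clear-sky maximum.
#' @return Forcing table with columns `month`, `slot`, `ppfd`, `temp`,
#'   `vpd` (576 rows).
#' @export
gen_forcing <- function(seed = 1, ppfd_max = 1100) {
  set.seed(seed)
  amp <- ppfd_max * (1 + 0.1 * sin(2 * pi * (1:12) / 12) +
                       rnorm(12, 0, 0.02))
  grid <- expand.grid(slot = 1:48, month = 1:12)
  hour <- (grid$slot - 0.5) / 2                 # hours after midnight
  daylight <- hour >= 6 & hour <= 18
  arc <- sin(pi * (hour - 6) / 12)
  ppfd <- ifelse(daylight, amp[grid$month] * pmax(0, arc), 0)
  temp <- 25 + 3 * sin(pi * (hour - 8) / 12) +
    1.5 * sin(2 * pi * (grid$month - 3) / 12)
  vpd <- pmax(0, 0.4 + 1.2 * ifelse(daylight, arc, 0) *
                (0.8 + 0.2 * sin(2 * pi * grid$month / 12)))
  data.frame(month = grid$month, slot = grid$slot, ppfd = ppfd,
             temp = temp, vpd = vpd)
}

#' Generate synthetic binned lightning-mortality observations
#'
#' Stands in for binned field observations of lightning mortality. Each cell
#' of the 5 distance x 3 DBH table receives `n_per_cell` trees at risk; each
#' tree independently dies outright, is damaged, or is unaffected, with
#' probabilities chosen so that the effective observed mortality
#' `n_killed + d_true * n_damaged` is unbiased for `n_trees * P(r, D)` under
#' the community-level risk model with parameters (`a`, `p_direct`). When
#' `noise = FALSE` the expected (non-integer) counts are returned, which a
#' grid search should recover exactly for lattice parameter values.
#'
#' @param a,p_direct Generating community-level parameters.
#' @param d_true Generating damaged-tree death fraction.
#' @param n_per_cell Trees at risk per cell (scalar or length 15).
#' @param seed RNG seed.
#' @param noise Draw multinomial counts (`TRUE`) or return expectations.
#' @param immediate_frac Target fraction of eventual deaths that are
#'   observed as outright kills (reduced per cell when infeasible).
#' @return A [binned_mortality()] table.
#' @export
gen_binned_mortality <- function(a = -3.04, p_direct = 0.62, d_true = 0.35,
                                 n_per_cell = 1000, seed = 1, noise = TRUE,
                                 immediate_frac = 0.5) {
  set.seed(seed)
  cells <- expand.grid(dist_class = 1:5, dbh_class = 1:3)
  dist_edges <- cbind(lo = c(0, 0, 5, 10, 15)[cells$dist_class],
                      hi = c(0, 5, 10, 15, 25)[cells$dist_class])
  dbh_edges <- cbind(lo = c(10, 30, 60)[cells$dbh_class],
                     hi = c(30, 60, 100)[cells$dbh_class])
  n <- rep(n_per_cell, length.out = 15)
  bm <- binned_mortality(dist_edges[, "lo"], dist_edges[, "hi"],
                         dbh_edges[, "lo"], dbh_edges[, "hi"],
                         n, rep(0, 15), rep(0, 15))
  lp <- lightning_params(a = a, p_direct = p_direct, d = d_true)
  p <- cllr_probability(bm$distance_rep, bm$dbh_rep, lp)
  # per-tree immediate-death and damage probabilities; q chosen per cell so
  # E[killed + d_true * damaged] = n * p while killed + damaged <= n
  q <- rep(immediate_frac, 15)
  if (d_true > 0) {
    tot <- p * (q + (1 - q) / d_true)
    bad <- tot > 1
    if (any(bad)) {
      # raise q until immediate + damaged probabilities sum to 1
      q[bad] <- (1 / d_true - 1 / p[bad]) / (1 / d_true - 1)
    }
    p_imm <- p * q
    p_dam <- p * (1 - q) / d_true
  } else {
    p_imm <- p
    p_dam <- rep(0, 15)
  }
  if (noise) {
    draws <- vapply(seq_len(15), function(i) {
      rmultinom(1, n[i], c(p_imm[i], p_dam[i],
                           max(0, 1 - p_imm[i] - p_dam[i])))[1:2]
    }, numeric(2))
    killed <- draws[1, ]
    damaged <- draws[2, ]
  } else {
    killed <- n * p_imm
    damaged <- n * p_dam
  }
  binned_mortality(bm$distance_lo, bm$distance_hi, bm$dbh_lo, bm$dbh_hi,
                   n, killed, damaged)
}
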