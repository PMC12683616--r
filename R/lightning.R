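#' Lightning parameters
#'
#' Governs strike occurrence, targeting, and flashover mortality. Strikes
#' arrive as independent per-voxel Bernoulli events consistent with an areal
#' cloud-to-ground flash frequency `lam`. A strike targets the tallest tree
#' within `search_radius` of the struck voxel; mortality then follows the
#' community-level risk model (mode `"CLLR"`), its species-specific
#' log-odds-shifted generalization (mode `"SSLR"`), or nothing (`"none"`).
#'
#' @param lam Cloud-to-ground flash frequency (CG fl km-2 yr-1).
#' @param a Decay-rate exponent of the community-level model; negative, in
#'   the calibration range `[-7, -1]`.
#' @param p_direct Mortality probability of a direct strike, in `[0, 1]`.
#' @param d Proportion of lightning-damaged trees that eventually die; used
#'   by the calibration, not by the simulator directly.
#' @param mode `"none"`, `"CLLR"`, or `"SSLR"`.
#' @param r_max Flashover cutoff radius (m): trees farther than this from the
#'   struck tree are unaffected.
#' @param search_radius Targeting radius (m) searched for the tallest tree.
#' @export
lightning_params <- function(lam = 12.7, a = -2.5, p_direct = 0.75, d = 0.5,
                             mode = c("CLLR", "SSLR", "none"),
                             r_max = 25, search_radius = 15) {
  mode <- match.arg(mode)
  if (lam < 0) stop("lam must be nonnegative", call. = FALSE)
  if (p_direct < 0 || p_direct > 1) {
    stop("p_direct must be in [0, 1]", call. = FALSE)
  }
  if (d < 0 || d > 1) stop("d must be in [0, 1]", call. = FALSE)
  if (r_max < 0) stop("r_max must be nonnegative", call. = FALSE)
  structure(list(lam = lam, a = a, p_direct = p_direct, d = d, mode = mode,
                 r_max = r_max, search_radius = search_radius),
            class = "lightning_params")
}

#' Per-voxel monthly strike probability
#'
#' Converts an areal flash frequency (CG fl km-2 yr-1) to the probability
#' that a given 1 m2 ground voxel is struck in one month:
#' `lam * 1e-6 / 12`.
#' @param lam Flash frequency (CG fl km-2 yr-1).
#' @export
strike_probability <- function(lam) {
  p <- lam * 1e-6 / 12
  if (any(p > 1)) stop("per-voxel strike probability exceeds 1", call. = FALSE)
  p
}

#' Sample lightning strikes for one month
#'
#' Every ground voxel is struck independently with probability
#' [strike_probability()]. Implemented as a binomial draw of the number of
#' struck voxels followed by a uniform draw of distinct voxel locations,
#' which is distributionally identical.
#'
#' @param grid A `forest_grid`.
#' @param lp [lightning_params()].
#' @return Data frame of struck voxels (`x`, `y`); zero rows if none.
#' @export
sample_strikes <- function(grid, lp) {
  n <- n_ground_voxels(grid)
  k <- rbinom(1, n, strike_probability(lp$lam))
  if (k == 0) return(data.frame(x = integer(), y = integer()))
  v <- sample.int(n, k) - 1L
  data.frame(x = v %% grid$width, y = v %/% grid$width)
}

#' Select the strike target near a struck voxel
#'
#' The tallest living tree within `search_radius` of the struck voxel is
#' targeted; ties are broken deterministically toward the smallest `(x, y)`
#' lexicographic voxel index. Returns `NULL` when the neighborhood is
#' treeless (the strike has no effect).
#'
#' @param grid A `forest_grid`.
#' @param struck_voxel Length-2 vector `c(x, y)`.
#' @param lp [lightning_params()].
#' @return One row of the tree table, or `NULL`.
#' @export
select_target <- function(grid, struck_voxel, lp) {
  live <- grid$trees[grid$trees$alive, , drop = FALSE]
  if (!nrow(live)) return(NULL)
  d <- mapply(function(x, y) voxel_distance(grid, struck_voxel, c(x, y)),
              live$x, live$y)
  cand <- live[d <= lp$search_radius, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(-cand$height, cand$x, cand$y), , drop = FALSE]
  cand[1, ]
}

#' Community-level lightning mortality probability
#'
#' Two-parameter risk model: `P = p_direct * 10^(a * (70 / dbh) * (r / 45))`
#' with `a < 0`, so mortality probability equals the direct-hit baseline at
#' `r = 0`, decays with distance from the struck tree, and increases with
#' tree size at a given distance.
#'
#' @param r Distance from the struck tree (m, >= 0); vectorized.
#' @param dbh Diameter at breast height (cm, > 0); vectorized.
#' @param lp [lightning_params()] supplying `a` and `p_direct`.
#' @export
cllr_probability <- function(r, dbh, lp) {
  cpp_cllr_prob(as.numeric(r), as.numeric(dbh), lp$a, lp$p_direct)
}

#' Species-specific lightning mortality probability
#'
#' Shifts the base-10 log-odds of the community-level probability by the
#' species tolerance `delta`:
#' `log10(P_i / (1 - P_i)) = log10(P_com / (1 - P_com)) + delta`.
#' Boundary values are preserved (0 maps to 0, 1 to 1). Monotone increasing
#' in both arguments; `delta = 0` recovers the community-level probability.
#'
#' @param p_com Community-level probability; vectorized.
#' @param delta Species log-odds shift; vectorized.
#' @export
sslr_probability <- function(p_com, delta) {
  cpp_sslr_prob(as.numeric(p_com), as.numeric(delta))
}

#' Lightning tolerance scaling factor
#'
#' `s = 1 / (1 + exp(-delta))`: the species' mortality risk under the
#' species-specific model when the community-level risk is one half
#' (exactly so for base-10 log-odds shifts of magnitude interpreted on the
#' logistic scale). Bounded in (0, 1); 0.5 marks neutrality, values below
#' 0.5 lightning tolerance, above 0.5 intolerance.
#'
#' @param delta Species log-odds shift; vectorized.
#' @export
scaling_factor <- function(delta) {
  1 / (1 + exp(-delta))
}

#' Apply one lightning strike to the grid
#'
#' Selects the target (tallest tree within the search radius), then evaluates
#' the configured risk model for the target (at distance 0) and for every
#' living tree within `r_max` of the target, killing each by an independent
#' Bernoulli draw. Killed trees are removed immediately and their voxels
#' freed.
#'
#' @param grid A `forest_grid`.
#' @param struck_voxel Length-2 vector `c(x, y)`.
#' @param lp [lightning_params()].
#' @param traits [species_traits()] table (supplies `delta_i` for SSLR mode).
#' @return A list with the updated `grid` and a data frame `kills`
#'   (`tree_id`, `species_id`, `dbh`, `r`).
#' @export
apply_strike <- function(grid, struck_voxel, lp, traits = NULL) {
  kills <- data.frame(tree_id = integer(), species_id = character(),
                      dbh = numeric(), r = numeric(),
                      stringsAsFactors = FALSE)
  target <- select_target(grid, struck_voxel, lp)
  if (is.null(target) || lp$mode == "none") {
    return(list(grid = grid, kills = kills, target = target))
  }
  live <- grid$trees[grid$trees$alive, , drop = FALSE]
  r <- mapply(function(x, y) {
    voxel_distance(grid, c(target$x, target$y), c(x, y))
  }, live$x, live$y)
  cand <- live[r <= lp$r_max, , drop = FALSE]
  rc <- r[r <= lp$r_max]
  p <- cllr_probability(rc, cand$dbh, lp)
  if (lp$mode == "SSLR") {
    if (is.null(traits)) {
      stop("SSLR mode needs a species-trait table with delta_i",
           call. = FALSE)
    }
    delta <- traits$delta_i[match(cand$species_id, traits$species_id)]
    delta[is.na(delta)] <- 0
    p <- sslr_probability(p, delta)
  }
  dead <- runif(nrow(cand)) < p
  if (any(dead)) {
    kills <- data.frame(tree_id = cand$tree_id[dead],
                        species_id = cand$species_id[dead],
                        dbh = cand$dbh[dead], r = rc[dead],
                        stringsAsFactors = FALSE)
    grid$trees$alive[grid$trees$tree_id %in% kills$tree_id] <- FALSE
  }
  list(grid = grid, kills = kills, target = target)
}
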