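#' Mortality parameters
#'
#' Stage-1 mortality combines a wood-density-dependent background rate with
#' carbon starvation; stage-2 mortality is treefall. The background monthly
#' probability declines linearly in wood specific gravity from `m0 / 12` at
#' the softest wood (`wsg_ref`) to zero at `wsg_max`. Treefall probability is
#' a saturating (Hill) function of height: zero at zero height, half of
#' `treefall_max_prob` at `treefall_height_scale`.
#'
#' @param m0 Maximal baseline mortality rate (yr-1), in `[0, 0.03]`.
#' @param treefall_height_scale Height midpoint of the treefall curve (m).
#' @param treefall_exponent Hill exponent (steepness) of the treefall curve.
#' @param treefall_max_prob Monthly treefall probability ceiling.
#' @param wsg_ref Wood specific gravity of the softest configured wood, at
#'   which the background rate equals `m0 / 12` per month.
#' @param wsg_max Wood specific gravity at which the background rate is zero.
#' @param seedbank_local_weight Extra seedbank weight for a species with at
#'   least one mature tree in the domain, relative to unit external seed
#'   rain per species.
#' @export
mortality_params <- function(m0 = 0.015, treefall_height_scale = 30,
                             treefall_exponent = 3,
                             treefall_max_prob = 0.0015,
                             wsg_ref = 0, wsg_max = 1,
                             seedbank_local_weight = 1) {
  if (m0 < 0 || m0 > 0.03) stop("m0 must be in [0, 0.03]", call. = FALSE)
  if (treefall_max_prob < 0 || treefall_max_prob > 1) {
    stop("treefall_max_prob must be a probability", call. = FALSE)
  }
  if (wsg_max <= wsg_ref) stop("wsg_max must exceed wsg_ref", call. = FALSE)
  structure(list(
    m0 = m0, treefall_height_scale = treefall_height_scale,
    treefall_exponent = treefall_exponent,
    treefall_max_prob = treefall_max_prob,
    wsg_ref = wsg_ref, wsg_max = wsg_max,
    seedbank_local_weight = seedbank_local_weight
  ), class = "mortality_params")
}

#' Background mortality probability per month
#'
#' Linear in wood specific gravity: `(m0/12) * (1 - (wsg - wsg_ref) /
#' (wsg_max - wsg_ref))`, clamped to `[0, m0/12]`.
#' @param wsg Wood specific gravity (vectorized).
#' @param mort [mortality_params()].
#' @export
background_probability <- function(wsg, mort = mortality_params()) {
  p <- (mort$m0 / 12) *
    (1 - (wsg - mort$wsg_ref) / (mort$wsg_max - mort$wsg_ref))
  pmin(pmax(p, 0), mort$m0 / 12)
}

#' Stage-1 mortality probability (background + carbon starvation)
#'
#' Carbon starvation contributes probability 1 once the consecutive months
#' with negative NPP exceed the species leaf lifespan, and 0 otherwise; the
#' total is capped at 1.
#'
#' @param tree One row of a grid tree table.
#' @param mort [mortality_params()].
#' @param traits The tree's species traits row.
#' @param phys [physiology_params()] (leaf lifespan is derived from LMA).
#' @export
stage1_probability <- function(tree, mort = mortality_params(), traits,
                               phys = physiology_params()) {
  lifespan <- derive_physiology(traits, phys)$leaf_lifespan_months
  p_starv <- as.numeric(tree$npp_negative_months > lifespan)
  min(1, background_probability(traits$wsg, mort) + p_starv)
}

#' Monthly treefall probability
#'
#' @param height Tree height (m), vectorized.
#' @param mort [mortality_params()].
#' @export
treefall_probability <- function(height, mort = mortality_params()) {
  he <- pmax(height, 0)^mort$treefall_exponent
  mort$treefall_max_prob * he /
    (he + mort$treefall_height_scale^mort$treefall_exponent)
}

#' Stage-2 mortality: primary and secondary treefall
#'
#' Draws a Bernoulli primary treefall with probability increasing in height.
#' On a fall, a uniform random azimuth is drawn and every living tree whose
#' voxel lies in the fall corridor (length equal to the faller's height,
#' half-width its crown radius) is crushed; crushed trees die when shorter
#' than half the faller's height.
#'
#' @param grid A `forest_grid`.
#' @param tree_id Identifier of the candidate faller.
#' @param mort [mortality_params()].
#' @return A list with the updated `grid` and a data frame `deaths`
#'   (columns `tree_id`, `cause` in `"treefall_primary"` /
#'   `"treefall_secondary"`).
#' @export
stage2_treefall <- function(grid, tree_id, mort = mortality_params()) {
  i <- which(grid$trees$tree_id == tree_id & grid$trees$alive)
  if (!length(i)) stop("no living tree with that id", call. = FALSE)
  tr <- grid$trees[i, ]
  deaths <- data.frame(tree_id = integer(), cause = character(),
                       stringsAsFactors = FALSE)
  if (runif(1) >= treefall_probability(tr$height, mort)) {
    return(list(grid = grid, deaths = deaths))
  }
  grid$trees$alive[i] <- FALSE
  deaths <- data.frame(tree_id = tr$tree_id, cause = "treefall_primary",
                       stringsAsFactors = FALSE)
  az <- runif(1, 0, 2 * pi)
  ux <- cos(az); uy <- sin(az)
  liv <- which(grid$trees$alive)
  for (j in liv) {
    dx <- grid$trees$x[j] - tr$x
    dy <- grid$trees$y[j] - tr$y
    if (grid$boundary == "torus") {
      if (dx > grid$width / 2) dx <- dx - grid$width
      if (dx < -grid$width / 2) dx <- dx + grid$width
      if (dy > grid$length / 2) dy <- dy - grid$length
      if (dy < -grid$length / 2) dy <- dy + grid$length
    }
    proj <- dx * ux + dy * uy
    perp <- abs(-dx * uy + dy * ux)
    if (proj > 0 && proj <= tr$height && perp <= tr$crown_radius &&
        grid$trees$height[j] < tr$height / 2) {
      grid$trees$alive[j] <- FALSE
      deaths <- rbind(deaths, data.frame(
        tree_id = grid$trees$tree_id[j], cause = "treefall_secondary",
        stringsAsFactors = FALSE
      ))
    }
  }
  list(grid = grid, deaths = deaths)
}

#' Recruit new trees into empty, sufficiently lit ground voxels
#'
#' For every unoccupied ground voxel, a species is drawn from the seedbank
#' (unit external seed rain for every species plus extra weight per mature
#' conspecific in the domain). The draw recruits at DBH = 1 cm when the
#' voxel's mean-day ground PPFD exceeds the species light-compensation
#' threshold.
#'
#' @param grid A `forest_grid`.
#' @param ground_ppfd Numeric vector of mean-day PPFD at ground level, one
#'   value per ground voxel in column-major (x fastest) order.
#' @param traits A [species_traits()] table.
#' @param phys [physiology_params()].
#' @param mort [mortality_params()].
#' @return The updated grid (new trees appended to its tree table).
#' @export
recruit <- function(grid, ground_ppfd, traits, phys = physiology_params(),
                    mort = mortality_params()) {
  stopifnot(length(ground_ppfd) == n_ground_voxels(grid))
  dp <- derive_physiology(traits, phys)
  live <- grid$trees[grid$trees$alive, , drop = FALSE]
  w <- rep(1, nrow(traits))
  if (nrow(live)) {
    mature <- live$dbh >= traits$maturity_dbh[match(live$species_id,
                                                    traits$species_id)]
    tab <- table(factor(live$species_id[mature], levels = traits$species_id))
    # presence bonus: bounded so abundant species cannot monopolize the bank
    w <- w + mort$seedbank_local_weight * as.numeric(tab > 0)
  }
  occ <- rep(FALSE, n_ground_voxels(grid))
  if (nrow(live)) occ[live$x + live$y * grid$width + 1] <- TRUE
  cw <- cumsum(w) / sum(w)
  for (v in which(!occ)) {
    # inverse-CDF draw: one uniform per empty voxel, replayable
    s <- findInterval(runif(1), cw) + 1L
    if (ground_ppfd[v] > dp$comp_ppfd[s]) {
      x <- (v - 1) %% grid$width
      y <- (v - 1) %/% grid$width
      grid <- place_tree(grid, traits[s, ], x, y, dbh = 1, phys = phys,
                         leaf_area = 1)
    }
  }
  grid
}
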