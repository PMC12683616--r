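#' Physiology and allocation parameters
#'
#' Collects the whole-plant carbon-balance constants. Net primary production
#' is split into belowground, wood, and canopy fractions which must sum to 1.
#' The allocation can be given either as (`f_wood`, `f_canopy`) directly or
#' through the cylindrical parameterization (`f_below`, `theta`) used by the
#' uncertainty analysis (see [allocation_from_cylindrical()]).
#'
#' @param phi Apparent quantum yield for carbon fixation,
#'   mol C (mol photon)-1; must lie in (0, 0.1].
#' @param f_below Fraction of NPP allocated belowground.
#' @param f_wood,f_canopy Aboveground allocation fractions. If `theta` is
#'   given they are derived from it instead.
#' @param theta Optional allocation angle (radians, in (0, pi/2)).
#' @param medlyn_g1 Stomatal slope parameter (kPa^0.5).
#' @param k_ext Beer-Lambert canopy extinction coefficient.
#' @param rg_frac Growth respiration as a fraction of (GPP - maintenance).
#' @param rstem_coef Stem maintenance respiration per sapwood volume
#'   (umol C m-3 s-1 at 25 C).
#' @param rbelow_frac Belowground respiration as a fraction of aboveground
#'   maintenance respiration.
#' @param form_factor Stem volume form factor (volume relative to a cylinder).
#' @param cfrac Carbon fraction of dry biomass.
#' @param wood_reduction Multiplier on the wood allocation fraction above the
#'   species size threshold.
#' @param size_threshold_frac Fraction of the species maximum DBH above which
#'   wood allocation is reduced.
#' @param lai_max Cap on crown leaf area index.
#' @param cr_a,cr_b Crown radius allometry `cr = cr_a * dbh^cr_b` (m, cm).
#' @param cd_frac Crown depth as a fraction of tree height.
#' @param vcmax_int,vcmax_sn,vcmax_sp Intercept and N/P slopes of the
#'   log10-linear Vcmax25 trait relationship (area basis).
#' @param vcmax_int_n Intercept of the N-only route used when leaf %P is
#'   missing (the mean P contribution is folded in).
#' @param jv_ratio Jmax25 : Vcmax25 ratio.
#' @param rd_frac Leaf dark respiration at 25 C as a fraction of Vcmax25.
#' @param comp_factor Safety margin on the leaf light-compensation PPFD used
#'   as the recruitment light threshold.
#' @return A validated list of class `physiology_params`.
#' @export
physiology_params <- function(phi = 0.065, f_below = 0.30,
                              f_wood = 0.35, f_canopy = 0.35, theta = NULL,
                              medlyn_g1 = 3.77, k_ext = 0.5, rg_frac = 0.25,
                              rstem_coef = 40, rbelow_frac = 0.5,
                              form_factor = 0.6, cfrac = 0.45,
                              wood_reduction = 0.5, size_threshold_frac = 0.5,
                              lai_max = 8, cr_a = 0.5, cr_b = 0.6,
                              cd_frac = 0.25,
                              vcmax_int = 1.75, vcmax_sn = 0.55,
                              vcmax_sp = 0.25, vcmax_int_n = 1.52,
                              jv_ratio = 1.67, rd_frac = 0.015,
                              comp_factor = 2) {
  if (!is.null(theta)) {
    fc <- allocation_from_cylindrical(f_below, theta)
    f_wood <- fc[["f_wood"]]; f_canopy <- fc[["f_canopy"]]
  }
  if (phi <= 0 || phi > 0.1) stop("phi must be in (0, 0.1]", call. = FALSE)
  fr <- c(f_below = f_below, f_wood = f_wood, f_canopy = f_canopy)
  if (any(fr < 0 | fr > 1)) {
    stop("allocation fractions must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-12) {
    stop("f_below + f_wood + f_canopy must equal 1", call. = FALSE)
  }
  structure(list(
    phi = phi, f_below = f_below, f_wood = f_wood, f_canopy = f_canopy,
    g1 = medlyn_g1, k_ext = k_ext, rg_frac = rg_frac,
    rstem_coef = rstem_coef, rbelow_frac = rbelow_frac,
    form_factor = form_factor, cfrac = cfrac,
    wood_reduction = wood_reduction,
    size_threshold_frac = size_threshold_frac, lai_max = lai_max,
    cr_a = cr_a, cr_b = cr_b, cd_frac = cd_frac,
    vcmax_int = vcmax_int, vcmax_sn = vcmax_sn, vcmax_sp = vcmax_sp,
    vcmax_int_n = vcmax_int_n, jv_ratio = jv_ratio, rd_frac = rd_frac,
    comp_factor = comp_factor
  ), class = "physiology_params")
}

#' Tree height from DBH
#'
#' Generalized Michaelis-Menten allometry
#' `H = allom_a * dbh^allom_b / (allom_k + dbh^allom_b)`: monotone increasing
#' in DBH and bounded above by the asymptote `allom_a`.
#'
#' @param dbh Diameter at breast height, cm (> 0); vectorized.
#' @param traits One row of a [species_traits()] table (or any list with
#'   `allom_a`, `allom_b`, `allom_k`).
#' @return Height in metres.
#' @examples
#' allometric_height(60, list(allom_a = 40, allom_b = 1, allom_k = 20)) # 30
#' @export
allometric_height <- function(dbh, traits) {
  cpp_allom_height(as.numeric(dbh), as.numeric(traits$allom_a),
                   as.numeric(traits$allom_b), as.numeric(traits$allom_k))
}

#' Canopy light field
#'
#' Attenuates top-of-canopy PPFD downward through each voxel column with the
#' Beer-Lambert law. Crowns are umbrella-shaped: one-voxel-thick disk layers
#' spanning the crown depth with uniform leaf area density. Returns, per
#' voxel, the fraction of incident light arriving from above, and per tree
#' the absorbed flux per unit leaf area (as a fraction of the incident flux).
#'
#' @param grid A `forest_grid` with trees.
#' @param phys [physiology_params()] (supplies `k_ext` and `lai_max`).
#' @param incident Top-of-canopy PPFD; results scale linearly (default 1, so
#'   everything is reported as a fraction).
#' @return A list with `frac_above` (height x column matrix), `lai`
#'   (leaf area density per voxel), `ground_frac` (per-column fraction
#'   reaching the ground), and `afrac_leaf` (per living tree, in tree-table
#'   order).
#' @export
light_field <- function(grid, phys = physiology_params(), incident = 1) {
  stopifnot(inherits(grid, "forest_grid"))
  tr <- grid$trees[grid$trees$alive, , drop = FALSE]
  lf <- cpp_light_field(
    grid$width, grid$length, grid$height,
    as.integer(tr$x), as.integer(tr$y), tr$height, tr$crown_radius,
    as.integer(tr$crown_depth), tr$leaf_area,
    phys$k_ext, phys$lai_max, grid$boundary == "torus"
  )
  lf$frac_above <- lf$frac_above * incident
  lf$ground_ppfd <- lf$ground_frac * incident
  lf
}

#' Monthly net primary production of one tree
#'
#' Integrates the leaf carbon balance over one month of the half-hourly
#' climatology. Gross photosynthesis per slot is the minimum of a
#' Rubisco-limited rate (scaled by temperature and a stomatal VPD factor)
#' and an RuBP-regeneration rate (`phi` times absorbed PPFD, capped by
#' electron transport). NPP = GPP - leaf, stem, and belowground maintenance
#' respiration - growth respiration, and may be negative.
#'
#' @param tree One row of a grid tree table (needs `dbh`, `leaf_area`).
#' @param absorbed_ppfd Absorbed PPFD per unit leaf area for each of the 48
#'   half-hourly slots (umol m-2 s-1).
#' @param forcing_month Data frame with 48 rows and columns `ppfd`, `temp`,
#'   `vpd` (only `temp` and `vpd` are used; light enters via
#'   `absorbed_ppfd`).
#' @param phys [physiology_params()].
#' @param traits The tree's species traits row.
#' @return A list with components `gpp`, `r_leaf`, `r_stem`, `r_below`,
#'   `r_growth`, and `npp`, all in kg C per month.
#' @export
monthly_npp <- function(tree, absorbed_ppfd, forcing_month,
                        phys = physiology_params(), traits) {
  if (nrow(forcing_month) != 48 || length(absorbed_ppfd) != 48) {
    stop("one month of forcing must have 48 half-hourly slots", call. = FALSE)
  }
  dp <- derive_physiology(traits, phys)
  sv <- stem_volume(tree$dbh, traits, phys)
  cpp_npp_month(
    1.0, tree$leaf_area, dp$vcmax25, dp$jmax25, dp$rd25, sv, tree$dbh,
    as.numeric(absorbed_ppfd), as.numeric(forcing_month$temp),
    as.numeric(forcing_month$vpd),
    phys$phi, phys$g1, phys$rstem_coef, phys$rbelow_frac, phys$rg_frac
  )
}

# Stem volume (m3) implied by DBH through the form-factor cylinder model.
stem_volume <- function(dbh, traits, phys) {
  h <- allometric_height(dbh, traits)
  phys$form_factor * pi / 4 * (dbh / 100)^2 * h
}

# Woody carbon mass (kg C) implied by DBH.
wood_mass_from_dbh <- function(dbh, traits, phys) {
  stem_volume(dbh, traits, phys) * phys$cfrac * 1000 * traits$wsg
}

# Invert wood carbon mass to DBH with a few Newton steps (monotone).
dbh_from_wood_mass <- function(wood, dbh0, traits, phys) {
  v_target <- wood / (phys$cfrac * 1000 * traits$wsg)
  d <- dbh0
  for (i in 1:5) {
    h <- allometric_height(d, traits)
    db <- d^traits$allom_b
    hprime <- traits$allom_a * traits$allom_b * d^(traits$allom_b - 1) *
      traits$allom_k / (traits$allom_k + db)^2
    f <- phys$form_factor * pi / 4 * (d / 100)^2 * h - v_target
    fp <- phys$form_factor * pi / 4 * (2 * d / 1e4 * h + (d / 100)^2 * hprime)
    if (fp <= 0) break
    d <- d - f / fp
    if (d < dbh0) return(dbh0)
  }
  max(d, dbh0)
}

#' Allocate NPP and grow a tree
#'
#' Positive NPP is split into belowground, wood, and canopy increments.
#' Above the species size threshold (a fixed fraction of the species maximum
#' DBH) the wood fraction is multiplied by `wood_reduction` and the remainder
#' is diverted belowground, so the three increments always sum to NPP.
#' Wood growth updates stem volume, DBH (never decreasing), height, crown
#' radius, and crown depth through the allometries. Nonpositive NPP produces
#' no growth and increments the consecutive negative-NPP counter.
#'
#' @param tree One row of a grid tree table.
#' @param npp Net primary production for the month (kg C).
#' @param phys [physiology_params()].
#' @param traits The tree's species traits row.
#' @return The updated tree row, with an `increments` attribute holding the
#'   belowground/wood/canopy split.
#' @export
allocate_and_grow <- function(tree, npp, phys = physiology_params(), traits) {
  if (!isTRUE(tree$alive)) stop("tree is not alive", call. = FALSE)
  if (npp <= 0) {
    tree$npp_negative_months <- tree$npp_negative_months + 1L
    attr(tree, "increments") <- c(below = 0, wood = 0, canopy = 0)
    return(tree)
  }
  tree$npp_negative_months <- 0L
  thresh <- phys$size_threshold_frac * species_max_dbh(traits)
  red <- if (tree$dbh > thresh) phys$wood_reduction else 1
  if (tree$dbh >= species_max_dbh(traits)) red <- 0 # growth cap
  d_wood <- phys$f_wood * red * npp
  d_canopy <- phys$f_canopy * npp
  d_below <- npp - d_wood - d_canopy
  wood <- wood_mass_from_dbh(tree$dbh, traits, phys) + d_wood
  tree$dbh <- dbh_from_wood_mass(wood, tree$dbh, traits, phys)
  tree$height <- allometric_height(tree$dbh, traits)
  tree$crown_radius <- phys$cr_a * tree$dbh^phys$cr_b
  tree$crown_depth <- max(1, round(phys$cd_frac * tree$height))
  tree$leaf_area <- tree$leaf_area +
    d_canopy / (traits$lma * phys$cfrac * 1e-3)
  # crown holds at most lai_max over its area; excess canopy is shed
  lacap <- phys$lai_max * max(1, pi * tree$crown_radius^2)
  tree$leaf_area <- min(tree$leaf_area, lacap)
  attr(tree, "increments") <- c(below = d_below, wood = d_wood,
                                canopy = d_canopy)
  tree
}
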