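#' Validate a species-trait table
#'
#' A species is defined by leaf mass per area (LMA, g m-2), wood specific
#' gravity (unitless), leaf nitrogen (% mass), leaf phosphorus (% mass,
#' optionally missing), three generalized Michaelis-Menten DBH-height
#' allometric parameters (`allom_a` asymptote in m, `allom_b` exponent,
#' `allom_k` half-saturation), a reproductive maturity DBH (cm), and a
#' lightning log-odds shift `delta_i` (0 = community-mean risk; negative =
#' tolerant). Missing `delta_i` is treated as 0 (unknown tolerance).
#'
#' @param df Data frame with one row per species.
#' @return The validated table with class `species_traits`.
#' @export
species_traits <- function(df) {
  req <- c("species_id", "lma", "wsg", "leaf_n", "allom_a", "allom_b",
           "allom_k", "maturity_dbh")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("species table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"leaf_p" %in% names(df)) df$leaf_p <- NA_real_
  if (!"delta_i" %in% names(df)) df$delta_i <- 0
  if (!"max_dbh" %in% names(df)) {
    # fall back to the DBH where height reaches 90% of the asymptote,
    # bounded by the largest stems seen in mature tropical forest
    df$max_dbh <- pmin(250, (9 * df$allom_k)^(1 / df$allom_b))
  }
  df$delta_i[is.na(df$delta_i)] <- 0
  if (anyDuplicated(df$species_id)) {
    stop("duplicated species_id", call. = FALSE)
  }
  bad <- function(v, cond) any(!is.na(v) & cond(v)) || anyNA(v)
  if (bad(df$wsg, function(v) v <= 0 | v > 1.2)) {
    stop("wsg must be in (0, 1.2]", call. = FALSE)
  }
  if (bad(df$lma, function(v) v <= 0)) stop("lma must be > 0", call. = FALSE)
  if (bad(df$allom_a, function(v) v <= 0)) {
    stop("allom_a must be > 0", call. = FALSE)
  }
  if (bad(df$maturity_dbh, function(v) v <= 0)) {
    stop("maturity_dbh must be > 0", call. = FALSE)
  }
  if (any(!is.finite(df$delta_i))) {
    stop("delta_i must be finite (use NA for unknown)", call. = FALSE)
  }
  df$species_id <- as.character(df$species_id)
  class(df) <- c("species_traits", "data.frame")
  df
}

#' Read or write a species-trait table as CSV
#'
#' One row per species; header names match the fields of [species_traits()].
#' Blank `delta_i` entries are read as 0.
#' @param path File path.
#' @export
read_species_table <- function(path) {
  species_traits(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_species_table
#' @param traits A `species_traits` table.
#' @export
write_species_table <- function(traits, path) {
  write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

# Trait-derived leaf physiology. Carboxylation and electron-transport
# capacities and leaf dark respiration come from log-linear relationships
# with area-based leaf N and P; when leaf %P is missing the same relationship
# is used with the P term dropped and its mean contribution folded into the
# intercept.
derive_physiology <- function(traits, phys = physiology_params()) {
  narea <- traits$leaf_n / 100 * traits$lma      # g N m-2
  parea <- traits$leaf_p / 100 * traits$lma      # g P m-2
  lv <- ifelse(
    is.na(parea),
    phys$vcmax_int_n + phys$vcmax_sn * log10(narea),
    phys$vcmax_int + phys$vcmax_sn * log10(narea) + phys$vcmax_sp * log10(parea)
  )
  vcmax25 <- 10^lv
  jmax25 <- phys$jv_ratio * vcmax25
  rd25 <- phys$rd_frac * vcmax25
  # lifespan proportional to LMA keeps the leaf construction cost per
  # unit leaf area trait-neutral (leaf economics spectrum midline)
  lifespan <- pmax(2, round(12 * (traits$lma / 100)))
  comp_ppfd <- phys$comp_factor * rd25 / phys$phi
  data.frame(vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25,
             leaf_lifespan_months = lifespan, comp_ppfd = comp_ppfd)
}

# Species maximum DBH (cm): an explicit trait when present, otherwise the
# DBH where height reaches 90% of the asymptote, bounded at 250 cm. Wood
# allocation is reduced above size_threshold_frac times this value and stops
# entirely at it.
species_max_dbh <- function(traits) {
  if (!is.null(traits$max_dbh)) {
    return(traits$max_dbh)
  }
  pmin(250, (9 * traits$allom_k)^(1 / traits$allom_b))
}

# Species parameter matrix handed to the C++ engine. Column order must match
# the enum in engine.cpp.
.sp_matrix <- function(traits, phys, mort) {
  dp <- derive_physiology(traits, phys)
  pb <- background_probability(traits$wsg, mort)
  cbind(
    lma = traits$lma, wsg = traits$wsg,
    aa = traits$allom_a, ab = traits$allom_b, ak = traits$allom_k,
    maturity = traits$maturity_dbh, delta = traits$delta_i,
    vcmax = dp$vcmax25, jmax = dp$jmax25, rd = dp$rd25,
    lifespan = dp$leaf_lifespan_months, pb_month = pb,
    comp_ppfd = dp$comp_ppfd,
    dbh_thresh = phys$size_threshold_frac * species_max_dbh(traits),
    max_dbh = species_max_dbh(traits)
  )
}
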