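#' Run the forest simulator
#'
#' Runs the monthly individual-based simulation: canopy light transfer and
#' tree carbon balance, allometric growth, stage-1 mortality (background +
#' carbon starvation), stage-2 treefall with secondary damage, lightning
#' (optional third stage), and recruitment into vacated voxels. Starts from
#' bare ground. Deterministic given `config$seed`.
#'
#' @param config A run configuration, see [default_config()] /
#'   [load_config()].
#' @param traits A [species_traits()] table; defaults to the table at
#'   `config$paths$species`, or a synthetic community from [gen_species()]
#'   seeded by `config$seed` when no path is set.
#' @param forcing A forcing table (`month`, `slot`, `ppfd`, `temp`, `vpd`,
#'   576 rows); defaults analogously to [gen_forcing()].
#' @param lam_schedule Optional per-month lightning frequency vector
#'   (CG fl km-2 yr-1) overriding the constant `config$lightning$lam`; see
#'   [transient_lambda()].
#' @param keep_events Keep the per-strike event log (default `TRUE`).
#' @return An object of class `forest_run`: annual state table `years`,
#'   per-species annual AGB `species_agb`, cumulative lightning
#'   `kills_by_class`, the strike `events` log, the final tree table, and a
#'   `summary` list averaged over the final `config$avg_window_yr` years
#'   (AGB Mg ha-1, GPP Mg C ha-1 yr-1, N10/N30/N60 stems per domain,
#'   strike and kill rates).
#' @export
simulate_forest <- function(config = default_config(), traits = NULL,
                            forcing = NULL, lam_schedule = NULL,
                            keep_events = TRUE) {
  config <- validate_config(config)
  if (is.null(traits)) {
    traits <- if (!is.null(config$paths$species)) {
      read_species_table(config$paths$species)
    } else {
      gen_species(seed = config$seed)
    }
  }
  traits <- species_traits(traits)
  if (config$mode == "SSLR" && !"delta_i" %in% names(traits)) {
    stop("SSLR mode requires a species table with delta_i", call. = FALSE)
  }
  if (is.null(forcing)) {
    forcing <- if (!is.null(config$paths$forcing)) {
      read_forcing(config$paths$forcing)
    } else {
      gen_forcing(seed = config$seed)
    }
  }
  fm <- forcing_matrices(forcing)
  phys <- do.call(physiology_params, config$physiology)
  mort <- do.call(mortality_params, config$mortality)
  lg <- config$lightning
  n_months <- config$duration_yr * 12L
  if (is.null(lam_schedule)) {
    lam_schedule <- rep(lg$lam, n_months)
  }
  if (any(lam_schedule < 0)) {
    stop("lightning frequency schedule must be nonnegative", call. = FALSE)
  }
  mode_int <- match(config$mode, c("none", "CLLR", "SSLR")) - 1L
  set.seed(config$seed)
  res <- cpp_run_forest(
    config$domain$width, config$domain$length, config$domain$height,
    config$domain$boundary == "torus",
    .sp_matrix(traits, phys, mort),
    fm$ppfd, fm$temp, fm$vpd,
    phys[c("phi", "f_wood", "f_canopy", "k_ext", "g1", "rg_frac",
           "rstem_coef", "rbelow_frac", "form_factor", "cfrac",
           "wood_reduction", "lai_max", "cr_a", "cr_b", "cd_frac")],
    mort[c("treefall_max_prob", "treefall_height_scale",
           "treefall_exponent", "seedbank_local_weight")],
    list(mode = mode_int, a = lg$a, p_direct = lg$p_direct,
         r_max = lg$r_max, search_radius = lg$search_radius,
         lam_schedule = as.numeric(lam_schedule)),
    n_months, config$avg_window_yr, keep_events
  )
  years <- data.frame(
    year = seq_len(config$duration_yr),
    agb = res$agb, gpp = res$gpp, n10 = res$n10, n30 = res$n30,
    n60 = res$n60, strikes = res$strikes, kills = res$kills,
    kills60 = res$kills60, recruits = res$recruits,
    deaths_background = res$deaths[, 1], deaths_starvation = res$deaths[, 2],
    deaths_treefall = res$deaths[, 3], deaths_lightning = res$deaths[, 4]
  )
  spagb <- res$species_agb
  colnames(spagb) <- traits$species_id
  kb <- res$kills_by_class
  dimnames(kb) <- list(traits$species_id,
                       c("dbh_le10", "dbh_10_30", "dbh_30_60", "dbh_gt60"))
  win <- seq(max(1, config$duration_yr - config$avg_window_yr + 1),
             config$duration_yr)
  total_strikes <- sum(years$strikes[win])
  total_kills <- sum(years$kills[win])
  summary <- list(
    agb = mean(years$agb[win]), gpp = mean(years$gpp[win]),
    n10 = mean(years$n10[win]), n30 = mean(years$n30[win]),
    n60 = mean(years$n60[win]),
    strikes_per_yr = total_strikes / length(win),
    kills_per_yr = total_kills / length(win),
    kills_per_strike = if (total_strikes > 0) {
      total_kills / total_strikes
    } else {
      NA_real_
    },
    species_agb = colMeans(spagb[win, , drop = FALSE])
  )
  structure(list(
    years = years, species_agb = spagb, kills_by_class = kb,
    events = as.data.frame(res$events),
    final_trees = as.data.frame(res$final_trees),
    summary = summary, config = config, traits = traits
  ), class = "forest_run")
}

#' @export
print.forest_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<forest_run> %d x %d m, %d yr, mode %s\n",
    x$config$domain$width, x$config$domain$length, x$config$duration_yr,
    x$config$mode))
  cat(sprintf(
    "  final %d-yr means: AGB %.1f Mg/ha, GPP %.1f MgC/ha/yr, N10 %.0f, N30 %.0f, N60 %.0f\n",
    x$config$avg_window_yr, s$agb, s$gpp, s$n10, s$n30, s$n60))
  if (x$config$mode != "none") {
    cat(sprintf("  lightning: %.2f strikes/yr, %.2f kills/yr (%.2f per strike)\n",
                s$strikes_per_yr, s$kills_per_yr, s$kills_per_strike))
  }
  invisible(x)
}

# 12 x 48 forcing matrices from the long table
forcing_matrices <- function(forcing) {
  names(forcing)[names(forcing) == "temperature"] <- "temp"
  req <- c("month", "slot", "ppfd", "temp", "vpd")
  miss <- setdiff(req, names(forcing))
  if (length(miss)) {
    stop("forcing lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(forcing) != 576) {
    stop("forcing must have 12 months x 48 half-hourly slots", call. = FALSE)
  }
  if (any(forcing$ppfd < 0) || any(forcing$vpd < 0)) {
    stop("ppfd and vpd must be nonnegative", call. = FALSE)
  }
  forcing <- forcing[order(forcing$month, forcing$slot), ]
  list(
    ppfd = matrix(forcing$ppfd, 12, 48, byrow = TRUE),
    temp = matrix(forcing$temp, 12, 48, byrow = TRUE),
    vpd = matrix(forcing$vpd, 12, 48, byrow = TRUE)
  )
}

#' Read or write half-hourly climatological forcing as CSV
#'
#' Columns `month` (1-12), `slot` (1-48, half-hours from midnight), `ppfd`
#' (umol photon m-2 s-1), `temp` (C), `vpd` (kPa); 576 rows.
#' @param path File path.
#' @export
read_forcing <- function(path) {
  df <- read.csv(path)
  names(df)[names(df) == "temperature"] <- "temp"
  forcing_matrices(df) # validation
  df
}

#' @rdname read_forcing
#' @param forcing A forcing table.
#' @export
write_forcing <- function(forcing, path) {
  write.csv(forcing, path, row.names = FALSE)
  invisible(path)
}
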