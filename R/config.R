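#' Default run configuration
#'
#' Flat, YAML-serializable list controlling a simulation: domain dimensions
#' and boundary rule, duration and averaging window, lightning mode and
#' parameters, physiology and mortality parameter overrides, seed, and
#' optional input paths. Every field has a documented default; [load_config()]
#' fills omitted keys with these values.
#'
#' @param ... Named overrides of top-level keys (nested lists are merged).
#' @export
default_config <- function(...) {
  cfg <- list(
    domain = list(width = 200L, length = 200L, height = 50L,
                  boundary = "torus"),
    duration_yr = 600L,
    avg_window_yr = 50L,
    mode = "none",
    seed = 1L,
    lightning = list(lam = 12.7, a = -2.5, p_direct = 0.75, d = 0.5,
                     r_max = 25, search_radius = 15),
    physiology = list(),
    mortality = list(),
    paths = list(species = NULL, forcing = NULL, mortality_bins = NULL)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

known_config_keys <- function() {
  list(
    top = c("domain", "duration_yr", "avg_window_yr", "mode", "seed",
            "lightning", "physiology", "mortality", "paths"),
    domain = c("width", "length", "height", "boundary"),
    lightning = c("lam", "a", "p_direct", "d", "r_max", "search_radius"),
    physiology = names(formals(physiology_params)),
    mortality = names(formals(mortality_params)),
    paths = c("species", "forcing", "mortality_bins")
  )
}

#' Validate a run configuration
#'
#' Checks key names, value ranges, and cross-field constraints (averaging
#' window within duration; SSLR mode requires a species table carrying
#' `delta_i` when a species path is given). All failures are reported
#' together.
#'
#' @param config A configuration list.
#' @return The validated configuration (with defaults filled in).
#' @export
validate_config <- function(config) {
  cfg <- do.call(default_config, config)
  keys <- known_config_keys()
  errs <- character()
  unknown <- setdiff(names(cfg), keys$top)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown keys: ", paste(unknown, collapse = ", ")))
  }
  for (sect in c("domain", "lightning", "physiology", "mortality", "paths")) {
    bad <- setdiff(names(cfg[[sect]]), keys[[sect]])
    if (length(bad)) {
      errs <- c(errs, paste0("unknown ", sect, " keys: ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (!cfg$mode %in% c("none", "CLLR", "SSLR")) {
    errs <- c(errs, "mode must be one of none, CLLR, SSLR")
  }
  if (cfg$avg_window_yr > cfg$duration_yr) {
    errs <- c(errs, "avg_window_yr must not exceed duration_yr")
  }
  d <- cfg$domain
  if (any(unlist(d[c("width", "length", "height")]) <= 0)) {
    errs <- c(errs, "domain dimensions must be positive")
  }
  if (!d$boundary %in% c("torus", "hard")) {
    errs <- c(errs, "boundary must be torus or hard")
  }
  lg <- cfg$lightning
  if (lg$lam < 0) errs <- c(errs, "lightning: lam must be nonnegative")
  if (lg$p_direct < 0 || lg$p_direct > 1) {
    errs <- c(errs, "lightning: p_direct must be in [0, 1]")
  }
  if (lg$d < 0 || lg$d > 1) errs <- c(errs, "lightning: d must be in [0, 1]")
  if (cfg$mode == "SSLR" && !is.null(cfg$paths$species)) {
    sp <- tryCatch(read.csv(cfg$paths$species), error = function(e) NULL)
    if (!is.null(sp) && !"delta_i" %in% names(sp)) {
      errs <- c(errs, "SSLR mode requires a species table with delta_i")
    }
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$domain$width <- as.integer(cfg$domain$width)
  cfg$domain$length <- as.integer(cfg$domain$length)
  cfg$domain$height <- as.integer(cfg$domain$height)
  cfg$duration_yr <- as.integer(cfg$duration_yr)
  cfg$avg_window_yr <- as.integer(cfg$avg_window_yr)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load or save a run configuration (YAML)
#'
#' An empty file yields the full default configuration. Unknown keys and
#' out-of-range values are rejected with field-level messages; save followed
#' by load is the identity.
#'
#' @param path File path.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param config A configuration list.
#' @export
save_config <- function(config, path) {
  cfg <- validate_config(config)
  cfg$paths <- cfg$paths[!vapply(cfg$paths, is.null, logical(1))]
  if (!length(cfg$paths)) cfg$paths <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write run outputs to a directory
#'
#' Writes the annual state table (`annual_state.csv`), the per-species annual
#' AGB table (`species_agb.csv`, columns sum to the total AGB), the lightning
#' event log (`lightning_events.csv`, header only for zero-strike runs), and
#' a metadata record (`run_metadata.json`: configuration, seed, package
#' version) sufficient to reproduce the run.
#'
#' @param run A `forest_run`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_outputs <- function(run, dir) {
  stopifnot(inherits(run, "forest_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(run$years, file.path(dir, "annual_state.csv"), row.names = FALSE)
  spagb <- data.frame(year = run$years$year, run$species_agb,
                      check.names = FALSE)
  write.csv(spagb, file.path(dir, "species_agb.csv"), row.names = FALSE)
  write.csv(run$events, file.path(dir, "lightning_events.csv"),
            row.names = FALSE)
  meta <- list(
    config = run$config,
    seed = run$config$seed,
    package_version = as.character(utils::packageVersion("lightgap")),
    summary = run$summary[c("agb", "gpp", "n10", "n30", "n60")]
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}

#' Read back run outputs written by [write_outputs()]
#'
#' @param dir Directory written by [write_outputs()].
#' @return A list with `years`, `species_agb`, `events`, and `metadata`.
#' @export
read_outputs <- function(dir) {
  list(
    years = read.csv(file.path(dir, "annual_state.csv")),
    species_agb = read.csv(file.path(dir, "species_agb.csv"),
                           check.names = FALSE),
    events = read.csv(file.path(dir, "lightning_events.csv")),
    metadata = jsonlite::read_json(file.path(dir, "run_metadata.json"))
  )
}
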