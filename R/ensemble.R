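#' Allocation fractions from the cylindrical parameterization
#'
#' The wood and canopy NPP allocation fractions satisfy
#' `f_wood + f_canopy + f_below = 1`, so they are sampled through an angle
#' `theta` with `tan(theta) = f_canopy / f_wood`:
#' `f_wood = (1 - f_below) cos(theta) / (cos(theta) + sin(theta))` and
#' analogously for `f_canopy`. The sum constraint holds exactly.
#'
#' @param f_below Belowground fraction, in `[0, 1)`; vectorized.
#' @param theta Allocation angle in radians, strictly inside (0, pi/2);
#'   vectorized.
#' @return A list with components `f_wood` and `f_canopy`.
#' @export
allocation_from_cylindrical <- function(f_below, theta) {
  if (any(theta <= 0 | theta >= pi / 2)) {
    stop("theta must lie strictly inside (0, pi/2)", call. = FALSE)
  }
  if (any(f_below < 0 | f_below >= 1)) {
    stop("f_below must lie in [0, 1)", call. = FALSE)
  }
  denom <- cos(theta) + sin(theta)
  list(f_wood = (1 - f_below) * cos(theta) / denom,
       f_canopy = (1 - f_below) * sin(theta) / denom)
}

#' Run one ensemble member
#'
#' Applies one uncertainty-analysis parameter set to a base configuration and
#' runs the simulator. `phi`, `m0`, `f_below`, and `theta` override the
#' physiology and mortality settings; `lam` sets the lightning frequency; and
#' `d` re-calibrates the community-level risk parameters (`a`, `p_direct`)
#' against the binned mortality observations before the run (lightning modes
#' only).
#'
#' @param config Base configuration.
#' @param params One row of a [sobol_sample()] data frame (or any list with
#'   some of `phi`, `m0`, `f_below`, `theta`, `lam`, `d`).
#' @param duration Simulation length in years (default from config).
#' @param seed RNG seed for this member.
#' @param traits,forcing Passed to [simulate_forest()].
#' @param binned Binned mortality observations used to re-calibrate from `d`;
#'   required when `params$d` is supplied and lightning is on.
#' @return A `forest_run`.
#' @export
run_one <- function(config, params = NULL, duration = NULL, seed = NULL,
                    traits = NULL, forcing = NULL, binned = NULL) {
  config <- validate_config(config)
  if (!is.null(duration)) config$duration_yr <- as.integer(duration)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (config$duration_yr < config$avg_window_yr) {
    stop("duration must cover the averaging window", call. = FALSE)
  }
  if (!is.null(params)) {
    params <- as.list(params)
    if (!is.null(params$phi)) config$physiology$phi <- params$phi
    if (!is.null(params$f_below) || !is.null(params$theta)) {
      fb <- if (is.null(params$f_below)) {
        config$physiology$f_below
      } else {
        params$f_below
      }
      th <- if (is.null(params$theta)) pi / 4 else params$theta
      fc <- allocation_from_cylindrical(fb, th)
      config$physiology$f_below <- fb
      config$physiology$f_wood <- fc$f_wood
      config$physiology$f_canopy <- fc$f_canopy
    }
    if (!is.null(params$m0)) config$mortality$m0 <- params$m0
    if (!is.null(params$lam)) config$lightning$lam <- params$lam
    if (!is.null(params$d) && config$mode != "none") {
      if (is.null(binned)) {
        stop("re-calibration from d requires binned mortality observations",
             call. = FALSE)
      }
      cal <- calibrate_cllr(binned, params$d)
      config$lightning$a <- cal$a_star
      config$lightning$p_direct <- cal$p_direct_star
      config$lightning$d <- params$d
    }
  }
  simulate_forest(config, traits = traits, forcing = forcing)
}

#' Filter ensemble members consistent with observations
#'
#' Keeps the runs whose equilibrium AGB, GPP, N10, and N60 all fall inside
#' the supplied observational confidence intervals.
#'
#' @param outputs Data frame with columns `agb`, `gpp`, `n10`, `n60` (one row
#'   per run), e.g. built from `forest_run$summary`.
#' @param ci Named list of `c(lower, upper)` intervals for `agb`, `gpp`,
#'   `n10`, `n60`.
#' @return Integer indices of the consistent runs.
#' @export
filter_consistent <- function(outputs, ci) {
  metrics <- c("agb", "gpp", "n10", "n60")
  miss <- setdiff(metrics, names(ci))
  if (length(miss)) {
    stop("missing intervals for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(outputs))
  for (m in metrics) {
    iv <- ci[[m]]
    if (length(iv) != 2 || anyNA(iv) || iv[1] > iv[2]) {
      stop("interval for ", m, " must be c(lower, upper)", call. = FALSE)
    }
    keep <- keep & outputs[[m]] >= iv[1] & outputs[[m]] <= iv[2]
  }
  which(keep)
}

#' Build the lightning-frequency sweep manifest
#'
#' Cross-product of strike frequencies and parameter sets: the same parameter
#' combinations are used for every frequency. Each row gets a deterministic
#' seed derived from the run id, so the manifest is pure (no RNG) and every
#' run is independently replayable.
#'
#' @param freqs Strike frequencies (CG fl km-2 yr-1); the full design uses
#'   the 15 integers 9 to 23.
#' @param paramsets Data frame of parameter sets (e.g. [sobol_sample()]).
#' @param base_seed Integer folded into each run's seed.
#' @return A data frame with `run_id`, `lam`, `param_id`, a `seed` column,
#'   and the parameter columns.
#' @export
lambda_sweep_manifest <- function(freqs = 9:23, paramsets,
                                  base_seed = 1L) {
  np <- nrow(paramsets)
  grid <- expand.grid(param_id = seq_len(np), lam_idx = seq_along(freqs))
  out <- data.frame(
    run_id = seq_len(nrow(grid)),
    lam = freqs[grid$lam_idx],
    param_id = grid$param_id
  )
  # deterministic per-run seed, kept below 2^31
  out$seed <- as.integer(
    (as.numeric(base_seed) * 7919 + out$run_id * 104729 +
       grid$lam_idx * 31337) %% 2147483647
  )
  params <- paramsets[grid$param_id, setdiff(names(paramsets), "lam"),
                      drop = FALSE]
  rownames(params) <- NULL
  cbind(out, params)
}

#' Run a lightning-frequency sweep
#'
#' Executes every row of a [lambda_sweep_manifest()] and collects the
#' equilibrium summaries. The manifest's `lam` overrides the parameter set's.
#'
#' @param manifest A sweep manifest.
#' @param config Base configuration (its `mode` decides CLLR/SSLR).
#' @param traits,forcing,binned Passed to [run_one()].
#' @param duration Optional duration override (years).
#' @return Data frame with one row per run: manifest keys plus `agb`, `gpp`,
#'   `n10`, `n30`, `n60`, `strikes_per_yr`, `kills_per_yr`,
#'   `kills_per_strike`, and per-tolerance-bin AGB (`agb_tolerant`,
#'   `agb_neutral`, `agb_intolerant`).
#' @export
run_sweep <- function(manifest, config, traits = NULL, forcing = NULL,
                      binned = NULL, duration = NULL) {
  config <- validate_config(config)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    mrow <- manifest[i, ]
    params <- as.list(mrow[setdiff(names(mrow),
                                   c("run_id", "param_id", "seed"))])
    run <- run_one(config, params = params, duration = duration,
                   seed = mrow$seed, traits = traits, forcing = forcing,
                   binned = binned)
    s <- run$summary
    bins <- tolerance_binning(s$species_agb, run$traits$delta_i)
    # strike/kill tallies over the second (near-equilibrium) half of the run
    late <- run$years$year > max(run$years$year) / 2
    data.frame(
      run_id = mrow$run_id, lam = mrow$lam, param_id = mrow$param_id,
      seed = mrow$seed, agb = s$agb, gpp = s$gpp, n10 = s$n10, n30 = s$n30,
      n60 = s$n60, strikes_per_yr = s$strikes_per_yr,
      kills_per_yr = s$kills_per_yr, kills_per_strike = s$kills_per_strike,
      strikes_late = sum(run$years$strikes[late]),
      kills_late = sum(run$years$kills[late]),
      agb_tolerant = bins["tolerant"], agb_neutral = bins["neutral"],
      agb_intolerant = bins["intolerant"]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a per-species quantity by lightning-tolerance bin
#'
#' Species are binned by their scaling factor `s = 1 / (1 + exp(-delta))`:
#' tolerant (`s < 0.5`), neutral (`s = 0.5`, i.e. `delta = 0`), intolerant
#' (`s > 0.5`). The bins partition the species set, so the bin sums add up to
#' the community total.
#'
#' @param values Named-or-not numeric vector of per-species values (AGB,
#'   N60, kills, ...).
#' @param deltas Per-species log-odds shifts, aligned with `values`.
#' @return Named numeric vector `c(tolerant, neutral, intolerant)`.
#' @export
tolerance_binning <- function(values, deltas) {
  stopifnot(length(values) == length(deltas))
  s <- scaling_factor(deltas)
  c(tolerant = sum(values[s < 0.5]),
    neutral = sum(values[s == 0.5]),
    intolerant = sum(values[s > 0.5]))
}

#' AGB response between two lightning frequencies
#'
#' For every parameter set present at both frequencies, computes the
#' equilibrium AGB difference (high minus low) in total and per tolerance
#' bin, plus the empirical CDF of the total difference across parameter sets
#' and the fraction of sets showing a decline in each bin.
#'
#' @param sweep Output of [run_sweep()].
#' @param lambda_low,lambda_high The two frequencies to compare.
#' @return A list with `diffs` (per parameter set), `cdf` (the ecdf of the
#'   total AGB difference), and `frac_decline` per bin.
#' @export
agb_delta_summary <- function(sweep, lambda_low = 9, lambda_high = 23) {
  lo <- sweep[sweep$lam == lambda_low, ]
  hi <- sweep[sweep$lam == lambda_high, ]
  if (!nrow(lo) || !nrow(hi)) {
    stop("both frequencies must be present in the sweep", call. = FALSE)
  }
  ids <- intersect(lo$param_id, hi$param_id)
  if (!setequal(lo$param_id, hi$param_id)) {
    stop("parameter sets differ between the two frequencies", call. = FALSE)
  }
  lo <- lo[match(ids, lo$param_id), ]
  hi <- hi[match(ids, hi$param_id), ]
  diffs <- data.frame(
    param_id = ids,
    agb = hi$agb - lo$agb,
    agb_tolerant = hi$agb_tolerant - lo$agb_tolerant,
    agb_neutral = hi$agb_neutral - lo$agb_neutral,
    agb_intolerant = hi$agb_intolerant - lo$agb_intolerant
  )
  list(
    diffs = diffs,
    cdf = ecdf(diffs$agb),
    frac_decline = c(
      total = mean(diffs$agb < 0),
      tolerant = mean(diffs$agb_tolerant < 0),
      neutral = mean(diffs$agb_neutral < 0),
      intolerant = mean(diffs$agb_intolerant < 0)
    )
  )
}

#' Linear transient lightning-frequency schedule
#'
#' Monthly lightning frequency that stays at `lam_start` until `t_start`
#' years, ramps linearly to `lam_end` at `t_end` years, and stays there.
#' Evaluated at month midpoints.
#'
#' @param lam_start,lam_end Frequencies (CG fl km-2 yr-1).
#' @param t_start,t_end Ramp start and end (years, `t_start < t_end`).
#' @param duration_yr Schedule length (years).
#' @return Numeric vector of length `12 * duration_yr`.
#' @export
transient_lambda <- function(lam_start, lam_end, t_start, t_end,
                             duration_yr) {
  if (t_start >= t_end) stop("t_start must precede t_end", call. = FALSE)
  if (lam_start < 0 || lam_end < 0) {
    stop("frequencies must be nonnegative", call. = FALSE)
  }
  t <- (seq_len(12 * duration_yr) - 0.5) / 12
  lam <- lam_start + (lam_end - lam_start) *
    pmin(1, pmax(0, (t - t_start) / (t_end - t_start)))
  lam
}
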