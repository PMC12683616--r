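#' Binned lightning-mortality observations
#'
#' Field observations of lightning mortality binned into 5 distance classes
#' and 3 DBH classes (15 cells). Each cell records the number of trees at
#' risk, the number observed killed outright, and the number damaged but
#' alive at the end of the observation period. Representative values used to
#' evaluate the risk model are geometric bin midpoints for distance (0 for a
#' direct-hit class starting at 0) and arithmetic midpoints for DBH.
#'
#' @param distance_lo,distance_hi Distance class edges (m), length 5 each
#'   when crossed with the 3 DBH classes (15 rows total).
#' @param dbh_lo,dbh_hi DBH class edges (cm).
#' @param n_trees,n_killed,n_damaged Per-cell counts.
#' @return A data frame of class `binned_mortality` with added
#'   `distance_rep` and `dbh_rep` columns.
#' @export
binned_mortality <- function(distance_lo, distance_hi, dbh_lo, dbh_hi,
                             n_trees, n_killed, n_damaged) {
  df <- data.frame(distance_lo, distance_hi, dbh_lo, dbh_hi,
                   n_trees, n_killed, n_damaged)
  if (nrow(df) != 15) {
    stop("binned mortality table must have exactly 15 cells ",
         "(5 distance x 3 DBH classes)", call. = FALSE)
  }
  if (length(unique(paste(df$distance_lo, df$distance_hi))) != 5 ||
      length(unique(paste(df$dbh_lo, df$dbh_hi))) != 3) {
    stop("expected 5 distance classes and 3 DBH classes", call. = FALSE)
  }
  if (any(df$n_killed + df$n_damaged > df$n_trees)) {
    stop("killed + damaged cannot exceed trees at risk", call. = FALSE)
  }
  df$distance_rep <- ifelse(df$distance_lo == 0,
                            ifelse(df$distance_hi == 0, 0, df$distance_hi / 2),
                            sqrt(df$distance_lo * df$distance_hi))
  df$dbh_rep <- (df$dbh_lo + df$dbh_hi) / 2
  class(df) <- c("binned_mortality", "data.frame")
  df
}

#' Read or write binned-mortality observations as CSV
#'
#' Columns: `distance_lo, distance_hi, dbh_lo, dbh_hi, n_trees, n_killed,
#' n_damaged`.
#' @param path File path.
#' @export
read_binned_mortality <- function(path) {
  df <- read.csv(path)
  binned_mortality(df$distance_lo, df$distance_hi, df$dbh_lo, df$dbh_hi,
                   df$n_trees, df$n_killed, df$n_damaged)
}

#' @rdname read_binned_mortality
#' @param binned A `binned_mortality` table.
#' @export
write_binned_mortality <- function(binned, path) {
  cols <- c("distance_lo", "distance_hi", "dbh_lo", "dbh_hi",
            "n_trees", "n_killed", "n_damaged")
  write.csv(as.data.frame(binned)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Effective observed mortalities
#'
#' Field counts separate outright kills from damaged-but-alive trees; the
#' fraction `d` of damaged trees assumed to eventually die converts them to
#' an effective observed mortality per cell: `O = n_killed + d * n_damaged`
#' (the same `d` applies to every cell; `O` may be non-integer).
#'
#' @param binned A [binned_mortality()] table.
#' @param d Proportion of damaged trees that die, in `[0, 1]`.
#' @return Numeric vector of `O` values, one per cell, in table order.
#' @export
effective_observed <- function(binned, d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0 || d > 1) {
    stop("d must be a single number in [0, 1]", call. = FALSE)
  }
  binned$n_killed + d * binned$n_damaged
}

#' Predicted mortalities per cell
#'
#' `M = n_trees * P(r_rep, dbh_rep)` under the community-level risk model
#' evaluated at the class-representative distance and DBH.
#'
#' @param binned A [binned_mortality()] table.
#' @param a,p_direct Community-level model parameters.
#' @return Numeric vector of `M` values, one per cell.
#' @export
predicted_mortalities <- function(binned, a, p_direct) {
  lp <- lightning_params(a = a, p_direct = p_direct)
  binned$n_trees * cllr_probability(binned$distance_rep, binned$dbh_rep, lp)
}

#' Scaled residual between predicted and observed mortalities
#'
#' `R = sum((M - O)^2 / O)` over the 15 cells. Cells with `O = 0` cannot be
#' scaled and are skipped with a warning.
#'
#' @param m,o Conformable numeric vectors of predicted and observed
#'   mortalities.
#' @export
scaled_residual <- function(m, o) {
  stopifnot(length(m) == length(o))
  zero <- o == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero observed mortality skipped")
  }
  sum((m[!zero] - o[!zero])^2 / o[!zero])
}

#' Bias and root-mean-square error of a fit
#'
#' `bias = mean(M - O)`; `rmse = sqrt(mean((M - O)^2))` over the cells.
#' @param m,o Conformable numeric vectors.
#' @return Named vector `c(bias, rmse)`.
#' @export
goodness_of_fit <- function(m, o) {
  stopifnot(length(m) == length(o))
  c(bias = mean(m - o), rmse = sqrt(mean((m - o)^2)))
}

#' Calibrate the community-level risk model by exhaustive grid search
#'
#' Minimizes the scaled residual over the full parameter lattice:
#' 101 values of `a` from -7 to -1 (step 0.06) crossed with 101 values of
#' `p_direct` from 0 to 1 (step 0.01). Exact ties are broken toward smaller
#' `|a|`, then smaller `p_direct`.
#'
#' @param binned A [binned_mortality()] table.
#' @param d Proportion of damaged trees that die, in `[0, 1]`.
#' @param keep_lattice If `TRUE`, attach the full residual lattice as a data
#'   frame (columns `a`, `p_direct`, `r`).
#' @return A list of class `cllr_calibration`: `a_star`, `p_direct_star`,
#'   `r_min`, `bias`, `rmse`, `d`, and optionally `lattice`.
#' @export
calibrate_cllr <- function(binned, d, keep_lattice = FALSE) {
  o <- effective_observed(binned, d)
  if (all(o == 0)) stop("all observed mortalities are zero", call. = FALSE)
  a_grid <- seq(-7, -1, by = 0.06)
  p_grid <- seq(0, 1, by = 0.01)
  keep <- o > 0
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with zero observed mortality skipped")
  }
  # per-cell probability factor 10^(a * (70/D) * (r/45)), vectorized over the
  # lattice: decay^a for cell-specific decay exponents
  expo <- (70 / binned$dbh_rep[keep]) * (binned$distance_rep[keep] / 45)
  n <- binned$n_trees[keep]
  ok <- o[keep]
  res <- matrix(NA_real_, length(a_grid), length(p_grid))
  for (i in seq_along(a_grid)) {
    pm <- 10^(a_grid[i] * expo)          # per-cell decay at this a
    for (j in seq_along(p_grid)) {
      m <- n * p_grid[j] * pm
      res[i, j] <- sum((m - ok)^2 / ok)
    }
  }
  rmin <- min(res)
  hits <- which(res == rmin, arr.ind = TRUE)
  ord <- order(abs(a_grid[hits[, 1]]), p_grid[hits[, 2]])
  best <- hits[ord[1], ]
  a_star <- a_grid[best[1]]
  p_star <- p_grid[best[2]]
  m_star <- predicted_mortalities(binned, a_star, p_star)
  gof <- goodness_of_fit(m_star[keep], ok)
  out <- list(a_star = a_star, p_direct_star = p_star, r_min = rmin,
              bias = unname(gof["bias"]), rmse = unname(gof["rmse"]), d = d)
  if (keep_lattice) {
    out$lattice <- data.frame(
      a = rep(a_grid, times = length(p_grid)),
      p_direct = rep(p_grid, each = length(a_grid)),
      r = as.vector(res)
    )
  }
  class(out) <- "cllr_calibration"
  out
}

#' @export
print.cllr_calibration <- function(x, ...) {
  cat(sprintf(
    "CLLR calibration (d = %.2f): a* = %.2f, P_direct* = %.2f\n", x$d,
    x$a_star, x$p_direct_star))
  cat(sprintf("  scaled residual = %.4g, bias = %.4g, rmse = %.4g\n",
              x$r_min, x$bias, x$rmse))
  invisible(x)
}
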