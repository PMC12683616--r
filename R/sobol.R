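#' Sobol' low-discrepancy sequence
#'
#' Standard (unscrambled) Sobol' sequence in the unit hypercube, built from
#' primitive-polynomial direction numbers (the widely used Joe-Kuo set) with
#' Gray-code ordering. The first point is the origin. Deterministic: the
#' sequence for a given dimension is always the same, and shorter runs are
#' prefixes of longer ones.
#'
#' @param n Number of points (>= 1).
#' @param dim Dimension (1 to 10).
#' @return An `n` x `dim` matrix with entries in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (dim < 1 || dim > 10) stop("dim must be in 1..10", call. = FALSE)
  nbits <- 31L
  maxcol <- max(1L, ceiling(log2(max(n, 2))) + 1L)
  # primitive polynomial degree s, coefficient a, and initial direction
  # numbers m for dimensions 2..10
  poly <- list(
    list(s = 1L, a = 0L, m = c(1L)),
    list(s = 2L, a = 1L, m = c(1L, 3L)),
    list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
    list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
    list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
    list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
    list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
    list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
    list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
  )
  ncols <- max(maxcol, nbits)
  v <- matrix(0L, dim, ncols)
  v[1, ] <- bitwShiftL(1L, nbits - seq_len(ncols))  # van der Corput, base 2
  if (dim > 1) {
    for (j in 2:dim) {
      p <- poly[[j - 1]]
      s <- p$s
      m <- integer(ncols)
      m[seq_len(s)] <- p$m
      if (ncols > s) {
        for (k in (s + 1):ncols) {
          newm <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
          for (q in seq_len(s - 1)) {
            abit <- bitwAnd(bitwShiftR(p$a, s - 1L - q), 1L)
            if (abit == 1L) newm <- bitwXor(newm, bitwShiftL(m[k - q], q))
          }
          m[k] <- newm
        }
      }
      v[j, ] <- bitwShiftL(m, nbits - seq_len(ncols))
    }
  }
  x <- integer(dim)
  out <- matrix(0, n, dim)
  if (n >= 2) {
    for (i in 2:n) {
      c0 <- 1L
      ii <- i - 2L  # Gray-code step index
      while (bitwAnd(ii, 1L) == 1L) {
        ii <- bitwShiftR(ii, 1L)
        c0 <- c0 + 1L
      }
      x <- bitwXor(x, v[, c0])
      out[i, ] <- x / 2^nbits
    }
  }
  out
}

#' Parameter ranges for the uncertainty analysis
#'
#' Default ranges of the six uncertain parameters: apparent quantum yield
#' `phi` (0.04, 0.09) mol C (mol photon)-1, maximal baseline mortality `m0`
#' (0, 0.03) yr-1, belowground allocation fraction `f_below` (0.1, 0.5),
#' allocation angle `theta` (pi/12, 5 pi/12) rad, lightning frequency `lam`
#' (10.9, 14.5) CG fl km-2 yr-1 (its current-day 95% confidence interval),
#' and the damaged-tree death fraction `d` (0, 1).
#'
#' @param ... Named length-2 numeric vectors overriding individual ranges.
#' @return A named list of `c(lower, upper)` ranges.
#' @export
param_ranges <- function(...) {
  r <- list(
    phi = c(0.04, 0.09), m0 = c(0, 0.03), f_below = c(0.1, 0.5),
    theta = c(pi / 12, 5 * pi / 12), lam = c(10.9, 14.5), d = c(0, 1)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(r)) stop("unknown parameter: ", nm, call. = FALSE)
    r[[nm]] <- over[[nm]]
  }
  r
}

#' Sobol' sample of uncertainty-analysis parameter sets
#'
#' The first `n` points of the Sobol' sequence, scaled affinely to the
#' parameter ranges, with the derived allocation fractions `f_wood` and
#' `f_canopy` appended (see [allocation_from_cylindrical()]). Deterministic
#' and prefix-stable.
#'
#' @param n Number of parameter sets.
#' @param ranges A [param_ranges()] list.
#' @return A data frame with one row per parameter set.
#' @export
sobol_sample <- function(n, ranges = param_ranges()) {
  u <- sobol_sequence(n, length(ranges))
  out <- as.data.frame(mapply(function(col, rg) {
    rg[1] + u[, col] * (rg[2] - rg[1])
  }, seq_along(ranges), ranges, SIMPLIFY = FALSE))
  names(out) <- names(ranges)
  if (all(c("f_below", "theta") %in% names(out))) {
    fc <- allocation_from_cylindrical(out$f_below, out$theta)
    out$f_wood <- fc$f_wood
    out$f_canopy <- fc$f_canopy
  }
  out
}
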