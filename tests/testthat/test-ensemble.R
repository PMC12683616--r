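test_that("Sobol' sequence matches the reference low-discrepancy points", {
  # first eight points of the standard 6-d Joe-Kuo sequence (reference
  # values frozen from an independent quasi-Monte-Carlo implementation)
  expected <- matrix(c(
    0,     0,     0,     0,     0,     0,
    0.5,   0.5,   0.5,   0.5,   0.5,   0.5,
    0.75,  0.25,  0.25,  0.25,  0.75,  0.75,
    0.25,  0.75,  0.75,  0.75,  0.25,  0.25,
    0.375, 0.375, 0.625, 0.875, 0.375, 0.125,
    0.875, 0.875, 0.125, 0.375, 0.875, 0.625,
    0.625, 0.125, 0.875, 0.625, 0.625, 0.875,
    0.125, 0.625, 0.375, 0.125, 0.125, 0.375
  ), nrow = 8, byrow = TRUE)
  expect_equal(sobol_sequence(8, 6), expected, tolerance = 1e-12)
})

test_that("Sobol' samples stay in range and are prefix-stable", {
  rg <- param_ranges()
  s <- sobol_sample(200, rg)
  for (nm in names(rg)) {
    expect_true(all(s[[nm]] >= rg[[nm]][1] & s[[nm]] <= rg[[nm]][2]))
  }
  expect_equal(sobol_sequence(20, 6), sobol_sequence(1000, 6)[1:20, ])
  # derived fractions respect the sum constraint
  expect_equal(s$f_wood + s$f_canopy + s$f_below, rep(1, 200))
  # default ranges
  expect_equal(rg$phi, c(0.04, 0.09))
  expect_equal(rg$m0, c(0, 0.03))
  expect_equal(rg$f_below, c(0.1, 0.5))
  expect_equal(rg$theta, c(pi / 12, 5 * pi / 12))
  expect_equal(rg$lam, c(10.9, 14.5))
  expect_equal(rg$d, c(0, 1))
})

test_that("cylindrical allocation keeps the fraction constraint exactly", {
  a <- allocation_from_cylindrical(0.5, pi / 4)
  expect_equal(a$f_wood, 0.25)
  expect_equal(a$f_canopy, 0.25)
  b <- allocation_from_cylindrical(0.1, pi / 3)
  expect_equal(b$f_canopy / b$f_wood, tan(pi / 3))
  set.seed(3)
  fb <- runif(50, 0, 0.9); th <- runif(50, 0.01, pi / 2 - 0.01)
  cc <- allocation_from_cylindrical(fb, th)
  expect_equal(cc$f_wood + cc$f_canopy + fb, rep(1, 50), tolerance = 1e-15)
  expect_error(allocation_from_cylindrical(0.3, 0), "theta")
  expect_error(allocation_from_cylindrical(0.3, pi / 2), "theta")
  expect_error(allocation_from_cylindrical(1, pi / 4), "f_below")
})

test_that("sweep manifest is the pure cross-product with replayable seeds", {
  ps <- sobol_sample(7)
  m1 <- lambda_sweep_manifest(9, ps[1, , drop = FALSE])
  expect_identical(nrow(m1), 1L)
  m <- lambda_sweep_manifest(c(9, 16, 23), ps)
  expect_identical(nrow(m), 21L)
  # identical parameter sets in every frequency group
  for (col in c("phi", "m0", "f_below", "theta", "d")) {
    grp <- split(m[[col]], m$lam)
    expect_equal(grp[[1]], grp[[2]])
    expect_equal(grp[[1]], grp[[3]])
    expect_equal(grp[[1]], ps[[col]])
  }
  expect_true(all(m$seed >= 0 & m$seed < 2^31))
  # pure: no RNG consumed, rebuilding gives the identical manifest
  expect_identical(m, lambda_sweep_manifest(c(9, 16, 23), ps))
})

test_that("observational filtering keeps runs inside all four intervals", {
  set.seed(11)
  out <- data.frame(agb = runif(40, 200, 400), gpp = runif(40, 20, 40),
                    n10 = runif(40, 300, 700), n60 = runif(40, 10, 60))
  inf_ci <- list(agb = c(-Inf, Inf), gpp = c(-Inf, Inf),
                 n10 = c(-Inf, Inf), n60 = c(-Inf, Inf))
  expect_identical(filter_consistent(out, inf_ci), seq_len(40))
  none_ci <- inf_ci; none_ci$agb <- c(0, 1)
  expect_identical(length(filter_consistent(out, none_ci)), 0L)
  ci <- list(agb = c(250, 350), gpp = c(25, 35), n10 = c(350, 650),
             n60 = c(15, 50))
  oracle <- which(out$agb >= 250 & out$agb <= 350 & out$gpp >= 25 &
                    out$gpp <= 35 & out$n10 >= 350 & out$n10 <= 650 &
                    out$n60 >= 15 & out$n60 <= 50)
  got <- filter_consistent(out, ci)
  expect_identical(got, oracle)
  # idempotent
  expect_identical(filter_consistent(out[got, , drop = FALSE], ci),
                   seq_along(got))
  expect_error(filter_consistent(out, ci[1:3]), "missing")
  bad <- ci; bad$gpp <- c(10, 5)
  expect_error(filter_consistent(out, bad), "lower, upper")
})

test_that("tolerance binning partitions species by scaling factor", {
  expect_equal(tolerance_binning(c(1, 2, 3), c(0, 0, 0)),
               c(tolerant = 0, neutral = 6, intolerant = 0))
  got <- tolerance_binning(c(10, 5, 3), c(-2, 0, 1))
  expect_equal(got, c(tolerant = 10, neutral = 5, intolerant = 3))
  set.seed(13)
  v <- runif(30); d <- rnorm(30)
  expect_equal(sum(tolerance_binning(v, d)), sum(v)) # conservation
})

test_that("AGB difference summary counts declines correctly", {
  ps <- sobol_sample(6)
  base <- data.frame(param_id = 1:6, agb = c(300, 310, 290, 305, 295, 300),
                     agb_tolerant = 100, agb_neutral = 100,
                     agb_intolerant = 100)
  lo <- cbind(lam = 9, base)
  hi <- cbind(lam = 23, base)
  hi$agb <- base$agb + c(-20, -5, 0, 3, -1, -10)
  hi$agb_intolerant <- 100 - c(20, 5, 0, -3, 1, 10)
  sw <- rbind(lo, hi)
  s <- agb_delta_summary(sw, 9, 23)
  expect_equal(s$diffs$agb, c(-20, -5, 0, 3, -1, -10))
  expect_equal(unname(s$frac_decline["total"]), 4 / 6)
  expect_equal(unname(s$frac_decline["intolerant"]), 4 / 6)
  expect_equal(unname(s$frac_decline["tolerant"]), 0)
  # CDF properties
  ks <- knots(s$cdf)
  expect_true(all(diff(s$cdf(ks)) > 0))
  expect_equal(s$cdf(min(ks) - 1), 0)
  expect_equal(s$cdf(max(ks)), 1)
  # identical outputs: degenerate CDF at zero
  s0 <- agb_delta_summary(rbind(lo, within(lo, lam <- 23)), 9, 23)
  expect_true(all(s0$diffs$agb == 0))
  bad <- rbind(lo, hi[hi$param_id != 3, ])
  expect_error(agb_delta_summary(bad, 9, 23), "differ")
})

test_that("transient schedule interpolates linearly between frequencies", {
  const <- transient_lambda(12, 12, 10, 20, 30)
  expect_equal(const, rep(12, 360))
  ramp <- transient_lambda(9, 23, 100, 200, 300)
  expect_equal(ramp[1], 9)
  expect_equal(ramp[3600], 23)
  # midpoint of the ramp
  mid <- ramp[12 * 150]
  expect_equal(mid, 16, tolerance = 0.01)
  # monthly discretization integrates to the trapezoid value
  t_edges <- seq(0, 300, by = 1 / 12)
  lam_f <- function(t) 9 + 14 * pmin(1, pmax(0, (t - 100) / 100))
  trap <- sum((lam_f(t_edges[-1]) + lam_f(t_edges[-length(t_edges)])) / 2) / 12
  expect_equal(sum(ramp) / 12, trap, tolerance = trap * 1e-3)
  expect_error(transient_lambda(9, 23, 50, 50, 100), "precede")
  expect_error(transient_lambda(-1, 23, 0, 10, 20), "nonnegative")
})
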