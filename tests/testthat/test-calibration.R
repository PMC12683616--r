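make_binned <- function(killed, damaged, n = 100) {
  binned_mortality(
    distance_lo = rep(c(0, 0, 5, 10, 15), 3),
    distance_hi = rep(c(0, 5, 10, 15, 25), 3),
    dbh_lo = rep(c(10, 30, 60), each = 5),
    dbh_hi = rep(c(30, 60, 100), each = 5),
    n_trees = rep(n, 15),
    n_killed = rep_len(killed, 15),
    n_damaged = rep_len(damaged, 15)
  )
}

test_that("effective observed mortality blends kills and damaged deaths", {
  b <- make_binned(4, 10)
  expect_equal(effective_observed(b, 0), rep(4, 15))
  expect_equal(effective_observed(b, 1), rep(14, 15))
  expect_equal(effective_observed(b, 0.3), rep(7, 15))
  expect_error(effective_observed(b, -0.1), "0, 1")
  expect_error(effective_observed(b, 1.5), "0, 1")
})

test_that("predicted mortalities evaluate the risk model cell by cell", {
  b <- make_binned(4, 10)
  expect_equal(predicted_mortalities(b, -3, 0), rep(0, 15))
  # direct-hit cells: M = n * p_direct regardless of a
  m <- predicted_mortalities(b, -4.3, 0.6)
  expect_equal(m[b$distance_rep == 0], rep(60, 3))
  # element-wise oracle over all 15 cells
  oracle <- b$n_trees * 0.6 * 10^(-4.3 * (70 / b$dbh_rep) * (b$distance_rep / 45))
  expect_equal(m, oracle, tolerance = 1e-14)
})

test_that("scaled residual sums (M-O)^2/O and skips empty cells", {
  o <- rep(4, 15)
  expect_equal(scaled_residual(o, o), 0)
  m <- o; m[7] <- 6
  expect_equal(scaled_residual(m, o), 1.0) # (2)^2 / 4
  set.seed(8)
  mm <- runif(15, 1, 20); oo <- runif(15, 1, 20)
  acc <- 0
  for (i in 1:15) acc <- acc + (mm[i] - oo[i])^2 / oo[i]
  expect_equal(scaled_residual(mm, oo), acc)
  # linear scaling: R(cM, cO) = c R(M, O)
  expect_equal(scaled_residual(3 * mm, 3 * oo), 3 * scaled_residual(mm, oo))
  oz <- oo; oz[3] <- 0
  expect_warning(r <- scaled_residual(mm, oz), "skipped")
  expect_equal(r, sum((mm[-3] - oz[-3])^2 / oz[-3]))
})

test_that("bias and rmse match their definitions", {
  o <- rep(5, 15)
  expect_equal(goodness_of_fit(o, o), c(bias = 0, rmse = 0))
  expect_equal(goodness_of_fit(o + 1, o), c(bias = 1, rmse = 1))
  set.seed(9)
  mm <- runif(15); oo <- runif(15)
  expect_equal(goodness_of_fit(mm, oo),
               c(bias = mean(mm - oo), rmse = sqrt(mean((mm - oo)^2))))
})

test_that("grid search recovers generating parameters", {
  # noise-free data from lattice parameters: exact identity recovery
  b <- gen_binned_mortality(a = -3.04, p_direct = 0.62, d_true = 0.35,
                            n_per_cell = 1000, noise = FALSE)
  fit <- calibrate_cllr(b, d = 0.35)
  expect_equal(fit$a_star, -3.04)
  expect_equal(fit$p_direct_star, 0.62)
  expect_lt(fit$r_min, 1e-20)
  expect_lt(abs(fit$bias), 1e-10)

  # off-lattice generator: recovered within one lattice step per parameter
  b2 <- gen_binned_mortality(a = -3.00, p_direct = 0.615, d_true = 0.5,
                             n_per_cell = 5000, noise = FALSE)
  fit2 <- calibrate_cllr(b2, d = 0.5)
  expect_lte(abs(fit2$a_star - (-3.00)), 0.06 + 1e-9)
  expect_lte(abs(fit2$p_direct_star - 0.615), 0.01 + 1e-9)

  expect_error(calibrate_cllr(make_binned(0, 0), d = 0), "zero")
})

test_that("lattice respects the published search ranges and resolution", {
  b <- gen_binned_mortality(noise = FALSE)
  fit <- calibrate_cllr(b, d = 0.35, keep_lattice = TRUE)
  a_vals <- sort(unique(fit$lattice$a))
  p_vals <- sort(unique(fit$lattice$p_direct))
  expect_identical(length(a_vals), 101L)
  expect_identical(length(p_vals), 101L)
  expect_equal(range(a_vals), c(-7, -1))
  expect_equal(range(p_vals), c(0, 1))
  expect_equal(unique(round(diff(a_vals), 10)), 0.06)
  expect_equal(unique(round(diff(p_vals), 10)), 0.01)
})

test_that("raising d weakly raises the fitted direct-hit probability", {
  b <- gen_binned_mortality(a = -2.5, p_direct = 0.5, d_true = 0.5,
                            n_per_cell = 5000, noise = FALSE)
  fits <- vapply(c(0.2, 0.5, 0.8), function(d) {
    calibrate_cllr(b, d)$p_direct_star
  }, numeric(1))
  expect_true(all(diff(fits) >= 0))
})
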