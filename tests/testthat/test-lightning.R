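test_that("per-voxel strike probability converts units correctly", {
  expect_equal(strike_probability(12), 1e-6)
  expect_equal(strike_probability(0), 0)
  expect_error(strike_probability(2e7), "exceeds 1")
})

test_that("strike sampling matches the configured frequency", {
  g <- forest_grid(100, 100)
  lp0 <- lightning_params(lam = 0)
  set.seed(5)
  for (i in 1:20) expect_identical(nrow(sample_strikes(g, lp0)), 0L)

  # inflated frequency so a short run carries signal: p = 1e-3 per voxel-month
  lp <- lightning_params(lam = 12000)
  set.seed(6)
  n <- sum(vapply(1:200, function(i) nrow(sample_strikes(g, lp)), integer(1)))
  expected <- 200 * 1e4 * 1e-3
  expect_lt(abs(n - expected), 4 * sqrt(expected))
})

test_that("target selection picks the tallest tree with deterministic ties", {
  tr <- tiny_traits(3)
  lp <- lightning_params(search_radius = 15)
  g <- forest_grid(40, 40)
  expect_null(select_target(g, c(20, 20), lp))

  # a single tree in range is targeted regardless of height
  g1 <- place_tree(g, tr[1, ], 22, 20, dbh = 1)
  expect_identical(select_target(g1, c(20, 20), lp)$tree_id, 1L)

  # tallest wins; out-of-range trees are ignored
  g2 <- place_tree(g1, tr[2, ], 25, 25, dbh = 50)
  g2 <- place_tree(g2, tr[3, ], 3, 39, dbh = 80) # far away
  expect_identical(select_target(g2, c(20, 20), lp)$tree_id, 2L)

  # exact tie: exhaustive-scan oracle with (x, y) lexicographic tie-break
  g3 <- place_tree(g, tr[1, ], 24, 18, dbh = 30)
  g3 <- place_tree(g3, tr[1, ], 18, 24, dbh = 30)
  live <- g3$trees[g3$trees$alive, ]
  d <- mapply(function(x, y) voxel_distance(g3, c(20, 20), c(x, y)),
              live$x, live$y)
  inr <- live[d <= 15, ]
  inr <- inr[inr$height == max(inr$height), ]
  oracle <- inr[order(inr$x, inr$y), ][1, ]
  expect_identical(select_target(g3, c(20, 20), lp)$tree_id, oracle$tree_id)
})

test_that("community-level risk decays with distance and grows with size", {
  lp <- lightning_params(a = -1, p_direct = 0.8)
  expect_equal(cllr_probability(0, 5, lp), 0.8)      # direct hit, any size
  expect_equal(cllr_probability(0, 300, lp), 0.8)
  expect_equal(cllr_probability(45, 70, lp), 0.08)   # one decade of decay
  lp3 <- lightning_params(a = -3, p_direct = 0.8)
  expect_equal(cllr_probability(22.5, 35, lp3), 8e-4)
  expect_error(cllr_probability(5, 0, lp), "positive")
  expect_error(cllr_probability(-1, 10, lp), "nonnegative")
})

test_that("species shift moves the base-10 log-odds as printed", {
  expect_equal(sslr_probability(0.37, 0), 0.37)
  expect_equal(sslr_probability(0.25, log10(3)), 0.5)
  expect_equal(sslr_probability(0.5, -50), 0, tolerance = 1e-12)
  expect_equal(sslr_probability(0, 5), 0)   # boundary handling
  expect_equal(sslr_probability(1, -5), 1)
  # monotone in both arguments
  p <- sslr_probability(seq(0.01, 0.99, by = 0.01), 0.4)
  expect_true(all(diff(p) > 0))
  q <- sslr_probability(0.3, seq(-3, 3, by = 0.1))
  expect_true(all(diff(q) > 0))
})

test_that("tolerance scaling factor is the logistic of the shift", {
  expect_identical(scaling_factor(0), 0.5)
  expect_equal(scaling_factor(log(3)), 0.75)
  expect_equal(scaling_factor(1e4), 1)
  expect_equal(scaling_factor(-1e4), 0)
})

test_that("strikes kill by independent Bernoulli draws around the target", {
  lp <- lightning_params(a = -2, p_direct = 1, mode = "CLLR", r_max = 20)
  g <- forest_grid(30, 30)
  out0 <- apply_strike(g, c(15, 15), lp)
  expect_identical(nrow(out0$kills), 0L) # treeless

  # a certain direct hit always kills the target
  tr <- tiny_traits(3)
  g1 <- small_stand(traits = tr)
  set.seed(9)
  for (i in 1:10) {
    out <- apply_strike(g1, c(15, 15), lp)
    expect_true(out$target$tree_id %in% out$kills$tree_id)
  }

  # mean kills per strike matches the analytic expectation
  lp2 <- lightning_params(a = -1.5, p_direct = 0.7, mode = "CLLR", r_max = 25)
  target <- select_target(g1, c(15, 15), lp2)
  live <- g1$trees[g1$trees$alive, ]
  r <- mapply(function(x, y) {
    voxel_distance(g1, c(target$x, target$y), c(x, y))
  }, live$x, live$y)
  p <- cllr_probability(r[r <= 25], live$dbh[r <= 25], lp2)
  mu <- sum(p)
  sdev <- sqrt(sum(p * (1 - p)))
  set.seed(10)
  nrep <- 3000
  kills <- vapply(seq_len(nrep), function(i) {
    nrow(apply_strike(g1, c(15, 15), lp2)$kills)
  }, integer(1))
  expect_lt(abs(mean(kills) - mu), 3 * sdev / sqrt(nrep))
})

test_that("SSLR with zero shifts reproduces CLLR under a shared RNG stream", {
  tr <- tiny_traits(3, delta_i = 0)
  g <- small_stand(traits = tr)
  lpc <- lightning_params(a = -2, p_direct = 0.9, mode = "CLLR")
  lps <- lightning_params(a = -2, p_direct = 0.9, mode = "SSLR")
  for (s in 1:5) {
    set.seed(s)
    kc <- apply_strike(g, c(12, 12), lpc)$kills
    set.seed(s)
    ks <- apply_strike(g, c(12, 12), lps, traits = tr)$kills
    expect_identical(kc, ks)
  }
})

test_that("lightning parameter validation", {
  expect_error(lightning_params(lam = -1), "nonnegative")
  expect_error(lightning_params(p_direct = 1.2), "0, 1")
  expect_error(lightning_params(d = -0.1), "0, 1")
  expect_error(lightning_params(mode = "both"))
})
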