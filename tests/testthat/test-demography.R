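test_that("background mortality scales with wood specific gravity", {
  expect_equal(background_probability(0.5, mortality_params(m0 = 0)), 0)
  # at the softest configured wood the monthly rate is m0 / 12
  m <- mortality_params(m0 = 0.024, wsg_ref = 0.3)
  expect_equal(background_probability(0.3, m), 0.002)
  p <- background_probability(seq(0.3, 1, by = 0.05), m)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 0.002))
})

test_that("carbon starvation sets stage-1 probability to one", {
  tr <- tiny_traits(lma = 100) # leaf lifespan 12 months
  g <- place_tree(forest_grid(5, 5), tr, 1, 1, dbh = 5)
  tree <- g$trees[1, ]
  m <- mortality_params(m0 = 0.012)
  expect_lt(stage1_probability(tree, m, tr), 0.01)
  tree$npp_negative_months <- 13L
  expect_equal(stage1_probability(tree, m, tr), 1)
  tree$npp_negative_months <- 12L # not exceeded yet
  expect_lt(stage1_probability(tree, m, tr), 0.01)
  expect_equal(stage1_probability(tree, mortality_params(m0 = 0), tr), 0)
})

test_that("treefall probability rises from zero and saturates with height", {
  m <- mortality_params()
  expect_equal(treefall_probability(0, m), 0)
  h <- seq(0, 60, by = 0.5)
  p <- treefall_probability(h, m)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= m$treefall_max_prob))
  expect_equal(treefall_probability(m$treefall_height_scale, m),
               m$treefall_max_prob / 2)
})

test_that("empirical treefall frequency matches the configured probability", {
  tr <- tiny_traits(allom_a = 45)
  g <- place_tree(forest_grid(8, 8), tr, 4, 4, dbh = 200) # ~40 m tall
  m <- mortality_params(treefall_max_prob = 0.4)
  p_true <- treefall_probability(g$trees$height[1], m)
  set.seed(12)
  n <- 4000
  falls <- 0
  for (i in seq_len(n)) {
    out <- stage2_treefall(g, g$trees$tree_id[1], m)
    falls <- falls + (nrow(out$deaths) > 0)
  }
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(falls / n - p_true), 3 * se)
})

test_that("secondary treefall follows the fall corridor deterministically", {
  tr <- tiny_traits(allom_a = 45)
  g <- forest_grid(40, 40)
  g <- place_tree(g, tr, 20, 20, dbh = 200) # faller: tall, wide crown
  # ring of short trees at distance 6
  short <- tiny_traits(allom_a = 8)
  ring <- cbind(x = 20 + round(6 * cos(seq(0, 2 * pi, length.out = 13)[-13])),
                y = 20 + round(6 * sin(seq(0, 2 * pi, length.out = 13)[-13])))
  ring <- unique(ring)
  for (i in seq_len(nrow(ring))) {
    g <- place_tree(g, short, ring[i, 1], ring[i, 2], dbh = 2)
  }
  m <- mortality_params(treefall_max_prob = 1) # force the fall
  set.seed(31)
  out <- stage2_treefall(g, 1L, m)
  # replay the same RNG stream to predict the corridor
  set.seed(31)
  runif(1) # the fall draw
  az <- runif(1, 0, 2 * pi)
  faller <- g$trees[1, ]
  expected <- g$trees$tree_id[-1][vapply(seq_len(nrow(ring)), function(i) {
    dx <- ring[i, 1] - 20; dy <- ring[i, 2] - 20
    proj <- dx * cos(az) + dy * sin(az)
    perp <- abs(-dx * sin(az) + dy * cos(az))
    proj > 0 && proj <= faller$height && perp <= faller$crown_radius &&
      g$trees$height[i + 1] < faller$height / 2
  }, logical(1))]
  got <- out$deaths$tree_id[out$deaths$cause == "treefall_secondary"]
  expect_setequal(got, expected)
  expect_true(1L %in% out$deaths$tree_id[out$deaths$cause == "treefall_primary"])
})

test_that("recruitment fills empty lit voxels at DBH 1 cm", {
  tr <- tiny_traits()
  phys <- physiology_params()
  g <- forest_grid(5, 5)
  bright <- rep(1000, 25)

  # empty, fully lit, one species: every voxel recruits at 1 cm
  set.seed(2)
  g1 <- recruit(g, bright, tr, phys)
  expect_identical(sum(g1$trees$alive), 25L)
  expect_true(all(g1$trees$dbh == 1))

  # fully occupied grid: no recruits
  g2 <- recruit(g1, bright, tr, phys)
  expect_identical(nrow(g2$trees), nrow(g1$trees))

  # dark grid: nothing establishes
  g3 <- recruit(g, rep(0, 25), tr, phys)
  expect_identical(nrow(g3$trees), 0L)
})

test_that("recruit species draws replay the uniform RNG stream", {
  tr3 <- tiny_traits(3)
  phys <- physiology_params()
  mort <- mortality_params()
  g <- forest_grid(4, 4)
  set.seed(77)
  g1 <- recruit(g, rep(1000, 16), tr3, phys, mort)
  # independent replay: equal seedbank weights, inverse-CDF over 3 species
  set.seed(77)
  expected <- vapply(1:16, function(i) {
    findInterval(runif(1), cumsum(rep(1, 3)) / 3) + 1L
  }, integer(1))
  expect_identical(g1$trees$species_id, tr3$species_id[expected])
})
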