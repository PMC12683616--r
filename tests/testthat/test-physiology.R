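test_that("DBH-height allometry follows the generalized Michaelis-Menten form", {
  tr <- list(allom_a = 40, allom_b = 1, allom_k = 20)
  expect_equal(allometric_height(60, tr), 30.0)
  # half-saturation: dbh = allom_k^(1/allom_b) gives half the asymptote
  tr2 <- list(allom_a = 35, allom_b = 0.8, allom_k = 12)
  expect_equal(allometric_height(12^(1 / 0.8), tr2), 17.5)
  # asymptote
  expect_lt(allometric_height(1e8, tr2), 35)
  expect_gt(allometric_height(1e8, tr2), 34.99)
  # monotone increasing
  h <- allometric_height(seq(1, 200, by = 0.5), tr2)
  expect_true(all(diff(h) > 0))
  expect_error(allometric_height(0, tr), "positive")
  expect_error(allometric_height(-2, tr), "positive")
})

test_that("light field obeys the Beer-Lambert law", {
  phys <- physiology_params()
  g <- forest_grid(20, 20)
  lf <- light_field(g, phys)
  expect_true(all(lf$ground_frac == 1))
  expect_true(all(lf$frac_above == 1))

  # single one-layer crown of known leaf area on one column
  tr <- tiny_traits()
  g1 <- place_tree(g, tr, 5, 5, dbh = 1, leaf_area = 2)
  g1$trees$crown_depth <- 1L
  lf1 <- light_field(g1, phys)
  col <- 5 + 5 * 20 + 1
  expect_equal(lf1$ground_frac[col], exp(-phys$k_ext * 2))

  # a second, taller crown spanning the same column: transmissions compose
  g2 <- place_tree(g1, tr, 6, 5, dbh = 40, leaf_area = 10)
  g2$trees$crown_depth <- 1L
  g2$trees$crown_radius[2] <- 1.0 # covers 5 columns incl. (5, 5)
  lf2 <- light_field(g2, phys)
  l2 <- 10 / 5 # uniform leaf area density per crown column
  expect_equal(lf2$ground_frac[col], exp(-phys$k_ext * (2 + l2)))

  # energy balance: total absorbed cannot exceed incident
  absorbed <- sum(lf2$afrac_leaf * g2$trees$leaf_area)
  expect_lte(absorbed, n_ground_voxels(g2))
  expect_true(all(lf2$afrac_leaf >= 0))
})

test_that("monthly NPP decomposes as GPP minus respiration terms", {
  tr <- tiny_traits()
  g <- place_tree(forest_grid(10, 10), tr, 2, 2, dbh = 20, leaf_area = 30)
  tree <- g$trees[1, ]
  phys <- physiology_params()
  fm <- flat_month()

  # dark limit: no photosynthesis, maintenance respiration only
  dark <- monthly_npp(tree, rep(0, 48), fm, phys, tr)
  expect_equal(dark$gpp, 0)
  expect_lt(dark$npp, 0)
  expect_equal(dark$r_growth, 0)

  # optically thin limit: absorbed flux low, GPP linear in light
  thin1 <- monthly_npp(tree, rep(1, 48) * (fm$ppfd > 0), fm, phys, tr)
  thin2 <- monthly_npp(tree, rep(2, 48) * (fm$ppfd > 0), fm, phys, tr)
  expect_equal(thin2$gpp, 2 * thin1$gpp, tolerance = 1e-10)

  # slot-by-slot independent re-integration
  dp <- lightgap:::derive_physiology(tr, phys)
  absorbed <- 300 * sin(pi * (1:48) / 48) # arbitrary per-slot profile
  got <- monthly_npp(tree, absorbed, fm, phys, tr)
  ftv <- pmin(2, 1.8^((fm$temp - 25) / 10))
  ftr <- 2^((fm$temp - 25) / 10)
  ac <- 0.25 * dp$vcmax25 * ftv / (1 + sqrt(pmax(fm$vpd, 0.05)) / phys$g1)
  aj <- pmin(phys$phi * absorbed, 0.2 * dp$jmax25 * ftv)
  a <- pmax(0, pmin(ac, aj)) * (absorbed > 0)
  fac <- 1800 * 30.4375 * 12.011e-9
  gpp <- sum(a) * tree$leaf_area * fac
  r_leaf <- sum(dp$rd25 * ftr) * tree$leaf_area * fac
  sv <- lightgap:::stem_volume(tree$dbh, tr, phys)
  sapfrac <- min(1, 0.2 + 2 / tree$dbh)
  r_stem <- phys$rstem_coef * sv * sapfrac * mean(ftr) *
    30.4375 * 86400 * 12.011e-9
  r_below <- phys$rbelow_frac * (r_leaf + r_stem)
  rm <- r_leaf + r_stem + r_below
  rg <- phys$rg_frac * max(0, gpp - rm)
  expect_equal(got$gpp, gpp, tolerance = 1e-12)
  expect_equal(got$r_leaf, r_leaf, tolerance = 1e-12)
  expect_equal(got$r_stem, r_stem, tolerance = 1e-12)
  expect_equal(got$npp, gpp - rm - rg, tolerance = 1e-12)

  expect_error(monthly_npp(tree, rep(1, 47), fm[1:47, ], phys, tr), "48")
})

test_that("GPP is nondecreasing in incident PPFD", {
  tr <- tiny_traits()
  g <- place_tree(forest_grid(10, 10), tr, 2, 2, dbh = 20, leaf_area = 30)
  tree <- g$trees[1, ]
  phys <- physiology_params()
  fm <- flat_month()
  gpps <- vapply(seq(0, 2000, by = 100), function(i) {
    monthly_npp(tree, rep(i, 48), fm, phys, tr)$gpp
  }, numeric(1))
  expect_true(all(diff(gpps) >= 0))
})

test_that("allocation conserves NPP and respects the size threshold", {
  phys <- physiology_params()
  # max_dbh 120, threshold at half: 60 cm
  tr <- tiny_traits(max_dbh = 120)
  g <- place_tree(forest_grid(10, 10), tr, 2, 2, dbh = 20)
  tree <- g$trees[1, ]

  t0 <- allocate_and_grow(tree, 0, phys, tr)
  expect_identical(t0$npp_negative_months, 1L)
  expect_identical(t0$dbh, tree$dbh)

  t1 <- allocate_and_grow(tree, 5, phys, tr)
  inc <- attr(t1, "increments")
  expect_equal(unname(inc["wood"]), phys$f_wood * 5)
  expect_equal(unname(sum(inc)), 5) # conservation
  expect_gt(t1$dbh, tree$dbh)
  expect_identical(t1$npp_negative_months, 0L)

  gbig <- place_tree(forest_grid(10, 10), tr, 2, 2, dbh = 80)
  big <- gbig$trees[1, ]
  t2 <- allocate_and_grow(big, 5, phys, tr)
  inc2 <- attr(t2, "increments")
  expect_equal(unname(inc2["wood"]), 0.5 * phys$f_wood * 5)
  expect_equal(unname(sum(inc2)), 5) # reduction diverted belowground
})

test_that("physiology parameter validation", {
  expect_error(physiology_params(phi = 0), "phi")
  expect_error(physiology_params(phi = 0.2), "phi")
  expect_error(physiology_params(f_below = 0.5, f_wood = 0.4, f_canopy = 0.4),
               "equal 1")
  p <- physiology_params(f_below = 0.5, theta = pi / 4)
  expect_equal(p$f_wood, 0.25)
  expect_equal(p$f_canopy, 0.25)
})
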