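# Small builders shared across tests. Everything is generated in code; no
# stored fixtures.

# a minimal trait table with controllable allometry and tolerance
tiny_traits <- function(n = 1, allom_a = 40, allom_b = 1, allom_k = 20,
                        wsg = 0.6, lma = 100, leaf_n = 2.2, leaf_p = 0.12,
                        maturity_dbh = 10, max_dbh = 120, delta_i = 0) {
  species_traits(data.frame(
    species_id = sprintf("t%02d", seq_len(n)),
    lma = rep_len(lma, n), wsg = rep_len(wsg, n),
    leaf_n = rep_len(leaf_n, n), leaf_p = rep_len(leaf_p, n),
    allom_a = rep_len(allom_a, n), allom_b = rep_len(allom_b, n),
    allom_k = rep_len(allom_k, n),
    maturity_dbh = rep_len(maturity_dbh, n),
    max_dbh = rep_len(max_dbh, n),
    delta_i = rep_len(delta_i, n)
  ))
}

# one month of flat half-hourly forcing (constant temperature and vpd,
# rectangular daylight ppfd)
flat_month <- function(ppfd = 1000, temp = 25, vpd = 1) {
  hour <- (1:48 - 0.5) / 2
  data.frame(ppfd = ifelse(hour >= 6 & hour <= 18, ppfd, 0),
             temp = temp, vpd = vpd)
}

# small stand on a grid for lightning tests
small_stand <- function(width = 30, n = 12, dbh = seq(10, 65, length.out = n),
                        traits = tiny_traits(3)) {
  g <- forest_grid(width, width)
  set.seed(99)
  xy <- expand.grid(x = seq(5, width - 5, by = 4), y = seq(5, width - 5, by = 4))
  xy <- xy[sample.int(nrow(xy), n), ]
  for (i in seq_len(n)) {
    g <- place_tree(g, traits[1 + (i %% nrow(traits)), ],
                    xy$x[i], xy$y[i], dbh = dbh[i])
  }
  g
}
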