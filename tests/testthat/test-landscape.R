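test_that("deme layouts respect counts, separation and sampling scheme", {
  extent <- uniform_raster(24, 24)
  mirror_sizes <- c(18, 9, 7, 6, 5, 3, 2, 1, 1) # 52 individuals, range 1-18
  demes <- generate_deme_layout(39, 9, extent, mirror_sizes, seed = 4)
  expect_equal(nrow(demes), 39L)
  expect_equal(demes$id, 1:39)
  expect_equal(sum(demes$sampled), 9L)
  expect_equal(sum(demes$n_individuals), 52L)
  expect_equal(sort(demes$n_individuals[demes$sampled]), sort(mirror_sizes))
  expect_true(all(demes$n_individuals[!demes$sampled] == 0L))
  d2 <- as.matrix(stats::dist(cbind(demes$row, demes$col)))
  expect_true(min(d2[upper.tri(d2)]) >= 2)
})

test_that("deme layout is seed-reproducible and seed-sensitive", {
  extent <- uniform_raster(16, 16)
  a <- generate_deme_layout(10, 4, extent, rep(2L, 4), seed = 7)
  b <- generate_deme_layout(10, 4, extent, rep(2L, 4), seed = 7)
  expect_identical(a, b)
  differs <- vapply(1:10, function(s) {
    !identical(generate_deme_layout(10, 4, extent, rep(2L, 4), seed = 100 + s),
               a)
  }, logical(1))
  expect_true(mean(differs) > 0.8)
})

test_that("degenerate and infeasible layouts are handled", {
  extent <- uniform_raster(5, 5)
  one <- generate_deme_layout(1, 1, extent, 1L, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(one$sampled)
  expect_error(generate_deme_layout(200, 1, extent, 1L, seed = 1),
               "extent too small")
  expect_error(generate_deme_layout(3, 5, extent, rep(1L, 5), seed = 1),
               "n_sampled")
})

test_that("layer stacks match their contracts per kind", {
  g <- list(n_rows = 20, n_cols = 20)
  dist <- generate_layer_stack("distance", g, seed = 1)
  expect_length(dist$layers, 1L)
  expect_true(all(dist$layers[[1]]$values == 1))

  slope <- generate_layer_stack("slope", g, seed = 2)
  expect_length(slope$layers, 1L)
  expect_true(all(slope$layers[[1]]$values >= 0 &
                  slope$layers[[1]]$values <= 1))

  hab <- generate_layer_stack("habitat_shifts", g, seed = 3)
  expect_length(hab$layers, 21L)
  expect_true(all(vapply(hab$layers, function(l)
    all(l$values %in% c(0, 1)), logical(1))))
  # 1000-year epochs tiling 21-0 kyr
  ey <- do.call(rbind, hab$epoch_years)
  expect_equal(ey[, 1], 21:1)
  expect_equal(ey[, 2], 20:0)

  niche <- generate_layer_stack("niche_suitability", g, seed = 4)
  expect_length(niche$layers, 7L)
  ey <- do.call(rbind, niche$epoch_years)
  expect_equal(ey[1, ], c(21, 17))
  expect_equal(ey[7, ], c(4.2, 0))
  expect_equal(ey[-1, 1], ey[-7, 2]) # slices tile without overlap
  expect_true(all(vapply(niche$layers, function(l)
    all(l$values >= 0 & l$values <= 1), logical(1))))

  expect_error(generate_layer_stack("altitude", g, seed = 1), "unknown")
})

test_that("rivers are connected channels with downstream accumulation", {
  g <- list(n_rows = 20, n_cols = 20)
  rv <- generate_layer_stack("rivers", g, params = list(n_channels = 1L),
                             seed = 5)$layers[[1]]
  expect_true(all(rv$values >= 0 & rv$values <= 1))
  expect_gt(sum(rv$values > 0), 0)
  expect_lt(mean(rv$values > 0), 0.5) # channels are a small set of cells
  zero <- generate_layer_stack("rivers", g,
                               params = list(channel_fraction = 0),
                               seed = 5)$layers[[1]]
  expect_true(all(zero$values == 0))
})

test_that("dynamic stacks are temporally autocorrelated", {
  g <- list(n_rows = 16, n_cols = 16)
  for (kind in c("habitat_shifts", "niche_suitability")) {
    adjacent <- numeric(10)
    distant <- numeric(10)
    for (s in 1:10) {
      st <- generate_layer_stack(kind, g, seed = 700 + s)
      n <- length(st$layers)
      v <- function(i) as.vector(st$layers[[i]]$values)
      adjacent[s] <- mean(vapply(seq_len(n - 1), function(i)
        cor(v(i), v(i + 1)), numeric(1)))
      gap <- min(10, n - 1)
      distant[s] <- mean(vapply(seq_len(n - gap), function(i)
        cor(v(i), v(i + gap)), numeric(1)))
    }
    expect_gt(mean(adjacent), mean(distant))
  }
})

test_that("layer generation is bit-reproducible under a seed", {
  g <- list(n_rows = 12, n_cols = 12)
  for (kind in c("slope", "rivers", "habitat_shifts", "niche_suitability")) {
    a <- generate_layer_stack(kind, g, seed = 31)
    b <- generate_layer_stack(kind, g, seed = 31)
    expect_identical(a, b)
  }
})

test_that("composite resistance follows the weighted-sum contract", {
  g <- list(n_rows = 4, n_cols = 4)
  dist <- generate_layer_stack("distance", g, seed = 1)
  # no non-distance layers: pure IBD surface of ones
  ibd <- composite_resistance(list(dist))
  expect_true(all(ibd$values == 1))

  # constant layer normalizes to zero, so hand examples use 0/1-ranged layers
  half <- structure(list(kind = "slope", layers = list(
    raster_grid(matrix(c(0, rep(1, 7), rep(0.5, 8)), 4, 4))),
    epoch_years = list(c(21, 0))), class = "layer_stack")
  out <- composite_resistance(list(half), weights = c(slope = 4))
  expect_equal(out$values[2, 1], 1 + 4 * 1)
  expect_equal(out$values[1, 3], 1 + 4 * 0.5)
  expect_equal(out$values[1, 1], 1)

  # two layers: slope-normalized 1.0 and rivers 0.0 with weights 2 and 5
  slope1 <- structure(list(kind = "slope", layers = list(
    raster_grid(matrix(c(0, 1, 1, 1), 2, 2))),
    epoch_years = list(c(21, 0))), class = "layer_stack")
  rivers0 <- structure(list(kind = "rivers", layers = list(
    raster_grid(matrix(c(0, 0, 0, 1), 2, 2))),
    epoch_years = list(c(21, 0))), class = "layer_stack")
  both <- composite_resistance(list(slope1, rivers0),
                               weights = c(slope = 2, rivers = 5))
  expect_equal(both$values[2, 1], 1 + 2 * 1 + 5 * 0) # = 3
  expect_gte(min(both$values), 1)
})

test_that("composite is linear in each layer weight", {
  g <- list(n_rows = 8, n_cols = 8)
  slope <- generate_layer_stack("slope", g, seed = 9)
  base <- composite_resistance(list(slope), weights = c(slope = 2))
  dbl <- composite_resistance(list(slope), weights = c(slope = 4))
  expect_equal(dbl$values - 1, 2 * (base$values - 1))
})

test_that("composite rejects mismatched geometry and missing weights", {
  a <- generate_layer_stack("slope", list(n_rows = 4, n_cols = 4), seed = 1)
  b <- generate_layer_stack("rivers", list(n_rows = 5, n_cols = 4), seed = 1)
  expect_error(composite_resistance(list(a, b),
                                    weights = c(slope = 2, rivers = 2)),
               "composition error")
  expect_error(composite_resistance(list(a)), "weight")
})
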