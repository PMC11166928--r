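test_that("least-cost distance on a uniform surface is geometric", {
  r <- uniform_raster(7, 9)
  demes <- manual_demes(r, cbind(c(3, 3), c(2, 7)))
  d <- least_cost_distances(r, demes)
  expect_equal(d[1, 2], 5) # straight rook path, unit cost per step
  expect_equal(d[2, 1], 5)
  expect_equal(diag(d), c("1" = 0, "2" = 0))
  diag_demes <- manual_demes(r, cbind(c(1, 4), c(1, 4)))
  expect_equal(least_cost_distances(r, diag_demes)[1, 2], 3 * sqrt(2))
})

test_that("least-cost distances match the relaxation oracle on small grids", {
  set.seed(99)
  for (case in 1:50) {
    nr <- sample(3:5, 1)
    nc <- sample(3:5, 1)
    vals <- matrix(sample(1:9, nr * nc, replace = TRUE), nr, nc)
    r <- raster_grid(vals)
    from <- c(1, 1)
    to <- c(nr, nc)
    demes <- manual_demes(r, rbind(from, to))
    d <- least_cost_distances(r, demes)
    expect_equal(d[1, 2], oracle_grid_distance(vals, from, to),
                 tolerance = 1e-12)
  }
})

test_that("a wall with a gap routes the least-cost path through the gap", {
  vals <- matrix(1, 7, 7)
  vals[, 4] <- 100
  vals[4, 4] <- 1 # the gap
  r <- raster_grid(vals)
  demes <- manual_demes(r, cbind(c(1, 1), c(1, 7)))
  d <- least_cost_distances(r, demes)[1, 2]
  unobstructed <- least_cost_distances(uniform_raster(7, 7), demes)[1, 2]
  straight_through <- 5 + (1 + 100) / 2 * 2 # crossing the wall head-on
  expect_lt(d, straight_through)
  expect_gt(d, unobstructed)
  expect_equal(d, oracle_grid_distance(vals, c(1, 1), c(1, 7)),
               tolerance = 1e-12)
})

test_that("raising a cell's resistance never shortens any distance", {
  set.seed(12)
  vals <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  r <- raster_grid(vals)
  demes <- manual_demes(r, cbind(c(1, 6, 3), c(1, 6, 5)))
  d0 <- least_cost_distances(r, demes)
  for (k in 1:10) {
    vals2 <- vals
    cell <- c(sample(6, 1), sample(6, 1))
    vals2[cell[1], cell[2]] <- vals2[cell[1], cell[2]] + sample(1:10, 1)
    d1 <- least_cost_distances(raster_grid(vals2), demes)
    expect_true(all(d1 - d0 >= -1e-12))
  }
})

test_that("disconnected demes raise an unreachable error naming the pair", {
  vals <- matrix(1, 5, 5)
  mask <- matrix(FALSE, 5, 5)
  mask[, 3] <- TRUE
  r <- raster_grid(vals, nodata_mask = mask)
  demes <- manual_demes(r, cbind(c(2, 2), c(1, 5)))
  expect_error(least_cost_distances(r, demes),
               "demes [12] and [12] are disconnected")
})

test_that("resistance-to-migration follows the cubic decay exactly", {
  x1 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(resistance_to_migration(x1, dispersal = 1, cap = Inf)[1, 2], 1)
  x2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_identical(resistance_to_migration(x2, 0.2, cap = Inf)[1, 2],
                   0.2 * (1 / 2)^3)
  expect_equal(resistance_to_migration(x2, 0.2, cap = Inf)[1, 2], 0.025)
  # doubling x divides m by 8, for any dispersal
  for (d in c(0.1, 0.17, 0.3)) {
    x <- matrix(c(0, 3, 3, 0), 2, 2)
    m1 <- resistance_to_migration(x, d, cap = Inf)[1, 2]
    m2 <- resistance_to_migration(2 * x, d, cap = Inf)[1, 2]
    expect_equal(m2, m1 / 8)
  }
  expect_true(all(diag(resistance_to_migration(x2, 0.2)) == 0))
})

test_that("the rate cap bounds row sums while preserving symmetry", {
  set.seed(5)
  x <- as.matrix(stats::dist(matrix(runif(10), 5, 2))) * 0.2
  m <- resistance_to_migration(x, 0.3, cap = 0.5)
  expect_true(all(abs(rowSums(m) <= 0.5 + 1e-12)))
  expect_equal(max(rowSums(m)), 0.5)
  expect_equal(m, t(m))
  expect_true(all(resistance_to_migration(x, 0.3, cap = 0) == 0))
  expect_error(resistance_to_migration(matrix(0, 2, 2), 0.2), "co-located")
})

test_that("migration schedules have the model's epoch structure", {
  base <- reduced_design(seed = 2, n_snps = 50)
  stacks <- default_stacks(base$extent, seed = 2)
  draw <- manual_draw(12, effect_weights = c(slope = 3, rivers = 4,
                                             niche_suitability = 2.5,
                                             habitat_shifts = 2))

  one <- build_migration_schedule(landscape_model(1L), stacks, draw,
                                  base$demes)
  expect_length(one$epochs, 1L)
  expect_equal(one$epochs[[1]]$start_gen, 0)
  expect_equal(one$epochs[[1]]$end_gen, 21000)
  # model 1: migration is dispersal * (1 / geographic least-cost)^3
  geo <- least_cost_distances(landcnn:::ibd_surface(base$extent), base$demes)
  expected <- resistance_to_migration(geo, draw$dispersal)
  expect_equal(one$epochs[[1]]$matrix, expected)

  hab <- build_migration_schedule(landscape_model(4L, "habitat_shifts"),
                                  stacks, draw, base$demes)
  expect_length(hab$epochs, 21L)
  starts <- vapply(hab$epochs, `[[`, numeric(1), "start_gen")
  ends <- vapply(hab$epochs, `[[`, numeric(1), "end_gen")
  expect_equal(sort(starts), seq(0, 20000, by = 1000))
  expect_equal(sort(ends), seq(1000, 21000, by = 1000))

  m12 <- landscape_model(12L, c("slope", "rivers", "niche_suitability"))
  full <- build_migration_schedule(m12, stacks, draw, base$demes)
  expect_length(full$epochs, 7L)
  ends <- sort(vapply(full$epochs, `[[`, numeric(1), "end_gen"))
  expect_equal(ends, c(4200, 8326, 11700, 12900, 14700, 17000, 21000))

  # epochs tile [0, 21000] exactly
  for (sch in list(one, hab, full)) {
    s <- vapply(sch$epochs, `[[`, numeric(1), "start_gen")
    e <- vapply(sch$epochs, `[[`, numeric(1), "end_gen")
    o <- order(s)
    expect_equal(s[o][1], 0)
    expect_equal(e[o][length(e)], 21000)
    if (length(s) > 1) expect_equal(s[o][-1], e[o][-length(e)])
  }
})

test_that("zeroing the dynamic weight collapses epochs to a static model", {
  base <- reduced_design(seed = 2, n_snps = 50)
  stacks <- default_stacks(base$extent, seed = 2)
  m12 <- landscape_model(12L, c("slope", "rivers", "niche_suitability"))
  draw0 <- manual_draw(12, effect_weights = c(slope = 3, rivers = 4,
                                              niche_suitability = 0))
  sch <- build_migration_schedule(m12, stacks, draw0, base$demes)
  mats <- lapply(sch$epochs, `[[`, "matrix")
  for (i in 2:length(mats)) expect_equal(mats[[i]], mats[[1]])
  # and with a nonzero weight the suitability epochs differ
  draw1 <- manual_draw(12, effect_weights = c(slope = 3, rivers = 4,
                                              niche_suitability = 4))
  sch1 <- build_migration_schedule(m12, stacks, draw1, base$demes)
  mats1 <- lapply(sch1$epochs, `[[`, "matrix")
  expect_false(isTRUE(all.equal(mats1[[1]], mats1[[7]])))
})

test_that("schedules reject models whose predictor stacks are missing", {
  base <- reduced_design(seed = 2, n_snps = 50)
  stacks <- default_stacks(base$extent, seed = 2)
  draw <- manual_draw(12, effect_weights = c(slope = 3))
  expect_error(build_migration_schedule(landscape_model(2L, "slope"),
                                        stacks["distance"], draw,
                                        base$demes),
               "configuration error")
})

test_that("matrices and schedules round-trip through disk formats", {
  m <- matrix(runif(9), 3, 3, dimnames = list(1:3, 1:3))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  expect_equal(unname(read_matrix_tsv(path)), unname(m), tolerance = 1e-12)
  sch <- manual_schedule(m)
  dir <- withr::local_tempdir()
  write_schedule(sch, dir)
  idx <- jsonlite::read_json(file.path(dir, "schedule.json"),
                             simplifyVector = TRUE)
  expect_equal(idx$split_time, 21000)
  expect_equal(nrow(idx$epochs), 1L)
})
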