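# Ground-truth generator: hard-core placement, spatial ratio field,
# distractors, condition switches.

test_that("hard-core centre placement honours count, bounds and separation", {
  expect_equal(nrow(sample_cell_centers(0, c(100, 100, 100), 10, seed = 1)), 0)
  one <- sample_cell_centers(1, c(50, 60, 70), 10, seed = 2)
  expect_equal(dim(one), c(1, 3))
  expect_true(all(one >= 0 & one <= c(50, 60, 70)))

  p1 <- sample_cell_centers(200, c(100, 300, 300), 12, seed = 1)
  p2 <- sample_cell_centers(200, c(100, 300, 300), 12, seed = 1)
  expect_identical(p1, p2)                      # deterministic given seed
  expect_equal(nrow(p1), 200)
  expect_true(all(p1[, 1] <= 100 & p1[, 2] <= 300 & p1[, 3] <= 300 & p1 >= 0))
  # exhaustive all-pairs distance oracle
  dmin <- min(dist(p1))
  expect_gte(dmin, 12)
  p3 <- sample_cell_centers(200, c(100, 300, 300), 12, seed = 99)
  expect_false(identical(p1, p3))
})

test_that("impossible hard-core packings fail with a clear message", {
  expect_error(sample_cell_centers(50, c(10, 10, 10), 20, seed = 1,
                                   max_attempts = 2000),
               "could not place")
})

test_that("degenerate ratio fields are exact and the covariance matches its closed form", {
  ctr <- sample_cell_centers(5, c(50, 50, 50), 5, seed = 3)
  flat <- sample_ratio_field(ctr, ratio_field_params(mean_ratio = 2, sill = 0,
                                                     nugget = 0), seed = 1)
  expect_identical(flat, rep(2, 5))

  # Monte-Carlo oracle: two cells at distance d, empirical correlation over
  # seeds must approach sill*exp(-d/range) / (sill + nugget)
  two <- rbind(c(0, 0, 0), c(0, 0, 15))
  pars <- ratio_field_params(mean_ratio = 2.5, sill = 0.09, range_um = 30,
                             nugget = 0.01)
  sims <- vapply(1:3000, function(s) sample_ratio_field(two, pars, seed = s),
                 numeric(2))
  rho_hat <- cor(sims[1, ], sims[2, ])
  rho <- pars$sill * exp(-15 / pars$range_um) / (pars$sill + pars$nugget)
  expect_lt(abs(rho_hat - rho), 0.06)           # MC error ~ 1/sqrt(3000)

  # nugget-only field: inter-cell correlation ~ 0
  pars0 <- ratio_field_params(mean_ratio = 2.5, sill = 0, range_um = 30,
                              nugget = 0.1)
  sims0 <- vapply(1:3000, function(s) sample_ratio_field(two, pars0, seed = s),
                  numeric(2))
  expect_lt(abs(cor(sims0[1, ], sims0[2, ])), 0.06)
})

test_that("duplicate centres without nugget are rejected as non-positive-definite", {
  dup <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_error(sample_ratio_field(dup, ratio_field_params(sill = 0.1,
                                                          nugget = 0),
                                  seed = 1),
               "not positive definite")
})

test_that("scene simulation is deterministic and respects its invariants", {
  s1 <- small_scene(seed = 11, n_distractors = 9)
  s2 <- small_scene(seed = 11, n_distractors = 9)
  expect_identical(s1, s2)
  expect_true(all(s1$cells$true_ratio > 0))
  expect_true(all(s1$cells$radius_um > 0))
  expect_true(all(s1$cells$donor_amplitude > 0))
  expect_gte(min(dist(s1$cells[, 1:3])), s1$min_separation_um)
  # distractor bodies clear every soma surface (blob centres by their own
  # reach, filaments along their whole segment)
  for (i in seq_len(nrow(s1$distractors))) {
    di <- s1$distractors[i, ]
    reach <- if (di$shape == "irregular-elongated") 2 * di$size_um else di$size_um
    p0 <- c(di$center_z_um, di$center_y_um, di$center_x_um) -
      di$length_um / 2 * c(di$dir_z, di$dir_y, di$dir_x)
    p1 <- c(di$center_z_um, di$center_y_um, di$center_x_um) +
      di$length_um / 2 * c(di$dir_z, di$dir_y, di$dir_x)
    for (j in seq_len(nrow(s1$cells))) {
      cc <- as.numeric(s1$cells[j, 1:3])
      seg <- p1 - p0
      tt <- if (sum(seg^2) > 0) {
        min(max(sum((cc - p0) * seg) / sum(seg^2), 0), 1)
      } else 0
      dseg <- sqrt(sum((cc - (p0 + tt * seg))^2))
      expect_gte(dseg, s1$cells$radius_um[j] + reach + 1)
    }
  }
})

test_that("distractor ground truth stays below the exclusion threshold", {
  sc <- small_scene(seed = 5)
  expect_identical(add_distractors(sc, 0), sc)
  sc30 <- add_distractors(sc, 30, ratio_low = 0.6, ratio_high = 1.2)
  expect_equal(nrow(sc30$distractors), 30)
  expect_true(all(sc30$distractors$true_ratio < 1.5))
  expect_true(all(sc30$distractors$true_ratio >= 0.6 &
                    sc30$distractors$true_ratio <= 1.2))
  expect_error(add_distractors(sc, 5, ratio_low = 0.5, ratio_high = 1.6))
})

test_that("global ratio scaling multiplies cell ratios exactly, distractors untouched", {
  sc <- small_scene(seed = 8, n_distractors = 6)
  expect_identical(apply_global_ratio_scaling(sc, 1), sc)
  scaled <- apply_global_ratio_scaling(sc, 0.779)
  expect_equal(scaled$cells$true_ratio, sc$cells$true_ratio * 0.779)
  expect_equal(mean(scaled$cells$true_ratio),
               0.779 * mean(sc$cells$true_ratio))
  expect_identical(scaled$distractors$true_ratio, sc$distractors$true_ratio)
  expect_error(apply_global_ratio_scaling(sc, 0))
})

test_that("shuffling permutes the ratio multiset across fixed positions", {
  sc <- small_scene(seed = 9)
  sh <- shuffle_ratio_positions(sc, seed = 4)
  expect_identical(sh$cells[, 1:3], sc$cells[, 1:3])
  expect_identical(sort(sh$cells$true_ratio), sort(sc$cells$true_ratio))
  expect_equal(mean(sh$cells$true_ratio), mean(sc$cells$true_ratio))
  expect_equal(var(sh$cells$true_ratio), var(sc$cells$true_ratio))
  expect_false(identical(sh$cells$true_ratio, sc$cells$true_ratio))
})

test_that("scene ground truth round-trips through JSON", {
  sc <- small_scene(seed = 13, n_distractors = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, f)
  back <- read_scene(f)
  expect_equal(back$cells, sc$cells, tolerance = 1e-12)
  expect_equal(back$distractors, sc$distractors, tolerance = 1e-12)
  expect_equal(back$field_params, sc$field_params)
  expect_equal(back$field_dims_um, sc$field_dims_um)
})

test_that("oracle neighbour correlation approaches 1 for a linear ratio gradient", {
  # cells on a line, ratios a linear function of position: symmetric kNN
  # neighbourhoods average to a linear function of the cell's own ratio
  n <- 21
  sc <- small_scene(seed = 1, n_cells = 5)
  sc$cells <- data.frame(center_z_um = rep(10, n),
                         center_y_um = rep(10, n),
                         center_x_um = seq(5, 145, length.out = n),
                         radius_um = 5, donor_amplitude = 1000,
                         true_ratio = seq(1.5, 3.5, length.out = n))
  co <- oracle_neighbor_correlation(sc, neighborhood_spec("knn", k = 2))
  expect_gt(co$r, 0.99)
  expect_error(oracle_neighbor_correlation(small_scene(n_cells = 2)),
               "at least 3")
})
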