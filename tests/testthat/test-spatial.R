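# Distances, neighbourhoods, Pearson inference, permutation null.

fake_records <- function(z, y, x, ratio, label = seq_along(ratio)) {
  data.frame(label = label, volume_vox = 500L,
             centroid_z_um = z, centroid_y_um = y, centroid_x_um = x,
             mean_670 = 100, mean_720 = 100 * ratio,
             ratio_720_670 = ratio, excluded_reason = "none")
}

test_that("pairwise distances are Euclidean in physical um", {
  d <- pairwise_distances(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(d[1, 2], 10)
  # voxel indices (0,0,0) and (3,0,0) in z with dz = 2 um -> 6 um apart
  cz <- c(0, 3) * 2
  expect_equal(pairwise_distances(cbind(cz, 0, 0))[1, 2], 6)

  set.seed(14)
  pts <- matrix(runif(300) * 100, ncol = 3)
  D <- pairwise_distances(pts)
  # brute-force double loop
  for (i in 1:10) {
    for (j in 1:100) {
      expect_equal(D[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # triangle inequality on a subsample
  for (k in 1:50) {
    ijk <- sample(100, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("kNN and radius neighbourhoods match the worked collinear example", {
  rec <- fake_records(z = c(0, 0, 0), y = c(0, 0, 0), x = c(0, 10, 25),
                      ratio = c(1.5, 2.0, 2.5))
  k1 <- assign_neighbors(rec, neighborhood_spec("knn", k = 1))
  expect_equal(k1$neighbor_mean_ratio, c(2.0, 1.5, 2.0))
  rad <- assign_neighbors(rec, neighborhood_spec("radius", radius_um = 20))
  expect_equal(rad$neighbor_mean_ratio, c(2.0, 2.0, 2.0))
  expect_identical(rad$neighbor_labels[[2]], c(1L, 3L))
  expect_true(all(rad$usable))
  # radius comparison is inclusive at exactly radius_um
  rec2 <- fake_records(z = c(0, 0), y = c(0, 0), x = c(0, 20), ratio = c(1, 2))
  rad2 <- assign_neighbors(rec2, neighborhood_spec("radius", radius_um = 20))
  expect_true(all(rad2$usable))
})

test_that("kNN selection equals the exhaustive full-sort oracle for 250 random cells", {
  set.seed(31)
  n <- 250
  rec <- fake_records(z = runif(n, 0, 100), y = runif(n, 0, 300),
                      x = runif(n, 0, 300), ratio = runif(n, 1.5, 3.5))
  asg <- assign_neighbors(rec, neighborhood_spec("knn", k = 5))
  pts <- cbind(rec$centroid_z_um, rec$centroid_y_um, rec$centroid_x_um)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(pts) - pts[i, ])^2))
    d[i] <- Inf
    oracle <- sort(order(d)[1:5])
    expect_identical(sort(asg$neighbor_labels[[i]]), oracle)
  }
})

test_that("self is never a neighbour; knn can be asymmetric, radius is symmetric", {
  rec <- fake_records(z = rep(0, 4), y = rep(0, 4), x = c(0, 1, 2, 50),
                      ratio = c(1, 2, 3, 4))
  k1 <- assign_neighbors(rec, neighborhood_spec("knn", k = 1))
  for (i in 1:4) expect_false(i %in% k1$neighbor_labels[[i]])
  # cell 4's nearest is 3, but 3's nearest is 2: asymmetric
  expect_identical(k1$neighbor_labels[[4]], 3L)
  expect_identical(k1$neighbor_labels[[3]], 2L)
  rad <- assign_neighbors(rec, neighborhood_spec("radius", radius_um = 5))
  for (i in 1:4) {
    for (j in rad$neighbor_labels[[i]]) {
      expect_true(i %in% rad$neighbor_labels[[j]])
    }
  }
  expect_false(rad$usable[4])                    # isolated cell unusable
  expect_error(assign_neighbors(rec, neighborhood_spec("knn", k = 4)),
               "at least 5")
})

test_that("kNN distance ties break deterministically toward the lower label", {
  rec <- fake_records(z = rep(0, 3), y = c(0, 1, -1), x = c(0, 0, 0),
                      ratio = c(1, 2, 3), label = c(10L, 20L, 30L))
  k1 <- assign_neighbors(rec, neighborhood_spec("knn", k = 1))
  expect_identical(k1$neighbor_labels[[1]], 20L)  # tie 20 vs 30 -> lower label
})

test_that("pearson_correlation matches hand-worked values and reports degeneracy", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1.0)
  co <- pearson_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(co$r, 0.8, tolerance = 1e-15)
  expect_equal(co$n, 5)
  z <- pearson_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_true(z$degenerate && is.na(z$r))
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("r is invariant under positive affine transforms of either variable", {
  set.seed(9)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, 0.1 * y - 4)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(-2 * x, y)$r, -r0, tolerance = 1e-12)
})

test_that("k = n-1 neighbour means equal the self-exclusion closed form", {
  set.seed(12)
  n <- 30
  rec <- fake_records(z = runif(n, 0, 50), y = runif(n, 0, 100),
                      x = runif(n, 0, 100), ratio = runif(n, 1, 3))
  asg <- assign_neighbors(rec, neighborhood_spec("knn", k = n - 1))
  closed <- (sum(rec$ratio_720_670) - rec$ratio_720_670) / (n - 1)
  expect_equal(asg$neighbor_mean_ratio, closed, tolerance = 1e-12)
})

test_that("correlate_with_neighbors returns the scatter table and flags significance", {
  sc <- small_scene(seed = 3, n_cells = 60)
  co <- oracle_neighbor_correlation(sc, neighborhood_spec("knn", k = 5))
  expect_s3_class(co, "fret_neighbor_cor")
  expect_equal(co$n, 60)
  expect_equal(nrow(co$table), 60)
  expect_identical(co$significant, isTRUE(co$p_value < 0.001))
  # degenerate ratios are reported, not silently NaN
  rec <- fake_records(z = runif(10), y = runif(10, 0, 50),
                      x = runif(10, 0, 50), ratio = rep(2, 10))
  cd <- correlate_with_neighbors(rec, neighborhood_spec("knn", k = 3))
  expect_true(cd$degenerate)
})

test_that("a perfectly spatially ordered field attains the minimal permutation p", {
  n <- 40
  rec <- fake_records(z = rep(0, n), y = rep(0, n), x = seq(0, 390, by = 10),
                      ratio = seq(1.5, 3.5, length.out = n))
  pn <- permutation_null(rec, neighborhood_spec("knn", k = 2),
                         n_perm = 999, seed = 8)
  expect_equal(pn$p_empirical, 1 / 1000)
  expect_gt(pn$r_obs, 0.99)
  expect_length(pn$r_null, 999)
  # deterministic given seed
  pn2 <- permutation_null(rec, neighborhood_spec("knn", k = 2),
                          n_perm = 999, seed = 8)
  expect_identical(pn$r_null, pn2$r_null)
})

test_that("empirical and parametric p agree for independent ratios", {
  # nugget-only scenes: the two p-values should be of the same order
  ratios <- vapply(1:25, function(s) {
    sc <- simulate_scene(n_cells = 100, seed = s,
                         field_params = ratio_field_params(sill = 0,
                                                          nugget = 0.09))
    co <- oracle_neighbor_correlation(sc, neighborhood_spec("knn", k = 5))
    rec <- data.frame(label = seq_len(100),
                      centroid_z_um = sc$cells$center_z_um,
                      centroid_y_um = sc$cells$center_y_um,
                      centroid_x_um = sc$cells$center_x_um,
                      ratio_720_670 = sc$cells$true_ratio,
                      excluded_reason = "none")
    pn <- permutation_null(rec, neighborhood_spec("knn", k = 5),
                           n_perm = 199, seed = s)
    # compare on the log scale only where both are estimable
    c(pn$p_empirical, co$p_value)
  }, numeric(2))
  est <- pmax(ratios[1, ], 1 / 200)
  par <- pmin(pmax(ratios[2, ], 1 / 200), 1)
  expect_lt(median(abs(log(est / par))), log(2))
})
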