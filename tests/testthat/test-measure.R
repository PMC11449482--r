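# ROI quantification and the ratio-threshold exclusion.

test_that("uniform ROIs give exact means, ratios and physical centroids", {
  donor <- array(0, c(6, 8, 8))
  acceptor <- array(0, c(6, 8, 8))
  lab <- array(0L, c(6, 8, 8))
  donor[2:4, 3:5, 3:5] <- 100
  acceptor[2:4, 3:5, 3:5] <- 180
  lab[2:4, 3:5, 3:5] <- 1L
  rec <- measure_rois(stack_from(donor, acceptor), lab)
  expect_equal(rec$mean_670, 100)
  expect_equal(rec$mean_720, 180)
  expect_equal(rec$ratio_720_670, 1.8)
  expect_equal(rec$volume_vox, 27L)
  expect_equal(rec$excluded_reason, "none")

  # two voxels at z-indices 0 and 3 (0-based), dz = 2 um -> centroid_z = 3 um
  lab2 <- array(0L, c(4, 2, 2))
  lab2[1, 1, 1] <- 1L
  lab2[4, 1, 1] <- 1L
  d2 <- array(10, c(4, 2, 2))
  rec2 <- measure_rois(stack_from(d2, d2), lab2)
  expect_equal(rec2$centroid_z_um, 3.0)
  expect_equal(rec2$centroid_y_um, 0.0)
})

test_that("zero-donor ROIs are flagged and excluded with a warning", {
  donor <- array(0, c(3, 4, 4))
  acceptor <- array(5, c(3, 4, 4))
  lab <- array(0L, c(3, 4, 4)); lab[2, 2:3, 2:3] <- 1L
  expect_warning(rec <- measure_rois(stack_from(donor, acceptor), lab),
                 "zero donor")
  expect_identical(rec$excluded_reason, "ratio")
})

test_that("border contact is flagged but not excluded by default", {
  donor <- array(1, c(3, 6, 6))
  lab <- array(0L, c(3, 6, 6))
  lab[1, 1:3, 1:3] <- 1L                 # touches z and lateral borders
  lab[2, 3:4, 3:4] <- 2L                 # interior
  rec <- measure_rois(stack_from(donor, donor), lab)
  expect_identical(rec$touches_border, c(TRUE, FALSE))
  expect_identical(rec$excluded_reason, c("none", "none"))
})

test_that("the ratio filter is strict-below with the published threshold", {
  rec <- data.frame(label = 1:4, volume_vox = 400L,
                    centroid_z_um = 0, centroid_y_um = 0, centroid_x_um = 0,
                    mean_670 = 100, mean_720 = 100,
                    ratio_720_670 = c(1.2, 1.49, 1.5, 2.0),
                    excluded_reason = "none")
  fl <- filter_by_ratio(rec, 1.5)
  expect_setequal(fl$retained$ratio_720_670, c(1.5, 2.0))
  expect_setequal(fl$excluded$ratio_720_670, c(1.2, 1.49))
  expect_true(all(fl$excluded$excluded_reason == "ratio"))
  # threshold zero retains everything
  expect_equal(nrow(filter_by_ratio(rec, 1e-9)$retained), 4)
})

test_that("raising the threshold never increases the retained count; partition is exhaustive", {
  set.seed(20)
  rec <- data.frame(label = 1:50, volume_vox = 500L,
                    centroid_z_um = 0, centroid_y_um = 0, centroid_x_um = 0,
                    mean_670 = 100, mean_720 = 100,
                    ratio_720_670 = runif(50, 0.5, 3),
                    excluded_reason = "none")
  kept <- vapply(seq(0.5, 3, by = 0.25), function(th) {
    fl <- filter_by_ratio(rec, th)
    expect_equal(nrow(fl$retained) + nrow(fl$excluded), 50)
    expect_length(intersect(fl$retained$label, fl$excluded$label), 0)
    nrow(fl$retained)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("ratios are invariant under a common positive rescaling of both channels", {
  set.seed(4)
  donor <- array(rexp(4 * 10 * 10, 1 / 50) + 1, c(4, 10, 10))
  acceptor <- donor * 1.9
  lab <- array(0L, c(4, 10, 10)); lab[2:3, 3:7, 3:7] <- 1L
  r1 <- measure_rois(stack_from(donor, acceptor), lab)
  r2 <- measure_rois(stack_from(donor * 7.3, acceptor * 7.3), lab)
  expect_equal(r2$ratio_720_670, r1$ratio_720_670, tolerance = 1e-12)
})

test_that("the expression-vs-ratio scatter reports r, p and degeneracy honestly", {
  rec <- data.frame(label = 1:3, volume_vox = 400L,
                    centroid_z_um = 0, centroid_y_um = 0, centroid_x_um = 0,
                    mean_670 = c(10, 20, 30), mean_720 = c(16, 36, 60),
                    ratio_720_670 = c(1.6, 1.8, 2.0),
                    excluded_reason = "none")
  s <- ratio_scatter_summary(rec)
  expect_equal(s$cor$r, 1.0)
  expect_identical(names(s$table),
                   c("label", "mean_720", "mean_670", "ratio_720_670"))

  # acceptor exactly 2 x donor: zero ratio variance -> explicit degeneracy
  rec$ratio_720_670 <- 2
  s2 <- ratio_scatter_summary(rec)
  expect_true(s2$cor$degenerate)
  expect_true(is.na(s2$cor$r))
  expect_error(ratio_scatter_summary(rec[1:2, ]), "at least 3")
})

test_that("expression level and true ratio are independent in the generator", {
  # ground-truth-level check across seeds: biosensor expression (donor
  # amplitude) must not predict the ratio
  pvals <- vapply(1:50, function(s) {
    sc <- simulate_scene(n_cells = 120, seed = s)
    pearson_correlation(sc$cells$donor_amplitude,
                        sc$cells$true_ratio)$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.95)
})
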