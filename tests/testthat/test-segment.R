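# Component tree, MSER selection, opening filter.

test_that("a sharp-edged in-band sphere is recovered as exactly one exact ROI", {
  vol <- make_sphere(c(20, 24, 24), c(10, 12, 12), 36)   # ~925 voxels
  tree <- build_component_tree(vol, levels = 10)
  lab <- select_stable_regions(tree)
  expect_equal(max(lab), 1)
  expect_identical(which(lab == 1), which(vol > 0))
  sel <- attr(lab, "selection")
  expect_equal(sel$volume_vox, sum(vol > 0))
})

test_that("spheres below the volume band yield zero ROIs", {
  vol <- make_sphere(c(20, 24, 24), c(10, 12, 12), 10.5, value = 50)  # ~150 vox
  expect_lt(sum(vol > 0), 300)
  lab <- select_stable_regions(build_component_tree(vol, levels = 10))
  expect_equal(max(lab), 0)
})

test_that("well-separated spheres form independent chains; a dim bridge merges them at its intensity", {
  dims <- c(12, 30, 14)
  vol <- make_sphere(dims, c(6, 8, 7), 9, value = 95) +
    make_sphere(dims, c(6, 22, 7), 9, value = 80)
  # without a bridge: two components at every threshold
  tree0 <- build_component_tree(vol, levels = 12, volume_min_vox = 1,
                                volume_max_vox = 1e6, keep_records = TRUE)
  for (l in seq_along(tree0$thresholds)) {
    expect_equal(sum(tree0$records$level == l),
                 max(naive_label_26(vol >= tree0$thresholds[l])))
  }
  # with a bridge of intensity 30: chains merge at the first threshold <= 30
  volb <- vol
  volb[6, 11:19, 7] <- 30
  tree <- build_component_tree(volb, levels = 12, volume_min_vox = 1,
                               volume_max_vox = 1e6, keep_records = TRUE)
  rec <- tree$records
  ncomp_tree <- vapply(seq_along(tree$thresholds),
                       function(l) sum(rec$level == l), integer(1))
  ncomp_naive <- vapply(tree$thresholds,
                        function(t) max(naive_label_26(volb >= t)), integer(1))
  expect_identical(ncomp_tree, ncomp_naive)
  # three regimes: above 80 only the brighter sphere; between the bridge
  # intensity and 80 two chains; at the first threshold <= 30 they merge
  thr <- tree$thresholds
  expect_true(all(ncomp_tree[thr > 80] == 1))
  expect_true(all(ncomp_tree[thr <= 80 & thr > 30] == 2))
  expect_true(all(ncomp_tree[thr <= 30] == 1))
  expect_gte(sum(thr <= 30), 1)                  # the merge is reached
  # per-level component volumes match brute-force labeling exactly
  for (l in seq_along(tree$thresholds)) {
    nl <- naive_label_26(volb >= tree$thresholds[l])
    expect_identical(sort(as.integer(tabulate(nl[nl > 0]))),
                     sort(rec$volume[rec$level == l]))
  }
})

test_that("two Gaussian blobs with overlapping halos give two most-stable ROIs at their centres", {
  dims <- c(16, 32, 32)
  grid <- expand.grid(z = 1:16, y = 1:32, x = 1:32)
  g <- function(c0, amp, sig) {
    amp * exp(-((grid$z - c0[1])^2 + (grid$y - c0[2])^2 +
                  (grid$x - c0[3])^2) / (2 * sig^2))
  }
  vol <- array(g(c(8, 6, 16), 100, 3) + g(c(8, 26, 16), 90, 3), dims)
  vol[vol < 1] <- 0
  lab <- select_stable_regions(build_component_tree(vol, levels = 40,
                                                    volume_min_vox = 300,
                                                    volume_max_vox = 5000))
  expect_equal(max(lab), 2)
  label_centroid <- sapply(1:2, function(k) {
    idx <- arrayInd(which(lab == k), dims)
    colMeans(idx)
  })
  ys <- sort(label_centroid[2, ])
  expect_lt(abs(ys[1] - 6), 1.5)
  expect_lt(abs(ys[2] - 26), 1.5)
  # regions are disjoint by construction; both volumes inside the band
  sel <- attr(lab, "selection")
  expect_true(all(sel$volume_vox >= 300 & sel$volume_vox <= 5000))
})

test_that("segmentation is invariant to positive intensity scaling", {
  vol <- make_sphere(c(14, 20, 20), c(7, 10, 10), 20, value = 60) +
    make_sphere(c(14, 20, 20), c(7, 10, 10), 60, value = 5)
  lab1 <- select_stable_regions(build_component_tree(vol, levels = 20,
                                                     volume_min_vox = 50,
                                                     volume_max_vox = 5000))
  lab2 <- select_stable_regions(build_component_tree(vol * 417.3, levels = 20,
                                                     volume_min_vox = 50,
                                                     volume_max_vox = 5000))
  expect_identical(as.integer(lab1), as.integer(lab2))
})

test_that("constant volumes give an empty tree and no ROIs", {
  vol <- array(0, c(6, 8, 8))
  tree <- build_component_tree(vol, levels = 5)
  expect_equal(nrow(tree$nodes), 0)
  expect_equal(max(select_stable_regions(tree)), 0)
})

test_that("opening keeps solid bodies, removes thin structures, matches the naive oracle", {
  # solid 10^3 cube survives essentially intact
  lab <- array(0L, c(16, 16, 16))
  lab[4:13, 4:13, 4:13] <- 1L
  op <- opening_filter(lab, radius_vox = 2, volume_min_vox = 300)
  expect_equal(nrow(attr(op, "removed")), 0)
  expect_identical(op == 1L, naive_open_ball(lab == 1L, 2))
  expect_gt(sum(op == 1), 700)                   # only corner/edge rounding lost
  expect_true(all(op[lab == 0L] == 0L))          # anti-extensive

  # 1-voxel filament of 400 voxels is opened away
  filament <- array(0L, c(3, 25, 25))
  filament[2, , ] <- ifelse(row(matrix(0, 25, 25)) %in% 12:13, 1L, 0L)
  expect_gte(sum(filament), 40)
  opf <- opening_filter(filament, radius_vox = 2, volume_min_vox = 30)
  expect_equal(max(opf), 0)
  expect_equal(attr(opf, "removed")$label, 1L)

  # sphere with a spur: spur removed, body retained, exact oracle equality
  vol <- make_sphere(c(20, 20, 20), c(10, 10, 10), 30)
  mask <- vol > 0
  mask[10, 10, 14:19] <- TRUE                    # 1-voxel spur
  lab3 <- array(0L, dim(mask)); lab3[mask] <- 1L
  op3 <- opening_filter(lab3, radius_vox = 2, volume_min_vox = 10)
  oracle <- naive_open_ball(mask, 2)
  expect_identical(op3 == 1L, oracle)
})

test_that("opened ROIs that fall below the volume floor are removed and reported", {
  lab <- array(0L, c(16, 16, 16))
  lab[4:13, 4:13, 4:13] <- 1L                    # survives
  lab[2, 1:14, 2] <- 2L                          # thin line, opened away
  op <- opening_filter(lab, radius_vox = 2, volume_min_vox = 100)
  rem <- attr(op, "removed")
  expect_equal(rem$label, 2L)
  expect_equal(rem$volume_after, 0L)
  expect_identical(sort(unique(op[op > 0])), 1L)
})
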