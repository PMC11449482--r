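# Brute-force reference implementations, deliberately naive and independent
# of the package's C++ code paths, plus small fixture builders.

disk_offsets <- function(radius) {
  fp <- fretseg:::disk_footprint(radius)
  which(fp, arr.ind = TRUE) - (radius + 1)
}

# exact grayscale erosion/dilation of one 2-D slice, window clipped at borders
naive_minmax_slice <- function(sl, radius, op = min) {
  off <- disk_offsets(radius)
  out <- sl
  for (y in seq_len(nrow(sl))) {
    for (x in seq_len(ncol(sl))) {
      yy <- y + off[, 1]
      xx <- x + off[, 2]
      ok <- yy >= 1 & yy <= nrow(sl) & xx >= 1 & xx <= ncol(sl)
      out[y, x] <- op(sl[cbind(yy[ok], xx[ok])])
    }
  }
  out
}

naive_tophat_slice <- function(sl, radius) {
  sl - naive_minmax_slice(naive_minmax_slice(sl, radius, min), radius, max)
}

naive_median_slice <- function(sl, radius) {
  off <- disk_offsets(radius)
  out <- sl
  for (y in seq_len(nrow(sl))) {
    for (x in seq_len(ncol(sl))) {
      yy <- y + off[, 1]
      xx <- x + off[, 2]
      ok <- yy >= 1 & yy <= nrow(sl) & xx >= 1 & xx <= ncol(sl)
      out[y, x] <- median(sl[cbind(yy[ok], xx[ok])])
    }
  }
  out
}

ball_offsets <- function(radius) {
  g <- expand.grid(dz = -radius:radius, dy = -radius:radius, dx = -radius:radius)
  as.matrix(g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, ])
}

# naive 3-D binary opening with a ball (out-of-volume treated as background)
naive_open_ball <- function(mask, radius) {
  d <- dim(mask)
  off <- ball_offsets(radius)
  inb <- function(p) all(p >= 1) && all(p <= d)
  ero <- array(FALSE, d)
  for (i in which(mask)) {
    p <- arrayInd(i, d)
    keep <- TRUE
    for (k in seq_len(nrow(off))) {
      q <- p + off[k, ]
      if (!inb(q) || !mask[q[1], q[2], q[3]]) { keep <- FALSE; break }
    }
    ero[p] <- keep
  }
  out <- array(FALSE, d)
  for (i in which(ero)) {
    p <- arrayInd(i, d)
    for (k in seq_len(nrow(off))) {
      q <- p + off[k, ]
      if (inb(q)) out[q[1], q[2], q[3]] <- TRUE
    }
  }
  out
}

# naive 26-connected labeling of a 3-D logical mask (pure R BFS)
naive_label_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(nb == 0) < 3, ]
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0) next
    cur <- cur + 1L
    queue <- list(arrayInd(i, d))
    lab[i] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# definitional Pearson r (sum-of-products form, no stats:: shortcuts)
naive_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx * dx) * sum(dy * dy))
}

# a solid ellipsoid/sphere mask in a zero volume
make_sphere <- function(dims, center, r2, value = 100) {
  vol <- array(0, dims)
  for (z in seq_len(dims[1])) {
    for (y in seq_len(dims[2])) {
      for (x in seq_len(dims[3])) {
        if (sum((c(z, y, x) - center)^2) <= r2) vol[z, y, x] <- value
      }
    }
  }
  vol
}

# two-channel stack from a pair of volumes
stack_from <- function(donor, acceptor, voxel = c(2, 0.62, 0.62)) {
  image_stack(list(donor_670 = donor, acceptor_720 = acceptor),
              voxel_size_um = voxel)
}

# a small scene that renders and segments in a couple of seconds
small_scene <- function(seed = 7, n_cells = 40, n_distractors = 0, ...) {
  sc <- simulate_scene(n_cells = n_cells,
                       field_dims_um = c(80, 159.04, 159.04),
                       voxel_size_um = c(2, 0.994, 0.994),
                       seed = seed, ...)
  if (n_distractors > 0) sc <- add_distractors(sc, n_distractors)
  sc
}

# one-to-one matching of retained ROIs to planted cells: a cell is recovered
# when a unique retained centroid lies within one soma radius of its centre
match_rois <- function(scene, retained) {
  cells <- scene$cells
  cmat <- cbind(cells$center_z_um, cells$center_y_um, cells$center_x_um)
  if (nrow(retained) == 0) {
    return(list(recovered = logical(nrow(cells)), roi_of_cell = rep(NA, nrow(cells)),
                spurious = integer(0)))
  }
  rmat <- cbind(retained$centroid_z_um, retained$centroid_y_um,
                retained$centroid_x_um)
  D <- as.matrix(dist(rbind(cmat, rmat)))[seq_len(nrow(cmat)),
                                          nrow(cmat) + seq_len(nrow(rmat)),
                                          drop = FALSE]
  nearest <- apply(D, 1, which.min)
  dmin <- D[cbind(seq_len(nrow(cmat)), nearest)]
  hit <- dmin <= cells$radius_um
  # one-to-one: drop cells whose matched ROI is claimed by a closer cell
  roi_of_cell <- ifelse(hit, nearest, NA)
  for (j in unique(na.omit(roi_of_cell))) {
    claimants <- which(!is.na(roi_of_cell) & roi_of_cell == j)
    if (length(claimants) > 1) {
      best <- claimants[which.min(dmin[claimants])]
      roi_of_cell[setdiff(claimants, best)] <- NA
    }
  }
  droi <- apply(D, 2, min)
  list(recovered = !is.na(roi_of_cell), roi_of_cell = roi_of_cell,
       spurious = which(droi > max(cells$radius_um)))
}
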