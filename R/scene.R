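#' Parameters of the latent spatial ratio field
#'
#' The per-cell acceptor/donor (720/670) emission ratios are modelled as a
#' Gaussian random field sampled at the cell centres, with an exponential
#' spatial covariance plus an independent per-cell ("nugget") component:
#' \deqn{C(d) = \mathrm{sill}\cdot e^{-d/\mathrm{range}} +
#'       \mathrm{nugget}\cdot 1[d=0].}
#' The structured component is what makes neighbouring cells carry similar
#' ratios; the nugget is cell-intrinsic variability.
#'
#' @param mean_ratio Mean 720/670 ratio of the field (unitless).
#' @param sill Variance of the spatially structured component.
#' @param range_um Correlation length of the exponential covariance, in
#'   micrometres.
#' @param nugget Variance of the independent per-cell component.
#' @return An object of class `ratio_field_params`.
#' @export
ratio_field_params <- function(mean_ratio = 2.5, sill = 0.09, range_um = 30,
                               nugget = 0.01) {
  stopifnot(sill >= 0, nugget >= 0, range_um > 0, mean_ratio > 0)
  if (mean_ratio - 3 * sqrt(sill + nugget) <= 0) {
    stop("ratio field allows non-positive ratios: require mean_ratio - 3*sqrt(sill+nugget) > 0")
  }
  structure(list(mean_ratio = mean_ratio, sill = sill, range_um = range_um,
                 nugget = nugget), class = "ratio_field_params")
}

#' Sample hard-core cell centres
#'
#' Places `n` points uniformly inside the field with a minimum pairwise
#' separation (a hard-core point process), by rejection sampling.  Cells are
#' kept at least `margin_um` away from every field face so somata are not
#' clipped by the stack border.
#'
#' @param n Number of centres to place.
#' @param field_dims_um Field extent, a length-3 vector `(z, y, x)` in um.
#' @param min_separation_um Minimum pairwise centre distance in um.
#' @param seed Integer seed; the same seed reproduces the same centres.
#' @param margin_um Margin kept from every field face, in um.
#' @param max_attempts Bound on rejection-sampling attempts before failing.
#' @return An `n x 3` matrix of centres, columns `(z, y, x)` in um.
#' @export
sample_cell_centers <- function(n, field_dims_um, min_separation_um, seed,
                                margin_um = 0, max_attempts = 200 * n + 1000) {
  stopifnot(n >= 0, min_separation_um >= 0, length(field_dims_um) == 3,
            all(field_dims_um > 0), all(field_dims_um > 2 * margin_um))
  out <- matrix(numeric(0), ncol = 3,
                dimnames = list(NULL, c("z", "y", "x")))
  if (n == 0) return(out)
  with_seed(seed, {
    pts <- matrix(NA_real_, nrow = n, ncol = 3)
    placed <- 0L
    attempts <- 0L
    msq <- min_separation_um^2
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(paste0("could not place %d hard-core points (separation ",
                            "%.3g um) in a %s um field after %d attempts"),
                     n, min_separation_um,
                     paste(signif(field_dims_um, 4), collapse = " x "),
                     max_attempts))
      }
      cand <- margin_um + runif(3) * (field_dims_um - 2 * margin_um)
      ok <- TRUE
      if (placed > 0L) {
        d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
          (pts[seq_len(placed), 2] - cand[2])^2 +
          (pts[seq_len(placed), 3] - cand[3])^2
        ok <- all(d2 >= msq)
      }
      if (ok) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
    }
    colnames(pts) <- c("z", "y", "x")
    out <- pts
  })
  out
}

#' Sample per-cell ratios from the spatial field
#'
#' Draws one multivariate-normal realisation of the ratio field at the given
#' centres: mean `mean_ratio`, covariance
#' `sill * exp(-d/range_um) + nugget * I`.
#'
#' @param centers Matrix of cell centres (rows = cells, columns z,y,x in um).
#' @param params A [ratio_field_params()] object.
#' @param seed Integer seed.
#' @return Numeric vector of true ratios, one per centre.
#' @export
sample_ratio_field <- function(centers, params, seed) {
  stopifnot(inherits(params, "ratio_field_params"), nrow(centers) >= 1)
  n <- nrow(centers)
  if (params$sill == 0 && params$nugget == 0) {
    return(rep(params$mean_ratio, n))
  }
  covm <- params$sill * exp(-as.matrix(dist(centers)) / params$range_um) +
    diag(params$nugget, n)
  ch <- tryCatch(chol(covm), error = function(e) {
    stop("ratio-field covariance is not positive definite ",
         "(duplicate centres with nugget = 0?)")
  })
  with_seed(seed, {
    z <- rnorm(n)
  })
  as.numeric(params$mean_ratio + crossprod(ch, z))
}

#' Simulate a ground-truth scene
#'
#' Builds the ground truth of one imaging field: hard-core cell centres,
#' quasi-spherical soma radii, lognormal donor amplitudes (emulating uneven
#' viral transduction, independent of the ratio), and per-cell true 720/670
#' ratios drawn from the spatial ratio field.  The scene carries no pixels;
#' [render_stack()] turns it into a two-channel image stack.
#'
#' The defaults emulate one cortical field of view: 512 x 512 pixels at
#' 0.994 um laterally (the ~509 um field of a 25x objective at zoom 1),
#' 60 planes at 2 um steps, with about 250 labelled somata.
#'
#' @param n_cells Number of cells.
#' @param field_dims_um Field extent `(z, y, x)` in um.
#' @param voxel_size_um Voxel pitch `(dz, dy, dx)` in um.
#' @param min_separation_um Hard-core minimum centre separation in um.
#' @param radius_range_um Soma radii are drawn uniformly from this range,
#'   then capped at half the nearest-neighbour distance so adjacent somata
#'   never overlap.
#' @param amplitude_meanlog,amplitude_sdlog Lognormal parameters of the donor
#'   amplitude (photons per voxel at the soma centre).
#' @param field_params A [ratio_field_params()] object.
#' @param seed Master integer seed (placement, field, amplitudes and any
#'   later noise draw from independent sub-streams).
#' @return An object of class `fret_scene`.
#' @export
simulate_scene <- function(n_cells = 250,
                           field_dims_um = c(120, 508.928, 508.928),
                           voxel_size_um = c(2, 0.994, 0.994),
                           min_separation_um = 16,
                           radius_range_um = c(7, 9),
                           amplitude_meanlog = log(10000),
                           amplitude_sdlog = 0.3,
                           field_params = ratio_field_params(),
                           seed = 1) {
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0),
            diff(radius_range_um) >= 0, radius_range_um[1] > 0)
  seeds <- stage_seeds(seed)
  centers <- sample_cell_centers(n_cells, field_dims_um, min_separation_um,
                                 seed = seeds[["placement"]],
                                 margin_um = radius_range_um[2])
  cells <- data.frame(center_z_um = centers[, 1], center_y_um = centers[, 2],
                      center_x_um = centers[, 3])
  with_seed(seeds[["placement"]] + 1, {
    cells$radius_um <- runif(n_cells, radius_range_um[1], radius_range_um[2])
    cells$donor_amplitude <- rlnorm(n_cells, amplitude_meanlog, amplitude_sdlog)
  })
  if (n_cells >= 2) {
    # adjacent somata may sit closer than two nominal radii; cap each radius
    # at half the nearest-neighbour distance less 1.5 um, so soma supports stay
    # >= 3 um apart (beyond the strong PSF tail) while close pairs - the 20 um
    # neighbourhoods - exist
    dm <- as.matrix(dist(centers))
    diag(dm) <- Inf
    nn <- apply(dm, 1, min)
    cells$radius_um <- pmin(cells$radius_um, nn / 2 - 1.5)
  }
  cells$true_ratio <- if (n_cells > 0) {
    sample_ratio_field(centers, field_params, seed = seeds[["field"]])
  } else numeric(0)
  if (any(cells$true_ratio <= 0)) {
    stop("sampled ratio field produced non-positive ratios; ",
         "reduce sill/nugget or raise mean_ratio")
  }
  structure(list(field_dims_um = field_dims_um,
                 voxel_size_um = voxel_size_um,
                 cells = cells,
                 distractors = empty_distractors(),
                 field_params = field_params,
                 min_separation_um = min_separation_um,
                 rng_seed = seed,
                 stage_seeds = seeds),
            class = "fret_scene")
}

empty_distractors <- function() {
  data.frame(center_z_um = numeric(0), center_y_um = numeric(0),
             center_x_um = numeric(0), shape = character(0),
             size_um = numeric(0), length_um = numeric(0),
             dir_z = numeric(0), dir_y = numeric(0), dir_x = numeric(0),
             amplitude = numeric(0), true_ratio = numeric(0))
}

#' @export
print.fret_scene <- function(x, ...) {
  cat("Synthetic FRET scene\n")
  cat(sprintf("  field: %s um, voxels %s um\n",
              paste(signif(x$field_dims_um, 4), collapse = " x "),
              paste(signif(x$voxel_size_um, 3), collapse = " x ")))
  cat(sprintf("  cells: %d (mean true ratio %.3f), distractors: %d\n",
              nrow(x$cells), mean(x$cells$true_ratio),
              nrow(x$distractors)))
  cat(sprintf("  ratio field: mean %.3g, sill %.3g, range %.3g um, nugget %.3g\n",
              x$field_params$mean_ratio, x$field_params$sill,
              x$field_params$range_um, x$field_params$nugget))
  invisible(x)
}

#' Add autofluorescent distractor objects
#'
#' Plants non-cell objects with low 720/670 ratios, emulating the
#' autofluorescent structures whose size and morphology differ from neurons.
#' Three shapes are cycled through: small blobs (below the minimum ROI
#' volume), thin elongated filaments (removed by morphological opening), and
#' compact blobs of neuron-like volume whose low ratio is caught by the
#' ratio threshold.
#'
#' @param scene A `fret_scene`.
#' @param n_distractors Number of objects to add.
#' @param ratio_low,ratio_high Distractor ratios are drawn uniformly from
#'   `[ratio_low, ratio_high]`; both must be below the 1.5 exclusion
#'   threshold.
#' @param seed Integer seed; defaults to the scene's distractor sub-stream.
#' @return The scene with distractors added to its ground truth.
#' @export
add_distractors <- function(scene, n_distractors = 30, ratio_low = 0.6,
                            ratio_high = 1.2, seed = NULL) {
  stopifnot(inherits(scene, "fret_scene"),
            ratio_low > 0, ratio_low <= ratio_high, ratio_high < 1.5)
  if (n_distractors == 0) return(scene)
  seed <- seed %||% scene$stage_seeds[["distractor"]]
  fd <- scene$field_dims_um
  shapes <- rep(c("small-blob", "irregular-elongated", "compact-blob"),
                length.out = n_distractors)
  cells <- scene$cells
  cmat <- as.matrix(cells[, c("center_z_um", "center_y_um", "center_x_um")])
  with_seed(seed, {
    # pre-draw per-object geometry, then place each object so that its own
    # extent clears every soma (objects must not contaminate cell ratios)
    sizes <- numeric(n_distractors)
    sizes[shapes == "small-blob"] <- runif(sum(shapes == "small-blob"), 2, 3.4)
    sizes[shapes == "irregular-elongated"] <-
      runif(sum(shapes == "irregular-elongated"), 0.5, 0.7)
    sizes[shapes == "compact-blob"] <-
      runif(sum(shapes == "compact-blob"), 7, 9)
    lens <- ifelse(shapes == "irregular-elongated",
                   runif(n_distractors, 40, 70), 0)
    dirs <- matrix(0, n_distractors, 3)
    ne <- which(shapes == "irregular-elongated")
    if (length(ne)) {
      v <- matrix(rnorm(3 * length(ne)), ncol = 3)
      v[, 1] <- v[, 1] * 0.2          # filaments run mostly laterally
      v <- v / sqrt(rowSums(v^2))
      dirs[ne, ] <- v
    }
    # clearance of a segment (or point, len = 0) from every soma surface
    clears_somata <- function(p0, p1, reach) {
      if (!nrow(cmat)) return(TRUE)
      dseg <- p1 - p0
      L2 <- sum(dseg^2)
      t <- if (L2 > 0) {
        pmin(pmax(((cmat[, 1] - p0[1]) * dseg[1] +
                     (cmat[, 2] - p0[2]) * dseg[2] +
                     (cmat[, 3] - p0[3]) * dseg[3]) / L2, 0), 1)
      } else rep(0, nrow(cmat))
      near <- cbind(p0[1] + t * dseg[1], p0[2] + t * dseg[2],
                    p0[3] + t * dseg[3])
      all(sqrt(rowSums((cmat - near)^2)) >= cells$radius_um + reach + 1)
    }
    ctrs <- matrix(NA_real_, n_distractors, 3)
    for (i in seq_len(n_distractors)) {
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > 4000) stop("could not place distractors away from cells")
        cand <- 8 + runif(3) * (fd - 16)
        if (shapes[i] == "irregular-elongated") {
          p0 <- cand - lens[i] / 2 * dirs[i, ]
          p1 <- cand + lens[i] / 2 * dirs[i, ]
          ok <- clears_somata(p0, p1, 2 * sizes[i])
        } else {
          ok <- clears_somata(cand, cand, sizes[i])
        }
        if (ok && i > 1L) {
          d2d <- (ctrs[seq_len(i - 1L), 1] - cand[1])^2 +
            (ctrs[seq_len(i - 1L), 2] - cand[2])^2 +
            (ctrs[seq_len(i - 1L), 3] - cand[3])^2
          ok <- min(d2d, na.rm = TRUE) >= 8^2
        }
        if (ok) break
      }
      ctrs[i, ] <- cand
    }
    d <- data.frame(
      center_z_um = ctrs[, 1],
      center_y_um = ctrs[, 2],
      center_x_um = ctrs[, 3],
      shape = shapes,
      size_um = NA_real_, length_um = 0,
      dir_z = 0, dir_y = 0, dir_x = 0,
      amplitude = rlnorm(n_distractors, log(6000), 0.3),
      true_ratio = runif(n_distractors, ratio_low, ratio_high))
    d$size_um <- sizes
    d$length_um <- lens
    d$dir_z <- dirs[, 1]
    d$dir_y <- dirs[, 2]
    d$dir_x <- dirs[, 3]
    scene$distractors <- rbind(scene$distractors, d)
  })
  scene
}

#' Scale every cell's true ratio by a global factor
#'
#' Emulates pharmacological gamma-secretase inhibition, which shifts the
#' population 720/670 ratio without touching distractor objects.
#'
#' @param scene A `fret_scene`.
#' @param factor Positive multiplicative factor applied to all cell ratios.
#' @return The modified scene.
#' @export
apply_global_ratio_scaling <- function(scene, factor) {
  stopifnot(inherits(scene, "fret_scene"), factor > 0)
  scene$cells$true_ratio <- scene$cells$true_ratio * factor
  scene
}

#' Randomly permute true ratios across cell positions
#'
#' Keeps the multiset of per-cell ratios but destroys their spatial
#' arrangement, producing a matched null scene in which no neighbour
#' correlation should be detectable.
#'
#' @param scene A `fret_scene` with at least two cells.
#' @param seed Integer seed; defaults to the scene's shuffle sub-stream.
#' @return The scene with shuffled ratios.
#' @export
shuffle_ratio_positions <- function(scene, seed = NULL) {
  stopifnot(inherits(scene, "fret_scene"), nrow(scene$cells) >= 2)
  seed <- seed %||% scene$stage_seeds[["shuffle"]]
  with_seed(seed, {
    scene$cells$true_ratio <- sample(scene$cells$true_ratio)
  })
  scene
}

#' Ground-truth neighbour correlation of a scene
#'
#' Computes the Pearson correlation between each cell's true ratio and the
#' mean true ratio of its neighbours, using true centres and bypassing
#' imaging entirely.  It shares the neighbourhood and correlation code path
#' with the image-derived analysis ([correlate_with_neighbors()]), so any
#' discrepancy between the two isolates the imaging stages.
#'
#' @param scene A `fret_scene` with at least three cells.
#' @param spec A [neighborhood_spec()].
#' @param alpha Significance level.
#' @return A `fret_neighbor_cor` object (see [correlate_with_neighbors()]).
#' @export
oracle_neighbor_correlation <- function(scene, spec = neighborhood_spec(),
                                        alpha = 0.001) {
  stopifnot(inherits(scene, "fret_scene"))
  if (nrow(scene$cells) < 3) {
    stop("need at least 3 cells for a neighbour correlation")
  }
  correlate_with_neighbors(truth_records(scene), spec, alpha = alpha)
}

# ground-truth cells presented as CellRecords (the shared spatial-analysis
# code path then applies unchanged)
truth_records <- function(scene) {
  cells <- scene$cells
  data.frame(label = seq_len(nrow(cells)),
             volume_vox = NA_integer_,
             centroid_z_um = cells$center_z_um,
             centroid_y_um = cells$center_y_um,
             centroid_x_um = cells$center_x_um,
             mean_670 = cells$donor_amplitude,
             mean_720 = cells$donor_amplitude * cells$true_ratio,
             ratio_720_670 = cells$true_ratio,
             excluded_reason = "none")
}

#' Write / read a scene ground-truth file
#'
#' Scenes serialise to JSON (cells, distractors, field parameters, seeds) so
#' a rendered stack can always be matched back to its ground truth.
#'
#' @param scene A `fret_scene`.
#' @param path Output JSON path.
#' @return `write_scene` returns `path` invisibly; `read_scene` returns the
#'   `fret_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "fret_scene"))
  x <- unclass(scene)
  x$field_params <- unclass(x$field_params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cells <- as.data.frame(x$cells)
  x$distractors <- if (length(x$distractors) == 0 ||
                       is.null(x$distractors$center_z_um)) {
    empty_distractors()
  } else as.data.frame(x$distractors)
  x$field_params <- do.call(ratio_field_params, x$field_params)
  x$stage_seeds <- unlist(x$stage_seeds)
  structure(x, class = "fret_scene")
}
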