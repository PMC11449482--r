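# Spatial neighbour statistics: pairwise distances, kNN / fixed-radius
# neighbourhoods, neighbour-mean ratios, Pearson correlation with a
# parametric p and a seeded permutation null.

#' Neighbourhood specification
#'
#' @param mode `"knn"` (k nearest cells by centroid distance) or `"radius"`
#'   (all cells within a fixed distance).
#' @param k Number of neighbours in knn mode (default 5; 2 and 10 are the
#'   standard alternates).
#' @param radius_um Inclusive neighbour radius in um for radius mode
#'   (default 20).
#' @return An object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(mode = c("knn", "radius"), k = 5,
                              radius_um = 20) {
  mode <- match.arg(mode)
  if (mode == "knn") stopifnot(k >= 1) else stopifnot(radius_um > 0)
  structure(list(mode = mode, k = as.integer(k), radius_um = radius_um),
            class = "neighborhood_spec")
}

spec_label <- function(spec) {
  if (spec$mode == "knn") sprintf("knn%d", spec$k)
  else sprintf("radius%g", spec$radius_um)
}

#' Pairwise 3-D distances between cell centroids
#'
#' @param centroids_um Matrix (or data frame) with one row per cell and
#'   three columns `(z, y, x)` in um.
#' @return Symmetric matrix of Euclidean distances in um, zero diagonal.
#' @export
pairwise_distances <- function(centroids_um) {
  m <- as.matrix(centroids_um)
  stopifnot(ncol(m) == 3, nrow(m) >= 2)
  as.matrix(dist(m))
}

records_centroids <- function(records, project_2d = FALSE) {
  m <- cbind(records$centroid_z_um, records$centroid_y_um,
             records$centroid_x_um)
  if (project_2d) m[, 1] <- 0
  m
}

#' Assign neighbourhoods and neighbour-mean ratios
#'
#' For each retained cell, finds its neighbours — the k nearest other cells
#' (ties at equal distance broken by ascending label) or all other cells
#' within `radius_um` (inclusive) — and averages their 720/670 ratios.
#' Cells are never their own neighbours; radius-mode cells with no
#' neighbour are marked unusable.
#'
#' @param records Retained CellRecord data frame.
#' @param spec A [neighborhood_spec()].
#' @param project_2d If `TRUE`, ignore the z coordinate (2-D projected
#'   distances, for sensitivity analysis).
#' @return Data frame with `label`, `usable`, `n_neighbors`,
#'   `neighbor_mean_ratio` and a list-column `neighbor_labels`.
#' @export
assign_neighbors <- function(records, spec = neighborhood_spec(),
                             project_2d = FALSE) {
  stopifnot(inherits(spec, "neighborhood_spec"))
  n <- nrow(records)
  if (spec$mode == "knn" && n < spec$k + 1) {
    stop(sprintf("knn with k = %d needs at least %d cells, have %d",
                 spec$k, spec$k + 1, n))
  }
  if (n < 2) stop("need at least 2 cells to assign neighbours")
  dmat <- pairwise_distances(records_centroids(records, project_2d))
  labs <- records$label
  ratio <- records$ratio_720_670
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dmat[i, ]
    if (spec$mode == "knn") {
      ord <- order(d, labs)                     # ties -> lower label
      ord <- ord[ord != i][seq_len(spec$k)]
      nb <- ord
    } else {
      nb <- which(d <= spec$radius_um)
      nb <- nb[nb != i]
    }
    out[[i]] <- nb
  }
  nn <- lengths(out)
  data.frame(label = labs,
             usable = nn >= if (spec$mode == "knn") spec$k else 1L,
             n_neighbors = nn,
             neighbor_mean_ratio = vapply(out, function(ix) {
               if (length(ix)) mean(ratio[ix]) else NA_real_
             }, numeric(1)),
             neighbor_labels = I(lapply(out, function(ix) labs[ix])))
}

#' Pearson correlation with a parametric two-sided p-value
#'
#' Sample Pearson r with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom.  Zero variance in either variable makes r
#' undefined; this is reported explicitly (`degenerate = TRUE`, r = NA)
#' rather than as a silent NaN.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return An object of class `fret_cor` with elements `r`, `p_value`, `n`,
#'   `degenerate`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n = n,
                          degenerate = TRUE), class = "fret_cor"))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
                 degenerate = FALSE), class = "fret_cor")
}

#' @importFrom stats sd
#' @export
print.fret_cor <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Pearson correlation undefined (zero variance), n = %d\n", x$n))
  } else {
    cat(sprintf("Pearson r = %.4f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
    if (!is.null(x$significant)) {
      cat(sprintf("  %s at alpha = %g\n",
                  if (x$significant) "significant" else "not significant",
                  x$alpha))
    }
  }
  invisible(x)
}

#' Correlate each cell's ratio with its neighbours' mean ratio
#'
#' The cell-by-cell spatial analysis: x is each usable cell's 720/670
#' ratio, y the mean ratio of its neighbours under `spec`; returns the
#' Pearson correlation, significance at `alpha`, and the scatter table.
#'
#' @param records Retained CellRecord data frame.
#' @param spec A [neighborhood_spec()].
#' @param alpha Significance level (default 0.001).
#' @param project_2d Passed to [assign_neighbors()].
#' @return An object of class `fret_neighbor_cor` (also `fret_cor`):
#'   `r`, `p_value`, `n`, `significant`, `alpha`, `spec`, and `table` with
#'   one row per usable cell.
#' @export
correlate_with_neighbors <- function(records, spec = neighborhood_spec(),
                                     alpha = 0.001, project_2d = FALSE) {
  asg <- assign_neighbors(records, spec, project_2d)
  use <- asg$usable
  if (sum(use) < 3) {
    stop(sprintf("only %d usable cells under %s; need at least 3",
                 sum(use), spec_label(spec)))
  }
  idx <- match(asg$label[use], records$label)
  x <- records$ratio_720_670[idx]
  y <- asg$neighbor_mean_ratio[use]
  co <- pearson_correlation(x, y)
  structure(list(r = co$r, p_value = co$p_value, n = co$n,
                 degenerate = co$degenerate,
                 significant = isTRUE(co$p_value < alpha),
                 alpha = alpha, spec = spec,
                 table = data.frame(label = asg$label[use], ratio = x,
                                    neighbor_mean_ratio = y)),
            class = c("fret_neighbor_cor", "fret_cor"))
}

#' @export
#' @importFrom graphics abline plot
plot.fret_neighbor_cor <- function(x, ...) {
  plot(x$table$ratio, x$table$neighbor_mean_ratio,
       xlab = "720/670 ratio (cell)",
       ylab = sprintf("mean 720/670 ratio (%s neighbours)",
                      spec_label(x$spec)),
       main = sprintf("r = %.3f, p = %.2g, n = %d", x$r, x$p_value, x$n),
       pch = 19, col = grDevices::adjustcolor("steelblue", 0.7), ...)
  if (!x$degenerate) abline(stats::lm(neighbor_mean_ratio ~ ratio,
                                      data = x$table), col = "firebrick")
  invisible(x)
}

#' Permutation null for the neighbour correlation
#'
#' Permutes the cell ratios across the fixed cell positions `n_perm` times,
#' recomputing the neighbour means and Pearson r for each permutation, and
#' reports the empirical two-sided p-value
#' `(1 + #permutations with |r| >= |r_obs|) / (n_perm + 1)`.  This is the
#' recommended confirmatory test: it conditions on the observed geometry
#' and ratio distribution, assuming only exchangeability under the null.
#'
#' @param records Retained CellRecord data frame.
#' @param spec A [neighborhood_spec()].
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed.
#' @return A list: `p_empirical`, `r_obs`, `r_null` (the permuted r's),
#'   `n_perm`.
#' @export
permutation_null <- function(records, spec = neighborhood_spec(),
                             n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99)
  asg <- assign_neighbors(records, spec)
  use <- which(asg$usable)
  if (length(use) < 3) stop("fewer than 3 usable cells")
  ratio <- records$ratio_720_670[match(asg$label, records$label)]
  nb_idx <- lapply(asg$neighbor_labels, match, table = asg$label)
  y_obs <- vapply(nb_idx[use], function(ix) mean(ratio[ix]), numeric(1))
  r_obs <- suppressWarnings(stats::cor(ratio[use], y_obs))
  n <- length(ratio)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  })
  V <- matrix(ratio[perm], n, n_perm)             # permuted values, n x B
  X <- V[use, , drop = FALSE]
  cnt <- lengths(nb_idx[use])
  Y <- matrix(0, length(use), n_perm)
  for (k in seq_len(max(cnt))) {                  # ragged neighbour sums
    sel <- which(cnt >= k)
    idx <- vapply(nb_idx[use][sel], `[[`, integer(1), k)
    Y[sel, ] <- Y[sel, ] + V[idx, , drop = FALSE]
  }
  Y <- Y / cnt
  cx <- sweep(X, 2, colMeans(X))
  cy <- sweep(Y, 2, colMeans(Y))
  r_null <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  p <- (1 + sum(abs(r_null) >= abs(r_obs), na.rm = TRUE)) / (n_perm + 1)
  list(p_empirical = p, r_obs = r_obs, r_null = r_null, n_perm = n_perm)
}
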