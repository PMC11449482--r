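# 3-D cell-body segmentation: iterative thresholding over a descending
# quantile sweep with an MSER-style stability criterion, then pruning by
# volume band and morphological opening.

#' Build a component tree over a descending threshold sweep
#'
#' Thresholds are `levels` evenly spaced intensity values between the 1st
#' percentile and the maximum of the volume's nonzero intensities (ladder
#' `"linear"`, the default — the uniform gray-level steps classic MSER
#' assumes), or `levels` evenly spaced quantiles of the nonzero-intensity
#' distribution (ladder `"quantile"`; with noise-dominated histograms this
#' concentrates levels in the background and biases stability towards
#' halo-sized regions).  The sweep runs from the highest threshold down.
#' At each threshold the
#' 26-connected components of `volume >= t` are tracked incrementally
#' (union-find); components are linked across adjacent thresholds by
#' containment, forming a forest.  When two components merge, the larger
#' one keeps its identity and the smaller closes with a parent link to the
#' survivor, so every node is one extremal region followed through the
#' sweep.
#'
#' MSER stability is evaluated during the sweep: at level `l` a node of
#' volume `V(l)` has stability `(V(l+delta) - V(l-delta)) / V(l)` (relative
#' volume change across `delta_levels` adjacent levels, one-sided at chain
#' ends), and the node's most stable level with volume inside
#' `[volume_min_vox, volume_max_vox]` is recorded.
#'
#' @param volume Single-channel 3-D array `(z, y, x)`.
#' @param levels Number of quantile threshold levels (>= 3).
#' @param delta_levels Stability half-window in levels.
#' @param volume_min_vox,volume_max_vox Inclusive candidate volume band.
#' @param keep_records If `TRUE`, also return the full per-level component
#'   table (node, level, volume) — intended for small volumes and
#'   diagnostics.
#' @param ladder `"log"` (geometrically spaced intensity values — every
#'   object sees the same relative threshold resolution regardless of its
#'   brightness), `"linear"` (evenly spaced values) or `"quantile"`
#'   (evenly spaced quantiles).
#' @return An object of class `component_tree`: thresholds, node table,
#'   optional records, and the input volume (needed to paint regions).
#' @export
build_component_tree <- function(volume, levels = 100, delta_levels = 1,
                                 volume_min_vox = 300, volume_max_vox = 10000,
                                 keep_records = FALSE,
                                 ladder = c("log", "linear", "quantile")) {
  stopifnot(length(dim(volume)) == 3, levels >= 3,
            volume_min_vox <= volume_max_vox)
  ladder <- match.arg(ladder)
  nz <- volume[volume > 0]
  if (length(nz) == 0) {
    return(structure(list(thresholds = numeric(0),
                          nodes = data.frame(), records = NULL,
                          volume = volume, dims = dim(volume),
                          levels = levels, delta_levels = delta_levels,
                          volume_min_vox = volume_min_vox,
                          volume_max_vox = volume_max_vox),
                     class = "component_tree"))
  }
  thr <- if (ladder == "quantile") {
    unname(quantile(nz, probs = seq_len(levels) / (levels + 1), type = 7))
  } else {
    lo <- unname(quantile(nz, 0.01, type = 7))
    hi <- max(nz)
    t <- if (ladder == "linear") {
      seq(lo, hi, length.out = levels)
    } else {
      exp(seq(log(lo), log(hi), length.out = levels))
    }
    # pin the endpoints exactly (exp(log(x)) can overshoot by an ulp)
    t[1] <- lo
    t[levels] <- hi
    pmin(pmax(t, lo), hi)
  }
  thr <- rev(unique(thr))                       # strictly descending
  res <- ct_build_cpp(volume, dim(volume), thr, as.integer(delta_levels),
                      volume_min_vox, volume_max_vox,
                      emit_records = isTRUE(keep_records))
  nodes <- as.data.frame(res$nodes)
  records <- if (keep_records) as.data.frame(res$records) else NULL
  structure(list(thresholds = thr, nodes = nodes, records = records,
                 volume = volume, dims = dim(volume), levels = levels,
                 delta_levels = delta_levels,
                 volume_min_vox = volume_min_vox,
                 volume_max_vox = volume_max_vox),
            class = "component_tree")
}

#' @export
print.component_tree <- function(x, ...) {
  cat(sprintf("component_tree: %d thresholds, %d nodes (%d with an in-band level)\n",
              length(x$thresholds), nrow(x$nodes),
              if (nrow(x$nodes)) sum(x$nodes$best_level > 0) else 0L))
  invisible(x)
}

#' Select maximally stable regions from a component tree
#'
#' Every node with an in-band most-stable level is a candidate.  Candidates
#' are ranked by stability (smaller is more stable), ties broken toward the
#' smaller volume (soma over soma-plus-halo) and then toward the higher
#' threshold — fully deterministic — and accepted greedily provided their
#' region does not nest with an already accepted region.  Accepted regions
#' are painted into a label volume by flood fill at their selected
#' threshold; labels are assigned in raster order of the regions' seed
#' voxels.
#'
#' @param tree A [build_component_tree()] result.
#' @param volume_min_vox,volume_max_vox Inclusive volume band; must equal
#'   the band the tree was built with (stability bookkeeping happens during
#'   the sweep).
#' @return A 3-D integer label volume (`LabelVolume`); 0 is background.
#'   Attribute `selection` holds the per-ROI node table.
#' @export
select_stable_regions <- function(tree, volume_min_vox = tree$volume_min_vox,
                                  volume_max_vox = tree$volume_max_vox) {
  stopifnot(inherits(tree, "component_tree"))
  if (volume_min_vox != tree$volume_min_vox ||
      volume_max_vox != tree$volume_max_vox) {
    stop("volume band differs from the one the tree was built with; rebuild")
  }
  empty <- array(0L, tree$dims)
  if (!nrow(tree$nodes)) {
    attr(empty, "selection") <- data.frame()
    return(empty)
  }
  nodes <- tree$nodes
  cand <- which(nodes$best_level > 0)
  if (!length(cand)) {
    attr(empty, "selection") <- data.frame()
    return(empty)
  }
  ord <- cand[order(nodes$best_stability[cand], nodes$best_volume[cand],
                    nodes$best_level[cand])]
  accepted <- logical(nrow(nodes))
  anc_min_level <- new.env(parent = emptyenv())
  keep <- integer(0)
  for (j in ord) {
    conflict <- FALSE
    cur <- j
    repeat {
      m <- nodes$close_level[cur]
      anc <- nodes$parent[cur]
      if (anc == 0) break
      if (accepted[anc] && nodes$best_level[anc] >= m) { conflict <- TRUE; break }
      cur <- anc
    }
    if (!conflict) {
      am <- get0(as.character(j), envir = anc_min_level)
      if (!is.null(am) && nodes$best_level[j] >= am) conflict <- TRUE
    }
    if (conflict) next
    accepted[j] <- TRUE
    keep <- c(keep, j)
    # register j's ancestors with the merge level at which j's lineage joins
    cur <- j
    repeat {
      m <- nodes$close_level[cur]
      anc <- nodes$parent[cur]
      if (anc == 0) break
      key <- as.character(anc)
      old <- get0(key, envir = anc_min_level)
      assign(key, if (is.null(old)) m else min(old, m), envir = anc_min_level)
      cur <- anc
    }
  }
  sel <- data.frame(node = keep,
                    level = nodes$best_level[keep],
                    threshold = tree$thresholds[nodes$best_level[keep]],
                    volume_vox = nodes$best_volume[keep],
                    stability = nodes$best_stability[keep],
                    rep_voxel = nodes$rep_voxel[keep])
  sel <- sel[order(sel$rep_voxel), , drop = FALSE]
  sel$label <- seq_len(nrow(sel))
  labels <- ct_paint_cpp(tree$volume, tree$dims, sel$rep_voxel,
                         sel$threshold, sel$label)
  attr(labels, "selection") <- sel
  labels
}

#' Morphological opening filter on a label volume
#'
#' Opens every ROI's binary mask in 3-D with a ball of the given radius
#' (voxel units) and replaces the ROI by its opened mask; ROIs whose opened
#' volume falls below `volume_min_vox` are removed.  Opening is
#' anti-extensive, so ROIs only shrink and remain pairwise disjoint.  If
#' opening disconnects an ROI, only its largest 26-connected piece is kept
#' (ties broken by raster order).
#'
#' @param labels 3-D integer label volume.
#' @param radius_vox Ball radius in voxels (default 2).
#' @param volume_min_vox Minimum surviving volume (default 300).
#' @return The opened label volume; attribute `removed` is a data frame of
#'   the dropped ROIs (label, volume before/after opening).
#' @export
opening_filter <- function(labels, radius_vox = 2, volume_min_vox = 300) {
  stopifnot(length(dim(labels)) == 3, radius_vox >= 1)
  dims <- dim(labels)
  opened <- open_labels_ball_cpp(as.integer(labels), dims,
                                 as.integer(radius_vox))
  pos0 <- which(labels > 0)
  labs <- sort(unique(labels[pos0]))
  nb <- if (length(labs)) max(labs) else 0L
  vol_before <- tabulate(labels[pos0], nbins = nb)
  pos <- which(opened > 0)
  vol_after <- tabulate(opened[pos], nbins = nb)
  idx_by_lab <- split(pos, opened[pos])
  # opening can split a mask: keep only the largest connected piece
  for (nm in names(idx_by_lab)) {
    lab <- as.integer(nm)
    idx <- idx_by_lab[[nm]]
    sub <- largest_component_indices(opened, dims, lab, idx)
    if (length(sub) < length(idx)) {
      opened[setdiff(idx, sub)] <- 0L
      idx_by_lab[[nm]] <- sub
      vol_after[lab] <- length(sub)
    }
  }
  removed <- labs[vol_after[labs] < volume_min_vox]
  if (length(removed)) {
    opened[unlist(idx_by_lab[as.character(removed)], use.names = FALSE)] <- 0L
  }
  attr(opened, "removed") <- data.frame(label = removed,
                                        volume_before = vol_before[removed],
                                        volume_after = vol_after[removed])
  opened
}

# largest 26-connected piece of one label's mask (bounding-box local)
largest_component_indices <- function(labels, dims, lab, idx) {
  coord <- arrayInd(idx, dims)
  lo <- apply(coord, 2, min); hi <- apply(coord, 2, max)
  sub_dims <- hi - lo + 1L
  mask <- array(FALSE, sub_dims)
  local <- cbind(coord[, 1] - lo[1] + 1L, coord[, 2] - lo[2] + 1L,
                 coord[, 3] - lo[3] + 1L)
  mask[local] <- TRUE
  cc <- cc_label_26(mask, sub_dims)
  if (max(cc) <= 1) return(idx)
  sizes <- tabulate(cc[cc > 0])
  best <- which.max(sizes)                      # ties: lowest id = raster order
  keep_local <- cc[local] == best
  idx[keep_local]
}

#' Segment cell bodies in a preprocessed stack
#'
#' Convenience wrapper: sums the two channels (maximising SNR without
#' biasing the ratio), builds the component tree, selects stable regions in
#' the volume band, and applies the opening filter.
#'
#' @param stack A preprocessed [image_stack()].
#' @param config A [pipeline_config()].
#' @param channel `"sum"` (default), `"donor"` or `"acceptor"`: the volume
#'   segmentation runs on.
#' @return Label volume with attributes `selection` and `removed`.
#' @export
segment_stack <- function(stack, config = pipeline_config(),
                          channel = c("sum", "donor", "acceptor")) {
  channel <- match.arg(channel)
  v <- switch(channel,
              sum = channel_volume(stack, 1) + channel_volume(stack, 2),
              donor = channel_volume(stack, 1),
              acceptor = channel_volume(stack, 2))
  tree <- build_component_tree(v, levels = config$threshold_levels,
                               delta_levels = config$delta_levels,
                               volume_min_vox = config$volume_min_vox,
                               volume_max_vox = config$volume_max_vox)
  labels <- select_stable_regions(tree)
  sel <- attr(labels, "selection")
  opened <- opening_filter(labels, radius_vox = config$opening_radius_vox,
                           volume_min_vox = config$volume_min_vox)
  attr(opened, "selection") <- sel
  opened
}
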