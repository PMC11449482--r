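# Per-ROI quantification: channel intensities, 720/670 ratio, centroid,
# and the ratio-threshold exclusion of autofluorescent objects.

#' Measure ROI intensities and 720/670 ratios
#'
#' For every labelled ROI, computes the mean donor (670) and acceptor (720)
#' intensity over the ROI's voxels on the preprocessed stack, the ratio of
#' means `mean_720 / mean_670`, and the unweighted centroid in physical um
#' (first z-plane centre at z = 0).  ROIs whose donor mean is zero cannot
#' have a ratio and are flagged excluded with a warning.
#'
#' @param stack The preprocessed [image_stack()] intensities are read from.
#' @param labels 3-D integer label volume of the same `(z, y, x)` shape.
#' @return A CellRecord data frame with columns `label, volume_vox,
#'   centroid_z_um, centroid_y_um, centroid_x_um, mean_670, mean_720,
#'   ratio_720_670, excluded_reason` plus a logical `touches_border`.
#' @export
measure_rois <- function(stack, labels) {
  stopifnot(inherits(stack, "image_stack"),
            identical(dim(stack$data)[2:4], dim(labels)))
  st <- label_stats_cpp(as.integer(labels), dim(labels),
                        channel_volume(stack, 1), channel_volume(stack, 2))
  present <- which(st$volume > 0)
  n <- st$volume[present]
  vs <- stack$voxel_size_um
  rec <- data.frame(
    label = present,
    volume_vox = n,
    centroid_z_um = st$sum_z[present] / n * vs[1],
    centroid_y_um = st$sum_y[present] / n * vs[2],
    centroid_x_um = st$sum_x[present] / n * vs[3],
    mean_670 = st$sum_670[present] / n,
    mean_720 = st$sum_720[present] / n,
    excluded_reason = "none",
    touches_border = st$touches_border[present],
    stringsAsFactors = FALSE)
  rec$ratio_720_670 <- ifelse(rec$mean_670 > 0,
                              rec$mean_720 / rec$mean_670, NA_real_)
  bad <- is.na(rec$ratio_720_670)
  if (any(bad)) {
    warning(sprintf("%d ROI(s) with zero donor signal excluded", sum(bad)))
    rec$excluded_reason[bad] <- "ratio"
  }
  rec[, c("label", "volume_vox", "centroid_z_um", "centroid_y_um",
          "centroid_x_um", "mean_670", "mean_720", "ratio_720_670",
          "excluded_reason", "touches_border")]
}

#' Exclude low-ratio (autofluorescent) ROIs
#'
#' Records with `ratio_720_670` strictly below the threshold are moved to
#' the excluded set with reason `ratio`; a ratio exactly equal to the
#' threshold is retained.  Only records not already excluded are
#' considered.
#'
#' @param records A CellRecord data frame.
#' @param ratio_threshold Exclusion threshold (default 1.5).
#' @return A list with elements `retained` and `excluded`.
#' @export
filter_by_ratio <- function(records, ratio_threshold = 1.5) {
  stopifnot(ratio_threshold > 0)
  live <- records$excluded_reason == "none"
  drop <- live & !is.na(records$ratio_720_670) &
    records$ratio_720_670 < ratio_threshold
  records$excluded_reason[drop] <- "ratio"
  list(retained = records[records$excluded_reason == "none", , drop = FALSE],
       excluded = records[records$excluded_reason != "none", , drop = FALSE])
}

#' Ratio-versus-intensity scatter summary
#'
#' Emits the per-ROI `(mean_720, mean_670, ratio)` table together with the
#' Pearson correlation between donor intensity and ratio — the check that
#' biosensor expression level does not drive the measured ratio.  With
#' degenerate (zero) variance the correlation is reported as undefined
#' rather than silently NaN.
#'
#' @param records Retained CellRecord data frame (>= 3 rows).
#' @return A list: `table` (per-record values) and `cor` (a `fret_cor`).
#' @export
ratio_scatter_summary <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 records")
  tab <- records[, c("label", "mean_720", "mean_670", "ratio_720_670")]
  list(table = tab,
       cor = pearson_correlation(records$mean_670, records$ratio_720_670))
}
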