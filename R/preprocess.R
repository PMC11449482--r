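# Preprocessing: background removal and impulse-noise suppression.
#
# Both operations are applied per 2-D z-slice with a disk footprint by
# default (lateral illumination structure, coarse z-sampling); a 3-D
# spherical-element mode is available behind `three_d`.  Both channels are
# always filtered with identical parameters so the 720/670 ratio is not
# biased by asymmetric smoothing, and both operations commute with positive
# intensity scaling, so downstream ratios are unaffected by global gain.

# apply f(volume) to each channel of a stack
map_channels <- function(stack, f) {
  d <- dim(stack$data)
  out <- stack
  for (ch in 1:2) {
    v <- channel_volume(stack, ch)
    out$data[ch, , , ] <- f(v)
  }
  out
}

#' White top-hat background subtraction
#'
#' Removes uneven background illumination: the grayscale opening of each
#' 2-D z-slice (disk structuring element of the given radius) is subtracted
#' from the slice, leaving bright structures smaller than the element.
#' Output is non-negative and never exceeds the input.  Applied identically
#' to both channels.
#'
#' @param stack An [image_stack()].
#' @param radius_vox Structuring-element radius in voxels (default 7).
#' @param three_d If `TRUE`, use a 3-D ball element instead of per-slice
#'   disks (slower; intended for isotropic data).
#' @return The filtered [image_stack()].
#' @export
tophat_subtract <- function(stack, radius_vox = 7, three_d = FALSE) {
  stopifnot(inherits(stack, "image_stack"), radius_vox >= 1)
  d <- dim(stack$data)
  if (!three_d && (2 * radius_vox + 1 > d[3] || 2 * radius_vox + 1 > d[4])) {
    stop("top-hat radius exceeds slice extent")
  }
  if (three_d) {
    map_channels(stack, function(v) {
      er <- gray_ball_cpp(v, dim(v), radius_vox, 0L)
      op <- gray_ball_cpp(er, dim(v), radius_vox, 1L)
      pmax(v - op, 0)
    })
  } else {
    map_channels(stack, function(v) {
      er <- gray_disk_cpp(v, dim(v), radius_vox, 0L)
      op <- gray_disk_cpp(er, dim(v), radius_vox, 1L)
      pmax(v - op, 0)
    })
  }
}

#' Median noise filtering
#'
#' Replaces each voxel by the median of its disk-shaped 2-D neighbourhood
#' (per z-slice; window clipped at borders, even-sized windows averaged as
#' in [stats::median()]).  Idempotent on flat regions.  Applied identically
#' to both channels.
#'
#' @param stack An [image_stack()].
#' @param radius_vox Footprint radius in voxels (default 3).
#' @param three_d If `TRUE`, use a 3-D ball footprint.
#' @return The filtered [image_stack()].
#' @export
median_filter <- function(stack, radius_vox = 3, three_d = FALSE) {
  stopifnot(inherits(stack, "image_stack"), radius_vox >= 1)
  if (three_d) {
    map_channels(stack, function(v) gray_ball_cpp(v, dim(v), radius_vox, 2L))
  } else {
    map_channels(stack, function(v) median_disk_cpp(v, dim(v), radius_vox))
  }
}
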