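#' Two-channel 3D image stack
#'
#' The package's in-memory imaging container: a 4-D intensity array ordered
#' `(channel, z, y, x)` with exactly two channels — donor (miRFP670) first,
#' acceptor (miRFP720) second — and physical voxel sizes `(dz, dy, dx)` in
#' micrometres.  Voxel indices are 0-based in physical terms: the centre of
#' the first z-plane is at z = 0 um.
#'
#' @param data Either a 4-D array `(2, z, y, x)` or a list of two 3-D arrays
#'   `(z, y, x)` named or ordered donor, acceptor.
#' @param voxel_size_um Numeric length-3, `(dz, dy, dx)` in um, all positive.
#' @param channels Channel names; fixed order, donor first.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size_um,
                        channels = c("donor_670", "acceptor_720")) {
  if (is.list(data)) {
    stopifnot(length(data) == 2, identical(dim(data[[1]]), dim(data[[2]])))
    d3 <- dim(data[[1]])
    stopifnot(length(d3) == 3)
    arr <- array(0, c(2, d3))
    arr[1, , , ] <- data[[1]]
    arr[2, , , ] <- data[[2]]
    data <- arr
  }
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (dim(data)[1] != 2) {
    stop(sprintf("image_stack requires exactly 2 channels, got %d", dim(data)[1]))
  }
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0),
            length(channels) == 2)
  if (min(data) < 0) stop("intensities must be non-negative")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 channels = channels),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d channels x %d z x %d y x %d x voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (dz, dy, dx): %s um\n",
              paste(signif(x$voxel_size_um, 4), collapse = ", ")))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

# channel volume as a (z, y, x) array
channel_volume <- function(stack, channel) {
  i <- if (is.character(channel)) match(channel, stack$channels) else channel
  stopifnot(!is.na(i), i %in% c(1, 2))
  v <- stack$data[i, , , , drop = TRUE]
  dim(v) <- dim(stack$data)[2:4]
  v
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack to a multi-page TIFF
#'
#' Pages are ordered channel-fastest (donor z1, acceptor z1, donor z2, ...),
#' the ImageJ hyperstack convention.  Samples are stored as 32-bit unsigned
#' integers scaled by a per-file intensity scale; a JSON sidecar
#' (`<path>.json`) records the voxel sizes, channel names, page layout and
#' intensity scale.  Integer data up to 2^32 - 1 round-trips exactly;
#' arbitrary floating data round-trips to within 2^-32 of the full-scale
#' value.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  smax <- max(stack$data)
  is_int <- max(abs(stack$data - round(stack$data))) == 0
  scale <- if (is_int && smax <= 2^32 - 1) 2^32 - 1 else if (smax > 0) smax else 1
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      pg <- stack$data[ch, z, , , drop = TRUE] / scale
      dim(pg) <- d[3:4]
      pages[[k]] <- pg
      k <- k + 1L
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "deflate"), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write TIFF to ", path, ": ", attr(ok, "condition")$message)
  }
  meta <- list(format = "fretseg-stack", n_channels = d[1], n_z = d[2],
               n_y = d[3], n_x = d[4],
               channels = stack$channels,
               voxel_size_um = stack$voxel_size_um,
               intensity_scale = scale, page_order = "channel_fastest")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# pull voxel sizes out of OME-XML or ImageJ-style TIFF descriptions
parse_tiff_voxel_size <- function(info) {
  desc <- attr(info, "description", exact = TRUE)
  out <- c(NA_real_, NA_real_, NA_real_)
  if (!is.null(desc) && length(desc) == 1 && nzchar(desc)) {
    if (grepl("PhysicalSize", desc)) {            # OME-XML (preferred)
      g <- function(tag) {
        m <- regmatches(desc, regexec(paste0(tag, '="([0-9.eE+-]+)"'), desc))[[1]]
        if (length(m) == 2) as.numeric(m[2]) else NA_real_
      }
      out <- c(g("PhysicalSizeZ"), g("PhysicalSizeY"), g("PhysicalSizeX"))
    } else if (grepl("ImageJ", desc)) {
      m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
      if (length(m) == 2) out[1] <- as.numeric(m[2])
    }
  }
  xres <- attr(info, "x.resolution", exact = TRUE)
  yres <- attr(info, "y.resolution", exact = TRUE)
  if (is.na(out[3]) && !is.null(xres) && is.finite(xres) && xres > 0) {
    out[3] <- 1 / xres
  }
  if (is.na(out[2]) && !is.null(yres) && is.finite(yres) && yres > 0) {
    out[2] <- 1 / yres
  }
  out
}

# number of channels recorded in an ImageJ/OME description, if any
parse_tiff_channels <- function(info) {
  desc <- attr(info, "description", exact = TRUE)
  if (is.null(desc) || !length(desc) || !nzchar(desc[1])) return(NA_integer_)
  m <- regmatches(desc, regexec("channels=([0-9]+)", desc))[[1]]
  if (length(m) == 2) return(as.integer(m[2]))
  m <- regmatches(desc, regexec('SizeC="([0-9]+)"', desc))[[1]]
  if (length(m) == 2) return(as.integer(m[2]))
  NA_integer_
}

#' Read a two-channel image stack from TIFF
#'
#' Reads stacks written by [write_stack()] (using their JSON sidecar) as
#' well as foreign ImageJ/OME TIFFs, whose voxel sizes are taken from the
#' OME-XML `PhysicalSize*` attributes (preferred) or the ImageJ
#' `spacing=`/resolution tags.  An explicit `voxel_size_override` wins over
#' any metadata, with a notice.
#'
#' @param path TIFF path.
#' @param voxel_size_override Optional `(dz, dy, dx)` in um.
#' @param swap_channels If `TRUE`, swap the two channels on read (for files
#'   stored acceptor-first).  Never done silently.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, voxel_size_override = NULL, swap_channels = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (!identical(meta$format, "fretseg-stack")) meta <- NULL
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) stop("unreadable TIFF ", path, ": ", e$message))
  if (!is.list(pages)) pages <- list(pages)
  npg <- length(pages)
  nchan <- if (!is.null(meta)) meta$n_channels else parse_tiff_channels(pages[[1]])
  if (is.na(nchan) || is.null(nchan)) nchan <- if (npg >= 2 && npg %% 2 == 0) 2L else 1L
  if (nchan != 2) {
    stop(sprintf("expected a 2-channel stack, file has %d channel(s)", nchan))
  }
  if (npg %% 2 != 0) stop("odd page count for a 2-channel stack")
  nz <- npg %/% 2L
  pdim <- dim(pages[[1]])[1:2]
  arr <- array(0, c(2, nz, pdim[1], pdim[2]))
  for (z in seq_len(nz)) {
    for (ch in 1:2) {
      pg <- pages[[(z - 1) * 2 + ch]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]   # tolerate grey stored as RGB
      if (!is.null(meta)) {
        # our own files: 32-bit unsigned samples (as.is reads them signed)
        pg <- as.numeric(pg)
        pg[pg < 0] <- pg[pg < 0] + 2^32
        pg <- pg / (2^32 - 1) * meta$intensity_scale
      }
      arr[ch, z, , ] <- pg
    }
  }
  vs <- if (!is.null(meta)) meta$voxel_size_um else parse_tiff_voxel_size(pages[[1]])
  if (!is.null(voxel_size_override)) {
    if (!is.null(meta) || !all(is.na(vs))) {
      message("read_stack: voxel_size_override supersedes file metadata")
    }
    vs <- voxel_size_override
  }
  if (any(is.na(vs))) {
    stop("voxel sizes not found in TIFF metadata; pass voxel_size_override")
  }
  channels <- if (!is.null(meta)) meta$channels else c("donor_670", "acceptor_720")
  if (isTRUE(swap_channels)) {
    arr <- arr[c(2, 1), , , , drop = FALSE]
    channels <- rev(channels)
    message("read_stack: channels swapped on request")
  }
  image_stack(arr, voxel_size_um = vs, channels = channels)
}

#' Write a label volume to TIFF
#'
#' Integer labels are stored losslessly (16- or 32-bit depending on the
#' maximum label) with a JSON sidecar, one page per z-plane.
#'
#' @param labels 3-D integer array `(z, y, x)`; 0 is background.
#' @param voxel_size_um `(dz, dy, dx)` in um.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, voxel_size_um, path) {
  stopifnot(length(dim(labels)) == 3, min(labels) >= 0)
  d <- dim(labels)
  scale <- 2^32 - 1
  pages <- lapply(seq_len(d[1]), function(z) {
    pg <- labels[z, , , drop = TRUE] / scale
    dim(pg) <- d[2:3]
    pg
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate")
  meta <- list(format = "fretseg-labels", n_z = d[1], n_y = d[2], n_x = d[3],
               voxel_size_um = as.numeric(voxel_size_um),
               intensity_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  stopifnot(identical(meta$format, "fretseg-labels"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  arr <- array(0L, c(meta$n_z, meta$n_y, meta$n_x))
  for (z in seq_along(pages)) {
    pg <- as.numeric(pages[[z]])
    pg[pg < 0] <- pg[pg < 0] + 2^32
    arr[z, , ] <- as.integer(round(pg / (2^32 - 1) * meta$intensity_scale))
  }
  attr(arr, "voxel_size_um") <- meta$voxel_size_um
  arr
}

record_columns <- c("label", "volume_vox", "centroid_z_um", "centroid_y_um",
                    "centroid_x_um", "mean_670", "mean_720", "ratio_720_670",
                    "excluded_reason")

#' Write / read the per-cell results table
#'
#' CSV with one row per ROI and the fixed column order: `label, volume_vox,
#' centroid_z_um, centroid_y_um, centroid_x_um, mean_670, mean_720,
#' ratio_720_670, excluded_reason`.  Numeric values are written with 17
#' significant digits so a read round-trips to full double precision.
#'
#' @param records A CellRecord data frame (see [measure_rois()]).
#' @param path Output CSV path.
#' @return `write_records_table` returns `path` invisibly;
#'   `read_records_table` returns the data frame.
#' @export
write_records_table <- function(records, path) {
  stopifnot(all(record_columns %in% names(records)))
  df <- records[, record_columns, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(v) {
      if (is.na(v)) "NA" else if (v == round(v) && abs(v) < 2^53) {
        sprintf("%.0f", v)
      } else sprintf("%.17g", v)
    }, character(1))
  }
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_records_table
#' @export
read_records_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(label = "integer", volume_vox = "integer",
                                centroid_z_um = "numeric",
                                centroid_y_um = "numeric",
                                centroid_x_um = "numeric",
                                mean_670 = "numeric", mean_720 = "numeric",
                                ratio_720_670 = "numeric",
                                excluded_reason = "character"))
  df
}

#' Pseudo-colour ratio rendering
#'
#' Maximum-intensity projection (over z) of the label volume in which every
#' retained ROI is filled with a colour mapped from its 720/670 ratio;
#' excluded ROIs are omitted and the background is black.  A vertical colour
#' bar with the ratio limits is appended on the right.
#'
#' @param records CellRecord data frame; only rows with
#'   `excluded_reason == "none"` are drawn.
#' @param labels 3-D label volume `(z, y, x)`.
#' @param path Output PNG path.
#' @param ratio_limits Length-2 `(low, high)`; ratios are clamped to this
#'   range before colour mapping.  Defaults to the range of retained ratios.
#' @param palette Colour palette function name passed to
#'   [grDevices::hcl.colors()].
#' @return `path`, invisibly.
#' @export
render_pseudocolor <- function(records, labels, path, ratio_limits = NULL,
                               palette = "Viridis") {
  kept <- records[records$excluded_reason == "none", , drop = FALSE]
  if (is.null(ratio_limits)) {
    ratio_limits <- if (nrow(kept)) range(kept$ratio_720_670) else c(0, 1)
    if (diff(ratio_limits) == 0) ratio_limits <- ratio_limits + c(-0.5, 0.5)
  }
  stopifnot(ratio_limits[1] < ratio_limits[2])
  maxlab <- max(labels)
  lut <- rep(NA_real_, max(1, maxlab))
  lut[kept$label] <- pmin(pmax(kept$ratio_720_670, ratio_limits[1]),
                          ratio_limits[2])
  d <- dim(labels)
  # per-voxel ratio value, then max-project over z
  val <- array(NA_real_, d)
  pos <- labels > 0
  val[pos] <- lut[labels[pos]]
  proj <- apply(val, c(2, 3), function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  ncol_map <- 256L
  cols <- grDevices::hcl.colors(ncol_map, palette)
  rgbm <- grDevices::col2rgb(cols) / 255
  img <- array(0, c(d[2], d[3], 3))
  idx <- !is.na(proj)
  ci <- pmin(ncol_map, 1L + as.integer((proj[idx] - ratio_limits[1]) /
                                         diff(ratio_limits) * (ncol_map - 1L)))
  for (k in 1:3) {
    plane <- img[, , k]
    plane[idx] <- rgbm[k, ci]
    img[, , k] <- plane
  }
  # colour bar: 12 px gap + 20 px bar, high ratio at top
  barw <- 20L; gap <- 12L
  bar <- array(0, c(d[2], barw, 3))
  bi <- pmin(ncol_map, 1L + as.integer(rev(seq_len(d[2]) - 1) / (d[2] - 1) *
                                         (ncol_map - 1L)))
  for (k in 1:3) bar[, , k] <- matrix(rgbm[k, bi], d[2], barw)
  out <- array(0, c(d[2], d[3] + gap + barw, 3))
  out[, seq_len(d[3]), ] <- img
  out[, d[3] + gap + seq_len(barw), ] <- bar
  png::writePNG(out, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable parameters of the analysis with the published defaults:
#' top-hat radius 7, median radius 3, 100 threshold levels, ROI volume band
#' 300–10000 voxels (inclusive), opening radius 2, ratio threshold 1.5,
#' k = 5 nearest neighbours, 20 um neighbour radius, alpha = 0.001.
#'
#' @param tophat_radius_vox Top-hat structuring-element radius (voxels).
#' @param median_radius_vox Median-filter radius (voxels).
#' @param threshold_levels Number of quantile threshold levels in the sweep.
#' @param volume_min_vox,volume_max_vox Inclusive ROI volume band (voxels).
#' @param opening_radius_vox Ball radius of the 3-D morphological opening.
#' @param ratio_threshold ROIs with 720/670 ratio strictly below this are
#'   excluded as autofluorescent.
#' @param neighbor_k k of the primary kNN neighbourhood.
#' @param neighbor_radius_um Radius of the fixed-radius neighbourhood (um).
#' @param alpha Significance level.
#' @param delta_levels MSER stability half-window, in threshold levels.
#' @param exclude_border If `TRUE`, ROIs touching the stack border are
#'   excluded (reason `border`) instead of only being flagged.
#' @param seed Master seed for the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tophat_radius_vox = 7, median_radius_vox = 3,
                            threshold_levels = 100, volume_min_vox = 300,
                            volume_max_vox = 10000, opening_radius_vox = 2,
                            ratio_threshold = 1.5, neighbor_k = 5,
                            neighbor_radius_um = 20, alpha = 0.001,
                            delta_levels = 1, exclude_border = FALSE,
                            seed = 1) {
  stopifnot(tophat_radius_vox >= 1, median_radius_vox >= 1,
            threshold_levels >= 3, volume_min_vox >= 1,
            volume_min_vox <= volume_max_vox, opening_radius_vox >= 1,
            ratio_threshold > 0, neighbor_k >= 1, neighbor_radius_um > 0,
            alpha > 0, alpha < 1, delta_levels >= 1)
  structure(list(tophat_radius_vox = as.integer(tophat_radius_vox),
                 median_radius_vox = as.integer(median_radius_vox),
                 threshold_levels = as.integer(threshold_levels),
                 volume_min_vox = as.integer(volume_min_vox),
                 volume_max_vox = as.integer(volume_max_vox),
                 opening_radius_vox = as.integer(opening_radius_vox),
                 ratio_threshold = ratio_threshold,
                 neighbor_k = as.integer(neighbor_k),
                 neighbor_radius_um = neighbor_radius_um,
                 alpha = alpha,
                 delta_levels = as.integer(delta_levels),
                 exclude_border = isTRUE(exclude_border),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON by extension)
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @param config A [pipeline_config()].
#' @return `read_config` returns a [pipeline_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json")
  x <- x[intersect(names(x), names(formals(pipeline_config)))]
  do.call(pipeline_config, x)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
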