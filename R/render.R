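#' Optical and noise parameters for rendering
#'
#' @param psf_sigma_um Gaussian PSF sigma per axis `(z, y, x)` in um; zero
#'   disables blurring along that axis.
#' @param background_offset Uniform background level (photons/voxel), applied
#'   identically to both channels.
#' @param background_gradient_amplitude Amplitude of a smooth planar lateral
#'   gradient added to the background (uneven illumination).
#' @param attenuation_length_um Depth decay constant: signal at depth z is
#'   scaled by `exp(-z / attenuation_length_um)`.
#' @param read_noise_sd Standard deviation of additive Gaussian read noise.
#' @param shot_noise If `TRUE`, apply Poisson shot noise to the noise-free
#'   photon image (signal plus background).
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(psf_sigma_um = c(1.5, 0.5, 0.5),
                          background_offset = 2,
                          background_gradient_amplitude = 5,
                          attenuation_length_um = 60,
                          read_noise_sd = 1,
                          shot_noise = TRUE) {
  stopifnot(length(psf_sigma_um) == 3, all(psf_sigma_um >= 0),
            attenuation_length_um > 0, background_offset >= 0,
            read_noise_sd >= 0)
  structure(list(psf_sigma_um = psf_sigma_um,
                 background_offset = background_offset,
                 background_gradient_amplitude = background_gradient_amplitude,
                 attenuation_length_um = attenuation_length_um,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "optics_params")
}

#' Noise-free "clean" optics: no PSF, no background, no noise, no attenuation
#' (attenuation length is effectively infinite).
#' @rdname optics_params
#' @export
optics_none <- function() {
  optics_params(psf_sigma_um = c(0, 0, 0), background_offset = 0,
                background_gradient_amplitude = 0,
                attenuation_length_um = 1e12, read_noise_sd = 0,
                shot_noise = FALSE)
}

# Profile of one truncated-Gaussian blob on the voxel grid.
# Soma profile: exp(-d^2 / (2 sigma^2)) with sigma = radius/2, cut at
# d = radius (2 sigma), so the support equals the nominal soma radius.
# Returns NULL when the support misses the grid.
blob_profile <- function(dims, voxel, center, radius) {
  zc <- (seq_len(dims[1]) - 1) * voxel[1]
  yc <- (seq_len(dims[2]) - 1) * voxel[2]
  xc <- (seq_len(dims[3]) - 1) * voxel[3]
  iz <- which(abs(zc - center[1]) <= radius)
  iy <- which(abs(yc - center[2]) <= radius)
  ix <- which(abs(xc - center[3]) <= radius)
  if (!length(iz) || !length(iy) || !length(ix)) return(NULL)
  d2 <- outer(outer((zc[iz] - center[1])^2, (yc[iy] - center[2])^2, `+`),
              (xc[ix] - center[3])^2, `+`)
  sigma <- radius / 2
  prof <- exp(-d2 / (2 * sigma^2))
  prof[d2 > radius^2] <- 0
  list(iz = iz, iy = iy, ix = ix, prof = prof)
}

# Profile of a thin filament: Gaussian cross-section around a line segment.
filament_profile <- function(dims, voxel, center, dir, len, sigma) {
  half <- len / 2
  p0 <- center - half * dir
  p1 <- center + half * dir
  support <- 2 * sigma
  lo <- pmin(p0, p1) - support
  hi <- pmax(p0, p1) + support
  zc <- (seq_len(dims[1]) - 1) * voxel[1]
  yc <- (seq_len(dims[2]) - 1) * voxel[2]
  xc <- (seq_len(dims[3]) - 1) * voxel[3]
  iz <- which(zc >= lo[1] & zc <= hi[1])
  iy <- which(yc >= lo[2] & yc <= hi[2])
  ix <- which(xc >= lo[3] & xc <= hi[3])
  if (!length(iz) || !length(iy) || !length(ix)) return(NULL)
  g <- as.matrix(expand.grid(z = zc[iz], y = yc[iy], x = xc[ix]))
  rel <- sweep(g, 2, p0)
  t <- pmin(pmax(rel %*% dir, 0), len)
  nearest <- cbind(p0[1] + t * dir[1], p0[2] + t * dir[2], p0[3] + t * dir[3])
  d2 <- rowSums((g - nearest)^2)
  prof <- exp(-d2 / (2 * sigma^2))
  prof[d2 > support^2] <- 0
  list(iz = iz, iy = iy, ix = ix,
       prof = array(prof, dim = c(length(iz), length(iy), length(ix))))
}

#' Render a scene into a two-channel image stack
#'
#' Turns ground truth into pixels: each soma contributes a truncated
#' Gaussian profile with donor amplitude `A` and acceptor amplitude
#' `A * true_ratio`; both channels are convolved with the Gaussian PSF,
#' attenuated with depth, summed with a smooth background, and then Poisson
#' shot noise and Gaussian read noise are applied.  The scene's ground truth
#' is not modified.
#'
#' @param scene A `fret_scene`.
#' @param optics An [optics_params()] object.
#' @param seed Integer seed for the noise; defaults to the scene's render
#'   sub-stream.
#' @return An [image_stack()] with channels `(donor_670, acceptor_720)`.
#' @export
render_stack <- function(scene, optics = optics_params(), seed = NULL) {
  stopifnot(inherits(scene, "fret_scene"), inherits(optics, "optics_params"))
  seed <- seed %||% scene$stage_seeds[["render"]]
  dims <- scene$field_dims_um / scene$voxel_size_um
  if (any(abs(dims - round(dims)) > 1e-6) || any(round(dims) < 1)) {
    stop("field_dims_um / voxel_size_um must give positive integer stack dimensions")
  }
  dims <- as.integer(round(dims))
  donor <- array(0, dims)
  acceptor <- array(0, dims)
  cells <- scene$cells
  for (i in seq_len(nrow(cells))) {
    p <- blob_profile(dims, scene$voxel_size_um,
                      c(cells$center_z_um[i], cells$center_y_um[i],
                        cells$center_x_um[i]), cells$radius_um[i])
    if (is.null(p)) next
    inc <- cells$donor_amplitude[i] * p$prof
    donor[p$iz, p$iy, p$ix] <- donor[p$iz, p$iy, p$ix, drop = FALSE] + inc
    acceptor[p$iz, p$iy, p$ix] <- acceptor[p$iz, p$iy, p$ix, drop = FALSE] +
      cells$true_ratio[i] * inc
  }
  dis <- scene$distractors
  for (i in seq_len(nrow(dis))) {
    ctr <- c(dis$center_z_um[i], dis$center_y_um[i], dis$center_x_um[i])
    p <- if (dis$shape[i] == "irregular-elongated") {
      filament_profile(dims, scene$voxel_size_um, ctr,
                       c(dis$dir_z[i], dis$dir_y[i], dis$dir_x[i]),
                       dis$length_um[i], dis$size_um[i])
    } else {
      # blob distractors: size_um is the support radius, like cell radius_um
      blob_profile(dims, scene$voxel_size_um, ctr, dis$size_um[i])
    }
    if (is.null(p)) next
    inc <- dis$amplitude[i] * p$prof
    donor[p$iz, p$iy, p$ix] <- donor[p$iz, p$iy, p$ix, drop = FALSE] + inc
    acceptor[p$iz, p$iy, p$ix] <- acceptor[p$iz, p$iy, p$ix, drop = FALSE] +
      dis$true_ratio[i] * inc
  }
  sigma_vox <- optics$psf_sigma_um / scene$voxel_size_um
  if (any(sigma_vox > 0)) {
    donor <- gauss_blur3_cpp(donor, dims, sigma_vox)
    acceptor <- gauss_blur3_cpp(acceptor, dims, sigma_vox)
  }
  zatt <- exp(-((seq_len(dims[1]) - 1) * scene$voxel_size_um[1]) /
                optics$attenuation_length_um)
  donor <- donor * zatt          # recycles along z (first dimension)
  acceptor <- acceptor * zatt
  bg <- optics$background_offset
  if (optics$background_gradient_amplitude > 0) {
    yn <- (seq_len(dims[2]) - 1) / max(1, dims[2] - 1)
    xn <- (seq_len(dims[3]) - 1) / max(1, dims[3] - 1)
    plane <- outer(yn, xn, function(a, b) (a + b) / 2)
    bgvol <- array(rep(optics$background_gradient_amplitude * plane,
                       each = dims[1]), dims) + optics$background_offset
    donor <- donor + bgvol
    acceptor <- acceptor + bgvol
  } else if (bg > 0) {
    donor <- donor + bg
    acceptor <- acceptor + bg
  }
  if (optics$shot_noise || optics$read_noise_sd > 0) {
    with_seed(seed, {
      if (optics$shot_noise) {
        donor <- array(rpois(length(donor), donor), dims)
        acceptor <- array(rpois(length(acceptor), acceptor), dims)
      }
      if (optics$read_noise_sd > 0) {
        donor <- donor + array(rnorm(length(donor), 0, optics$read_noise_sd), dims)
        acceptor <- acceptor + array(rnorm(length(acceptor), 0, optics$read_noise_sd), dims)
      }
    })
    # detector output is non-negative
    donor[donor < 0] <- 0
    acceptor[acceptor < 0] <- 0
  }
  image_stack(list(donor_670 = donor, acceptor_720 = acceptor),
              voxel_size_um = scene$voxel_size_um)
}
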