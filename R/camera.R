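#' Camera configuration for synthetic frame rendering
#'
#' A linear camera with Gaussian read noise and hard saturation. Two cameras
#' with different exposures image the model simultaneously: the low-exposure
#' camera covers the full concentration range unsaturated, while the
#' high-exposure camera saturates at moderate concentrations but resolves the
#' dilute range finely. [low_exposure_camera()] and [high_exposure_camera()]
#' provide the defaults (12-bit, low unsaturated to ~52 µM, high saturating
#' near 20 µM).
#'
#' @param exposure_label `"low"` or `"high"`.
#' @param gain Intensity counts per µM.
#' @param offset Background intensity (counts).
#' @param saturation_level Maximum intensity (counts).
#' @param noise_sd Gaussian noise SD (counts).
#' @param bit_depth Nominal bit depth (metadata only).
#' @return A `camera_config` list.
#' @export
camera_config <- function(exposure_label, gain, offset, saturation_level,
                          noise_sd = 8, bit_depth = 12) {
  if (gain <= 0) stop("gain must be positive")
  if (saturation_level <= offset) stop("saturation_level must exceed offset")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(exposure_label = exposure_label, gain = gain, offset = offset,
                 saturation_level = saturation_level, noise_sd = noise_sd,
                 bit_depth = bit_depth), class = "camera_config")
}

#' @rdname camera_config
#' @param noise_sd Gaussian noise SD (counts).
#' @export
low_exposure_camera <- function(noise_sd = 8) {
  camera_config("low", gain = (4095 - 100) / 52, offset = 100,
                saturation_level = 4095, noise_sd = noise_sd)
}

#' @rdname camera_config
#' @export
high_exposure_camera <- function(noise_sd = 8) {
  camera_config("high", gain = (4095 - 100) / 20, offset = 100,
                saturation_level = 4095, noise_sd = noise_sd)
}

new_image_stack <- function(frames, camera, frame_interval, t_s, z_mm) {
  structure(list(frames = frames, camera = camera,
                 frame_interval = frame_interval, t_s = t_s, z_mm = z_mm),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image stack (%s exposure): %d frames of %d x %d px, every %g s\n",
              x$camera$exposure_label, length(x$frames), d[1], d[2],
              x$frame_interval))
  invisible(x)
}

#' Render camera frames from a concentration field
#'
#' Each frame maps the axial concentration profile through the linear camera
#' model `clip(offset + gain * C + noise, 0, saturation_level)`, replicating
#' each axial row across `width` transverse columns. Deterministic under a
#' fixed seed.
#'
#' @param field A `concentration_field` (or any object with `C`, `z_mm`,
#'   `t_s`).
#' @param camera A [camera_config()].
#' @param seed Integer seed for the noise.
#' @param width Transverse width in pixels, default 32.
#' @return An `image_stack` (list of z-by-width intensity matrices).
#' @export
render_frames <- function(field, camera, seed = 1, width = 32) {
  nz <- length(field$z_mm)
  nt <- length(field$t_s)
  dtf <- if (nt > 1) field$t_s[2] - field$t_s[1] else NA_real_
  frames <- withr::with_seed(seed, {
    lapply(seq_len(nt), function(k) {
      base <- camera$offset + camera$gain * field$C[, k]
      img <- matrix(base, nz, width)
      if (camera$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(nz * width, sd = camera$noise_sd), nz, width)
      }
      img[img < 0] <- 0
      img[img > camera$saturation_level] <- camera$saturation_level
      img
    })
  })
  new_image_stack(frames, camera, dtf, field$t_s, field$z_mm)
}

#' Render calibration stacks at known concentrations
#'
#' One uniform-concentration frame per calibration level, rendered through
#' [render_frames()] with the given camera. Used by
#' [fit_calibration()] to build the intensity-to-concentration map.
#'
#' @param camera A [camera_config()].
#' @param levels Strictly increasing non-negative concentrations (µM).
#' @param seed Integer seed.
#' @param nz,width Frame dimensions in pixels.
#' @return A list with elements `stacks` (one single-frame `image_stack` per
#'   level) and `levels`.
#' @export
calibration_stacks <- function(camera, levels = c(0, 1, 2, 5, 10, 15, 20, 30, 40, 50),
                               seed = 1, nz = 64, width = 32) {
  if (any(levels < 0)) stop("calibration levels must be non-negative")
  if (any(diff(levels) <= 0)) stop("calibration levels must be strictly increasing")
  stacks <- lapply(seq_along(levels), function(i) {
    f <- new_concentration_field(matrix(levels[i], nz, 1), seq_len(nz), 0)
    render_frames(f, camera, seed = seed + i, width = width)
  })
  list(stacks = stacks, levels = levels)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Intensities are stored normalized by the camera's saturation level (TIFF
#' expects values in `[0, 1]`) at 16 bits per sample.
#'
#' @param stack An `image_stack`.
#' @param path File path.
#' @param camera Camera used to de-normalize on read.
#' @param frame_interval Frame interval (s) to attach on read.
#' @return `read_image_stack()` returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  sat <- stack$camera$saturation_level
  pages <- lapply(stack$frames, function(f) f / sat)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, camera, frame_interval = 30) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) p * camera$saturation_level)
  nz <- nrow(frames[[1]])
  t_s <- (seq_along(frames) - 1) * frame_interval
  new_image_stack(frames, camera, frame_interval, t_s, seq_len(nz))
}
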