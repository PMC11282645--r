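#' Construct a slice-volume profile
#'
#' A volume profile is the axial representation of the CSF space: the fluid
#' volume contained in each 1 mm-thick transverse slice, indexed by the axial
#' coordinate z. The convention throughout the package is z = 0 at the foramen
#' magnum with z positive cranially, so spinal locations are negative and the
#' extra-axial (cranial) CSF spans positive z.
#'
#' @param z_mm Numeric vector of slice-centre positions (mm), uniformly spaced.
#' @param volume_ml Non-negative numeric vector of per-slice CSF volumes (ml).
#' @param slice_thickness Axial slice thickness (mm).
#' @return A `volume_profile`: a tibble with columns `z_mm` and `volume_ml`
#'   and attributes `slice_thickness` (mm) and `total_volume` (ml).
#' @export
volume_profile <- function(z_mm, volume_ml, slice_thickness = 1) {
  if (length(z_mm) != length(volume_ml) || length(z_mm) == 0) {
    stop("z_mm and volume_ml must be non-empty vectors of equal length")
  }
  if (any(volume_ml < 0)) stop("slice volumes must be non-negative")
  if (length(z_mm) > 1) {
    dzs <- diff(z_mm)
    if (any(abs(dzs - slice_thickness) > 1e-8 * max(1, slice_thickness))) {
      stop("z_mm must be uniformly spaced at slice_thickness intervals")
    }
  }
  total <- sum(volume_ml)
  if (total <= 0) stop("total volume must be positive")
  out <- tibble::tibble(z_mm = as.numeric(z_mm), volume_ml = as.numeric(volume_ml))
  attr(out, "slice_thickness") <- slice_thickness
  attr(out, "total_volume") <- total
  class(out) <- c("volume_profile", class(out))
  out
}

#' Total CSF volume of a profile
#' @param profile A [volume_profile()].
#' @return Total volume (ml).
#' @export
total_volume <- function(profile) sum(profile$volume_ml)

#' Slice thickness of a profile
#' @param profile A [volume_profile()].
#' @return Slice thickness (mm).
#' @export
slice_thickness <- function(profile) {
  dz <- attr(profile, "slice_thickness")
  if (is.null(dz)) dz <- if (nrow(profile) > 1) diff(profile$z_mm)[1] else 1
  dz
}

#' Build a synthetic phantom CSF geometry
#'
#' Generates a smooth axial slice-volume profile emulating the bench-top
#' cynomolgus CSF model: a narrow spinal canal with a mild lumbosacral
#' enlargement, opening at the foramen magnum (z = 0) into a bulged cranial
#' compartment that tapers toward the top of the model. The raw shape is
#' rescaled so the total volume matches `total_volume_ml` exactly.
#'
#' @param total_volume_ml Target total CSF volume (ml); default 16.86, the
#'   volume of the subject-specific model.
#' @param spinal_length Caudal extent of the canal below the foramen magnum
#'   (mm). Not a measured quantity; configurable, default 280.
#' @param cranial_length Extent of the cranial compartment above the foramen
#'   magnum (mm); default 60, the extra-axial CSF span.
#' @param slice_thickness Slice thickness (mm), default 1.
#' @param cranial_volume_fraction Fraction of total volume placed in the
#'   cranial compartment; default 0.42.
#' @param caudal_terminus_area Cross-sectional area of the caudal end of the
#'   thecal sac relative to the canal, default 0.05 (the sac narrows sharply
#'   toward the filum terminale).
#' @return A [volume_profile()].
#' @export
build_synthetic_geometry <- function(total_volume_ml = 16.86,
                                     spinal_length = 280,
                                     cranial_length = 60,
                                     slice_thickness = 1,
                                     cranial_volume_fraction = 0.42,
                                     caudal_terminus_area = 0.05) {
  if (total_volume_ml <= 0) stop("total_volume_ml must be positive")
  if (spinal_length <= 0 || cranial_length <= 0) stop("lengths must be positive")
  if (cranial_volume_fraction <= 0 || cranial_volume_fraction >= 1) {
    stop("cranial_volume_fraction must be in (0, 1)")
  }
  dz <- slice_thickness
  z <- seq(-spinal_length + dz / 2, cranial_length - dz / 2, by = dz)
  spinal <- z < 0
  # unit-area canal with a lumbosacral enlargement, tapering smoothly to the
  # narrow caudal terminus of the thecal sac (filum terminale)
  a <- numeric(length(z))
  zs <- z[spinal]
  x <- pmin(pmax((zs + spinal_length) / 25, 0), 1)
  ta <- caudal_terminus_area
  taper <- ta + (1 - ta) * x^2 * (3 - 2 * x)
  a[spinal] <- taper * (1 + 0.3 * exp(-((zs + 0.85 * spinal_length) / 25)^2))
  # cranial bulge: continuous with the canal at z = 0 and at the top, with a
  # half-sine bulge whose height is solved from the target volume fraction
  zc <- z[!spinal]
  s <- sin(pi * zc / cranial_length)
  v_sp_raw <- sum(a[spinal]) * dz
  # cranial raw volume = length + b * sum(s) * dz; solve b for the fraction
  target_cr <- v_sp_raw * cranial_volume_fraction / (1 - cranial_volume_fraction)
  b <- (target_cr - cranial_length) / (sum(s) * dz)
  if (b < 0) b <- 0
  a[!spinal] <- 1 + b * s
  vols <- a * dz
  vols <- vols * total_volume_ml / sum(vols)
  volume_profile(z, vols, slice_thickness = dz)
}

#' Slice volumes from a binary segmentation mask
#'
#' Bins a 3D binary mask (rows x columns x axial pages) into axial slabs of
#' `slice_thickness` and reports the segmented volume per slab as the count of
#' true voxels times the voxel volume. Partially covered slabs at the cranial
#' end are truncated, not padded.
#'
#' @param mask Logical (or 0/1) 3D array; the third dimension is axial.
#' @param voxel_size Numeric length-3 voxel edge lengths (mm).
#' @param slice_thickness Output slab thickness (mm), default 1.
#' @param z_origin Axial position (mm) of the caudal face of the first page.
#' @return A [volume_profile()] (volumes in ml).
#' @export
slice_volumes_from_mask <- function(mask, voxel_size, slice_thickness = 1,
                                    z_origin = 0) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive edge lengths (mm)")
  }
  mask <- mask != 0
  if (!any(mask)) warning("mask contains no segmented voxels; returning a zero profile")
  dzv <- voxel_size[3]
  npages <- dim(mask)[3]
  vox_ml <- prod(voxel_size) / 1000  # mm^3 -> ml
  pages_per_bin <- slice_thickness / dzv
  nbins <- floor(npages * dzv / slice_thickness)
  if (nbins < 1) stop("mask too thin for one slab at slice_thickness")
  counts <- vapply(seq_len(nbins), function(k) {
    p0 <- floor((k - 1) * pages_per_bin) + 1
    p1 <- floor(k * pages_per_bin + 1e-9)
    sum(mask[, , p0:p1])
  }, numeric(1))
  vols <- counts * vox_ml
  z <- z_origin + (seq_len(nbins) - 0.5) * slice_thickness
  if (all(vols == 0)) {
    # bypass positive-total validation for the warned empty case
    out <- tibble::tibble(z_mm = z, volume_ml = vols)
    attr(out, "slice_thickness") <- slice_thickness
    attr(out, "total_volume") <- 0
    class(out) <- c("volume_profile", class(out))
    return(out)
  }
  volume_profile(z, vols, slice_thickness = slice_thickness)
}

#' Regress one volume profile on another
#'
#' Ordinary least squares of the per-slice volumes of `b` on those of `a`,
#' used to verify agreement between two segmentations of the same geometry
#' (e.g. a printed model's micro-CT volumes against the MRI-derived volumes).
#'
#' @param a,b [volume_profile()]s on the same axial grid; `b` is regressed
#'   on `a`.
#' @return A `profile_regression` object with slope, intercept, r_squared and
#'   both total volumes; see [tidy()] and [glance()].
#' @export
compare_profiles <- function(a, b) {
  if (nrow(a) != nrow(b) || any(abs(a$z_mm - b$z_mm) > 1e-8)) {
    stop("profiles must share the same z grid")
  }
  fit <- stats::lm(b$volume_ml ~ a$volume_ml)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((b$volume_ml - mean(b$volume_ml))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    total_volume_a = sum(a$volume_ml),
    total_volume_b = sum(b$volume_ml),
    n_slices = nrow(a)
  )
  class(out) <- "profile_regression"
  out
}

#' @export
print.profile_regression <- function(x, ...) {
  cat("Volume-profile regression (b ~ a) over", x$n_slices, "slices\n")
  cat(sprintf("  slope = %.4f, intercept = %.4g, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  total volumes: a = %.2f ml, b = %.2f ml\n",
              x$total_volume_a, x$total_volume_b))
  invisible(x)
}

#' Named axial regions of the CSF space
#'
#' Regions are half-open intervals `[z_start, z_end)` in mm. The default map
#' places the extra-axial CSF (eaCSF) at `[0, 60)` — foramen magnum to the top
#' of the model — with cervical, thoracic and lumbar segments below it.
#'
#' @param ... Named length-2 numeric vectors `c(z_start, z_end)` (mm).
#' @return A `region_map` tibble with columns `region`, `z_start`, `z_end`.
#' @examples
#' region_map() # default eaCSF/cervical/thoracic/lumbar partition
#' @export
region_map <- function(...) {
  regions <- list(...)
  if (length(regions) == 0) {
    regions <- list(
      eaCSF = c(0, 60), cervical = c(-60, 0),
      thoracic = c(-180, -60), lumbar = c(-280, -180)
    )
  }
  if (is.null(names(regions)) || any(names(regions) == "")) {
    stop("all regions must be named")
  }
  out <- tibble::tibble(
    region = names(regions),
    z_start = vapply(regions, `[`, numeric(1), 1),
    z_end = vapply(regions, `[`, numeric(1), 2)
  )
  if (any(out$z_end <= out$z_start)) stop("region z_end must exceed z_start")
  o <- order(out$z_start)
  so <- out[o, ]
  if (nrow(so) > 1 && any(so$z_start[-1] < so$z_end[-nrow(so)] - 1e-12)) {
    stop("regions must not overlap")
  }
  attr(out, "convention") <- "z = 0 at foramen magnum, positive cranial"
  class(out) <- c("region_map", class(out))
  out
}

#' Assign each slice of a profile to a region
#'
#' @param profile A [volume_profile()].
#' @param regions A [region_map()]. Intervals are half-open `[z_start, z_end)`.
#' @return A tibble `z_mm`, `region` with `"unassigned"` for slices outside
#'   every region; each slice receives exactly one label.
#' @export
region_partition <- function(profile, regions) {
  if (!inherits(regions, "region_map")) regions <- do.call(region_map, as.list(regions))
  lab <- rep("unassigned", nrow(profile))
  for (i in seq_len(nrow(regions))) {
    hit <- profile$z_mm >= regions$z_start[i] & profile$z_mm < regions$z_end[i]
    if (any(lab[hit] != "unassigned")) stop("regions must not overlap")
    lab[hit] <- regions$region[i]
  }
  tibble::tibble(z_mm = profile$z_mm, region = lab)
}

region_indices <- function(profile, regions, region_name) {
  part <- region_partition(profile, regions)
  idx <- which(part$region == region_name)
  if (length(idx) == 0) stop("region '", region_name, "' contains no slices")
  idx
}

#' Read / write a volume profile as CSV
#'
#' The on-disk format is a two-column CSV with a header row: `z_mm`,
#' `volume_ml`.
#'
#' @param path File path.
#' @return `read_volume_profile()` returns a [volume_profile()];
#'   `write_volume_profile()` returns `path` invisibly.
#' @export
read_volume_profile <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("z_mm", "volume_ml") %in% names(df))) {
    stop("volume profile CSV must have columns z_mm, volume_ml")
  }
  dz <- if (nrow(df) > 1) diff(df$z_mm)[1] else 1
  volume_profile(df$z_mm, df$volume_ml, slice_thickness = dz)
}

#' @rdname read_volume_profile
#' @param profile A [volume_profile()].
#' @export
write_volume_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile[, c("z_mm", "volume_ml")]), path,
                   row.names = FALSE)
  invisible(path)
}
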