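#' Quantification configuration
#'
#' @param merge_threshold Concentration (µM) below which low-exposure values
#'   are replaced by high-exposure values when merging; default 10, the
#'   mid-point across the calibration maps.
#' @param frame_interval Imaging interval (s), default 30.
#' @param duration Imaging duration (h), default 3.
#' @param auc_windows List of `(start, end)` integration windows (h).
#' @return A `quant_config` list.
#' @export
quant_config <- function(merge_threshold = 10, frame_interval = 30,
                         duration = 3, auc_windows = list(c(0, 1), c(0, 3))) {
  if (merge_threshold <= 0) stop("merge_threshold must be positive")
  bad <- vapply(auc_windows, function(w) w[1] < 0 || w[2] > duration, logical(1))
  if (any(bad)) stop("auc_windows must lie within the imaging duration")
  structure(list(merge_threshold = merge_threshold,
                 frame_interval = frame_interval, duration = duration,
                 auc_windows = auc_windows), class = "quant_config")
}

#' Fit an intensity-to-concentration calibration map
#'
#' Builds a monotone piecewise-linear interpolant through the (mean frame
#' intensity, known concentration) pairs of the calibration stacks. Levels
#' whose frames are saturated are excluded; extrapolation beyond the fitted
#' intensity range is clamped to the end values.
#'
#' @param stacks List of single-frame `image_stack`s, one per level (as from
#'   [calibration_stacks()], whose result's `$stacks` element is accepted
#'   directly).
#' @param levels Known concentrations (µM), strictly increasing.
#' @param saturation_margin Fraction of the saturation level above which a
#'   level's mean intensity is treated as saturated and excluded (default
#'   0.98).
#' @return A `calibration_map` with the node intensities/concentrations and
#'   the camera label.
#' @export
fit_calibration <- function(stacks, levels = NULL, saturation_margin = 0.98) {
  if (is.list(stacks) && !is.null(stacks$stacks)) {
    if (is.null(levels)) levels <- stacks$levels
    stacks <- stacks$stacks
  }
  if (length(stacks) < 2 || is.null(levels) || length(levels) != length(stacks)) {
    stop("need at least two calibration levels with one stack each")
  }
  camera <- stacks[[1]]$camera
  means <- vapply(stacks, function(s) mean(s$frames[[1]]), numeric(1))
  keep <- means < saturation_margin * camera$saturation_level
  if (sum(keep) < 2) stop("fewer than two unsaturated calibration levels")
  mi <- means[keep]; lv <- levels[keep]
  inc <- diff(mi) > 0
  if (any(!inc)) {
    j <- which(!inc)[1]
    stop(sprintf(
      "calibration mean intensities not strictly increasing between levels %g and %g uM",
      lv[j], lv[j + 1]))
  }
  structure(list(intensity = mi, concentration = lv,
                 camera_label = camera$exposure_label,
                 saturation_level = camera$saturation_level),
            class = "calibration_map")
}

#' Apply a calibration map to intensities
#'
#' @param object A `calibration_map`.
#' @param intensity Numeric intensities.
#' @param ... Unused.
#' @return Concentrations (µM); values outside the fitted range are clamped
#'   to the end concentrations.
#' @export
predict.calibration_map <- function(object, intensity, ...) {
  stats::approx(object$intensity, object$concentration, xout = intensity,
                rule = 2)$y
}

#' Axial concentration profile of one frame
#'
#' Averages pixel intensity across the transverse direction (one mean per
#' axial row), then maps the row means through the calibration map. Averaging
#' precedes mapping.
#'
#' @param frame Intensity matrix (axial rows x transverse columns).
#' @param map A `calibration_map`.
#' @return Numeric concentration per axial row (µM).
#' @export
axial_concentration <- function(frame, map) {
  predict(map, rowMeans(frame))
}

#' Merge low- and high-exposure concentration profiles
#'
#' Points where the low-exposure estimate is strictly below the threshold are
#' replaced by the high-exposure estimate; ties at the threshold keep the
#' low-exposure value.
#'
#' @param low,high Equal-length concentration profiles (µM).
#' @param threshold Merge threshold (µM), default 10.
#' @return Merged profile.
#' @export
merge_exposures <- function(low, high, threshold = 10) {
  if (length(low) != length(high)) stop("profiles must have equal length")
  ifelse(low < threshold, high, low)
}

new_spatiotemporal_map <- function(C, z_mm, t_s, source = NULL) {
  structure(list(C = C, z_mm = z_mm, t_s = t_s, source = source),
            class = c("spatiotemporal_map", "concentration_field"))
}

#' @export
print.spatiotemporal_map <- function(x, ...) {
  cat("Spatial-temporal concentration map:", length(x$z_mm), "slices x",
      length(x$t_s), "frames\n")
  cat(sprintf("  max %.3g uM; %.1f%% of points from the high-exposure camera\n",
              max(x$C), 100 * mean(x$source == "high")))
  invisible(x)
}

#' Build the merged spatial-temporal concentration map
#'
#' Runs [axial_concentration()] on every frame of the low- and high-exposure
#' stacks through their respective calibration maps and merges the two
#' estimates per [merge_exposures()], assembling the merged concentration
#' estimate on the imaging grid.
#'
#' @param low_stack,high_stack Time-aligned `image_stack`s.
#' @param maps Named list with elements `low` and `high` (`calibration_map`s).
#' @param config A [quant_config()].
#' @return A `spatiotemporal_map` with matrix `C` (slices x frames, µM),
#'   grids `z_mm`, `t_s`, and a provenance matrix `source` (`"low"`/`"high"`).
#' @export
build_spatiotemporal <- function(low_stack, high_stack, maps,
                                 config = quant_config()) {
  nlo <- length(low_stack$frames); nhi <- length(high_stack$frames)
  if (nlo != nhi) {
    stop(sprintf("camera frame counts differ: low has %d, high has %d", nlo, nhi))
  }
  if (any(abs(low_stack$t_s - high_stack$t_s) > 1e-9)) {
    stop("camera stacks are not time-aligned at: ",
         paste(utils::head(low_stack$t_s[abs(low_stack$t_s - high_stack$t_s) > 1e-9], 5),
               collapse = ", "))
  }
  nz <- nrow(low_stack$frames[[1]])
  C <- matrix(0, nz, nlo)
  src <- matrix("low", nz, nlo)
  for (k in seq_len(nlo)) {
    lo <- axial_concentration(low_stack$frames[[k]], maps$low)
    hi <- axial_concentration(high_stack$frames[[k]], maps$high)
    C[, k] <- merge_exposures(lo, hi, config$merge_threshold)
    src[, k] <- ifelse(lo < config$merge_threshold, "high", "low")
  }
  C[C < 0] <- 0
  new_spatiotemporal_map(C, low_stack$z_mm, low_stack$t_s, source = src)
}

#' Area-under-curve profile
#'
#' Per-slice trapezoidal time-integral of the concentration map over an
#' integration window, in µM·hr.
#'
#' @param map A `spatiotemporal_map` or `concentration_field`.
#' @param window Length-2 numeric `(start, end)` in hours.
#' @return An `auc_profile` tibble with columns `z_mm`, `auc_uM_hr` and the
#'   window as an attribute.
#' @export
auc_profile <- function(map, window = c(0, 3)) {
  if (window[2] <= window[1]) stop("window end must exceed its start")
  t_h <- map$t_s / 3600
  sel <- t_h >= window[1] - 1e-9 & t_h <= window[2] + 1e-9
  if (sum(sel) < 2) stop("window contains fewer than two frames")
  tt <- t_h[sel]
  Csub <- map$C[, sel, drop = FALSE]
  w <- diff(tt)
  # trapezoid weights per frame
  wt <- c(w / 2, 0) + c(0, w / 2)
  auc <- as.numeric(Csub %*% wt)
  out <- tibble::tibble(z_mm = map$z_mm, auc_uM_hr = auc)
  attr(out, "window_h") <- window
  class(out) <- c("auc_profile", class(out))
  out
}

#' Percent injected dose delivered to the extra-axial CSF
#'
#' The volume-weighted tracer mass in the eaCSF region at the frame nearest
#' `at_time`, as a percentage of the injected mass:
#' `%ID = 100 * sum_z V(z) C(z) / injected mass` over the eaCSF slices.
#'
#' @param map A `spatiotemporal_map` or ground-truth `concentration_field`.
#' @param at_time Evaluation time (h), default 3.
#' @param geometry The [volume_profile()] on the map's grid.
#' @param regions A [region_map()] defining `eaCSF`.
#' @param injected_mass Injected tracer mass (µM·ml).
#' @param region Region name, default `"eaCSF"`.
#' @return Percent injected dose (scalar).
#' @export
percent_id_eacsf <- function(map, at_time = 3, geometry, regions = region_map(),
                             injected_mass, region = "eaCSF") {
  if (injected_mass <= 0) stop("injected_mass must be positive")
  if (length(map$z_mm) != nrow(geometry) ||
      any(abs(map$z_mm - geometry$z_mm) > 1e-8)) {
    stop("map and geometry grids differ")
  }
  k <- which.min(abs(map$t_s / 3600 - at_time))
  idx <- region_indices(geometry, regions, region)
  100 * sum(geometry$volume_ml[idx] * map$C[idx, k]) / injected_mass
}

#' Mean AUC over a named region
#'
#' Arithmetic mean of the per-slice AUC over the region's slices (unweighted
#' by default; optionally volume-weighted).
#'
#' @param auc An [auc_profile()].
#' @param regions A [region_map()].
#' @param region_name Region to average over.
#' @param geometry Required when `volume_weighted = TRUE`.
#' @param volume_weighted Weight slices by their CSF volume.
#' @return Mean AUC (µM·hr).
#' @export
region_mean_auc <- function(auc, regions = region_map(), region_name = "eaCSF",
                            geometry = NULL, volume_weighted = FALSE) {
  prof <- tibble::tibble(z_mm = auc$z_mm, volume_ml = 1)
  part_idx <- which(auc$z_mm >= regions$z_start[match(region_name, regions$region)] &
                      auc$z_mm < regions$z_end[match(region_name, regions$region)])
  if (is.na(match(region_name, regions$region))) stop("unknown region: ", region_name)
  if (length(part_idx) == 0) stop("region '", region_name, "' contains no slices")
  if (volume_weighted) {
    if (is.null(geometry)) stop("geometry needed for volume weighting")
    w <- geometry$volume_ml[part_idx]
    sum(auc$auc_uM_hr[part_idx] * w) / sum(w)
  } else {
    mean(auc$auc_uM_hr[part_idx])
  }
}
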