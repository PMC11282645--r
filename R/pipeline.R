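#' Study configuration
#'
#' Bundles everything needed to run a full synthetic injection study:
#' geometry, flow waveform, transport parameters, the protocol table, imaging
#' and quantification settings, and seeding. Defaults reproduce the study
#' conditions: eight protocols, three repetitions each, 30 s frames for 3 h.
#'
#' @param geometry A [volume_profile()].
#' @param waveform A `flow_waveform` (default the combined cardiac +
#'   respiratory waveform).
#' @param params A [transport_params()].
#' @param protocols Protocol tibble (default [nhp_protocols()]).
#' @param regions A [region_map()].
#' @param repetitions Repetitions per protocol, default 3.
#' @param base_seed Base integer seed; per-repetition seeds derive from it.
#' @param quant A [quant_config()].
#' @param cameras Named list `low`, `high` of [camera_config()]s.
#' @param calibration_levels Calibration concentrations (µM).
#' @param noise_free Disable camera noise and injection-start jitter.
#' @param image_width Transverse pixels per frame.
#' @param injection_jitter Half-width (s) of the uniform jitter applied to
#'   the injection start per repetition, default 5.
#' @param dt Simulator step during injection (s).
#' @param output_dir Optional directory; when set, [run_study()] writes maps,
#'   per-protocol results and group tables there.
#' @return A `study_config` list.
#' @export
study_config <- function(geometry = build_synthetic_geometry(),
                         waveform = combined_waveform(waveform_config()),
                         params = transport_params(),
                         protocols = nhp_protocols(),
                         regions = region_map(),
                         repetitions = 3,
                         base_seed = 1,
                         quant = quant_config(),
                         cameras = list(low = low_exposure_camera(),
                                        high = high_exposure_camera()),
                         calibration_levels = c(0, 1, 2, 5, 10, 15, 20, 30, 40, 50),
                         noise_free = FALSE,
                         image_width = 32,
                         injection_jitter = 5,
                         dt = 0.5,
                         output_dir = NULL) {
  if (repetitions < 1) stop("repetitions must be at least 1")
  structure(list(
    geometry = geometry, waveform = waveform, params = params,
    protocols = protocols, regions = regions, repetitions = repetitions,
    base_seed = base_seed, quant = quant, cameras = cameras,
    calibration_levels = calibration_levels, noise_free = noise_free,
    image_width = image_width, injection_jitter = injection_jitter,
    dt = dt, output_dir = output_dir
  ), class = "study_config")
}

repetition_seed <- function(base_seed, protocol_index, repetition) {
  (base_seed * 1000L + protocol_index * 10L + repetition) %% .Machine$integer.max
}

#' Run one protocol repetition end to end
#'
#' Simulates the ground-truth field for the named protocol, renders both
#' camera stacks (with per-repetition injection-start jitter and camera
#' noise, unless `noise_free`), fits per-camera calibrations, builds the
#' merged spatial-temporal map, and computes the quantification metrics.
#' Deterministic under the (base seed, protocol, repetition) triple.
#'
#' @param config A [study_config()].
#' @param protocol_name Protocol name (must exist in `config$protocols`).
#' @param repetition Repetition index (1-based).
#' @return A list with `result` (one-row tibble: `protocol`, `repetition`,
#'   `seed`, `percent_id_eacsf`, `auc_eacsf_0_1h`, `auc_eacsf_0_3h`,
#'   `injected_mass`, `percent_id_truth`), `map` (the `spatiotemporal_map`)
#'   and `field` (the ground-truth `concentration_field`).
#' @export
run_protocol <- function(config, protocol_name, repetition = 1) {
  prot <- config$protocols[config$protocols$name == protocol_name, ]
  if (nrow(prot) != 1) stop("unknown protocol: ", protocol_name)
  p_idx <- match(protocol_name, config$protocols$name)
  seed <- repetition_seed(config$base_seed, p_idx, repetition)

  jitter <- if (config$noise_free) 0 else {
    withr::with_seed(seed, stats::runif(1, -config$injection_jitter,
                                        config$injection_jitter))
  }
  duration_s <- config$quant$duration * 3600
  field <- simulate_transport(
    config$geometry, config$waveform, prot, config$params,
    duration = duration_s, dt = config$dt,
    frame_interval = config$quant$frame_interval,
    injection_start = 30 + jitter
  )

  cams <- config$cameras
  if (config$noise_free) {
    cams <- lapply(cams, function(cm) { cm$noise_sd <- 0; cm })
  }
  low_stack <- render_frames(field, cams$low, seed = seed + 1L,
                             width = config$image_width)
  high_stack <- render_frames(field, cams$high, seed = seed + 2L,
                              width = config$image_width)
  maps <- list(
    low = fit_calibration(calibration_stacks(cams$low, config$calibration_levels,
                                             seed = seed + 3L)),
    high = fit_calibration(calibration_stacks(cams$high, config$calibration_levels,
                                              seed = seed + 4L))
  )
  st <- build_spatiotemporal(low_stack, high_stack, maps, config$quant)

  mass <- injected_mass(prot)
  pid <- if (mass > 0) {
    percent_id_eacsf(st, at_time = config$quant$duration, config$geometry,
                     config$regions, mass)
  } else 0
  pid_truth <- if (mass > 0) {
    percent_id_eacsf(field, at_time = config$quant$duration, config$geometry,
                     config$regions, mass)
  } else 0
  aucs <- vapply(config$quant$auc_windows, function(w) {
    region_mean_auc(auc_profile(st, w), config$regions, "eaCSF")
  }, numeric(1))

  result <- tibble::tibble(
    protocol = protocol_name, repetition = repetition, seed = seed,
    percent_id_eacsf = pid,
    auc_eacsf_0_1h = aucs[1], auc_eacsf_0_3h = aucs[length(aucs)],
    injected_mass = mass, percent_id_truth = pid_truth
  )
  list(result = result, map = st, field = field)
}

#' Run the full synthetic study
#'
#' Executes every protocol x repetition, then computes per-protocol
#' repeatability statistics and the five injection-parameter group contrasts.
#' Deterministic under the config's base seed. When `config$output_dir` is
#' set, per-repetition maps (CSV), the per-repetition results table, and the
#' group-contrast table are written there.
#'
#' @param config A [study_config()].
#' @param protocols Optional subset of protocol names to run.
#' @param keep_maps Keep all spatial-temporal maps in the result (memory
#'   permitting), default `TRUE`.
#' @return A `study_result` list: `results` (per-repetition tibble),
#'   `repeat_stats` (named list per protocol), `groups` (the [delta_table()]
#'   tibble, when all group protocols were run), `maps`, and `config`.
#' @export
run_study <- function(config, protocols = config$protocols$name,
                      keep_maps = TRUE) {
  runs <- tidyr::expand_grid(protocol = protocols,
                             repetition = seq_len(config$repetitions))
  outs <- purrr::pmap(runs, function(protocol, repetition) {
    out <- tryCatch(run_protocol(config, protocol, repetition),
                    error = function(e) {
                      stop(sprintf("protocol %s repetition %d failed: %s",
                                   protocol, repetition, conditionMessage(e)),
                           call. = FALSE)
                    })
    out
  })
  results <- dplyr::bind_rows(purrr::map(outs, "result"))
  maps <- purrr::map(outs, "map")
  names(maps) <- paste(runs$protocol, runs$repetition, sep = "_r")

  rstats <- NULL
  if (config$repetitions >= 2) {
    rstats <- purrr::map(unique(protocols), function(p) {
      repetition_stats(maps[runs$protocol == p])
    })
    names(rstats) <- unique(protocols)
  }
  groups <- NULL
  grp <- parameter_groups()
  if (all(c(grp$a, grp$b) %in% protocols) && config$repetitions >= 2) {
    groups <- delta_table(
      dplyr::rename(results[, c("protocol", "percent_id_eacsf")],
                    percent_id = "percent_id_eacsf"))
  }
  res <- structure(list(results = results, repeat_stats = rstats,
                        groups = groups,
                        maps = if (keep_maps) maps else NULL,
                        config = config),
                   class = "study_result")
  if (!is.null(config$output_dir)) write_study_result(res, config$output_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("Synthetic injection study:",
      length(unique(x$results$protocol)), "protocols x",
      x$config$repetitions, "repetitions\n")
  print(dplyr::summarise(dplyr::group_by(x$results, .data$protocol),
                         mean_percent_id = mean(.data$percent_id_eacsf),
                         mean_auc_0_3h = mean(.data$auc_eacsf_0_3h)))
  if (!is.null(x$groups)) {
    cat("\nGroup contrasts (delta %ID to eaCSF at 3 h):\n")
    print(x$groups[, c("parameter", "protocol_a", "protocol_b",
                       "delta_percent_id", "p_value", "significant")])
  }
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits `results.csv` (per-repetition metrics), `groups.csv` (the
#' group-contrast table), `summary.json`, and one `map_<protocol>_r<i>.csv`
#' per repetition.
#'
#' @param res A `study_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res$results),
                   file.path(dir, "results.csv"), row.names = FALSE)
  if (!is.null(res$groups)) {
    g <- res$groups[, setdiff(names(res$groups), "comparison")]
    utils::write.csv(as.data.frame(g), file.path(dir, "groups.csv"),
                     row.names = FALSE)
  }
  summ <- list(
    protocols = unique(res$results$protocol),
    repetitions = res$config$repetitions,
    base_seed = res$config$base_seed,
    percent_dynamic_range = if (!is.null(res$repeat_stats)) {
      lapply(res$repeat_stats, `[[`, "percent_dynamic_range")
    }
  )
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$maps)) {
    for (nm in names(res$maps)) {
      write_concentration_field(res$maps[[nm]],
                                file.path(dir, paste0("map_", nm, ".csv")))
    }
  }
  invisible(dir)
}

#' Load a study configuration from YAML
#'
#' The YAML may override any default scalar (heart rate, dispersion factor,
#' repetitions, seeds, ...) and reference a protocol CSV via `protocol_csv`.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  wf_args <- y$waveform %||% list()
  tp_args <- y$transport %||% list()
  geom_args <- y$geometry %||% list()
  protocols <- if (!is.null(y$protocol_csv)) {
    read_protocols(if (file.exists(y$protocol_csv)) y$protocol_csv
                   else file.path(dirname(path), y$protocol_csv))
  } else nhp_protocols()
  study_config(
    geometry = do.call(build_synthetic_geometry, geom_args),
    waveform = combined_waveform(do.call(waveform_config, wf_args)),
    params = do.call(transport_params, tp_args),
    protocols = protocols,
    repetitions = y$repetitions %||% 3,
    base_seed = y$base_seed %||% 1,
    noise_free = isTRUE(y$noise_free),
    output_dir = y$output_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
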