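#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a volume-profile regression
#'
#' @param x A `profile_regression` from [compare_profiles()].
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.profile_regression <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.profile_regression
#' @export
glance.profile_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept,
                 total_volume_a = x$total_volume_a,
                 total_volume_b = x$total_volume_b,
                 n_slices = x$n_slices)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble mirroring the group-contrast table columns.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(parameter = x$name,
                 protocol_a = x$protocols[1], protocol_b = x$protocols[2],
                 mean_a = x$mean_a, mean_b = x$mean_b,
                 delta_percent_id = x$delta_percent_id,
                 t_statistic = x$t_statistic, p_value = x$p_value,
                 significant = x$significant)
}

#' Tidy repeatability statistics
#'
#' @param x A `repeat_stats`.
#' @param ... Unused.
#' @return Long tibble: `z_mm`, `t_s`, `mean`, `sd`, `ci`.
#' @export
tidy.repeat_stats <- function(x, ...) {
  tibble::tibble(
    z_mm = rep(x$z_mm, times = length(x$t_s)),
    t_s = rep(x$t_s, each = length(x$z_mm)),
    mean = as.numeric(x$mean_map),
    sd = as.numeric(x$sd_map),
    ci = as.numeric(x$ci_map)
  )
}

#' @rdname tidy.repeat_stats
#' @export
glance.repeat_stats <- function(x, ...) {
  tibble::tibble(n_reps = x$n_reps, max_sd = x$max_sd, max_ci = x$max_ci,
                 c_max = x$c_max,
                 percent_dynamic_range = x$percent_dynamic_range)
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @return The long per-point differences tibble.
#' @export
tidy.bland_altman <- function(x, ...) x$differences

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_difference = x$mean_difference,
                 sd_difference = x$sd_difference,
                 lower_limit = x$lower_limit, upper_limit = x$upper_limit)
}

#' Tidy a concentration field or spatial-temporal map
#'
#' @param x A `concentration_field` or `spatiotemporal_map`.
#' @param ... Unused.
#' @return Long tibble `z_mm`, `t_s`, `concentration_uM`.
#' @export
tidy.concentration_field <- function(x, ...) {
  tibble::tibble(
    z_mm = rep(x$z_mm, times = length(x$t_s)),
    t_s = rep(x$t_s, each = length(x$z_mm)),
    concentration_uM = as.numeric(x$C)
  )
}
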