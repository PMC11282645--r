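#' Repeatability statistics across repetitions
#'
#' Pointwise mean and sample standard deviation across repeated
#' spatial-temporal maps, the 95% confidence band as 1.96 x SD (the
#' limits-of-agreement convention), and the maximum CI expressed as a percent
#' of the dynamic range, `%DR = max CI / C_max * 100`, where `C_max` is the
#' maximum of the repetition-mean map.
#'
#' @param maps List of at least two `spatiotemporal_map`s (or
#'   `concentration_field`s) on identical grids.
#' @return A `repeat_stats` object with `mean_map`, `sd_map`, `ci_map`
#'   (matrices), `max_sd`, `max_ci`, `c_max` (µM) and
#'   `percent_dynamic_range` (%).
#' @export
repetition_stats <- function(maps) {
  if (length(maps) < 2) stop("need at least two repetitions")
  z <- maps[[1]]$z_mm; t <- maps[[1]]$t_s
  for (m in maps[-1]) {
    if (length(m$z_mm) != length(z) || any(abs(m$z_mm - z) > 1e-8) ||
        length(m$t_s) != length(t) || any(abs(m$t_s - t) > 1e-6)) {
      stop("all repetitions must share the same grid")
    }
  }
  arr <- simplify2array(lapply(maps, `[[`, "C"))  # z x t x rep
  mean_map <- apply(arr, c(1, 2), mean)
  sd_map <- apply(arr, c(1, 2), stats::sd)
  ci_map <- 1.96 * sd_map
  c_max <- max(mean_map)
  structure(list(
    mean_map = mean_map, sd_map = sd_map, ci_map = ci_map,
    z_mm = z, t_s = t, n_reps = length(maps),
    max_sd = max(sd_map), max_ci = max(ci_map), c_max = c_max,
    percent_dynamic_range = if (c_max > 0) max(ci_map) / c_max * 100 else 0
  ), class = "repeat_stats")
}

#' @export
print.repeat_stats <- function(x, ...) {
  cat(sprintf("Repeatability over %d repetitions\n", x$n_reps))
  cat(sprintf("  max SD = %.2f uM, max 95%% CI = %.2f uM (%.2f%% of range, C_max = %.2f uM)\n",
              x$max_sd, x$max_ci, x$percent_dynamic_range, x$c_max))
  invisible(x)
}

#' Bland-Altman agreement between repetitions
#'
#' Differences of each repetition from the pointwise mean of repetitions,
#' with the overall mean difference and limits of agreement
#' (mean difference ± 1.96 x SD of the differences).
#'
#' @param values A repetitions-by-points numeric matrix, or a list of
#'   equal-length numeric vectors (one per repetition).
#' @return A `bland_altman` object with the long `differences` tibble
#'   (`repetition`, `point`, `mean_value`, `difference`), `mean_difference`,
#'   `lower_limit`, `upper_limit`, and per-repetition mean differences.
#' @export
bland_altman <- function(values) {
  if (is.list(values) && !is.matrix(values)) {
    lens <- lengths(values)
    if (length(unique(lens)) != 1) stop("repetitions must have equal length")
    values <- do.call(rbind, values)
  }
  if (nrow(values) < 2) stop("need at least two repetitions")
  m <- colMeans(values)
  d <- sweep(values, 2, m)
  diffs <- as.numeric(t(d))
  md <- mean(diffs)
  sdd <- stats::sd(diffs)
  long <- tibble::tibble(
    repetition = rep(seq_len(nrow(values)), each = ncol(values)),
    point = rep(seq_len(ncol(values)), nrow(values)),
    mean_value = rep(m, nrow(values)),
    difference = as.numeric(t(d))
  )
  structure(list(
    differences = long,
    mean_difference = md,
    sd_difference = sdd,
    lower_limit = md - 1.96 * sdd,
    upper_limit = md + 1.96 * sdd,
    per_repetition_mean = rowMeans(d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g, limits of agreement [%.4g, %.4g]\n",
              x$mean_difference, x$lower_limit, x$upper_limit))
  invisible(x)
}

#' Compare two protocols' percent-injected-dose values
#'
#' Unpaired two-sample t-test (Student's pooled-variance by default; Welch
#' optionally) on per-repetition %ID values, reporting
#' `delta = mean(b) - mean(a)` and significance at alpha = 0.05. Degenerate
#' zero-variance inputs return finite sentinels: equal means give `t = 0`,
#' `p = 1`; unequal means give a large-magnitude `t` and `p` at the smallest
#' representable double.
#'
#' @param name Parameter-group label (e.g. `"location"`).
#' @param a_values,b_values Numeric %ID vectors (n >= 2 each) for the
#'   reference and comparison protocols.
#' @param protocols Optional length-2 character naming the pair.
#' @param var_equal Pooled-variance test if `TRUE` (default); Welch otherwise.
#' @param alpha Significance level, default 0.05.
#' @return A `group_comparison` object; see [tidy()].
#' @export
group_comparison <- function(name, a_values, b_values, protocols = c(NA, NA),
                             var_equal = TRUE, alpha = 0.05) {
  if (length(a_values) < 2 || length(b_values) < 2) {
    stop("each group needs at least two repetitions")
  }
  delta <- mean(b_values) - mean(a_values)
  va <- stats::var(a_values); vb <- stats::var(b_values)
  if (va == 0 && vb == 0) {
    if (delta == 0) { tstat <- 0; p <- 1 } else {
      tstat <- sign(delta) / .Machine$double.eps
      p <- .Machine$double.xmin
    }
  } else {
    tt <- stats::t.test(b_values, a_values, var.equal = var_equal)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(
    name = name, protocols = protocols,
    a_values = a_values, b_values = b_values,
    mean_a = mean(a_values), mean_b = mean(b_values),
    delta_percent_id = delta, t_statistic = tstat, p_value = p,
    significant = p < alpha, alpha = alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s vs %s): %.1f vs %.1f, delta %+.1f%%ID, p = %.4g%s\n",
              x$name, x$protocols[1], x$protocols[2], x$mean_a, x$mean_b,
              x$delta_percent_id, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Default injection-parameter groupings
#'
#' The five parameter contrasts of the eight-protocol study, each pairing a
#' reference protocol `a` with a comparison protocol `b` differing in exactly
#' one injection parameter.
#' @return A tibble `parameter`, `a`, `b`.
#' @export
parameter_groups <- function() {
  tibble::tribble(
    ~parameter,     ~a,      ~b,
    "location",     "2NHP2", "3G1",
    "bolus_volume", "1NHP1", "3G2",
    "bolus_rate",   "1NHP3", "1NHP2",
    "flush_volume", "1NHP2", "2G2",
    "flush_rate",   "5NHP1", "2G2"
  )
}

#' Group-contrast table across all parameter groups
#'
#' Computes one [group_comparison()] per injection-parameter pair from a long
#' table of per-repetition %ID values.
#'
#' @param percent_ids Tibble with columns `protocol` and `percent_id` (one
#'   row per repetition).
#' @param groups Pairing table as from [parameter_groups()].
#' @param ... Passed to [group_comparison()].
#' @return A tibble with one row per group: `parameter`, `protocol_a`,
#'   `protocol_b`, `mean_a`, `mean_b`, `delta_percent_id`, `t_statistic`,
#'   `p_value`, `significant`, and the comparison objects in a list column.
#' @export
delta_table <- function(percent_ids, groups = parameter_groups(), ...) {
  need <- unique(c(groups$a, groups$b))
  missing <- setdiff(need, unique(percent_ids$protocol))
  if (length(missing)) {
    stop("missing protocol(s): ", paste(missing, collapse = ", "))
  }
  comps <- purrr::pmap(groups, function(parameter, a, b) {
    group_comparison(parameter,
                     percent_ids$percent_id[percent_ids$protocol == a],
                     percent_ids$percent_id[percent_ids$protocol == b],
                     protocols = c(a, b), ...)
  })
  tibble::tibble(
    parameter = groups$parameter,
    protocol_a = groups$a,
    protocol_b = groups$b,
    mean_a = vapply(comps, `[[`, numeric(1), "mean_a"),
    mean_b = vapply(comps, `[[`, numeric(1), "mean_b"),
    delta_percent_id = vapply(comps, `[[`, numeric(1), "delta_percent_id"),
    t_statistic = vapply(comps, `[[`, numeric(1), "t_statistic"),
    p_value = vapply(comps, `[[`, numeric(1), "p_value"),
    significant = vapply(comps, `[[`, logical(1), "significant"),
    comparison = comps
  )
}
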