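#' Lumbar injection protocols of the parametric study
#'
#' The eight-protocol study varies one lumbar-injection parameter at a time —
#' injection location (L4/L5 vs L3/L4), bolus volume, bolus rate, flush volume
#' and flush rate — while holding the injected tracer dose constant at
#' 165.5 µM·ml (concentration x bolus volume). The flush, where present, is
#' tracer-free.
#'
#' @param sites Named numeric vector mapping location labels to axial
#'   injection coordinates (mm, negative = spinal). Defaults place L4/L5 8 mm
#'   cranial of the caudal end of the default 280 mm canal and L3/L4 one
#'   vertebral spacing (8 mm) cranial of that.
#' @return A tibble with one row per protocol: `name`, `location`, `site_z`,
#'   `tracer_concentration_uM`, `bolus_volume_ml`, `bolus_rate_ml_min`,
#'   `flush_volume_ml`, `flush_rate_ml_min`.
#' @export
nhp_protocols <- function(sites = c("L4/L5" = -272, "L3/L4" = -264)) {
  tab <- tibble::tribble(
    ~name,    ~location, ~tracer_concentration_uM, ~bolus_volume_ml, ~bolus_rate_ml_min, ~flush_volume_ml, ~flush_rate_ml_min,
    "2NHP2",  "L4/L5",   331,    0.5, 1,   1.5, 1,
    "3G1",    "L3/L4",   331,    0.5, 1,   1.5, 1,
    "1NHP1",  "L3/L4",   165.5,  1,   1,   0,   0,
    "3G2",    "L3/L4",   82.75,  2,   1,   0,   0,
    "1NHP3",  "L4/L5",   165.5,  1,   0.1, 0,   0,
    "1NHP2",  "L4/L5",   165.5,  1,   1,   0,   0,
    "2G2",    "L4/L5",   165.5,  1,   1,   1.5, 1,
    "5NHP1",  "L4/L5",   165.5,  1,   1,   1.5, 0.5
  )
  tab$site_z <- unname(sites[tab$location])
  validate_protocols(tab)
  tab[, c("name", "location", "site_z", "tracer_concentration_uM",
          "bolus_volume_ml", "bolus_rate_ml_min", "flush_volume_ml",
          "flush_rate_ml_min")]
}

validate_protocols <- function(tab) {
  stopifnot(all(tab$tracer_concentration_uM > 0),
            all(tab$bolus_volume_ml >= 0), all(tab$flush_volume_ml >= 0))
  bad <- (tab$bolus_volume_ml > 0 & tab$bolus_rate_ml_min <= 0) |
    (tab$flush_volume_ml > 0 & tab$flush_rate_ml_min <= 0)
  if (any(bad)) {
    stop("rates must be positive wherever the corresponding volume is positive: ",
         paste(tab$name[bad], collapse = ", "))
  }
  invisible(tab)
}

#' Injected tracer mass of a protocol
#'
#' The dose denominator of the percent-injected-dose metric: tracer
#' concentration times bolus volume. The flush carries no tracer.
#'
#' @param protocol A one-row protocol data frame (see [nhp_protocols()]), or a
#'   protocol table, in which case a vector is returned.
#' @return Injected mass in µM·ml.
#' @export
injected_mass <- function(protocol) {
  protocol$tracer_concentration_uM * protocol$bolus_volume_ml
}

#' Read / write an injection-protocol table as CSV
#'
#' Columns: `name`, `location`, `tracer_concentration_uM`, `bolus_volume_ml`,
#' `bolus_rate_ml_min`, `flush_volume_ml`, `flush_rate_ml_min`, and optionally
#' `site_z`.
#'
#' @param path File path.
#' @param sites Named location-to-coordinate map used to fill `site_z` when
#'   the column is absent.
#' @return A protocol tibble.
#' @export
read_protocols <- function(path, sites = c("L4/L5" = -272, "L3/L4" = -264)) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  need <- c("name", "location", "tracer_concentration_uM", "bolus_volume_ml",
            "bolus_rate_ml_min", "flush_volume_ml", "flush_rate_ml_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("protocol CSV missing columns: ", paste(miss, collapse = ", "))
  df$flush_volume_ml[is.na(df$flush_volume_ml)] <- 0
  df$flush_rate_ml_min[is.na(df$flush_rate_ml_min)] <- 0
  if (!"site_z" %in% names(df)) df$site_z <- unname(sites[df$location])
  validate_protocols(df)
  df
}

#' @rdname read_protocols
#' @param protocols A protocol tibble.
#' @export
write_protocols <- function(protocols, path) {
  utils::write.csv(as.data.frame(protocols), path, row.names = FALSE)
  invisible(path)
}
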