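#' Transport parameters for the 1D dispersion simulator
#'
#' The simulator models cross-section-averaged tracer transport along the
#' CSF axis. Oscillatory cardiac/respiratory flow does not transport net mass
#' but enhances axial mixing; this is closed as a cycle-averaged effective
#' dispersion coefficient
#' `D_eff(z) = molecular_diffusivity + dispersion_factor * <|u(z)|> * h(z)`,
#' with `<|u|>` the cycle-mean axial speed `mean(|Q|)/A(z)` and `h(z)` a local
#' hydraulic length scale `sqrt(A(z))` (A as a cross-sectional area in mm^2).
#'
#' @param molecular_diffusivity Molecular diffusivity of the tracer (mm^2/s);
#'   default 5e-4, of the order of small-molecule dyes in water.
#' @param dispersion_factor Dimensionless multiplier on the oscillatory
#'   enhancement. The default (0.012) was fixed once so that a flushed L4/L5
#'   injection first delivers 1 µM to the foramen magnum between 15 and 45
#'   minutes, the qualitative timing seen in the bench model; it is a tuning,
#'   not a measurement.
#' @param production_rate CSF production rate (ml/min), default 0.018; fresh
#'   (tracer-free) fluid infused at `production_site_z`.
#' @param absorption_rate CSF absorption rate (ml/min), default 0.018; bulk
#'   fluid carrying the local concentration withdrawn at `absorption_site_z`.
#' @param production_site_z,absorption_site_z Axial coordinates (mm) of the
#'   ventricular production port and intracranial absorption port.
#' @return A `transport_params` list.
#' @export
transport_params <- function(molecular_diffusivity = 5e-4,
                             dispersion_factor = 0.012,
                             production_rate = 0.018,
                             absorption_rate = 0.018,
                             production_site_z = 40,
                             absorption_site_z = 30) {
  if (molecular_diffusivity <= 0) stop("molecular_diffusivity must be positive")
  if (dispersion_factor < 0 || production_rate < 0 || absorption_rate < 0) {
    stop("dispersion_factor and rates must be non-negative")
  }
  structure(list(
    molecular_diffusivity = molecular_diffusivity,
    dispersion_factor = dispersion_factor,
    production_rate = production_rate,
    absorption_rate = absorption_rate,
    production_site_z = production_site_z,
    absorption_site_z = absorption_site_z
  ), class = "transport_params")
}

new_concentration_field <- function(C, z_mm, t_s, mass_budget = NULL) {
  structure(list(C = C, z_mm = z_mm, t_s = t_s, mass_budget = mass_budget),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("Concentration field:", length(x$z_mm), "slices x", length(x$t_s),
      "frames\n")
  cat(sprintf("  z in [%.1f, %.1f] mm, t in [%.0f, %.0f] s, max C = %.3g uM\n",
              min(x$z_mm), max(x$z_mm), min(x$t_s), max(x$t_s), max(x$C)))
  invisible(x)
}

nearest_cell <- function(z_mm, z) {
  i <- which.min(abs(z_mm - z))
  if (abs(z_mm[i] - z) > diff(range(z_mm))) stop("site outside domain")
  i
}

#' Simulate 1D tracer transport for one injection protocol
#'
#' Finite-volume advection-dispersion on the geometry's 1 mm axial grid. The
#' bolus adds fluid and tracer mass at the injection site over its programmed
#' duration; the flush adds tracer-free fluid; CSF production adds fresh fluid
#' at the ventricular port and absorption removes fluid carrying the local
#' concentration at the intracranial port. The domain is rigid, so net
#' injected/produced volume leaves through the two domain ends in proportion
#' to the end cross-sectional areas, carrying the local concentration with it.
#' Dispersion is treated semi-implicitly (unconditionally stable); the slow
#' net drift is explicit first-order upwind with a CFL guard.
#'
#' @param geometry A [volume_profile()].
#' @param waveform A `flow_waveform`; only its cycle-mean absolute flow enters
#'   the effective-dispersion closure.
#' @param protocol One row of a protocol table (see [nhp_protocols()]).
#' @param params A [transport_params()].
#' @param duration Simulated time (s), default 10800 (3 h).
#' @param dt Time step (s) while injection flow is active, default 0.5. An
#'   unstable value errors with the stability bound.
#' @param dt_coast Upper bound on the step used outside injection windows
#'   (dispersion is implicit, so only the small production/absorption drift
#'   limits it), default 5.
#' @param frame_interval Output sampling interval (s), default 30.
#' @param injection_start Time (s) at which the bolus begins, default 30.
#' @param end_outflow If `FALSE`, the domain ends are closed (a numerical
#'   test mode: excess injected volume is not advected out).
#' @param initial Optional initial concentration vector (µM) per slice.
#' @return A `concentration_field` with the concentration matrix `C`
#'   (slices x frames, µM), grids `z_mm` and `t_s`, and a per-frame
#'   `mass_budget` tibble (`t_s`, `domain_mass`, `injected_cum`,
#'   `absorbed_cum`, `outflow_cum`, all µM·ml).
#' @export
simulate_transport <- function(geometry, waveform, protocol, params,
                               duration = 10800, dt = 0.5, dt_coast = 5,
                               frame_interval = 30, injection_start = 30,
                               end_outflow = TRUE, initial = NULL) {
  z <- geometry$z_mm
  dz <- slice_thickness(geometry)
  V <- geometry$volume_ml
  n <- length(z)
  A <- V / dz                              # ml/mm
  A_mm2 <- A * 1000                        # mm^2
  if (any(A <= 0)) stop("geometry must have positive area everywhere")

  # effective dispersion per cell and at faces
  mean_abs_q <- mean(abs(waveform$q_ml_per_s))       # ml/s
  u_osc <- mean_abs_q / A                            # mm/s
  D_eff <- params$molecular_diffusivity +
    params$dispersion_factor * u_osc * sqrt(A_mm2)   # mm^2/s
  D_face <- (D_eff[-n] + D_eff[-1]) / 2
  A_face <- (A[-n] + A[-1]) / 2
  g <- D_face * A_face / dz                          # (uM*ml/s) per uM

  # implicit dispersion operator (shared across steps; dt enters diagonally)
  K <- Matrix::bandSparse(n, n,
    k = c(-1, 0, 1),
    diagonals = list(-g, c(g, 0) + c(0, g), -g),
    symmetric = FALSE
  )

  site <- nearest_cell(z, protocol$site_z)
  if (abs(z[site] - protocol$site_z) > dz) stop("injection site outside domain")
  prod_cell <- nearest_cell(z, params$production_site_z)
  abs_cell <- nearest_cell(z, params$absorption_site_z)
  q_prod <- params$production_rate / 60
  q_abs <- params$absorption_rate / 60

  r_bolus <- protocol$bolus_rate_ml_min / 60
  r_flush <- protocol$flush_rate_ml_min / 60
  t_b0 <- injection_start
  t_b1 <- t_b0 + if (protocol$bolus_volume_ml > 0) {
    60 * protocol$bolus_volume_ml / protocol$bolus_rate_ml_min
  } else 0
  t_f1 <- t_b1 + if (protocol$flush_volume_ml > 0) {
    60 * protocol$flush_volume_ml / protocol$flush_rate_ml_min
  } else 0

  frame_t <- seq(0, duration, by = frame_interval)
  breaks <- sort(unique(c(frame_t, t_b0, t_b1, t_f1)))
  breaks <- breaks[breaks >= 0 & breaks <= duration]

  C <- if (is.null(initial)) numeric(n) else {
    stopifnot(length(initial) == n, all(initial >= 0))
    as.numeric(initial)
  }

  out <- matrix(0, n, length(frame_t))
  budget <- matrix(0, length(frame_t), 4)
  injected_cum <- absorbed_cum <- outflow_cum <- 0
  w_caud <- A[1] / (A[1] + A[n])

  record <- function(k) {
    out[, k] <<- C
    budget[k, ] <<- c(sum(V * C), injected_cum, absorbed_cum, outflow_cum)
  }
  fidx <- 1
  if (breaks[1] == frame_t[fidx]) { record(fidx); fidx <- fidx + 1 }

  fact_cache <- list()
  get_fact <- function(dts) {
    key <- sprintf("%.12g", dts)
    f <- fact_cache[[key]]
    if (is.null(f)) {
      M <- K + Matrix::Diagonal(n, V / dts)
      f <- Matrix::lu(M)
      fact_cache[[key]] <<- f
    }
    f
  }

  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    mid <- (t0 + t1) / 2
    inj_rate <- if (mid >= t_b0 && mid < t_b1) r_bolus
                else if (mid >= t_b1 && mid < t_f1) r_flush else 0
    tracer_rate <- if (mid >= t_b0 && mid < t_b1) {
      r_bolus * protocol$tracer_concentration_uM
    } else 0

    S <- numeric(n)
    S[site] <- S[site] + inj_rate
    S[prod_cell] <- S[prod_cell] + q_prod
    S[abs_cell] <- S[abs_cell] - q_abs
    S_tot <- sum(S)
    if (end_outflow) {
      Q_caud <- -S_tot * w_caud           # boundary face flow, +z positive
      Q_cran <- S_tot * (1 - w_caud)
    } else {
      Q_caud <- Q_cran <- 0
    }
    Qf <- c(Q_caud, Q_caud + cumsum(S))   # n+1 face flows; last ~ Q_cran
    if (end_outflow) Qf[n + 1] <- Q_cran else Qf[n + 1] <- 0

    # CFL for the explicit drift
    cour_face <- abs(Qf[2:n]) / (pmin(A[-n], A[-1]) * dz)
    umax <- max(cour_face, abs(Qf[1]) / (A[1] * dz), abs(Qf[n + 1]) / (A[n] * dz))
    active <- inj_rate > 0
    dt_req <- if (active) dt else dt_coast
    if (umax > 0 && active && dt > 1 / umax) {
      stop(sprintf("dt = %g s unstable for drift; CFL bound is %.4g s", dt, 1 / umax))
    }
    if (umax > 0) dt_req <- min(dt_req, 0.5 / umax)
    nsub <- max(1L, ceiling((t1 - t0) / dt_req - 1e-9))
    dts <- (t1 - t0) / nsub
    fact <- get_fact(dts)

    for (k in seq_len(nsub)) {
      # upwind advective mass fluxes across faces (+z positive)
      Fint <- ifelse(Qf[2:n] > 0, Qf[2:n] * C[-n], Qf[2:n] * C[-1])
      F1 <- if (Qf[1] > 0) 0 else Qf[1] * C[1]
      Fn1 <- if (Qf[n + 1] > 0) Qf[n + 1] * C[n] else 0
      Fl <- c(F1, Fint, Fn1)
      m <- V * C + dts * (Fl[1:n] - Fl[2:(n + 1)])
      m[site] <- m[site] + dts * tracer_rate
      m[abs_cell] <- m[abs_cell] - dts * q_abs * C[abs_cell]
      injected_cum <- injected_cum + dts * tracer_rate
      absorbed_cum <- absorbed_cum + dts * q_abs * C[abs_cell]
      outflow_cum <- outflow_cum + dts * (max(-Fl[1], 0) + max(Fl[n + 1], 0))
      # implicit dispersion: (V/dts + K) C_new = m / dts
      C <- as.numeric(Matrix::solve(fact, m / dts))
      C[C < 0 & C > -1e-12] <- 0
    }
    if (fidx <= length(frame_t) && abs(t1 - frame_t[fidx]) < 1e-9) {
      record(fidx); fidx <- fidx + 1
    }
  }

  mb <- tibble::tibble(
    t_s = frame_t,
    domain_mass = budget[, 1],
    injected_cum = budget[, 2],
    absorbed_cum = budget[, 3],
    outflow_cum = budget[, 4]
  )
  new_concentration_field(out, z, frame_t, mass_budget = mb)
}

#' Tracer mass-budget closure of a simulated field
#'
#' For every output frame, compares cumulative injected mass with the sum of
#' the mass present in the domain, the mass absorbed, and the mass advected
#' out through the domain ends.
#'
#' @param field A `concentration_field` from [simulate_transport()].
#' @return A tibble with columns `t_s`, `injected_cum`, `accounted` and
#'   `relative_error` (|injected - accounted| / injected; 0 where nothing has
#'   been injected yet).
#' @export
mass_budget_check <- function(field) {
  mb <- field$mass_budget
  if (is.null(mb)) stop("field has no mass budget (not produced by simulate_transport)")
  accounted <- mb$domain_mass + mb$absorbed_cum + mb$outflow_cum
  rel <- ifelse(mb$injected_cum > 0,
                abs(mb$injected_cum - accounted) / mb$injected_cum, 0)
  tibble::tibble(t_s = mb$t_s, injected_cum = mb$injected_cum,
                 accounted = accounted, relative_error = rel)
}

#' Write / read a concentration field as a CSV matrix
#'
#' Rows are axial slices, columns time frames; the first column holds `z_mm`
#' and the header row the frame times (seconds, prefixed `t`).
#'
#' @param field A `concentration_field` (or `spatiotemporal_map`).
#' @param path File path.
#' @return `read_concentration_field()` returns a `concentration_field`.
#' @export
write_concentration_field <- function(field, path) {
  df <- data.frame(z_mm = field$z_mm, field$C, check.names = FALSE)
  names(df) <- c("z_mm", paste0("t", field$t_s))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentration_field
#' @export
read_concentration_field <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  t_s <- as.numeric(sub("^t", "", names(df)[-1]))
  new_concentration_field(unname(as.matrix(df[, -1, drop = FALSE])), df$z_mm, t_s)
}
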