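#' Waveform synthesis configuration
#'
#' Parameters for the combined cardiac + respiratory CSF flow waveform. The
#' defaults are the cynomolgus conditions used throughout the package: heart
#' rate 120 bpm, respiratory amplitude 0.52 of the cardiac amplitude and
#' respiratory frequency 1/4.29 of the cardiac frequency, normalized to a
#' stroke volume of 0.2597 ml.
#'
#' @param heart_rate Heart rate (beats per minute).
#' @param amplitude_ratio Respiratory-to-cardiac flow-amplitude ratio.
#' @param frequency_ratio Cardiac-to-respiratory frequency ratio.
#' @param target_stroke_volume Target stroke volume (ml) of the combined
#'   waveform.
#' @param sample_rate Sampling rate (Hz).
#' @param duration Record length (s). The default holds whole cardiac cycles.
#' @param cardiac_template Either `"biphasic"` (built-in parametric shape:
#'   zero-mean fundamental plus a 0.3-weight second harmonic giving a skewed
#'   systolic peak — a stand-in for a measured C2-C3 waveform), `"sine"`, or a
#'   data frame with columns `t_s`, `q_ml_per_s` sampling one cardiac period.
#' @return A `waveform_config` list.
#' @export
waveform_config <- function(heart_rate = 120,
                            amplitude_ratio = 0.52,
                            frequency_ratio = 4.29,
                            target_stroke_volume = 0.2597,
                            sample_rate = 200,
                            duration = 30,
                            cardiac_template = "biphasic") {
  if (heart_rate <= 0) stop("heart_rate must be positive")
  if (amplitude_ratio < 0) stop("amplitude_ratio must be non-negative")
  if (frequency_ratio <= 0 || target_stroke_volume <= 0 ||
      sample_rate <= 0 || duration <= 0) {
    stop("frequency_ratio, target_stroke_volume, sample_rate and duration must be positive")
  }
  structure(list(
    heart_rate = heart_rate,
    amplitude_ratio = amplitude_ratio,
    frequency_ratio = frequency_ratio,
    target_stroke_volume = target_stroke_volume,
    sample_rate = sample_rate,
    duration = duration,
    cardiac_template = cardiac_template
  ), class = "waveform_config")
}

new_flow_waveform <- function(t, q, cardiac_period, respiratory_period = NA_real_) {
  out <- tibble::tibble(t_s = t, q_ml_per_s = q)
  attr(out, "cardiac_period") <- cardiac_period
  attr(out, "respiratory_period") <- respiratory_period
  class(out) <- c("flow_waveform", class(out))
  out
}

cardiac_shape <- function(phase, template) {
  if (is.data.frame(template)) {
    if (!all(c("t_s", "q_ml_per_s") %in% names(template))) {
      stop("cardiac template data frame needs columns t_s, q_ml_per_s")
    }
    tt <- template$t_s - template$t_s[1]
    period <- tt[length(tt)] + (tt[2] - tt[1])
    ph <- (phase / (2 * pi)) %% 1
    q <- stats::approx(c(tt / period, 1), c(template$q_ml_per_s, template$q_ml_per_s[1]),
                       xout = ph, rule = 2)$y
    q
  } else if (identical(template, "sine")) {
    sin(phase)
  } else if (identical(template, "biphasic")) {
    # skewed systolic peak: fundamental + 0.3-weight second harmonic
    sin(phase) + 0.3 * sin(2 * phase)
  } else {
    stop("unknown cardiac template: ", template)
  }
}

#' Cardiac component of the CSF flow waveform
#'
#' Synthesizes a zero-mean periodic waveform at the cardiac period
#' (60 / heart rate seconds), normalized to unit peak amplitude. The shape is
#' either a built-in parametric template or a user-supplied one-period sample
#' series resampled onto the output grid.
#'
#' @param config A [waveform_config()].
#' @return A `flow_waveform` tibble (`t_s`, `q_ml_per_s`) with the cardiac
#'   period stored as an attribute.
#' @export
cardiac_component <- function(config = waveform_config()) {
  stopifnot(inherits(config, "waveform_config"))
  period <- 60 / config$heart_rate
  t <- seq(0, config$duration, by = 1 / config$sample_rate)
  q <- cardiac_shape(2 * pi * t / period, config$cardiac_template)
  q <- q - mean(q)
  pk <- max(abs(q))
  if (pk == 0) stop("cardiac template has zero amplitude")
  new_flow_waveform(t, q / pk, cardiac_period = period)
}

#' Combined cardiac + respiratory CSF flow waveform
#'
#' Superimposes the cardiac component with a sinusoidal respiratory component
#' whose peak amplitude is `amplitude_ratio` times the cardiac amplitude and
#' whose frequency is the cardiac frequency divided by `frequency_ratio`. The
#' sum is rescaled so that its stroke volume equals `target_stroke_volume`,
#' then any residual sample mean is removed (the waveform is oscillatory with
#' zero net flow).
#'
#' @param config A [waveform_config()].
#' @return A `flow_waveform` with attributes `cardiac_period`,
#'   `respiratory_period` and `stroke_volume`.
#' @export
combined_waveform <- function(config = waveform_config()) {
  card <- cardiac_component(config)
  t <- card$t_s
  period <- attr(card, "cardiac_period")
  resp_period <- period * config$frequency_ratio
  resp <- config$amplitude_ratio * sin(2 * pi * t / resp_period)
  resp <- resp - mean(resp)
  q <- card$q_ml_per_s + resp
  w <- new_flow_waveform(t, q, cardiac_period = period,
                         respiratory_period = resp_period)
  sv <- stroke_volume(w)
  if (sv <= 0) stop("combined waveform has zero stroke volume before scaling")
  q <- q * config$target_stroke_volume / sv
  q <- q - mean(q)
  w <- new_flow_waveform(t, q, cardiac_period = period,
                         respiratory_period = resp_period)
  attr(w, "stroke_volume") <- stroke_volume(w)
  w
}

#' Stroke volume of a flow waveform
#'
#' The CSF volume displaced per cardiac cycle: the integral of the positive
#' part of the flow rate over one cardiac period, averaged over all whole
#' cardiac cycles contained in the record (trapezoidal integration).
#'
#' @param w A `flow_waveform`.
#' @param cardiac_period Cardiac period (s); taken from the waveform's
#'   attribute when omitted.
#' @return Stroke volume (ml).
#' @export
stroke_volume <- function(w, cardiac_period = attr(w, "cardiac_period")) {
  if (is.null(cardiac_period) || is.na(cardiac_period) || cardiac_period <= 0) {
    stop("cardiac_period must be supplied for waveforms without one")
  }
  t <- w$t_s
  span <- t[length(t)] - t[1]
  ncyc <- floor(span / cardiac_period + 1e-9)
  if (ncyc < 1) stop("record shorter than one cardiac period")
  qp <- pmax(w$q_ml_per_s, 0)
  sv <- vapply(seq_len(ncyc), function(k) {
    sel <- t >= t[1] + (k - 1) * cardiac_period - 1e-12 &
      t <= t[1] + k * cardiac_period + 1e-12
    pracma::trapz(t[sel], qp[sel])
  }, numeric(1))
  mean(sv)
}

#' Root-mean-square error between two waveforms
#'
#' @param a,b `flow_waveform`s on the same time grid.
#' @return RMSE (ml/s).
#' @export
waveform_rmse <- function(a, b) {
  if (nrow(a) != nrow(b) || any(abs(a$t_s - b$t_s) > 1e-9)) {
    stop("waveforms must share the same time grid")
  }
  sqrt(mean((a$q_ml_per_s - b$q_ml_per_s)^2))
}

#' Read / write a flow waveform as CSV
#'
#' Columns `t_s`, `q_ml_per_s` with a header row.
#'
#' @param path File path.
#' @param cardiac_period Cardiac period (s) to attach on read, if known.
#' @return `read_waveform()` returns a `flow_waveform`; `write_waveform()`
#'   returns `path` invisibly.
#' @export
read_waveform <- function(path, cardiac_period = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "q_ml_per_s") %in% names(df))) {
    stop("waveform CSV must have columns t_s, q_ml_per_s")
  }
  new_flow_waveform(df$t_s, df$q_ml_per_s, cardiac_period = cardiac_period)
}

#' @rdname read_waveform
#' @param w A `flow_waveform`.
#' @export
write_waveform <- function(w, path) {
  utils::write.csv(as.data.frame(w[, c("t_s", "q_ml_per_s")]), path,
                   row.names = FALSE)
  invisible(path)
}
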