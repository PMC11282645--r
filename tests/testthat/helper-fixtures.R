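# Small fixtures shared across test files. Everything is generated in code.

uniform_geometry <- function(n = 100, area_ml_per_mm = 0.05, dz = 1,
                             z0 = -n * dz / 2) {
  z <- seq(z0 + dz / 2, by = dz, length.out = n)
  volume_profile(z, rep(area_ml_per_mm * dz, n), slice_thickness = dz)
}

quick_waveform <- function(duration = 5, sample_rate = 200) {
  combined_waveform(waveform_config(duration = duration,
                                    sample_rate = sample_rate))
}

still_waveform <- function() {
  # near-zero oscillation: removes the oscillatory dispersion enhancement
  w <- combined_waveform(waveform_config(duration = 2,
                                         target_stroke_volume = 1e-12))
  w
}

single_protocol <- function(name = "TEST", site_z = -272,
                            conc = 165.5, bolus_vol = 1, bolus_rate = 1,
                            flush_vol = 0, flush_rate = 0) {
  tibble::tibble(
    name = name, location = "L4/L5", site_z = site_z,
    tracer_concentration_uM = conc, bolus_volume_ml = bolus_vol,
    bolus_rate_ml_min = bolus_rate, flush_volume_ml = flush_vol,
    flush_rate_ml_min = flush_rate
  )
}

# a scaled-down study configuration for pipeline tests: 30 min imaging
quick_config <- function(...) {
  study_config(
    quant = quant_config(duration = 0.5,
                         auc_windows = list(c(0, 0.25), c(0, 0.5))),
    image_width = 8,
    ...
  )
}

make_field <- function(C, z_mm = seq_len(nrow(C)) - 0.5,
                       t_s = (seq_len(ncol(C)) - 1) * 30) {
  csfdispersion:::new_concentration_field(C, z_mm, t_s)
}
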