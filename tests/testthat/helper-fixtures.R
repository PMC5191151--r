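# Shared fixtures: noiseless spec and small analytic helpers used as
# independent oracles against the integer pipeline.

spec_clean <- function(...) sensor_spec(noise_sd_g = 0, ...)

# Floating-point oracle for the tilt decomposition.
oracle_angles <- function(ax, ay, az) {
  list(
    pitch = atan2(ax, sqrt(ay^2 + az^2)) * 180 / pi,
    roll = atan2(ay, az) * 180 / pi,
    inclination = atan2(sqrt(ax^2 + ay^2), az) * 180 / pi
  )
}

magnitude_g <- function(rec, ch = "CHEST") {
  spec <- recording_spec(rec)
  d <- rec[rec$placement == ch, ]
  sqrt(d$ax^2 + d$ay^2 + d$az^2) * spec$lsb_g
}
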