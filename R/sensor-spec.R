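#' Sensor front-end specification
#'
#' Describes the acquisition parameters of one 3-axis MEMS accelerometer as
#' configured on the vest: a sensing range of +/- `range_g` gravity units
#' digitized at `resolution_bits` bits and sampled at `sample_rate_hz`. The
#' defaults reproduce the vest's configuration: +/-2 g, 12 bits, 100 Hz, with a
#' sensitivity (least significant bit) of 1 mg where 1 mg = 2^-10 g = 1/1024 g,
#' so 1 g corresponds to 1024 counts and positive full scale is 2047 counts.
#'
#' `lsb_g` is tied to the range and resolution by the two's-complement ADC
#' relation `lsb_g * 2^(resolution_bits - 1) = range_g`; the constructor
#' asserts it.
#'
#' @param range_g Half-range of the sensor in gravity units (the sensor spans
#'   `[-range_g, +range_g)`). Default 2.
#' @param resolution_bits ADC resolution in bits, between 8 and 16. Default 12.
#' @param sample_rate_hz Sampling rate in Hz. Default 100.
#' @param lsb_g Gravity units per count. Default `2^-10` (1 mg).
#' @param noise_sd_g Standard deviation of the additive white per-axis sensor
#'   noise, in gravity units. Default 0.005.
#' @param bias_g Numeric length-3 per-axis bias in gravity units. Default 0.
#'
#' @return An object of class `pk_sensor_spec` (a named list).
#' @examples
#' spec <- sensor_spec()
#' spec$lsb_g * 2^(spec$resolution_bits - 1) # = range_g
#' @export
sensor_spec <- function(range_g = 2, resolution_bits = 12L, sample_rate_hz = 100,
                        lsb_g = 2^-10, noise_sd_g = 0.005,
                        bias_g = c(0, 0, 0)) {
  resolution_bits <- as.integer(resolution_bits)
  if (!is.numeric(range_g) || length(range_g) != 1 || range_g <= 0)
    abort("`range_g` must be a single positive number.")
  if (resolution_bits < 8L || resolution_bits > 16L)
    abort("`resolution_bits` must lie in [8, 16].")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    abort("`sample_rate_hz` must be positive.")
  if (!isTRUE(all.equal(lsb_g * 2^(resolution_bits - 1), range_g)))
    abort("`lsb_g * 2^(resolution_bits - 1)` must equal `range_g` (two's-complement ADC).")
  if (!is.numeric(noise_sd_g) || length(noise_sd_g) != 1 || noise_sd_g < 0)
    abort("`noise_sd_g` must be a single non-negative number.")
  if (length(bias_g) == 1) bias_g <- rep(bias_g, 3)
  if (!is.numeric(bias_g) || length(bias_g) != 3)
    abort("`bias_g` must be numeric of length 3.")
  structure(
    list(range_g = range_g, resolution_bits = resolution_bits,
         sample_rate_hz = sample_rate_hz, lsb_g = lsb_g,
         noise_sd_g = noise_sd_g, bias_g = as.numeric(bias_g)),
    class = "pk_sensor_spec"
  )
}

#' @export
print.pk_sensor_spec <- function(x, ...) {
  cat(sprintf(
    "<pk_sensor_spec> +/-%g g, %d bit (lsb = %g g), %g Hz, noise sd %g g\n",
    x$range_g, x$resolution_bits, x$lsb_g, x$sample_rate_hz, x$noise_sd_g))
  invisible(x)
}

#' The five sensor placements of the vest
#'
#' The vest carries five accelerometers: on the lower cervical spine, the
#' middle of the chest, the lumbar L3 section of the back (the centre of mass,
#' COM), and the right and left sides of the waist. Channel ids 1..5 in the
#' streaming frame protocol follow this order.
#'
#' @return Character vector of the five placement names, in channel order.
#' @examples
#' placements()
#' @export
placements <- function() {
  c("CERVICAL", "CHEST", "COM_L3", "WAIST_RIGHT", "WAIST_LEFT")
}

count_bounds <- function(spec) {
  half <- bitwShiftL(1L, spec$resolution_bits - 1L)
  c(lo = -half, hi = half - 1L)
}

#' Quantize gravity-unit acceleration to integer sensor counts
#'
#' Applies the sensor front-end model: adds the per-axis bias, divides by the
#' least-significant-bit size, rounds half away from zero (so the mapping is
#' odd-symmetric), and saturates at the representable two's-complement bounds.
#' Under the default spec a 1 mg (= 2^-10 g) input step changes the output by
#' exactly one count.
#'
#' @param accel_g Acceleration in gravity units: a numeric length-3 vector
#'   `(x, y, z)`, or a data frame / matrix with three columns, one row per
#'   sample.
#' @param spec A [sensor_spec()].
#' @return A tibble with integer columns `ax`, `ay`, `az`, one row per sample.
#' @examples
#' quantize_sample(c(0, 0, 1), sensor_spec())     # (0, 0, 1024)
#' quantize_sample(c(0, 0, 9.9), sensor_spec())   # saturates at 2047
#' @export
quantize_sample <- function(accel_g, spec = sensor_spec()) {
  stopifnot(inherits(spec, "pk_sensor_spec"))
  if (is.numeric(accel_g) && is.null(dim(accel_g))) {
    if (length(accel_g) != 3) abort("`accel_g` vector must have length 3.")
    accel_g <- matrix(accel_g, nrow = 1)
  }
  m <- as.matrix(as.data.frame(accel_g))
  if (ncol(m) != 3) abort("`accel_g` must have exactly three columns (x, y, z).")
  tibble(
    ax = quantize_counts(m[, 1], spec, axis = 1L),
    ay = quantize_counts(m[, 2], spec, axis = 2L),
    az = quantize_counts(m[, 3], spec, axis = 3L)
  )
}

# Workhorse: numeric g -> integer counts for one axis.
quantize_counts <- function(g, spec, axis = 1L) {
  if (any(!is.finite(g)))
    abort("Non-finite acceleration value cannot be quantized.")
  x <- (g + spec$bias_g[axis]) / spec$lsb_g
  counts <- trunc(x + 0.5 * sign(x)) # round half away from zero: odd-symmetric
  b <- count_bounds(spec)
  as.integer(pmin(pmax(counts, b["lo"]), b["hi"]))
}

#' Convert integer counts back to gravity units
#'
#' Inverse of the quantizer up to quantization error: multiplies by the LSB
#' size. Bias is not removed (the analysis stages treat bias as part of the
#' signal, as the hardware does).
#'
#' @param counts Integer counts.
#' @param spec A [sensor_spec()].
#' @return Numeric acceleration in gravity units.
#' @export
counts_to_g <- function(counts, spec = sensor_spec()) {
  counts * spec$lsb_g
}
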