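#' Arctangent lookup table for the CORDIC core
#'
#' Builds the table of micro-rotation angles `atan(2^-i)`, `i = 0 ..
#' n_iter-1`, stored as integers in units of `1/scale` degree. The first entry
#' encodes 45 degrees; entries are strictly decreasing. Entries are rounded to
#' nearest, so the accumulated rounding error is at most `n_iter / (2 *
#' scale)` degrees — far below the final rotation step.
#'
#' @param n_iter Number of CORDIC iterations, in `[1, 24]` (above 24 the
#'   entries round to zero at micro-degree scale and add nothing). Default 16.
#' @param scale Integer units per degree. Default `1e6` (micro-degrees).
#' @return A `pk_angle_lut`: list with integer `entries`, `n_iter`, `scale`.
#' @examples
#' build_atan_lut(2)$entries # 45000000, 26565051
#' @export
build_atan_lut <- function(n_iter = 16L, scale = 1e6) {
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L || n_iter > 24L) abort("`n_iter` must lie in [1, 24].")
  # 180 * scale must be representable: quadrant offsets share the unit.
  if (180 * scale >= 2^31) abort("`scale` overflows 32-bit angle units.")
  entries <- as.integer(round(atan(2^-(0:(n_iter - 1))) * 180 / pi * scale))
  structure(list(entries = entries, n_iter = n_iter, scale = scale),
            class = "pk_angle_lut")
}

#' CORDIC gain for a given iteration count
#'
#' The vectoring micro-rotations are not normalized, so the output magnitude
#' is inflated by `K = prod(sqrt(1 + 2^-2i))` (about 1.6468 as the iteration
#' count grows).
#'
#' @param n_iter Number of iterations.
#' @return The gain `K` as a double.
#' @export
cordic_gain <- function(n_iter = 16L) {
  prod(sqrt(1 + 2^(-2 * (0:(n_iter - 1)))))
}

# Number of guard bits the inputs are shifted left by before iterating.
# Truncating arithmetic shifts would otherwise dominate the error for
# small-magnitude vectors; with 13-bit inputs and 16 guard bits every
# intermediate provably fits a 32-bit integer (see the interval-analysis
# bound in cordic_state_bound()).
.cordic_prescale <- 16L
.cordic_max_input <- 8191L

# Interval-analysis bound on |x|, |y| over the iterations, for inputs with
# max-norm `max_input` up-shifted by `prescale` bits. Used by tests to prove
# closure over 32-bit integers.
cordic_state_bound <- function(n_iter = 16L, max_input = .cordic_max_input,
                               prescale = .cordic_prescale) {
  X <- Y <- max_input * 2^prescale
  worst <- max(X, Y)
  for (i in 0:(n_iter - 1)) {
    X1 <- X + Y / 2^i          # x grows by |y| >> i
    Y1 <- max(Y, X / 2^i)      # |y| moves toward 0, overshoot bounded
    X <- X1; Y <- Y1
    worst <- max(worst, X, Y)
  }
  worst
}

#' CORDIC vectoring iteration (integer core)
#'
#' Rotates each input vector onto the positive x axis using only integer
#' add/subtract and arithmetic-shift operations, accumulating the rotation
#' angle from the lookup table. At iteration `i` the decision is
#' `d = -sign(y)` (with `sign(0) = +1`), and the state update is
#' `x <- x - d * (y >> i)`, `y <- y + d * (x >> i)`,
#' `z <- z - d * lut[i]`. On exit `z` approximates `atan(y/x)` in LUT units
#' and `x` approximates `K * sqrt(x0^2 + y0^2)` where `K` is the CORDIC gain.
#'
#' Inputs must already lie in the right half plane (`x > 0`); quadrant
#' pre-rotation is the caller's job (see [tilt_from_counts()]). Inputs are
#' up-shifted by 16 guard bits internally so that the truncation of the
#' arithmetic shifts is negligible; all intermediate state stays within
#' 32-bit integers for inputs up to 13 bits.
#'
#' @param x,y Integer vectors (counts), `x > 0`, `max(|x|, |y|) <= 8191`.
#' @param n_iter Number of iterations. Default 16.
#' @param lut A [build_atan_lut()] with at least `n_iter` entries; built on
#'   the fly if `NULL`.
#' @return A list with integer vectors `angle` (LUT units) and
#'   `magnitude_scaled` (gain-inflated counts).
#' @examples
#' v <- cordic_vectoring(1024L, 1024L)
#' v$angle / 1e6 # ~45 degrees
#' @export
cordic_vectoring <- function(x, y, n_iter = 16L, lut = NULL) {
  lut <- lut %||% build_atan_lut(n_iter)
  stopifnot(inherits(lut, "pk_angle_lut"), n_iter <= lut$n_iter)
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (any(x == 0L & y == 0L)) abort("Angle of the zero vector is undefined.")
  if (any(x <= 0L)) abort("`x` must be positive: pre-rotate into the right half plane.")
  if (any(pmax(abs(x), abs(y)) > .cordic_max_input))
    abort("Inputs exceed the 13-bit bound of the integer core.")
  s <- .cordic_prescale
  xx <- bitwShiftL(x, s)
  yy <- bitwShiftL(y, s)
  zz <- integer(length(x))
  for (i in 0:(n_iter - 1L)) {
    p2 <- bitwShiftL(1L, i)
    d <- ifelse(yy >= 0L, -1L, 1L)           # d = -sign(y), sign(0) = +1
    xs <- xx %/% p2                           # arithmetic shift right by i
    ys <- yy %/% p2
    x1 <- xx - d * ys
    yy <- yy + d * xs
    zz <- zz - d * lut$entries[i + 1L]
    xx <- x1
  }
  half <- bitwShiftL(1L, s - 1L)
  list(angle = zz, magnitude_scaled = (xx + half) %/% bitwShiftL(1L, s))
}

#' Remove the CORDIC gain from a magnitude
#'
#' Multiplies by the fixed-point reciprocal `round(2^15 / K)` and shifts back,
#' recovering the true magnitude within one count. The constant multiply is a
#' shift-add operation; no division or floating point touches the data path.
#'
#' @param magnitude_scaled Non-negative integer magnitudes as returned by
#'   [cordic_vectoring()].
#' @param n_iter Iteration count the magnitude was produced with.
#' @return Integer magnitudes in counts.
#' @examples
#' gain_compensate(round(cordic_gain(16) * 1024)) # 1024 (+/- 1)
#' @export
gain_compensate <- function(magnitude_scaled, n_iter = 16L) {
  m <- as.integer(magnitude_scaled)
  if (any(m < 0L)) abort("`magnitude_scaled` must be non-negative.")
  recip <- as.integer(round(2^15 / cordic_gain(n_iter)))
  as.integer((m * recip + 16384L) %/% 32768L)
}

# Full-plane arctangent: quadrant pre-rotation by sign swaps, vectoring, then
# fold-back. Returns angle in LUT units in (-180, 180] and the gain-inflated
# magnitude. Callers must mask out (0, 0) inputs beforehand.
cordic_atan2 <- function(x, y, n_iter = 16L, lut = NULL) {
  lut <- lut %||% build_atan_lut(n_iter)
  x <- as.integer(x); y <- as.integer(y)
  if (any(x == 0L & y == 0L)) abort("Angle of the zero vector is undefined.")
  xr <- x; yr <- y
  offset <- integer(length(x))
  i <- x <= 0L & y > 0L   # rotate by -90
  xr[i] <- y[i]; yr[i] <- -x[i]; offset[i] <- 90L
  i <- x <= 0L & y < 0L   # rotate by +90
  xr[i] <- -y[i]; yr[i] <- x[i]; offset[i] <- -90L
  i <- x < 0L & y == 0L   # rotate by 180
  xr[i] <- -x[i]; yr[i] <- 0L; offset[i] <- 180L
  v <- cordic_vectoring(xr, yr, n_iter, lut)
  list(angle = v$angle + offset * as.integer(lut$scale),
       magnitude_scaled = v$magnitude_scaled)
}

# Gain-compensated magnitude of (x, y); tolerates the zero vector.
cordic_mag <- function(x, y, n_iter = 16L, lut = NULL) {
  x <- abs(as.integer(x)); y <- abs(as.integer(y))
  out <- integer(length(x))
  nz <- !(x == 0L & y == 0L)
  if (any(nz)) {
    xx <- pmax(x[nz], y[nz]); yy <- pmin(x[nz], y[nz]) # swap keeps magnitude
    v <- cordic_vectoring(xx, yy, n_iter, lut)
    out[nz] <- gain_compensate(v$magnitude_scaled, n_iter)
  }
  out
}

#' Tilt angles from integer accelerometer counts
#'
#' Two-stage integer CORDIC pipeline converting one or more 3-axis samples to
#' tilt angles, in degrees:
#' * `roll` — rotation about the anterior (x) axis, `atan2(ay, az)`, full
#'   `(-180, 180]` range via quadrant pre-rotation;
#' * `pitch` — forward rotation of the trunk, `atan2(ax, sqrt(ay^2 + az^2))`
#'   in `[-90, 90]`, positive when leaning forward;
#' * `inclination` — the tilting angle proper: the angle between the sensor z
#'   axis (up the spine) and gravity, `atan2(sqrt(ax^2 + ay^2), az)` in
#'   `[0, 180]`.
#'
#' Stage 1 vectors the (az, ay) pair, yielding the roll and the in-plane
#' magnitude; the gain-compensated magnitude is then vectored against the
#' remaining axis in stage 2 to give pitch and inclination. All arithmetic on
#' the data path is integer add/subtract/shift; angles are converted from
#' scaled integer units (half-microdegrees: one guard bit over the
#' micro-degree LUT) to degrees only at this boundary. A gain-compensated
#' total magnitude is returned alongside, in counts.
#'
#' @param ax,ay,az Integer count vectors of equal length.
#' @param n_iter CORDIC iterations. Default 16.
#' @return A tibble with columns `pitch`, `roll`, `inclination` (degrees) and
#'   `magnitude` (counts).
#' @examples
#' tilt_from_counts(0L, 0L, 1024L)    # upright: all angles 0
#' tilt_from_counts(1024L, 0L, 0L)    # pitch 90
#' @export
tilt_from_counts <- function(ax, ay, az, n_iter = 16L) {
  ax <- as.integer(ax); ay <- as.integer(ay); az <- as.integer(az)
  if (any(ax == 0L & ay == 0L & az == 0L))
    abort("Tilt of a zero-magnitude sample is undefined.")
  lut <- build_atan_lut(n_iter, scale = 2e6) # guard bit on z accumulation
  n <- length(ax)

  roll_i <- integer(n)
  m_yz <- integer(n)
  nz <- !(ay == 0L & az == 0L)
  if (any(nz)) {
    s1 <- cordic_atan2(az[nz], ay[nz], n_iter, lut)
    roll_i[nz] <- s1$angle
    m_yz[nz] <- gain_compensate(s1$magnitude_scaled, n_iter)
  }

  # pitch: atan2(ax, m_yz); m_yz >= 0 so the result lies in [-90, 90].
  p2 <- cordic_atan2(m_yz, ax, n_iter, lut)
  pitch_i <- p2$angle

  m_xy <- cordic_mag(ax, ay, n_iter, lut)
  i2 <- cordic_atan2(az, m_xy, n_iter, lut) # m_xy >= 0: angle in [0, 180]
  incl_i <- i2$angle
  mag <- gain_compensate(i2$magnitude_scaled, n_iter)

  # The accumulated angle can undershoot an exact boundary (e.g. 0 for an
  # on-axis vector) by the residual rotation; clamp to the admissible range.
  tibble(pitch = pitch_i / lut$scale, roll = roll_i / lut$scale,
         inclination = pmin(pmax(incl_i / lut$scale, 0), 180),
         magnitude = mag)
}

#' Tilt-angle streams for a whole recording
#'
#' Runs the integer CORDIC pipeline over every channel of a recording.
#' Zero-magnitude samples (possible only in pathological input) yield `NA`
#' angles rather than an error.
#'
#' @param recording A `pk_recording`.
#' @param n_iter CORDIC iterations. Default 16.
#' @return A `pk_tilt` tibble: `placement`, `t`, `pitch`, `roll`,
#'   `inclination` (degrees) and `magnitude_g` (gravity units).
#' @examples
#' r <- simulate_static(30, 10, duration = 1, seed = 1)
#' head(transform_tilt(r))
#' @export
transform_tilt <- function(recording, n_iter = 16L) {
  spec <- recording_spec(recording)
  zero <- recording$ax == 0L & recording$ay == 0L & recording$az == 0L
  out <- tibble(placement = recording$placement, t = recording$t,
                pitch = NA_real_, roll = NA_real_, inclination = NA_real_,
                magnitude_g = NA_real_)
  if (any(!zero)) {
    tl <- tilt_from_counts(recording$ax[!zero], recording$ay[!zero],
                           recording$az[!zero], n_iter)
    out$pitch[!zero] <- tl$pitch
    out$roll[!zero] <- tl$roll
    out$inclination[!zero] <- tl$inclination
    out$magnitude_g[!zero] <- tl$magnitude * spec$lsb_g
  }
  structure(out, spec = spec, class = c("pk_tilt", class(tibble())))
}
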