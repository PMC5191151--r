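#' @title Synthetic accelerometer data generation
#' @description Internal kinematic helpers shared by the simulators.
#' @name synth-internal
#' @keywords internal
NULL

# Gravity (specific force at rest) in the sensor frame for a trunk pitched by
# `pitch` degrees (body X axis, anterior, toward the ground) and rolled by
# `roll` degrees about X. Upright reads (0, 0, 1) g: Z up the spine.
gravity_vector <- function(pitch_deg, roll_deg = 0) {
  p <- pitch_deg * pi / 180
  r <- roll_deg * pi / 180
  cbind(x = sin(p), y = cos(p) * sin(r), z = cos(p) * cos(r))
}

default_mounting <- function() {
  m <- diag(3)
  setNames(rep(list(m), 5), placements())
}

# Assemble a pk_recording from per-channel gravity-unit signals.
# signals: named list placement -> n x 3 matrix (g units);
# labels: named list placement -> character vector length n (NA where none).
build_recording <- function(signals, spec, seed, labels = list(),
                            mounting = NULL) {
  mounting <- mounting %||% default_mounting()
  n <- nrow(signals[[1]])
  tt <- (seq_len(n) - 1) / spec$sample_rate_hz
  rows <- withr::with_seed(seed, {
    purrr::imap(signals, function(sig, pl) {
      sig <- sig %*% t(mounting[[pl]])
      if (spec$noise_sd_g > 0)
        sig <- sig + matrix(stats::rnorm(3 * n, sd = spec$noise_sd_g), ncol = 3)
      q <- quantize_sample(sig, spec)
      lab <- labels[[pl]] %||% rep(NA_character_, n)
      tibble(placement = pl, t = tt, ax = q$ax, ay = q$ay, az = q$az,
             label = lab)
    })
  })
  as_recording(bind_rows(rows), spec = spec, seed = seed)
}

#' Simulate a static posture
#'
#' Generates a recording of a motionless wearer whose trunk is held at a fixed
#' pitch/roll orientation: every channel sees the gravity vector rotated into
#' its sensor frame, plus white per-axis noise, then quantization. For a
#' noiseless spec every sample of an upright recording is exactly
#' `(0, 0, 1024)` counts, and for any orientation the magnitude
#' `sqrt(ax^2 + ay^2 + az^2)` equals 1 g within quantization error.
#'
#' @param pitch_deg,roll_deg Trunk orientation in degrees (see
#'   [tilt_from_counts()] for the angle conventions).
#' @param duration Recording length in seconds (>= 1).
#' @param spec A [sensor_spec()].
#' @param seed Integer seed; identical arguments give identical recordings.
#' @param mounting Optional named list of 3x3 rotation matrices (body frame to
#'   sensor frame), one per placement; identity by default. The vest's true
#'   per-placement mounting orientations are not fixed by the hardware
#'   description, so they are exposed as parameters.
#' @return A `pk_recording`; all samples carry the label `"static"` and the
#'   true orientation is stored in the `truth` attribute.
#' @examples
#' r <- simulate_static(30, 0, duration = 2, seed = 1)
#' glance(r)
#' @export
simulate_static <- function(pitch_deg = 0, roll_deg = 0, duration = 10,
                            spec = sensor_spec(), seed = 1L,
                            mounting = NULL) {
  if (duration < 1) abort("`duration` must be at least 1 s.")
  n <- round(duration * spec$sample_rate_hz)
  g <- gravity_vector(pitch_deg, roll_deg)
  sig <- matrix(rep(g, each = n), ncol = 3)
  signals <- setNames(rep(list(sig), 5), placements())
  labels <- setNames(rep(list(rep("static", n)), 5), placements())
  rec <- build_recording(signals, spec, seed, labels, mounting)
  attr(rec, "truth") <- list(pitch_deg = pitch_deg, roll_deg = roll_deg)
  rec
}

raised_cosine_train <- function(tt, centers, amplitude, width) {
  out <- numeric(length(tt))
  half <- width / 2
  for (s in centers) {
    i <- which(tt >= s - half & tt <= s + half)
    out[i] <- out[i] + amplitude * 0.5 * (1 + cos(2 * pi * (tt[i] - s) / width))
  }
  out
}

#' Simulate walking with controllable asymmetry and forward lean
#'
#' Generates a walk in which heel strikes alternate right/left. The mean step
#' time is `60/cadence` s; an `asymmetry` fraction `a` splits the step times
#' so that the left step time (previous right strike to left strike) is
#' `T(1 + a/2)` and the right step time is `T(1 - a/2)`, which makes the
#' interval-based step symmetry index of the gait equal `100 * a` percent by
#' construction. Each strike places a raised-cosine vertical impulse on the
#' ipsilateral waist channel; the chest carries a constant forward-lean pitch
#' of `lean_deg` plus a small gait oscillation, and the centre-of-mass channel
#' carries a vertical bounce at step frequency. True per-side step times are
#' written into the labels (`"step_left"` / `"step_right"` on the waist
#' channels).
#'
#' @param cadence Steps per minute (both sides combined), in `[40, 200]`.
#' @param duration Recording length in seconds; must admit at least two steps
#'   per side.
#' @param asymmetry Step-time asymmetry fraction in `[0, 0.5)`; the injected
#'   symmetry index is `100 * asymmetry` percent.
#' @param lean_deg Constant forward trunk lean of the chest channel, degrees.
#' @param step_jitter_sd Standard deviation of gaussian timing jitter added to
#'   each strike, seconds. Default 0.01.
#' @inheritParams simulate_static
#' @return A `pk_recording` with step ground truth in the labels (see
#'   [labeled_steps()]).
#' @examples
#' w <- simulate_walk(cadence = 100, duration = 30, asymmetry = 0.1, seed = 1)
#' nrow(labeled_steps(w))
#' @export
simulate_walk <- function(cadence = 100, duration = 60, asymmetry = 0,
                          lean_deg = 0, spec = sensor_spec(), seed = 1L,
                          step_jitter_sd = 0.01, mounting = NULL) {
  if (cadence < 40 || cadence > 200) abort("`cadence` must lie in [40, 200].")
  if (asymmetry < 0 || asymmetry >= 0.5) abort("`asymmetry` must lie in [0, 0.5).")
  T_step <- 60 / cadence
  t0 <- 0.5
  t_end <- duration - 0.5
  if (t_end - t0 < 4 * T_step)
    abort("`duration` too short to contain at least two steps per side.")

  # Alternating strikes: right first; right->left interval T(1+a/2),
  # left->right interval T(1-a/2).
  times <- t0; sides <- "right"
  repeat {
    nxt_side <- if (sides[length(sides)] == "right") "left" else "right"
    gap <- if (nxt_side == "left") T_step * (1 + asymmetry / 2)
           else T_step * (1 - asymmetry / 2)
    nxt <- times[length(times)] + gap
    if (nxt > t_end) break
    times <- c(times, nxt); sides <- c(sides, nxt_side)
  }
  jitter <- withr::with_seed(seed + 1L, stats::rnorm(length(times), sd = step_jitter_sd))
  jtimes <- times + jitter
  jtimes <- pmin(pmax(jtimes, 0), duration - 1 / spec$sample_rate_hz)

  n <- round(duration * spec$sample_rate_hz)
  tt <- (seq_len(n) - 1) / spec$sample_rate_hz
  f_step <- cadence / 60 # strikes per second, both sides

  left_t <- jtimes[sides == "left"]; right_t <- jtimes[sides == "right"]
  bump_l <- raised_cosine_train(tt, left_t, amplitude = 0.4, width = 0.3)
  bump_r <- raised_cosine_train(tt, right_t, amplitude = 0.4, width = 0.3)

  chest_pitch <- lean_deg + 2 * sin(2 * pi * f_step * tt)
  cerv_pitch <- 0.5 * lean_deg + 1.5 * sin(2 * pi * f_step * tt + 0.5)

  upright <- gravity_vector(0, 0)
  sig_waist_l <- cbind(0, 0, 1 + bump_l)
  sig_waist_r <- cbind(0, 0, 1 + bump_r)
  sig_com <- cbind(0.05 * sin(2 * pi * f_step * tt), 0,
                   1 + 0.2 * sin(2 * pi * f_step * tt))
  sig_chest <- gravity_vector(chest_pitch, 0)
  sig_cerv <- gravity_vector(cerv_pitch, 0)

  lab_side <- function(step_times, tag) {
    lab <- rep(NA_character_, n)
    idx <- pmin(pmax(round(step_times * spec$sample_rate_hz) + 1, 1), n)
    lab[idx] <- tag
    lab
  }
  signals <- list(CERVICAL = sig_cerv, CHEST = sig_chest, COM_L3 = sig_com,
                  WAIST_RIGHT = sig_waist_r, WAIST_LEFT = sig_waist_l)
  labels <- list(WAIST_LEFT = lab_side(left_t, "step_left"),
                 WAIST_RIGHT = lab_side(right_t, "step_right"))
  rec <- build_recording(signals, spec, seed, labels, mounting)
  attr(rec, "truth") <- list(cadence = cadence, asymmetry = asymmetry,
                             lean_deg = lean_deg,
                             step_times = tibble(side = sides, time = jtimes))
  rec
}

#' Simulate an alert-worthy event
#'
#' Produces the kinematic signature of one event with its exact window in the
#' labels:
#' * `fall` — brief free-fall (magnitude near 0 g), a saturating impact spike,
#'   then a sustained lying orientation;
#' * `lying_to_sitting` — chest inclination sweeping monotonically from
#'   near-horizontal (`from_deg`) to near-vertical (`to_deg`) over `ramp`
#'   seconds, crossing 45 degrees exactly once;
#' * `trunk_bend` — trunk pitches forward past `bend_angle` and holds for
#'   `hold` seconds;
#' * `head_down` — the cervical channel tilts past `bend_angle` and holds
#'   (chest stays upright).
#'
#' @param kind One of `"fall"`, `"lying_to_sitting"`, `"trunk_bend"`,
#'   `"head_down"`.
#' @param bend_angle Peak bend angle in degrees (trunk_bend / head_down).
#' @param hold Hold duration at the peak angle, seconds (trunk_bend /
#'   head_down).
#' @param ramp Ramp time of the lying-to-sitting sweep, seconds.
#' @param from_deg,to_deg Start/end inclination of the lying-to-sitting sweep.
#' @inheritParams simulate_static
#' @return A `pk_recording`; the event window carries the event kind as label
#'   on the channel that defines it.
#' @examples
#' ev <- simulate_event("trunk_bend", bend_angle = 40, hold = 5, seed = 2)
#' recording_labels(ev)
#' @export
simulate_event <- function(kind = c("fall", "lying_to_sitting", "trunk_bend",
                                    "head_down"),
                           bend_angle = 40, hold = 30, ramp = 2,
                           from_deg = 80, to_deg = 10,
                           spec = sensor_spec(), seed = 1L, mounting = NULL) {
  kind <- match.arg(kind)
  fs <- spec$sample_rate_hz
  switch(kind,
    trunk_bend = , head_down = {
      if (bend_angle <= 0 || bend_angle > 90) abort("`bend_angle` must lie in (0, 90].")
      if (hold <= 0) abort("`hold` must be positive.")
      seg <- c(pre = 2, up = 1, hold = hold, down = 1, post = 2)
      n <- round(sum(seg) * fs)
      tt <- (seq_len(n) - 1) / fs
      b <- cumsum(seg)
      ang <- ifelse(tt < b[1], 0,
             ifelse(tt < b[2], bend_angle * (tt - b[1]) / seg[2],
             ifelse(tt < b[3], bend_angle,
             ifelse(tt < b[4], bend_angle * (1 - (tt - b[3]) / seg[4]), 0))))
      upright <- cbind(0 * tt, 0, 1 + 0 * tt)
      if (kind == "trunk_bend") {
        signals <- list(CERVICAL = gravity_vector(ang, 0),
                        CHEST = gravity_vector(ang, 0),
                        COM_L3 = gravity_vector(0.3 * ang, 0),
                        WAIST_RIGHT = upright, WAIST_LEFT = upright)
        lab_ch <- "CHEST"
      } else {
        signals <- list(CERVICAL = gravity_vector(ang, 0),
                        CHEST = upright, COM_L3 = upright,
                        WAIST_RIGHT = upright, WAIST_LEFT = upright)
        lab_ch <- "CERVICAL"
      }
      lab <- rep(NA_character_, n)
      lab[tt >= b[2] & tt < b[3]] <- kind
      rec <- build_recording(signals, spec, seed,
                             setNames(list(lab), lab_ch), mounting)
    },
    lying_to_sitting = {
      if (ramp <= 0) abort("`ramp` must be positive.")
      seg <- c(lying = 3, ramp = ramp, sitting = 3)
      n <- round(sum(seg) * fs)
      tt <- (seq_len(n) - 1) / fs
      b <- cumsum(seg)
      ang <- ifelse(tt < b[1], from_deg,
             ifelse(tt < b[2], from_deg + (to_deg - from_deg) * (tt - b[1]) / ramp,
                    to_deg))
      sig <- gravity_vector(ang, 0)
      upright <- cbind(0 * tt, 0, 1 + 0 * tt)
      signals <- list(CERVICAL = sig, CHEST = sig, COM_L3 = sig,
                      WAIST_RIGHT = upright, WAIST_LEFT = upright)
      lab <- rep(NA_character_, n)
      lab[tt >= b[1] & tt < b[2]] <- "lying_to_sitting"
      rec <- build_recording(signals, spec, seed, list(CHEST = lab), mounting)
    },
    fall = {
      seg <- c(pre = 2, freefall = 0.3, impact = 0.1, lying = 6)
      n <- round(sum(seg) * fs)
      tt <- (seq_len(n) - 1) / fs
      b <- cumsum(seg)
      phase <- findInterval(tt, b) + 1 # 1 pre, 2 freefall, 3 impact, 4 lying
      pitch <- ifelse(phase <= 2, 0, 80)
      sig <- gravity_vector(pitch, 0)
      scale <- ifelse(phase == 2, 0.05, 1)
      sig <- sig * scale
      sig[phase == 3, 1] <- sig[phase == 3, 1] + 3.5 # impact spike, saturates
      upright <- cbind(0 * tt, 0, 1 + 0 * tt)
      signals <- list(CERVICAL = sig, CHEST = sig, COM_L3 = sig,
                      WAIST_RIGHT = sig, WAIST_LEFT = sig)
      lab <- rep(NA_character_, n)
      lab[phase %in% c(2, 3)] <- "fall"
      rec <- build_recording(signals, spec, seed, list(CHEST = lab), mounting)
    }
  )
  attr(rec, "truth") <- list(kind = kind, bend_angle = bend_angle, hold = hold,
                             ramp = ramp)
  rec
}
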