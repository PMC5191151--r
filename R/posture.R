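#' Alert and classification thresholds
#'
#' All thresholds of the posture/event stage live here so they stay
#' configurable: the monitoring concept is "bends the trunk by a certain
#' degree for a default amount of time", and the defaults below are the
#' package's documented choices, not hardware constants.
#'
#' @param lying_angle Chest inclination above which the trunk counts as lying,
#'   degrees. Default 60.
#' @param head_down_angle,head_down_hold Cervical tilt threshold (degrees) and
#'   minimum dwell (seconds) for a HEAD_DOWN warning. Defaults 30 / 60.
#' @param trunk_bend_angle,trunk_bend_hold Chest pitch threshold (degrees) and
#'   minimum dwell (seconds) for a TRUNK_BEND warning. Defaults 30 / 10.
#' @param lying_to_sitting_angle Inclination below which the wearer counts as
#'   sat up, degrees. Default 45.
#' @param freefall_g,freefall_min_s Free-fall stage of the fall signature:
#'   magnitude below `freefall_g` (gravity units) for at least
#'   `freefall_min_s` seconds. Defaults 0.5 / 0.2.
#' @param impact_g Impact stage: magnitude at or above this (gravity units),
#'   which a saturated sample always satisfies, within `impact_window_s`
#'   seconds of the free-fall end. Defaults 1.8 / 1.
#' @param impact_window_s See `impact_g`.
#' @param post_fall_hold Seconds the lying orientation must persist after
#'   impact. Default 5.
#' @param hysteresis Release hysteresis on duration warnings, degrees.
#'   Default 5.
#' @param max_ramp_s Longest lying-to-sitting ramp accepted, seconds.
#'   Default 10.
#' @param sitting_com_angle Centre-of-mass inclination above which an upright,
#'   inactive posture is read as sitting (pelvic tilt heuristic), degrees.
#'   Default 20.
#' @param transition_range Within-window swing of chest inclination that marks
#'   a TRANSITION window, degrees. Default 20.
#' @param lean_band Chest-pitch band (degrees, length 2) read as leaning
#'   forward while walking. Default `c(10, 45)`.
#' @param activity_sd_g Standard deviation of the centre-of-mass magnitude
#'   above which a window counts as active/walking, gravity units.
#'   Default 0.05.
#' @return An `pk_alert_rules` list.
#' @export
alert_rules <- function(lying_angle = 60, head_down_angle = 30,
                        head_down_hold = 60, trunk_bend_angle = 30,
                        trunk_bend_hold = 10, lying_to_sitting_angle = 45,
                        freefall_g = 0.5, freefall_min_s = 0.2,
                        impact_g = 1.8, impact_window_s = 1,
                        post_fall_hold = 5, hysteresis = 5, max_ramp_s = 10,
                        sitting_com_angle = 20, transition_range = 20,
                        lean_band = c(10, 45), activity_sd_g = 0.05) {
  angles <- c(lying_angle, head_down_angle, trunk_bend_angle,
              lying_to_sitting_angle)
  if (any(angles <= 0 | angles > 90))
    abort("All angle thresholds must lie in (0, 90] degrees.")
  holds <- c(head_down_hold, trunk_bend_hold, post_fall_hold, freefall_min_s)
  if (any(holds <= 0)) abort("All hold durations must be positive.")
  structure(as.list(environment()), class = "pk_alert_rules")
}

new_alerts <- function(kind = character(), start = numeric(),
                       end = numeric(), peak_angle = numeric()) {
  structure(tibble(kind = kind, start = start, end = end,
                   peak_angle = peak_angle),
            class = c("pk_alerts", class(tibble())))
}

channel_tilt <- function(tilt, ch) {
  d <- tilt[tilt$placement == ch, ]
  d[order(d$t), ]
}

#' Classify posture over sliding windows
#'
#' Windows the tilt streams (1 s windows, 0.5 s step by default) and assigns
#' one posture state per window:
#' * `LYING` — median chest inclination above `lying_angle`;
#' * `TRANSITION` — chest inclination swings more than `transition_range`
#'   within the window;
#' * `LEANING_FORWARD` — activity detected on the centre-of-mass channel and
#'   chest pitch inside `lean_band`;
#' * `STANDING` / `SITTING` — upright and inactive, split by the
#'   centre-of-mass orientation heuristic (`sitting_com_angle`); trunk
#'   orientation alone cannot separate the two, so this split is heuristic by
#'   design;
#' * `UNKNOWN` — no chest channel in the window.
#'
#' @param tilt A `pk_tilt` from [transform_tilt()].
#' @param rules An [alert_rules()].
#' @param window,step Window length and hop, seconds.
#' @return A tibble: `start`, `end`, `state`, `chest_inclination`,
#'   `cervical_tilt` (window medians, degrees).
#' @export
classify_posture <- function(tilt, rules = alert_rules(), window = 1,
                             step = 0.5) {
  if (window < 1) abort("`window` must cover at least 1 s.")
  chest <- channel_tilt(tilt, "CHEST")
  cerv <- channel_tilt(tilt, "CERVICAL")
  com <- channel_tilt(tilt, "COM_L3")
  t_max <- max(tilt$t)
  starts <- seq(0, max(0, t_max - window), by = step)
  rows <- purrr::map(starts, function(w0) {
    w1 <- w0 + window
    ch <- chest[chest$t >= w0 & chest$t < w1, ]
    cv <- cerv[cerv$t >= w0 & cerv$t < w1, ]
    cm <- com[com$t >= w0 & com$t < w1, ]
    cerv_tilt <- if (nrow(cv)) median(cv$inclination) else NA_real_
    if (!nrow(ch))
      return(tibble(start = w0, end = w1, state = "UNKNOWN",
                    chest_inclination = NA_real_, cervical_tilt = cerv_tilt))
    med_incl <- median(ch$inclination)
    med_pitch <- median(ch$pitch)
    swing <- diff(range(ch$inclination))
    active <- nrow(cm) > 0 && sd(cm$magnitude_g) > rules$activity_sd_g
    state <-
      if (swing > rules$transition_range) "TRANSITION"
      else if (med_incl > rules$lying_angle) "LYING"
      else if (active && between(med_pitch, rules$lean_band[1], rules$lean_band[2]))
        "LEANING_FORWARD"
      else if (nrow(cm) > 0 && median(cm$inclination) > rules$sitting_com_angle)
        "SITTING"
      else "STANDING"
    tibble(start = w0, end = w1, state = state,
           chest_inclination = med_incl, cervical_tilt = cerv_tilt)
  })
  bind_rows(rows)
}

# Excursion scan shared by the duration warnings: runs where `v` exceeds
# `angle`, released only when it drops below `angle - hysteresis`.
threshold_excursions <- function(tt, v, angle, hysteresis) {
  inside <- FALSE
  s <- NA_real_; peak <- -Inf
  out <- list()
  for (i in seq_along(tt)) {
    if (!inside && !is.na(v[i]) && v[i] > angle) {
      inside <- TRUE; s <- tt[i]; peak <- v[i]
    } else if (inside) {
      if (!is.na(v[i]) && v[i] > peak) peak <- v[i]
      if (!is.na(v[i]) && v[i] < angle - hysteresis) {
        out[[length(out) + 1]] <- list(start = s, end = tt[i], peak = peak)
        inside <- FALSE
      }
    }
  }
  if (inside)
    out[[length(out) + 1]] <- list(start = s, end = tt[length(tt)], peak = peak)
  out
}

#' Sustained head-down and trunk-bend warnings
#'
#' Emits a `HEAD_DOWN` alert when the neck flexion — cervical tilt in excess
#' of the chest inclination, so a bent trunk with a neutral neck does not
#' count — stays above `head_down_angle` continuously for at least
#' `head_down_hold` seconds, and a `TRUNK_BEND` alert analogously on the
#' chest pitch. An excursion only ends
#' once the angle drops 5 degrees (the hysteresis) below its threshold, so
#' jitter around the threshold does not split one long excursion into many
#' short ones. Increasing a hold can only ever remove alerts, never add them.
#'
#' Both warnings are gated on the wearer not lying (chest inclination at or
#' below `lying_angle`): a recumbent trunk reads as a large pitch too, and
#' must not raise posture warnings.
#'
#' @inheritParams classify_posture
#' @return A `pk_alerts` tibble: `kind`, `start`, `end`, `peak_angle`.
#' @export
detect_duration_warnings <- function(tilt, rules = alert_rules()) {
  res <- list()
  chest <- channel_tilt(tilt, "CHEST")
  lying_at <- function(tt) {
    if (!nrow(chest)) return(rep(FALSE, length(tt)))
    idx <- findInterval(tt, chest$t)
    idx[idx < 1] <- 1L
    !is.na(chest$inclination[idx]) & chest$inclination[idx] > rules$lying_angle
  }
  chest_incl_at <- function(tt) {
    if (!nrow(chest)) return(rep(0, length(tt)))
    idx <- pmax(findInterval(tt, chest$t), 1L)
    ifelse(is.na(chest$inclination[idx]), 0, chest$inclination[idx])
  }
  cerv <- channel_tilt(tilt, "CERVICAL")
  if (nrow(cerv)) {
    # neck flexion = cervical tilt beyond the trunk's own inclination
    flex <- cerv$inclination - chest_incl_at(cerv$t)
    v <- ifelse(lying_at(cerv$t), 0, flex) # lying gates release
    for (e in threshold_excursions(cerv$t, v,
                                   rules$head_down_angle, rules$hysteresis))
      if (e$end - e$start >= rules$head_down_hold)
        res[[length(res) + 1]] <- c(kind = "HEAD_DOWN", e)
  }
  if (nrow(chest)) {
    v <- ifelse(lying_at(chest$t), 0, chest$pitch)
    for (e in threshold_excursions(chest$t, v,
                                   rules$trunk_bend_angle, rules$hysteresis))
      if (e$end - e$start >= rules$trunk_bend_hold)
        res[[length(res) + 1]] <- c(kind = "TRUNK_BEND", e)
  }
  if (!length(res)) return(new_alerts())
  new_alerts(purrr::map_chr(res, "kind"), purrr::map_dbl(res, "start"),
             purrr::map_dbl(res, "end"), purrr::map_dbl(res, "peak"))
}

#' Fall detection
#'
#' A fall is reported only when all three stages of the signature occur in
#' order on the chest and centre-of-mass channels:
#' 1. free fall: magnitude below `freefall_g` on both channels for at least
#'    `freefall_min_s` seconds;
#' 2. impact: magnitude at or above `impact_g` (a saturated sample always
#'    qualifies) within `impact_window_s` seconds of the free-fall end;
#' 3. aftermath: chest inclination above `lying_angle` for at least 90% of
#'    the `post_fall_hold` seconds following the impact.
#'
#' Walking, lying down deliberately, or an impact without the preceding
#' free-fall dip produce no alert.
#'
#' @inheritParams classify_posture
#' @return A `pk_alerts` tibble.
#' @export
detect_fall <- function(tilt, rules = alert_rules()) {
  chest <- channel_tilt(tilt, "CHEST")
  com <- channel_tilt(tilt, "COM_L3")
  if (!nrow(chest)) return(new_alerts())
  mag <- chest$magnitude_g
  if (nrow(com) == nrow(chest)) mag <- pmax(mag, com$magnitude_g)
  tt <- chest$t
  dt <- median(diff(tt))
  low <- !is.na(mag) & mag < rules$freefall_g
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  res <- list()
  for (k in which(r$values)) {
    if (r$lengths[k] * dt < rules$freefall_min_s) next
    ff_start <- tt[starts[k]]; ff_end <- tt[ends[k]]
    imp <- which(tt > ff_end & tt <= ff_end + rules$impact_window_s &
                   !is.na(mag) & mag >= rules$impact_g)
    if (!length(imp)) next
    t_imp <- tt[imp[1]]
    aft <- chest[chest$t > t_imp & chest$t <= t_imp + rules$post_fall_hold, ]
    if (!nrow(aft) ||
        max(aft$t) < t_imp + rules$post_fall_hold - 2 * dt) next
    if (mean(aft$inclination > rules$lying_angle, na.rm = TRUE) < 0.9) next
    res[[length(res) + 1]] <- list(start = ff_start,
                                   end = t_imp + rules$post_fall_hold,
                                   peak = max(aft$inclination, na.rm = TRUE))
  }
  if (!length(res)) return(new_alerts())
  out <- new_alerts(rep("FALL", length(res)), purrr::map_dbl(res, "start"),
                    purrr::map_dbl(res, "end"), purrr::map_dbl(res, "peak"))
  # merge overlapping detections of the same fall
  keep <- c(TRUE, diff(out$start) > rules$post_fall_hold)
  out[keep, ]
}

#' Lying-to-sitting transition detection
#'
#' Watches the chest inclination for the bed-exit signature: the wearer has
#' been lying (inclination above `lying_angle` for at least 1 s), then the
#' inclination falls through `lying_to_sitting_angle` within `max_ramp_s`
#' seconds of leaving the lying band. Each crossing yields one event; rolling
#' over in bed (roll changes while the inclination stays high) and the
#' reverse sit-to-lie motion yield none.
#'
#' @inheritParams classify_posture
#' @return A `pk_alerts` tibble.
#' @export
detect_lying_to_sitting <- function(tilt, rules = alert_rules()) {
  chest <- channel_tilt(tilt, "CHEST")
  if (!nrow(chest)) return(new_alerts())
  tt <- chest$t; incl <- chest$inclination
  dt <- median(diff(tt))
  min_lying_n <- max(1L, round(1 / dt))
  res <- list()
  lying_run <- 0L; in_lying <- FALSE
  lying_from <- NA_integer_; leave_i <- NA_integer_; peak <- NA_real_
  for (i in seq_along(tt)) {
    v <- incl[i]
    if (is.na(v)) next
    if (v > rules$lying_angle) {
      lying_run <- lying_run + 1L
      if (lying_run >= min_lying_n && !in_lying) {
        in_lying <- TRUE
        lying_from <- i - lying_run + 1L
      }
      if (in_lying) peak <- max(peak, v, na.rm = TRUE)
      leave_i <- NA_integer_
    } else {
      if (in_lying && is.na(leave_i)) leave_i <- i
      lying_run <- 0L
      if (in_lying && v < rules$lying_to_sitting_angle) {
        if (tt[i] - tt[leave_i] <= rules$max_ramp_s) {
          # onset: when the inclination left its lying plateau, not merely
          # the lying band -- backtrack to the last sample near the plateau
          plateau <- median(incl[lying_from:(leave_i - 1L)], na.rm = TRUE)
          near <- which(incl[lying_from:leave_i] >= plateau - 3)
          onset_i <- if (length(near)) lying_from + max(near) - 1L else leave_i
          res[[length(res) + 1]] <- list(start = tt[onset_i], end = tt[i],
                                         peak = peak)
        }
        in_lying <- FALSE; leave_i <- NA_integer_
        lying_from <- NA_integer_; peak <- NA_real_
      }
    }
  }
  if (!length(res)) return(new_alerts())
  new_alerts(rep("LYING_TO_SITTING", length(res)),
             purrr::map_dbl(res, "start"), purrr::map_dbl(res, "end"),
             purrr::map_dbl(res, "peak"))
}

#' Run every event detector over a recording
#'
#' Transforms the recording to tilt streams and applies the duration
#' warnings, the fall detector and the lying-to-sitting detector.
#'
#' @param recording A `pk_recording`.
#' @param rules An [alert_rules()].
#' @param n_iter CORDIC iterations for the tilt transform.
#' @return A `pk_alerts` tibble sorted by start time.
#' @examples
#' ev <- simulate_event("trunk_bend", bend_angle = 40, hold = 12, seed = 1)
#' monitor_events(ev)
#' @export
monitor_events <- function(recording, rules = alert_rules(), n_iter = 16L) {
  tilt <- transform_tilt(recording, n_iter)
  out <- bind_rows(detect_duration_warnings(tilt, rules),
                   detect_fall(tilt, rules),
                   detect_lying_to_sitting(tilt, rules))
  structure(arrange(out, start), class = c("pk_alerts", class(tibble())))
}
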