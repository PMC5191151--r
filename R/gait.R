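#' Step detection on the bilateral waist channels
#'
#' Band-passes (0.5–3 Hz, zero-phase second-order Butterworth) the
#' acceleration magnitude of each waist channel and picks local maxima above
#' an adaptive threshold — the running median plus `3 * MAD` of the filtered
#' magnitude over 5 s windows, floored at `min_peak_g` — with a 250 ms
#' refractory period per side. Streams shorter than 2 s give an empty series.
#'
#' @param recording A `pk_recording` containing `WAIST_LEFT` and
#'   `WAIST_RIGHT` channels.
#' @param min_peak_g Absolute floor on the peak threshold, gravity units;
#'   keeps sensor noise on a motionless wearer from reading as steps.
#'   Default 0.05.
#' @param refractory_s Minimum spacing between accepted peaks on one side,
#'   seconds. Default 0.25.
#' @return A `pk_steps` tibble: `side` ("left"/"right"), `time` (s), strictly
#'   increasing within each side.
#' @examples
#' w <- simulate_walk(cadence = 100, duration = 20, seed = 1)
#' nrow(detect_steps(w))
#' @export
detect_steps <- function(recording, min_peak_g = 0.05, refractory_s = 0.25) {
  spec <- recording_spec(recording)
  fs <- spec$sample_rate_hz
  one_side <- function(ch, side) {
    d <- recording[recording$placement == ch, ]
    d <- d[order(d$t), ]
    if (nrow(d) < 2 * fs) return(tibble(side = character(), time = numeric()))
    mag <- sqrt(d$ax^2 + d$ay^2 + d$az^2) * spec$lsb_g
    bf <- signal::butter(2, c(0.5, 3) / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, mag - mean(mag))
    # adaptive threshold per 5 s block
    block <- pmin(floor(d$t / 5), floor(max(d$t) / 5))
    thr <- stats::ave(x, block, FUN = function(v) median(v) + 3 * mad(v))
    thr <- pmax(thr, min_peak_g)
    n <- length(x)
    is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                   x[2:(n - 1)] >= x[3:n], FALSE) & x > thr
    pk_t <- d$t[is_peak]
    keep <- numeric(0)
    for (tp in pk_t) {
      if (!length(keep) || tp - keep[length(keep)] >= refractory_s)
        keep <- c(keep, tp)
    }
    tibble(side = rep(side, length(keep)), time = keep)
  }
  out <- bind_rows(one_side("WAIST_LEFT", "left"),
                   one_side("WAIST_RIGHT", "right")) |> arrange(time)
  structure(out, spec = spec, class = c("pk_steps", class(tibble())))
}

# Walking bouts: maximal spans of >= 4 steps (both sides merged) whose
# successive inter-step gaps stay below `max_gap_s`.
walking_intervals <- function(steps, max_gap_s = 2, min_steps = 4L) {
  if (nrow(steps) < min_steps)
    return(tibble(start = numeric(), end = numeric(), n_steps = integer()))
  tt <- sort(steps$time)
  brk <- cumsum(c(0, diff(tt) >= max_gap_s))
  segs <- split(tt, brk)
  rows <- purrr::keep(segs, ~ length(.x) >= min_steps)
  if (!length(rows))
    return(tibble(start = numeric(), end = numeric(), n_steps = integer()))
  tibble(start = purrr::map_dbl(rows, min), end = purrr::map_dbl(rows, max),
         n_steps = purrr::map_int(rows, length))
}

# Step times per side: interval from the immediately preceding
# contralateral step (the step-time definition of gait timing).
step_times_by_side <- function(steps) {
  d <- arrange(steps, time)
  if (nrow(d) < 2) return(tibble(side = character(), interval = numeric()))
  prev_side <- d$side[-nrow(d)]
  iv <- diff(d$time)
  cur_side <- d$side[-1]
  keep <- cur_side != prev_side
  tibble(side = cur_side[keep], interval = iv[keep])
}

#' Interval-based step symmetry index
#'
#' `SI = |mean left step time - mean right step time| /
#' (0.5 * (mean left + mean right)) * 100`, where a side's step time is the
#' interval from the immediately preceding contralateral step. 0% is perfect
#' symmetry; the index is invariant to overall cadence (rescaling all step
#' times) and to swapping the two sides.
#'
#' @param steps A `pk_steps` tibble (or any data frame with `side` and
#'   `time` columns).
#' @return The symmetry index in percent, or `NA` (with a warning) when
#'   either side has fewer than 3 steps.
#' @examples
#' s <- tibble::tibble(
#'   side = rep(c("right", "left"), 10),
#'   time = cumsum(rep(c(0.45, 0.55), 10))
#' )
#' step_symmetry_index(s) # 20
#' @export
step_symmetry_index <- function(steps) {
  if (sum(steps$side == "left") < 3 || sum(steps$side == "right") < 3) {
    warn("Fewer than 3 steps on one side: symmetry index undefined.")
    return(NA_real_)
  }
  iv <- step_times_by_side(steps)
  ml <- mean(iv$interval[iv$side == "left"])
  mr <- mean(iv$interval[iv$side == "right"])
  abs(ml - mr) / (0.5 * (ml + mr)) * 100
}

#' Gait summary of one recording
#'
#' Composes step detection, the symmetry index and the forward-lean estimate:
#' `n_steps` counts detected steps inside walking bouts, `walk_time` is the
#' summed bout span plus one mean step time, `symmetry_index` is
#' [step_symmetry_index()] over bout steps, `sd_symmetry` is the sample
#' standard deviation (n-1) of the signed per-step asymmetry, and
#' `mean_forward_lean` is the mean chest pitch over the walking bouts only.
#' A recording with no walking yields zero steps and `NA` for the
#' step-timing and lean fields.
#'
#' @param recording A `pk_recording` with both waist channels and a chest
#'   channel.
#' @param tilt Optional precomputed `pk_tilt`; computed from the recording
#'   when `NULL`.
#' @param date Optional date attached to the summary (for
#'   [aggregate_trend()]).
#' @return A one-row `pk_gait_summary` tibble.
#' @examples
#' w <- simulate_walk(cadence = 100, duration = 30, lean_deg = 10, seed = 1)
#' walk_summary(w)
#' @export
walk_summary <- function(recording, tilt = NULL, date = NULL) {
  for (ch in c("WAIST_LEFT", "WAIST_RIGHT", "CHEST")) {
    if (!ch %in% recording$placement)
      abort(paste0("Recording is missing the ", ch, " channel."))
  }
  steps <- detect_steps(recording)
  bouts <- walking_intervals(steps)
  dur <- recording_duration(recording)
  if (nrow(bouts) == 0) {
    out <- tibble(n_steps = 0L, walk_time = 0, symmetry_index = NA_real_,
                  sd_symmetry = NA_real_, mean_forward_lean = NA_real_,
                  duration = dur)
  } else {
    in_bout <- purrr::map_lgl(steps$time, function(tp)
      any(tp >= bouts$start & tp <= bouts$end))
    bsteps <- steps[in_bout, ]
    iv <- step_times_by_side(bsteps)
    mean_step <- mean(iv$interval)
    walk_time <- min(sum(bouts$end - bouts$start) + mean_step, dur)
    si <- withCallingHandlers(step_symmetry_index(bsteps),
                              warning = function(w) invokeRestart("muffleWarning"))
    denom <- mean(iv$interval)
    signed <- (iv$interval - denom) / denom * 100
    sd_sym <- if (length(signed) > 1) sd(signed) else NA_real_
    tilt <- tilt %||% transform_tilt(recording)
    chest <- tilt[tilt$placement == "CHEST", ]
    in_walk <- purrr::map_lgl(chest$t, function(tp)
      any(tp >= bouts$start & tp <= bouts$end))
    lean <- if (any(in_walk)) mean(chest$pitch[in_walk], na.rm = TRUE) else NA_real_
    out <- tibble(n_steps = nrow(bsteps), walk_time = walk_time,
                  symmetry_index = si, sd_symmetry = sd_sym,
                  mean_forward_lean = lean, duration = dur)
  }
  if (!is.null(date)) out$date <- as.Date(date)
  structure(out, class = c("pk_gait_summary", class(tibble())))
}

#' Long-term gait trend aggregation
#'
#' Aggregates dated gait summaries into the long-term tracking series used to
#' watch for festination: per calendar period (month by default), the mean
#' and sample standard deviation (n-1 denominator) of the symmetry index and
#' the mean forward lean. Periods between the first and last summary that
#' contain no data are present in the output with `NA` values.
#'
#' @param summaries A data frame of gait summaries carrying a `date` column
#'   (e.g. rows from [walk_summary()] with `date` set).
#' @param period `"month"` or `"week"`.
#' @return A `pk_trend` tibble: `period`, `mean_symmetry`, `sd_symmetry`,
#'   `mean_lean`, `n`.
#' @export
aggregate_trend <- function(summaries, period = c("month", "week")) {
  period <- match.arg(period)
  if (!"date" %in% names(summaries))
    abort("Each summary must carry a `date` to be aggregated.")
  d <- as_tibble(summaries)
  d$date <- as.Date(d$date)
  key <- function(x) if (period == "month") format(x, "%Y-%m")
                     else format(x, "%Y-W%V")
  agg <- d |>
    group_by(period = key(date)) |>
    summarise(mean_symmetry = mean(symmetry_index, na.rm = TRUE),
              sd_symmetry = if (sum(!is.na(symmetry_index)) > 1)
                sd(symmetry_index, na.rm = TRUE) else NA_real_,
              mean_lean = mean(mean_forward_lean, na.rm = TRUE),
              n = dplyr::n(), .groups = "drop")
  # make empty periods explicit
  if (period == "month") {
    rng <- range(d$date)
    all_m <- seq(as.Date(format(rng[1], "%Y-%m-01")),
                 as.Date(format(rng[2], "%Y-%m-01")), by = "month")
    full <- tibble(period = format(all_m, "%Y-%m"))
    agg <- left_join(full, agg, by = "period")
    agg$n[is.na(agg$n)] <- 0L
  }
  structure(arrange(agg, period),
            class = c("pk_trend", class(tibble())))
}

#' @export
tidy.pk_gait_summary <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[setdiff(names(x), "date")],
                      dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @export
glance.pk_gait_summary <- function(x, ...) as_tibble(x)

#' @export
tidy.pk_steps <- function(x, ...) as_tibble(x)
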