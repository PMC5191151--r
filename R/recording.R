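#' Multichannel accelerometer recordings
#'
#' A recording is a tibble with one row per (placement, sample): columns
#' `placement` (one of [placements()]), `t` (seconds), integer counts `ax`,
#' `ay`, `az`, and `label` (ground-truth annotation of the sample, `NA` where
#' unlabelled). The [sensor_spec()] and generating seed travel as attributes.
#' All channels share the same strictly increasing timestamp grid at
#' `1/sample_rate_hz` spacing.
#'
#' @param data A data frame with columns `placement`, `t`, `ax`, `ay`, `az`
#'   and optionally `label`.
#' @param spec The [sensor_spec()] the counts were produced with.
#' @param seed Optional integer seed recorded for provenance.
#' @return A `pk_recording` tibble.
#' @export
as_recording <- function(data, spec = sensor_spec(), seed = NA_integer_) {
  d <- as_tibble(data)
  need <- c("placement", "t", "ax", "ay", "az")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("Recording is missing column(s): ", paste(miss, collapse = ", ")))
  if (!"label" %in% names(d)) d$label <- NA_character_
  bad <- setdiff(unique(d$placement), placements())
  if (length(bad))
    abort(paste0("Unknown placement(s): ", paste(bad, collapse = ", ")))
  d <- arrange(d, match(placement, placements()), t)
  d$ax <- as.integer(d$ax); d$ay <- as.integer(d$ay); d$az <- as.integer(d$az)
  validate_recording_grid(d, spec)
  structure(d, spec = spec, seed = as.integer(seed),
            class = c("pk_recording", class(tibble())))
}

validate_recording_grid <- function(d, spec) {
  dt <- 1 / spec$sample_rate_hz
  by_ch <- split(d$t, d$placement)
  ref <- NULL
  for (ch in names(by_ch)) {
    tt <- by_ch[[ch]]
    if (any(diff(tt) <= 0))
      abort(paste0("Timestamps not strictly increasing in channel ", ch, "."))
    if (any(abs(diff(tt) - dt) > 1e-6))
      abort(paste0("Timestamps in channel ", ch, " not on the 1/",
                   spec$sample_rate_hz, " s grid."))
    if (is.null(ref)) ref <- tt
    else if (length(tt) != length(ref) || any(abs(tt - ref) > 1e-9))
      abort("All channels must share length and timestamps.")
  }
  invisible(d)
}

#' @export
print.pk_recording <- function(x, ...) {
  spec <- recording_spec(x)
  nt <- length(unique(x$t))
  cat(sprintf("<pk_recording> %d channel(s) x %d samples (%.2f s at %g Hz)\n",
              length(unique(x$placement)), nt, nt / spec$sample_rate_hz,
              spec$sample_rate_hz))
  NextMethod()
}

#' @rdname as_recording
#' @param recording A `pk_recording`.
#' @export
recording_spec <- function(recording) {
  attr(recording, "spec") %||% sensor_spec()
}

#' Ground-truth annotation intervals of a recording
#'
#' Collapses runs of identical per-sample labels into `(placement, kind,
#' start, end)` intervals. Point events (e.g. individual step times written by
#' the walking simulator) come out as intervals of one sample. `end` is the
#' time just after the last labelled sample, so a window labelled for 30 s has
#' `end - start = 30`.
#'
#' @param recording A `pk_recording`.
#' @return A tibble with columns `placement`, `kind`, `start`, `end`.
#' @export
recording_labels <- function(recording) {
  spec <- recording_spec(recording)
  dt <- 1 / spec$sample_rate_hz
  d <- recording[!is.na(recording$label), c("placement", "t", "label")]
  if (nrow(d) == 0)
    return(tibble(placement = character(), kind = character(),
                  start = numeric(), end = numeric()))
  d <- arrange(d, placement, t)
  out <- d |>
    group_by(placement) |>
    mutate(.run = cumsum(label != lag(label, default = "") |
                           c(TRUE, diff(t) > dt + 1e-9))) |>
    group_by(placement, kind = label, .run) |>
    summarise(start = min(t), end = max(t) + dt, .groups = "drop") |>
    select(placement, kind, start, end) |>
    arrange(start, placement)
  out
}

#' Step ground truth of a simulated walk
#'
#' Extracts the labelled per-side step times written by [simulate_walk()].
#'
#' @param recording A `pk_recording` produced by [simulate_walk()].
#' @return A tibble with columns `side` ("left"/"right") and `time` (s).
#' @export
labeled_steps <- function(recording) {
  d <- recording[!is.na(recording$label) &
                   recording$label %in% c("step_left", "step_right"), ]
  tibble(side = sub("^step_", "", d$label), time = d$t) |>
    dplyr::distinct() |>
    arrange(time)
}

# Duration of a recording in seconds (per channel).
recording_duration <- function(recording) {
  spec <- recording_spec(recording)
  length(unique(recording$t)) / spec$sample_rate_hz
}

#' @export
glance.pk_recording <- function(x, ...) {
  spec <- recording_spec(x)
  tibble(
    n_channels = length(unique(x$placement)),
    n_samples = length(unique(x$t)),
    duration_s = recording_duration(x),
    sample_rate_hz = spec$sample_rate_hz,
    n_labeled = sum(!is.na(x$label))
  )
}
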