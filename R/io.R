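RECORDING_HEADER <- "# posturekit-recording v1"

#' Write and read recording CSV files
#'
#' The on-disk format is a plain CSV with the version header line
#' `# posturekit-recording v1` followed by `placement,t,ax,ay,az,label` rows:
#' counts as integers, `t` in seconds with 4 decimals, empty label where a
#' sample is unlabelled. Serialization is byte-deterministic for a given
#' recording. The sensor spec is stored in a JSON sidecar comment line so the
#' round trip preserves it.
#'
#' @param recording A `pk_recording`.
#' @param path File path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the `pk_recording`.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' r <- simulate_static(20, 5, duration = 1, seed = 7)
#' write_recording(r, p)
#' identical(dim(read_recording(p)), dim(r))
#' @export
write_recording <- function(recording, path) {
  spec <- recording_spec(recording)
  spec_json <- jsonlite::toJSON(
    spec[c("range_g", "resolution_bits", "sample_rate_hz", "lsb_g",
           "noise_sd_g", "bias_g")], auto_unbox = TRUE, digits = NA)
  lab <- ifelse(is.na(recording$label), "", recording$label)
  body <- sprintf("%s,%.4f,%d,%d,%d,%s", recording$placement, recording$t,
                  recording$ax, recording$ay, recording$az, lab)
  writeLines(c(RECORDING_HEADER,
               paste0("# spec ", spec_json),
               "placement,t,ax,ay,az,label",
               body), path)
  invisible(path)
}

parse_error <- function(msg, line = NA_integer_) {
  abort(if (is.na(line)) msg else sprintf("%s (line %d)", msg, line),
        class = "pk_parse_error")
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != RECORDING_HEADER)
    parse_error("Missing or unrecognized recording version header", 1L)
  spec <- sensor_spec()
  i <- 2L
  if (startsWith(lines[i], "# spec ")) {
    sj <- jsonlite::fromJSON(sub("^# spec ", "", lines[i]))
    spec <- sensor_spec(range_g = sj$range_g,
                        resolution_bits = sj$resolution_bits,
                        sample_rate_hz = sj$sample_rate_hz, lsb_g = sj$lsb_g,
                        noise_sd_g = sj$noise_sd_g, bias_g = sj$bias_g)
    i <- i + 1L
  }
  if (lines[i] != "placement,t,ax,ay,az,label")
    parse_error("Malformed column header", i)
  d <- utils::read.csv(text = lines[-seq_len(i)], header = FALSE,
                       col.names = c("placement", "t", "ax", "ay", "az", "label"),
                       colClasses = c("character", "numeric", "integer",
                                      "integer", "integer", "character"))
  d$label[d$label == ""] <- NA_character_
  bad <- which(!d$placement %in% placements())
  if (length(bad))
    parse_error(paste0("Unknown placement '", d$placement[bad[1]], "'"),
                bad[1] + i)
  for (ch in unique(d$placement)) {
    tt <- d$t[d$placement == ch]
    if (any(diff(tt) <= 0)) {
      j <- which(d$placement == ch)[which(diff(tt) <= 0)[1] + 1]
      parse_error("Timestamps not strictly increasing", j + i)
    }
  }
  as_recording(d, spec = spec)
}

#' Streaming frame protocol of the multiplexed gateway
#'
#' The acquisition gateway polls the five accelerometers in a fixed
#' round-robin order, one sample per channel per tick, by raising enable
#' lines en1..en5. `frames_from_recording()` serializes a recording into that
#' frame order with contiguous sequence numbers; `recording_from_frames()`
#' reassembles it losslessly and verifies contiguity — a dropped frame is
#' detected as a sequence gap and reported as a classed error
#' (`pk_frame_gap`) carrying the missing `(tick, channel)` pairs.
#'
#' @param recording A `pk_recording` with all five channels.
#' @return `frames_from_recording()`: a `pk_frames` tibble `seq_no`,
#'   `channel` (1..5), `placement`, `t`, `ax`, `ay`, `az`, `label`;
#'   `recording_from_frames()`: the reassembled `pk_recording`.
#' @examples
#' r <- simulate_static(0, 0, duration = 1, seed = 1)
#' f <- frames_from_recording(r)
#' nrow(f) # 5 channels x 100 samples
#' @export
frames_from_recording <- function(recording) {
  spec <- recording_spec(recording)
  if (!all(placements() %in% recording$placement))
    abort("Frame serialization needs all five channels.")
  d <- recording |>
    mutate(channel = match(placement, placements())) |>
    arrange(t, channel) |>
    mutate(seq_no = dplyr::row_number()) |>
    select(seq_no, channel, placement, t, ax, ay, az, label)
  structure(as_tibble(d), spec = spec, seed = attr(recording, "seed"),
            class = c("pk_frames", class(tibble())))
}

#' @rdname frames_from_recording
#' @param frames A `pk_frames` tibble (possibly with frames missing).
#' @export
recording_from_frames <- function(frames) {
  spec <- attr(frames, "spec") %||% sensor_spec()
  d <- arrange(as_tibble(frames), seq_no)
  n_ch <- 5L
  ticks <- (d$seq_no - 1L) %/% n_ch + 1L
  chan <- (d$seq_no - 1L) %% n_ch + 1L
  if (any(chan != d$channel))
    abort("Frame channel ids do not follow round-robin order.",
          class = "pk_frame_order")
  expected <- seq_len(max(d$seq_no))
  missing <- setdiff(expected, d$seq_no)
  if (length(missing)) {
    gaps <- tibble(tick = (missing - 1L) %/% n_ch + 1L,
                   channel = (missing - 1L) %% n_ch + 1L)
    abort(sprintf("%d frame(s) missing from the stream.", length(missing)),
          class = "pk_frame_gap", gaps = gaps)
  }
  as_recording(d[, c("placement", "t", "ax", "ay", "az", "label")],
               spec = spec, seed = attr(frames, "seed") %||% NA_integer_)
}

#' Write detected alerts as CSV
#'
#' Columns `kind,start,end,peak_angle`, times with 3 decimals — the format
#' consumed by the monitoring log tooling.
#'
#' @param alerts A `pk_alerts` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_alerts <- function(alerts, path) {
  body <- sprintf("%s,%.3f,%.3f,%.3f", alerts$kind, alerts$start, alerts$end,
                  alerts$peak_angle)
  writeLines(c("kind,start,end,peak_angle", body), path)
  invisible(path)
}

#' Flat key-value JSON configuration files
#'
#' Simulation parameters and alert rules are exchanged as flat key-value
#' JSON. Unknown keys are rejected so typos fail loudly.
#'
#' @param path File path.
#' @param allowed Character vector of permitted keys (`NULL` allows all).
#' @return A named list.
#' @export
read_config <- function(path, allowed = NULL) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(allowed)) {
    extra <- setdiff(names(cfg), allowed)
    if (length(extra))
      abort(paste0("Unknown configuration key(s): ",
                   paste(extra, collapse = ", ")))
  }
  cfg
}
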