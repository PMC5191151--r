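rules_fast <- alert_rules(trunk_bend_hold = 10, head_down_hold = 10)

test_that("posture classification recognises lying, upright and bent-forward windows", {
  ly <- simulate_static(85, 0, duration = 4, seed = 1)
  cls <- classify_posture(transform_tilt(ly))
  expect_true(all(cls$state == "LYING"))

  up <- simulate_static(2, 0, duration = 4, seed = 2)
  cls_up <- classify_posture(transform_tilt(up))
  expect_true(all(cls_up$state %in% c("STANDING", "SITTING")))
  expect_false(any(cls_up$state == "LYING"))

  tb <- simulate_event("trunk_bend", bend_angle = 40, hold = 6, seed = 3)
  cls_tb <- classify_posture(transform_tilt(tb))
  win <- recording_labels(tb)
  inside <- cls_tb[cls_tb$start >= win$start & cls_tb$end <= win$end, ]
  expect_true("TRANSITION" %in% cls_tb$state)
  expect_true(all(inside$chest_inclination > 30))
})

test_that("classification reports UNKNOWN without a chest channel and walking lean", {
  w <- simulate_walk(cadence = 110, duration = 12, lean_deg = 20, seed = 4)
  tl <- transform_tilt(w)
  cls <- classify_posture(tl)
  expect_true("LEANING_FORWARD" %in% cls$state)
  cls2 <- classify_posture(tl[tl$placement != "CHEST", ])
  expect_true(all(cls2$state == "UNKNOWN"))
})

test_that("a sustained excursion raises exactly one warning; short dwells raise none", {
  hd <- simulate_event("head_down", bend_angle = 50, hold = 20, seed = 5)
  al <- detect_duration_warnings(transform_tilt(hd), rules_fast)
  expect_equal(al$kind, "HEAD_DOWN")
  expect_equal(nrow(al), 1)
  expect_gt(al$peak_angle, 45)

  # oscillation across the threshold with dwell < hold: no alert
  tt <- seq(0, 60, by = 0.01)
  osc <- ifelse(floor(tt / 4) %% 2 == 0, 50, 10) # 4 s above, 4 s well below
  tilt <- tibble::tibble(placement = "CERVICAL", t = tt, pitch = osc,
                         roll = 0, inclination = osc, magnitude_g = 1)
  expect_equal(nrow(detect_duration_warnings(tilt, rules_fast)), 0)
})

test_that("trunk-bend warning fires with the configured threshold and hold", {
  tb <- simulate_event("trunk_bend", bend_angle = 40, hold = 30, seed = 6)
  al <- detect_duration_warnings(transform_tilt(tb),
                                 alert_rules(trunk_bend_angle = 30,
                                             trunk_bend_hold = 10))
  expect_equal(al$kind, "TRUNK_BEND")
  win <- recording_labels(tb)
  expect_lt(abs(al$start - win$start), 10.5)
})

test_that("increasing a hold threshold never increases the number of alerts", {
  tb <- simulate_event("trunk_bend", bend_angle = 40, hold = 15, seed = 7)
  tl <- transform_tilt(tb)
  counts <- sapply(c(2, 5, 10, 14, 16, 40), function(h)
    nrow(detect_duration_warnings(tl, alert_rules(trunk_bend_hold = h))))
  expect_true(all(diff(counts) <= 0))
})

test_that("falls need all three stages: dip, impact, sustained lying", {
  fl <- simulate_event("fall", seed = 8)
  al <- detect_fall(transform_tilt(fl))
  expect_equal(nrow(al), 1)
  win <- recording_labels(fl)
  expect_true(al$start >= win$start - 0.1 && al$start <= win$end)

  # lying down deliberately: no impact stage, no alert
  ly <- simulate_static(85, 0, duration = 12, seed = 9)
  expect_equal(nrow(detect_fall(transform_tilt(ly))), 0)
})

test_that("lying-to-sitting fires once per crossing, not on turning or reverse motion", {
  ev <- simulate_event("lying_to_sitting", ramp = 2, seed = 10)
  al <- detect_lying_to_sitting(transform_tilt(ev))
  expect_equal(nrow(al), 1)
  win <- recording_labels(ev)
  expect_lt(abs(al$start - win$start), 0.5)

  # reverse (sit-to-lie): monotone rise in inclination, no event
  rev <- simulate_event("lying_to_sitting", ramp = 2, from_deg = 10,
                        to_deg = 80, seed = 11)
  expect_equal(nrow(detect_lying_to_sitting(transform_tilt(rev))), 0)

  # body turning while lying: roll changes, inclination stays high
  seg1 <- simulate_static(85, -30, duration = 3, seed = 12)
  seg2 <- simulate_static(85, 30, duration = 3, seed = 13)
  seg2$t <- seg2$t + 3
  turn <- as_recording(dplyr::bind_rows(seg1, seg2))
  expect_equal(nrow(detect_lying_to_sitting(transform_tilt(turn))), 0)
})

test_that("alert detection is deterministic for a fixed stream", {
  fl <- simulate_event("fall", seed = 14)
  a <- monitor_events(fl); b <- monitor_events(fl)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("alert rules validate their ranges", {
  expect_error(alert_rules(lying_angle = 120), "angle")
  expect_error(alert_rules(trunk_bend_hold = 0), "hold")
})
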