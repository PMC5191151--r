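test_that("step detection recovers labeled steps and ignores rest", {
  w <- simulate_walk(cadence = 100, duration = 60, seed = 1)
  st <- detect_steps(w)
  expect_lte(abs(nrow(st) - nrow(labeled_steps(w))), 2)
  r <- simulate_static(5, 0, duration = 10, seed = 2)
  expect_equal(nrow(detect_steps(r)), 0)
  # streams shorter than 2 s: empty series
  short <- simulate_static(0, 0, duration = 1.5, seed = 3)
  expect_equal(nrow(detect_steps(short)), 0)
})

test_that("step detection is seed-stable", {
  counts <- sapply(1:10, function(s)
    nrow(detect_steps(simulate_walk(cadence = 100, duration = 30, seed = s))))
  expect_lte(diff(range(counts)), 2)
})

test_that("symmetry index matches its closed form and signals undefined cases", {
  sym <- tibble::tibble(side = rep(c("right", "left"), 10),
                        time = cumsum(rep(0.5, 20)))
  expect_equal(step_symmetry_index(sym), 0)
  asym <- tibble::tibble(side = rep(c("right", "left"), 10),
                         time = cumsum(rep(c(0.45, 0.55), 10)))
  expect_equal(step_symmetry_index(asym), 20, tolerance = 1e-9)
  expect_warning(si <- step_symmetry_index(asym[1:4, ]), "Fewer than 3")
  expect_true(is.na(si))
})

test_that("symmetry index is scale-invariant and side-symmetric", {
  set.seed(4)
  w <- simulate_walk(cadence = 90, duration = 40, asymmetry = 0.15, seed = 4)
  st <- detect_steps(w)
  si <- step_symmetry_index(st)
  scaled <- dplyr::mutate(st, time = time * 3.7)
  expect_equal(step_symmetry_index(scaled), si)
  swapped <- dplyr::mutate(st, side = ifelse(side == "left", "right", "left"))
  expect_equal(step_symmetry_index(swapped), si)
})

test_that("walk summary recovers injected cadence, symmetry and lean", {
  w <- simulate_walk(cadence = 100, duration = 60, asymmetry = 0.1,
                     lean_deg = 10, seed = 5)
  s <- walk_summary(w)
  expect_lte(abs(s$n_steps / s$walk_time * 60 - 100), 2)
  expect_lt(abs(s$symmetry_index - 10), 2)
  expect_lt(abs(s$mean_forward_lean - 10), 1)
  expect_lte(s$walk_time, s$duration)
  expect_gte(s$symmetry_index, 0)
})

test_that("walking time tracks the walking interval in a walk-then-rest recording", {
  w <- simulate_walk(cadence = 100, duration = 60, seed = 6)
  r <- simulate_static(0, 0, duration = 60, seed = 7)
  r$t <- r$t + 60
  both <- as_recording(dplyr::bind_rows(w, r), spec = recording_spec(w))
  s <- walk_summary(both)
  expect_lt(abs(s$walk_time - 60), 2)
})

test_that("degenerate static input yields a zero-step summary with absent fields", {
  r <- simulate_static(3, 0, duration = 10, seed = 8)
  s <- walk_summary(r)
  expect_equal(s$n_steps, 0L)
  expect_equal(s$walk_time, 0)
  expect_true(is.na(s$symmetry_index))
  expect_true(is.na(s$mean_forward_lean))
  r2 <- r[r$placement != "WAIST_LEFT", ]
  expect_error(walk_summary(r2), "WAIST_LEFT")
})

test_that("trend aggregation averages per month, keeps empty months, uses n-1 sd", {
  mk <- function(d, si, lean) tibble::tibble(
    n_steps = 100L, walk_time = 60, symmetry_index = si, sd_symmetry = 1,
    mean_forward_lean = lean, duration = 120, date = as.Date(d))
  sums <- dplyr::bind_rows(
    mk("2025-01-10", 10, 5), mk("2025-01-20", 20, 5),
    mk("2025-03-15", 12, 8))
  tr <- aggregate_trend(sums)
  expect_equal(tr$period, c("2025-01", "2025-02", "2025-03"))
  jan <- tr[tr$period == "2025-01", ]
  expect_equal(jan$mean_symmetry, 15)
  expect_equal(jan$sd_symmetry, sd(c(10, 20)))
  expect_equal(tr$n, c(2L, 0L, 1L))

  # monotone drifting lean gives strictly increasing monthly means
  months <- seq(as.Date("2025-01-15"), by = "month", length.out = 12)
  drift <- dplyr::bind_rows(purrr::map2(as.list(months),
                                        seq(5, 15, length.out = 12),
                                        ~ mk(.x, 10, .y)))
  trd <- aggregate_trend(drift)
  expect_true(all(diff(trd$mean_lean) > 0))

  # constant summaries give a flat trend equal to the constant
  flat <- dplyr::bind_rows(purrr::map(as.list(months), ~ mk(.x, 10, 7)))
  trf <- aggregate_trend(flat)
  expect_true(all(trf$mean_symmetry == 10) && all(trf$mean_lean == 7))
})

test_that("tidiers expose the summary in broom shape", {
  w <- simulate_walk(cadence = 100, duration = 20, seed = 9)
  s <- walk_summary(w)
  td <- generics::tidy(s)
  expect_named(td, c("term", "estimate"))
  expect_true("symmetry_index" %in% td$term)
  expect_s3_class(generics::glance(s), "tbl_df")
})
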