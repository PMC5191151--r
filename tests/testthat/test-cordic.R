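test_that("LUT entries encode arctan(2^-i), strictly decreasing, 45 deg first", {
  lut <- build_atan_lut(2)
  expect_equal(lut$entries, c(45000000L, 26565051L))
  lut16 <- build_atan_lut(16)
  expect_length(lut16$entries, 16)
  expect_true(all(diff(lut16$entries) < 0))
  # total rotation capability: sum of micro-rotations ~ 99.88 degrees
  expect_equal(sum(lut16$entries) / 1e6, 99.881, tolerance = 1e-4)
  expect_error(build_atan_lut(0), "n_iter")
  expect_error(build_atan_lut(30), "n_iter")
  expect_error(build_atan_lut(16, scale = 1e8), "overflow")
})

test_that("vectoring recovers on-axis and diagonal angles with scaled magnitude", {
  v0 <- cordic_vectoring(1024L, 0L)
  expect_lt(abs(v0$angle / 1e6), 0.002)
  expect_lt(abs(v0$magnitude_scaled - round(cordic_gain(16) * 1024)), 1.5)
  v45 <- cordic_vectoring(1024L, 1024L)
  expect_lt(abs(v45$angle / 1e6 - 45), 0.002)
  expect_error(cordic_vectoring(0L, 0L), "zero vector")
  expect_error(cordic_vectoring(-5L, 3L), "pre-rotate")
})

test_that("vectoring matches the atan2 oracle within 0.01 degree on random vectors", {
  set.seed(7)
  n <- 10000
  x <- sample(1:2047, n, replace = TRUE)
  y <- sample(-2047:2047, n, replace = TRUE)
  v <- cordic_vectoring(x, y)
  err <- abs(v$angle / 1e6 - atan2(y, x) * 180 / pi)
  # bound: LUT resolution + residual rotation 2^-15 rad
  expect_lt(max(err), 0.01)
  merr <- abs(v$magnitude_scaled - cordic_gain(16) * sqrt(x^2 + y^2))
  expect_lt(max(merr), 1.5)
})

test_that("gain compensation recovers magnitudes within one count, with no division", {
  K <- cordic_gain(16)
  expect_equal(gain_compensate(0L), 0L)
  expect_lte(abs(gain_compensate(round(K * 1024)) - 1024L), 1L)
  expect_lte(abs(gain_compensate(round(K * 1448)) - 1448L), 1L) # sqrt(2)*1024
  set.seed(8)
  m <- sample(0:3000, 500)
  expect_true(all(abs(gain_compensate(round(K * m)) - m) <= 1L))
  expect_error(gain_compensate(-3L), "non-negative")
})

test_that("integer state provably fits 32-bit words (interval analysis)", {
  for (n in c(16L, 20L)) {
    expect_lt(cordic_state_bound(n_iter = n), 2^31)
  }
  # and empirically: no NA (the R overflow sentinel) on extreme inputs
  ext <- expand.grid(x = c(1L, 2047L, 8191L), y = c(-8191L, -1L, 0L, 1L, 8191L))
  v <- cordic_vectoring(ext$x, ext$y, n_iter = 20L, lut = build_atan_lut(20))
  expect_false(any(is.na(v$angle)) || any(is.na(v$magnitude_scaled)))
})

test_that("tilt decomposition handles canonical orientations and full quadrants", {
  up <- tilt_from_counts(0L, 0L, 1024L)
  expect_equal(up$pitch, 0, tolerance = 0.01)
  expect_equal(up$roll, 0, tolerance = 0.01)
  expect_equal(up$inclination, 0, tolerance = 0.01)
  fwd <- tilt_from_counts(1024L, 0L, 0L)
  expect_equal(fwd$pitch, 90, tolerance = 0.01)
  expect_equal(fwd$inclination, 90, tolerance = 0.01)
  inv <- tilt_from_counts(0L, 0L, -1024L) # upside down
  expect_equal(inv$inclination, 180, tolerance = 0.01)
  left <- tilt_from_counts(0L, 1024L, 0L)
  expect_equal(left$roll, 90, tolerance = 0.01)
  expect_equal(left$inclination, 90, tolerance = 0.01)
  expect_error(tilt_from_counts(0L, 0L, 0L), "zero-magnitude")
})

test_that("tilt angles satisfy their range invariants on random inputs", {
  set.seed(9)
  n <- 2000
  ax <- sample(-2048:2047, n, TRUE); ay <- sample(-2048:2047, n, TRUE)
  az <- sample(-2048:2047, n, TRUE)
  keep <- !(ax == 0 & ay == 0 & az == 0)
  tl <- tilt_from_counts(ax[keep], ay[keep], az[keep])
  expect_true(all(tl$inclination >= 0 & tl$inclination <= 180))
  expect_true(all(tl$pitch > -90.01 & tl$pitch < 90.01))
  expect_true(all(tl$roll > -180.01 & tl$roll <= 180.01))
  o <- oracle_angles(ax[keep], ay[keep], az[keep])
  expect_lt(max(abs(tl$inclination - o$inclination)), 0.1)
})

test_that("inclination is invariant under azimuthal flip", {
  set.seed(10)
  ax <- sample(-1024:1024, 300, TRUE); ay <- sample(-1024:1024, 300, TRUE)
  az <- sample(-1024:1024, 300, TRUE)
  keep <- !(ax == 0 & ay == 0 & az == 0)
  a <- tilt_from_counts(ax[keep], ay[keep], az[keep])
  b <- tilt_from_counts(-ax[keep], -ay[keep], az[keep])
  expect_equal(a$inclination, b$inclination, tolerance = 0.01)
})

test_that("end-to-end tilt error on the quantized 5-degree sweep stays within 0.5 deg", {
  grid <- expand.grid(p = seq(-90, 90, 5), r = seq(-90, 90, 5))
  gv <- gravity_vector(grid$p, grid$r)
  q <- quantize_sample(gv, spec_clean())
  tl <- tilt_from_counts(q$ax, q$ay, q$az)
  incl_true <- atan2(sqrt(gv[, 1]^2 + gv[, 2]^2), gv[, 3]) * 180 / pi
  expect_lt(max(abs(tl$inclination - incl_true)), 0.5)
})

test_that("transform_tilt maps whole recordings and tolerates zero samples", {
  r <- simulate_static(25, -40, duration = 2, spec = spec_clean(), seed = 2)
  tl <- transform_tilt(r)
  expect_setequal(unique(tl$placement), placements())
  ch <- tl[tl$placement == "CHEST", ]
  expect_equal(median(ch$pitch), 25, tolerance = 0.1)
  expect_equal(median(ch$roll), -40, tolerance = 0.2)
  expect_equal(median(ch$magnitude_g), 1, tolerance = 0.005)
})
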