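test_that("intensity series fills the track span and marks gaps", {
  tr <- data.frame(frame = c(3, 4, 7), peak = c(10, 12, 11))
  s <- intensity_series(tr)
  expect_equal(s$frame, 3:7)
  expect_equal(s$peak, c(10, 12, NA, NA, 11))
  expect_equal(nrow(intensity_series(data.frame(frame = 1:3, peak = 5))), 3)
})

test_that("flash segmentation run-length arithmetic matches by hand", {
  # 5 on / 5 off repeated at 30 fps
  st <- rep(rep(c(1, 0), each = 5), 6) * 100
  tr <- segment_flashes(st, fps = 30, level = 50)
  expect_true(all(tr$on_intervals == 5 / 30))
  expect_true(all(tr$off_intervals == 5 / 30))
  # leading and trailing runs are excluded from the interval statistics
  expect_length(tr$on_intervals, 5)
  expect_length(tr$off_intervals, 5)

  # all off -> valid empty train
  off <- segment_flashes(rep(0, 20), 30, level = 10)
  expect_length(off$on_intervals, 0)
  # one run spanning the record -> no interval statistics
  allon <- segment_flashes(rep(100, 20), 30, level = 10)
  expect_length(allon$on_intervals, 0)
  # NA intensities (bridged gaps) count as off
  g <- segment_flashes(c(0, 100, 100, NA, NA, 100, 100, 0, 100, 0),
                       30, level = 50)
  expect_equal(sum(g$states), 5)
  # reconstruction round-trips exactly
  expect_identical(reconstruct_states(tr), tr$states)
  expect_identical(reconstruct_states(g), g$states)
})

test_that("flash statistics reproduce nominal-duration arithmetic", {
  trains <- lapply(1:13, function(i) {
    s <- flash_train_signal(0.166, 0.168, 30, 300, phase_s = (i - 1) * 0.021)
    segment_flashes(as.numeric(s), 30, level = 0.5)
  })
  fs <- flash_stats(trains)
  expect_equal(fs$mean_on_s, 0.166, tolerance = 0.01)
  expect_equal(fs$mean_off_s, 0.168, tolerance = 0.01)
  expect_equal(mean(fs$duty_cycles), 0.166 / 0.334, tolerance = 0.01)
  expect_equal(fs$blink_rate_hz, 1 / 0.334, tolerance = 0.01)
  expect_true(all(fs$duty_cycles >= 0 & fs$duty_cycles <= 1))
  expect_lte(fs$blink_rate_hz, 30 / 2)

  # 13 trains built with exactly 18 complete cycles each -> 234 flashes
  one <- c(rep(FALSE, 3), rep(rep(c(TRUE, FALSE), each = 5), 18),
           rep(TRUE, 2))
  t13 <- lapply(1:13, function(i)
    segment_flashes(as.numeric(one) * 100, 30, level = 50))
  expect_equal(flash_stats(t13)$n_flashes, 234)

  expect_error(flash_stats(segment_flashes(rep(0, 30), 30, level = 1)),
               "complete")
})

test_that("duty cycles and blink rate stay bounded under jitter", {
  set.seed(14)
  for (r in 1:10) {
    s <- flash_train_signal(0.166, 0.168, 30, 450, jitter_sd_s = 0.04)
    tr <- segment_flashes(as.numeric(s), 30, level = 0.5)
    fs <- try(flash_stats(tr), silent = TRUE)
    if (inherits(fs, "try-error")) next
    expect_true(all(fs$duty_cycles >= 0 & fs$duty_cycles <= 1))
    expect_lte(fs$blink_rate_hz, 15)
    expect_identical(reconstruct_states(tr), tr$states)
  }
})

test_that("the averaged spectrum peaks at the square-wave fundamental", {
  trains <- lapply(1:13, function(i) {
    s <- flash_train_signal(0.166, 0.168, 30, 300, phase_s = (i - 1) * 0.02)
    segment_flashes(as.numeric(s), 30, level = 0.5)
  })
  sp <- flash_spectrum(trains)
  expect_equal(sp$peak_frequency_hz, 1 / 0.334, tolerance = 0.1 / 3)
  expect_lte(max(sp$frequencies_hz), 15 + 1e-9)     # Nyquist

  # phase invariance: cyclic shift leaves the periodogram unchanged
  sa <- as.numeric(flash_train_signal(1 / 6, 1 / 6, 30, 300))
  a <- segment_flashes(sa, 30, level = 0.5)
  b <- segment_flashes(sa[c(4:300, 1:3)], 30, level = 0.5)
  expect_equal(flash_spectrum(list(a))$power,
               flash_spectrum(list(b))$power, tolerance = 1e-8)
  expect_equal(flash_spectrum(list(a, b))$power,
               flash_spectrum(list(a))$power, tolerance = 1e-8)

  # constant-on train has no peak above 0.5 Hz
  con <- segment_flashes(rep(100, 90), 30, level = 50)
  expect_error(flash_spectrum(list(con)), "peak")
  # too-short record
  short <- segment_flashes(rep(c(100, 0), 10), 30, level = 50)
  expect_error(flash_spectrum(list(short)), "short")
})
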