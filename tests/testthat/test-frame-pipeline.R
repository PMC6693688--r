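test_that("FPN estimation is the per-pixel temporal mean", {
  C <- matrix(37, 8, 8)
  st <- frame_stack(array(rep(C, 5), c(8, 8, 5)))
  expect_equal(estimate_fpn(st), C)
  expect_error(estimate_fpn(frame_stack(array(1, c(4, 4, 1)))),
               "at least 2")
})

test_that("FPN estimate recovers the synthetic offset distribution", {
  set.seed(21)
  fpn <- make_fpn_map(64, 64, 100, 5)
  # 60 frames of offsets + read noise + a few sparse flashes
  data <- array(0L, c(64, 64, 60))
  for (t in 1:60) {
    img <- fpn + rnorm(64 * 64, 0, 2)
    if (t %% 2 == 0) img[20:22, 30:32] <- img[20:22, 30:32] + 400
    data[, , t] <- as.integer(pmax(round(img), 0))
  }
  est <- estimate_fpn(frame_stack(data))
  expect_lt(abs(mean(est) - 100), 1)
  # correction of a flash-free stack leaves ~zero temporal mean
  quiet <- array(0L, c(64, 64, 60))
  for (t in 1:60)
    quiet[, , t] <- as.integer(pmax(round(fpn + rnorm(64 * 64, 0, 2)), 0))
  qs <- frame_stack(quiet)
  corr <- correct_frames(qs, estimate_fpn(qs))
  resid <- rowMeans(corr$data, dims = 2)
  expect_lt(mean(resid), 1)
})

test_that("frame correction subtracts, clips and preserves amplitude", {
  fpn <- matrix(100, 6, 6)
  fr <- array(100, c(6, 6, 2))
  fr[3, 3, 1] <- 50          # below FPN -> clipped to 0
  fr[4, 4, 2] <- 100 + 250   # blob of amplitude 250
  out <- correct_frames(frame_stack(fr, fps = 25), fpn)
  expect_equal(out$fps, 25)
  expect_equal(out$data[3, 3, 1], 0)
  expect_equal(out$data[4, 4, 2], 250)
  expect_true(all(out$data[, , 1][-c(3 + 6 * 2)] == 0))
  expect_error(correct_frames(frame_stack(fr), matrix(0, 3, 3)), "shape")
})

test_that("segmentation drops isolated pixels and keeps solid blocks", {
  fr <- matrix(0, 20, 20)
  fr[2, 2] <- 500                      # isolated hot pixel
  fr[8:12, 8:12] <- 500                # solid 5x5 block
  bw <- segment_frame(fr, threshold = 100)
  expect_equal(bw[2, 2], FALSE)
  # opening with the 3x3 cross removes the block's four corners
  expect_equal(sum(bw), 21)
  expect_true(all(bw[9:11, 9:11]))
  expect_equal(sum(segment_frame(matrix(0, 10, 10), threshold = 10)), 0)
})

test_that("the default threshold survives a zero-clipped background", {
  set.seed(8)
  # corrected background: clipped centred noise + one bright blob
  fr <- pmax(matrix(rnorm(128 * 128, 0, 2), 128, 128), 0)
  rr <- outer((1:128 - 60)^2, (1:128 - 70)^2, "+")
  fr <- fr + 600 * exp(-rr / (2 * 4))
  bw <- segment_frame(fr)
  det <- extract_detections(bw, fr, min_area = 5)
  expect_equal(nrow(det), 1)
  expect_equal(det$row, 59, tolerance = 0.05)   # 0-based
  expect_equal(det$col, 69, tolerance = 0.05)
})

test_that("detection extraction uses 8-connectivity and a strict area filter", {
  bin <- matrix(FALSE, 30, 40)
  bin[11:15, 21:25] <- TRUE            # 25 px, rows 10-14 cols 20-24 0-based
  fr <- matrix(0, 30, 40); fr[bin] <- 300; fr[13, 23] <- 700
  det <- extract_detections(bin, fr)
  expect_equal(nrow(det), 1)
  expect_equal(det$row, 12)
  expect_equal(det$col, 22)
  expect_equal(det$area, 25L)
  expect_equal(det$peak, 700)

  # exactly 20 px is rejected (strict >)
  b20 <- matrix(FALSE, 30, 40); b20[1:4, 1:5] <- TRUE
  expect_equal(nrow(extract_detections(b20, fr)), 0)

  # diagonal touch joins components under 8-connectivity
  bd <- matrix(FALSE, 10, 10)
  bd[2:3, 2:3] <- TRUE; bd[4:5, 4:5] <- TRUE
  expect_equal(nrow(extract_detections(bd, matrix(1, 10, 10),
                                       min_area = 0)), 1)

  expect_equal(nrow(extract_detections(matrix(FALSE, 5, 5),
                                       matrix(0, 5, 5))), 0)
})

test_that("every rendered blob above threshold yields one centroid within 1 px", {
  sc <- make_scene(n_frames = 30, n_fish = 3, seed = 5)
  det <- detect_stack(sc$stack, fpn = sc$truth$fpn)
  truth_on <- sc$truth$table[sc$truth$table$on, ]
  # one detection per on-fish per frame
  expect_equal(nrow(det), nrow(truth_on))
  m <- merge(det, truth_on, by = "frame")
  m$d <- sqrt((m$row.x - m$row.y)^2 + (m$col.x - m$col.y)^2)
  # match each detection to its nearest truth entry
  dmin <- tapply(m$d, paste(m$frame, m$row.x), min)
  expect_lt(max(dmin), 1)
})
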