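test_that("msync matches hand-evaluated cases and error contract", {
  expect_equal(msync(rbind(c(1, 0, 0), c(1, 0, 0))), 1)
  expect_equal(msync(rbind(c(1, 0, 0), c(-1, 0, 0))), 0)
  expect_equal(msync(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               sqrt(3) / 3)
  expect_error(msync(matrix(0, 3, 3)), "undefined")
})

test_that("msync is bounded, direction-only, and invariant to rotation and rescaling", {
  set.seed(10)
  for (r in 1:20) {
    v <- matrix(rnorm(15), 5, 3)
    m <- msync(v)
    expect_gte(m, 0); expect_lte(m, 1)
    # uniform speed rescale
    expect_equal(msync(3.7 * v), m, tolerance = 1e-12)
    # rotation
    R <- rotation_matrix(runif(1, 0, 2 * pi), runif(1, 0, pi))
    expect_equal(msync(v %*% t(R)), m, tolerance = 1e-12)
  }
  # equals 1 iff directions identical (speeds may differ)
  u <- c(1, 2, -1) / sqrt(6)
  v1 <- rbind(0.5 * u, 2 * u, 7 * u)
  expect_equal(msync(v1), 1, tolerance = 1e-12)
  v1[1, ] <- v1[1, ] + c(0.05, 0, 0)
  expect_lt(msync(v1), 1)
})

test_that("direction correlation matches its definition and scale invariance", {
  vL <- c(1, 0, 0)
  expect_equal(direction_correlation(rbind(c(2, 0, 0), c(0.5, 0, 0)), vL), 1)
  expect_equal(direction_correlation(rbind(c(0, 1, 0), c(0, 0, 2)), vL), 0)
  expect_equal(direction_correlation(rbind(c(1, 0, 0), c(-1, 0, 0)), vL), 0)
  # anti-aligned fish give negative values (unclamped)
  expect_lt(direction_correlation(rbind(c(-1, 0, 0)), vL), 0)
  set.seed(3)
  v <- matrix(rnorm(12), 4, 3)
  expect_equal(direction_correlation(v, vL),
               direction_correlation(v, 42 * vL), tolerance = 1e-12)
  expect_error(direction_correlation(v, c(0, 0, 0)), "undefined")
})

test_that("random-motion null concentrates mSync near zero", {
  one <- random_motion_null(1.3, n_fish = 1, n_frames = 3, seed = 1)
  expect_equal(kinematics_series(one)$msync, rep(1, 4))

  big <- random_motion_null(runif(40, 0.5, 2), 1000, 3, seed = 2)
  expect_true(all(kinematics_series(big)$msync < 0.1))

  a <- random_motion_null(1, 20, 5, seed = 7)
  b <- random_motion_null(1, 20, 5, seed = 7)
  expect_identical(a$velocity, b$velocity)
})

test_that("kinematics series handles static, rigid and tracked motion", {
  # rigid translation -> mSync 1 every frame
  n <- 6
  pos <- array(0, c(n, 3, 5)); vel <- array(0, c(n, 3, 5))
  for (t in 1:5) vel[, , t] <- matrix(rep(c(1, 2, 0), each = n), n, 3)
  tr <- structure(list(position = pos, velocity = vel,
                       flashing = matrix(TRUE, n, 5),
                       dark = rep(FALSE, n), motivated = rep(FALSE, n),
                       dt = 1 / 30, n_frames = 4L),
                  class = "school_trajectory")
  expect_equal(kinematics_series(tr)$msync, rep(1, 5))

  # all static -> undefined everywhere
  vel0 <- array(0, c(n, 3, 5))
  tr0 <- tr; tr0$velocity <- vel0
  expect_true(all(is.na(kinematics_series(tr0)$msync)))

  # tracked table: two fish translating together at 1 px/frame in col
  tk <- data.frame(track_id = rep(1:2, each = 10),
                   frame = rep(0:9, 2),
                   row = c(rep(5, 10), rep(20, 10)),
                   col = rep(0:9, 2))
  ks <- kinematics_series(tk, fps = 30)
  expect_equal(ks$msync[1:9], rep(1, 9))
  expect_equal(ks$mean_speed[1:9], rep(30, 9))     # 1 px/frame * 30 fps
  expect_true(is.na(ks$msync[10]))                 # no forward difference
  expect_error(kinematics_series(tk[0, ]), "empty")
})

test_that("rank-sum exact enumeration matches spec cases and the library oracle", {
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)          # 2 / C(6,3) doubled tail
  expect_equal(r$statistic, 6)          # minimal rank sum
  expect_equal(r$method, "exact")

  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(5)
  for (r in 1:50) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), 0.8)
    expect_equal(rank_sum_test(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact and normal-approximation branches agree at the boundary", {
  set.seed(6)
  for (r in 1:40) {
    a <- rnorm(8); b <- rnorm(8)
    p_exact <- rank_sum_test(a, b)$p_value
    p_norm <- stats::wilcox.test(a, b, exact = FALSE,
                                 correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
  big <- rank_sum_test(rnorm(50), rnorm(50))
  expect_equal(big$method, "normal-approximation")
})
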