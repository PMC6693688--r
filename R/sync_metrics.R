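#' mSync polarization order parameter
#'
#' `msync` measures the synchrony of a set of velocities as the magnitude
#' of the mean velocity divided by the mean speed. It is 0 for perfectly
#' cancelling motion (shoaling) and 1 exactly when every non-zero velocity
#' points the same way (ideal schooling); speeds may differ. The formula
#' is dimension-agnostic: 2-D for image-plane tracks, 3-D for the model.
#'
#' @param velocities numeric matrix, one row per fish.
#' @return a number in `[0, 1]`.
#' @export
msync <- function(velocities) {
  v <- as.matrix(velocities)
  speeds <- sqrt(rowSums(v^2))
  ms <- mean(speeds)
  if (ms == 0) stop("undefined value: all speeds zero")
  sqrt(sum(colMeans(v)^2)) / ms
}

#' Per-frame kinematics of a school
#'
#' Computes the mean speed and `msync` of every frame. For a simulated
#' [run_simulation()] trajectory the stored velocities are used; for a
#' table of linked video tracks (columns `track_id`, `frame`, `row`,
#' `col`) velocities are forward finite differences of centroids between
#' consecutive frames, in px/s, and only fish tracked in both frames
#' contribute to a frame. Frames with no moving fish get `NA`.
#'
#' @param x a `school_trajectory` or a tracks `data.frame`.
#' @param ... passed on to methods.
#' @return `data.frame` with columns `frame` (0-based), `mean_speed`,
#'   `msync`, `n_fish`.
#' @export
kinematics_series <- function(x, ...) UseMethod("kinematics_series")

#' @export
kinematics_series.school_trajectory <- function(x, ...) {
  T_total <- dim(x$velocity)[3]
  if (T_total < 2) stop("trajectory must have at least 2 frames")
  out <- data.frame(frame = seq_len(T_total) - 1L,
                    mean_speed = NA_real_, msync = NA_real_,
                    n_fish = dim(x$velocity)[1])
  for (t in seq_len(T_total)) {
    v <- x$velocity[, , t, drop = FALSE]
    v <- matrix(v, dim(x$velocity)[1], 3)
    sp <- sqrt(rowSums(v^2))
    out$mean_speed[t] <- mean(sp)
    if (any(sp > 0)) out$msync[t] <- msync(v)
  }
  out
}

#' @param fps frames per second used to scale track displacements to px/s.
#' @rdname kinematics_series
#' @export
kinematics_series.data.frame <- function(x, fps = 30, ...) {
  stopifnot(all(c("track_id", "frame", "row", "col") %in% names(x)))
  if (nrow(x) == 0L) stop("empty trajectory")
  x <- x[order(x$track_id, x$frame), ]
  frames <- seq(min(x$frame), max(x$frame))
  out <- data.frame(frame = frames, mean_speed = NA_real_,
                    msync = NA_real_, n_fish = 0L)
  # forward difference: velocity at frame t needs the same track at t+1
  nxt <- match(paste(x$track_id, x$frame + 1L), paste(x$track_id, x$frame))
  has <- !is.na(nxt)
  vr <- (x$row[nxt[has]] - x$row[has]) * fps
  vc <- (x$col[nxt[has]] - x$col[has]) * fps
  fr <- x$frame[has]
  for (i in seq_along(frames)) {
    sel <- fr == frames[i]
    n <- sum(sel)
    out$n_fish[i] <- n
    if (n > 0) {
      v <- cbind(vr[sel], vc[sel])
      sp <- sqrt(rowSums(v^2))
      out$mean_speed[i] <- mean(sp)
      if (any(sp > 0)) out$msync[i] <- msync(v)
    }
  }
  out
}

#' Direction correlation with motivated leaders
#'
#' Normalized summed inner product between the leader velocity `v_L` and
#' all fish velocities: `sum(<v_L, v_i>) / (|v_L| * sum(|v_i|))`. With two
#' motivated fish, `v_L` is their average velocity. The value is 1 when
#' every fish moves parallel to the leader and is invariant to rescaling
#' `v_L`. Note: although often described as lying in `[0, 1]`, the
#' formula admits negative values (fish anti-aligned with the leader);
#' values are reported unclamped.
#'
#' @param velocities matrix of fish velocities, one row each.
#' @param v_L leader velocity (non-zero).
#' @return a number in `[-1, 1]`.
#' @export
direction_correlation <- function(velocities, v_L) {
  v <- as.matrix(velocities)
  nl <- sqrt(sum(v_L^2))
  ss <- sum(sqrt(rowSums(v^2)))
  if (nl == 0 || ss == 0) stop("undefined value: zero-magnitude inputs")
  sum(v %*% v_L) / (nl * ss)
}

#' Random-motion null model for mSync
#'
#' Simulates fish whose velocity each frame has a uniformly random
#' direction (on the sphere or circle) and a speed resampled with
#' replacement from observed speeds. The per-frame mSync of such motion
#' concentrates near zero as the school grows (|mean of n random unit
#' vectors| ~ n^-1/2), providing the null distribution against which
#' observed synchrony is tested.
#'
#' @param speed_samples non-empty numeric vector of speeds to resample.
#' @param n_fish,n_frames school size and number of frames.
#' @param seed optional integer seed.
#' @param dim 2 or 3 dimensions.
#' @param dt frame interval in seconds (for integrated positions).
#' @return a `school_trajectory` with random velocities.
#' @export
random_motion_null <- function(speed_samples, n_fish, n_frames,
                               seed = NULL, dim = 3, dt = 1 / 30) {
  stopifnot(length(speed_samples) > 0, n_fish >= 1, n_frames >= 1,
            dim %in% c(2, 3))
  if (!is.null(seed)) set.seed(seed)
  T_total <- n_frames + 1L
  vel <- array(0, c(n_fish, 3, T_total))
  for (t in seq_len(T_total)) {
    u <- matrix(stats::rnorm(n_fish * dim), n_fish, dim)
    u <- u / sqrt(rowSums(u^2))
    sp <- sample(speed_samples, n_fish, replace = TRUE)
    vel[, seq_len(dim), t] <- u * sp
  }
  pos <- array(0, c(n_fish, 3, T_total))
  for (t in 2:T_total) pos[, , t] <- pos[, , t - 1] + vel[, , t] * dt
  structure(list(position = pos, velocity = vel,
                 flashing = matrix(TRUE, n_fish, T_total),
                 dark = rep(FALSE, n_fish),
                 motivated = rep(FALSE, n_fish),
                 dt = dt, n_frames = as.integer(n_frames)),
            class = "school_trajectory")
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided Mann-Whitney/Wilcoxon test. When both samples have at most 8
#' observations the null distribution of the rank sum is computed exactly
#' by enumerating every assignment of ranks to the smaller sample
#' (midranks under ties); otherwise the normal approximation with tie
#' correction (via [stats::wilcox.test()]) is used. The reported
#' statistic is the rank sum of the smaller sample (the first on ties in
#' size); the two-sided p doubles the smaller tail, capped at 1.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return object of class `rank_sum_result`: list with `statistic`,
#'   `p_value`, `method` (`"exact"` or `"normal-approximation"`), `n_a`,
#'   `n_b`.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  na <- length(sample_a); nb <- length(sample_b)
  swap <- nb < na
  small <- if (swap) sample_b else sample_a
  large <- if (swap) sample_a else sample_b
  ns <- length(small); ntot <- ns + length(large)
  r <- rank(c(small, large))
  w_obs <- sum(r[seq_len(ns)])

  if (na <= 8 && nb <= 8) {
    splits <- utils::combn(ntot, ns)
    w_all <- colSums(matrix(r[splits], nrow = ns))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(w_all <= w_obs + eps),
                        mean(w_all >= w_obs - eps)))
    method <- "exact"
  } else {
    p <- stats::wilcox.test(small, large, exact = FALSE,
                            correct = TRUE)$p.value
    method <- "normal-approximation"
  }
  structure(list(statistic = w_obs, p_value = p, method = method,
                 n_a = na, n_b = nb),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): W = %g, p = %.4g (n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
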