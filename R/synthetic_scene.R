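#' Configuration for a synthetic low-light scene
#'
#' Describes a rendered stand-in for a low-light recording of flashing
#' fish: image geometry, blob appearance, sensor noise, and flash timing.
#' Defaults emulate the recording conditions this package targets: 30 fps
#' 16-bit video whose flashes use at most ~1% of the dynamic range
#' (peak 655 of 65535), additive fixed-pattern noise of mean 100 and sd 5
#' counts, and square-wave flashing with on 0.166 s / off 0.168 s.
#'
#' @param width,height image size in px.
#' @param fps frame rate (default 30).
#' @param n_fish number of rendered fish.
#' @param blob_sigma Gaussian blob sigma in px.
#' @param peak_amplitude blob peak in counts above background.
#' @param fpn_mean,fpn_sd fixed-pattern-noise distribution in counts.
#' @param read_noise_sd per-pixel-per-frame Gaussian read noise sd.
#' @param flash_on_s,flash_off_s square-wave durations in seconds.
#' @param motion one of `"constant-velocity"`, `"random-walk"`,
#'   `"simulator-projection"` (how trajectories are meant to be built).
#' @param amplitude_factors optional per-fish brightness factors
#'   (emulating closer fish appearing brighter).
#' @param seed optional integer seed used by [render_stack()].
#' @return object of class `scene_config`.
#' @export
scene_config <- function(width = 256, height = 256, fps = 30, n_fish = 5,
                         blob_sigma = 2, peak_amplitude = 655,
                         fpn_mean = 100, fpn_sd = 5, read_noise_sd = 2,
                         flash_on_s = 0.166, flash_off_s = 0.168,
                         motion = c("constant-velocity", "random-walk",
                                    "simulator-projection"),
                         amplitude_factors = NULL,
                         seed = NULL) {
  motion <- match.arg(motion)
  stopifnot(width >= 8, height >= 8, fps > 0, n_fish >= 0,
            blob_sigma > 0, peak_amplitude > 0, peak_amplitude <= 65535,
            fpn_mean >= 0, fpn_sd >= 0, read_noise_sd >= 0,
            flash_on_s > 0, flash_off_s > 0)
  if (is.null(amplitude_factors)) amplitude_factors <- rep(1, max(n_fish, 1))
  structure(list(width = width, height = height, fps = fps,
                 n_fish = as.integer(n_fish), blob_sigma = blob_sigma,
                 peak_amplitude = peak_amplitude,
                 fpn_mean = fpn_mean, fpn_sd = fpn_sd,
                 read_noise_sd = read_noise_sd,
                 flash_on_s = flash_on_s, flash_off_s = flash_off_s,
                 motion = motion, amplitude_factors = amplitude_factors,
                 seed = seed),
            class = "scene_config")
}

#' Draw a fixed-pattern-noise map
#'
#' Per-pixel independent Normal(mean, sd^2) offsets, truncated at zero
#' (counts cannot be negative).
#'
#' @param height,width map size in px.
#' @param mean,sd offset distribution in counts (defaults 100 and 5).
#' @param seed optional integer seed.
#' @return `height x width` numeric matrix.
#' @export
make_fpn_map <- function(height, width, mean = 100, sd = 5, seed = NULL) {
  stopifnot(sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  pmax(matrix(stats::rnorm(height * width, mean, sd), height, width), 0)
}

#' Sample a square-wave flash signal
#'
#' Samples a (possibly jittered) on/off square wave at the frame rate.
#' Without jitter the state of frame `k` is
#' `((k / fps + phase_s) mod (on + off)) < on`. With jitter, successive
#' run durations are drawn from truncated normals around the nominal
#' durations and the continuous switching times are then sampled. The
#' exact continuous run durations are attached as attributes
#' (`on_truth_s`, `off_truth_s`) as ground truth.
#'
#' @param on_s,off_s nominal on/off durations in seconds (positive).
#' @param fps sampling rate in Hz.
#' @param n_frames number of samples.
#' @param phase_s phase offset in seconds.
#' @param jitter_sd_s sd of per-run duration jitter (0 = deterministic).
#' @param seed optional integer seed (used only when jittering).
#' @return logical vector of length `n_frames`.
#' @export
flash_train_signal <- function(on_s, off_s, fps, n_frames, phase_s = 0,
                               jitter_sd_s = 0, seed = NULL) {
  stopifnot(on_s > 0, off_s > 0, fps > 0, n_frames >= 1)
  t <- (seq_len(n_frames) - 1) / fps + phase_s
  if (jitter_sd_s == 0) {
    period <- on_s + off_s
    st <- (t %% period) < on_s
    attr(st, "on_truth_s") <- on_s
    attr(st, "off_truth_s") <- off_s
    return(st)
  }
  if (!is.null(seed)) set.seed(seed)
  span <- max(t) + on_s + off_s
  ons <- numeric(0); offs <- numeric(0); bounds <- 0; total <- 0
  min_d <- 1 / fps
  while (total < span + on_s + off_s) {
    d_on <- max(min_d, stats::rnorm(1, on_s, jitter_sd_s))
    d_off <- max(min_d, stats::rnorm(1, off_s, jitter_sd_s))
    ons <- c(ons, d_on); offs <- c(offs, d_off)
    bounds <- c(bounds, total + d_on, total + d_on + d_off)
    total <- total + d_on + d_off
  }
  # intervals alternate on/off starting with an on-run at time 0;
  # findInterval gives odd indices for on-runs
  iv <- findInterval(t, bounds)
  st <- iv %% 2 == 1
  attr(st, "on_truth_s") <- ons
  attr(st, "off_truth_s") <- offs
  st
}

#' Straight-line trajectories for rendered fish
#'
#' @param starts `n_fish x 2` matrix of starting (row, col) positions, px.
#' @param velocities `n_fish x 2` matrix of velocities in px/frame.
#' @param n_frames number of frames.
#' @return `data.frame` with columns `frame` (0-based), `fish`, `row`,
#'   `col`.
#' @export
constant_velocity_trajectories <- function(starts, velocities, n_frames) {
  starts <- as.matrix(starts); velocities <- as.matrix(velocities)
  n <- nrow(starts)
  frames <- rep(seq_len(n_frames) - 1L, each = n)
  data.frame(frame = frames,
             fish = rep(seq_len(n), n_frames),
             row = rep(starts[, 1], n_frames) + frames * rep(velocities[, 1], n_frames),
             col = rep(starts[, 2], n_frames) + frames * rep(velocities[, 2], n_frames))
}

#' Random-walk trajectories in the image plane
#'
#' Each fish takes an independent step in a uniformly random direction
#' every frame, with step length resampled from `speeds_px` (px/frame);
#' walks reflect off a margin inside the image bounds. Used for the
#' random-motion mSync null at the video level.
#'
#' @param config a [scene_config()].
#' @param n_frames number of frames.
#' @param speeds_px step-length pool in px/frame.
#' @param margin reflection margin in px.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `frame`, `fish`, `row`, `col`.
#' @export
random_walk_trajectories <- function(config, n_frames, speeds_px = 1,
                                     margin = 10, seed = NULL) {
  stopifnot(config$n_fish >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_fish
  lo_r <- margin; hi_r <- config$height - 1 - margin
  lo_c <- margin; hi_c <- config$width - 1 - margin
  r <- stats::runif(n, lo_r, hi_r)
  cc <- stats::runif(n, lo_c, hi_c)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      ang <- stats::runif(n, 0, 2 * pi)
      sp <- speeds_px[sample.int(length(speeds_px), n, replace = TRUE)]
      r <- r + sp * sin(ang)
      cc <- cc + sp * cos(ang)
      r <- pmin(pmax(r, lo_r), hi_r)    # clamp at margin
      cc <- pmin(pmax(cc, lo_c), hi_c)
    }
    out[[f]] <- data.frame(frame = f - 1L, fish = seq_len(n),
                           row = r, col = cc)
  }
  do.call(rbind, out)
}

#' Render a synthetic 16-bit video stack with ground truth
#'
#' Each frame is the fixed-pattern-noise map plus one isotropic Gaussian
#' blob per currently-on fish (peak `peak_amplitude` times the fish's
#' brightness factor, sigma `blob_sigma`, centred on the true position)
#' plus Gaussian read noise, rounded and clipped to the 16-bit range.
#' Returns the stack alongside the ground truth (true centroids, on/off
#' states and the true FPN map).
#'
#' @param config a [scene_config()]; `config$seed`, when set, seeds the
#'   FPN map and read noise.
#' @param trajectories `data.frame` with columns `frame` (0-based,
#'   covering `0..n_frames-1`), `fish`, `row`, `col` (0-based px).
#' @param trains list (one logical vector per fish) of per-frame on/off
#'   states, e.g. from [flash_train_signal()].
#' @param fpn optional pre-built FPN map (drawn from the config
#'   otherwise).
#' @return list with `stack` (a [frame_stack()]) and `truth` (list with
#'   `table`: frame/fish/row/col/on, and `fpn`).
#' @export
render_stack <- function(config, trajectories, trains, fpn = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  h <- config$height; w <- config$width
  n_frames <- max(trajectories$frame) + 1L
  n <- config$n_fish
  stopifnot(length(trains) >= n)
  if (any(trajectories$row < 0 | trajectories$row > h - 1 |
          trajectories$col < 0 | trajectories$col > w - 1))
    stop("trajectory out of image bounds")
  if (is.null(fpn))
    fpn <- make_fpn_map(h, w, config$fpn_mean, config$fpn_sd)
  half <- ceiling(4 * config$blob_sigma)
  data <- array(0L, c(h, w, n_frames))
  truth <- trajectories[order(trajectories$frame, trajectories$fish), ]
  truth$on <- FALSE
  for (f in seq_len(n_frames)) {
    img <- fpn
    sel <- which(truth$frame == f - 1L)
    for (k in sel) {
      fish <- truth$fish[k]
      if (fish > n || !isTRUE(trains[[fish]][f])) next
      truth$on[k] <- TRUE
      r0 <- truth$row[k]; c0 <- truth$col[k]
      rr <- max(0, floor(r0 - half)):min(h - 1, ceiling(r0 + half))
      cc <- max(0, floor(c0 - half)):min(w - 1, ceiling(c0 + half))
      amp <- config$peak_amplitude * config$amplitude_factors[fish]
      blob <- amp * exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) /
                          (2 * config$blob_sigma^2))
      img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + blob
    }
    if (config$read_noise_sd > 0)
      img <- img + stats::rnorm(h * w, 0, config$read_noise_sd)
    img <- round(img)
    img[img < 0] <- 0
    img[img > 65535] <- 65535
    data[, , f] <- as.integer(img)
  }
  list(stack = frame_stack(data, config$fps),
       truth = list(table = truth, fpn = fpn))
}
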