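#' Peak-intensity time series of one track
#'
#' Orders a track's samples by frame and fills every frame of the track's
#' span; frames where the fish was not detected (e.g. gaps bridged by the
#' linker while the light organ was occluded) get `NA` and are treated as
#' off by the flash segmenter.
#'
#' @param track rows of a tracks table for a single `track_id` (columns
#'   `frame`, `peak`).
#' @return `data.frame` with columns `frame` and `peak` covering the full
#'   span.
#' @export
intensity_series <- function(track) {
  stopifnot(nrow(track) > 0)
  track <- track[order(track$frame), ]
  frames <- seq(min(track$frame), max(track$frame))
  peak <- rep(NA_real_, length(frames))
  peak[match(track$frame, frames)] <- track$peak
  data.frame(frame = frames, peak = peak)
}

#' Segment a flash train from an intensity series
#'
#' A frame is "on" when its intensity reaches `level`; missing intensities
#' are off. The default level is half the 95th percentile of the track's
#' intensities, which is robust both to single hot frames and to the
#' near-zero off-phase floor. Runs are run-length encoded; the leading
#' and trailing runs are truncated by the observation window, so they are
#' excluded from the on/off interval statistics (but retained in
#' `states`).
#'
#' @param series numeric vector of intensities, or the `data.frame` from
#'   [intensity_series()]; length at least 2.
#' @param fps frame rate in Hz.
#' @param level absolute on-threshold; default
#'   `0.5 * quantile(series, 0.95)`.
#' @return object of class `flash_train`: list with `fps`, logical
#'   `states`, `on_intervals` and `off_intervals` (seconds, interior runs
#'   only), and the run-length encoding `runs`.
#' @export
segment_flashes <- function(series, fps, level = NULL) {
  if (is.data.frame(series)) series <- series$peak
  stopifnot(length(series) >= 2, fps > 0)
  if (is.null(level))
    level <- 0.5 * stats::quantile(series, 0.95, na.rm = TRUE, names = FALSE)
  states <- !is.na(series) & series >= level
  r <- rle(states)
  k <- length(r$lengths)
  interior <- if (k > 2) seq(2L, k - 1L) else integer(0)
  on_iv <- r$lengths[interior][r$values[interior]] / fps
  off_iv <- r$lengths[interior][!r$values[interior]] / fps
  structure(list(fps = fps, states = states,
                 on_intervals = as.numeric(on_iv),
                 off_intervals = as.numeric(off_iv),
                 runs = r),
            class = "flash_train")
}

#' Rebuild the binary state sequence from a train's run encoding
#'
#' @param train a `flash_train`.
#' @return logical vector identical to `train$states`.
#' @export
reconstruct_states <- function(train) inverse.rle(train$runs)

# complete cycles of one train: interior on-runs paired with the
# immediately following interior off-run
complete_cycles <- function(train) {
  r <- train$runs
  k <- length(r$lengths)
  if (k < 4) return(data.frame(on_s = numeric(0), off_s = numeric(0)))
  on_s <- numeric(0); off_s <- numeric(0)
  for (j in seq(2L, k - 2L)) {
    if (r$values[j] && !r$values[j + 1L]) {
      on_s <- c(on_s, r$lengths[j] / train$fps)
      off_s <- c(off_s, r$lengths[j + 1L] / train$fps)
    }
  }
  data.frame(on_s = on_s, off_s = off_s)
}

#' Aggregate flash statistics over one or more trains
#'
#' A complete flash is an on-run followed by an off-run, both fully
#' inside the observation window (truncated first/last runs are
#' excluded to avoid biasing durations downward). Each complete flash
#' contributes one duty cycle `on / (on + off)`. The blink rate is the
#' number of complete flashes divided by the total duration they cover,
#' so a jitter-free square wave recovers `1 / (on + off)`.
#'
#' @param trains a `flash_train` or list of them.
#' @return object of class `flash_stats`: list with `mean_on_s`,
#'   `mean_off_s`, `duty_cycles`, `blink_rate_hz`, `n_flashes`.
#' @export
flash_stats <- function(trains) {
  if (inherits(trains, "flash_train")) trains <- list(trains)
  cyc <- do.call(rbind, lapply(trains, complete_cycles))
  if (is.null(cyc) || nrow(cyc) == 0L)
    stop("no complete on/off cycle in any train")
  duty <- cyc$on_s / (cyc$on_s + cyc$off_s)
  structure(list(mean_on_s = mean(cyc$on_s),
                 mean_off_s = mean(cyc$off_s),
                 duty_cycles = duty,
                 blink_rate_hz = nrow(cyc) / sum(cyc$on_s + cyc$off_s),
                 n_flashes = nrow(cyc)),
            class = "flash_stats")
}

#' @export
print.flash_stats <- function(x, ...) {
  cat(sprintf(
    "flash_stats: %d flashes, mean on %.3f s, mean off %.3f s, duty %.1f%%, rate %.2f Hz\n",
    x$n_flashes, x$mean_on_s, x$mean_off_s, 100 * mean(x$duty_cycles),
    x$blink_rate_hz))
  invisible(x)
}

#' Averaged power spectrum of flash trains
#'
#' Periodogram of each train's mean-removed binary state sequence,
#' averaged across fish (power discards phase, so trains at different
#' phases average coherently). Trains are truncated to the shortest
#' length so the frequency grids match; every train must span at least
#' 2 s for a usable ~0.5 Hz resolution. The peak is the frequency of
#' maximum mean power above 0.5 Hz, excluding slow drift.
#'
#' @param trains a `flash_train` or list of them.
#' @param fps frame rate; defaults to the trains' own.
#' @return object of class `flash_spectrum`: list with `frequencies_hz`,
#'   `power`, `peak_frequency_hz`.
#' @export
flash_spectrum <- function(trains, fps = NULL) {
  if (inherits(trains, "flash_train")) trains <- list(trains)
  if (is.null(fps)) fps <- trains[[1]]$fps
  lens <- vapply(trains, function(tr) length(tr$states), 1L)
  if (any(lens < 2 * fps))
    stop("record too short: every train must span at least 2 s")
  L <- min(lens)
  specs <- lapply(trains, function(tr) {
    x <- as.numeric(tr$states[seq_len(L)])
    stats::spec.pgram(x - mean(x), taper = 0, detrend = FALSE,
                      demean = FALSE, fast = FALSE, plot = FALSE)
  })
  freq <- specs[[1]]$freq * fps
  power <- rowMeans(vapply(specs, `[[`, numeric(length(freq)), "spec"))
  above <- freq > 0.5
  if (!any(above) || max(power[above]) <= 0)
    stop("no spectral peak above 0.5 Hz")
  structure(list(frequencies_hz = freq, power = power,
                 peak_frequency_hz = freq[above][which.max(power[above])]),
            class = "flash_spectrum")
}

#' Recover flash kinetics from linked tracks
#'
#' Per-track driver: builds each track's intensity series, segments it
#' into a flash train, and aggregates statistics and (optionally) the
#' averaged power spectrum.
#'
#' @param tracks table from [build_tracks()].
#' @param fps frame rate.
#' @param level optional absolute on-threshold passed to
#'   [segment_flashes()].
#' @param spectrum also compute [flash_spectrum()]? Skipped when any
#'   track is too short.
#' @return list with `trains`, `stats`, and `spectrum` (or `NULL`).
#' @export
recover_flash_kinetics <- function(tracks, fps, level = NULL,
                                   spectrum = TRUE) {
  ids <- unique(tracks$track_id)
  trains <- lapply(ids, function(id) {
    segment_flashes(intensity_series(tracks[tracks$track_id == id, ]),
                    fps, level)
  })
  spec <- NULL
  if (spectrum) {
    lens <- vapply(trains, function(tr) length(tr$states), 1L)
    if (all(lens >= 2 * fps)) spec <- flash_spectrum(trains, fps)
  }
  list(trains = trains, stats = flash_stats(trains), spectrum = spec)
}
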