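#' Linking configuration
#'
#' @param max_radius maximum per-frame displacement in px; when bridging a
#'   gap of `g` missed frames the allowed displacement grows to
#'   `max_radius * (g + 1)`.
#' @param max_gap number of consecutive frames a track may go undetected
#'   before it is closed (default 0: strictly frame-to-frame, since
#'   non-flashing fish cannot be tracked; raise it to bridge the ~5-frame
#'   off-phase for flash-kinetics work).
#' @param min_track_length minimum number of samples for a track to be
#'   kept (default 2).
#' @return object of class `link_config`.
#' @export
link_config <- function(max_radius, max_gap = 0L, min_track_length = 2L) {
  stopifnot(is.numeric(max_radius), max_radius > 0, max_gap >= 0,
            min_track_length >= 1)
  structure(list(max_radius = max_radius, max_gap = as.integer(max_gap),
                 min_track_length = as.integer(min_track_length)),
            class = "link_config")
}

new_track <- function(id, frame, det)
  list(id = id, frame = frame, row = det$row, col = det$col,
       area = det$area, peak = det$peak)

#' Link one frame of detections to open tracks
#'
#' Globally greedy nearest-distance assignment (a Crocker-Grier-style
#' cost without global optimization): among all (track, detection) pairs
#' within the allowed radius, repeatedly commit the closest pair, using
#' each track and detection at most once. Unmatched detections open new
#' tracks; tracks undetected for more than `max_gap` frames are closed.
#'
#' @param open_tracks list of track records (as built by
#'   [build_tracks()]), each with vectors `frame`, `row`, `col`, `area`,
#'   `peak`.
#' @param detections `data.frame` of detections, all from frame `t`.
#' @param t current frame index (0-based).
#' @param config a [link_config()].
#' @param next_id first id for newly opened tracks.
#' @return list with `open` (updated open tracks), `closed` (tracks
#'   closed at this frame), `next_id`.
#' @export
link_frame <- function(open_tracks, detections, t, config, next_id = 1L) {
  last_frame <- vapply(open_tracks, function(tr) tr$frame[length(tr$frame)],
                       numeric(1))
  gap <- t - last_frame - 1
  keep <- gap <= config$max_gap
  closed <- open_tracks[!keep]
  open <- open_tracks[keep]
  gap <- gap[keep]

  nd <- nrow(detections)
  nt <- length(open)
  if (nd > 0 && nt > 0) {
    lr <- vapply(open, function(tr) tr$row[length(tr$row)], numeric(1))
    lc <- vapply(open, function(tr) tr$col[length(tr$col)], numeric(1))
    dmat <- sqrt(outer(lr, detections$row, "-")^2 +
                 outer(lc, detections$col, "-")^2)
    allow <- config$max_radius * (gap + 1)
    cand <- which(dmat <= matrix(allow, nt, nd), arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dmat[cand])
      used_t <- logical(nt); used_d <- logical(nd)
      for (k in ord) {
        ti <- cand[k, 1]; di <- cand[k, 2]
        if (used_t[ti] || used_d[di]) next
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        tr <- open[[ti]]
        tr$frame <- c(tr$frame, t)
        tr$row <- c(tr$row, detections$row[di])
        tr$col <- c(tr$col, detections$col[di])
        tr$area <- c(tr$area, detections$area[di])
        tr$peak <- c(tr$peak, detections$peak[di])
        open[[ti]] <- tr
      }
    } else used_d <- logical(nd)
  } else used_d <- logical(nd)

  if (nd > 0) {
    for (di in which(!used_d)) {
      open[[length(open) + 1L]] <-
        new_track(next_id, t, detections[di, , drop = FALSE])
      next_id <- next_id + 1L
    }
  }
  list(open = open, closed = closed, next_id = next_id)
}

#' Build tracks from all detections
#'
#' Applies [link_frame()] frame by frame over the detection table, then
#' drops tracks shorter than `min_track_length`. Deterministic for a
#' fixed input.
#'
#' @param detections `data.frame` with columns `frame`, `row`, `col` and
#'   optionally `area`, `peak`, sorted or not.
#' @param config a [link_config()].
#' @return `data.frame` with columns `track_id`, `frame`, `row`, `col`,
#'   `area`, `peak`; track ids are 1..K in order of creation.
#' @export
build_tracks <- function(detections, config) {
  stopifnot(inherits(config, "link_config"))
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0),
                      area = integer(0), peak = numeric(0))
  if (nrow(detections) == 0L) return(empty)
  if (is.null(detections$area)) detections$area <- NA_integer_
  if (is.null(detections$peak)) detections$peak <- NA_real_
  detections <- detections[order(detections$frame), ]
  open <- list(); done <- list(); next_id <- 1L
  for (t in sort(unique(detections$frame))) {
    res <- link_frame(open, detections[detections$frame == t, ,
                                       drop = FALSE],
                      t, config, next_id)
    open <- res$open
    done <- c(done, res$closed)
    next_id <- res$next_id
  }
  done <- c(done, open)
  done <- done[vapply(done, function(tr) length(tr$frame), 1L) >=
                 config$min_track_length]
  if (length(done) == 0L) return(empty)
  done <- done[order(vapply(done, `[[`, 1L, "id"))]
  out <- do.call(rbind, lapply(seq_along(done), function(k) {
    tr <- done[[k]]
    data.frame(track_id = k, frame = tr$frame, row = tr$row,
               col = tr$col, area = tr$area, peak = tr$peak)
  }))
  rownames(out) <- NULL
  out
}
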