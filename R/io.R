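#' Read and write 16-bit multi-page TIFF stacks
#'
#' Grayscale stacks are stored as multi-page 16-bit TIFF with intensities
#' in counts (0-65535).
#'
#' @param path file path.
#' @param fps frame rate to attach on read.
#' @return [read_stack()] returns a [frame_stack()].
#' @export
read_stack <- function(path, fps = 30) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  data <- array(0L, c(h, w, length(pages)))
  for (t in seq_along(pages)) data[, , t] <- pages[[t]]
  frame_stack(data, fps)
}

#' @param stack a [frame_stack()] with counts in 0-65535.
#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  T_total <- dim(stack$data)[3]
  pages <- lapply(seq_len(T_total), function(t) {
    m <- stack$data[, , t]
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read and write trajectory tables
#'
#' The long CSV schema shared by simulated trajectories and tracked
#' video: one row per agent-frame with columns `frame, agent_id, x, y, z,
#' vx, vy, vz, flashing, dark, motivated`.
#'
#' @param traj a `school_trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  n <- max(df$agent_id)
  T_total <- max(df$frame) + 1L
  df <- df[order(df$frame, df$agent_id), ]
  pos <- array(0, c(n, 3, T_total)); vel <- array(0, c(n, 3, T_total))
  pos[, 1, ] <- df$x; pos[, 2, ] <- df$y; pos[, 3, ] <- df$z
  vel[, 1, ] <- df$vx; vel[, 2, ] <- df$vy; vel[, 3, ] <- df$vz
  structure(list(position = pos, velocity = vel,
                 flashing = matrix(df$flashing == 1, n, T_total),
                 dark = df$dark[df$frame == 0] == 1,
                 motivated = df$motivated[df$frame == 0] == 1,
                 dt = NA_real_, n_frames = T_total - 1L),
            class = "school_trajectory")
}

#' Read and write simulator configurations as JSON
#'
#' JSON mirrors the [sim_config()] field names; vision regions are nested
#' objects.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  for (f in c("cohesion_region", "alignment_region", "separation_region"))
    x[[f]] <- unclass(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- function(r) vision_region(r$radius, r$blind_behind_deg,
                                   r$blind_front_deg)
  sim_config(n_fish = x$n_fish, w_c = x$w_c, w_a = x$w_a, w_s = x$w_s,
             w_f = x$w_f, w_v = x$w_v, v_max = x$v_max,
             v_cruise = x$v_cruise, dt = x$dt, P = x$P, D = x$D,
             cohesion_region = reg(x$cohesion_region),
             alignment_region = reg(x$alignment_region),
             separation_region = reg(x$separation_region),
             init_half_width = x$init_half_width,
             flash_mode = x$flash_mode,
             flash_on_s = x$flash_on_s, flash_off_s = x$flash_off_s,
             flash_gates_all_forces = x$flash_gates_all_forces,
             seed = x$seed)
}
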