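# shared fixture builders; everything is generated in code at test time

# a hand-built school state (bypasses init_school) for geometry tests
make_state <- function(position, velocity = NULL, flashing = NULL,
                       dark = NULL) {
  n <- nrow(position)
  if (is.null(velocity)) velocity <- matrix(0, n, 3)
  if (is.null(flashing)) flashing <- rep(TRUE, n)
  if (is.null(dark)) dark <- rep(FALSE, n)
  structure(list(position = position, velocity = velocity, dark = dark,
                 flashing = flashing, motivated = rep(FALSE, n),
                 mot_vel = matrix(0, n, 3), phase = integer(n),
                 frame = 0L),
            class = "school_state")
}

# small rendered scene with known ground truth: n_fish well-separated
# constant-velocity blobs flashing on 0.166 s / off 0.168 s
make_scene <- function(n_frames, n_fish = 3, seed = 11, fps = 30,
                       size = 160, read_noise_sd = 2, drift = 0.2) {
  cfg <- scene_config(width = size, height = size, fps = fps,
                      n_fish = n_fish, read_noise_sd = read_noise_sd,
                      seed = seed)
  starts <- cbind(seq(30, size - 30, length.out = n_fish), rep(25, n_fish))
  vels <- cbind(rep(0, n_fish), rep(drift, n_fish))
  traj <- constant_velocity_trajectories(starts, vels, n_frames)
  trains <- lapply(seq_len(n_fish), function(i)
    flash_train_signal(0.166, 0.168, fps, n_frames,
                       phase_s = (i - 1) * 0.05))
  out <- render_stack(cfg, traj, trains)
  out$config <- cfg
  out$trains <- trains
  out
}

rotation_matrix <- function(theta_z, theta_x) {
  rz <- rbind(c(cos(theta_z), -sin(theta_z), 0),
              c(sin(theta_z), cos(theta_z), 0),
              c(0, 0, 1))
  rx <- rbind(c(1, 0, 0),
              c(0, cos(theta_x), -sin(theta_x)),
              c(0, sin(theta_x), cos(theta_x)))
  rz %*% rx
}
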