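test_that("initialization places fish at rest in the cube and draws dark flags", {
  cfg <- sim_config(n_fish = 100)
  set.seed(1)
  st <- init_school(cfg)
  expect_equal(dim(st$position), c(100, 3))
  expect_true(all(abs(st$position) <= cfg$init_half_width))
  expect_true(all(st$velocity == 0))
  expect_false(any(st$dark))                      # D = 0

  set.seed(2)
  expect_true(all(init_school(sim_config(n_fish = 50, D = 1))$dark))

  set.seed(1)
  st2 <- init_school(cfg)
  expect_identical(st$position, st2$position)     # reproducible

  expect_error(sim_config(n_fish = 0), "n_fish")
})

test_that("visible_neighbors applies range, blind cones and flash gating", {
  pos <- rbind(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(30, 0, 0))
  vel <- rbind(c(1, 0, 0), matrix(0, 3, 3))
  st <- make_state(pos, vel)
  coh <- vision_region(25, blind_behind_deg = 90)

  # neighbour dead behind falls in the 90-degree rear cone
  expect_false(2 %in% visible_neighbors(1, st, coh))
  expect_true(3 %in% visible_neighbors(1, st, coh))
  # beyond the radius
  expect_false(4 %in% visible_neighbors(1, st, coh))
  # non-flashing neighbour is invisible when gated, visible when not
  st$flashing[3] <- FALSE
  expect_false(3 %in% visible_neighbors(1, st, coh, flash_gated = TRUE))
  expect_true(3 %in% visible_neighbors(1, st, coh, flash_gated = FALSE))
  # a focal fish at rest has no heading: no blind cones
  st$velocity[1, ] <- 0
  st$flashing[3] <- TRUE
  expect_setequal(visible_neighbors(1, st, coh), c(2, 3))
})

test_that("force laws reproduce hand-evaluated cases", {
  # cohesion: steer at v_max toward the visible centroid
  expect_equal(cohesion_force(c(0, 0, 0), c(0, 0, 0),
                              rbind(c(2, 0, 0)), 1), c(1, 0, 0))
  expect_equal(cohesion_force(c(0, 0, 0), c(1, 0, 0),
                              rbind(c(2, 0, 0)), 1), c(0, 0, 0))
  expect_equal(cohesion_force(c(0, 0, 0), c(1, 0, 0),
                              matrix(0, 0, 3), 1), c(0, 0, 0))

  # alignment: steer toward the mean neighbour direction
  expect_equal(alignment_force(c(0, 0, 0),
                               rbind(c(0, 2, 0), c(0, 1, 0)), 1),
               c(0, 1, 0))
  expect_equal(alignment_force(c(0, 1, 0), rbind(c(0, 5, 0)), 1),
               c(0, 0, 0))
  # opposite neighbour velocities cancel: zero-direction convention
  expect_equal(alignment_force(c(0.3, 0, 0),
                               rbind(c(0, 1, 0), c(0, -1, 0)), 1),
               c(0, 0, 0))

  # separation: inverse-square repulsion
  expect_equal(separation_force(c(0, 0, 0), c(0, 0, 0),
                                rbind(c(1, 0, 0)), 1), c(-1, 0, 0))
  f <- separation_force(c(0, 0, 0), c(0, 0, 0),
                        rbind(c(1, 0, 0), c(0, 2, 0)), 1)
  expect_equal(f, c(-2, -1, 0) / sqrt(5), tolerance = 1e-12)
  expect_error(separation_force(c(0, 0, 0), c(0, 0, 0),
                                rbind(c(0, 0, 0)), 1), "degenerate")

  # internal forces
  fi <- internal_forces(c(0, 0, 0), 1)
  expect_equal(fi$friction, c(0, 0, 0))
  expect_equal(fi$speed_control, c(0, 0, 0))
  expect_equal(internal_forces(c(2, 0, 0), 1)$friction, c(-2, 0, 0))
  expect_equal(internal_forces(c(1, 0, 0), 1)$speed_control, c(0, 0, 0))
})

test_that("an isolated fish at rest stays at rest", {
  cfg <- sim_config(n_fish = 1, seed = 4)
  tr <- run_simulation(cfg, 10)
  expect_true(all(tr$velocity == 0))
  expect_true(all(tr$position == tr$position[, , 1]))
})

test_that("compiled and reference engines produce the same trajectories", {
  cfg <- sim_config(n_fish = 12, seed = 42)
  a <- run_simulation(cfg, 30, engine = "cpp")
  b <- run_simulation(cfg, 30, engine = "r")
  expect_equal(a$position, b$position, tolerance = 1e-12)
  expect_equal(a$velocity, b$velocity, tolerance = 1e-12)
  expect_identical(a$flashing, b$flashing)

  cfg2 <- sim_config(n_fish = 8, seed = 9, flash_mode = "square_wave")
  a2 <- run_simulation(cfg2, 25, engine = "cpp")
  b2 <- run_simulation(cfg2, 25, engine = "r")
  expect_equal(a2$position, b2$position, tolerance = 1e-12)
  expect_identical(a2$flashing, b2$flashing)
})

test_that("speed never exceeds v_max and runs are seed-deterministic", {
  cfg <- sim_config(n_fish = 40, seed = 7, v_max = 1.5)
  tr <- run_simulation(cfg, 150)
  speeds <- sqrt(apply(tr$velocity^2, c(1, 3), sum))
  expect_lte(max(speeds), cfg$v_max + 1e-12)

  tr2 <- run_simulation(cfg, 150)
  expect_identical(tr$position, tr2$position)
  expect_identical(tr$flashing, tr2$flashing)
})

test_that("dynamics are equivariant under rotation of the initial state", {
  cfg <- sim_config(n_fish = 15, P = 1, seed = 3)
  set.seed(31)
  st <- init_school(cfg)
  R <- rotation_matrix(pi / 5, pi / 7)
  str <- st
  str$position <- st$position %*% t(R)
  str$velocity <- st$velocity %*% t(R)
  a <- run_simulation(cfg, 40, state = st)
  b <- run_simulation(cfg, 40, state = str)
  for (t in c(10, 25, 41))
    expect_equal(b$position[, , t], a$position[, , t] %*% t(R),
                 tolerance = 1e-8)
})

test_that("a mirror-symmetric pair stays mirror-symmetric", {
  p <- c(1, 0.4, 0.2); v <- c(0.1, -0.2, 0.05)
  st <- make_state(rbind(p, -p), rbind(v, -v))
  cfg <- sim_config(n_fish = 2, P = 1, seed = 1)
  tr <- run_simulation(cfg, 50, state = st)
  expect_equal(tr$position[1, , ], -tr$position[2, , ], tolerance = 1e-12)
  expect_equal(tr$velocity[1, , ], -tr$velocity[2, , ], tolerance = 1e-12)
})

test_that("bernoulli flash edge cases and dark fish behave as defined", {
  cfg <- sim_config(n_fish = 30, P = 1, seed = 5)
  tr <- run_simulation(cfg, 10)
  expect_true(all(tr$flashing))
  cfg0 <- sim_config(n_fish = 30, P = 0, seed = 5)
  tr0 <- run_simulation(cfg0, 10)
  expect_false(any(tr0$flashing[, -1]))
  # dark fish never flash even with P = 1
  cfgd <- sim_config(n_fish = 30, P = 1, D = 1, seed = 5)
  trd <- run_simulation(cfgd, 10)
  expect_false(any(trd$flashing))
})

test_that("motivated fish move at the capped speed and are validated", {
  cfg <- sim_config(n_fish = 20, seed = 8)
  set.seed(8)
  st <- init_school(cfg)
  st2 <- set_motivated(st, 1:2, c(1, 0, 0), speed_factor = 100, cfg)
  expect_equal(sqrt(sum(st2$mot_vel[1, ]^2)), cfg$v_max)  # capped
  st3 <- set_motivated(st, 3, c(0, 1, 0), 1.5, cfg)
  expect_equal(st3$mot_vel[3, ], c(0, min(1.5 * cfg$v_cruise, cfg$v_max), 0))
  expect_error(set_motivated(st, 99, c(1, 0, 0), 1, cfg), "unknown")
  expect_error(set_motivated(st, integer(0), c(1, 0, 0), 1, cfg))
  std <- st; std$dark[4] <- TRUE
  expect_error(set_motivated(std, 4, c(1, 0, 0), 1, cfg), "dark")

  # all motivated -> identical velocities -> mSync 1 immediately
  iv <- list(list(frame = 2L, fn = function(state, config)
    set_motivated(state, 1:20, c(0, 0, 1), 1, config)))
  tr <- run_simulation(cfg, 5, interventions = iv)
  expect_equal(msync(tr$velocity[, , 4]), 1)
})

test_that("trajectories flatten to the agent-frame long table", {
  cfg <- sim_config(n_fish = 5, seed = 2)
  tr <- run_simulation(cfg, 4)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 5 * 5)
  expect_named(df, c("frame", "agent_id", "x", "y", "z", "vx", "vy", "vz",
                     "flashing", "dark", "motivated"))
  expect_equal(df$x[df$frame == 2], tr$position[, 1, 3])
})
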