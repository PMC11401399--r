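test_that("fully surrounded cancer cells are quiescent and skip cycle progression", {
  cfg <- abm_config(
    dynamics = frozen_dynamics(),
    recruitment = no_recruitment()
  )
  xs <- rep(9:11, each = 3)
  ys <- rep(9:11, 3)
  set.seed(1)
  st <- state_at(xs, ys, "C", cfg, div_length = 1e6, cycle_position = 0)
  st <- advance_timestep(st, cfg)
  a <- st$agents
  center <- a$x == 10 & a$y == 10
  expect_equal(a$cycle_position[center], 0) # no vacant Moore node
  expect_true(all(a$cycle_position[!center] == 1)) # boundary cells progress
  expect_true(a$quiescent_prev[center])
  expect_false(any(a$quiescent_prev[!center]))
})

test_that("mitosis places a daughter in a vacant Moore node and resets the parent", {
  cfg <- abm_config(dynamics = frozen_dynamics(), recruitment = no_recruitment())
  set.seed(2)
  st <- state_at(10, 10, "C", cfg, div_length = 24, cycle_position = 24)
  st <- advance_timestep(st, cfg)
  a <- st$agents
  expect_equal(nrow(a), 2L)
  expect_equal(st$ledger$c_mitosis, 1L)
  parent <- a$x == 10 & a$y == 10
  expect_equal(a$cycle_position[parent], 0)
  daughter <- a[!parent, ]
  expect_lte(max(abs(daughter$x - 10), abs(daughter$y - 10)), 1)
  expect_true(daughter$div_length >= 18 && daughter$div_length <= 30)
  expect_equal(daughter$cycle_position, 0)
})

test_that("spontaneous apoptosis frees the node and is ledgered immediately", {
  cfg <- abm_config(
    dynamics = frozen_dynamics(p_a = 1),
    recruitment = no_recruitment()
  )
  set.seed(3)
  st <- state_at(c(5, 20, 40), c(5, 20, 40), "C", cfg, div_length = 1e6)
  st <- advance_timestep(st, cfg)
  expect_equal(nrow(st$agents), 0L)
  expect_equal(st$ledger$c_apoptosis, 3L)
})

test_that("doomed cancer agents are removed at their death time as radiation deaths", {
  cfg <- abm_config(dynamics = frozen_dynamics(), recruitment = no_recruitment())
  set.seed(4)
  st <- state_at(10, 10, "C", cfg, div_length = 1e6)
  st$agents$doomed <- TRUE
  st$agents$death_time <- 2
  st1 <- advance_timestep(st, cfg)
  expect_equal(nrow(st1$agents), 1L) # hour 1 < death_time
  st2 <- advance_timestep(st1, cfg)
  expect_equal(nrow(st2$agents), 0L)
  expect_equal(st2$ledger$c_tx, 1L)
  expect_equal(st2$ledger$c_apoptosis, 0L)
})

test_that("cancer lifetimes under pure apoptosis are geometric with mean 1/p_a", {
  p_a <- 0.05
  cfg <- abm_config(
    domain = lattice_domain(68, 51),
    dynamics = frozen_dynamics(p_a = p_a),
    recruitment = no_recruitment()
  )
  g <- expand.grid(x = 0:67, y = 0:50)
  set.seed(5)
  st <- state_at(g$x, g$y, "C", cfg, div_length = 1e9)
  res <- run_sim(st, cfg, 400)
  tr <- res$trajectory
  n <- sum(tr$deaths_apoptosis)
  expect_gte(n, 3400) # essentially everyone dies within 400 h
  lifetimes <- rep(tr$hour, tr$deaths_apoptosis)
  se <- sd(lifetimes) / sqrt(n)
  expect_lt(abs(mean(lifetimes) - 1 / p_a), 3 * se)
})

test_that("per-timestep displacement respects the sub-move budgets", {
  cfg <- abm_config(
    dynamics = dynamics_params(p_a = 0, p_m = 1),
    recruitment = no_recruitment()
  )
  set.seed(6)
  st <- state_at(34, 25, "C", cfg, div_length = 1e6)
  for (k in 1:10) {
    prev <- c(st$agents$x, st$agents$y)
    st <- advance_timestep(st, cfg)
    moved <- max(abs(st$agents$x - prev[1]), abs(st$agents$y - prev[2]))
    expect_lte(moved, 6)
  }

  # a lone effector has no targets and random-walks up to 15 nodes
  st <- new_abm_state(data.frame(x = 34, y = 25, class = "E"), cfg)
  for (k in 1:10) {
    prev <- c(st$agents$x, st$agents$y)
    st <- advance_timestep(st, cfg)
    moved <- max(abs(st$agents$x - prev[1]), abs(st$agents$y - prev[2]))
    expect_lte(moved, 15)
  }
})

test_that("directed migration closes in on the target", {
  cfg <- abm_config(
    dynamics = dynamics_params(p_a = 0, p_m = 0, eta_directed = 1),
    recruitment = no_recruitment()
  )
  set.seed(7)
  cells <- data.frame(x = c(5, 50), y = c(25, 25), class = c("E", "C"))
  st <- new_abm_state(cells, cfg)
  st$agents$div_length[st$agents$class == "C"] <- 1e6
  d0 <- 45
  st <- advance_timestep(st, cfg)
  e <- st$agents[st$agents$class == "E", ]
  d1 <- sqrt((e$x - 50)^2 + (e$y - 25)^2)
  expect_lte(d1, d0 - 10) # 15 sub-moves, mostly toward the target
  expect_gte(d1, d0 - 15)
})

test_that("three hits in one timestep kill; fewer fully repair", {
  cfg <- abm_config(dynamics = frozen_dynamics(), recruitment = no_recruitment())
  set.seed(8)
  st3 <- state_at(
    c(10, 9, 11, 10), c(10, 10, 10, 9),
    c("C", "E", "E", "E"), cfg, div_length = 1e6
  )
  st3 <- advance_timestep(st3, cfg)
  expect_equal(sum(st3$agents$class == "C"), 0L)
  expect_equal(st3$ledger$c_effector, 1L)
  expect_true(all(st3$agents$hits_delivered == 1L))

  # two effectors per step never reach the three-hit threshold
  set.seed(9)
  st2 <- state_at(
    c(10, 9, 11), c(10, 10, 10),
    c("C", "E", "E"), cfg, div_length = 1e6
  )
  for (k in 1:5) st2 <- advance_timestep(st2, cfg)
  expect_equal(sum(st2$agents$class == "C"), 1L)
  expect_equal(st2$ledger$c_effector, 0L)
})

test_that("immune agents exhaust after ten lifetime hits", {
  cfg <- abm_config(dynamics = frozen_dynamics(), recruitment = no_recruitment())
  set.seed(10)
  st <- state_at(c(10, 9), c(10, 10), c("C", "E"), cfg, div_length = 1e6)
  for (k in 1:9) st <- advance_timestep(st, cfg)
  e <- st$agents[st$agents$class == "E", ]
  expect_equal(e$hits_delivered, 9L)
  st <- advance_timestep(st, cfg)
  expect_equal(sum(st$agents$class == "E"), 0L) # removed on the 10th hit
  expect_equal(sum(st$agents$class == "C"), 1L) # never got 3 hits in one step
})

test_that("regulatory agents kill effectors without touching the cancer ledger", {
  cfg <- abm_config(dynamics = frozen_dynamics(), recruitment = no_recruitment())
  set.seed(11)
  st <- state_at(
    c(10, 9, 11, 10), c(10, 10, 10, 9),
    c("E", "R", "R", "R"), cfg
  )
  st <- advance_timestep(st, cfg)
  expect_equal(sum(st$agents$class == "E"), 0L)
  expect_equal(sum(st$agents$class == "R"), 3L)
  expect_equal(st$ledger$c_effector, 0L)
  expect_equal(st$ledger$c_apoptosis, 0L)
})

test_that("doomed cancer killed by effectors first counts as an effector kill", {
  cfg <- abm_config(dynamics = frozen_dynamics(), recruitment = no_recruitment())
  set.seed(12)
  st <- state_at(
    c(10, 9, 11, 10), c(10, 10, 10, 9),
    c("C", "E", "E", "E"), cfg, div_length = 1e6
  )
  st$agents$doomed[st$agents$class == "C"] <- TRUE
  st$agents$death_time[st$agents$class == "C"] <- 100
  st <- advance_timestep(st, cfg)
  expect_equal(st$ledger$c_effector, 1L)
  expect_equal(st$ledger$c_tx, 0L)
})

test_that("deaths at one timestep recruit immune cells at the next", {
  cfg <- abm_config(
    dynamics = frozen_dynamics(p_a = 1),
    recruitment = no_recruitment(zeta_apoptosis = 1)
  )
  set.seed(13)
  st <- state_at(10, 10, "C", cfg, div_length = 1e6)
  st1 <- advance_timestep(st, cfg)
  expect_equal(unname(population_counts(st1)), c(0L, 0L, 0L)) # death, no recruit yet
  expect_equal(st1$ledger$c_apoptosis, 1L)
  st2 <- advance_timestep(st1, cfg)
  expect_equal(unname(population_counts(st2)["E"]), 1L)
})

test_that("unopposed tumors grow monotonically to lattice capacity", {
  dom <- lattice_domain(12, 12)
  cfg <- abm_config(
    domain = dom,
    dynamics = dynamics_params(p_a = 0, p_m = 0.9),
    recruitment = no_recruitment()
  )
  set.seed(14)
  st <- new_abm_state(data.frame(x = c(5, 6), y = c(5, 6), class = "C"), cfg)
  res <- run_sim(st, cfg, 600)
  tr <- res$trajectory
  expect_true(all(diff(tr$C) >= 0))
  expect_equal(tail(tr$C, 1), 144L)
  expect_equal(tr$E + tr$R, rep(0L, nrow(tr)))
})

test_that("occupancy and the death ledger stay conserved over long random runs", {
  sched <- make_schedule("WTRT", weeks = 2)
  for (seed in c(1, 2)) {
    cfg <- abm_config(recruitment = recruitment_rates(zeta_tx = 0.1))
    slide <- generate_synthetic_slide(400, 80, 40, clustering = 0.5, seed = seed)
    init <- build_initial_state(slide)
    set.seed(seed + 100)
    st0 <- new_abm_state(init, cfg)
    c0 <- population_counts(st0)[["C"]]
    res <- run_sim(st0, cfg, 500, sched)
    tr <- res$trajectory
    expect_valid_occupancy(res$state)
    fin <- population_counts(res$state)
    last <- tail(as.data.frame(tr), 1)
    expect_equal(unname(fin), c(last$C, last$E, last$R))
    deaths <- sum(tr$deaths_apoptosis + tr$deaths_effector + tr$deaths_radiation)
    expect_equal(fin[["C"]], c0 + sum(tr$mitoses) - deaths)
  }
})

test_that("simulations replay exactly under a fixed seed", {
  slide <- generate_synthetic_slide(200, 40, 20, clustering = 0.5, seed = 3)
  init <- build_initial_state(slide)
  cfg <- abm_config(recruitment = recruitment_rates(zeta_tx = 0.01))
  sched <- make_schedule("WTRT", weeks = 1)
  runs <- lapply(1:2, function(i) {
    set.seed(321)
    run_sim(new_abm_state(init, cfg), cfg, 300, sched)
  })
  expect_identical(
    as.data.frame(runs[[1]]$trajectory),
    as.data.frame(runs[[2]]$trajectory)
  )
  expect_identical(runs[[1]]$state$agents, runs[[2]]$state$agents)
})

test_that("direction vectors mix random and directed components as specified", {
  expect_equal(direction_vector(c(0, 0), c(3, 4), eta_directed = 1), c(0.6, 0.8))
  expect_equal(
    direction_vector(c(0, 0), c(3, 4), eta_directed = 0.19, v = c(1, 0)),
    c(0.81 * 1 + 0.19 * 0.6, 0.19 * 0.8)
  )
  set.seed(15)
  w <- direction_vector(c(2, 2), c(9, 9), eta_directed = 0)
  expect_equal(sqrt(sum(w^2)), 1) # pure random unit vector
  expect_error(direction_vector(c(1, 1), c(1, 1)), "coincide")
})
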