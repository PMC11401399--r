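test_that("LQ calibration solves SF(2 Gy) exactly given the alpha/beta ratio", {
  ab <- calibrate_lq(0.49, 10)
  expect_equal(ab[["beta"]], -log(0.49) / 24, tolerance = 1e-12)
  expect_equal(ab[["alpha"]], 10 * ab[["beta"]], tolerance = 1e-12)
  expect_equal(exp(-(2 * ab[["alpha"]] + 4 * ab[["beta"]])), 0.49, tolerance = 1e-9)

  ab1 <- calibrate_lq(1, 5)
  expect_equal(unname(ab1), c(0, 0))

  expect_error(calibrate_lq(1.2, 10), "\\(0, 1\\]")
  expect_error(calibrate_lq(0, 10), "\\(0, 1\\]")
  expect_error(calibrate_lq(0.5, -1), "positive")
})

test_that("survival probabilities honor calibration and quiescent dose scaling", {
  par <- radiosensitivity_params()
  expect_equal(survival_probability(0, par, "C"), 1)
  expect_equal(survival_probability(2, par, "C", cycling = TRUE), 0.49, tolerance = 1e-9)
  expect_equal(survival_probability(2, par, "E"), 0.60, tolerance = 1e-9)
  expect_equal(survival_probability(2, par, "R"), 0.77, tolerance = 1e-9)

  # quiescent cells see d / 3
  expect_equal(
    survival_probability(2, par, "C", cycling = FALSE),
    survival_probability(2 / 3, par, "C", cycling = TRUE),
    tolerance = 1e-12
  )
  for (d in c(0.5, 1, 2, 5, 10)) {
    expect_gt(
      survival_probability(d, par, "C", cycling = FALSE),
      survival_probability(d, par, "C", cycling = TRUE)
    )
  }
  expect_error(survival_probability(-1, par, "C"), "non-negative")
})

test_that("Monte-Carlo survival matches the closed form", {
  par <- radiosensitivity_params()
  set.seed(41)
  n <- 2e4
  for (case in list(list("C", TRUE), list("C", FALSE), list("R", TRUE))) {
    sf <- survival_probability(2, par, case[[1]], case[[2]])
    phat <- mean(simulate_survival(n, 2, par, case[[1]], case[[2]]))
    expect_lt(abs(phat - sf), 4 * sqrt(sf * (1 - sf) / n))
  }
})

test_that("GRID dose maps are binary peak/valley with the derived opening size", {
  dom <- lattice_domain()
  geom <- grid_geometry(center_spacing = 30)
  dm <- build_grid_dose_map(geom, peak_dose = 2, dom)
  expect_setequal(unique(as.numeric(dm)), c(2, 0.3))
  expect_true(attr(dm, "open_fraction") > 0 && attr(dm, "open_fraction") < 1)
  expect_equal(mean(dm == 2), attr(dm, "open_fraction"))

  # a fully interior opening covers 97 nodes (brute-force disk count)
  big <- lattice_domain(61, 61)
  one <- build_grid_dose_map(
    grid_geometry(opening_diameter = 11, center_spacing = 100), 2, big
  )
  expect_equal(sum(one == 2), 97L)

  # degenerate valley fraction gives a uniform (whole-tumor) map
  uni <- build_grid_dose_map(grid_geometry(valley_fraction = 1), 2, dom)
  expect_equal(as.numeric(uni), rep(2, 68 * 51), ignore_attr = TRUE)
  expect_equal(unclass(uni)[, ], build_wtrt_dose_map(2, dom)[, ], ignore_attr = TRUE)

  expect_error(grid_geometry(opening_diameter = 30, center_spacing = 30), "merge")
})

test_that("GRID maps repeat with the center-spacing period away from boundaries", {
  dom <- lattice_domain(68, 51)
  geom <- grid_geometry(center_spacing = 30)
  dm <- build_grid_dose_map(geom, 2, dom)
  inner_x <- 1:(68 - 30)
  inner_y <- 1:(51 - 30)
  expect_equal(dm[inner_x, inner_y], dm[inner_x + 30, inner_y], ignore_attr = TRUE)
  expect_equal(dm[inner_x, inner_y], dm[inner_x, inner_y + 30], ignore_attr = TRUE)
})

test_that("mean dose agrees between the open-fraction formula and map averaging", {
  expect_equal(mean_dose(0.30, 2, 0.15), 0.81)
  expect_equal(mean_dose(0.50, 2, 0.15), 1.15)
  expect_equal(mean_dose(1, 2, 0.15), 2)

  dm <- build_grid_dose_map(grid_geometry(center_spacing = 30), 2, lattice_domain())
  f <- attr(dm, "open_fraction")
  expect_equal(mean_dose(dm), mean_dose(f, 2, 0.15), tolerance = 1e-12)
  expect_error(mean_dose(1.2), "\\[0, 1\\]")
})

test_that("weekday schedules deliver the prescribed fractionation", {
  s <- make_schedule("WTRT", weeks = 7, peak_dose = 2)
  expect_equal(nrow(s$fractions), 35L)
  expect_equal(s$total_dose, 70)
  expect_true(all(diff(s$fractions$hour) > 0))
  # 5-on / 2-off weekday pattern
  days <- (s$fractions$hour %/% 24) %% 7
  expect_true(all(days %in% 0:4))

  expect_equal(nrow(make_schedule("WTRT", weeks = 1)$fractions), 5L)
  expect_equal(nrow(make_schedule("WTRT", weeks = 0)$fractions), 0L)

  abl <- make_schedule("custom", custom = data.frame(hour = 0, dose = 15))
  expect_equal(abl$fractions$peak_dose, 15)
  expect_equal(abl$total_dose, 15)
  expect_error(
    make_schedule("custom", custom = data.frame(hour = 0, dose = -1)),
    "negative"
  )

  g30 <- make_schedule("GRID30", weeks = 7)
  expect_equal(nrow(g30$fractions), 35L)
  expect_setequal(unique(as.numeric(g30$dose_map)), c(1, 0.15))
})

test_that("apply_fraction lengthens survivor cycles and dooms casualties", {
  dom <- lattice_domain()
  # guaranteed survival: SF(2) = 1
  par_live <- radiosensitivity_params(sf2 = c(C = 1, E = 1, R = 1))
  cfg <- abm_config(dynamics = frozen_dynamics(), recruitment = no_recruitment())
  set.seed(61)
  st <- state_at(c(10, 20), c(10, 20), "C", cfg, div_length = 24)
  st2 <- apply_fraction(st, build_wtrt_dose_map(2, dom), par_live)
  expect_equal(st2$agents$div_length, c(28, 28)) # +2 h/Gy x 2 Gy
  expect_false(any(st2$agents$doomed))

  # quiescent survivors are not cycle-lengthened
  st$agents$quiescent_prev <- TRUE
  st3 <- apply_fraction(st, build_wtrt_dose_map(2, dom), par_live)
  expect_equal(st3$agents$div_length, c(24, 24))

  # guaranteed kill: SF(2) ~ 0 -> doomed with the 8 h delay, removed later
  par_kill <- radiosensitivity_params(sf2 = c(C = 1e-12, E = 1e-12, R = 1e-12))
  cfg_kill <- abm_config(
    dynamics = frozen_dynamics(), recruitment = no_recruitment(),
    radiation = par_kill
  )
  sched <- make_schedule("custom", custom = data.frame(hour = 1, dose = 2))
  set.seed(62)
  st <- state_at(10, 10, "C", cfg_kill, div_length = 1e6)
  res <- run_sim(st, cfg_kill, 12, sched)
  tr <- res$trajectory
  expect_equal(tr$C[tr$hour == 8], 1L) # still occupying its node
  expect_equal(tr$C[tr$hour == 9], 0L) # removed at +8 h
  expect_equal(tr$deaths_radiation[tr$hour == 9], 1L)
  expect_true(is_cleared(res$trajectory))
})

test_that("lethally irradiated immune agents are removed after the same delay", {
  par_kill <- radiosensitivity_params(sf2 = c(C = 1, E = 1e-12, R = 1e-12))
  cfg <- abm_config(
    dynamics = frozen_dynamics(), recruitment = no_recruitment(),
    radiation = par_kill
  )
  sched <- make_schedule("custom", custom = data.frame(hour = 1, dose = 2))
  set.seed(63)
  st <- state_at(c(10, 20), c(10, 20), c("C", "E"), cfg, div_length = 1e6)
  res <- run_sim(st, cfg, 12, sched)
  tr <- res$trajectory
  expect_equal(tr$E[tr$hour == 8], 1L)
  expect_equal(tr$E[tr$hour == 9], 0L)
  # immune removal is not a cancer death
  expect_equal(sum(tr$deaths_radiation), 0L)
  expect_equal(tr$C[tr$hour == 12], 1L) # cancer survived (SF_C = 1)
})

test_that("a uniform 2 Gy fraction kills the calibrated fraction of a large cohort", {
  dom <- lattice_domain(110, 100)
  cfg <- abm_config(domain = dom)
  g <- expand.grid(x = 0:109, y = 0:99)
  set.seed(64)
  st <- new_abm_state(data.frame(x = g$x, y = g$y, class = "C"), cfg)
  n <- nrow(st$agents)

  cycling <- apply_fraction(st, build_wtrt_dose_map(2, dom), cfg$radiation)
  p <- mean(!cycling$agents$doomed)
  expect_lt(abs(p - 0.49), 4 * sqrt(0.49 * 0.51 / n))

  st$agents$quiescent_prev <- TRUE
  quiescent <- apply_fraction(st, build_wtrt_dose_map(2, dom), cfg$radiation)
  sf_q <- survival_probability(2, cfg$radiation, "C", cycling = FALSE)
  p_q <- mean(!quiescent$agents$doomed)
  expect_lt(abs(p_q - sf_q), 4 * sqrt(sf_q * (1 - sf_q) / n))
  expect_gt(p_q, p)
})

test_that("dose maps and schedules export to plain text", {
  dm <- build_grid_dose_map(grid_geometry(), 2, lattice_domain())
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_map(dm, path)
  back <- as.matrix(utils::read.table(path, sep = ","))
  expect_equal(dim(back), c(51L, 68L)) # height rows x width columns
  expect_equal(unname(back[1, 1]), dm[1, 1])

  sp <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(make_schedule("WTRT", weeks = 1), sp)
  sched <- utils::read.table(sp, header = TRUE, sep = "\t")
  expect_equal(nrow(sched), 5L)
  expect_equal(sum(sched$peak_dose), 10)
})
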