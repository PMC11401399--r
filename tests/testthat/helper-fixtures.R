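# Shared fixtures: tiny in-code cell tables and states.

# A cell table with boxes centered at the given micrometre coordinates.
cell_table_at <- function(cx, cy, phenotype = "PCK+", half = 10) {
  data.frame(
    x_min = cx - half, x_max = cx + half,
    y_min = cy - half, y_max = cy + half,
    phenotype = rep_len(phenotype, length(cx)),
    stringsAsFactors = FALSE
  )
}

write_csv_fixture <- function(df, names = c("XMin", "XMax", "YMin", "YMax", "Phenotype")) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  colnames(df) <- names
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A state built directly from explicit node coordinates and classes.
state_at <- function(x, y, class, config = abm_config(),
                     div_length = 24, cycle_position = 0) {
  cells <- data.frame(x = x, y = y, class = class, stringsAsFactors = FALSE)
  st <- new_abm_state(cells, config)
  st$agents$div_length[st$agents$class == "C"] <- div_length
  st$agents$cycle_position[st$agents$class == "C"] <- cycle_position
  st
}

# Parameters that freeze all motion and spontaneous death.
frozen_dynamics <- function(...) {
  args <- list(
    p_a = 0, p_m = 0, cancer_submoves = 0L, immune_submoves = 0L,
    hits_to_kill = 3L, max_hits = 10L
  )
  args[names(list(...))] <- list(...)
  do.call(dynamics_params, args)
}

no_recruitment <- function(...) {
  args <- list(
    zeta_apoptosis = 0, zeta_effector = 0, mu = 0,
    zeta_regulatory = 0, zeta_tx = 0
  )
  args[names(list(...))] <- list(...)
  do.call(recruitment_rates, args)
}

# Occupied-node bookkeeping check: every agent on a unique in-bounds node.
expect_valid_occupancy <- function(state) {
  a <- state$agents
  expect_true(all(a$x >= 0 & a$x < state$dom$width))
  expect_true(all(a$y >= 0 & a$y < state$dom$height))
  expect_equal(anyDuplicated(a$x + state$dom$width * a$y), 0L)
}
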