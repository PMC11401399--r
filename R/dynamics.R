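#' Motion and interaction parameters
#'
#' Per-timestep behavioral parameters of the agents. Defaults follow the
#' model's stated rates: cancer apoptosis probability `p_a = 3e-3` per
#' hour (mean lifespan ~14 days), migration probability `p_m = 0.9` per
#' hour with up to 6 single-node sub-moves (2.3 um/min at 20 um nodes),
#' immune cells performing 15 sub-moves per hour (5 um/min) with directed
#' weight `eta_directed = 0.19` toward the nearest target within a
#' 50-node search radius, and the multi-hit interaction rule: 3 hits
#' within one timestep kill a target, each immune cell delivers at most
#' one hit per timestep and is exhausted (removed) after 10 lifetime
#' hits.
#'
#' @param p_a Cancer apoptosis probability per timestep.
#' @param p_m Cancer migration probability per timestep (one draw enables
#'   the whole sub-move walk).
#' @param cancer_submoves,immune_submoves Sub-move budgets per timestep.
#' @param eta_directed Directed-motion weight in `[0, 1]`;
#'   `eta_rnd = 1 - eta_directed`.
#' @param search_radius Immune target-search radius, nodes.
#' @param hits_to_kill Hits required within a single timestep to kill a
#'   target.
#' @param max_hits Lifetime hit budget of an immune cell before
#'   exhaustion.
#' @return Object of class `dynamics_params`.
#' @export
dynamics_params <- function(p_a = 3e-3, p_m = 0.9,
                            cancer_submoves = 6L, immune_submoves = 15L,
                            eta_directed = 0.19, search_radius = 50,
                            hits_to_kill = 3L, max_hits = 10L) {
  stopifnot(
    p_a >= 0, p_a <= 1, p_m >= 0, p_m <= 1,
    cancer_submoves >= 0, immune_submoves >= 0,
    eta_directed >= 0, eta_directed <= 1, search_radius > 0,
    hits_to_kill >= 1, max_hits >= 1
  )
  structure(
    list(
      p_a = p_a, p_m = p_m,
      cancer_submoves = as.integer(cancer_submoves),
      immune_submoves = as.integer(immune_submoves),
      eta_directed = eta_directed, search_radius = search_radius,
      hits_to_kill = as.integer(hits_to_kill),
      max_hits = as.integer(max_hits)
    ),
    class = "dynamics_params"
  )
}

#' Cancer cell-cycle initialization parameters
#'
#' Cell-cycle lengths are drawn from a normal distribution centered on
#' 24 h, truncated to `[div_min, div_max]`; at initialization each cancer
#' agent's position in its cycle is drawn uniformly on
#' `[0, div_length / 2]`. Daughters created by mitosis draw a fresh cycle
#' length and start at position 0.
#'
#' @param div_mean Mean cycle length, hours (default 24).
#' @param div_sd Standard deviation, hours (default 2).
#' @param div_min,div_max Truncation bounds, hours (default 18, 30).
#' @return Object of class `init_params`.
#' @export
init_params <- function(div_mean = 24, div_sd = 2, div_min = 18, div_max = 30) {
  stopifnot(div_sd >= 0, div_min > 0, div_min <= div_mean, div_mean <= div_max)
  structure(
    list(div_mean = div_mean, div_sd = div_sd, div_min = div_min, div_max = div_max),
    class = "init_params"
  )
}

#' Full simulation configuration
#'
#' Bundles all parameter blocks of the model. The timestep is fixed at
#' 1 hour.
#'
#' @param domain A [lattice_domain()].
#' @param dynamics A [dynamics_params()].
#' @param recruitment A [recruitment_rates()].
#' @param radiation A [radiosensitivity_params()].
#' @param init An [init_params()].
#' @return Object of class `abm_config`.
#' @export
abm_config <- function(domain = lattice_domain(),
                       dynamics = dynamics_params(),
                       recruitment = recruitment_rates(),
                       radiation = radiosensitivity_params(),
                       init = init_params()) {
  stopifnot(
    inherits(domain, "lattice_domain"),
    inherits(dynamics, "dynamics_params"),
    inherits(recruitment, "recruitment_rates"),
    inherits(radiation, "radiosensitivity_params"),
    inherits(init, "init_params")
  )
  structure(
    list(
      domain = domain, dynamics = dynamics, recruitment = recruitment,
      radiation = radiation, init = init
    ),
    class = "abm_config"
  )
}

cfg_to_cpp <- function(config) {
  d <- config$dynamics
  r <- config$recruitment
  x <- config$radiation
  list(
    width = config$domain$width, height = config$domain$height,
    p_a = d$p_a, p_m = d$p_m,
    cancer_submoves = d$cancer_submoves, immune_submoves = d$immune_submoves,
    eta_directed = d$eta_directed, search_radius = d$search_radius,
    hits_to_kill = d$hits_to_kill, max_hits = d$max_hits,
    div_mean = config$init$div_mean, div_sd = config$init$div_sd,
    div_min = config$init$div_min, div_max = config$init$div_max,
    zeta_apoptosis = r$zeta_apoptosis, zeta_effector = r$zeta_effector,
    mu = r$mu, zeta_regulatory = r$zeta_regulatory, zeta_tx = r$zeta_tx,
    recruit_radius = r$recruit_radius,
    alpha = unname(x$alpha[c("C", "E", "R")]),
    beta = unname(x$beta[c("C", "E", "R")]),
    xi_quiescent = x$xi_quiescent,
    cycle_delay = x$cycle_delay_h_per_gy,
    death_delay = x$death_delay_h
  )
}

empty_ledger <- function() {
  list(
    c_apoptosis = 0L, c_effector = 0L, c_tx = 0L, c_mitosis = 0L,
    kill_x = integer(0), kill_y = integer(0)
  )
}

class_codes <- c(cancer = "C", effector = "E", regulatory = "R", C = "C", E = "E", R = "R")

#' Build a simulation state from initial cell positions
#'
#' Creates the agent population: cancer agents sample a cycle length from
#' the truncated normal of `config$init` and a cycle position uniform on
#' `[0, div_length / 2]`; immune agents start with zero delivered hits.
#' Uses the current R RNG stream, so `set.seed()` beforehand makes state
#' construction reproducible.
#'
#' @param cells Either an `initial_state` from [build_initial_state()] or
#'   a data.frame with columns `x`, `y` (0-based node coordinates) and
#'   `class` (`"cancer"`/`"effector"`/`"regulatory"` or `"C"`/`"E"`/`"R"`).
#' @param config An [abm_config()].
#' @return Object of class `abm_state`: list with `agents` (data.frame),
#'   `hour` (0), `ledger` (last closed per-timestep death/mitosis
#'   counts), `accumulators` (fractional recruit carries),
#'   `discarded_recruits` and `dom`.
#' @export
new_abm_state <- function(cells, config = abm_config()) {
  if (inherits(cells, "initial_state")) cells <- cells$cells
  stopifnot(is.data.frame(cells), all(c("x", "y", "class") %in% names(cells)))
  dom <- config$domain
  klass <- unname(class_codes[as.character(cells$class)])
  if (any(is.na(klass))) stop("unknown agent class in `cells`", call. = FALSE)
  if (nrow(cells) > 0L) {
    if (any(cells$x < 0 | cells$x >= dom$width | cells$y < 0 | cells$y >= dom$height)) {
      stop("cell coordinates outside the domain", call. = FALSE)
    }
    if (anyDuplicated(cells$x + as.numeric(dom$width) * cells$y)) {
      stop("two cells share a lattice node", call. = FALSE)
    }
  }
  n <- nrow(cells)
  div <- rep(0, n)
  cyc <- rep(0, n)
  is_c <- klass == "C"
  if (any(is_c)) {
    div[is_c] <- rtrunc_normal(
      sum(is_c), config$init$div_mean, config$init$div_sd,
      config$init$div_min, config$init$div_max
    )
    cyc[is_c] <- stats::runif(sum(is_c), 0, div[is_c] / 2)
  }
  agents <- data.frame(
    x = as.integer(cells$x), y = as.integer(cells$y), class = klass,
    div_length = div, cycle_position = cyc,
    doomed = FALSE, death_time = 0,
    hits_delivered = 0L, quiescent_prev = FALSE,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      agents = agents, hour = 0L, ledger = empty_ledger(),
      accumulators = c(apoptosis = 0, effector = 0, tx = 0, regulatory = 0),
      discarded_recruits = 0L, dom = dom
    ),
    class = "abm_state"
  )
}

rtrunc_normal <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    v <- stats::rnorm(length(todo), mean, sd)
    ok <- v >= lo & v <= hi
    out[todo[ok]] <- v[ok]
    todo <- todo[!ok]
  }
  out
}

#' @export
print.abm_state <- function(x, ...) {
  k <- table(factor(x$agents$class, levels = c("C", "E", "R")))
  cat(sprintf(
    "<abm_state> hour %d: C=%d, E=%d, R=%d\n",
    x$hour, k[["C"]], k[["E"]], k[["R"]]
  ))
  invisible(x)
}

#' Per-class population counts of a state
#'
#' @param state An `abm_state`.
#' @return Named integer vector `c(C = , E = , R = )`.
#' @export
population_counts <- function(state) {
  k <- table(factor(state$agents$class, levels = c("C", "E", "R")))
  c(C = unname(k[["C"]]), E = unname(k[["E"]]), R = unname(k[["R"]]))
}

#' Integer-coded occupancy snapshot
#'
#' @param state An `abm_state`.
#' @return Integer `width x height` matrix: 0 = empty, 1 = cancer,
#'   2 = effector, 3 = regulatory.
#' @export
occupancy_matrix <- function(state) {
  m <- matrix(0L, state$dom$width, state$dom$height)
  code <- c(C = 1L, E = 2L, R = 3L)
  if (nrow(state$agents) > 0L) {
    m[cbind(state$agents$x + 1L, state$agents$y + 1L)] <- code[state$agents$class]
  }
  m
}

schedule_to_cpp <- function(schedule, dom) {
  if (is.null(schedule)) {
    return(list(
      hours = integer(0), scale = numeric(0),
      dose_map = matrix(0, dom$width, dom$height)
    ))
  }
  stopifnot(inherits(schedule, "treatment_schedule"))
  dm <- schedule$dose_map
  if (nrow(dm) != dom$width || ncol(dm) != dom$height) {
    stop("schedule dose map does not match the domain dimensions", call. = FALSE)
  }
  o <- order(schedule$fractions$hour)
  list(
    hours = as.integer(schedule$fractions$hour[o]),
    scale = as.numeric(schedule$fractions$peak_dose[o]),
    dose_map = dm
  )
}

agents_to_cpp <- function(agents) {
  code <- c(C = 1L, E = 2L, R = 3L)
  list(
    x = as.integer(agents$x), y = as.integer(agents$y),
    class = unname(code[agents$class]),
    div_length = as.numeric(agents$div_length),
    cycle_position = as.numeric(agents$cycle_position),
    doomed = as.logical(agents$doomed),
    death_time = as.numeric(agents$death_time),
    hits_delivered = as.integer(agents$hits_delivered),
    quiescent_prev = as.logical(agents$quiescent_prev)
  )
}

agents_from_cpp <- function(a) {
  lab <- c("C", "E", "R")
  data.frame(
    x = a$x, y = a$y, class = lab[a$class],
    div_length = a$div_length, cycle_position = a$cycle_position,
    doomed = a$doomed, death_time = a$death_time,
    hits_delivered = a$hits_delivered, quiescent_prev = a$quiescent_prev,
    stringsAsFactors = FALSE
  )
}

#' Run a simulation forward
#'
#' Advances a state hour by hour until `until_hour` or until the cancer
#' population is eradicated, whichever comes first. Each timestep runs
#' the fixed phase order: (1) place recruits computed from the previous
#' timestep's death/mitosis ledger; (2) apply a radiation fraction if one
#' is scheduled at this hour; (3) step every agent in a uniformly
#' shuffled order (cancer: delayed radiation death, apoptosis, cycle
#' progression/quiescence, mitosis, migration; immune: 15 directed
#' sub-moves then at most one hit); (4) resolve hits (3 hits within the
#' timestep kill; fewer fully repair); (5) close the ledger and record
#' populations.
#'
#' @param state An `abm_state`.
#' @param config An [abm_config()].
#' @param until_hour Absolute simulation hour to stop at.
#' @param schedule Optional [make_schedule()] treatment schedule.
#' @param record Record the per-hour trajectory (default `TRUE`).
#' @param stop_on_clearance Halt as soon as the cancer population reaches
#'   zero (default `TRUE`, the replicate semantics). With `FALSE` the
#'   simulation keeps stepping the immune populations to `until_hour`.
#' @return List of class `sim_result` with `state` (the advanced state)
#'   and `trajectory` (a data.frame of per-hour `C`, `E`, `R` counts and
#'   death/mitosis tallies, with attributes `cleared` and
#'   `clearance_hour`).
#' @export
run_sim <- function(state, config, until_hour, schedule = NULL, record = TRUE,
                    stop_on_clearance = TRUE) {
  stopifnot(inherits(state, "abm_state"), inherits(config, "abm_config"))
  if (until_hour < state$hour) stop("until_hour precedes the state's hour", call. = FALSE)
  sc <- schedule_to_cpp(schedule, state$dom)
  out <- cpp_run_sim(
    agents_to_cpp(state$agents), cfg_to_cpp(config), state$ledger,
    unname(state$accumulators), state$discarded_recruits,
    as.integer(state$hour), as.integer(until_hour),
    sc$dose_map, sc$hours, sc$scale, record, stop_on_clearance
  )
  new_state <- structure(
    list(
      agents = agents_from_cpp(out$agents),
      hour = out$hour,
      ledger = out$ledger,
      accumulators = c(
        apoptosis = out$accumulators[1], effector = out$accumulators[2],
        tx = out$accumulators[3], regulatory = out$accumulators[4]
      ),
      discarded_recruits = out$discarded_recruits,
      dom = state$dom
    ),
    class = "abm_state"
  )
  traj <- make_trajectory(
    out$trajectory,
    cleared = out$cleared,
    clearance_hour = if (out$cleared) out$clearance_hour else NA_integer_
  )
  structure(list(state = new_state, trajectory = traj), class = "sim_result")
}

#' Advance a state by one timestep
#'
#' Runs one hour of the simulation (all five phases). After the call,
#' `state$ledger` holds the death and mitosis counts of the completed
#' timestep, which drive recruitment at the next one.
#'
#' @inheritParams run_sim
#' @return The advanced `abm_state`.
#' @export
advance_timestep <- function(state, config, schedule = NULL) {
  run_sim(state, config, state$hour + 1L, schedule,
    record = FALSE,
    stop_on_clearance = FALSE
  )$state
}

#' Immune migration direction vector
#'
#' Combines a random unit vector `v` with the unit vector `u` pointing
#' from the immune cell `p` toward its chosen target `q`:
#' `w = (1 - eta_directed) * v + eta_directed * u`. With
#' `eta_directed = 0` motion is Brownian; with 1 it is purely directed.
#' The result is not re-normalized: only its direction is used to choose
#' the vacant Moore node minimizing the angle to `w`.
#'
#' @param p,q Length-2 coordinates with `p != q`.
#' @param eta_directed Directed weight (default 0.19).
#' @param v Optional forced random unit vector (for testing); when `NULL`
#'   a uniformly random direction is drawn from the R RNG.
#' @return Length-2 numeric vector `w`.
#' @export
direction_vector <- function(p, q, eta_directed = 0.19, v = NULL) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (all(p == q)) stop("p and q coincide: direction undefined", call. = FALSE)
  u <- (q - p) / sqrt(sum((q - p)^2))
  if (is.null(v)) {
    th <- stats::runif(1, 0, 2 * pi)
    v <- c(cos(th), sin(th))
  }
  (1 - eta_directed) * v + eta_directed * u
}
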