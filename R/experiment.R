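#' Construct a trajectory object
#'
#' A per-replicate record of the population dynamics: one row per
#' simulated hour with `C`, `E`, `R` counts, per-mechanism cancer death
#' counts and mitoses, plus clearance metadata as attributes.
#'
#' @param df Data.frame with columns `hour`, `C`, `E`, `R`,
#'   `deaths_apoptosis`, `deaths_effector`, `deaths_radiation`,
#'   `mitoses`.
#' @param cleared Logical: did the cancer population reach zero?
#' @param clearance_hour First hour at whose end `C = 0` (or `NA`).
#' @return The data.frame with class `abm_trajectory` and attributes
#'   `cleared`, `clearance_hour`.
#' @export
make_trajectory <- function(df, cleared, clearance_hour = NA_integer_) {
  need <- c(
    "hour", "C", "E", "R", "deaths_apoptosis", "deaths_effector",
    "deaths_radiation", "mitoses"
  )
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  structure(df,
    cleared = isTRUE(cleared),
    clearance_hour = as.integer(clearance_hour),
    class = c("abm_trajectory", "data.frame")
  )
}

#' Did a trajectory clear its tumor?
#'
#' @param trajectory An `abm_trajectory`.
#' @return Logical.
#' @export
is_cleared <- function(trajectory) {
  isTRUE(attr(trajectory, "cleared"))
}

#' Clearance hour of a trajectory
#'
#' @param trajectory An `abm_trajectory`.
#' @return Integer hour, or `NA` when the tumor was not eradicated.
#' @export
clearance_hour <- function(trajectory) {
  attr(trajectory, "clearance_hour")
}

#' Run seeded replicate simulations
#'
#' Runs independent replicates of the same initial condition and
#' configuration. Replicate `k` is seeded deterministically with
#' `base_seed + k`, which governs every stochastic choice in that
#' replicate (cycle-length sampling at initialization, agent shuffling,
#' migration, survival draws, recruit placement), so a rerun with the
#' same arguments reproduces all trajectories exactly. Each replicate
#' halts when the cancer population is eradicated or at `horizon` hours
#' (default 15 weeks = 2520 h), whichever comes first.
#'
#' @param cells Initial cell positions: an `initial_state` from
#'   [build_initial_state()] or a data.frame of `x`, `y`, `class`.
#' @param config An [abm_config()].
#' @param schedule Optional [make_schedule()] treatment schedule.
#' @param replicates Number of replicates (default 50).
#' @param base_seed Integer base seed (default 1).
#' @param horizon Simulation horizon in hours (default 2520).
#' @return List of `abm_trajectory` objects, length `replicates`.
#' @export
run_replicates <- function(cells, config = abm_config(), schedule = NULL,
                           replicates = 50L, base_seed = 1L, horizon = 2520L) {
  stopifnot(replicates >= 1, horizon > 0)
  lapply(seq_len(replicates), function(k) {
    set.seed(as.integer(base_seed) + k)
    state <- new_abm_state(cells, config)
    run_sim(state, config, horizon, schedule)$trajectory
  })
}

#' Tumor eradication probability
#'
#' Fraction of replicate simulations whose cancer population reached zero
#' by the end of the simulation: `TE = cleared replicates / replicates`.
#'
#' @param trajectories List of `abm_trajectory` objects.
#' @return Probability in `[0, 1]`.
#' @export
tumor_eradication_probability <- function(trajectories) {
  if (length(trajectories) == 0L) {
    stop("no trajectories supplied", call. = FALSE)
  }
  mean(vapply(trajectories, is_cleared, logical(1)))
}

#' Mechanism attribution over a pre-clearance window
#'
#' For a cleared trajectory, sums the cancer deaths by mechanism
#' (apoptosis, effector-mediated, radiation) over the window of the given
#' length ending at and including the clearance timestep (truncated at
#' hour 0 for early clearances), and labels the primary mechanism as the
#' argmax. Ties are reported, not silently broken. Windows of 168 h
#' (7 days) and 24 h (1 day) are the standard choices. Trajectories that
#' did not clear have no anchor and return `NA` totals (the
#' "non-responding" subset).
#'
#' @param trajectory An `abm_trajectory`.
#' @param window Window length in hours (> 0).
#' @return List with `totals` (named numeric: `apoptosis`, `effector`,
#'   `radiation`), `primary` (character label, or `NA` for an uncleared
#'   trajectory), and `tied` (logical).
#' @export
mechanism_attribution <- function(trajectory, window = 168) {
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("window must be a single positive number of hours", call. = FALSE)
  }
  if (!is_cleared(trajectory)) {
    return(list(
      totals = c(apoptosis = NA_real_, effector = NA_real_, radiation = NA_real_),
      primary = NA_character_, tied = NA
    ))
  }
  ch <- clearance_hour(trajectory)
  rows <- trajectory$hour > ch - window & trajectory$hour <= ch
  totals <- c(
    apoptosis = sum(trajectory$deaths_apoptosis[rows]),
    effector = sum(trajectory$deaths_effector[rows]),
    radiation = sum(trajectory$deaths_radiation[rows])
  )
  top <- which(totals == max(totals))
  list(
    totals = totals,
    primary = if (length(top) == 1L) names(totals)[top] else names(totals)[top][1],
    tied = length(top) > 1L
  )
}

#' Per-replicate mechanism attribution table
#'
#' Applies [mechanism_attribution()] to every cleared ("responding")
#' trajectory and returns the per-replicate window totals, suitable for
#' two-sided rank-sum comparisons between mechanisms.
#'
#' @param trajectories List of `abm_trajectory` objects.
#' @param window Window length in hours.
#' @return Data.frame with columns `replicate`, `apoptosis`, `effector`,
#'   `radiation`, `primary`, `tied`; one row per cleared trajectory.
#' @export
attribution_table <- function(trajectories, window = 168) {
  cleared <- which(vapply(trajectories, is_cleared, logical(1)))
  rows <- lapply(cleared, function(k) {
    a <- mechanism_attribution(trajectories[[k]], window)
    data.frame(
      replicate = k,
      apoptosis = a$totals[["apoptosis"]],
      effector = a$totals[["effector"]],
      radiation = a$totals[["radiation"]],
      primary = a$primary, tied = a$tied,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(
      replicate = integer(0), apoptosis = numeric(0), effector = numeric(0),
      radiation = numeric(0), primary = character(0), tied = logical(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Rank-sum comparison between two death mechanisms
#'
#' Two-sided Wilcoxon rank-sum test between the per-replicate window
#' totals of two mechanisms (e.g. radiation vs effector-mediated deaths
#' in the week before clearance).
#'
#' @param tbl Data.frame from [attribution_table()].
#' @param a,b Mechanism column names (`"apoptosis"`, `"effector"`,
#'   `"radiation"`).
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
mechanism_ranksum <- function(tbl, a = "radiation", b = "effector") {
  stopifnot(a %in% names(tbl), b %in% names(tbl))
  stats::wilcox.test(tbl[[a]], tbl[[b]], alternative = "two.sided", exact = NULL)
}

#' Latin Hypercube sample of recruitment parameter sets
#'
#' Draws `n_sets` parameter sets for the four immune recruitment
#' parameters by Latin Hypercube Sampling: for each parameter
#' independently, the `n_sets` values occupy the `n_sets` equal-width
#' strata of its range exactly once (uniform within stratum, random
#' permutation across sets). Deterministic for a fixed seed.
#'
#' @param n_sets Number of parameter sets (default 15).
#' @param bounds Named list of length-2 ranges for `zeta_apoptosis`,
#'   `zeta_effector`, `mu`, `zeta_regulatory` (defaults `[0, 1]` each).
#' @param seed Integer seed.
#' @return Data.frame with `n_sets` rows and one column per parameter.
#' @export
lhs_sample <- function(n_sets = 15L,
                       bounds = list(
                         zeta_apoptosis = c(0, 1), zeta_effector = c(0, 1),
                         mu = c(0, 1), zeta_regulatory = c(0, 1)
                       ),
                       seed = 1L) {
  stopifnot(n_sets >= 1)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop(sprintf("bounds for %s must be finite with lower < upper", nm),
        call. = FALSE
      )
    }
  }
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(as.integer(n_sets), length(bounds))
  out <- as.data.frame(mapply(function(col, b) b[1] + col * (b[2] - b[1]),
    asplit(u, 2), bounds,
    SIMPLIFY = FALSE
  ))
  names(out) <- names(bounds)
  out
}

#' Summarize replicate outcomes
#'
#' @param trajectories List of `abm_trajectory` objects.
#' @param windows Attribution window lengths in hours.
#' @return List with `TE`, `n_replicates`, `clearance_hours` (of cleared
#'   replicates) and one attribution table per window.
#' @export
summarize_outcomes <- function(trajectories, windows = c(168, 24)) {
  ch <- vapply(trajectories, clearance_hour, integer(1))
  list(
    TE = tumor_eradication_probability(trajectories),
    n_replicates = length(trajectories),
    clearance_hours = ch[!is.na(ch)],
    attribution = stats::setNames(
      lapply(windows, function(w) attribution_table(trajectories, w)),
      paste0("window_", windows, "h")
    )
  )
}

#' Write a trajectory as TSV
#'
#' @param trajectory An `abm_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Write an outcome summary as JSON
#'
#' @param summary List from [summarize_outcomes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_outcome_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
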