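#' Immune recruitment rates
#'
#' The four recruitment channels of the model plus the
#' radiation-immunogenicity channel. Cancer deaths and mitoses recorded
#' in the ledger at timestep `t` recruit immune cells at timestep
#' `t + 1`:
#' effectors at `zeta_apoptosis` per apoptotic cancer death, effectors at
#' `zeta_effector` per effector-mediated cancer death (placed near the
#' kill site with probability `mu`, the "postcode" homing assumption),
#' effectors at `zeta_tx` per radiation-induced cancer death
#' (0, 0.01 and 0.1 are the non-, low- and highly immunogenic scenarios),
#' and regulatory cells at `zeta_regulatory` per mitosis.
#'
#' The default rates are the package's reference parameter set, fixed
#' once by a coarse screen under the model's conceptual calibration:
#' untreated tumors must escape immune surveillance (clinically
#' detectable tumors have, by definition, evaded immunity) and
#' fractionated radiotherapy whose only effect is DNA damage must not
#' eradicate. Baseline effector seeding is weak (`zeta_apoptosis`
#' small), effector-kill amplification is strongly supercritical
#' (`zeta_effector` with full postcode homing, `mu = 1`), and regulatory
#' recruitment is modest. See the package vignette for the screening
#' rationale.
#'
#' @param zeta_apoptosis Effectors recruited per apoptotic cancer death.
#' @param zeta_effector Effectors recruited per effector-kill.
#' @param mu Probability that an effector-kill recruit is placed within
#'   `recruit_radius` of a kill location from the previous timestep.
#' @param zeta_regulatory Regulatory cells recruited per mitosis.
#' @param zeta_tx Effectors recruited per radiation-induced cancer death.
#' @param recruit_radius Postcode placement radius, nodes (default 10).
#' @return Object of class `recruitment_rates`.
#' @export
recruitment_rates <- function(zeta_apoptosis = 0.01, zeta_effector = 8,
                              mu = 1, zeta_regulatory = 0.1,
                              zeta_tx = 0, recruit_radius = 10) {
  stopifnot(
    zeta_apoptosis >= 0, zeta_effector >= 0, zeta_regulatory >= 0,
    zeta_tx >= 0, mu >= 0, mu <= 1, recruit_radius > 0
  )
  structure(
    list(
      zeta_apoptosis = zeta_apoptosis, zeta_effector = zeta_effector,
      mu = mu, zeta_regulatory = zeta_regulatory, zeta_tx = zeta_tx,
      recruit_radius = recruit_radius
    ),
    class = "recruitment_rates"
  )
}

#' Compute recruit counts from a closed ledger
#'
#' Converts the previous timestep's death and mitosis counts into integer
#' recruit counts per channel using a floor-with-carry rule: per channel,
#' `raw = rate * count + accumulator`, `recruits = floor(raw)`, and the
#' fractional remainder is carried to the next timestep. The carry
#' guarantees that over any horizon the total number of recruits per
#' channel differs from `rate * total deaths` by less than one.
#'
#' @param ledger A closed per-timestep ledger (list with `c_apoptosis`,
#'   `c_effector`, `c_tx`, `c_mitosis`), e.g. `state$ledger` after
#'   [advance_timestep()].
#' @param rates A [recruitment_rates()].
#' @param accumulators Named numeric vector of fractional carries
#'   (`apoptosis`, `effector`, `tx`, `regulatory`), each in `[0, 1)`.
#' @return List with `counts` (named integer vector per channel) and the
#'   updated `accumulators`.
#' @examples
#' led <- list(c_apoptosis = 7L, c_effector = 0L, c_tx = 10L, c_mitosis = 0L)
#' compute_recruits(led, recruitment_rates(zeta_apoptosis = 0.5, zeta_tx = 0.1))
#' @export
compute_recruits <- function(ledger, rates,
                             accumulators = c(
                               apoptosis = 0, effector = 0,
                               tx = 0, regulatory = 0
                             )) {
  stopifnot(inherits(rates, "recruitment_rates"))
  take <- function(rate, count, acc) {
    raw <- rate * count + acc
    n <- floor(raw)
    c(n = n, acc = raw - n)
  }
  a <- take(rates$zeta_apoptosis, ledger$c_apoptosis, accumulators[["apoptosis"]])
  e <- take(rates$zeta_effector, ledger$c_effector, accumulators[["effector"]])
  t <- take(rates$zeta_tx, ledger$c_tx, accumulators[["tx"]])
  r <- take(rates$zeta_regulatory, ledger$c_mitosis, accumulators[["regulatory"]])
  list(
    counts = c(
      apoptosis = as.integer(a[["n"]]), effector = as.integer(e[["n"]]),
      tx = as.integer(t[["n"]]), regulatory = as.integer(r[["n"]])
    ),
    accumulators = c(
      apoptosis = a[["acc"]], effector = e[["acc"]],
      tx = t[["acc"]], regulatory = r[["acc"]]
    )
  )
}

#' Place newly recruited immune agents
#'
#' Apoptosis- and radiation-recruited effectors and all regulatory
#' recruits are placed on uniformly random vacant nodes anywhere in the
#' domain (uniform distribution of blood vessels). Each
#' effector-kill-recruited agent is, with probability `mu`, placed on a
#' uniformly random vacant node within `recruit_radius` of a uniformly
#' chosen kill location from the previous timestep (falling back to
#' global placement when that disk has no vacancy), and otherwise placed
#' globally at random. Recruits that find no vacant node anywhere are
#' discarded and counted in `state$discarded_recruits`.
#'
#' @param state An `abm_state`.
#' @param counts Named integer vector from [compute_recruits()]
#'   (`apoptosis`, `effector`, `tx`, `regulatory`).
#' @param kill_locations Integer matrix with columns `x`, `y`: locations
#'   of effector-kill events in the previous timestep (possibly 0 rows).
#' @param rates A [recruitment_rates()] (supplies `mu` and
#'   `recruit_radius`).
#' @return The updated `abm_state`.
#' @export
place_recruits <- function(state, counts, kill_locations, rates) {
  stopifnot(inherits(state, "abm_state"), inherits(rates, "recruitment_rates"))
  dom <- state$dom
  occ <- matrix(FALSE, dom$width, dom$height)
  if (nrow(state$agents) > 0L) {
    occ[cbind(state$agents$x + 1L, state$agents$y + 1L)] <- TRUE
  }
  new_x <- integer(0)
  new_y <- integer(0)
  new_class <- character(0)

  place_global <- function() {
    vac <- which(!occ)
    if (length(vac) == 0L) {
      return(NULL)
    }
    n <- vac[sample.int(length(vac), 1L)]
    c((n - 1L) %% dom$width, (n - 1L) %/% dom$width)
  }
  place_postcode <- function() {
    if (nrow(kill_locations) > 0L && stats::runif(1) < rates$mu) {
      k <- kill_locations[sample.int(nrow(kill_locations), 1L), ]
      disk <- nodes_within_radius(c(k[1], k[2]), rates$recruit_radius, dom)
      disk <- rbind(disk, matrix(c(k[1], k[2]), 1, 2)) # the kill site itself
      vac <- disk[!occ[cbind(disk[, 1] + 1L, disk[, 2] + 1L)], , drop = FALSE]
      if (nrow(vac) > 0L) {
        return(vac[sample.int(nrow(vac), 1L), ])
      }
    }
    place_global()
  }
  add <- function(pos, klass) {
    if (is.null(pos)) {
      state$discarded_recruits <<- state$discarded_recruits + 1L
      return(invisible(NULL))
    }
    occ[pos[1] + 1L, pos[2] + 1L] <<- TRUE
    new_x <<- c(new_x, pos[1])
    new_y <<- c(new_y, pos[2])
    new_class <<- c(new_class, klass)
  }

  for (k in seq_len(counts[["apoptosis"]])) add(place_global(), "E")
  for (k in seq_len(counts[["effector"]])) add(place_postcode(), "E")
  for (k in seq_len(counts[["tx"]])) add(place_global(), "E")
  for (k in seq_len(counts[["regulatory"]])) add(place_global(), "R")

  if (length(new_x) > 0L) {
    state$agents <- rbind(state$agents, data.frame(
      x = as.integer(new_x), y = as.integer(new_y), class = new_class,
      div_length = 0, cycle_position = 0,
      doomed = FALSE, death_time = 0,
      hits_delivered = 0L, quiescent_prev = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  state
}
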