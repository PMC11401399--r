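#' Calibrate linear-quadratic parameters from survival at 2 Gy
#'
#' Solves for `(alpha, beta)` of the LQ survival model
#' `SF(d) = exp(-alpha d - beta d^2)` such that `SF(2 Gy)` equals a
#' calibration target, given the `alpha/beta` ratio. The linear system is
#' `2 alpha + 4 beta = -log(sf)` with `alpha = ratio * beta`.
#'
#' @param sf_at_2gy Surviving fraction at 2 Gy, in `(0, 1]`.
#' @param alpha_beta_ratio The alpha/beta ratio in Gy (> 0).
#' @return Named numeric vector `c(alpha = , beta = )` in 1/Gy and 1/Gy^2.
#' @examples
#' calibrate_lq(0.49, 10) # beta = -log(0.49)/24, alpha = 10 beta
#' @export
calibrate_lq <- function(sf_at_2gy, alpha_beta_ratio) {
  if (!is.numeric(sf_at_2gy) || length(sf_at_2gy) != 1L ||
    sf_at_2gy <= 0 || sf_at_2gy > 1) {
    stop("sf_at_2gy must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(alpha_beta_ratio) || length(alpha_beta_ratio) != 1L ||
    alpha_beta_ratio <= 0) {
    stop("alpha_beta_ratio must be a single positive number", call. = FALSE)
  }
  beta <- -log(sf_at_2gy) / (2 * alpha_beta_ratio + 4)
  c(alpha = alpha_beta_ratio * beta, beta = beta)
}

#' Radiosensitivity parameters for the three agent classes
#'
#' Bundles the LQ radiosensitivity of cancer (C), effector (E) and
#' regulatory (R) agents, each calibrated from its surviving fraction at
#' 2 Gy, together with the proliferative-state dose divisor (`xi = 1` for
#' actively cycling cells, `xi = 3` for quiescent cells), the
#' dose-dependent cycle lengthening and the delay between irradiation and
#' death of lethally hit cells.
#'
#' The default 2 Gy survival targets are 0.49 (cancer), 0.60 (effector)
#' and 0.77 (regulatory). Only SF(2 Gy) is pinned by the calibration; the
#' alpha/beta split (default 10 Gy for cancer, 3 Gy for the lymphocyte
#' classes) matters only away from 2 Gy per fraction.
#'
#' Immune agents do not cycle in this model, so they are irradiated with
#' `xi = 1`: their SF(2 Gy) targets already encode their sensitivity.
#'
#' @param sf2 Named numeric vector of SF(2 Gy) per class `C`, `E`, `R`.
#' @param alpha_beta Named numeric vector of alpha/beta ratios (Gy).
#' @param xi_quiescent Dose divisor for quiescent cells (default 3).
#' @param cycle_delay_h_per_gy Cycle lengthening of surviving cycling
#'   cancer cells, hours per Gy of nominal node dose (default 2).
#' @param death_delay_h Delay between irradiation and removal of lethally
#'   hit cells, hours (default 8).
#' @return Object of class `radiosensitivity_params` with per-class
#'   `alpha` and `beta` and the auxiliary parameters.
#' @export
radiosensitivity_params <- function(sf2 = c(C = 0.49, E = 0.60, R = 0.77),
                                    alpha_beta = c(C = 10, E = 3, R = 3),
                                    xi_quiescent = 3,
                                    cycle_delay_h_per_gy = 2,
                                    death_delay_h = 8) {
  stopifnot(
    all(c("C", "E", "R") %in% names(sf2)),
    all(c("C", "E", "R") %in% names(alpha_beta)),
    xi_quiescent >= 1, cycle_delay_h_per_gy >= 0, death_delay_h >= 0
  )
  ab <- lapply(c(C = "C", E = "E", R = "R"), function(k) {
    calibrate_lq(sf2[[k]], alpha_beta[[k]])
  })
  structure(
    list(
      alpha = vapply(ab, `[[`, numeric(1), "alpha"),
      beta = vapply(ab, `[[`, numeric(1), "beta"),
      sf2 = sf2[c("C", "E", "R")],
      xi_quiescent = xi_quiescent,
      cycle_delay_h_per_gy = cycle_delay_h_per_gy,
      death_delay_h = death_delay_h
    ),
    class = "radiosensitivity_params"
  )
}

#' Linear-quadratic survival probability
#'
#' `SF_i(d) = exp(-alpha_i d/xi - beta_i (d/xi)^2)` where `xi = 1` for
#' actively cycling cells and `xi = xi_quiescent` (default 3) for
#' quiescent cells, reflecting the reduced radiosensitivity of
#' non-proliferating cells.
#'
#' @param d Dose in Gy (vectorized, >= 0).
#' @param params A [radiosensitivity_params()] object.
#' @param klass One of `"C"`, `"E"`, `"R"`.
#' @param cycling Logical: is the cell actively cycling?
#' @return Survival probability in `(0, 1]`, same length as `d`.
#' @export
survival_probability <- function(d, params, klass = c("C", "E", "R"),
                                 cycling = TRUE) {
  klass <- match.arg(klass)
  if (any(d < 0)) stop("dose must be non-negative", call. = FALSE)
  xi <- if (cycling) 1 else params$xi_quiescent
  de <- d / xi
  exp(-params$alpha[[klass]] * de - params$beta[[klass]] * de^2)
}

#' Monte-Carlo survival draws under the LQ model
#'
#' Draws independent Bernoulli survival outcomes for `n` agents exposed to
#' a uniform dose, through the same LQ survival probability used when a
#' treatment fraction is applied in the simulation. Used for stochastic
#' calibration checks of the radiation module.
#'
#' @inheritParams survival_probability
#' @param n Number of independent agents.
#' @param d Dose in Gy.
#' @return Logical vector of length `n`: `TRUE` for survivors.
#' @export
simulate_survival <- function(n, d, params, klass = c("C", "E", "R"),
                              cycling = TRUE) {
  klass <- match.arg(klass)
  p <- survival_probability(d, params, klass, cycling)
  stats::runif(n) < p
}

#' GRID collimator geometry
#'
#' Describes an in silico SFRT-GRID block: circular openings of a given
#' diameter whose centers tile the plane on a square lattice, with
#' shielded "valley" regions between them receiving a fixed fraction of
#' the peak dose. The defaults mirror scaled clinical blocks: 11-node
#' (220 um) openings at a center-to-center spacing of 30 or 35 nodes,
#' valleys at 15% of the peak dose.
#'
#' @param opening_diameter Opening diameter in nodes (default 11).
#' @param center_spacing Center-to-center distance in nodes (default 30).
#' @param valley_fraction Valley dose as a fraction of peak, in `(0, 1]`.
#' @param offset Length-2 numeric: shift of the opening-center pattern in
#'   nodes relative to the domain-centered default.
#' @return Object of class `grid_geometry`.
#' @export
grid_geometry <- function(opening_diameter = 11, center_spacing = 30,
                          valley_fraction = 0.15, offset = c(0, 0)) {
  stopifnot(
    opening_diameter > 0, center_spacing > 0,
    valley_fraction > 0, valley_fraction <= 1, length(offset) == 2L
  )
  if (opening_diameter >= center_spacing) {
    stop("opening_diameter must be smaller than center_spacing (openings would merge)",
      call. = FALSE
    )
  }
  structure(
    list(
      opening_diameter = opening_diameter,
      center_spacing = center_spacing,
      valley_fraction = valley_fraction,
      offset = as.numeric(offset)
    ),
    class = "grid_geometry"
  )
}

#' Build a GRID dose map
#'
#' Per-node dose for one fraction through a GRID block. A node is "open"
#' (receives `peak_dose`) iff its center lies within
#' `opening_diameter / 2` (inclusive) of any opening center; all other
#' nodes receive `valley_fraction * peak_dose`. Opening centers tile the
#' plane with period `center_spacing`, anchored so the pattern is
#' centered on the domain midpoint; the block never moves between
#' fractions (perfect inter-fraction alignment is assumed).
#'
#' @param geom A [grid_geometry()].
#' @param peak_dose Peak dose per fraction, Gy.
#' @param dom A [lattice_domain()].
#' @return Numeric `width x height` matrix of doses (Gy) with attribute
#'   `open_fraction`, the realized fraction of open nodes.
#' @export
build_grid_dose_map <- function(geom, peak_dose = 2, dom = lattice_domain()) {
  stopifnot(inherits(geom, "grid_geometry"), peak_dose >= 0)
  s <- geom$center_spacing
  rad <- geom$opening_diameter / 2
  mid <- c((dom$width - 1) / 2, (dom$height - 1) / 2) + geom$offset
  # opening centers covering the domain (one period of margin each side)
  kx <- seq(floor((0 - mid[1]) / s) - 1, ceiling((dom$width - 1 - mid[1]) / s) + 1)
  ky <- seq(floor((0 - mid[2]) / s) - 1, ceiling((dom$height - 1 - mid[2]) / s) + 1)
  cx <- mid[1] + kx * s
  cy <- mid[2] + ky * s

  x <- matrix(0:(dom$width - 1), dom$width, dom$height)
  y <- matrix(0:(dom$height - 1), dom$width, dom$height, byrow = TRUE)
  open <- matrix(FALSE, dom$width, dom$height)
  for (ax in cx) {
    for (ay in cy) {
      open <- open | ((x - ax)^2 + (y - ay)^2 <= rad^2)
    }
  }
  dose <- ifelse(open, peak_dose, geom$valley_fraction * peak_dose)
  attr(dose, "open_fraction") <- mean(open)
  dose
}

#' Uniform (whole-tumor) dose map
#'
#' @param peak_dose Dose per fraction, Gy.
#' @param dom A [lattice_domain()].
#' @return Numeric `width x height` matrix, all entries `peak_dose`, with
#'   attribute `open_fraction = 1`.
#' @export
build_wtrt_dose_map <- function(peak_dose = 2, dom = lattice_domain()) {
  stopifnot(peak_dose >= 0)
  m <- matrix(peak_dose, dom$width, dom$height)
  attr(m, "open_fraction") <- 1
  m
}

#' Mean dose over the domain
#'
#' Either the arithmetic mean of a dose-map matrix, or the closed form
#' `f * peak + (1 - f) * valley_fraction * peak` for an open fraction
#' `f`. With 2 Gy peak fractions and valleys at 15% of peak, open
#' fractions of 30% and 50% give mean doses of 0.81 Gy and 1.15 Gy per
#' fraction.
#'
#' @param x Either a dose-map matrix or a single open fraction in
#'   `[0, 1]`.
#' @param peak_dose Peak dose, Gy (ignored when `x` is a matrix).
#' @param valley_fraction Valley dose as fraction of peak (ignored when
#'   `x` is a matrix).
#' @return Mean dose in Gy.
#' @examples
#' mean_dose(0.30, 2, 0.15) # 0.81
#' mean_dose(0.50, 2, 0.15) # 1.15
#' @export
mean_dose <- function(x, peak_dose = 2, valley_fraction = 0.15) {
  if (is.matrix(x)) {
    return(mean(x))
  }
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 1) {
    stop("open fraction must be a single value in [0, 1]", call. = FALSE)
  }
  x * peak_dose + (1 - x) * valley_fraction * peak_dose
}

#' Build a treatment schedule
#'
#' Fractionated schedules deliver one fraction per weekday (5 on, 2 off)
#' at a fixed hour of day for a given number of weeks; the standard
#' course is 2 Gy x 35 weekday fractions over 7 weeks (70 Gy total).
#' `kind = "GRID30"` / `"GRID35"` attach a GRID dose map (center spacing
#' 30 or 35 nodes); `"WTRT"` uses a uniform map. `kind = "custom"` takes
#' an arbitrary data.frame of `(hour, dose)` rows (e.g. a single ablative
#' 15 Gy fraction), delivered through the same dose map shape.
#'
#' @param kind One of `"WTRT"`, `"GRID30"`, `"GRID35"`, `"custom"`.
#' @param weeks Number of treatment weeks (default 7).
#' @param peak_dose Peak dose per fraction, Gy (default 2).
#' @param dose_hour Hour of day at which fractions are delivered
#'   (default 8). Simulation hour 0 is midnight of the first Monday.
#' @param custom For `kind = "custom"`: data.frame with columns `hour`
#'   and `dose` (peak Gy per fraction).
#' @param geom [grid_geometry()] for the GRID kinds; defaults to spacing
#'   30 or 35 with 11-node openings and 15% valleys.
#' @param dom A [lattice_domain()].
#' @return Object of class `treatment_schedule`: list with `fractions`
#'   (data.frame `hour`, `peak_dose`, `label`), `dose_map` (the map for a
#'   1 Gy peak; scaled per fraction), `kind`, `total_dose` (sum of peak
#'   doses).
#' @examples
#' sched <- make_schedule("WTRT")
#' nrow(sched$fractions) # 35
#' sched$total_dose # 70
#' @export
make_schedule <- function(kind = c("WTRT", "GRID30", "GRID35", "custom"),
                          weeks = 7, peak_dose = 2, dose_hour = 8,
                          custom = NULL, geom = NULL, dom = lattice_domain()) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    stopifnot(is.data.frame(custom), all(c("hour", "dose") %in% names(custom)))
    if (any(custom$dose < 0)) stop("negative dose in custom schedule", call. = FALSE)
    if (is.unsorted(custom$hour, strictly = TRUE)) {
      stop("custom schedule hours must be strictly increasing", call. = FALSE)
    }
    fractions <- data.frame(
      hour = as.integer(custom$hour), peak_dose = custom$dose,
      label = sprintf("custom_%d", seq_len(nrow(custom)))
    )
  } else {
    stopifnot(weeks >= 0, peak_dose >= 0, dose_hour >= 0, dose_hour < 24)
    if (weeks == 0) {
      fractions <- data.frame(
        hour = integer(0), peak_dose = numeric(0),
        label = character(0)
      )
    } else {
      wd <- expand.grid(day = 0:4, week = seq_len(weeks) - 1)
      hour <- 24L * (7L * wd$week + wd$day) + as.integer(dose_hour)
      fractions <- data.frame(
        hour = sort(hour), peak_dose = peak_dose,
        label = sprintf("fx_%02d", seq_along(hour))
      )
    }
  }
  dose_map <- switch(kind,
    WTRT = build_wtrt_dose_map(1, dom),
    custom = build_wtrt_dose_map(1, dom),
    GRID30 = build_grid_dose_map(
      if (is.null(geom)) grid_geometry(center_spacing = 30) else geom, 1, dom
    ),
    GRID35 = build_grid_dose_map(
      if (is.null(geom)) grid_geometry(center_spacing = 35) else geom, 1, dom
    )
  )
  if (!is.null(geom) && kind %in% c("WTRT", "custom")) {
    dose_map <- build_grid_dose_map(geom, 1, dom)
  }
  structure(
    list(
      fractions = fractions,
      dose_map = dose_map,
      kind = kind,
      total_dose = sum(fractions$peak_dose)
    ),
    class = "treatment_schedule"
  )
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf(
    "<treatment_schedule> %s: %d fractions, %g Gy total peak dose, open fraction %.3f\n",
    x$kind, nrow(x$fractions), x$total_dose, attr(x$dose_map, "open_fraction")
  ))
  invisible(x)
}

#' Export a schedule as TSV
#'
#' @param schedule A [make_schedule()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(
    schedule$fractions[, c("hour", "label", "peak_dose")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Export a dose map as a CSV matrix
#'
#' Writes `height` rows by `width` columns of Gy-per-fraction values (row
#' `j` is lattice row `y = j - 1`), for inspection and regression tests.
#'
#' @param dose_map Matrix from [build_grid_dose_map()] or
#'   [build_wtrt_dose_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dose_map <- function(dose_map, path) {
  utils::write.table(t(dose_map), path,
    sep = ",", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Apply one radiation fraction to a simulation state
#'
#' Draws LQ survival for every agent at its node's dose. Cancer agents
#' count as actively cycling (`xi = 1`) iff they were not quiescent at
#' the last timestep and are not already doomed; quiescent cancer agents
#' are irradiated with `xi = xi_quiescent`. Immune agents are treated as
#' non-cycling cell types irradiated at `xi = 1` (their SF(2 Gy) targets
#' encode their sensitivity). Surviving cycling cancer agents have their
#' cycle lengthened by `cycle_delay_h_per_gy` hours per Gy of nominal
#' node dose. Non-survivors are not removed immediately: they are marked
#' doomed and removed `death_delay_h` hours later, at which point cancer
#' removals are counted as radiation (Tx) deaths.
#'
#' @param state An `abm_state` (see [new_abm_state()]).
#' @param dose_map Numeric `width x height` matrix of doses in Gy.
#' @param params A [radiosensitivity_params()].
#' @return The updated `abm_state`.
#' @export
apply_fraction <- function(state, dose_map, params) {
  stopifnot(inherits(state, "abm_state"), inherits(params, "radiosensitivity_params"))
  ag <- state$agents
  if (nrow(ag) == 0L) {
    return(state)
  }
  d <- dose_map[cbind(ag$x + 1L, ag$y + 1L)]
  cycling <- ifelse(ag$class == "C", !ag$quiescent_prev & !ag$doomed, FALSE)
  xi <- ifelse(ag$class == "C" & !cycling, params$xi_quiescent, 1)
  de <- d / xi
  alpha <- params$alpha[ag$class]
  beta <- params$beta[ag$class]
  p <- exp(-alpha * de - beta * de^2)
  survive <- stats::runif(nrow(ag)) < p

  lengthen <- survive & ag$class == "C" & cycling
  ag$div_length[lengthen] <- ag$div_length[lengthen] +
    params$cycle_delay_h_per_gy * d[lengthen]

  killed <- !survive & !ag$doomed
  ag$doomed[killed] <- TRUE
  ag$death_time[killed] <- state$hour + params$death_delay_h

  state$agents <- ag
  state
}
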