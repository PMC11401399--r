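#' Generate a synthetic mIHC-style cell table
#'
#' Emulates a digitized multiplex IHC slide of a head-and-neck tumor
#' section so the simulator can be exercised without patient data: a
#' cancer-cell mass placed as a Gaussian clump in a physical field
#' (default 1360 um x 1020 um, the extent of the standard 68 x 51 domain
#' at 20 um pitch) with effector and regulatory immune cells distributed
#' between uniform scatter and the tumor margin.
#'
#' The `clustering` weight controls the spatial mixing of the immune
#' compartment: each immune cell is placed near the cancer mass boundary
#' with probability `clustering` and uniformly in the field otherwise.
#' Low counts with `clustering` near 0 emulate an immune-desert
#' microenvironment; high counts with high `clustering` emulate an
#' inflamed, infiltrated one. Cells are written as 20 um square bounding
#' boxes centered on the sampled positions, clipped to the field, with
#' phenotype labels matching [default_phenotype_map()].
#'
#' The default composition is the package's reference study condition: a
#' dense cancer mass (2500 cells before node collisions) with sparse,
#' weakly clustered immune infiltration — an immune-poor
#' microenvironment whose untreated dynamics escape immune surveillance
#' under the reference parameter set.
#'
#' @param n_cancer,n_effector,n_regulatory Cell counts (>= 0).
#' @param clustering Immune mixing weight in `[0, 1]` (default 0.5).
#' @param seed Integer seed; the same arguments and seed always produce
#'   the same table.
#' @param field_width,field_height Physical field size in micrometres.
#' @param clump_sd Standard deviation of the cancer clump, micrometres
#'   (default 180).
#' @return Data.frame with columns `x_min`, `x_max`, `y_min`, `y_max`,
#'   `phenotype`, one row per cell.
#' @examples
#' slide <- generate_synthetic_slide(100, 20, 10, clustering = 0.5, seed = 1)
#' nrow(slide) # 130
#' @export
generate_synthetic_slide <- function(n_cancer = 2500, n_effector = 30,
                                     n_regulatory = 40,
                                     clustering = 0.5, seed = 1L,
                                     field_width = 1360, field_height = 1020,
                                     clump_sd = 320) {
  stopifnot(
    n_cancer >= 0, n_effector >= 0, n_regulatory >= 0,
    clustering >= 0, clustering <= 1,
    field_width > 0, field_height > 0, clump_sd > 0
  )
  capacity <- floor(field_width / 20) * floor(field_height / 20)
  total <- n_cancer + n_effector + n_regulatory
  if (total > capacity) {
    stop(sprintf(
      "requested %d cells exceed field capacity of %d nodes at 20 um pitch",
      total, capacity
    ), call. = FALSE)
  }
  if (total == 0L) {
    return(data.frame(
      x_min = numeric(0), x_max = numeric(0),
      y_min = numeric(0), y_max = numeric(0),
      phenotype = character(0), stringsAsFactors = FALSE
    ))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  cx <- field_width / 2
  cy <- field_height / 2

  sample_in_field <- function(n, fun) {
    # rejection sampling keeps positions inside the field
    xs <- numeric(0)
    ys <- numeric(0)
    while (length(xs) < n) {
      m <- max(n - length(xs), 1L) * 2L
      p <- fun(m)
      keep <- p$x >= 0 & p$x <= field_width & p$y >= 0 & p$y <= field_height
      xs <- c(xs, p$x[keep])
      ys <- c(ys, p$y[keep])
    }
    list(x = xs[seq_len(n)], y = ys[seq_len(n)])
  }

  clump <- function(m) {
    list(x = stats::rnorm(m, cx, clump_sd), y = stats::rnorm(m, cy, clump_sd))
  }
  margin <- function(m) {
    # ring around the clump boundary (~2 sd from the center)
    rad <- stats::rnorm(m, 2 * clump_sd, 0.4 * clump_sd)
    th <- stats::runif(m, 0, 2 * pi)
    list(x = cx + rad * cos(th), y = cy + rad * sin(th))
  }
  uniform <- function(m) {
    list(x = stats::runif(m, 0, field_width), y = stats::runif(m, 0, field_height))
  }

  place_immune <- function(n) {
    if (n == 0L) {
      return(list(x = numeric(0), y = numeric(0)))
    }
    near <- stats::runif(n) < clustering
    a <- sample_in_field(sum(near), margin)
    b <- sample_in_field(sum(!near), uniform)
    x <- numeric(n)
    y <- numeric(n)
    x[near] <- a$x
    y[near] <- a$y
    x[!near] <- b$x
    y[!near] <- b$y
    list(x = x, y = y)
  }

  can <- sample_in_field(n_cancer, clump)
  eff <- place_immune(n_effector)
  reg <- place_immune(n_regulatory)

  x <- c(can$x, eff$x, reg$x)
  y <- c(can$y, eff$y, reg$y)
  phen <- c(
    rep("PCK+", n_cancer),
    rep("CD3+CD8+", n_effector),
    rep("CD3+CD4+FOXP3+", n_regulatory)
  )
  half <- 10 # 20 um boxes
  data.frame(
    x_min = pmax(x - half, 0),
    x_max = pmin(x + half, field_width),
    y_min = pmax(y - half, 0),
    y_max = pmin(y + half, field_height),
    phenotype = phen,
    stringsAsFactors = FALSE
  )
}
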