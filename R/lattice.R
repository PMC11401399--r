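#' Construct a lattice domain
#'
#' The spatial substrate of the simulation: a rectangular grid of square
#' nodes, each of which can hold at most one agent. The default domain of
#' 68 x 51 nodes at 20 micrometre pitch represents roughly 1.39 mm^2 of
#' tissue, with the node pitch chosen to match an average cell diameter.
#'
#' Boundaries are closed (no-flux): agents can never leave the domain and
#' there is no wraparound. Node coordinates are 0-based integer indices in
#' `[0, width) x [0, height)`.
#'
#' @param width Number of nodes in x (default 68).
#' @param height Number of nodes in y (default 51).
#' @param node_pitch Physical edge length of one node, in micrometres
#'   (default 20).
#' @return An object of class `lattice_domain` with fields `width`,
#'   `height` and `node_pitch`.
#' @examples
#' dom <- lattice_domain()
#' domain_area_mm2(dom) # ~1.39 mm^2
#' @export
lattice_domain <- function(width = 68L, height = 51L, node_pitch = 20) {
  width <- as.integer(width)
  height <- as.integer(height)
  stopifnot(width >= 1L, height >= 1L, node_pitch > 0)
  structure(
    list(width = width, height = height, node_pitch = node_pitch),
    class = "lattice_domain"
  )
}

#' @export
print.lattice_domain <- function(x, ...) {
  cat(sprintf(
    "<lattice_domain> %d x %d nodes, %g um pitch (%.4f mm^2, %d nodes)\n",
    x$width, x$height, x$node_pitch, domain_area_mm2(x), x$width * x$height
  ))
  invisible(x)
}

#' Physical area of a lattice domain
#'
#' @param dom A [lattice_domain()].
#' @return Area in mm^2 (`width * height * node_pitch^2 / 1e6`).
#' @export
domain_area_mm2 <- function(dom) {
  dom$width * dom$height * dom$node_pitch^2 / 1e6
}

in_domain <- function(coord, dom) {
  coord[1] >= 0L && coord[1] < dom$width && coord[2] >= 0L && coord[2] < dom$height
}

as_coord <- function(c) {
  if (!is.numeric(c) || length(c) != 2L || any(c != floor(c))) {
    stop("coordinate must be a length-2 integer vector (x, y)", call. = FALSE)
  }
  as.integer(c)
}

coord_matrix <- function(x, y) {
  m <- cbind(x = as.integer(x), y = as.integer(y))
  m
}

#' Moore neighborhood of a node
#'
#' The up-to-8 in-bounds nodes at Chebyshev distance 1 from `c` (diagonals
#' included), excluding `c` itself. At domain edges and corners the
#' neighborhood is clipped (closed boundaries), giving 5 or 3 neighbors.
#'
#' @param c Length-2 integer vector `(x, y)`, 0-based node coordinate.
#' @param dom A [lattice_domain()].
#' @return Integer matrix with columns `x`, `y`, one row per neighbor, in
#'   raster order.
#' @examples
#' dom <- lattice_domain()
#' nrow(moore_neighbors(c(10, 10), dom)) # 8
#' nrow(moore_neighbors(c(0, 0), dom))   # 3
#' @export
moore_neighbors <- function(c, dom) {
  c <- as_coord(c)
  if (!in_domain(c, dom)) {
    stop(sprintf("coordinate (%d, %d) outside domain", c[1], c[2]), call. = FALSE)
  }
  off <- expand.grid(dy = -1L:1L, dx = -1L:1L)
  off <- off[!(off$dx == 0L & off$dy == 0L), ]
  x <- c[1] + off$dx
  y <- c[2] + off$dy
  keep <- x >= 0L & x < dom$width & y >= 0L & y < dom$height
  m <- coord_matrix(x[keep], y[keep])
  m[order(m[, "y"], m[, "x"]), , drop = FALSE]
}

#' Nodes within a Euclidean radius
#'
#' All in-bounds nodes whose Euclidean distance from `c` (in node units,
#' measured between integer node indices) lies in `(0, r]`; `c` itself is
#' excluded. This is the radius query used for immune target search
#' (r = 50) and postcode recruit placement (r = 10).
#'
#' @inheritParams moore_neighbors
#' @param r Radius in node units; must be positive.
#' @return Integer matrix with columns `x`, `y`, rows in raster order.
#' @examples
#' dom <- lattice_domain()
#' nrow(nodes_within_radius(c(30, 25), 1, dom))   # 4 (von Neumann)
#' nrow(nodes_within_radius(c(30, 25), 1.5, dom)) # 8 (Moore)
#' @export
nodes_within_radius <- function(c, r, dom) {
  c <- as_coord(c)
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("radius r must be a single positive number", call. = FALSE)
  }
  if (!in_domain(c, dom)) {
    stop(sprintf("coordinate (%d, %d) outside domain", c[1], c[2]), call. = FALSE)
  }
  k <- floor(r)
  dx <- seq(-k, k)
  g <- expand.grid(dx = dx, dy = dx)
  d2 <- g$dx^2 + g$dy^2
  keep <- d2 > 0 & d2 <= r^2
  x <- c[1] + g$dx[keep]
  y <- c[2] + g$dy[keep]
  inb <- x >= 0L & x < dom$width & y >= 0L & y < dom$height
  m <- coord_matrix(x[inb], y[inb])
  m[order(m[, "y"], m[, "x"]), , drop = FALSE]
}

#' Nearest targets within a radius
#'
#' Among `targets`, returns all coordinates at the minimal Euclidean
#' distance from `c`, restricted to distance at most `r`. Ties are all
#' returned; the caller (the migration rule) picks one uniformly at
#' random. An empty matrix means no target is in range, in which case an
#' immune cell falls back to random motion.
#'
#' @inheritParams nodes_within_radius
#' @param targets Integer matrix with columns `x`, `y` (possibly 0 rows).
#' @return Integer matrix of the tied nearest targets (0 rows when none in
#'   range).
#' @export
nearest_of_class <- function(c, r, targets) {
  c <- as_coord(c)
  if (!is.numeric(r) || length(r) != 1L || r <= 0) {
    stop("radius r must be a single positive number", call. = FALSE)
  }
  if (is.null(targets) || nrow(targets) == 0L) {
    return(coord_matrix(integer(0), integer(0)))
  }
  d2 <- (targets[, 1] - c[1])^2 + (targets[, 2] - c[2])^2
  keep <- d2 > 0 & d2 <= r^2
  if (!any(keep)) {
    return(coord_matrix(integer(0), integer(0)))
  }
  d2 <- d2[keep]
  targets <- targets[keep, , drop = FALSE]
  best <- d2 == min(d2)
  m <- targets[best, , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' Convert a physical migration speed to a per-timestep sub-move budget
#'
#' Agents move at most one node per sub-move, so a physical speed in
#' micrometres per minute translates to `floor(speed * 60 * dt /
#' node_pitch)` sub-moves per timestep. With the defaults (20 um nodes,
#' 1 h timestep) the model's immune speed of 5 um/min gives 15 sub-moves
#' and the cancer speed of 2.3 um/min gives 6.
#'
#' @param um_per_min Migration speed in micrometres per minute.
#' @param node_pitch Node edge length in micrometres (default 20).
#' @param dt_hours Timestep in hours (default 1).
#' @return Integer sub-move budget per timestep.
#' @examples
#' speed_to_submoves(5)   # 15
#' speed_to_submoves(2.3) # 6
#' @export
speed_to_submoves <- function(um_per_min, node_pitch = 20, dt_hours = 1) {
  stopifnot(um_per_min >= 0, node_pitch > 0, dt_hours > 0)
  as.integer(floor(um_per_min * 60 * dt_hours / node_pitch))
}
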