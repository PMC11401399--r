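#' Default phenotype-to-agent-class mapping
#'
#' Reduces a multiplex IHC marker vocabulary to the three agent classes of
#' the model. Pan-cytokeratin positive cells become cancer agents, CD8+
#' T cells become effector agents and FOXP3+ CD4+ T cells become
#' regulatory agents. Macrophages (CD68+) and non-regulatory helper
#' T cells are ignored: they are not represented in the three-population
#' model. The mapping is a documented default and fully overridable.
#'
#' @return Named character vector mapping phenotype label to one of
#'   `"cancer"`, `"effector"`, `"regulatory"`, `"ignore"`.
#' @export
default_phenotype_map <- function() {
  c(
    "PCK+" = "cancer",
    "CD3+CD8+" = "effector",
    "CD3+CD4+FOXP3+" = "regulatory",
    "CD3+CD4+FOXP3-" = "ignore",
    "CD68+" = "ignore"
  )
}

#' Read a HALO-style per-cell table
#'
#' Parses a delimited table of per-cell bounding boxes (in micrometres)
#' and phenotype labels, as exported by quantitative image analysis of
#' multiplex IHC slides.
#'
#' @param path Path to a delimited text file with a header row.
#' @param cols Named character vector giving the column names for the
#'   required fields `x_min`, `x_max`, `y_min`, `y_max`, `phenotype`.
#' @param sep Field delimiter (default `","`).
#' @return A data.frame with columns `x_min`, `x_max`, `y_min`, `y_max`
#'   (numeric, micrometres) and `phenotype` (character), rows in file
#'   order.
#' @export
read_cell_table <- function(path,
                            cols = c(
                              x_min = "XMin", x_max = "XMax",
                              y_min = "YMin", y_max = "YMax",
                              phenotype = "Phenotype"
                            ),
                            sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  need <- c("x_min", "x_max", "y_min", "y_max", "phenotype")
  if (!all(need %in% names(cols))) {
    stop("`cols` must name all of: ", paste(need, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = "character"
  )
  missing <- setdiff(unname(cols[need]), names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  out <- data.frame(
    x_min = suppressWarnings(as.numeric(raw[[cols[["x_min"]]]])),
    x_max = suppressWarnings(as.numeric(raw[[cols[["x_max"]]]])),
    y_min = suppressWarnings(as.numeric(raw[[cols[["y_min"]]]])),
    y_max = suppressWarnings(as.numeric(raw[[cols[["y_max"]]]])),
    phenotype = raw[[cols[["phenotype"]]]],
    stringsAsFactors = FALSE
  )
  for (f in c("x_min", "x_max", "y_min", "y_max")) {
    bad <- which(is.na(out[[f]]) & nzchar(raw[[cols[[f]]]]))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric value in column '%s' at data row %d",
        cols[[f]], bad[1]
      ), call. = FALSE)
    }
  }
  out
}

#' Map a cell bounding box to a lattice node
#'
#' Computes the box center `((x_min + x_max)/2, (y_min + y_max)/2)` in
#' micrometres and maps it to a 0-based node index by `floor(center /
#' kappa)`, where `kappa` is the micrometre-per-node conversion factor.
#' The default `kappa = 20` corresponds to an assumed average cell
#' diameter of 20 micrometres.
#'
#' All arguments are vectorized over rows.
#'
#' @param x_min,x_max,y_min,y_max Bounding-box coordinates, micrometres.
#' @param kappa Conversion factor, micrometres per node (> 0).
#' @return Integer matrix with columns `x`, `y`.
#' @examples
#' map_cell_to_node(100, 140, 60, 100, kappa = 20) # node (6, 4)
#' @export
map_cell_to_node <- function(x_min, x_max, y_min, y_max, kappa = 20) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("kappa must be a single positive number", call. = FALSE)
  }
  cx <- (x_min + x_max) / 2
  cy <- (y_min + y_max) / 2
  cbind(x = as.integer(floor(cx / kappa)), y = as.integer(floor(cy / kappa)))
}

#' Build the initial agent population from a cell table
#'
#' Maps each row of a per-cell table to a lattice node, translates
#' phenotypes to agent classes, and resolves single-occupancy collisions.
#' When several cells map to the same node, the first row in file order is
#' retained and later rows are dropped; rows mapping outside the domain
#' are dropped and counted as lost. Rows whose phenotype maps to
#' `"ignore"` are skipped entirely and excluded from the retention
#' denominator.
#'
#' The fraction of (non-ignored) cells retained falls as `kappa` grows,
#' since coarser nodes collide more cells.
#'
#' @param rows Data.frame as returned by [read_cell_table()] or
#'   [generate_synthetic_slide()].
#' @param phenotype_map Named character vector mapping each phenotype
#'   label to `"cancer"`, `"effector"`, `"regulatory"` or `"ignore"`; must
#'   cover every label present.
#' @param kappa Micrometres per node (default 20).
#' @param dom Target [lattice_domain()]. Defaults to the standard
#'   68 x 51 domain.
#' @return An object of class `initial_state`: a list with `cells` (a
#'   data.frame of `x`, `y`, `class`), `retention_fraction`, `kappa`,
#'   `n_input`, `n_ignored`, `n_collided`, `n_out_of_domain` and per-class
#'   `counts`.
#' @export
build_initial_state <- function(rows, phenotype_map = default_phenotype_map(),
                                kappa = 20, dom = lattice_domain()) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) > 0L) {
    unknown <- setdiff(unique(rows$phenotype), names(phenotype_map))
    if (length(unknown) > 0L) {
      stop(sprintf(
        "phenotype label(s) not covered by phenotype_map: %s",
        paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
  }
  klass <- unname(phenotype_map[rows$phenotype])
  considered <- which(klass != "ignore")
  n_ignored <- nrow(rows) - length(considered)

  nodes <- map_cell_to_node(
    rows$x_min[considered], rows$x_max[considered],
    rows$y_min[considered], rows$y_max[considered], kappa
  )
  inb <- nodes[, "x"] >= 0L & nodes[, "x"] < dom$width &
    nodes[, "y"] >= 0L & nodes[, "y"] < dom$height
  n_out <- sum(!inb)

  nodes_in <- nodes[inb, , drop = FALSE]
  klass_in <- klass[considered][inb]
  key <- nodes_in[, "x"] + as.numeric(dom$width) * nodes_in[, "y"]
  first <- !duplicated(key) # first in file order wins
  n_collided <- sum(!first)

  cells <- data.frame(
    x = nodes_in[first, "x"],
    y = nodes_in[first, "y"],
    class = klass_in[first],
    stringsAsFactors = FALSE
  )
  counts <- c(
    cancer = sum(cells$class == "cancer"),
    effector = sum(cells$class == "effector"),
    regulatory = sum(cells$class == "regulatory")
  )
  if (length(considered) > 0L && counts[["cancer"]] == 0L) {
    warning("no cancer cells retained: the simulation would start tumor-free",
      call. = FALSE
    )
  }
  structure(
    list(
      cells = cells,
      retention_fraction = if (length(considered) == 0L) NA_real_ else nrow(cells) / length(considered),
      kappa = kappa,
      n_input = length(considered),
      n_ignored = n_ignored,
      n_collided = n_collided,
      n_out_of_domain = n_out,
      counts = counts,
      dom = dom
    ),
    class = "initial_state"
  )
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf(
    "<initial_state> %d agents (C=%d, E=%d, R=%d), kappa=%g, retention=%.3f\n",
    nrow(x$cells), x$counts[["cancer"]], x$counts[["effector"]],
    x$counts[["regulatory"]], x$kappa, x$retention_fraction
  ))
  invisible(x)
}

#' Write an initial state to disk
#'
#' Writes the retained cells as a TSV of `(x, y, class)` plus a JSON
#' sidecar recording the conversion factor, retention fraction and
#' per-class counts.
#'
#' @param state An `initial_state` from [build_initial_state()].
#' @param path Path of the TSV to write; the sidecar gets `.json`
#'   appended.
#' @return Invisibly, `path`.
#' @export
write_initial_state <- function(state, path) {
  stopifnot(inherits(state, "initial_state"))
  utils::write.table(state$cells, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  meta <- list(
    kappa = state$kappa,
    retention_fraction = state$retention_fraction,
    n_input = state$n_input,
    n_ignored = state$n_ignored,
    n_collided = state$n_collided,
    n_out_of_domain = state$n_out_of_domain,
    counts = as.list(state$counts)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
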