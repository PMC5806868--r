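#' Electrode grid layouts
#'
#' A `mea_layout` is a bijection between electrode labels and positions on a
#' rectangular grid of `columns` x `rows` recording sites. Coordinates are
#' 0-based `(column, row)` pairs with the origin at the top-left of the array,
#' matching the physical orientation of a plated MEA viewed from above.
#'
#' @param electrodes Character vector of unique electrode labels.
#' @param columns,rows Grid extent (positive integers).
#' @param coords Integer matrix with one row per electrode and two columns
#'   (`column`, `row`), 0-based.
#' @return An object of class `mea_layout`.
#' @examples
#' lay <- default_layout()
#' n_electrodes(lay)
#' coordinates_for_electrode(lay, "F8")
#' @export
mea_layout <- function(electrodes, columns, rows, coords) {
  electrodes <- as.character(electrodes)
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("column", "row")))
  if (anyDuplicated(electrodes))
    rlang::abort("duplicate electrode labels in layout",
                 class = "spikegrid_validation_error")
  if (nrow(coords) != length(electrodes))
    rlang::abort("coords must have one row per electrode",
                 class = "spikegrid_validation_error")
  if (any(coords[, 1] < 0L) || any(coords[, 1] >= columns) ||
      any(coords[, 2] < 0L) || any(coords[, 2] >= rows))
    rlang::abort("electrode coordinates out of grid bounds",
                 class = "spikegrid_validation_error")
  key <- paste(coords[, 1], coords[, 2])
  if (anyDuplicated(key))
    rlang::abort("two electrodes share a grid position",
                 class = "spikegrid_validation_error")
  structure(
    list(electrodes = electrodes,
         columns = as.integer(columns), rows = as.integer(rows),
         coords = coords,
         forward = stats::setNames(seq_along(electrodes), electrodes),
         inverse = stats::setNames(electrodes, key)),
    class = "mea_layout")
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("<mea_layout: %d electrodes on a %d x %d grid>\n",
              length(x$electrodes), x$columns, x$rows))
  invisible(x)
}

#' @rdname mea_layout
#' @param layout A `mea_layout`.
#' @export
n_electrodes <- function(layout) length(layout$electrodes)

#' @rdname mea_layout
#' @param electrode Electrode label (string).
#' @return `coordinates_for_electrode()`: an integer vector `c(column, row)`,
#'   0-based.
#' @export
coordinates_for_electrode <- function(layout, electrode) {
  idx <- unname(layout$forward[as.character(electrode)])
  if (is.na(idx))
    rlang::abort(
      sprintf("unknown electrode '%s'; valid labels: %s", electrode,
              paste(layout$electrodes, collapse = ", ")),
      class = "spikegrid_lookup_error")
  c(column = unname(layout$coords[idx, 1]), row = unname(layout$coords[idx, 2]))
}

#' @rdname mea_layout
#' @param column,row 0-based grid coordinates.
#' @return `electrode_for_coordinates()`: the electrode label at that position.
#' @export
electrode_for_coordinates <- function(layout, column, row) {
  lab <- unname(layout$inverse[paste(as.integer(column), as.integer(row))])
  if (is.na(lab))
    rlang::abort(sprintf("no electrode at (column = %d, row = %d)",
                         as.integer(column), as.integer(row)),
                 class = "spikegrid_lookup_error")
  lab
}

#' @rdname mea_layout
#' @details `default_layout()` builds the standard 120-electrode layout: a
#'   12 x 12 grid with a 3-2-1 staircase of six sites removed from each corner
#'   (144 - 24 = 120). Columns are lettered A-M skipping "I" (to avoid
#'   confusion with the digit 1), rows are numbered 1-12, and a label is the
#'   column letter followed by the row number (so "F8" is column F, row 8).
#' @export
default_layout <- function() {
  letters12 <- c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")
  # 3-2-1 staircase: at each corner drop the 6 cells with taxi-depth < 3
  corner_cut <- function(col, row) {
    dc <- pmin(col, 11L - col)
    dr <- pmin(row, 11L - row)
    (dc + dr) < 3L
  }
  grid <- expand.grid(column = 0:11, row = 0:11)
  keep <- !corner_cut(grid$column, grid$row)
  grid <- grid[keep, ]
  labels <- paste0(letters12[grid$column + 1L], grid$row + 1L)
  mea_layout(labels, columns = 12L, rows = 12L,
             coords = cbind(grid$column, grid$row))
}

#' @rdname mea_layout
#' @param x A `mea_layout`.
#' @param ... Unused.
#' @export
as_tibble.mea_layout <- function(x, ...) {
  tibble::tibble(electrode = x$electrodes,
                 column = as.integer(x$coords[, 1]),
                 row = as.integer(x$coords[, 2]))
}
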