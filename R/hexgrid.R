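#' Build a hexagonal simulation grid
#'
#' Constructs a pointy-top, odd-row-offset hexagonal tessellation covering a
#' rectangular arena. Cell centres are `spacing_m` apart; rows are spaced
#' `spacing_m * sqrt(3) / 2` vertically, so each hexagon covers
#' `sqrt(3)/2 * spacing_m^2` square metres (86.60 m2 at the default 10 m
#' spacing). Cells are addressed either by 0-based `(col, row)` or by a
#' 1-based linear index `row * n_cols + col + 1`.
#'
#' @param width_m,height_m arena extent in metres.
#' @param spacing_m centre-to-centre distance between neighbouring hexagons
#'   (metres, default 10).
#' @return an object of class `hex_grid` with fields `width_m`, `height_m`,
#'   `spacing_m`, `n_cols`, `n_rows`, `n_cells`, `row_step_m`.
#' @export
#' @examples
#' g <- build_grid(15000, 30000, 10)
#' g$n_cells # 5,196,000
build_grid <- function(width_m, height_m, spacing_m = 10) {
  if (!is.numeric(width_m) || !is.numeric(height_m) || !is.numeric(spacing_m) ||
      length(width_m) != 1 || length(height_m) != 1 || length(spacing_m) != 1 ||
      !is.finite(width_m) || !is.finite(height_m) || !is.finite(spacing_m) ||
      width_m <= 0 || height_m <= 0 || spacing_m <= 0)
    stop_with("grid dimensions and spacing must be single positive numbers")
  row_step <- spacing_m * sqrt(3) / 2
  if (width_m < spacing_m || height_m < row_step)
    stop_with("degenerate grid: need width >= spacing and height >= spacing*sqrt(3)/2")
  n_cols <- floor(width_m / spacing_m)
  n_rows <- floor(height_m / row_step)
  structure(
    list(width_m = width_m, height_m = height_m, spacing_m = spacing_m,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         n_cells = as.double(n_cols) * as.double(n_rows),
         row_step_m = row_step),
    class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %g m x %g m, spacing %g m: %d cols x %d rows = %s cells (%.2f m2 each)\n",
              x$width_m, x$height_m, x$spacing_m, x$n_cols, x$n_rows,
              format(x$n_cells, big.mark = ","), cell_area(x)))
  invisible(x)
}

#' Hexagon cell area
#'
#' @param grid a [build_grid()] object.
#' @return cell area in square metres, `sqrt(3)/2 * spacing^2`.
#' @export
cell_area <- function(grid) sqrt(3) / 2 * grid$spacing_m^2

#' Convert between linear cell index and (col, row) addresses
#'
#' Linear indices are 1-based; `col`/`row` are 0-based.
#'
#' @param grid a [build_grid()] object.
#' @param col,row 0-based column and row.
#' @param cell 1-based linear cell index.
#' @return `cell_index` returns linear indices; `cell_colrow` a list with
#'   `col` and `row`.
#' @export
cell_index <- function(grid, col, row) {
  stopifnot(all(col >= 0), all(col < grid$n_cols), all(row >= 0), all(row < grid$n_rows))
  as.integer(row) * grid$n_cols + as.integer(col) + 1L
}

#' @rdname cell_index
#' @export
cell_colrow <- function(grid, cell) {
  cell0 <- as.integer(cell) - 1L
  stopifnot(all(cell0 >= 0), all(cell0 < grid$n_cells))
  list(col = cell0 %% grid$n_cols, row = cell0 %/% grid$n_cols)
}

#' Cell centre coordinates
#'
#' Odd rows are offset half a spacing to the right (odd-r layout).
#'
#' @inheritParams cell_index
#' @return two-column matrix of x, y centre coordinates in metres.
#' @export
cell_centers <- function(grid, cell) {
  cr <- cell_colrow(grid, cell)
  x <- (cr$col + 0.5 * (cr$row %% 2L)) * grid$spacing_m
  y <- cr$row * grid$row_step_m
  cbind(x = x, y = y)
}

# Map continuous coordinates to the nearest cell, clamped into the grid.
coords_to_cell <- function(grid, x, y) {
  row <- round(y / grid$row_step_m)
  row <- pmin(pmax(row, 0), grid$n_rows - 1L)
  col <- round(x / grid$spacing_m - 0.5 * (row %% 2))
  col <- pmin(pmax(col, 0), grid$n_cols - 1L)
  cell_index(grid, col, row)
}

#' Neighbours of hexagonal cells
#'
#' Returns the up-to-six adjacent cells of each query cell. Off-grid
#' neighbours are `NA`.
#'
#' @inheritParams cell_index
#' @return integer matrix, one row per query cell, six columns.
#' @export
hex_neighbors <- function(grid, cell) {
  cr <- cell_colrow(grid, cell)
  col <- cr$col; row <- cr$row
  odd <- row %% 2L
  # odd-r offset neighbour displacements: E, W, NE, NW, SE, SW
  dcol <- cbind(1L, -1L, odd, odd - 1L, odd, odd - 1L)
  drow <- matrix(c(0L, 0L, -1L, -1L, 1L, 1L), nrow = length(cell), ncol = 6L,
                 byrow = TRUE)
  ncol_ <- col + dcol
  nrow_ <- row + drow
  ok <- ncol_ >= 0L & ncol_ < grid$n_cols & nrow_ >= 0L & nrow_ < grid$n_rows
  out <- matrix(NA_integer_, nrow = length(cell), ncol = 6L,
                dimnames = list(NULL, c("E", "W", "NE", "NW", "SE", "SW")))
  out[ok] <- nrow_[ok] * grid$n_cols + ncol_[ok] + 1L
  out
}

#' Centre-to-centre distance between cells
#'
#' @inheritParams cell_index
#' @param cell_a,cell_b vectors of linear cell indices (recycled).
#' @return Euclidean distances in metres.
#' @export
cell_distance <- function(grid, cell_a, cell_b) {
  a <- cell_centers(grid, cell_a)
  b <- cell_centers(grid, cell_b)
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

#' Multi-source distance field over the hex lattice
#'
#' Breadth-first search from a set of target cells over the hexagonal
#' adjacency graph. Used to steer dispersing animals toward the nearest
#' rehydration or breeding cell.
#'
#' @inheritParams cell_index
#' @param targets integer vector of target cell indices.
#' @return list with `dist` (integer graph distance in cells, `Inf` where
#'   unreachable) and `nearest` (index of the nearest target cell, 0 where
#'   unreachable), each of length `n_cells`.
#' @export
distance_field <- function(grid, targets) {
  n <- as.integer(grid$n_cells)
  stopifnot(length(targets) >= 1, all(targets >= 1), all(targets <= n))
  dist <- rep.int(NA_integer_, n)
  nearest <- integer(n)
  targets <- unique(as.integer(targets))
  dist[targets] <- 0L
  nearest[targets] <- targets
  frontier <- targets
  d <- 0L
  while (length(frontier) > 0) {
    nb <- hex_neighbors(grid, frontier)
    src <- rep(frontier, times = 6L)
    nbv <- as.vector(nb)
    keep <- !is.na(nbv)
    nbv <- nbv[keep]; src <- src[keep]
    keep <- is.na(dist[nbv])
    nbv <- nbv[keep]; src <- src[keep]
    first <- !duplicated(nbv)
    nbv <- nbv[first]; src <- src[first]
    if (length(nbv) == 0) break
    d <- d + 1L
    dist[nbv] <- d
    nearest[nbv] <- nearest[src]
    frontier <- nbv
  }
  out_dist <- as.double(dist)
  out_dist[is.na(out_dist)] <- Inf
  list(dist = out_dist, nearest = nearest)
}
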