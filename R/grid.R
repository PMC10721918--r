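# The equal-area raster: build the grid, place firms in cells, aggregate
# pollutant quantities per cell-year.

#' Build an equal-size rectangular raster over a planar extent
#'
#' Tiles the extent with square cells of side `cell_size` km. Cells use a
#' half-open membership convention `[x_left, x_right) x [y_bottom, y_top)`
#' so every interior point belongs to exactly one cell; rows are counted
#' from the bottom (south) edge, columns from the left (west) edge, both
#' 1-based. If the extent is not an exact multiple of `cell_size` it is
#' expanded symmetrically to the next multiple so cells stay equal-sized.
#'
#' @param extent Numeric length-4: `c(xmin, xmax, ymin, ymax)` in km.
#' @param cell_size Cell side length in km (default 100).
#' @param east_boundary_x Optional planar x coordinate: cells whose centroid
#'   lies at or east of it are labelled region `"East"`, the rest
#'   `"Central&West"`. When `NULL` all cells get region `NA`.
#' @return An object of class `pg_grid`: list with `extent`, `cell_size`,
#'   `n_rows`, `n_cols`, and `cells`, a data frame with one row per cell
#'   (`cell`, `row`, `col`, `cx`, `cy`, `region`). Cell index `cell` runs
#'   column-major from the bottom-left cell.
#' @export
build_grid <- function(extent, cell_size = 100, east_boundary_x = NULL) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive width and height")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  w <- extent[2] - extent[1]
  h <- extent[4] - extent[3]
  n_cols <- max(1L, as.integer(ceiling(w / cell_size - 1e-9)))
  n_rows <- max(1L, as.integer(ceiling(h / cell_size - 1e-9)))
  # expand symmetrically so the tiling is exact
  pad_x <- (n_cols * cell_size - w) / 2
  pad_y <- (n_rows * cell_size - h) / 2
  x0 <- extent[1] - pad_x
  y0 <- extent[3] - pad_y
  col <- rep(seq_len(n_cols), each = n_rows)
  row <- rep(seq_len(n_rows), times = n_cols)
  cx <- x0 + (col - 0.5) * cell_size
  cy <- y0 + (row - 0.5) * cell_size
  region <- if (is.null(east_boundary_x)) NA_character_ else
    ifelse(cx >= east_boundary_x, "East", "Central&West")
  cells <- data.frame(cell = seq_len(n_rows * n_cols), row = row, col = col,
                      cx = cx, cy = cy, region = region,
                      stringsAsFactors = FALSE)
  structure(list(extent = c(x0, x0 + n_cols * cell_size, y0, y0 + n_rows * cell_size),
                 cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
                 cells = cells),
            class = "pg_grid")
}

#' @export
print.pg_grid <- function(x, ...) {
  cat(sprintf("pg_grid: %d x %d cells of %g km (extent x [%g, %g], y [%g, %g])\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  invisible(x)
}

#' Assign planar points to grid cells
#'
#' Maps each point to the unique cell containing it under the grid's
#' half-open convention. Points outside the extent are not an error: they
#' get `NA` and are collected in the `exclusions` attribute, mirroring the
#' practice of dropping sparse peripheral areas from a study region.
#'
#' @param x,y Planar coordinates in km (same plane as the grid).
#' @param grid A `pg_grid`.
#' @param ids Optional identifiers carried into the exclusion report.
#' @return Integer vector of cell indices (`NA` for excluded points) with
#'   attribute `exclusions`: a data frame (`id`, `x`, `y`).
#' @export
assign_cells <- function(x, y, grid, ids = NULL) {
  stopifnot(inherits(grid, "pg_grid"), length(x) == length(y))
  if (is.null(ids)) ids <- seq_along(x)
  cs <- grid$cell_size
  col <- floor((x - grid$extent[1]) / cs) + 1
  row <- floor((y - grid$extent[3]) / cs) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows &
    is.finite(x) & is.finite(y)
  cell <- rep(NA_integer_, length(x))
  cell[ok] <- as.integer((col[ok] - 1) * grid$n_rows + row[ok])
  excl <- data.frame(id = ids[!ok], x = x[!ok], y = y[!ok])
  attr(cell, "exclusions") <- excl
  cell
}

#' Aggregate a pollutant over firms into cell-year totals
#'
#' Sums one pollutant over all firms assigned to each cell, separately per
#' year. A cell-year with no firms is reported as missing (`NA`), not zero:
#' absence of reporting firms is not evidence of zero emission, and the
#' interpolation stage fills such cells from their neighbourhood. Set
#' `empty = "zero"` to treat firm-free cell-years as true zeros instead.
#'
#' @param firms Data frame with at least `year` and the pollutant column.
#' @param cell Integer cell assignment from [assign_cells()] (NA = excluded).
#' @param grid A `pg_grid`.
#' @param pollutant One of `"wastewater"`, `"cod"`, `"so2"` (a column of
#'   `firms`).
#' @param empty `"missing"` (default) or `"zero"` for firm-free cell-years.
#' @return Numeric matrix, `n_cells` rows x years columns (dimnames give
#'   cell index and calendar year).
#' @export
aggregate_emissions <- function(firms, cell, grid, pollutant,
                                empty = c("missing", "zero")) {
  empty <- match.arg(empty)
  stopifnot(inherits(grid, "pg_grid"))
  if (!pollutant %in% c("wastewater", "cod", "so2"))
    stop("unknown pollutant: ", pollutant,
         " (expected wastewater, cod or so2)")
  if (!pollutant %in% names(firms)) stop("column not found in firms: ", pollutant)
  keep <- !is.na(cell)
  years <- sort(unique(firms$year))
  n_cells <- nrow(grid$cells)
  out <- matrix(if (empty == "missing") NA_real_ else 0,
                nrow = n_cells, ncol = length(years),
                dimnames = list(seq_len(n_cells), years))
  if (any(keep)) {
    v <- firms[[pollutant]][keep]
    agg <- tapply(v, list(factor(cell[keep], levels = seq_len(n_cells)),
                          factor(firms$year[keep], levels = years)),
                  sum)
    has <- !is.na(agg)
    out[has] <- agg[has]
  }
  out
}
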