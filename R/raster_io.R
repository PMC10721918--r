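# Raster output: georeferenced ESRI ASCII grids (plain text, readable by
# any GIS) plus PNG previews for quick inspection.

# cells-x-? vector to matrix in map orientation (top row = north)
.layer_to_matrix <- function(values, grid) {
  m <- matrix(NA_real_, nrow = grid$n_rows, ncol = grid$n_cols)
  m[cbind(grid$cells$row, grid$cells$col)] <- values
  m[rev(seq_len(grid$n_rows)), , drop = FALSE]
}

#' Write a cell layer as an ESRI ASCII grid
#'
#' Georeferenced plain-text raster (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south).
#'
#' @param values Numeric vector, one value per grid cell.
#' @param grid A `pg_grid`.
#' @param path Output path (conventionally `.asc`).
#' @param nodata Value written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "pg_grid"), length(values) == nrow(grid$cells))
  m <- .layer_to_matrix(values, grid)
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.6f", grid$extent[1]),
           sprintf("yllcorner %.6f", grid$extent[3]),
           sprintf("cellsize %.6f", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#' @param path File path.
#' @return List with `values` (matrix, north at top), `xllcorner`,
#'   `yllcorner`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " +")
  val <- function(i) as.numeric(hdr[[i]][2])
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  nodata <- val(6)
  m[m == nodata] <- NA
  list(values = m, xllcorner = val(3), yllcorner = val(4),
       cellsize = val(5), nodata = nodata)
}

# standard LISA palette: HH red, LL blue, HL pale red, LH pale blue,
# not-significant grey
.lisa_palette <- c(HH = "#D7191C", LL = "#2C7BB6", HL = "#F4A582",
                   LH = "#92C5DE", "not-significant" = "#D9D9D9")

#' Export a cell layer as a PNG heatmap
#'
#' Continuous layers use a monotone sequential palette (darker = higher);
#' categorical LISA label layers use the fixed five-colour HH/LL/HL/LH/
#' not-significant palette. Each cell maps to a `scale` x `scale` pixel
#' block.
#'
#' @param values Numeric vector (continuous) or character labels (LISA).
#' @param grid A `pg_grid`.
#' @param path Output PNG path.
#' @param scale Pixels per cell side (default 4).
#' @return `path`, invisibly.
#' @export
export_heatmap_png <- function(values, grid, path, scale = 4) {
  stopifnot(inherits(grid, "pg_grid"), length(values) == nrow(grid$cells))
  if (is.character(values) || is.factor(values)) {
    lab <- as.character(values)
    bad <- setdiff(unique(lab), names(.lisa_palette))
    if (length(bad)) stop("unknown LISA label(s): ", paste(bad, collapse = ", "))
    cols <- .lisa_palette[lab]
  } else {
    rng <- range(values, na.rm = TRUE)
    u <- if (rng[1] == rng[2]) rep(0.5, length(values))
         else (values - rng[1]) / (rng[2] - rng[1])
    ramp <- grDevices::colorRamp(c("#FFFFCC", "#FD8D3C", "#800026"))
    cols <- rep("#FFFFFF", length(values))
    ok <- !is.na(u)
    cols[ok] <- grDevices::rgb(ramp(u[ok]), maxColorValue = 255)
  }
  cm <- matrix(NA_character_, nrow = grid$n_rows, ncol = grid$n_cols)
  cm[cbind(grid$cells$row, grid$cells$col)] <- cols
  cm <- cm[rev(seq_len(grid$n_rows)), , drop = FALSE]
  cm[is.na(cm)] <- "#FFFFFF"
  rgb_arr <- grDevices::col2rgb(cm) / 255
  img <- array(0, dim = c(grid$n_rows, grid$n_cols, 3))
  img[, , 1] <- matrix(rgb_arr[1, ], grid$n_rows)
  img[, , 2] <- matrix(rgb_arr[2, ], grid$n_rows)
  img[, , 3] <- matrix(rgb_arr[3, ], grid$n_rows)
  big <- img[rep(seq_len(grid$n_rows), each = scale),
             rep(seq_len(grid$n_cols), each = scale), , drop = FALSE]
  png::writePNG(big, path)
  invisible(path)
}
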