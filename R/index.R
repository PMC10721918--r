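# Constant-quality emission indices: min-max normalisation of interpolated
# levels, regional mean series, and percent changes.

#' Normalise interpolated emission levels to constant-quality indices
#'
#' `Index = (r - min) / (max - min)` with the min and max pooled, by
#' default, over all cells and all years of the pollutant, so the index is
#' comparable across space *and* time (a cell-year at the pooled minimum
#' maps to 0, at the pooled maximum to 1). `pooling = "per_cell"` instead
#' anchors each cell to its own min/max over the years, which compares a
#' cell only to its own history.
#'
#' @param r Matrix of interpolated levels (cells x years) for one pollutant.
#' @param pooling `"pooled"` (default) or `"per_cell"`.
#' @return An object of class `index_panel`: list with `index` (matrix in
#'   `[0, 1]`, same shape as `r`), `min`, `max`, `pooling`. With a constant
#'   `r` all indices are 0 and a warning is raised.
#' @export
normalize_indices <- function(r, pooling = c("pooled", "per_cell")) {
  pooling <- match.arg(pooling)
  r <- as.matrix(r)
  if (any(!is.finite(r))) stop("interpolated levels must be finite everywhere")
  if (pooling == "pooled") {
    lo <- min(r); hi <- max(r)
    if (hi == lo) {
      warning("all interpolated levels equal; indices set to 0")
      idx <- array(0, dim = dim(r), dimnames = dimnames(r))
    } else {
      idx <- (r - lo) / (hi - lo)
    }
  } else {
    lo <- apply(r, 1, min); hi <- apply(r, 1, max)
    rng <- hi - lo
    flat <- rng == 0
    if (any(flat)) warning(sum(flat), " cell(s) with constant levels; their indices set to 0")
    rng[flat] <- 1
    idx <- (r - lo) / rng
    idx[flat, ] <- 0
  }
  structure(list(index = idx, min = lo, max = hi, pooling = pooling),
            class = "index_panel")
}

#' @export
print.index_panel <- function(x, ...) {
  cat(sprintf("index_panel: %d cells x %d years (%s min/max pooling)\n",
              nrow(x$index), ncol(x$index), x$pooling))
  invisible(x)
}

#' Regional mean index series
#'
#' Unweighted mean of cell indices per region and year; `"All"` averages
#' over every cell. Regions present in `regions` but holding zero cells are
#' dropped with a warning.
#'
#' @param panel An `index_panel` (or a plain cells-x-years index matrix).
#' @param regions Character vector of region labels, one per cell.
#' @return Data frame with columns `year`, `region`, `index`.
#' @export
regional_series <- function(panel, regions) {
  idx <- if (inherits(panel, "index_panel")) panel$index else as.matrix(panel)
  stopifnot(length(regions) == nrow(idx))
  years <- as.integer(colnames(idx))
  if (any(is.na(years))) years <- seq_len(ncol(idx))
  levs <- unique(regions[!is.na(regions)])
  out <- data.frame(year = years, region = "All",
                    index = colMeans(idx), row.names = NULL)
  for (rg in levs) {
    sel <- which(!is.na(regions) & regions == rg)
    if (length(sel) == 0) { warning("region with zero cells omitted: ", rg); next }
    out <- rbind(out, data.frame(year = years, region = rg,
                                 index = colMeans(idx[sel, , drop = FALSE]),
                                 row.names = NULL))
  }
  out
}

#' Percent change of a series between two years
#'
#' `100 * (v(t1) - v(t0)) / v(t0)`, the reporting convention for the
#' 1998-to-2012 index declines.
#'
#' @param series Named numeric vector (names = years) or the data frame
#'   from [regional_series()] (then `region` selects the series).
#' @param t0,t1 Years (must both be present).
#' @param region Region label when `series` is a data frame (default "All").
#' @return Percent change (a single number).
#' @export
index_change <- function(series, t0, t1, region = "All") {
  if (is.data.frame(series)) {
    s <- series[series$region == region, ]
    v <- stats::setNames(s$index, s$year)
  } else v <- series
  k0 <- as.character(t0); k1 <- as.character(t1)
  if (!k0 %in% names(v) || !k1 %in% names(v))
    stop("both years must be present in the series")
  if (v[[k0]] == 0) stop("series is zero at the base year; percent change undefined")
  100 * (v[[k1]] - v[[k0]]) / v[[k0]]
}
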