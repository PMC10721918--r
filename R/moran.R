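# Spatial autocorrelation on the raster: contiguity weights, global
# Moran's I, Anselin's Local Moran's I (LISA) with conditional permutation
# inference, and cluster-class labelling.

#' Contiguity weights on a raster grid
#'
#' Queen contiguity (default) links the 8 surrounding cells, rook the 4
#' edge neighbours. `cells` restricts the structure to a subset of cells
#' (e.g. cells with data); neighbour relations are computed within the
#' subset, so excluded cells neither give nor receive weight. Cells left
#' without neighbours are flagged as islands.
#'
#' @param grid A `pg_grid`.
#' @param scheme `"queen"` or `"rook"`.
#' @param style `"W"` row-standardised (each row sums to 1) or `"B"` binary.
#' @param cells Optional integer vector of cell indices to keep.
#' @return An object of class `spatial_weights`: `nb` (list of neighbour
#'   positions, indexing into `cells`), `w` (matching weight lists), `n`,
#'   `S0` (sum of all weights), `cells`, `islands`, `scheme`, `style`.
#' @export
build_contiguity_weights <- function(grid, scheme = c("queen", "rook"),
                                     style = c("W", "B"), cells = NULL) {
  scheme <- match.arg(scheme)
  style <- match.arg(style)
  stopifnot(inherits(grid, "pg_grid"))
  if (is.null(cells)) cells <- grid$cells$cell
  cells <- sort(unique(as.integer(cells)))
  n <- length(cells)
  if (n < 2) stop("at least two cells are required for spatial weights")
  row <- grid$cells$row[cells]
  col <- grid$cells$col[cells]
  pos <- stats::setNames(seq_len(n), paste(row, col))
  offs <- if (scheme == "queen")
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    keys <- paste(row[i] + offs[, 1], col[i] + offs[, 2])
    hit <- pos[keys]
    nb[[i]] <- sort(unname(hit[!is.na(hit)]))
  }
  islands <- which(lengths(nb) == 0)
  w <- lapply(nb, function(j) {
    if (length(j) == 0) return(numeric(0))
    if (style == "W") rep(1 / length(j), length(j)) else rep(1, length(j))
  })
  ii <- rep(seq_len(n), lengths(nb))
  structure(list(nb = nb, w = w, n = n, S0 = sum(unlist(w)), cells = cells,
                 islands = islands, scheme = scheme, style = style,
                 ii = ii, jj = unlist(nb), ww = unlist(w)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d cells, %s contiguity, style %s, S0 = %g",
              x$n, x$scheme, x$style, x$S0))
  if (length(x$islands)) cat(sprintf(", %d island(s)", length(x$islands)))
  cat("\n")
  invisible(x)
}

# spatial lag of a vector under a weights object (triplet form, so the
# permutation loops stay vectorised)
.lag <- function(W, v) {
  out <- numeric(W$n)
  s <- rowsum(W$ww * v[W$jj], W$ii)
  out[as.integer(rownames(s))] <- s
  out
}

.moran_stat <- function(z, W) {
  (W$n / W$S0) * sum(W$ww * z[W$ii] * z[W$jj]) / sum(z^2)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' The pseudo p-value comes from random permutations of the values over the
#' cells (one-sided, in the direction of the observed departure from the
#' expectation `E[I] = -1/(n-1)`), `p = (1 + #{as or more extreme}) /
#' (n_perm + 1)`.
#'
#' @param x Numeric values, one per cell of `W` (finite, non-constant).
#' @param W A `spatial_weights` object.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `moran_global`: `I`, `expectation`, `p_value`,
#'   `n_perm`, `seed`, `n`.
#' @export
global_morans_i <- function(x, W, n_perm = 999, seed = 1L) {
  stopifnot(inherits(W, "spatial_weights"), length(x) == W$n)
  if (any(!is.finite(x))) stop("values must be finite")
  if (stats::var(x) == 0) stop("constant field has no autocorrelation")
  z <- x - mean(x)
  I_obs <- .moran_stat(z, W)
  E_I <- -1 / (W$n - 1)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    I_perm <- vapply(seq_len(n_perm), function(b) .moran_stat(sample(z), W),
                     numeric(1))
    extreme <- if (I_obs >= E_I) sum(I_perm >= I_obs) else sum(I_perm <= I_obs)
    p <- (1 + extreme) / (n_perm + 1)
  }
  structure(list(I = I_obs, expectation = E_I, p_value = p,
                 n_perm = n_perm, seed = seed, n = W$n),
            class = "moran_global")
}

#' @export
print.moran_global <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f, pseudo p = %s, %d permutations)\n",
              x$I, x$expectation, format.pval(x$p_value), x$n_perm))
  invisible(x)
}

#' Anselin's Local Moran's I (LISA)
#'
#' `I_i = (x_i - xbar)/m2 * sum_j w_ij (x_j - xbar)` with
#' `m2 = sum_k (x_k - xbar)^2 / n`. Under row-standardised weights the
#' local statistics satisfy `sum_i I_i = n * I`. Inference is by
#' conditional permutation: cell i's value is held fixed while its
#' neighbour values are drawn from the remaining cells, `n_perm` times;
#' the pseudo p-value is one-sided in the direction of each cell's
#' departure from its permutation mean. Quadrants classify each cell by
#' the sign of its deviation and of its spatial lag: HH, LL, HL
#' (high-surrounded-by-low) and LH.
#'
#' @inheritParams global_morans_i
#' @param n_perm Number of conditional permutations (default 999).
#' @return Object of class `moran_local`: data frame `local` with columns
#'   `cell`, `I_i`, `quadrant`, `p_value`, plus `I` (global), `n_perm`,
#'   `seed`.
#' @export
local_morans_i <- function(x, W, n_perm = 999, seed = 1L) {
  stopifnot(inherits(W, "spatial_weights"), length(x) == W$n)
  if (any(!is.finite(x))) stop("values must be finite")
  if (stats::var(x) == 0) stop("constant field has no autocorrelation")
  n <- W$n
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- .lag(W, z)
  I_i <- z / m2 * lag
  quadrant <- ifelse(z > 0,
                     ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  p <- rep(NA_real_, n)
  if (n_perm > 0) {
    set.seed(seed)
    for (i in seq_len(n)) {
      j <- W$nb[[i]]
      if (length(j) == 0) next
      others <- z[-i]
      wij <- W$w[[i]]
      k <- length(j)
      lag_perm <- vapply(seq_len(n_perm), function(b)
        sum(wij * others[sample.int(n - 1, k)]), numeric(1))
      I_perm <- z[i] / m2 * lag_perm
      extreme <- if (I_i[i] >= mean(I_perm)) sum(I_perm >= I_i[i])
                 else sum(I_perm <= I_i[i])
      p[i] <- (1 + extreme) / (n_perm + 1)
    }
  }
  structure(list(local = data.frame(cell = W$cells, I_i = I_i,
                                    quadrant = quadrant, p_value = p,
                                    stringsAsFactors = FALSE),
                 I = .moran_stat(z, W), n_perm = n_perm, seed = seed),
            class = "moran_local")
}

#' @export
print.moran_local <- function(x, ...) {
  cat(sprintf("Local Moran's I for %d cells (global I = %.4f, %d permutations)\n",
              nrow(x$local), x$I, x$n_perm))
  print(table(x$local$quadrant))
  invisible(x)
}

#' Label LISA cluster classes at a significance level
#'
#' A cell keeps its quadrant label when its conditional-permutation pseudo
#' p-value is at or below `alpha`, otherwise it is `"not-significant"`.
#'
#' @param result A `moran_local` object.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Character vector of labels (`HH`, `LL`, `HL`, `LH`,
#'   `not-significant`), one per cell.
#' @export
classify_clusters <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "moran_local"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  p <- result$local$p_value
  ifelse(!is.na(p) & p <= alpha, result$local$quadrant, "not-significant")
}
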