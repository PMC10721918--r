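# Modified Shepard scattered-data interpolation (Franke-Nielson/Renka
# construction): local weighted-least-squares quadratic nodal functions
# blended with compactly supported inverse-distance weights. Exact at the
# data nodes, continuous, and reproduces any bivariate quadratic when the
# nodal fits see enough neighbours.

#' Fit a Modified Shepard interpolant to scattered planar data
#'
#' For every node k a quadratic "nodal function"
#' `Q_k(x, y) = z_k + c1*dx + c2*dy + c3*dx^2 + c4*dx*dy + c5*dy^2`
#' (dx, dy relative to the node) is fitted by weighted least squares to the
#' `nq` nearest other nodes; the constant term is pinned to the node's own
#' value so `Q_k` interpolates it exactly. Fit weights decay with distance
#' and vanish at the neighbourhood radius `Rq_k` (the distance to the
#' `nq`-th neighbour). With fewer than 5 usable neighbours the fit degrades
#' to linear (>= 2 neighbours) and then to a constant.
#'
#' Coincident nodes (distance < `tol`) with equal values are merged; with
#' conflicting values they are rejected.
#'
#' @param x,y Node coordinates (planar, km).
#' @param z Node values.
#' @param nq Number of neighbours for the quadratic nodal fits (default 13).
#' @param nw Number of neighbours defining each node's blending radius
#'   (default 19).
#' @param tol Distance below which two nodes count as coincident.
#' @return An object of class `modified_shepard`.
#' @seealso [predict.modified_shepard()]
#' @export
fit_shepard <- function(x, y, z, nq = 13, nw = 19, tol = 1e-9) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  if (length(x) < 1) stop("at least one node is required")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("node coordinates and values must be finite")
  if (nq < 5) stop("nq must be at least 5 for quadratic nodal fits")
  if (nw < 1) stop("nw must be at least 1")

  # deduplicate coincident nodes
  if (length(x) > 1) {
    o <- order(x, y)
    xs <- x[o]; ys <- y[o]; zs <- z[o]
    dup <- c(FALSE, abs(diff(xs)) < tol & abs(diff(ys)) < tol)
    if (any(dup)) {
      conflict <- dup & c(FALSE, abs(diff(zs)) > tol)
      if (any(conflict)) {
        i <- which(conflict)[1]
        stop(sprintf(
          "coincident nodes with conflicting values at (%.6g, %.6g): %g vs %g",
          xs[i], ys[i], zs[i - 1], zs[i]))
      }
      x <- xs[!dup]; y <- ys[!dup]; z <- zs[!dup]
    }
  }

  n <- length(x)
  coefs <- matrix(0, nrow = n, ncol = 5)
  rq <- rw <- numeric(n)
  if (n == 1) {
    rq[] <- rw[] <- Inf
  } else {
    D <- as.matrix(stats::dist(cbind(x, y)))
    for (k in seq_len(n)) {
      d <- D[k, -k]
      idx <- order(d)
      ds <- d[idx]
      m <- length(ds)
      # radius of the quadratic-fit neighbourhood; if every node is closer
      # than nq-th would be, push the radius past the farthest so all get
      # positive weight
      rq[k] <- if (m > nq) ds[nq] else 1.1 * ds[m]
      rw[k] <- if (m > nw) ds[nw] else 1.1 * ds[m]
      nb <- which(d < rq[k] - .Machine$double.eps)
      w <- ((rq[k] - d[nb]) / (rq[k] * d[nb]))^2
      dx <- x[-k][nb] - x[k]
      dy <- y[-k][nb] - y[k]
      dz <- z[-k][nb] - z[k]
      coefs[k, ] <- .nodal_fit(dx, dy, dz, w)
    }
  }
  structure(list(x = x, y = y, z = z, coefs = coefs, rq = rq, rw = rw,
                 nq = nq, nw = nw, n = n),
            class = "modified_shepard")
}

# Weighted LS fit of dz on (dx, dy, dx^2, dx*dy, dy^2), no intercept,
# degrading quadratic -> linear -> constant when the design is too thin or
# rank-deficient. Returns length-5 coefficient vector.
.nodal_fit <- function(dx, dy, dz, w) {
  out <- numeric(5)
  m <- length(dx)
  if (m == 0) return(out)
  sw <- sqrt(w)
  try_fit <- function(X, p) {
    qr_ <- qr(X * sw)
    if (qr_$rank < p) return(NULL)
    qr.coef(qr_, dz * sw)
  }
  if (m >= 5) {
    b <- try_fit(cbind(dx, dy, dx^2, dx * dy, dy^2), 5L)
    if (!is.null(b)) { out[] <- b; return(out) }
  }
  if (m >= 2) {
    b <- try_fit(cbind(dx, dy), 2L)
    if (!is.null(b)) { out[1:2] <- b; return(out) }
  }
  out
}

#' Evaluate a Modified Shepard interpolant
#'
#' Blends the nodal functions with the compactly supported weights
#' `W_k(q) = ((R_k - d_k)_+ / (R_k * d_k))^2`, `R_k` being node k's
#' blending radius: `F(q) = sum W_k Q_k(q) / sum W_k`. At a node the weight
#' diverges, so the node value is returned exactly. At query points outside
#' every node's radius the value of the nearest node is returned (documented
#' far-field fallback).
#'
#' @param object A `modified_shepard` fit.
#' @param x,y Query coordinates.
#' @param ... Unused.
#' @return Numeric vector of interpolated values.
#' @export
predict.modified_shepard <- function(object, x, y, ...) {
  stopifnot(length(x) == length(y))
  n <- object$n
  out <- numeric(length(x))
  for (q in seq_along(x)) {
    dx <- x[q] - object$x
    dy <- y[q] - object$y
    d <- sqrt(dx^2 + dy^2)
    hit <- which(d < 1e-9)
    if (length(hit)) { out[q] <- object$z[hit[1]]; next }
    wk <- numeric(n)
    inside <- d < object$rw
    fin <- inside & is.finite(object$rw)
    wk[fin] <- ((object$rw[fin] - d[fin]) / (object$rw[fin] * d[fin]))^2
    # an unbounded radius (tiny node sets) degrades to plain inverse-distance
    wk[inside & !is.finite(object$rw)] <- 1 / d[inside & !is.finite(object$rw)]^2
    if (!any(wk > 0)) { out[q] <- object$z[which.min(d)]; next }
    qv <- object$z + object$coefs[, 1] * dx + object$coefs[, 2] * dy +
      object$coefs[, 3] * dx^2 + object$coefs[, 4] * dx * dy +
      object$coefs[, 5] * dy^2
    out[q] <- sum(wk * qv) / sum(wk)
  }
  out
}

#' @export
print.modified_shepard <- function(x, ...) {
  cat(sprintf("Modified Shepard interpolant: %d nodes (nq = %d, nw = %d)\n",
              x$n, x$nq, x$nw))
  invisible(x)
}

#' Interpolate one pollutant-year cell surface
#'
#' Takes the per-cell aggregates for a single pollutant and year (missing
#' cells `NA`), fits the Modified Shepard interpolant on the centroids of
#' the non-missing cells, and evaluates it at every cell centroid. Cells
#' that had data keep their aggregate exactly (interpolation exactness);
#' negative interpolated values are clamped to zero since emission levels
#' are physical quantities.
#'
#' @param values Numeric vector, one aggregate per grid cell (`NA` missing).
#' @param grid A `pg_grid`.
#' @param nq,nw Modified Shepard neighbourhood sizes, see [fit_shepard()].
#' @return Numeric vector of interpolated levels `r_i`, one per cell.
#' @export
build_surface <- function(values, grid, nq = 13, nw = 19) {
  stopifnot(inherits(grid, "pg_grid"), length(values) == nrow(grid$cells))
  obs <- which(!is.na(values))
  if (length(obs) == 0) stop("all cells are missing; cannot interpolate this year")
  if (length(obs) == 1) return(rep(values[obs], nrow(grid$cells)))
  fit <- fit_shepard(grid$cells$cx[obs], grid$cells$cy[obs], values[obs],
                     nq = nq, nw = nw)
  r <- predict(fit, grid$cells$cx, grid$cells$cy)
  r[obs] <- values[obs]
  pmax(r, 0)
}

#' Interpolate surfaces for all years of one pollutant
#'
#' @param agg Cell-by-year aggregate matrix from [aggregate_emissions()].
#' @inheritParams build_surface
#' @return Matrix of interpolated levels, same shape and dimnames as `agg`.
#' @export
build_surfaces <- function(agg, grid, nq = 13, nw = 19) {
  out <- agg
  for (j in seq_len(ncol(agg))) out[, j] <- build_surface(agg[, j], grid, nq, nw)
  out
}
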