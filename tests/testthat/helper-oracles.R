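# Independent oracles used across the suite. Each is a deliberately naive
# implementation (loops, closed forms) kept separate from the package's
# code paths.

# O(n^2) double-sum global Moran's I straight from the definition
bf_global_moran <- function(x, W) {
  n <- W$n
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) {
    nb <- W$nb[[i]]
    for (k in seq_along(nb)) num <- num + W$w[[i]][k] * z[i] * z[nb[k]]
  }
  (n / W$S0) * num / sum(z^2)
}

# brute-force point-in-rectangle cell lookup
bf_assign_cells <- function(x, y, grid) {
  cells <- grid$cells
  cs <- grid$cell_size
  out <- rep(NA_integer_, length(x))
  for (q in seq_along(x)) {
    for (i in seq_len(nrow(cells))) {
      xl <- cells$cx[i] - cs / 2; yb <- cells$cy[i] - cs / 2
      if (x[q] >= xl && x[q] < xl + cs && y[q] >= yb && y[q] < yb + cs) {
        out[q] <- cells$cell[i]; break
      }
    }
  }
  out
}

# all-pairs haversine buffer scan
bf_assign_buffers <- function(firms, villages, inner = 40, outer = 80) {
  f <- firms[!duplicated(firms$firm_id), ]
  out <- data.frame(firm_id = f$firm_id, distance_km = NA_real_,
                    buffer = NA_integer_)
  for (i in seq_len(nrow(f))) {
    d <- Inf; best <- NA
    for (j in order(villages$village_id)) {
      dj <- pollugrid::haversine_km(f$lon[i], f$lat[i],
                                    villages$lon[j], villages$lat[j])
      if (dj < d) { d <- dj; best <- j }
    }
    out$distance_km[i] <- d
    out$buffer[i] <- if (d <= inner) 1L else if (d <= outer) 0L else NA_integer_
  }
  out
}

# closed-form Welch t statistic
bf_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# iterative two-way within-demeaning (alternating projections) that
# reproduces the slopes of the corresponding dummy-variable OLS
demean_fit <- function(y, X, f1, f2 = NULL, tol = 1e-12, maxit = 500) {
  M <- cbind(y, X)
  for (it in seq_len(maxit)) {
    before <- M
    M <- M - apply(M, 2, function(v) ave(v, f1))
    if (!is.null(f2)) M <- M - apply(M, 2, function(v) ave(v, f2))
    if (max(abs(M - before)) < tol) break
  }
  yd <- M[, 1]; Xd <- M[, -1, drop = FALSE]
  qr.coef(qr(Xd), yd)
}

# hand-rolled CR1 cluster sandwich by explicit cluster loops
bf_cr1 <- function(X, e, cluster) {
  cl <- unique(cluster)
  K <- ncol(X); N <- nrow(X); G <- length(cl)
  meat <- matrix(0, K, K)
  for (g in cl) {
    rows <- which(cluster == g)
    s <- t(X[rows, , drop = FALSE]) %*% e[rows]
    meat <- meat + s %*% t(s)
  }
  bread <- solve(t(X) %*% X)
  G / (G - 1) * (N - 1) / (N - K) * bread %*% meat %*% bread
}

# independent cells-to-matrix layout (north at top) for raster round-trips
.layer_to_matrix_for_test <- function(values, grid) {
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  m[cbind(grid$cells$row, grid$cells$col)] <- values
  m[rev(seq_len(grid$n_rows)), , drop = FALSE]
}

png_colour_count <- function(path) {
  img <- png::readPNG(path)
  keys <- apply(round(img * 255), c(1, 2), paste0, collapse = "-")
  length(unique(as.vector(keys)))
}
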