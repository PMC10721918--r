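# Shared regression machinery: OLS with dummy-absorbed fixed effects,
# plain and CR1 cluster-robust covariance, tidy coefficient tables and a
# journal-style text formatter.

# CR1 cluster-robust covariance for an lm fit: sandwich with cluster score
# sums and the finite-sample factor G/(G-1) * (N-1)/(N-K).
.cluster_vcov_cr1 <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  keep <- !is.na(stats::coef(fit))
  X <- X[, keep, drop = FALSE]
  e <- stats::residuals(fit)
  cluster <- droplevels(as.factor(cluster))
  if (length(cluster) != nrow(X))
    stop("cluster vector length must match the estimation sample")
  Xe <- X * e
  S <- rowsum(Xe, cluster)           # G x K matrix of cluster score sums
  meat <- crossprod(S)
  bread <- chol2inv(chol(crossprod(X)))
  G <- nlevels(cluster); N <- nrow(X); K <- ncol(X)
  adj <- G / (G - 1) * (N - 1) / (N - K)
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# Build a pollreg object out of an lm fit. fe_terms are reported only as
# absorbed factor sets, not as rows of the coefficient table.
.make_pollreg <- function(fit, se_type, cluster = NULL, fe_terms = character(0),
                          call = sys.call(-1)) {
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  keep <- !is.na(cf)
  V <- if (se_type == "cluster") .cluster_vcov_cr1(fit, cluster)
       else suppressWarnings(stats::vcov(fit, complete = FALSE))
  est <- cf[keep]
  se <- sqrt(diag(V))
  df <- if (se_type == "cluster") nlevels(droplevels(as.factor(cluster))) - 1
        else fit$df.residual
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  tab <- data.frame(term = names(est), estimate = unname(est),
                    std_error = unname(se), t_value = unname(tval),
                    p_value = unname(pval), stringsAsFactors = FALSE)
  is_fe <- rep(FALSE, nrow(tab))
  for (f in fe_terms) is_fe <- is_fe | startsWith(tab$term, f)
  structure(list(coefficients = tab[!is_fe, , drop = FALSE],
                 fe_coefficients = tab[is_fe, , drop = FALSE],
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 nobs = stats::nobs(fit),
                 dropped = dropped, se_type = se_type,
                 fe_terms = fe_terms, vcov = V, df = df,
                 lm_fit = fit, call = call),
            class = "pollreg")
}

#' @export
coef.pollreg <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.pollreg <- function(object, ...) object$vcov

#' @export
nobs.pollreg <- function(object, ...) object$nobs

#' @export
print.pollreg <- function(x, digits = 4, ...) {
  cat(sprintf("Fixed-effects OLS (%s standard errors), N = %d, R-squared = %.3f\n",
              x$se_type, x$nobs, x$r_squared))
  if (length(x$fe_terms))
    cat("Absorbed fixed effects:", paste(x$fe_terms, collapse = ", "), "\n")
  tab <- x$coefficients
  tab$stars <- .stars(tab$p_value)
  print(format(tab, digits = digits), row.names = FALSE)
  if (length(x$dropped))
    cat("Dropped (collinear):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pollreg <- function(object, ...) object

.stars <- function(p) ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                      ifelse(p < 0.1, "*", "")))

#' Format regression results as a journal-style text table
#'
#' Coefficients with significance stars (***p < 0.01, **p < 0.05,
#' *p < 0.1) over parenthesised standard errors, one column per fitted
#' model, with observation counts and R-squared at the foot.
#'
#' @param ... `pollreg` objects (named arguments become column headers).
#' @param terms Optional term subset/order; default: union of all terms.
#' @return Character vector of table lines (print with `cat(x, sep =
#'   "\n")`).
#' @export
format_regression_table <- function(..., terms = NULL) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("(", seq_along(fits), ")")
  if (is.null(terms))
    terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  wid <- max(nchar(terms), 12)
  fmt_cell <- function(f, tm) {
    i <- match(tm, f$coefficients$term)
    if (is.na(i)) return(c("", ""))
    c(sprintf("%.3f%s", f$coefficients$estimate[i], .stars(f$coefficients$p_value[i])),
      sprintf("(%.3f)", f$coefficients$std_error[i]))
  }
  header <- sprintf("%-*s %s", wid, "", paste(sprintf("%12s", names(fits)), collapse = " "))
  lines <- header
  for (tm in terms) {
    cells <- lapply(fits, fmt_cell, tm = tm)
    lines <- c(lines,
               sprintf("%-*s %s", wid, tm,
                       paste(sprintf("%12s", vapply(cells, `[`, "", 1)), collapse = " ")),
               sprintf("%-*s %s", wid, "",
                       paste(sprintf("%12s", vapply(cells, `[`, "", 2)), collapse = " ")))
  }
  lines <- c(lines,
             sprintf("%-*s %s", wid, "Observations",
                     paste(sprintf("%12d", vapply(fits, function(f) f$nobs, 1L)), collapse = " ")),
             sprintf("%-*s %s", wid, "R-squared",
                     paste(sprintf("%12.3f", vapply(fits, function(f) f$r_squared, 1)), collapse = " ")),
             "*** p < 0.01; ** p < 0.05; * p < 0.1")
  lines
}
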