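# Regime-shift analysis: grid-panel trend regressions per Five-Year-Plan
# window with cell fixed effects and cluster-robust errors, and the
# cross-window sign contrast.

#' Five-Year-Plan regression windows
#'
#' The 10th FYP covers 2001-2005, the 11th FYP 2006-2010.
#' @param label `"FYP10"` or `"FYP11"`.
#' @return Integer vector of years.
#' @export
fyp_window <- function(label = c("FYP10", "FYP11")) {
  label <- match.arg(label)
  if (label == "FYP10") 2001:2005 else 2006:2010
}

#' Grid-panel trend regression for one FYP window
#'
#' OLS of a pollutant's index on the (centred) year trend, optionally the
#' `year x east` interaction, and the province controls `gdppc`,
#' `secondary`, `tertiary`, `urbanrate`, absorbing cell fixed effects:
#' `Index_it = a + b1 year_t x east_i + b2 year_t + X_kt G + lambda_i +
#' e_it`. Standard errors are CR1 cluster-robust, clustered at the cell.
#' The year enters as calendar year minus the window's first year, which
#' moves only the intercept. The `east` main effect is constant within a
#' cell and therefore absorbed by the cell fixed effects; only the
#' interaction is estimated.
#'
#' @param panel Data frame with `cell`, `year`, `east`, the index column,
#'   and the four province controls.
#' @param index_col Name of the index column (default `"index"`).
#' @param window Either a `"FYP10"`/`"FYP11"` label or an integer year
#'   vector; the panel is restricted to it.
#' @param interaction Include `year x east` (default TRUE). Dropped with a
#'   message when `east` does not vary across cells.
#' @param controls Province control columns (intersected with the panel).
#' @param se `"cluster"` (default, CR1 by cell) or `"plain"`.
#' @return A [`pollreg`][print.pollreg] object; the trend term is named
#'   `year_c`, the interaction `year_c:east`.
#' @export
fit_grid_panel_regression <- function(panel, index_col = "index",
                                      window = "FYP10", interaction = TRUE,
                                      controls = c("gdppc", "secondary",
                                                   "tertiary", "urbanrate"),
                                      se = c("cluster", "plain")) {
  se <- match.arg(se)
  years <- if (is.character(window)) fyp_window(window) else as.integer(window)
  d <- panel[panel$year %in% years, , drop = FALSE]
  if (length(unique(d$year)) < 2)
    stop("trend unidentified: the window holds fewer than two years")
  if (length(unique(d$cell)) < 2) stop("at least two cells are required")
  if (!index_col %in% names(d)) stop("index column not found: ", index_col)
  controls <- intersect(controls, names(d))
  d$.y <- d[[index_col]]
  d$year_c <- d$year - min(years)
  if (interaction && length(unique(d$east)) < 2) {
    message("east does not vary; year x east interaction dropped")
    interaction <- FALSE
  }
  rhs <- c("year_c", if (interaction) "year_c:east", controls, "factor(cell)")
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  cl <- d$cell
  if (!is.null(fit$na.action)) cl <- cl[-fit$na.action]
  res <- .make_pollreg(fit, se_type = se,
                       cluster = if (se == "cluster") cl,
                       fe_terms = "factor(cell)", call = match.call())
  res$window <- years
  res$index_col <- index_col
  res
}

#' Contrast trend signs across the two FYP windows
#'
#' Summarises the sign and significance of the year trend and the
#' `year x east` interaction in each window and flags a regime shift when
#' the trend changes sign between windows with both coefficients
#' significant at `alpha`; an interaction sign flip is flagged
#' analogously.
#'
#' @param fit10,fit11 `pollreg` fits of the same pollutant for the 10th
#'   and 11th FYP windows (from [fit_grid_panel_regression()]).
#' @param alpha Significance level for calling a coefficient significant
#'   (default 0.1, the published tables' loosest star).
#' @return Object of class `regime_contrast`: per-window sign/p summary,
#'   `trend_shift` and `interaction_shift` flags.
#' @export
regime_contrast <- function(fit10, fit11, alpha = 0.1) {
  stopifnot(inherits(fit10, "pollreg"), inherits(fit11, "pollreg"))
  if (!identical(fit10$index_col, fit11$index_col))
    stop("the two fits are for different outcome columns: ",
         fit10$index_col, " vs ", fit11$index_col)
  pick <- function(f, term) {
    i <- match(term, f$coefficients$term)
    if (is.na(i)) return(c(est = NA_real_, p = NA_real_))
    c(est = f$coefficients$estimate[i], p = f$coefficients$p_value[i])
  }
  y10 <- pick(fit10, "year_c"); y11 <- pick(fit11, "year_c")
  x10 <- pick(fit10, "year_c:east"); x11 <- pick(fit11, "year_c:east")
  sig <- function(v) !is.na(v["p"]) && v["p"] <= alpha
  flip <- function(a, b) !is.na(a["est"]) && !is.na(b["est"]) &&
    sign(a["est"]) != sign(b["est"]) && sign(a["est"]) != 0
  trend_shift <- flip(y10, y11) && sig(y10) && sig(y11)
  interaction_shift <- flip(x10, x11) && sig(x10) && sig(x11)
  structure(list(
    summary = data.frame(
      window = c("FYP10", "FYP11"),
      year = c(y10["est"], y11["est"]),
      year_p = c(y10["p"], y11["p"]),
      year_x_east = c(x10["est"], x11["est"]),
      year_x_east_p = c(x10["p"], x11["p"]),
      row.names = NULL),
    trend_shift = trend_shift, interaction_shift = interaction_shift,
    alpha = alpha), class = "regime_contrast")
}

#' @export
print.regime_contrast <- function(x, ...) {
  print(format(x$summary, digits = 4), row.names = FALSE)
  cat(if (x$trend_shift) "Regime shift detected: the year trend flips sign between windows.\n"
      else "No trend regime shift between windows.\n")
  if (!all(is.na(x$summary$year_x_east)))
    cat(if (x$interaction_shift) "East differential also flips sign.\n"
        else "No sign flip in the East differential.\n")
  invisible(x)
}

#' Assemble the grid-level regression panel
#'
#' Joins an index panel with the grid's region labels and province
#' covariates into the long data frame the regime regressions consume.
#' Each cell's province is taken from the modal province of the firms it
#' contains (cells without firms inherit the province of the nearest firm).
#'
#' @param panel An `index_panel` (or cells-x-years index matrix).
#' @param grid A `pg_grid` with region labels.
#' @param firms Firm data frame with planar `x`, `y` and `province`.
#' @param cell Cell assignment of the firms (from [assign_cells()]).
#' @param covariates Province-year covariate table
#'   ([simulate_city_covariates()] schema).
#' @return Long data frame: `cell`, `year`, `east`, `province`, controls,
#'   `index`.
#' @export
build_grid_regression_panel <- function(panel, grid, firms, cell, covariates) {
  idx <- if (inherits(panel, "index_panel")) panel$index else as.matrix(panel)
  cells <- grid$cells
  stopifnot(nrow(idx) == nrow(cells))
  firsts <- firms[!duplicated(firms$firm_id), ]
  cell1 <- cell[!duplicated(firms$firm_id)]
  modal <- function(v) names(sort(table(v), decreasing = TRUE))[1]
  prov_by_cell <- tapply(firsts$province, cell1, modal)
  province <- rep(NA_character_, nrow(cells))
  province[as.integer(names(prov_by_cell))] <- unname(prov_by_cell)
  empty <- which(is.na(province))
  if (length(empty)) {
    for (i in empty) {
      d2 <- (firsts$x - cells$cx[i])^2 + (firsts$y - cells$cy[i])^2
      province[i] <- firsts$province[which.min(d2)]
    }
  }
  years <- as.integer(colnames(idx))
  out <- data.frame(cell = rep(cells$cell, times = length(years)),
                    year = rep(years, each = nrow(cells)),
                    east = rep(as.integer(cells$region == "East"), length(years)),
                    province = rep(province, length(years)),
                    index = as.vector(idx),
                    stringsAsFactors = FALSE)
  merge(out, covariates[, c("province", "year", "gdppc", "secondary",
                            "tertiary", "urbanrate")],
        by = c("province", "year"), all.x = TRUE, sort = FALSE)
}
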