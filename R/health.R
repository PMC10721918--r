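# Cancer-village proximity analysis: buffer-ring assignment, covariate
# balance, and the firm-level fixed-effects pollutant regression.

#' Assign firms to cancer-village buffer rings
#'
#' Distance is the haversine distance to the nearest village centroid
#' (ties broken by the smallest village id). Firms within `inner_km` get
#' `buffer = 1` (treated ring), firms between `inner_km` and `outer_km`
#' get `buffer = 0` (control annulus), and firms beyond `outer_km` are
#' excluded from the regression sample (`buffer = NA`).
#'
#' @param firms Data frame with `firm_id`, `lon`, `lat` (one row per firm;
#'   firm-year panels are collapsed on `firm_id` first).
#' @param villages Data frame with `village_id`, `lon`, `lat`.
#' @param inner_km,outer_km Ring radii in km (defaults 40 and 80).
#' @return Data frame `firm_id`, `distance_km`, `nearest_village`,
#'   `buffer` (1, 0 or `NA` = excluded).
#' @export
assign_buffers <- function(firms, villages, inner_km = 40, outer_km = 80) {
  if (is.null(villages) || nrow(villages) == 0)
    stop("village list is empty; buffer assignment requires at least one village")
  stopifnot(inner_km > 0, outer_km > inner_km)
  f <- firms[!duplicated(firms$firm_id), c("firm_id", "lon", "lat")]
  v <- villages[order(villages$village_id), ]
  D <- outer(seq_len(nrow(f)), seq_len(nrow(v)), function(i, j)
    haversine_km(f$lon[i], f$lat[i], v$lon[j], v$lat[j]))
  nearest <- apply(D, 1, which.min)    # which.min takes the first = lowest id on ties
  dist <- D[cbind(seq_len(nrow(f)), nearest)]
  buffer <- ifelse(dist <= inner_km, 1L, ifelse(dist <= outer_km, 0L, NA_integer_))
  data.frame(firm_id = f$firm_id, distance_km = dist,
             nearest_village = v$village_id[nearest], buffer = buffer,
             stringsAsFactors = FALSE)
}

#' Covariate balance between buffer rings (Welch t-tests)
#'
#' Welch two-sample t-test of each covariate between the inner-ring
#' (`buffer = 1`) and annulus (`buffer = 0`) groups, the standard check
#' that treated and control areas are otherwise comparable.
#'
#' @param data Data frame of unit covariates including a `buffer` column
#'   (1/0; `NA` rows are dropped).
#' @param covariates Character vector of covariate column names.
#' @return Data frame: `covariate`, `mean_inner`, `mean_outer`, `t`, `df`,
#'   `p_value`. A covariate whose groups have fewer than 2 usable values
#'   is reported as `NA` with a warning.
#' @export
covariate_balance_test <- function(data, covariates) {
  g1 <- data$buffer %in% 1
  g0 <- data$buffer %in% 0
  if (!any(g1) || !any(g0)) stop("both buffer groups must be non-empty")
  out <- lapply(covariates, function(cv) {
    x1 <- data[[cv]][g1]; x0 <- data[[cv]][g0]
    x1 <- x1[is.finite(x1)]; x0 <- x0[is.finite(x0)]
    if (length(x1) < 2 || length(x0) < 2 ||
        (stats::sd(x1) == 0 && stats::sd(x0) == 0 && mean(x1) == mean(x0))) {
      # t.test errors on identical constant data; identical samples mean
      # perfect balance, so report t = 0, p = 1 rather than failing
      if (length(x1) >= 2 && length(x0) >= 2)
        return(data.frame(covariate = cv, mean_inner = mean(x1),
                          mean_outer = mean(x0), t = 0, df = NA_real_,
                          p_value = 1))
      warning("covariate skipped (group with < 2 values): ", cv)
      return(data.frame(covariate = cv, mean_inner = NA_real_,
                        mean_outer = NA_real_, t = NA_real_, df = NA_real_,
                        p_value = NA_real_))
    }
    tt <- stats::t.test(x1, x0)
    data.frame(covariate = cv, mean_inner = mean(x1), mean_outer = mean(x0),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  do.call(rbind, out)
}

#' Firm-level covariate presets for the pollutant regression
#'
#' `"table1"` is the published-table column list (includes `export`, no
#' unemployment); `"equation"` follows the model equation's narrative list
#' (includes unemployment). Both are merely presets: any covariate subset
#' can be passed directly.
#' @param preset `"table1"` or `"equation"`.
#' @return Character vector of covariate names.
#' @export
firm_covariate_preset <- function(preset = c("table1", "equation")) {
  preset <- match.arg(preset)
  base <- c("lnsize", "lnage", "export", "roa", "leverage",
            "state_owned", "foreign_owned", "pop_intensity", "gdppc")
  if (preset == "equation") c(setdiff(base, "export"), "unemployment") else base
}

#' Firm-level pollutant regression with buffer rings and fixed effects
#'
#' OLS of the log pollutant on the buffer dummy, buffer x FYP-period
#' interactions, firm and city covariates, and industry plus year dummy
#' sets:
#' `ln P_it = a0 + a1 buffer + a2 buffer x k10 + a2' buffer x k11 +
#' X_it A + lambda_industry + mu_year + e_it`,
#' with `k10 = 1` in 2001-2005 and `k11 = 1` from 2006 on. Firms beyond
#' the outer ring (`buffer = NA`) are excluded. Zero pollutant values are
#' handled by `log(1 + P)` by default; `log_mode = "strict"` drops them
#' and uses `log(P)`.
#'
#' @param panel Firm-year data frame carrying the pollutant column,
#'   covariates, `industry`, `year`, and a `buffer` column (e.g. merged
#'   from [assign_buffers()]).
#' @param pollutant `"wastewater"`, `"cod"` or `"so2"`.
#' @param covariates Covariate names (default the `"table1"` preset,
#'   intersected with the panel's columns).
#' @param fyp_interactions Include `buffer x k10` and `buffer x k11`
#'   (default TRUE).
#' @param fe Fixed-effect factors to absorb (default industry and year).
#' @param se `"plain"` (default, matching the published table) or
#'   `"cluster"`.
#' @param cluster Cluster variable name when `se = "cluster"` (default
#'   `"firm_id"`).
#' @param log_mode `"log1p"` (default) or `"strict"`.
#' @return A [`pollreg`][print.pollreg] object.
#' @export
fit_firm_regression <- function(panel, pollutant = c("wastewater", "cod", "so2"),
                                covariates = NULL, fyp_interactions = TRUE,
                                fe = c("industry", "year"),
                                se = c("plain", "cluster"),
                                cluster = "firm_id",
                                log_mode = c("log1p", "strict")) {
  pollutant <- match.arg(pollutant)
  se <- match.arg(se)
  log_mode <- match.arg(log_mode)
  if (is.null(covariates))
    covariates <- intersect(firm_covariate_preset("table1"), names(panel))
  missing_cov <- setdiff(covariates, names(panel))
  if (length(missing_cov))
    stop("covariates not found in panel: ", paste(missing_cov, collapse = ", "))
  if (!"buffer" %in% names(panel))
    stop("panel must carry a buffer column (see assign_buffers)")

  d <- panel[!is.na(panel$buffer), , drop = FALSE]
  P <- d[[pollutant]]
  if (log_mode == "strict") {
    keep <- P > 0
    d <- d[keep, , drop = FALSE]
    d$.y <- log(P[keep])
  } else {
    if (any(P < 0)) stop("negative pollutant values")
    d$.y <- log1p(P)
  }
  if (nrow(d) == 0) stop("empty estimation sample after filters")
  d$k10 <- as.integer(d$year >= 2001 & d$year <= 2005)
  d$k11 <- as.integer(d$year >= 2006)

  rhs <- c("buffer",
           if (fyp_interactions) c("buffer:k10", "buffer:k11"),
           covariates,
           paste0("factor(", fe, ")"))
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = d)

  # perfect collinearity among the named covariates (not the FE dummies)
  cf <- stats::coef(fit)
  bad <- names(cf)[is.na(cf)]
  bad_named <- bad[!grepl("^factor\\(", bad)]
  bad_core <- intersect(bad_named, c("buffer", "buffer:k10", "buffer:k11"))
  if (length(bad_core))
    stop("perfectly collinear core terms: ", paste(bad_core, collapse = ", "))
  cl <- NULL
  if (se == "cluster") {
    cl <- d[[cluster]]
    if (!is.null(fit$na.action)) cl <- cl[-fit$na.action]
  }
  .make_pollreg(fit, se_type = se, cluster = cl,
                fe_terms = paste0("factor(", fe, ")"),
                call = match.call())
}
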