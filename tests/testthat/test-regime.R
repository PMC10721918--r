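# Grid-panel trend regressions per FYP window, CR1 clustering and the
# regime contrast.

test_that("a zero-noise panel returns the trend coefficients exactly", {
  sim <- simulate_grid_panel(n_cells = 50, years = 2001:2005,
                             beta_year = 0.02, beta_east_x_year = 0,
                             noise_sd = 0, fe_sd = 0.05, seed = 4L)
  fit <- fit_grid_panel_regression(sim$panel, window = "FYP10",
                                   interaction = FALSE)
  expect_lt(abs(coef(fit)["year_c"] - 0.02), 1e-10)
  sim2 <- simulate_grid_panel(n_cells = 50, years = 2001:2005,
                              beta_year = 0.02, beta_east_x_year = 0.01,
                              noise_sd = 0, seed = 4L)
  fit2 <- fit_grid_panel_regression(sim2$panel, window = "FYP10")
  expect_lt(abs(coef(fit2)["year_c"] - 0.02), 1e-10)
  expect_lt(abs(coef(fit2)["year_c:east"] - 0.01), 1e-10)
})

test_that("single-year windows and degenerate east are handled", {
  sim <- simulate_grid_panel(n_cells = 30, years = 2006:2010, seed = 2L)
  expect_error(fit_grid_panel_regression(sim$panel, window = 2006),
               "unidentified")
  sim3 <- simulate_grid_panel(n_cells = 30, years = 2001:2005,
                              east_share = 0, seed = 3L)
  expect_message(f <- fit_grid_panel_regression(sim3$panel, window = "FYP10"),
                 "interaction dropped")
  expect_false("year_c:east" %in% f$coefficients$term)
})

test_that("CR1 covariance matches a hand-rolled cluster sandwich on a toy panel", {
  set.seed(14)
  toy <- simulate_grid_panel(n_cells = 5, years = 2001:2005, noise_sd = 0.1,
                             rho = 0.5, seed = 14L)
  fit <- fit_grid_panel_regression(toy$panel, window = "FYP10",
                                   interaction = FALSE, controls = character(0))
  lmf <- fit$lm_fit
  X <- model.matrix(lmf)
  V_ref <- bf_cr1(X, residuals(lmf),
                  toy$panel$cell[order(toy$panel$cell, toy$panel$year)])
  keep <- c("year_c")
  expect_equal(fit$vcov[keep, keep], V_ref[keep, keep], tolerance = 1e-10)
})

test_that("CR1 agrees with the sandwich package up to its stated adjustment", {
  skip_if_not_installed("sandwich")
  sim <- simulate_grid_panel(n_cells = 20, years = 2001:2005, noise_sd = 0.05,
                             rho = 0.6, seed = 8L)
  fit <- fit_grid_panel_regression(sim$panel, window = "FYP10")
  lmf <- fit$lm_fit
  cl <- sim$panel$cell
  V_hc0 <- sandwich::vcovCL(lmf, cluster = cl, type = "HC0", cadjust = TRUE)
  N <- nobs(lmf); K <- length(coef(lmf))
  expect_equal(fit$vcov, V_hc0 * (N - 1) / (N - K),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cluster-robust SEs exceed plain SEs under strong within-cell correlation", {
  for (seed in c(1L, 2L, 3L)) {
    sim <- simulate_grid_panel(n_cells = 60, years = 2001:2005,
                               noise_sd = 0.05, rho = 0.8, seed = seed)
    fc <- fit_grid_panel_regression(sim$panel, window = "FYP10",
                                    interaction = FALSE, se = "cluster")
    fp <- fit_grid_panel_regression(sim$panel, window = "FYP10",
                                    interaction = FALSE, se = "plain")
    se_c <- fc$coefficients$std_error[fc$coefficients$term == "year_c"]
    se_p <- fp$coefficients$std_error[fp$coefficients$term == "year_c"]
    expect_gt(se_c, se_p)
  }
})

test_that("absorbing cell FE via demeaning equals the dummy OLS slopes", {
  sim <- simulate_grid_panel(n_cells = 40, years = 2006:2010,
                             beta_year = -0.03, noise_sd = 0.02, seed = 21L)
  fit <- fit_grid_panel_regression(sim$panel, window = "FYP11")
  d <- sim$panel[order(sim$panel$cell, sim$panel$year), ]
  d$year_c <- d$year - 2006
  X <- cbind(year_c = d$year_c, gdppc = d$gdppc, secondary = d$secondary,
             tertiary = d$tertiary, urbanrate = d$urbanrate,
             `year_c:east` = d$year_c * d$east)
  ref <- demean_fit(d$index, X, factor(d$cell))
  got <- coef(fit)[c("year_c", "gdppc", "secondary", "tertiary", "urbanrate",
                     "year_c:east")]
  expect_equal(unname(got), unname(ref[names(got)]), tolerance = 1e-8)
})

test_that("estimates are consistent across seeds (mean within 2 MC standard errors)", {
  est <- vapply(1:20, function(s) {
    sim <- simulate_grid_panel(n_cells = 100, years = 2001:2005,
                               beta_year = 0.02, beta_east_x_year = 0.01,
                               noise_sd = 0.02, seed = 100L + s)
    unname(coef(fit_grid_panel_regression(sim$panel, window = "FYP10"))["year_c"])
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.02), 2 * mc_se + 1e-12)
})

test_that("the regime contrast flags a built-in sign flip and stays quiet without one", {
  mk <- function(beta10, beta11, seed) {
    s10 <- simulate_grid_panel(n_cells = 80, years = 2001:2005,
                               beta_year = beta10, beta_east_x_year = 0.01,
                               noise_sd = 0.02, seed = seed)
    s11 <- simulate_grid_panel(n_cells = 80, years = 2006:2010,
                               beta_year = beta11, beta_east_x_year = -0.01,
                               noise_sd = 0.02, seed = seed + 1L)
    list(f10 = fit_grid_panel_regression(s10$panel, window = "FYP10"),
         f11 = fit_grid_panel_regression(s11$panel, window = "FYP11"))
  }
  shifted <- mk(0.02, -0.03, 50L)
  ct <- regime_contrast(shifted$f10, shifted$f11)
  expect_true(ct$trend_shift)
  expect_true(ct$interaction_shift)
  same <- mk(0.02, 0.02, 60L)
  ct2 <- regime_contrast(same$f10, same$f11)
  expect_false(ct2$trend_shift)
  # mismatched outcomes are rejected
  f_alt <- shifted$f11; f_alt$index_col <- "other"
  expect_error(regime_contrast(shifted$f10, f_alt), "different outcome")
})
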