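# Buffer-ring assignment, covariate balance and the firm-level
# fixed-effects pollutant regression.

test_that("buffer rings follow the 40/80 km thresholds on the nearest village", {
  # villages on the equator; firm distances controlled via longitude
  villages <- data.frame(village_id = 1:2, lon = c(0, 3), lat = c(0, 0))
  deg <- function(km) km / 111.1950793
  firms <- data.frame(firm_id = c("a", "b", "c"),
                      lon = deg(c(30, 60, 100)), lat = 0)
  b <- assign_buffers(firms, villages)
  expect_equal(b$buffer, c(1L, 0L, NA_integer_))
  expect_equal(b$nearest_village, c(1L, 1L, 1L))
  expect_error(assign_buffers(firms, villages[0, ]), "empty")
})

test_that("assignments equal the all-pairs haversine scan on 500 firms x 20 villages", {
  set.seed(61)
  firms <- data.frame(firm_id = sprintf("f%03d", 1:500),
                      lon = runif(500, 100, 115), lat = runif(500, 25, 38))
  villages <- data.frame(village_id = 1:20,
                         lon = runif(20, 100, 115), lat = runif(20, 25, 38))
  got <- assign_buffers(firms, villages)
  ref <- bf_assign_buffers(firms, villages)
  expect_equal(got$buffer, ref$buffer)
  expect_equal(got$distance_km, ref$distance_km, tolerance = 1e-12)
})

test_that("Welch balance tests match the closed form and handle identical groups", {
  d <- data.frame(buffer = rep(c(1, 0), each = 20),
                  a = c(rnorm(20, 0, 1), rnorm(20, 2, 2)),
                  b = rep(c(1, 2, 3, 4), 10))
  set.seed(3); d$a <- c(rnorm(20, 0, 1), rnorm(20, 2, 2))
  out <- covariate_balance_test(d, c("a", "b"))
  expect_equal(out$t[1], bf_welch_t(d$a[d$buffer == 1], d$a[d$buffer == 0]),
               tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  expect_equal(out$t[2], 0)
  expect_equal(out$p_value[2], 1)
  # a genuine 5-sd shift is detected
  set.seed(9)
  d2 <- data.frame(buffer = rep(c(1, 0), each = 15),
                   z = c(rnorm(15), rnorm(15) + 5))
  expect_lt(covariate_balance_test(d2, "z")$p_value, 0.01)
  expect_error(covariate_balance_test(data.frame(buffer = c(1, 1), z = 1:2), "z"),
               "non-empty")
})

make_noisefree_panel <- function() {
  # East trend differentials off so the fitted span (year FE + buffer +
  # lnsize) nests the generating process exactly
  cfg <- sim_config(n_clusters = 6, firms_per_cluster_mean = 50,
                    noise_sd = 0, beta_east_x_year_pre = 0,
                    beta_east_x_year_post = 0, seed = 12L)
  sim <- simulate_firm_panel(cfg)
  p <- sim$panel
  buf <- assign_buffers(p, sim$truth$villages)
  list(panel = merge(p, buf[, c("firm_id", "buffer")], by = "firm_id"),
       truth = sim$truth, cfg = cfg)
}

test_that("a noise-free panel returns the generating coefficients exactly (strict log)", {
  nf <- make_noisefree_panel()
  # regression buffer dummy (<= 40 km of a village) coincides with the
  # generator's premium indicator, so the fit is exactly identified
  fit <- fit_firm_regression(nf$panel, "cod", covariates = "lnsize",
                             fyp_interactions = FALSE, log_mode = "strict")
  cf <- coef(fit)
  expect_lt(abs(cf["buffer"] - nf$truth$beta_buffer), 1e-8)
  expect_lt(abs(cf["lnsize"] - nf$truth$beta_size), 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("a duplicated covariate is dropped and reported, core fit unchanged", {
  nf <- make_noisefree_panel()
  p2 <- nf$panel
  p2$lnsize_copy <- p2$lnsize
  f1 <- fit_firm_regression(nf$panel, "cod", covariates = "lnsize",
                            fyp_interactions = FALSE, log_mode = "strict")
  f2 <- fit_firm_regression(p2, "cod", covariates = c("lnsize", "lnsize_copy"),
                            fyp_interactions = FALSE, log_mode = "strict")
  expect_true("lnsize_copy" %in% f2$dropped)
  expect_equal(coef(f2)[c("buffer", "lnsize")], coef(f1)[c("buffer", "lnsize")],
               tolerance = 1e-10)
  expect_error(fit_firm_regression(nf$panel, "cod", covariates = "nonexistent"),
               "not found")
})

test_that("dummy-variable OLS equals iterated within-demeaning on all slopes", {
  cfg <- sim_config(n_clusters = 4, firms_per_cluster_mean = 25,
                    noise_sd = 0.5, seed = 31L)
  sim <- simulate_firm_panel(cfg)
  buf <- assign_buffers(sim$panel, sim$truth$villages)
  p <- merge(sim$panel, buf[, c("firm_id", "buffer")], by = "firm_id")
  fit <- fit_firm_regression(p, "so2", covariates = c("lnsize", "lnage", "roa"),
                             fyp_interactions = FALSE, log_mode = "strict")
  d <- p[!is.na(p$buffer) & p$so2 > 0, ]
  X <- as.matrix(d[, c("buffer", "lnsize", "lnage", "roa")])
  ref <- demean_fit(log(d$so2), X, factor(d$industry), factor(d$year))
  expect_equal(unname(coef(fit)[colnames(X)]), unname(ref), tolerance = 1e-8)
})

test_that("the FYP interaction terms estimate period-specific premiums", {
  nf <- make_noisefree_panel()
  fit <- fit_firm_regression(nf$panel, "wastewater", covariates = "lnsize",
                             fyp_interactions = TRUE, log_mode = "strict")
  tab <- fit$coefficients
  expect_true(all(c("buffer", "buffer:k10", "buffer:k11") %in% tab$term))
  # the generator's premium is period-constant, so interactions vanish
  expect_lt(max(abs(tab$estimate[tab$term %in% c("buffer:k10", "buffer:k11")])),
            1e-8)
})
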