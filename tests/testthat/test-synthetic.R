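# The synthetic study system: determinism, the cluster process, the
# log-linear emission model and village placement.

small_cfg <- function(...) sim_config(n_clusters = 5,
                                      firms_per_cluster_mean = 40,
                                      seed = 42L, ...)

test_that("the panel has the expected size and schema", {
  sim <- simulate_firm_panel(small_cfg())
  p <- sim$panel
  n_firms <- length(unique(p$firm_id))
  # Poisson(40) x 5 clusters: total count within generous Poisson bounds
  expect_gt(n_firms, 200 - 4 * sqrt(200))
  expect_lt(n_firms, 200 + 4 * sqrt(200))
  expect_equal(nrow(p), n_firms * 15)
  expect_true(all(c("firm_id", "year", "lon", "lat", "industry", "province",
                    "region", "wastewater", "cod", "so2", "lnsize", "lnage",
                    "export", "roa", "leverage", "state_owned",
                    "foreign_owned") %in% names(p)))
  expect_true(all(p$industry %in% 13:42))
  expect_true(all(p$wastewater >= 0 & p$cod >= 0 & p$so2 >= 0))
  expect_false(any(duplicated(p[, c("firm_id", "year")])))
  expect_true(all(abs(p$lat) <= 90 & abs(p$lon) <= 180))
})

test_that("generation is byte-identical under the same seed and differs across seeds", {
  a <- simulate_firm_panel(small_cfg())
  b <- simulate_firm_panel(small_cfg())
  expect_identical(a, b)
  c_ <- simulate_firm_panel(sim_config(n_clusters = 5,
                                       firms_per_cluster_mean = 40, seed = 43L))
  expect_false(isTRUE(all.equal(a$panel$lon, c_$panel$lon)))
  cov_a <- simulate_city_covariates(small_cfg())
  cov_b <- simulate_city_covariates(small_cfg())
  expect_identical(cov_a, cov_b)
  va <- simulate_cancer_villages(a, small_cfg())
  vb <- simulate_cancer_villages(b, small_cfg())
  expect_identical(va, vb)
  expect_identical(va[, c("x", "y")], a$truth$villages[, c("x", "y")])
})

test_that("the noise-free size-only model makes ln(P) - beta_size*ln(size) constant", {
  cfg <- sim_config(n_clusters = 3, firms_per_cluster_mean = 20,
                    noise_sd = 0, beta_size = 1, beta_buffer = 0,
                    beta_year_pre = 0, beta_year_post = 0,
                    beta_east_x_year_pre = 0, beta_east_x_year_post = 0,
                    seed = 7L)
  p <- simulate_firm_panel(cfg)$panel
  resid <- log(p$wastewater) - p$lnsize
  expect_lt(diff(range(resid)), 1e-10)
  # and regression of mean log-emission on lnsize recovers beta_size exactly
  fit <- lm(log(wastewater) ~ lnsize, data = p)
  expect_lt(abs(coef(fit)["lnsize"] - 1), 1e-10)
})

test_that("the cluster process is more clustered than uniform at equal intensity", {
  cfg <- sim_config(n_clusters = 10, firms_per_cluster_mean = 120,
                    cluster_sd_km = 30, seed = 5L)
  p <- simulate_firm_panel(cfg)$panel
  f <- p[!duplicated(p$firm_id), ]
  expect_gte(nrow(f), 1000)
  nn_mean <- function(x, y) {
    D <- as.matrix(dist(cbind(x, y)))
    diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  set.seed(99)
  ux <- runif(nrow(f), cfg$extent[1], cfg$extent[2])
  uy <- runif(nrow(f), cfg$extent[3], cfg$extent[4])
  expect_lt(nn_mean(f$x, f$y), nn_mean(ux, uy))
})

test_that("villages sit at the top-emitting clusters and respect the count contract", {
  cfg <- sim_config(n_clusters = 6, firms_per_cluster_mean = 30,
                    n_villages = 1, seed = 11L)
  sim <- simulate_firm_panel(cfg)
  v <- sim$truth$villages
  expect_equal(nrow(v), 1L)
  # the single village lies within 2 cluster-sd of the top-emitting centre
  top <- v$cluster[1]
  d <- sqrt((v$x - sim$truth$centers[top, 1])^2 +
            (v$y - sim$truth$centers[top, 2])^2)
  expect_lt(d, 2 * cfg$cluster_sd_km)
  # top cluster really is the emission-mass maximum
  f <- sim$panel[!duplicated(sim$panel$firm_id), ]
  mass <- tapply(exp(cfg$beta_size * f$lnsize), f$cluster, sum)
  expect_equal(top, as.integer(names(which.max(mass))))
  # zero villages -> empty; more villages than clusters -> error
  cfg0 <- sim_config(n_clusters = 3, n_villages = 0, seed = 2L)
  expect_equal(nrow(simulate_firm_panel(cfg0)$truth$villages), 0L)
  expect_error(simulate_firm_panel(sim_config(n_clusters = 2, n_villages = 5)),
               "n_villages")
})

test_that("city covariates respect bounds and zero-noise configs give exact lines", {
  cfg <- small_cfg()
  cov <- simulate_city_covariates(cfg)
  expect_true(all(cov$secondary + cov$tertiary <= 100 + 1e-9))
  expect_true(all(cov$urbanrate >= 0 & cov$urbanrate <= 100))
  expect_true(all(cov$unemployment >= 0))
  cov0 <- simulate_city_covariates(sim_config(covariate_noise_sd = 0, seed = 3L))
  for (pr in unique(cov0$province)) {
    g <- cov0[cov0$province == pr, ]
    expect_lt(max(abs(resid(lm(gdppc ~ year, g)))), 1e-10)
    expect_lt(max(abs(resid(lm(urbanrate ~ year, g)))), 1e-10)
  }
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(extent = c(0, -10, 0, 10)), "extent")
  expect_error(sim_config(break_year = 1990), "break_year")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(n_clusters = 0), "at least 1")
})

test_that("panel and village writers round-trip through CSV/GeoJSON", {
  sim <- simulate_firm_panel(sim_config(n_clusters = 2, years = 1998:1999,
                                        break_year = 1999, n_villages = 1,
                                        firms_per_cluster_mean = 5, seed = 1L))
  td <- withr::local_tempdir()
  fp <- write_firm_panel(sim, file.path(td, "p.csv"))
  back <- read.csv(fp)
  expect_equal(nrow(back), nrow(sim$panel))
  vp <- write_villages_geojson(sim$truth$villages, file.path(td, "v.geojson"))
  vv <- read_villages_geojson(vp)
  expect_equal(vv$lon, sim$truth$villages$lon, tolerance = 1e-12)
  gj <- jsonlite::read_json(vp)
  expect_equal(gj$type, "FeatureCollection")
})
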