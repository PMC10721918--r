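# Synthetic study system: spatially clustered firm-year pollutant panels,
# province-year covariates, and cancer-village sites, all with recorded
# ground truth so every downstream stage has a parameter-recovery test.

#' Configuration for the synthetic study system
#'
#' Collects every knob of the generator in one validated object. The
#' defaults describe the emulated system: industrial firms agglomerated in
#' Matern-style clusters on a 2000 x 1500 km plane, three pollutant series
#' (wastewater in tons, COD and SO2 in kg) log-linear in firm size with a
#' piecewise-linear time trend that rises before `break_year` and falls
#' after it, an East-vs-rest trend differential, an emission premium for
#' firms within 40 km of a cancer village, and villages sited at the
#' highest-emitting clusters.
#'
#' @param n_clusters Number of firm agglomerations (parent points).
#' @param cluster_sd_km Gaussian spread of firms around their cluster
#'   centre (km). The default 30 km puts firm mass on both sides of the
#'   40 km village ring.
#' @param firms_per_cluster_mean Poisson mean number of firms per cluster.
#' @param years Inclusive year range of the panel.
#' @param break_year Year at which the emission trend changes sign.
#' @param beta0 Named log-scale intercepts for the three pollutants.
#' @param beta_size Elasticity of emissions w.r.t. firm size (log-log).
#' @param beta_buffer Log-emission premium for firms within
#'   `village_radius_km` of a village.
#' @param beta_year_pre,beta_year_post Log-emission trend per year before /
#'   after `break_year`.
#' @param beta_east_x_year_pre,beta_east_x_year_post Additional trend per
#'   year for firms in the East region.
#' @param noise_sd Std dev of the iid log-scale emission noise (>= 0).
#' @param n_villages Number of cancer villages (<= `n_clusters` when
#'   villages are generated).
#' @param extent Planar bounding box `c(xmin, xmax, ymin, ymax)` in km.
#' @param east_boundary_x Planar x separating East from Central & West.
#' @param west_boundary_x Planar x separating West from Central.
#' @param village_radius_km Radius of the emission premium around villages.
#' @param covariate_noise_sd Noise around the province covariate trends.
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 8, cluster_sd_km = 30,
                       firms_per_cluster_mean = 40,
                       years = 1998:2012, break_year = 2006,
                       beta0 = c(wastewater = 8, cod = 5.5, so2 = 5.8),
                       beta_size = 0.8, beta_buffer = 0.2,
                       beta_year_pre = 0.05, beta_year_post = -0.08,
                       beta_east_x_year_pre = 0.02,
                       beta_east_x_year_post = -0.01,
                       noise_sd = 0.5, n_villages = 3,
                       extent = c(0, 2000, 0, 1500),
                       east_boundary_x = 1300, west_boundary_x = 650,
                       village_radius_km = 40, covariate_noise_sd = 0.1,
                       seed = 1L) {
  stopifnot(length(years) >= 1, all(diff(years) == 1))
  if (!(break_year %in% years)) stop("break_year must lie within the year range")
  if (noise_sd < 0 || covariate_noise_sd < 0) stop("noise sds must be non-negative")
  if (n_clusters < 1 || firms_per_cluster_mean < 1) stop("counts must be at least 1")
  if (n_villages < 0) stop("n_villages must be non-negative")
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive area")
  if (!all(c("wastewater", "cod", "so2") %in% names(beta0)))
    stop("beta0 must name wastewater, cod and so2")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d clusters (sd %g km, ~%g firms each), years %d-%d ",
    "(break %d), noise_sd %g, %d villages, seed %d\n"),
    x$n_clusters, x$cluster_sd_km, x$firms_per_cluster_mean,
    min(x$years), max(x$years), x$break_year, x$noise_sd, x$n_villages,
    x$seed))
  invisible(x)
}

# Deterministic per-cluster emission mass used to rank clusters for village
# placement: the no-noise emission scale sum(exp(beta_size * lnsize)).
# Computable before any emission draw, which breaks the circularity between
# "villages sit at top-emitting clusters" and "emissions depend on village
# proximity".
.cluster_mass <- function(firms, beta_size) {
  tapply(exp(beta_size * firms$lnsize), firms$cluster, sum)
}

# Jittered village sites at the centres of the top-emitting clusters.
# Shared by simulate_firm_panel() and simulate_cancer_villages() with the
# same derived seed so both produce identical coordinates.
.place_villages <- function(firms, centers, config) {
  nv <- config$n_villages
  if (nv == 0)
    return(data.frame(village_id = integer(0), x = numeric(0), y = numeric(0)))
  if (nv > config$n_clusters)
    stop("n_villages exceeds n_clusters; villages are sited at cluster centres")
  mass <- .cluster_mass(firms, config$beta_size)
  top <- as.integer(names(sort(mass, decreasing = TRUE)))[seq_len(nv)]
  set.seed(config$seed + 2L)
  jit <- matrix(stats::rnorm(2 * nv, sd = config$cluster_sd_km / 2), ncol = 2)
  data.frame(village_id = seq_len(nv),
             x = centers[top, 1] + jit[, 1],
             y = centers[top, 2] + jit[, 2],
             cluster = top)
}

# piecewise-linear trend, continuous at the break year
.trend <- function(year, east, config) {
  t <- year - config$break_year
  pre <- pmin(t, 0); post <- pmax(t, 0)
  (config$beta_year_pre + east * config$beta_east_x_year_pre) * pre +
    (config$beta_year_post + east * config$beta_east_x_year_post) * post
}

#' Generate a synthetic firm-year pollutant panel
#'
#' Firm locations follow a Matern-style cluster process: cluster centres
#' uniform on the extent, firm counts Poisson, offsets isotropic Gaussian.
#' Each firm persists over all years. Log emissions follow
#' `ln(P_j) = beta0_j + beta_size*lnsize + beta_buffer*1[<= 40 km of a
#' village] + trend(year, east) + eps`, `eps ~ N(0, noise_sd)` iid per
#' record and pollutant, with the trend rising before `break_year` and
#' falling after, plus the East differential. Firm covariates (lnsize,
#' lnage, export, roa, leverage, ownership dummies) come from simple
#' parametric families; only their regression roles matter. Planar
#' coordinates are embedded into WGS84 through [plane_projection()].
#'
#' @param config A [sim_config()].
#' @return A list of class `firm_panel_sim` with `panel` (data frame, one
#'   row per firm-year) and `truth` (recorded ground truth: all
#'   coefficients, cluster centres, village coordinates, the config).
#' @export
simulate_firm_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ext <- config$extent
  nc <- config$n_clusters
  centers <- cbind(stats::runif(nc, ext[1], ext[2]),
                   stats::runif(nc, ext[3], ext[4]))
  n_k <- pmax(1L, stats::rpois(nc, config$firms_per_cluster_mean))
  n_firms <- sum(n_k)
  cluster <- rep(seq_len(nc), n_k)
  fx <- centers[cluster, 1] + stats::rnorm(n_firms, sd = config$cluster_sd_km)
  fy <- centers[cluster, 2] + stats::rnorm(n_firms, sd = config$cluster_sd_km)

  region_of <- function(x) ifelse(x >= config$east_boundary_x, "East",
                           ifelse(x < config$west_boundary_x, "West", "Central"))
  firms <- data.frame(
    firm_id = sprintf("F%05d", seq_len(n_firms)),
    cluster = cluster,
    x = fx, y = fy,
    province = sprintf("P%02d", cluster),
    region = region_of(centers[cluster, 1]),
    industry = sample(13:42, n_firms, replace = TRUE),
    lnsize = stats::rnorm(n_firms, 4, 1),
    age0 = sample(1:30, n_firms, replace = TRUE),
    export = stats::runif(n_firms),
    roa = stats::rnorm(n_firms, 0.05, 0.08),
    leverage = stats::runif(n_firms, 0, 2),
    stringsAsFactors = FALSE)
  own <- stats::runif(n_firms)
  firms$state_owned <- as.integer(own < 0.25)
  firms$foreign_owned <- as.integer(own > 0.90)

  villages <- .place_villages(firms, centers, config)
  ll <- unproject_coordinates(firms$x, firms$y, plane_projection())
  firms$lon <- ll$lon; firms$lat <- ll$lat
  if (nrow(villages)) {
    vll <- unproject_coordinates(villages$x, villages$y, plane_projection())
    villages$lon <- vll$lon; villages$lat <- vll$lat
    dmat <- outer(seq_len(n_firms), seq_len(nrow(villages)), function(i, j)
      haversine_km(firms$lon[i], firms$lat[i], villages$lon[j], villages$lat[j]))
    firms$dist_village <- apply(dmat, 1, min)
  } else {
    firms$dist_village <- Inf
  }
  firms$buffer_true <- as.integer(firms$dist_village <= config$village_radius_km)

  years <- config$years
  ny <- length(years)
  # re-seed the panel stage so panel draws do not depend on n_villages
  set.seed(config$seed + 1L)
  panel <- firms[rep(seq_len(n_firms), each = ny), ]
  panel$year <- rep(years, times = n_firms)
  panel$lnage <- log(panel$age0 + panel$year - min(years))
  east <- as.integer(panel$region == "East")
  mu_common <- config$beta_size * panel$lnsize +
    config$beta_buffer * panel$buffer_true + .trend(panel$year, east, config)
  for (j in c("wastewater", "cod", "so2")) {
    eps <- if (config$noise_sd > 0)
      stats::rnorm(nrow(panel), sd = config$noise_sd) else 0
    panel[[j]] <- exp(config$beta0[[j]] + mu_common + eps)
  }
  panel$age0 <- NULL
  rownames(panel) <- NULL

  truth <- list(
    centers = centers, villages = villages,
    beta0 = config$beta0, beta_size = config$beta_size,
    beta_buffer = config$beta_buffer,
    beta_year_pre = config$beta_year_pre,
    beta_year_post = config$beta_year_post,
    beta_east_x_year_pre = config$beta_east_x_year_pre,
    beta_east_x_year_post = config$beta_east_x_year_post,
    noise_sd = config$noise_sd, config = config)
  structure(list(panel = panel, truth = truth), class = "firm_panel_sim")
}

#' @export
print.firm_panel_sim <- function(x, ...) {
  cat(sprintf("firm_panel_sim: %d firm-years (%d firms x %d years), %d villages\n",
              nrow(x$panel), length(unique(x$panel$firm_id)),
              length(unique(x$panel$year)), nrow(x$truth$villages)))
  invisible(x)
}

#' Generate province-year control covariates
#'
#' One province per firm cluster. Each covariate follows a linear
#' province-specific trend plus `covariate_noise_sd` Gaussian noise (so a
#' zero-noise config gives exactly linear trends). GDP shares are scaled
#' so secondary + tertiary never exceed 100 and the urbanisation rate is
#' kept in [0, 100].
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `province`, `year`, `gdppc`,
#'   `secondary`, `tertiary`, `urbanrate`, `pop_intensity`, `unemployment`.
#' @export
simulate_city_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  nc <- config$n_clusters
  years <- config$years
  t <- rep(years - min(years), times = nc)
  province <- rep(sprintf("P%02d", seq_len(nc)), each = length(years))
  base_gdp <- rep(stats::runif(nc, 2, 6), each = length(years))
  slope_gdp <- rep(stats::runif(nc, 0.2, 0.6), each = length(years))
  base_sec <- rep(stats::runif(nc, 38, 48), each = length(years))
  base_ter <- rep(stats::runif(nc, 28, 38), each = length(years))
  base_urb <- rep(stats::runif(nc, 25, 45), each = length(years))
  base_pop <- rep(stats::runif(nc, 200, 800), each = length(years))
  n <- length(province)
  nz <- function() if (config$covariate_noise_sd > 0)
    stats::rnorm(n, sd = config$covariate_noise_sd) else 0
  out <- data.frame(
    province = province, year = rep(years, times = nc),
    gdppc = base_gdp + slope_gdp * t + nz(),
    secondary = base_sec + 0.1 * t + nz(),
    tertiary = base_ter + 0.2 * t + nz(),
    urbanrate = pmin(100, pmax(0, base_urb + 1.2 * t + nz())),
    pop_intensity = base_pop + 5 * t + nz(),
    unemployment = pmax(0, 4 + 0.05 * t + nz()),
    stringsAsFactors = FALSE)
  over <- out$secondary + out$tertiary > 100
  if (any(over)) {
    sc <- 100 / (out$secondary[over] + out$tertiary[over])
    out$secondary[over] <- out$secondary[over] * sc
    out$tertiary[over] <- out$tertiary[over] * sc
  }
  out
}

#' Generate cancer-village sites from a firm panel
#'
#' Places `n_villages` points at jittered centres of the highest-emitting
#' clusters (ranked by the deterministic no-noise emission mass of the
#' cluster), so that proximity to a village correlates positively with
#' emissions. Reproduces exactly the villages recorded in the panel's
#' ground truth for the same config.
#'
#' @param sim A `firm_panel_sim`, or a firm data frame carrying `cluster`
#'   and `lnsize` columns.
#' @param config The [sim_config()] used for generation.
#' @return Data frame of villages (`village_id`, `x`, `y`, `cluster`,
#'   `lon`, `lat`).
#' @export
simulate_cancer_villages <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  firms <- if (inherits(sim, "firm_panel_sim")) sim$panel else sim
  if (nrow(firms) == 0) stop("firm collection must be non-empty")
  firsts <- firms[!duplicated(firms$firm_id), ]
  centers <- if (inherits(sim, "firm_panel_sim")) sim$truth$centers else {
    cbind(tapply(firsts$x, firsts$cluster, mean),
          tapply(firsts$y, firsts$cluster, mean))
  }
  villages <- .place_villages(firsts, centers, config)
  if (nrow(villages)) {
    vll <- unproject_coordinates(villages$x, villages$y, plane_projection())
    villages$lon <- vll$lon; villages$lat <- vll$lat
  }
  villages
}

#' Simulate a grid-level index panel with known trend coefficients
#'
#' Direct generator for the regime-regression stage:
#' `index_it = alpha + lambda_i + beta_year * t + beta_east_x_year * t *
#' east_i + X_kt Gamma + eps_it`, with cell fixed effects
#' `lambda_i ~ N(0, fe_sd)`, province covariates from
#' [simulate_city_covariates()], and optionally AR(1)-correlated
#' within-cell errors (`rho`) to exercise cluster-robust inference.
#'
#' @param n_cells Number of grid cells (arranged on a near-square raster).
#' @param years Year range of the panel window.
#' @param beta_year Trend per year (on the centred year `t = year - min`).
#' @param beta_east_x_year East trend differential per year.
#' @param gamma Named coefficients for `gdppc`, `secondary`, `tertiary`,
#'   `urbanrate` (default all zero).
#' @param alpha Intercept.
#' @param fe_sd Std dev of cell fixed effects.
#' @param noise_sd Std dev of the idiosyncratic error.
#' @param rho Within-cell AR(1) correlation of the error (0 = iid).
#' @param east_share Share of cells in the East region.
#' @param n_provinces Number of provinces the cells are nested in.
#' @param covariate_noise_sd Year-to-year fluctuation of the province
#'   covariates around their trends. Kept well above the trend slopes so
#'   the year trend stays identified next to the trending controls.
#' @param seed Integer seed.
#' @return List of class `grid_panel_sim`: `panel` (data frame with `cell`,
#'   `year`, `east`, covariates, `index`) and `truth`.
#' @export
simulate_grid_panel <- function(n_cells = 400, years = 2001:2005,
                                beta_year = 0.02, beta_east_x_year = 0.01,
                                gamma = c(gdppc = 0, secondary = 0,
                                          tertiary = 0, urbanrate = 0),
                                alpha = 0.4, fe_sd = 0.05, noise_sd = 0.02,
                                rho = 0, east_share = 0.4,
                                n_provinces = 8, covariate_noise_sd = 1,
                                seed = 1L) {
  stopifnot(n_cells >= 2, length(years) >= 1)
  set.seed(seed)
  ny <- length(years)
  east <- as.integer(seq_len(n_cells) <= round(east_share * n_cells))
  prov <- sprintf("P%02d", 1 + (seq_len(n_cells) - 1) %% n_provinces)
  lambda <- stats::rnorm(n_cells, sd = fe_sd)
  cfg <- sim_config(n_clusters = n_provinces, years = years,
                    break_year = years[1],
                    covariate_noise_sd = covariate_noise_sd, seed = seed)
  cov <- simulate_city_covariates(cfg)
  panel <- data.frame(cell = rep(seq_len(n_cells), each = ny),
                      year = rep(years, times = n_cells),
                      east = rep(east, each = ny),
                      province = rep(prov, each = ny),
                      stringsAsFactors = FALSE)
  panel <- merge(panel, cov[, c("province", "year", "gdppc", "secondary",
                                "tertiary", "urbanrate")],
                 by = c("province", "year"), sort = FALSE)
  panel <- panel[order(panel$cell, panel$year), ]
  t <- panel$year - min(years)
  if (rho != 0) {
    eps <- numeric(nrow(panel))
    innov_sd <- noise_sd * sqrt(1 - rho^2)
    e <- stats::rnorm(n_cells, sd = noise_sd)
    for (j in seq_len(ny)) {
      rows <- seq(j, nrow(panel), by = ny)
      if (j > 1) e <- rho * e + stats::rnorm(n_cells, sd = innov_sd)
      eps[rows] <- e
    }
  } else {
    eps <- if (noise_sd > 0) stats::rnorm(nrow(panel), sd = noise_sd) else 0
  }
  panel$index <- alpha + rep(lambda, each = ny) + beta_year * t +
    beta_east_x_year * t * panel$east +
    as.matrix(panel[, names(gamma)]) %*% gamma + eps
  panel$index <- as.numeric(panel$index)
  rownames(panel) <- NULL
  structure(list(panel = panel,
                 truth = list(beta_year = beta_year,
                              beta_east_x_year = beta_east_x_year,
                              gamma = gamma, alpha = alpha, fe_sd = fe_sd,
                              noise_sd = noise_sd, rho = rho, seed = seed)),
            class = "grid_panel_sim")
}

#' Write the firm panel to CSV in the ingestion schema
#' @param sim A `firm_panel_sim` or firm-year data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_firm_panel <- function(sim, path) {
  panel <- if (inherits(sim, "firm_panel_sim")) sim$panel else sim
  cols <- c("firm_id", "year", "lon", "lat", "industry", "province", "region",
            "wastewater", "cod", "so2", "lnsize", "lnage", "export", "roa",
            "leverage", "state_owned", "foreign_owned")
  utils::write.csv(panel[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write village sites as a GeoJSON point collection (WGS84)
#' @param villages Data frame with `village_id`, `lon`, `lat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_villages_geojson <- function(villages, path) {
  features <- lapply(seq_len(nrow(villages)), function(i) list(
    type = "Feature",
    properties = list(village_id = villages$village_id[i]),
    geometry = list(type = "Point",
                    coordinates = c(villages$lon[i], villages$lat[i]))))
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read village sites from a GeoJSON point collection
#' @param path GeoJSON file path.
#' @return Data frame with `village_id`, `lon`, `lat`.
#' @export
read_villages_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (length(gj$features) == 0)
    return(data.frame(village_id = integer(0), lon = numeric(0), lat = numeric(0)))
  do.call(rbind, lapply(gj$features, function(f) data.frame(
    village_id = f$properties$village_id,
    lon = f$geometry$coordinates[[1]],
    lat = f$geometry$coordinates[[2]])))
}
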