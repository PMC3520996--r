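#' Ground truth for the synthetic study system
#'
#' Bundles every parameter the synthetic-data generators share, so that each
#' downstream stage can be tested against a known truth. The defaults encode
#' the study conditions the pipeline emulates: a linear August-SST abundance
#' response for species A (blacklip), a hump-shaped (quadratic, negative
#' curvature) response for species B (greenlip) with thermal optimum near
#' 17 deg C, overdispersed count noise, and two emissions scenarios — a
#' Reference scenario (WRE750) warming ~0.11 deg C per decade (~1.1 deg C by
#' 2100) and a mitigation Policy scenario (LEV1) warming ~0.046 deg C per
#' decade, optionally peaking around 2080 and easing slightly by 2100.
#'
#' @param sdm_coeffs_A Named vector `c(intercept, sst)`: log-scale intercept
#'   and linear August-SST slope for species A, SST centred at `sst_center_A`.
#' @param sdm_coeffs_B Named vector `c(intercept, sst, sst2)` for species B,
#'   SST centred at `sst_center_B`; `sst2` must be negative (hump-shaped).
#' @param sst_center_A,sst_center_B Centring constants (deg C) for the SST
#'   terms. Species B's centre is its thermal optimum when `sst = 0` slope.
#' @param covariate_coeffs Named vector of log-scale effects for `depth_m`,
#'   `harvest_intensity` and `dist_launch_km`.
#' @param dispersion Negative-binomial size parameter of the count noise
#'   (must be > 0); `Inf` gives the Poisson limit.
#' @param warming_per_decade Named vector, deg C per decade for scenarios
#'   `WRE750` (Reference) and `LEV1` (Policy); Reference must warm at least as
#'   fast as Policy and Policy must be non-negative.
#' @param march_offset Mean offset (deg C) added to the August field to build
#'   the March (late-summer) field.
#' @param policy_shape `"linear"` (default) or `"peak_decline"`: the Policy
#'   trajectory either rises linearly or peaks at +0.46 deg C in 2080 then
#'   eases to +0.44 deg C by 2100.
#'
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(sdm_coeffs_A = c(intercept = 3.6, sst = 0.15),
                            sdm_coeffs_B = c(intercept = 3.9, sst = 0, sst2 = -0.12),
                            sst_center_A = 15, sst_center_B = 17,
                            covariate_coeffs = c(depth_m = -0.02,
                                                 harvest_intensity = -0.5,
                                                 dist_launch_km = -0.005),
                            dispersion = 5,
                            warming_per_decade = c(WRE750 = 0.11, LEV1 = 0.046),
                            march_offset = 2.5,
                            policy_shape = c("linear", "peak_decline")) {
  policy_shape <- match.arg(policy_shape)
  stopifnot(sdm_coeffs_B[["sst2"]] < 0, dispersion > 0,
            warming_per_decade[["WRE750"]] >= warming_per_decade[["LEV1"]],
            warming_per_decade[["LEV1"]] >= 0)
  structure(list(sdm_coeffs_A = sdm_coeffs_A, sdm_coeffs_B = sdm_coeffs_B,
                 sst_center_A = sst_center_A, sst_center_B = sst_center_B,
                 covariate_coeffs = covariate_coeffs, dispersion = dispersion,
                 warming_per_decade = warming_per_decade,
                 march_offset = march_offset, policy_shape = policy_shape),
            class = "synthetic_truth")
}

#' Study-domain geometry and procedural coastline
#'
#' The emulated study area is a rectangular fine-resolution domain standing in
#' for a stretch of temperate southern coastline; the sea is a southern band
#' below a procedurally generated (deterministic, seed-free) coastline so no
#' shapefile is needed.
#'
#' @param nrow,ncol Grid dimensions (latitude rows, longitude columns).
#' @param lon_origin,lat_origin Centre of the south-west cell (degrees).
#' @param resolution Cell size in degrees (default 0.01, the SDM working
#'   resolution).
#' @return A list of class `domain_geometry`.
#' @export
domain_geometry <- function(nrow = 40, ncol = 50, lon_origin = 130,
                            lat_origin = -36, resolution = 0.01) {
  stopifnot(nrow >= 2, ncol >= 2, resolution > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 lon_origin = lon_origin, lat_origin = lat_origin,
                 resolution = resolution),
            class = "domain_geometry")
}

domain_uv <- function(domain) {
  u <- if (domain$ncol > 1) (seq_len(domain$ncol) - 1) / (domain$ncol - 1) else 0
  v <- if (domain$nrow > 1) (seq_len(domain$nrow) - 1) / (domain$nrow - 1) else 0
  list(u = u, v = v)  # u west->east, v south->north, both in [0,1]
}

#' @rdname domain_geometry
#' @param domain A `domain_geometry`.
#' @return `coastline_mask()` returns the logical sea mask (TRUE = sea): a
#'   southern band whose northern edge undulates along the coast.
#' @export
coastline_mask <- function(domain) {
  uv <- domain_uv(domain)
  coast_frac <- 0.7 + 0.12 * sin(2 * pi * 1.5 * uv$u) + 0.05 * sin(2 * pi * 3.3 * uv$u + 1)
  outer(uv$v, coast_frac, `<`)  # nrow x ncol; sea where below the coast line
}

#' Closed-form smooth climatology surface
#'
#' The deterministic (noise-free) component of the synthetic baseline:
#' a west-east warming gradient, a south-north cooling gradient and low-order
#' harmonics. August spans roughly 12-20 deg C over the domain; March adds a
#' spatially varying late-summer offset (~2.1-2.7 deg C) so it spans roughly
#' 14-23 deg C. The offset is sized so the hump-shaped species' August
#' optimum falls inside the 17-20 deg C March band while the domain's warm
#' end lies well beyond it, so present-day densities decline where March
#' reaches 20 deg C and beyond — the thermal structure the overlay analysis
#' probes.
#'
#' @param domain A [domain_geometry()].
#' @param month `"august"` or `"march"`.
#' @param truth A [synthetic_truth()] (supplies the March offset).
#' @return A numeric matrix (nrow x ncol), south row first.
#' @export
baseline_surface <- function(domain, month = c("august", "march"),
                             truth = synthetic_truth()) {
  month <- match.arg(month)
  uv <- domain_uv(domain)
  aug <- 12 + outer(2.5 * (1 - uv$v), 5.5 * uv$u, `+`) +
    0.5 * outer(cos(pi * uv$v), sin(2 * pi * uv$u))
  if (month == "august") return(aug)
  offset <- truth$march_offset + 0.2 * outer(rep(1, domain$nrow), sin(pi * uv$u)) -
    0.2 * outer(uv$v, rep(1, domain$ncol))
  aug + offset
}

#' Generate a synthetic baseline SST climatology
#'
#' Emulates a fine-resolution 20-year monthly climatology (August = austral
#' winter, March = late summer): the closed-form smooth surface of
#' [baseline_surface()] plus iid Gaussian observation noise, masked to sea
#' cells by the procedural coastline.
#'
#' @inheritParams baseline_surface
#' @param noise_sd Observation noise standard deviation (deg C), >= 0.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A [raster_grid()] with variable `"sst_august"` or `"sst_march"`.
#' @export
generate_baseline <- function(domain, month = c("august", "march"),
                              truth = synthetic_truth(), noise_sd = 0.3,
                              seed = 1) {
  month <- match.arg(month)
  stopifnot(noise_sd >= 0)
  surf <- baseline_surface(domain, month, truth)
  vals <- withr::with_seed(seed, {
    surf + matrix(stats::rnorm(length(surf), 0, noise_sd), nrow(surf), ncol(surf))
  })
  raster_grid(vals, domain$lon_origin, domain$lat_origin, domain$resolution,
              mask = coastline_mask(domain), variable = paste0("sst_", month))
}

#' Scenario warming at a decade
#'
#' Domain-mean SST anomaly (deg C) relative to the 2000 baseline implied by a
#' scenario trajectory: linear in decade by default; under the
#' `"peak_decline"` Policy shape the LEV1 trajectory passes through +0.46 deg C
#' at 2080 and +0.44 deg C at 2100.
#'
#' @param scenario `"WRE750"` or `"LEV1"`.
#' @param decade Numeric year(s), e.g. 2010 ... 2100.
#' @param truth A [synthetic_truth()].
#' @return Numeric vector of anomalies (deg C).
#' @export
scenario_warming <- function(scenario, decade, truth = synthetic_truth()) {
  scenario <- match.arg(scenario, c("WRE750", "LEV1"))
  if (scenario == "LEV1" && truth$policy_shape == "peak_decline") {
    stats::approx(x = c(2000, 2080, 2100), y = c(0, 0.46, 0.44),
                  xout = decade, rule = 2)$y
  } else {
    truth$warming_per_decade[[scenario]] * (decade - 2000) / 10
  }
}

coarse_cover_geometry <- function(domain, resolution = 2.5) {
  lon_min <- domain$lon_origin; lat_min <- domain$lat_origin
  lon_max <- lon_min + (domain$ncol - 1) * domain$resolution
  lat_max <- lat_min + (domain$nrow - 1) * domain$resolution
  # origin snapped below the domain with a one-cell margin each side
  lon0 <- lon_min - 1.5 * resolution
  lat0 <- lat_min - 1.5 * resolution
  nc <- max(4L, ceiling((lon_max - lon0) / resolution) + 2L)
  nr <- max(4L, ceiling((lat_max - lat0) / resolution) + 2L)
  domain_geometry(nrow = nr, ncol = nc, lon_origin = lon0, lat_origin = lat0,
                  resolution = resolution)
}

#' Generate per-model coarse GCM anomaly fields
#'
#' Emulates an archive of coarse (2.5 deg) GCM SST-anomaly fields for decadal
#' time slices under one emissions scenario. Model m's anomaly at decade d is
#' the scenario trajectory [scenario_warming()] plus a model-specific constant
#' offset (iid Gaussian, sd `spread_sd`) plus a smooth model-specific spatial
#' perturbation whose amplitude scales with `spread_sd`. When
#' `outlier_bias != 0`, exactly one model (chosen by the seed, recorded in the
#' `outlier_model` attribute) is additionally shifted by `outlier_bias`
#' everywhere — a deliberately poor model for the outlier analysis to find.
#'
#' @param n_models Number of models (>= 2).
#' @param decades Numeric years within 2010 ... 2100.
#' @param scenario `"WRE750"` or `"LEV1"`.
#' @param truth A [synthetic_truth()].
#' @param spread_sd Inter-model spread (deg C) of the constant offsets.
#' @param outlier_bias Extra constant bias (deg C) for the planted outlier; 0
#'   plants none.
#' @param seed Integer seed.
#' @param domain Fine [domain_geometry()] the coarse grids must cover.
#' @return A [grid_stack()] tibble with columns `model`, `decade`, `scenario`,
#'   `grid`; attribute `outlier_model` names the planted outlier (or NA).
#' @export
generate_gcm_anomalies <- function(n_models = 6, decades = seq(2010, 2100, 10),
                                   scenario = c("WRE750", "LEV1"),
                                   truth = synthetic_truth(), spread_sd = 0.15,
                                   outlier_bias = 0, seed = 1,
                                   domain = domain_geometry()) {
  scenario <- match.arg(scenario)
  stopifnot(n_models >= 2, all(decades >= 2010 & decades <= 2100))
  geom <- coarse_cover_geometry(domain)
  uv <- domain_uv(geom)
  withr::with_seed(seed, {
    offsets <- stats::rnorm(n_models, 0, spread_sd)
    phases <- stats::runif(n_models, 0, 2 * pi)
    outlier <- if (outlier_bias != 0) sample.int(n_models, 1L) else NA_integer_
    rows <- purrr::map(seq_len(n_models), function(m) {
      spat <- 0.3 * spread_sd * outer(cos(pi * uv$v), sin(2 * pi * uv$u + phases[m]))
      extra <- if (!is.na(outlier) && m == outlier) outlier_bias else 0
      purrr::map(decades, function(d) {
        vals <- scenario_warming(scenario, d, truth) + offsets[m] + spat + extra
        raster_grid(vals, geom$lon_origin, geom$lat_origin, geom$resolution,
                    variable = "anomaly")
      })
    })
    out <- tibble::tibble(
      model = rep(sprintf("model_%02d", seq_len(n_models)), each = length(decades)),
      decade = rep(decades, times = n_models),
      scenario = scenario,
      grid = purrr::flatten(rows)
    )
    attr(out, "outlier_model") <-
      if (is.na(outlier)) NA_character_ else sprintf("model_%02d", outlier)
    out
  })
}

species_eta <- function(sst, depth_m, harvest_intensity, dist_launch_km,
                        species, truth) {
  cc <- truth$covariate_coeffs
  cov_part <- cc[["depth_m"]] * depth_m + cc[["harvest_intensity"]] * harvest_intensity +
    cc[["dist_launch_km"]] * dist_launch_km
  if (species == "A") {
    b <- truth$sdm_coeffs_A
    s <- sst - truth$sst_center_A
    b[["intercept"]] + b[["sst"]] * s + cov_part
  } else {
    b <- truth$sdm_coeffs_B
    s <- sst - truth$sst_center_B
    b[["intercept"]] + b[["sst"]] * s + b[["sst2"]] * s^2 + cov_part
  }
}

#' Generate synthetic abundance surveys
#'
#' Emulates georeferenced SCUBA abundance surveys (counts per 100 m^2,
#' 5-30 m depth) with a known response: expected abundance is log-linear in
#' August SST for species A and log-quadratic (hump-shaped) for species B,
#' with additional fixed effects of depth, harvest intensity and distance to
#' the nearest boat launch. Records are placed on distinct sea cells of the
#' supplied baseline; counts are negative-binomial around the true mean
#' (Poisson when `truth$dispersion` is infinite).
#'
#' Harvest intensity is uniform on 0-1 and distance-to-launch uniform on
#' 0-50 km; both ranges are artefacts of the emulation (no observed ranges
#' exist to copy) and are documented here as such.
#'
#' @param baseline_august A [raster_grid()] of August SST.
#' @param truth A [synthetic_truth()].
#' @param n_records Number of survey records (each on its own sea cell).
#' @param species `"A"` (blacklip, linear) or `"B"` (greenlip, quadratic).
#' @param seed Integer seed.
#' @return A tibble with columns `lon`, `lat`, `depth_m`, `harvest_intensity`,
#'   `dist_launch_km`, `sst_august`, `count_per_100m2`, `species`.
#' @export
generate_surveys <- function(baseline_august, truth = synthetic_truth(),
                             n_records = 1000, species = c("A", "B"), seed = 1) {
  species <- match.arg(species)
  stopifnot(n_records >= 1)
  cells <- as_tibble.raster_grid(baseline_august)
  if (n_records > nrow(cells))
    stop(sprintf("n_records (%d) exceeds available sea cells (%d)",
                 n_records, nrow(cells)), call. = FALSE)
  withr::with_seed(seed, {
    picked <- cells[sample.int(nrow(cells), n_records), ]
    depth <- stats::runif(n_records, 5, 30)
    harvest <- stats::runif(n_records, 0, 1)
    dist <- stats::runif(n_records, 0, 50)
    eta <- species_eta(picked$value, depth, harvest, dist, species, truth)
    mu <- exp(eta)
    count <- if (is.infinite(truth$dispersion)) stats::rpois(n_records, mu)
             else stats::rnbinom(n_records, size = truth$dispersion, mu = mu)
    tibble::tibble(lon = picked$lon, lat = picked$lat, depth_m = depth,
                   harvest_intensity = harvest, dist_launch_km = dist,
                   sst_august = picked$value, count_per_100m2 = count,
                   species = species)
  })
}

#' Generate replicate-tank juvenile-mortality data
#'
#' Emulates a two-temperature laboratory experiment on juvenile abalone with
#' replicate aquaria per temperature: per-tank mortality percentages are
#' Gaussian around the group means, truncated to \[0, 100\].
#'
#' @param group_means Mortality means (%) per temperature group.
#' @param group_sds Standard deviations (%) per group (recycled).
#' @param n_tanks Replicate tanks per group (>= 2; the experiment used 4).
#' @param temperatures Temperature labels (deg C), default `c(17, 20)` — the
#'   lower and upper late-summer temperature categories.
#' @param seed Integer seed.
#' @return A tibble with columns `temperature`, `tank`, `mortality_pct`.
#' @export
generate_mortality <- function(group_means = c(3.1, 58.12),
                               group_sds = c(6.2, 17.2), n_tanks = 4,
                               temperatures = c(17, 20), seed = 1) {
  stopifnot(length(group_means) == length(temperatures),
            all(group_means >= 0), all(group_means <= 100), n_tanks >= 2)
  group_sds <- rep_len(group_sds, length(group_means))
  withr::with_seed(seed, {
    purrr::map2_dfr(seq_along(group_means), temperatures, function(g, temp) {
      x <- stats::rnorm(n_tanks, group_means[g], group_sds[g])
      tibble::tibble(temperature = temp, tank = seq_len(n_tanks),
                     mortality_pct = pmin(100, pmax(0, x)))
    })
  })
}
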