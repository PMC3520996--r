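plane_points <- function(n, a = 2, b = 3, c = -1, sd = 0, seed = 1) {
  withr::with_seed(seed, {
    lon <- runif(n, 130, 131); lat <- runif(n, -36, -35)
    tibble::tibble(lon = lon, lat = lat,
                   value = a + b * (lon - 130) + c * (lat + 36) + rnorm(n, 0, sd))
  })
}

test_that("thin-plate spline reproduces affine surfaces exactly for any lambda", {
  pts <- plane_points(40, seed = 2)
  for (lam in c(1e-6, 1e-2, 10)) {
    fit <- tps_fit(pts, lambda_grid = lam)
    lon <- c(130.2, 130.9); lat <- c(-35.3, -35.9)
    expect_equal(predict(fit, lon, lat),
                 2 + 3 * (lon - 130) - 1 * (lat + 36), tolerance = 1e-7)
  }
})

test_that("lambda -> 0 interpolates noiseless data at the knots", {
  withr::with_seed(3, {
    lon <- runif(30, 130, 131); lat <- runif(30, -36, -35)
    val <- sin(4 * (lon - 130)) * cos(3 * (lat + 36)) + 14  # smooth bump
  })
  pts <- tibble::tibble(lon = lon, lat = lat, value = val)
  fit <- tps_fit(pts, lambda_grid = c(0, 1e-12))
  expect_lt(max(abs(predict(fit, lon, lat) - val)), 1e-6)
})

test_that("GCV-selected smoothing beats interpolation on noisy planes", {
  wins <- 0L
  for (seed in 1:20) {
    pts <- plane_points(200, sd = 0.5, seed = 400 + seed)
    truth <- 2 + 3 * (pts$lon - 130) - 1 * (pts$lat + 36)
    fit <- tps_fit(pts)
    interp <- tps_fit(pts, lambda_grid = 1e-12)
    mse_gcv <- mean((predict(fit, pts$lon, pts$lat) - truth)^2)
    mse_int <- mean((predict(interp, pts$lon, pts$lat) - truth)^2)
    wins <- wins + (mse_gcv < mse_int)
    expect_gt(fit$lambda, 1e-12)  # GCV picks a positive lambda on noisy data
  }
  expect_gte(wins, 18L)  # >= 90% of 20 seeds
})

test_that("tps_fit rejects degenerate point sets", {
  line <- tibble::tibble(lon = seq(130, 131, length.out = 10), lat = -35.5,
                         value = 1:10)
  expect_error(tps_fit(line), "collinear")
  expect_error(tps_fit(plane_points(3)), "at least 4")
})

test_that("tps_evaluate reproduces knot values at lambda ~ 0 and planes anywhere", {
  dom <- small_domain(10, 12, resolution = 0.05)
  withr::with_seed(6, {
    pts <- tibble::tibble(
      lon = runif(25, 130, 130 + 11 * 0.05),
      lat = runif(25, -36, -36 + 9 * 0.05))
    pts$value <- 5 + 2 * (pts$lon - 130) + 3 * (pts$lat + 36)
  })
  fit <- tps_fit(pts, lambda_grid = 1e-12)
  expect_equal(predict(fit, pts$lon, pts$lat), pts$value, tolerance = 1e-6)
  g <- tps_evaluate(fit, dom)
  expected <- 5 + 2 * (grid_lons(g)[col(g$values)] - 130) +
    3 * (grid_lats(g)[row(g$values)] + 36)
  expect_equal(g$values, matrix(expected, nrow(g$values)), tolerance = 1e-6)
})

test_that("holdout error of the smoothed synthetic baseline is below 0.5 degC", {
  dom <- small_domain(30, 40)
  tr <- synthetic_truth()
  g <- generate_baseline(dom, "august", tr, noise_sd = 0.3, seed = 8)
  cells <- as_tibble(g)
  withr::with_seed(9, idx <- sample.int(nrow(cells), 250))
  train <- cells[idx[1:200], ]; hold <- cells[idx[201:250], ]
  fit <- tps_fit(train)
  pred <- predict(fit, hold$lon, hold$lat)
  expect_lt(mean(abs(pred - hold$value)), 0.5)
})

test_that("bilinear refinement: constants, planes, and a direct-formula oracle", {
  coarse_const <- const_grid(4.2, 4, 4, resolution = 2.5)
  fine <- bilinear_refine(coarse_const, 0.5)
  expect_equal(fine$resolution, 0.5)
  expect_true(all(fine$values == 4.2))

  # planar field reproduced exactly at fine centres
  lons <- 130 + (0:3) * 2.5; lats <- -40 + (0:3) * 2.5
  plane <- raster_grid(outer(lats, lons, function(la, lo) 1 + 0.2 * lo - 0.1 * la),
                       130, -40, 2.5)
  fp <- bilinear_refine(plane, 0.5)
  expected <- outer(grid_lats(fp), grid_lons(fp), function(la, lo) 1 + 0.2 * lo - 0.1 * la)
  expect_equal(fp$values, expected, tolerance = 1e-12)

  # random coarse field vs an independently coded bilinear formula
  rg <- random_grid(55, nrow = 4, ncol = 4, resolution = 2.5, lon = 130, lat = -40)
  fr <- bilinear_refine(rg, 0.5)
  withr::with_seed(56, {
    px <- runif(25, 130, 130 + 3 * 2.5)
    py <- runif(25, -40, -40 + 3 * 2.5)
  })
  # oracle: locate the surrounding coarse centres and interpolate directly
  oracle <- vapply(1:25, function(k) {
    gx <- (px[k] - 130) / 2.5; gy <- (py[k] + 40) / 2.5
    j0 <- min(floor(gx), 2); i0 <- min(floor(gy), 2)
    fx <- gx - j0; fy <- gy - i0
    v <- rg$values
    (1 - fy) * ((1 - fx) * v[i0 + 1, j0 + 1] + fx * v[i0 + 1, j0 + 2]) +
      fy * ((1 - fx) * v[i0 + 2, j0 + 1] + fx * v[i0 + 2, j0 + 2])
  }, 0)
  # fine grid lookup at nearest fine centre equals formula at that centre
  jj <- round((px - 130) / 0.5); ii <- round((py + 40) / 0.5)
  centre_oracle <- vapply(1:25, function(k) {
    gx <- jj[k] * 0.5 / 2.5; gy <- ii[k] * 0.5 / 2.5
    j0 <- min(floor(gx), 2); i0 <- min(floor(gy), 2)
    fx <- gx - j0; fy <- gy - i0
    v <- rg$values
    (1 - fy) * ((1 - fx) * v[i0 + 1, j0 + 1] + fx * v[i0 + 1, j0 + 2]) +
      fy * ((1 - fx) * v[i0 + 2, j0 + 1] + fx * v[i0 + 2, j0 + 2])
  }, 0)
  expect_equal(fr$values[cbind(ii + 1, jj + 1)], centre_oracle, tolerance = 1e-12)
  # and the mid-cell values stay within the coarse bounds
  expect_gte(min(fr$values), min(rg$values))
  expect_lte(max(fr$values), max(rg$values))
  expect_true(all(abs(oracle) < Inf))
  expect_error(bilinear_refine(fr, 2.5), "finer")
})

test_that("coarse cell-centre values are preserved by refinement", {
  rg <- random_grid(57, nrow = 4, ncol = 5, resolution = 2.5, lon = 100, lat = -50)
  fr <- bilinear_refine(rg, 0.5)
  step <- round(2.5 / 0.5)
  sub <- fr$values[seq(1, nrow(fr$values), by = step),
                   seq(1, ncol(fr$values), by = step)]
  expect_equal(sub, rg$values, tolerance = 1e-12)
})

test_that("change factor: null and constant anomalies shift the baseline exactly", {
  base <- generate_baseline(small_domain(), "august", seed = 12)
  zero <- const_grid(0, 6, 8, resolution = 0.5, lon = 129, lat = -37)
  proj0 <- change_factor(base, zero)
  expect_identical(proj0$values[proj0$mask], base$values[base$mask])

  plus <- grid_map(zero, function(v) v + 1.1)
  proj1 <- change_factor(base, plus)
  expect_equal(mean(proj1$values[proj1$mask]),
               mean(base$values[base$mask]) + 1.1, tolerance = 1e-12)
  expect_equal(proj1$values[proj1$mask], base$values[base$mask] + 1.1)
  expect_identical(proj1$mask, base$mask)
})

test_that("spatially varying change factors match per-cell brute force", {
  dom <- small_domain(50, 50)
  base <- generate_baseline(dom, "august", seed = 13)
  an <- random_grid(60, nrow = 5, ncol = 5, resolution = 0.5,
                    lon = 129.8, lat = -36.2)
  proj <- change_factor(base, an)
  idx <- which(base$mask, arr.ind = TRUE)
  oracle <- vapply(seq_len(nrow(idx)), function(k) {
    lon <- base$lon_origin + (idx[k, 2] - 1) * base$resolution
    lat <- base$lat_origin + (idx[k, 1] - 1) * base$resolution
    pj <- round((lon - an$lon_origin) / an$resolution) + 1
    pi_ <- round((lat - an$lat_origin) / an$resolution) + 1
    base$values[idx[k, 1], idx[k, 2]] + an$values[pi_, pj]
  }, 0)
  expect_identical(proj$values[idx], oracle)
  # projected - baseline is piecewise constant on parent blocks
  diffs <- proj$values - base$values
  expect_lte(length(unique(round(diffs[base$mask], 12))), length(an$values))
})

test_that("uncovered baseline cells raise an error naming a location", {
  base <- generate_baseline(small_domain(), "august", seed = 14)
  far <- const_grid(1, 3, 3, resolution = 0.5, lon = 100, lat = -10)
  expect_error(change_factor(base, far), "does not cover")
})

test_that("the full downscaling chain is deterministic", {
  dom <- small_domain()
  run_chain <- function() {
    base <- generate_baseline(dom, "august", seed = 15)
    an <- generate_gcm_anomalies(5, 2100, "WRE750", spread_sd = 0.1,
                                 seed = 16, domain = dom)
    mid <- bilinear_refine(an$grid[[1]], 0.5)
    change_factor(base, mid)
  }
  expect_identical(run_chain()$values, run_chain()$values)
})
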