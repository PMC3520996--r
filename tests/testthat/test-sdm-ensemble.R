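test_that("null-model fit recovers a constant mean through the intercept", {
  tr <- synthetic_truth(sdm_coeffs_A = c(intercept = 2.5, sst = 0),
                        covariate_coeffs = c(depth_m = 0, harvest_intensity = 0,
                                             dist_launch_km = 0))
  sv <- make_surveys(n = 800, species = "A", seed = 51, truth = tr)
  fit <- fit_glm(sv, "linear", sst_center = tr$sst_center_A, cv_folds = 0)
  ci <- suppressMessages(stats::confint.default(fit$fit))
  expect_gt(2.5, ci["(Intercept)", 1])
  expect_lt(2.5, ci["(Intercept)", 2])
})

test_that("quadratic fits recover the thermal optimum of species B", {
  tr <- synthetic_truth()
  opts <- vapply(1:5, function(seed) {
    sv <- make_surveys(n = 2000, species = "B", seed = 500 + seed, truth = tr)
    thermal_optimum(fit_glm(sv, "quadratic", cv_folds = 0))
  }, 0)
  expect_lt(abs(mean(opts) - tr$sst_center_B), 0.5)
})

test_that("cross-validated deviance prefers the correctly specified shape", {
  tr <- synthetic_truth()
  wins <- 0L
  for (seed in 1:6) {
    sv <- make_surveys(n = 1200, species = "B", seed = 600 + seed, truth = tr)
    dev_q <- fit_glm(sv, "quadratic", seed = seed)$cv_deviance
    dev_l <- fit_glm(sv, "linear", seed = seed)$cv_deviance
    wins <- wins + (dev_q < dev_l)
  }
  expect_gte(wins, 5L)
})

test_that("fit_glm enforces its preconditions", {
  sv <- make_surveys(n = 200, species = "A", seed = 55)
  expect_error(fit_glm(sv[1:40, ], "linear"), "at least")
  sv3 <- sv
  sv3$sst_august <- rep(c(14, 15), length.out = nrow(sv3))
  expect_error(fit_glm(sv3, "quadratic"), "distinct SST")
})

test_that("BRT reduces to a constant on constant responses", {
  sv <- make_surveys(n = 300, species = "A", seed = 61)
  sv$count_per_100m2 <- 7
  fit <- fit_brt(sv, n_trees = 400, seed = 1)
  pred <- abaclim:::component_predict(fit, sv)
  expect_equal(pred, rep(7, nrow(sv)), tolerance = 0.02)
})

test_that("BRT recovers a strong monotone signal (rank correlation > 0.9)", {
  tr <- synthetic_truth(dispersion = 50)  # strong signal, mild noise
  sv <- make_surveys(n = 2000, species = "A", seed = 62, truth = tr)
  fit <- fit_brt(sv, n_trees = 800, seed = 2)
  mu_true <- exp(abaclim:::species_eta(sv$sst_august, sv$depth_m,
                                       sv$harvest_intensity, sv$dist_launch_km,
                                       "A", tr))
  pred <- abaclim:::component_predict(fit, sv)
  expect_gt(stats::cor(pred, mu_true, method = "spearman"), 0.9)
})

test_that("BRT on permuted responses does no better than the null model", {
  tr <- synthetic_truth()
  worse <- 0L
  for (seed in 1:5) {
    sv <- make_surveys(n = 600, species = "A", seed = 700 + seed, truth = tr)
    perm <- withr::with_seed(seed, dplyr::mutate(
      sv, count_per_100m2 = sample(count_per_100m2)))
    n <- nrow(perm)
    hold <- withr::with_seed(seed + 99, sample.int(n, 150))
    fit <- fit_brt(perm[-hold, ], n_trees = 300, seed = seed)
    pred <- abaclim:::component_predict(fit, perm[hold, ])
    mse_brt <- mean((log1p(perm$count_per_100m2[hold]) - log1p(pred))^2)
    mse_null <- mean((log1p(perm$count_per_100m2[hold]) -
                        mean(log1p(perm$count_per_100m2[-hold])))^2)
    worse <- worse + (mse_brt > 0.9 * mse_null)  # no real skill beyond noise
  }
  expect_gte(worse, 4L)
  expect_error(fit_brt(make_surveys(n = 200, seed = 1), n_trees = 0), "positive")
})

test_that("BRT fitting is deterministic under a fixed seed", {
  sv <- make_surveys(n = 400, species = "A", seed = 63)
  p1 <- abaclim:::component_predict(fit_brt(sv, n_trees = 200, seed = 9), sv[1:20, ])
  p2 <- abaclim:::component_predict(fit_brt(sv, n_trees = 200, seed = 9), sv[1:20, ])
  expect_identical(p1, p2)
})

test_that("ensemble weights: symmetry, limit behaviour and the closed form", {
  sv <- make_surveys(n = 1000, species = "A", seed = 71)
  train <- sv[1:800, ]; valid <- sv[801:1000, ]
  g <- fit_glm(train, "linear", cv_folds = 0)
  b <- fit_brt(train, n_trees = 300, seed = 3)

  # identical components -> exactly (0.5, 0.5)
  dev_g <- sum(abaclim:::count_deviance(
    valid$count_per_100m2, abaclim:::component_predict(g, valid), g$theta))
  w_eq <- exp(-(c(dev_g, dev_g) - dev_g) / 2)
  expect_equal(w_eq / sum(w_eq), c(0.5, 0.5))

  # closed-form agreement for the real pair
  dev_b <- sum(abaclim:::count_deviance(
    valid$count_per_100m2, abaclim:::component_predict(b, valid), g$theta))
  w <- ensemble_weights(g, b, valid)
  delta <- c(dev_g, dev_b) - min(dev_g, dev_b)
  oracle <- exp(-delta / 2) / sum(exp(-delta / 2))
  expect_equal(unname(w), oracle, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # a deviance gap > 20 pushes the better component's weight above 0.99
  delta_big <- c(0, 25)
  w_big <- exp(-delta_big / 2) / sum(exp(-delta_big / 2))
  expect_gt(w_big[1], 0.99)
  expect_error(ensemble_weights(g, b, valid[0, ]), "empty")
  expect_equal(unname(ensemble_weights(g, b, valid, scheme = "equal")),
               c(0.5, 0.5))
})

test_that("predictions follow the closed form when the GLM has full weight", {
  sv <- make_surveys(n = 600, species = "A", seed = 81)
  g <- fit_glm(sv, "linear", cv_folds = 0)
  b <- fit_brt(sv, n_trees = 150, seed = 4)
  ens <- sdm_ensemble(g, b, c(glm = 1, brt = 0), species = "A")
  sst <- const_grid(16, 5, 6, resolution = 0.01)
  pred <- predict_abundance(ens, sst)
  cf <- stats::coef(g$fit)
  eta <- cf[["(Intercept)"]] + cf[["sst_c"]] * (16 - g$sst_center) +
    cf[["depth_m"]] * g$covariate_means[["depth_m"]] +
    cf[["harvest_intensity"]] * g$covariate_means[["harvest_intensity"]] +
    cf[["dist_launch_km"]] * g$covariate_means[["dist_launch_km"]]
  expect_equal(pred$values, matrix(exp(eta), 5, 6), tolerance = 1e-10)
})

test_that("ensemble predictions lie between the component predictions", {
  sv <- make_surveys(n = 600, species = "A", seed = 82)
  g <- fit_glm(sv, "linear", cv_folds = 0)
  b <- fit_brt(sv, n_trees = 200, seed = 5)
  ens <- sdm_ensemble(g, b, c(glm = 0.4, brt = 0.6), species = "A")
  aug <- generate_baseline(small_domain(), "august", seed = 83)
  p_ens <- predict_abundance(ens, aug)$values
  p_glm <- predict_abundance(sdm_ensemble(g, b, c(glm = 1, brt = 0)), aug)$values
  p_brt <- predict_abundance(sdm_ensemble(g, b, c(glm = 0, brt = 1)), aug)$values
  lo <- pmin(p_glm, p_brt); hi <- pmax(p_glm, p_brt)
  ok <- !is.na(p_ens)
  expect_true(all(p_ens[ok] >= lo[ok] - 1e-9 & p_ens[ok] <= hi[ok] + 1e-9))
  expect_true(all(is.finite(p_ens[ok]) & p_ens[ok] >= 0))
})

test_that("species-B predictions are unimodal along an SST gradient", {
  tr <- synthetic_truth()
  sv <- make_surveys(n = 2000, species = "B", seed = 84, truth = tr)
  g <- fit_glm(sv, "quadratic", cv_folds = 0)
  b <- fit_brt(sv, n_trees = 300, seed = 6)
  ens <- sdm_ensemble(g, b, c(glm = 1, brt = 0), species = "B")
  sst <- raster_grid(matrix(seq(13, 20, length.out = 40), 1, 40, byrow = TRUE),
                     130, -36, 0.01)
  prof <- predict_abundance(ens, sst)$values[1, ]
  peak <- which.max(prof)
  expect_gt(peak, 1); expect_lt(peak, 40)  # interior maximum
  expect_true(all(diff(prof[1:peak]) >= 0))
  expect_true(all(diff(prof[peak:40]) <= 0))
})

test_that("decadal projections respect null anomalies and scenario ordering", {
  dom <- small_domain(30, 40)
  tr <- synthetic_truth()
  aug <- generate_baseline(dom, "august", tr, seed = 91)
  sv <- generate_surveys(aug, tr, 800, "A", seed = 92)
  g <- fit_glm(sv, "linear", cv_folds = 0)
  b <- fit_brt(sv, n_trees = 200, seed = 7)
  ens <- sdm_ensemble(g, b, c(glm = 1, brt = 0), species = "A")

  zero_an <- grid_stack(list(const_grid(0, 6, 8, resolution = 0.5,
                                        lon = 129, lat = -37)), decade = 2010)
  proj0 <- project_decades(ens, aug, zero_an)
  expect_equal(proj0$grid[[1]]$values, predict_abundance(ens, aug)$values)

  # monotone warming with a positive linear response: totals non-decreasing
  warm <- grid_stack(purrr::map(c(0, 0.4, 1.1), function(a)
    const_grid(a, 6, 8, resolution = 0.5, lon = 129, lat = -37)),
    decade = c(2010, 2050, 2100))
  proj <- project_decades(ens, aug, warm)
  totals <- purrr::map_dbl(proj$grid, ~ sum(.x$values[.x$mask]))
  expect_true(all(diff(totals) > 0))

  # warmer Reference scenario beats Policy for the warm-loving species
  tr2 <- synthetic_truth()
  ref <- scenario_warming("WRE750", 2100, tr2)
  pol <- scenario_warming("LEV1", 2100, tr2)
  projs <- project_decades(ens, aug, grid_stack(
    purrr::map(c(ref, pol), ~ const_grid(.x, 6, 8, resolution = 0.5,
                                         lon = 129, lat = -37)),
    decade = 2100, scenario = c("WRE750", "LEV1")))
  tot <- purrr::map_dbl(projs$grid, ~ sum(.x$values[.x$mask]))
  expect_gte(tot[1], tot[2])
})

test_that("missing covariates are reported by name", {
  sv <- make_surveys(n = 600, species = "A", seed = 85)
  g <- fit_glm(sv, "linear", cv_folds = 0)
  b <- fit_brt(sv, n_trees = 150, seed = 8)
  ens <- sdm_ensemble(g, b, c(glm = 0.5, brt = 0.5))
  expect_error(predict_abundance(ens, list(depth_m = const_grid(10, 3, 3))),
               "sst_august")
  expect_error(sdm_ensemble(g, b, c(glm = 0.7, brt = 0.7)), "sum to 1")
})

test_that("tidy and glance methods return well-formed tibbles", {
  sv <- make_surveys(n = 600, species = "A", seed = 86)
  g <- fit_glm(sv, "linear", cv_folds = 0)
  b <- fit_brt(sv, n_trees = 150, seed = 9)
  ens <- sdm_ensemble(g, b, ensemble_weights(g, b, sv[1:100, ]), species = "A")
  td <- tidy(ens)
  expect_true(all(c("term", "estimate", "component") %in% names(td)))
  expect_true(all(c("weight_glm", "weight_brt") %in% td$term))
  gl <- glance(ens)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$weight_glm + gl$weight_brt, 1, tolerance = 1e-12)
  expect_s3_class(tidy(g), "tbl_df")
  expect_identical(nrow(glance(g)), 1L)
})
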