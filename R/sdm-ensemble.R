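#' Fit the GLM component of the abundance ensemble
#'
#' Fits a count GLM with log link to survey abundance: a linear August-SST
#' term for species with a monotone thermal response (blacklip) or linear +
#' quadratic (centred) SST terms for a hump-shaped response (greenlip), plus
#' fixed effects of depth, harvest intensity and distance to launch point.
#' The default family is negative binomial (via [MASS::glm.nb()]), matching
#' overdispersed abundance counts; `family = "poisson"` is available.
#'
#' @param surveys A survey tibble as from [generate_surveys()]: columns
#'   `count_per_100m2`, `sst_august`, `depth_m`, `harvest_intensity`,
#'   `dist_launch_km`.
#' @param response_shape `"linear"` or `"quadratic"` August-SST response.
#' @param family `"nb"` (negative binomial, default) or `"poisson"`.
#' @param sst_center Centring constant for the SST terms; defaults to the
#'   training mean. Supplying the generator's centre makes fitted
#'   coefficients directly comparable with the simulation truth.
#' @param cv_folds Folds for the cross-validated deviance (default 5; 0
#'   skips cross-validation).
#' @param seed Seed for the fold assignment.
#' @return An object of class `sdm_glm`: the fitted model, `sst_center`,
#'   `response_shape`, `family`, `cv_deviance` (mean held-out deviance per
#'   observation) and `covariate_means`.
#' @export
fit_glm <- function(surveys, response_shape = c("linear", "quadratic"),
                    family = c("nb", "poisson"), sst_center = NULL,
                    cv_folds = 5, seed = 1) {
  response_shape <- match.arg(response_shape)
  family <- match.arg(family)
  need <- c("count_per_100m2", "sst_august", "depth_m", "harvest_intensity",
            "dist_launch_km")
  stopifnot(all(need %in% names(surveys)))
  n_coef <- if (response_shape == "quadratic") 6L else 5L
  if (nrow(surveys) < 10L * n_coef)
    stop(sprintf("need at least %d records to fit %d coefficients",
                 10L * n_coef, n_coef), call. = FALSE)
  if (response_shape == "quadratic" &&
      length(unique(surveys$sst_august)) < 3)
    stop("quadratic SST response needs at least 3 distinct SST values",
         call. = FALSE)
  if (is.null(sst_center)) sst_center <- mean(surveys$sst_august)
  dat <- dplyr::mutate(surveys, sst_c = .data$sst_august - sst_center)
  fml <- if (response_shape == "quadratic")
    count_per_100m2 ~ sst_c + I(sst_c^2) + depth_m + harvest_intensity + dist_launch_km
  else
    count_per_100m2 ~ sst_c + depth_m + harvest_intensity + dist_launch_km
  fit_one <- function(d) {
    if (family == "nb") {
      fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(fml, data = d, control = stats::glm.control(maxit = 100))),
        error = function(e) stop("GLM did not converge: ", conditionMessage(e),
                                 call. = FALSE))
    } else {
      fit <- stats::glm(fml, data = d, family = stats::poisson())
    }
    if (!isTRUE(fit$converged))
      stop(sprintf("GLM did not converge after %d iterations", fit$iter), call. = FALSE)
    fit
  }
  fit <- fit_one(dat)
  cv_dev <- NA_real_
  if (cv_folds > 0) {
    theta <- if (family == "nb") fit$theta else Inf
    folds <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), nrow(dat))))
    dev <- vapply(seq_len(cv_folds), function(k) {
      f <- fit_one(dat[folds != k, ])
      mu <- stats::predict(f, newdata = dat[folds == k, ], type = "response")
      sum(count_deviance(dat$count_per_100m2[folds == k], mu, theta))
    }, 0)
    cv_dev <- sum(dev) / nrow(dat)
  }
  structure(list(fit = fit, sst_center = sst_center,
                 response_shape = response_shape, family = family,
                 theta = if (family == "nb") fit$theta else Inf,
                 cv_deviance = cv_dev,
                 covariate_means = colMeans(dat[c("depth_m", "harvest_intensity",
                                                  "dist_launch_km")])),
            class = "sdm_glm")
}

# unit deviance of counts about mean mu: negative binomial with size theta,
# Poisson in the theta = Inf limit
count_deviance <- function(y, mu, theta) {
  mu <- pmax(mu, 1e-10)
  if (is.infinite(theta)) {
    2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else {
    2 * (ifelse(y > 0, y * log(y / mu), 0) -
           (y + theta) * log((y + theta) / (mu + theta)))
  }
}

#' @export
print.sdm_glm <- function(x, ...) {
  cat(sprintf("<sdm_glm> %s response, %s family, %d obs; CV deviance/obs %.4f\n",
              x$response_shape, x$family, stats::nobs(x$fit), x$cv_deviance))
  print(stats::coef(x$fit))
  invisible(x)
}

#' Thermal optimum implied by a quadratic SST response
#'
#' For a fitted quadratic (hump-shaped) SST term, the abundance-maximising
#' August SST, `sst_center - b1/(2 b2)` on the original scale.
#'
#' @param glm_component An `sdm_glm` with `response_shape = "quadratic"`.
#' @return Optimum SST in deg C.
#' @export
thermal_optimum <- function(glm_component) {
  stopifnot(inherits(glm_component, "sdm_glm"),
            glm_component$response_shape == "quadratic")
  b <- stats::coef(glm_component$fit)
  glm_component$sst_center - b[["sst_c"]] / (2 * b[["I(sst_c^2)"]])
}

#' Fit the boosted-regression-tree component
#'
#' Gradient-boosted shallow regression trees on log1p(counts) (squared-error
#' loss), the standard BRT recipe in abundance modelling: tree depth 3,
#' learning rate 0.01, bag fraction 0.5, early stopping on a 20% holdout.
#' Deterministic under a fixed seed (single-threaded).
#'
#' @inheritParams fit_glm
#' @param depth Maximum tree depth.
#' @param learning_rate Shrinkage per tree.
#' @param n_trees Maximum number of trees (> 0).
#' @param bag_fraction Row subsample fraction per tree.
#' @param holdout_fraction Fraction of records held out for early stopping.
#' @param seed Seed controlling the holdout split and bagging.
#' @return An object of class `sdm_brt` wrapping the xgboost booster, its
#'   hyperparameters, the best iteration and the holdout deviance.
#' @export
fit_brt <- function(surveys, depth = 3, learning_rate = 0.01, n_trees = 2000,
                    bag_fraction = 0.5, holdout_fraction = 0.2, seed = 1) {
  if (n_trees <= 0) stop("n_trees must be positive", call. = FALSE)
  if (nrow(surveys) < 100)
    stop("need at least 100 records to fit the BRT component", call. = FALSE)
  feats <- c("sst_august", "depth_m", "harvest_intensity", "dist_launch_km")
  X <- as.matrix(surveys[feats])
  y <- log1p(surveys$count_per_100m2)
  n <- nrow(X)
  withr::with_seed(seed, {
    hold <- sample.int(n, max(1L, round(holdout_fraction * n)))
    dtrain <- xgboost::xgb.DMatrix(X[-hold, , drop = FALSE], label = y[-hold])
    dvalid <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE], label = y[hold])
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = depth,
                    eta = learning_rate, subsample = bag_fraction,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = n_trees,
      evals = list(valid = dvalid),
      early_stopping_rounds = 50, verbose = 0
    )
  })
  structure(list(booster = booster, features = feats,
                 best_iteration = as.integer(xgboost::xgb.attr(booster, "best_iteration")),
                 holdout_rmse = as.numeric(xgboost::xgb.attr(booster, "best_score")),
                 hyperparameters = list(depth = depth,
                                        learning_rate = learning_rate,
                                        n_trees = n_trees,
                                        bag_fraction = bag_fraction,
                                        holdout_fraction = holdout_fraction,
                                        seed = seed)),
            class = "sdm_brt")
}

#' @export
print.sdm_brt <- function(x, ...) {
  cat(sprintf("<sdm_brt> depth %d, eta %g, %d trees (early-stopped), holdout RMSE %.4f\n",
              x$hyperparameters$depth, x$hyperparameters$learning_rate,
              x$best_iteration, x$holdout_rmse))
  invisible(x)
}

# mean abundance predicted by either component on new data
component_predict <- function(component, newdata) {
  if (inherits(component, "sdm_glm")) {
    nd <- dplyr::mutate(newdata, sst_c = .data$sst_august - component$sst_center)
    as.vector(stats::predict(component$fit, newdata = nd, type = "response"))
  } else if (inherits(component, "sdm_brt")) {
    X <- as.matrix(newdata[component$features])
    # early-stopped boosters predict at their best iteration by default
    pmax(expm1(stats::predict(component$booster, X)), 0)
  } else stop("unknown SDM component", call. = FALSE)
}

#' Ensemble weights from held-out deviance
#'
#' Weights the GLM and BRT components by their predictive skill on a
#' validation set disjoint from training: weights proportional to
#' \eqn{\exp(-\Delta/2)} where \eqn{\Delta} is each component's total
#' validation deviance minus the best component's (the deviance-based
#' analogue of information-criterion weights). Equally skilled components get
#' weights (0.5, 0.5); a component whose deviance is worse by more than ~20
#' gets essentially zero weight.
#'
#' @param glm_component An `sdm_glm`.
#' @param brt_component An `sdm_brt`.
#' @param validation Held-out survey tibble (non-empty, disjoint from
#'   training).
#' @param scheme `"deviance"` (default) or `"equal"`.
#' @return Named numeric vector `c(glm = , brt = )`, non-negative, summing
#'   to 1.
#' @export
ensemble_weights <- function(glm_component, brt_component, validation,
                             scheme = c("deviance", "equal")) {
  scheme <- match.arg(scheme)
  if (is.null(validation) || nrow(validation) == 0)
    stop("validation set is empty", call. = FALSE)
  if (scheme == "equal") return(c(glm = 0.5, brt = 0.5))
  theta <- glm_component$theta
  y <- validation$count_per_100m2
  dev <- c(glm = sum(count_deviance(y, component_predict(glm_component, validation), theta)),
           brt = sum(count_deviance(y, component_predict(brt_component, validation), theta)))
  w <- exp(-(dev - min(dev)) / 2)
  w / sum(w)
}

#' Assemble a fitted SDM ensemble
#'
#' Bundles the GLM and BRT components with their weights and the covariate
#' recipe used at prediction time: every non-SST covariate is fixed to its
#' training mean when projecting (future forecasts exist only for SST).
#'
#' @param glm_component An `sdm_glm`.
#' @param brt_component An `sdm_brt`.
#' @param weights Named weights `c(glm =, brt =)` from [ensemble_weights()].
#' @param species Optional species label carried into outputs.
#' @return An object of class `sdm_ensemble`.
#' @export
sdm_ensemble <- function(glm_component, brt_component, weights,
                         species = NA_character_) {
  stopifnot(inherits(glm_component, "sdm_glm"), inherits(brt_component, "sdm_brt"),
            length(weights) == 2, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("ensemble weights must sum to 1", call. = FALSE)
  structure(list(glm_component = glm_component, brt_component = brt_component,
                 weights = c(glm = unname(weights[["glm"]]), brt = unname(weights[["brt"]])),
                 covariate_recipe = list(
                   fixed = as.list(glm_component$covariate_means),
                   features = c("sst_august", "depth_m", "harvest_intensity",
                                "dist_launch_km")),
                 species = species),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> species %s: w_glm = %.3f, w_brt = %.3f\n",
              x$species, x$weights[["glm"]], x$weights[["brt"]]))
  invisible(x)
}

#' Predict abundance on covariate grids
#'
#' Cell-wise model-averaged abundance, `w_glm * GLM + w_brt * BRT`
#' (individuals per 100 m^2, non-negative), on the geometry of the SST grid.
#' Non-SST covariates may be supplied as grids; absent ones are fixed to the
#' recipe's training means.
#'
#' @param ensemble An [sdm_ensemble()].
#' @param covariate_grids A named list of [raster_grid()]s containing at
#'   least `sst_august`, all on one geometry; or a single [raster_grid()]
#'   taken to be August SST.
#' @return A [raster_grid()] of predicted abundance.
#' @export
predict_abundance <- function(ensemble, covariate_grids) {
  if (inherits(covariate_grids, "raster_grid"))
    covariate_grids <- list(sst_august = covariate_grids)
  if (!"sst_august" %in% names(covariate_grids))
    stop("missing covariate grid: sst_august", call. = FALSE)
  sst <- covariate_grids$sst_august
  for (nm in names(covariate_grids))
    same_geometry_or_stop(sst, covariate_grids[[nm]], "covariate grids")
  idx <- which(sst$mask, arr.ind = TRUE)
  newdata <- tibble::tibble(sst_august = sst$values[idx])
  for (nm in setdiff(ensemble$covariate_recipe$features, "sst_august")) {
    newdata[[nm]] <- if (nm %in% names(covariate_grids))
      covariate_grids[[nm]]$values[idx]
    else {
      if (is.null(ensemble$covariate_recipe$fixed[[nm]]))
        stop(sprintf("missing covariate: %s", nm), call. = FALSE)
      ensemble$covariate_recipe$fixed[[nm]]
    }
  }
  w <- ensemble$weights
  pred <- w[["glm"]] * component_predict(ensemble$glm_component, newdata) +
    w[["brt"]] * component_predict(ensemble$brt_component, newdata)
  vals <- matrix(NA_real_, nrow(sst$values), ncol(sst$values))
  vals[idx] <- pmax(pred, 0)
  raster_grid(vals, sst$lon_origin, sst$lat_origin, sst$resolution,
              mask = sst$mask, variable = "abundance")
}

#' Project abundance at decadal time slices
#'
#' For each (decade, scenario) anomaly grid, downscales the anomaly onto the
#' August baseline via [change_factor()] and predicts model-averaged
#' abundance, holding all non-SST covariates at their training values.
#'
#' @param ensemble An [sdm_ensemble()].
#' @param baseline_august Fine-resolution August SST [raster_grid()].
#' @param anomalies A [grid_stack()] tibble with columns `decade`
#'   (optionally `scenario`) and `grid` of mid-resolution anomalies (e.g.
#'   the output of [select_and_average()] refined by [bilinear_refine()]).
#' @param method Passed to [change_factor()].
#' @return A [grid_stack()] tibble with `decade` (and `scenario`) labels and
#'   an abundance `grid` list-column.
#' @export
project_decades <- function(ensemble, baseline_august, anomalies,
                            method = "nearest") {
  stopifnot(nrow(anomalies) >= 1, "grid" %in% names(anomalies))
  out <- anomalies
  out$grid <- purrr::map(anomalies$grid, function(an) {
    sst <- change_factor(baseline_august, an, method = method)
    predict_abundance(ensemble, list(sst_august = sst))
  })
  out
}

#' @rdname tidy.sdm_ensemble
#' @export
tidy.sdm_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.sdm_ensemble
#' @export
glance.sdm_glm <- function(x, ...) {
  tibble::tibble(family = x$family, response_shape = x$response_shape,
                 theta = x$theta, sst_center = x$sst_center,
                 logLik = as.numeric(stats::logLik(x$fit)),
                 deviance = stats::deviance(x$fit), cv_deviance = x$cv_deviance,
                 nobs = stats::nobs(x$fit))
}

#' Tidiers for fitted SDM objects
#'
#' Broom-style [generics::tidy()] / [generics::glance()] methods: `tidy()`
#' returns per-term coefficients (GLM terms plus the two ensemble weights);
#' `glance()` returns one-row model summaries.
#'
#' @param x A fitted `sdm_glm` or `sdm_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdm_ensemble <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy.sdm_glm(x$glm_component), component = "glm"),
    tibble::tibble(term = c("weight_glm", "weight_brt"),
                   estimate = unname(x$weights), component = "ensemble")
  )
}

#' @rdname tidy.sdm_ensemble
#' @export
glance.sdm_ensemble <- function(x, ...) {
  tibble::tibble(species = x$species, weight_glm = x$weights[["glm"]],
                 weight_brt = x$weights[["brt"]],
                 glm_cv_deviance = x$glm_component$cv_deviance,
                 brt_trees = x$brt_component$best_iteration)
}
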