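#' Fit a thin-plate smoothing spline with GCV-selected smoothness
#'
#' Fits the classical 2-D thin-plate spline (radial kernel \eqn{r^2 \log r}
#' plus an affine part) to scattered (lon, lat, value) data, solving the
#' penalized augmented system for each candidate smoothing parameter
#' \eqn{\lambda} and selecting the one minimizing the generalized
#' cross-validation criterion
#' \deqn{GCV(\lambda) = n \, RSS(\lambda) / (n - tr H(\lambda))^2,}
#' where \eqn{H(\lambda)} is the influence (hat) matrix, computed exactly.
#' With \eqn{\lambda = 0} and distinct points the surface interpolates the
#' data (GCV is then undefined and such candidates are rejected unless no
#' candidate has positive equivalent residual degrees of freedom, in which
#' case the smallest-\eqn{\lambda} fit is returned with an infinite GCV
#' score). Deterministic; intended for up to ~2000 knots (dense algebra).
#'
#' @param points A data frame with columns `lon`, `lat`, `value` (>= 4
#'   non-collinear points).
#' @param lambda_grid Candidate smoothing parameters (default log-spaced over
#'   8 decades, 1e-6 to 1e2).
#' @return An object of class `tps_fit`: knots, coefficients (`c` radial,
#'   `a` affine), `lambda`, `gcv_score`, and the full `gcv_table` tibble.
#' @export
tps_fit <- function(points, lambda_grid = 10^seq(-6, 2, length.out = 17)) {
  stopifnot(all(c("lon", "lat", "value") %in% names(points)),
            length(lambda_grid) >= 1, all(lambda_grid >= 0))
  x <- points$lon; y <- points$lat; v <- points$value
  n <- length(v)
  if (n < 4) stop("need at least 4 points to fit a thin-plate spline", call. = FALSE)
  P <- cbind(1, x, y)
  if (qr(P)$rank < 3)
    stop("points are collinear or duplicate-only: thin-plate system is singular",
         call. = FALSE)
  K <- tps_kernel_matrix(x, y, x, y)
  lambda_grid <- sort(lambda_grid)
  fits <- purrr::map(lambda_grid, function(lam) {
    M <- rbind(cbind(K + n * lam * diag(n), P),
               cbind(t(P), matrix(0, 3, 3)))
    Minv <- tryCatch(solve(M), error = function(e)
      stop("thin-plate system is singular (duplicate points?)", call. = FALSE))
    B <- Minv[, seq_len(n), drop = FALSE]
    coefs <- B %*% v
    H <- cbind(K, P) %*% B
    fitted <- as.vector(H %*% v)
    rss <- sum((v - fitted)^2)
    edf <- n - sum(diag(H))
    gcv <- if (edf > 1e-8) n * rss / edf^2 else Inf
    list(lambda = lam, c = coefs[seq_len(n)], a = coefs[n + 1:3],
         rss = rss, edf_resid = edf, gcv = gcv)
  })
  gcv_table <- tibble::tibble(
    lambda = lambda_grid,
    rss = purrr::map_dbl(fits, "rss"),
    edf_resid = purrr::map_dbl(fits, "edf_resid"),
    gcv = purrr::map_dbl(fits, "gcv")
  )
  best <- if (all(is.infinite(gcv_table$gcv))) 1L else which.min(gcv_table$gcv)
  f <- fits[[best]]
  structure(list(knots_lon = x, knots_lat = y, coef_radial = f$c,
                 coef_affine = f$a, lambda = f$lambda, gcv_score = f$gcv,
                 gcv_table = gcv_table, n = n),
            class = "tps_fit")
}

# r^2 log r kernel between point sets, with E(0) = 0
tps_kernel_matrix <- function(x1, y1, x2, y2) {
  r2 <- outer(x1, x2, `-`)^2 + outer(y1, y2, `-`)^2
  E <- 0.5 * r2 * log(pmax(r2, .Machine$double.xmin))
  E[r2 == 0] <- 0
  E
}

#' @export
print.tps_fit <- function(x, ...) {
  cat(sprintf("<tps_fit> %d knots, lambda = %g (GCV = %g)\n",
              x$n, x$lambda, x$gcv_score))
  invisible(x)
}

#' Predict from a thin-plate spline at arbitrary points
#'
#' @param object A [tps_fit()].
#' @param lon,lat Coordinate vectors.
#' @param ... Unused.
#' @return Numeric vector of surface values.
#' @export
predict.tps_fit <- function(object, lon, lat, ...) {
  E <- tps_kernel_matrix(lon, lat, object$knots_lon, object$knots_lat)
  as.vector(E %*% object$coef_radial) +
    object$coef_affine[1] + object$coef_affine[2] * lon + object$coef_affine[3] * lat
}

#' Evaluate a thin-plate surface on a grid
#'
#' Evaluates the fitted surface at every sea-cell centre of a target geometry.
#'
#' @param fit A [tps_fit()].
#' @param target A [raster_grid()] (geometry and mask template) or a
#'   [domain_geometry()] (all cells valid unless `mask` given).
#' @param mask Optional logical matrix overriding the target mask.
#' @param variable Variable label for the output grid.
#' @return A [raster_grid()].
#' @export
tps_evaluate <- function(fit, target, mask = NULL, variable = "sst_smoothed") {
  if (inherits(target, "domain_geometry")) {
    target <- raster_grid(matrix(0, target$nrow, target$ncol), target$lon_origin,
                          target$lat_origin, target$resolution,
                          mask = if (is.null(mask)) NULL else mask)
  }
  msk <- if (is.null(mask)) target$mask else mask
  idx <- which(msk, arr.ind = TRUE)
  lon <- target$lon_origin + (idx[, 2] - 1) * target$resolution
  lat <- target$lat_origin + (idx[, 1] - 1) * target$resolution
  vals <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  vals[idx] <- predict.tps_fit(fit, lon, lat)
  raster_grid(vals, target$lon_origin, target$lat_origin, target$resolution,
              mask = msk, variable = variable)
}

#' Bilinear refinement of a coarse anomaly field
#'
#' Interpolates a coarse grid (e.g. 2.5 deg GCM output) to a finer resolution
#' (e.g. 0.5 deg) by standard bilinear interpolation on cell centres, to
#' reduce discontinuities at coarse grid-box boundaries before the change
#' factors are applied. Values at coarse cell centres are preserved and every
#' output value is bounded by the four surrounding coarse values; fine centres
#' outside the hull of coarse centres take the edge value (constant
#' extrapolation), preserving boundedness.
#'
#' @param coarse A [raster_grid()].
#' @param target_resolution Output resolution in degrees; must be finer than
#'   the input.
#' @return A [raster_grid()] with the same origin, spanning the hull of the
#'   coarse cell centres.
#' @export
bilinear_refine <- function(coarse, target_resolution = 0.5) {
  if (target_resolution >= coarse$resolution)
    stop("target resolution must be finer than the source resolution", call. = FALSE)
  nr_c <- nrow(coarse$values); nc_c <- ncol(coarse$values)
  span_lon <- (nc_c - 1) * coarse$resolution
  span_lat <- (nr_c - 1) * coarse$resolution
  nc_f <- floor(span_lon / target_resolution + 1e-9) + 1L
  nr_f <- floor(span_lat / target_resolution + 1e-9) + 1L
  lon <- coarse$lon_origin + (seq_len(nc_f) - 1) * target_resolution
  lat <- coarse$lat_origin + (seq_len(nr_f) - 1) * target_resolution
  vals <- bilinear_at(coarse, rep(lon, each = nr_f), rep(lat, times = nc_f))
  raster_grid(matrix(vals, nr_f, nc_f), coarse$lon_origin, coarse$lat_origin,
              target_resolution, variable = coarse$variable)
}

# bilinear interpolation of a grid at arbitrary points, clamped to the
# hull of cell centres (constant extrapolation at edges)
bilinear_at <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  gx <- (lon - grid$lon_origin) / grid$resolution
  gy <- (lat - grid$lat_origin) / grid$resolution
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  j0 <- pmin(floor(gx), nc - 2); i0 <- pmin(floor(gy), nr - 2)
  fx <- gx - j0; fy <- gy - i0
  v <- grid$values
  idx <- function(i, j) v[cbind(i + 1, j + 1)]
  (1 - fy) * ((1 - fx) * idx(i0, j0) + fx * idx(i0, j0 + 1)) +
    fy * ((1 - fx) * idx(i0 + 1, j0) + fx * idx(i0 + 1, j0 + 1))
}

#' Change-factor downscaling onto a fine baseline
#'
#' Adds a mid-resolution climate anomaly directly to a fine-resolution
#' baseline climatology: each fine sea cell receives the anomaly of its
#' parent (nearest-centre) anomaly cell, so the projected field preserves all
#' within-parent-cell spatial detail of the baseline and the difference
#' projected - baseline is piecewise constant on parent blocks. Fine cells
#' whose nearest parent lies just outside the anomaly grid (or is invalid)
#' take the nearest valid parent within one cell; farther gaps are an error.
#'
#' @param baseline_fine Fine-resolution [raster_grid()] (e.g. 0.01 deg).
#' @param anomaly_mid Mid-resolution anomaly [raster_grid()] (e.g. 0.5 deg)
#'   covering the baseline extent.
#' @param method `"nearest"` (default; the anomaly is added directly) or
#'   `"bilinear"` (a second interpolation of the anomaly to fine centres).
#' @param variable Variable label for the output.
#' @return A [raster_grid()] on the baseline geometry and mask.
#' @export
change_factor <- function(baseline_fine, anomaly_mid,
                          method = c("nearest", "bilinear"),
                          variable = "sst_projected") {
  method <- match.arg(method)
  b <- baseline_fine
  idx <- which(b$mask, arr.ind = TRUE)
  lon <- b$lon_origin + (idx[, 2] - 1) * b$resolution
  lat <- b$lat_origin + (idx[, 1] - 1) * b$resolution
  a <- anomaly_mid
  if (method == "bilinear") {
    add <- bilinear_at(a, lon, lat)
    if (anyNA(add)) stop("anomaly grid has invalid cells under the baseline", call. = FALSE)
  } else {
    nr <- nrow(a$values); nc <- ncol(a$values)
    gj <- round((lon - a$lon_origin) / a$resolution)
    gi <- round((lat - a$lat_origin) / a$resolution)
    # allow snapping back by at most one parent cell at the edge of coverage
    out_by <- pmax(0, -gj, gj - (nc - 1), -gi, gi - (nr - 1))
    if (any(out_by > 1)) {
      bad <- which(out_by > 1)
      stop(sprintf(
        "anomaly grid does not cover %d baseline cell(s), e.g. (lon %.4f, lat %.4f)",
        length(bad), lon[bad[1]], lat[bad[1]]), call. = FALSE)
    }
    gj <- pmin(pmax(gj, 0), nc - 1)
    gi <- pmin(pmax(gi, 0), nr - 1)
    add <- a$values[cbind(gi + 1, gj + 1)]
    if (anyNA(add)) {
      # nearest valid parent within one cell (coastal clipping of coarse grids)
      for (k in which(is.na(add))) {
        nb <- expand.grid(di = -1:1, dj = -1:1)
        ii <- pmin(pmax(gi[k] + nb$di, 0), nr - 1)
        jj <- pmin(pmax(gj[k] + nb$dj, 0), nc - 1)
        vv <- a$values[cbind(ii + 1, jj + 1)]
        ok <- which(!is.na(vv))
        if (!length(ok))
          stop(sprintf("no valid anomaly parent within 1 cell of (lon %.4f, lat %.4f)",
                       lon[k], lat[k]), call. = FALSE)
        d2 <- (a$lon_origin + jj * a$resolution - lon[k])^2 +
          (a$lat_origin + ii * a$resolution - lat[k])^2
        add[k] <- vv[ok[which.min(d2[ok])]]
      }
    }
  }
  vals <- matrix(NA_real_, nrow(b$values), ncol(b$values))
  vals[idx] <- b$values[idx] + add
  raster_grid(vals, b$lon_origin, b$lat_origin, b$resolution, mask = b$mask,
              variable = variable)
}
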