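#' Skill statistics of a modelled field against observations
#'
#' The four validation statistics used to score a climate model's simulated
#' field against an observed baseline over the shared valid cells:
#' \describe{
#'   \item{bias}{spatial mean of the model minus spatial mean of the
#'     observations (deg C);}
#'   \item{pattern_correlation}{Pearson correlation of the two fields after
#'     removing each field's spatial mean;}
#'   \item{rmse}{root-mean-square of the cell-wise differences;}
#'   \item{centred_rmse}{RMSE after removing each field's spatial mean.}
#' }
#' These satisfy the identity rmse^2 = bias^2 + centred_rmse^2.
#'
#' @param model_field,observed_field [raster_grid()]s on identical geometry
#'   with at least 3 shared valid cells.
#' @return A one-row tibble with columns `bias`, `pattern_correlation`,
#'   `rmse`, `centred_rmse`.
#' @export
skill_stats <- function(model_field, observed_field) {
  same_geometry_or_stop(model_field, observed_field, "model and observed fields")
  ok <- model_field$mask & observed_field$mask
  if (sum(ok) < 3)
    stop("fewer than 3 shared valid cells; correlation undefined", call. = FALSE)
  m <- model_field$values[ok]
  o <- observed_field$values[ok]
  dm <- m - mean(m); do <- o - mean(o)
  tibble::tibble(
    bias = mean(m) - mean(o),
    pattern_correlation = stats::cor(dm, do),
    rmse = sqrt(mean((m - o)^2)),
    centred_rmse = sqrt(mean((dm - do)^2))
  )
}

#' Rank climate models on their skill statistics
#'
#' Rather than comparing raw statistic values across models, each statistic is
#' converted to a rank (1 = best: smallest |bias|, largest pattern
#' correlation, smallest RMSE, smallest centred RMSE; ties get the average of
#' the tied ranks) and the four ranks are summed into the cumulative rank —
#' the overall comparison metric, smaller is better.
#'
#' @param tables A tibble with one row per model: columns `model`, `bias`,
#'   `pattern_correlation`, `rmse`, `centred_rmse` (as from [skill_stats()]).
#' @return The input with added `rank_bias`, `rank_cor`, `rank_rmse`,
#'   `rank_crmse`, `cumulative_rank`, sorted ascending by cumulative rank.
#' @export
rank_models <- function(tables) {
  need <- c("model", "bias", "pattern_correlation", "rmse", "centred_rmse")
  missing_col <- setdiff(need, names(tables))
  if (length(missing_col))
    stop("skill table missing column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  if (nrow(tables) < 2) stop("need at least 2 models to rank", call. = FALSE)
  bad <- tables$model[!stats::complete.cases(tables[need[-1]])]
  if (length(bad))
    stop("missing statistic for model(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tables |>
    dplyr::mutate(
      rank_bias = rank(abs(.data$bias), ties.method = "average"),
      rank_cor = rank(-.data$pattern_correlation, ties.method = "average"),
      rank_rmse = rank(.data$rmse, ties.method = "average"),
      rank_crmse = rank(.data$centred_rmse, ties.method = "average"),
      cumulative_rank = .data$rank_bias + .data$rank_cor + .data$rank_rmse +
        .data$rank_crmse
    ) |>
    dplyr::arrange(.data$cumulative_rank)
}

# mean over a list of matrices
matrix_mean <- function(mats) Reduce(`+`, mats) / length(mats)

#' Outlier analysis of model projections
#'
#' Compares each model's projected anomaly with the average projection of all
#' other models: a model's outlier score is the spatial-mean absolute
#' difference between its field and the cell-wise mean of the remaining
#' models' fields (averaged over decades when several are supplied). Models
#' whose score exceeds `flag_multiple` times the median score are flagged.
#'
#' @param anomalies A [grid_stack()] tibble with columns `model`, `grid` (and
#'   optionally `decade`/`scenario` labels); at least 3 models.
#' @param flag_multiple Flagging threshold as a multiple of the median score
#'   (default 3).
#' @return A tibble with columns `model`, `outlier_score` (deg C), `flagged`.
#' @export
outlier_analysis <- function(anomalies, flag_multiple = 3) {
  models <- unique(anomalies$model)
  if (length(models) < 3) stop("outlier analysis needs at least 3 models", call. = FALSE)
  g1 <- anomalies$grid[[1]]
  per_decade <- split(seq_len(nrow(anomalies)), anomalies$model)
  # mean field per model across its stack rows
  fields <- purrr::map(per_decade, function(i) {
    matrix_mean(purrr::map(anomalies$grid[i], "values"))
  })[models]
  scores <- purrr::map_dbl(seq_along(models), function(m) {
    others <- matrix_mean(fields[-m])
    d <- abs(fields[[m]] - others)
    mean(d[g1$mask])
  })
  med <- stats::median(scores)
  tibble::tibble(model = models, outlier_score = scores,
                 flagged = scores > flag_multiple * med)
}

#' Select the best-ranked models and average their anomaly fields
#'
#' Takes the `k` models with the smallest cumulative rank and forms the
#' unweighted cell-wise mean of their anomaly fields, per decade (and
#' scenario); the result's mask is the intersection of the member masks. Five
#' models is the conventional ensemble size: fewer makes the average
#' sensitive to model choice, more adds little.
#'
#' @param anomalies A [grid_stack()] tibble with columns `model`, `decade`,
#'   `grid` (optionally `scenario`).
#' @param ranking Output of [rank_models()] (column `model` in rank order).
#' @param k Number of top-ranked models to average (default 5).
#' @return A [grid_stack()] tibble with columns `decade` (and `scenario`) and
#'   the ensemble-mean `grid`.
#' @export
select_and_average <- function(anomalies, ranking, k = 5) {
  models <- ranking$model
  if (k > length(models))
    stop(sprintf("k = %d exceeds the %d ranked models", k, length(models)),
         call. = FALSE)
  top <- models[seq_len(k)]
  sel <- anomalies[anomalies$model %in% top, ]
  keys <- intersect(c("decade", "scenario"), names(sel))
  sel |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(grid = {
      gs <- .data$grid
      g1 <- gs[[1]]
      vals <- matrix_mean(purrr::map(gs, "values"))
      msk <- Reduce(`&`, purrr::map(gs, "mask"))
      list(raster_grid(vals, g1$lon_origin, g1$lat_origin, g1$resolution,
                       mask = msk, variable = "anomaly"))
    }, .groups = "drop")
}
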