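#' Pipeline configuration
#'
#' A single validated configuration object driving every stage of the
#' projection pipeline, with per-stage seeds so any stage can be re-run
#' reproducibly. Round-trips through YAML via [write_config()] /
#' [read_config()].
#'
#' @param domain A [domain_geometry()] (the fine working grid).
#' @param decades Decadal time slices (years within 2010-2100).
#' @param scenarios Character vector of emissions scenarios (subset of
#'   `"WRE750"`, `"LEV1"`).
#' @param n_models Number of candidate GCMs to emulate.
#' @param ensemble_k Number of best-ranked models averaged (default 5).
#' @param spread_sd Inter-model anomaly spread (deg C).
#' @param outlier_bias Constant bias of the planted outlier model (0 = none).
#' @param noise_sd Observation noise of the baseline climatology (deg C).
#' @param n_records Survey records generated per species.
#' @param species Species to model (`"A"` blacklip linear, `"B"` greenlip
#'   quadratic).
#' @param family GLM family, `"nb"` or `"poisson"`.
#' @param weight_scheme Ensemble weighting, `"deviance"` or `"equal"`.
#' @param brt_trees Maximum BRT trees (early-stopped).
#' @param tps_knots Knots sampled from the noisy baseline for the thin-plate
#'   smoothing of the climatology.
#' @param ground_threshold Fishing-ground density threshold (per 100 m^2).
#' @param march_bins Interior March-SST category boundaries (deg C).
#' @param occupancy_cutoff Present-day abundance defining the "current
#'   distribution" mask (per 100 m^2).
#' @param downscale_method `"nearest"` or `"bilinear"` anomaly transfer.
#' @param seed Base seed; per-stage seeds are derived as small fixed offsets.
#' @param outdir Output directory for stage artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(domain = domain_geometry(),
                            decades = c(2050, 2075, 2100),
                            scenarios = c("WRE750", "LEV1"),
                            n_models = 6, ensemble_k = 5, spread_sd = 0.15,
                            outlier_bias = 0, noise_sd = 0.3,
                            n_records = 500, species = c("A", "B"),
                            family = "nb", weight_scheme = "deviance",
                            brt_trees = 300, tps_knots = 250,
                            ground_threshold = 20, march_bins = c(17, 20),
                            occupancy_cutoff = 0.5,
                            downscale_method = "nearest",
                            seed = 1, outdir = tempfile("abaclim_run_")) {
  decades <- sort(unique(round(decades)))
  stopifnot(all(decades >= 2010 & decades <= 2100),
            all(scenarios %in% c("WRE750", "LEV1")),
            n_models >= 2, ensemble_k <= n_models,
            all(species %in% c("A", "B")), ground_threshold > 0)
  structure(list(domain = domain, decades = decades, scenarios = scenarios,
                 n_models = n_models, ensemble_k = ensemble_k,
                 spread_sd = spread_sd, outlier_bias = outlier_bias,
                 noise_sd = noise_sd, n_records = n_records, species = species,
                 family = family, weight_scheme = weight_scheme,
                 brt_trees = brt_trees, tps_knots = tps_knots,
                 ground_threshold = ground_threshold, march_bins = march_bins,
                 occupancy_cutoff = occupancy_cutoff,
                 downscale_method = downscale_method,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$domain <- unclass(x$domain)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$domain <- do.call(domain_geometry, x$domain)
  do.call(pipeline_config, x)
}

stage_seed <- function(config, stage) {
  offsets <- c(synth = 11L, gcm = 23L, downscale = 37L, sdm = 41L,
               project = 53L, range = 61L, overlay = 71L, mortality = 83L)
  config$seed + offsets[[stage]]
}

stage_path <- function(config, ...) file.path(config$outdir, sprintf(...))

require_artifact <- function(config, file, producer) {
  p <- file.path(config$outdir, file)
  if (!file.exists(p))
    stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                 file, producer), call. = FALSE)
  p
}

#' Run one pipeline stage (or all of them)
#'
#' Executes a stage of the projection pipeline against `config$outdir`,
#' writing plain-text artifacts (ESRI ASCII grids, CSV, JSON) plus a
#' manifest of every file with its MD5 hash. `"all"` runs the stages in
#' dependency order: synth, gcm, downscale, sdm, project, range, overlay,
#' mortality. Stages are idempotent given identical config: re-running
#' produces bit-identical artifacts.
#'
#' @param stage One of `"synth"`, `"gcm"`, `"downscale"`, `"sdm"`,
#'   `"project"`, `"range"`, `"overlay"`, `"mortality"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
run_stage <- function(stage = c("all", "synth", "gcm", "downscale", "sdm",
                                "project", "range", "overlay", "mortality"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("synth", "gcm", "downscale", "sdm", "project", "range", "overlay",
      "mortality")
  else stage
  for (s in stages) {
    fn <- switch(s, synth = stage_synth, gcm = stage_gcm,
                 downscale = stage_downscale, sdm = stage_sdm,
                 project = stage_project, range = stage_range,
                 overlay = stage_overlay, mortality = stage_mortality)
    fn(config)
  }
  files <- sort(setdiff(list.files(config$outdir, recursive = TRUE),
                        "manifest.csv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$outdir, files)))
  )
  utils::write.csv(manifest, file.path(config$outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config = pipeline_config()) run_stage("all", config)

truth_of <- function(config) synthetic_truth()

stage_synth <- function(config) {
  truth <- truth_of(config)
  seed <- stage_seed(config, "synth")
  aug <- generate_baseline(config$domain, "august", truth, config$noise_sd, seed)
  mar <- generate_baseline(config$domain, "march", truth, config$noise_sd, seed + 1)
  write_raster(aug, stage_path(config, "baseline_august.asc"))
  write_raster(mar, stage_path(config, "baseline_march.asc"))
  for (sp in config$species) {
    sv <- generate_surveys(aug, truth, config$n_records, sp,
                           seed + match(sp, c("A", "B")))
    utils::write.csv(sv, stage_path(config, "surveys_%s.csv", sp),
                     row.names = FALSE)
  }
  mort <- generate_mortality(seed = seed + 9)
  utils::write.csv(mort, stage_path(config, "mortality.csv"), row.names = FALSE)
  invisible(NULL)
}

# per-model emulated historical climatologies: observed surface plus a
# model-specific error field whose sd grows with model index, so the skill
# ordering is known
model_climatologies <- function(config, observed, seed) {
  n <- config$n_models
  sds <- 0.2 + 0.15 * (seq_len(n) - 1)
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(m) {
      grid_map(observed, function(v)
        v + 0.05 * (m - 1) +  # small warm bias growing with index
          matrix(stats::rnorm(length(v), 0, sds[m]), nrow(v), ncol(v)),
        variable = "sst_model")
    })
  })
}

stage_gcm <- function(config) {
  truth <- truth_of(config)
  seed <- stage_seed(config, "gcm")
  obs_path <- require_artifact(config, "baseline_august.asc", "synth")
  obs <- read_raster(obs_path, variable = "sst_august")
  sims <- model_climatologies(config, obs, seed)
  skill <- purrr::imap_dfr(sims, function(g, m)
    dplyr::mutate(skill_stats(g, obs), model = sprintf("model_%02d", m),
                  .before = 1))
  ranking <- rank_models(skill)
  for (sc in config$scenarios) {
    anoms <- generate_gcm_anomalies(config$n_models, config$decades, sc, truth,
                                    config$spread_sd, config$outlier_bias,
                                    seed + match(sc, config$scenarios),
                                    config$domain)
    if (sc == config$scenarios[[1]]) {
      out <- outlier_analysis(anoms |> dplyr::filter(.data$decade == max(.data$decade)))
      utils::write.csv(out, stage_path(config, "outliers.csv"), row.names = FALSE)
    }
    ens <- select_and_average(anoms, ranking, config$ensemble_k)
    for (i in seq_len(nrow(ens)))
      write_raster(ens$grid[[i]],
                   stage_path(config, "anomaly_%s_%d.asc", sc, ens$decade[i]))
  }
  utils::write.csv(ranking, stage_path(config, "skill_table.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

stage_downscale <- function(config) {
  seed <- stage_seed(config, "downscale")
  for (month in c("august", "march")) {
    raw <- read_raster(require_artifact(config, sprintf("baseline_%s.asc", month),
                                        "synth"),
                       variable = sprintf("sst_%s", month))
    cells <- as_tibble.raster_grid(raw)
    n_knots <- min(config$tps_knots, nrow(cells))
    knots <- withr::with_seed(seed + (month == "march"),
                              cells[sample.int(nrow(cells), n_knots), ])
    fit <- tps_fit(knots)
    smooth <- tps_evaluate(fit, raw, variable = sprintf("sst_%s", month))
    write_raster(smooth, stage_path(config, "baseline_%s_smoothed.asc", month))
    if (month == "august")
      jsonlite::write_json(
        list(lambda = fit$lambda, gcv = fit$gcv_score, n_knots = fit$n,
             gcv_table = fit$gcv_table),
        stage_path(config, "tps_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  aug <- read_raster(stage_path(config, "baseline_august_smoothed.asc"),
                     variable = "sst_august")
  mar <- read_raster(stage_path(config, "baseline_march_smoothed.asc"),
                     variable = "sst_march")
  for (sc in config$scenarios) for (d in config$decades) {
    coarse <- read_raster(require_artifact(config,
                                           sprintf("anomaly_%s_%d.asc", sc, d),
                                           "gcm"),
                          variable = "anomaly")
    mid <- bilinear_refine(coarse, 0.5)
    write_raster(change_factor(aug, mid, config$downscale_method,
                               variable = "sst_august"),
                 stage_path(config, "sst_august_%s_%d.asc", sc, d))
    write_raster(change_factor(mar, mid, config$downscale_method,
                               variable = "sst_march"),
                 stage_path(config, "sst_march_%s_%d.asc", sc, d))
  }
  invisible(NULL)
}

fit_species_ensemble <- function(config, sp) {
  seed <- stage_seed(config, "sdm")
  sv <- utils::read.csv(require_artifact(config, sprintf("surveys_%s.csv", sp),
                                         "synth"))
  n <- nrow(sv)
  val_idx <- withr::with_seed(seed, sample.int(n, max(1L, round(0.2 * n))))
  train <- sv[-val_idx, ]; valid <- sv[val_idx, ]
  shape <- if (sp == "A") "linear" else "quadratic"
  g <- fit_glm(train, shape, config$family, seed = seed)
  b <- fit_brt(train, n_trees = config$brt_trees, seed = seed)
  w <- ensemble_weights(g, b, valid, config$weight_scheme)
  sdm_ensemble(g, b, w, species = sp)
}

stage_sdm <- function(config) {
  for (sp in config$species) {
    ens <- fit_species_ensemble(config, sp)
    jsonlite::write_json(
      list(species = sp,
           weights = as.list(ens$weights),
           glm = list(coefficients = as.list(stats::coef(ens$glm_component$fit)),
                      theta = ens$glm_component$theta,
                      sst_center = ens$glm_component$sst_center,
                      cv_deviance = ens$glm_component$cv_deviance),
           brt = ens$brt_component$hyperparameters[
             c("depth", "learning_rate", "bag_fraction", "seed")],
           brt_trees = ens$brt_component$best_iteration,
           fixed_covariates = ens$covariate_recipe$fixed,
           seed = stage_seed(config, "sdm")),
      stage_path(config, "sdm_%s.json", sp), auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

stage_project <- function(config) {
  for (sp in config$species) {
    require_artifact(config, sprintf("sdm_%s.json", sp), "sdm")
    ens <- fit_species_ensemble(config, sp)  # deterministic refit
    base <- read_raster(require_artifact(config, "baseline_august_smoothed.asc",
                                         "downscale"), variable = "sst_august")
    write_raster(predict_abundance(ens, base),
                 stage_path(config, "abundance_%s_present.asc", sp))
    for (sc in config$scenarios) for (d in config$decades) {
      sst <- read_raster(require_artifact(config,
                                          sprintf("sst_august_%s_%d.asc", sc, d),
                                          "downscale"),
                         variable = "sst_august")
      write_raster(predict_abundance(ens, sst),
                   stage_path(config, "abundance_%s_%s_%d.asc", sp, sc, d))
    }
  }
  invisible(NULL)
}

stage_range <- function(config) {
  thr <- config$ground_threshold
  rows <- list()
  for (sp in config$species) {
    present <- read_raster(require_artifact(config,
                                            sprintf("abundance_%s_present.asc", sp),
                                            "project"), variable = "abundance")
    cur_g <- delineate_grounds(present, thr)
    for (sc in config$scenarios) {
      d <- max(config$decades)
      fut <- read_raster(require_artifact(config,
                                          sprintf("abundance_%s_%s_%d.asc", sp, sc, d),
                                          "project"), variable = "abundance")
      fmap <- classify_change(cur_g, delineate_grounds(fut, thr), thr,
                              decade = d, scenario = sc, species = sp)
      write_raster(fmap, stage_path(config, "grounds_change_%s_%s.asc", sp, sc))
      pc <- tryCatch(percent_change_above_threshold(present, fut, thr),
                     error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        tidyr::pivot_wider(fmap$counts, names_from = "category",
                           values_from = "n_cells"),
        species = sp, scenario = sc, decade = d,
        percent_change_harvestable = pc, .before = 1)
    }
  }
  utils::write.csv(dplyr::bind_rows(rows),
                   stage_path(config, "range_summary.csv"), row.names = FALSE)
  invisible(NULL)
}

stage_overlay <- function(config) {
  rows <- list()
  for (sp in config$species) {
    present <- read_raster(require_artifact(config,
                                            sprintf("abundance_%s_present.asc", sp),
                                            "project"), variable = "abundance")
    current_mask <- present$mask & !is.na(present$values) &
      present$values > config$occupancy_cutoff
    cur_g <- delineate_grounds(present, config$ground_threshold)
    for (sc in config$scenarios) {
      d <- max(config$decades)
      mar <- read_raster(require_artifact(config,
                                          sprintf("sst_march_%s_%d.asc", sc, d),
                                          "downscale"), variable = "sst_march")
      fut <- read_raster(require_artifact(config,
                                          sprintf("abundance_%s_%s_%d.asc", sp, sc, d),
                                          "project"), variable = "abundance")
      fmap <- classify_change(cur_g, delineate_grounds(fut, config$ground_threshold))
      expansion <- fmap$values == 2 & fmap$mask
      regions <- list(study_area = mar$mask, current_distribution = current_mask)
      if (any(expansion, na.rm = TRUE))
        regions$expansion_cells <- !is.na(fmap$values) & fmap$values == 2
      rep <- march_overlay(mar, regions, config$march_bins)
      rows[[length(rows) + 1]] <- dplyr::mutate(rep, species = sp,
                                                scenario = sc, decade = d,
                                                .before = 1)
    }
  }
  utils::write.csv(dplyr::bind_rows(rows),
                   stage_path(config, "overlay_report.csv"), row.names = FALSE)
  invisible(NULL)
}

stage_mortality <- function(config) {
  mort <- utils::read.csv(require_artifact(config, "mortality.csv", "synth"))
  res <- one_way_anova(mort)
  means <- sort(res$group_means)
  jsonlite::write_json(
    list(F = res$F, df_between = res$df_between, df_within = res$df_within,
         p = res$p, group_means = as.list(res$group_means),
         group_sds = as.list(res$group_sds),
         fold_change = fold_change(max(means), min(means)),
         infinite_F = res$infinite_F),
    stage_path(config, "mortality_stats.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
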