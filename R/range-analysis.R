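#' Delineate potential fishing grounds
#'
#' A sea cell is potential fishing ground when predicted abundance meets the
#' minimum density able to sustain harvest: at least `threshold` individuals
#' per 100 m^2 (default 20, the minimum density needed to maintain the
#' recruitment rates required to sustain catches). The comparison is
#' inclusive (>= threshold).
#'
#' @param abundance A [raster_grid()] of abundance (individuals per 100 m^2).
#' @param threshold Minimum density (default 20).
#' @return A [raster_grid()] of 0/1 values (1 = fishing ground) on the same
#'   mask.
#' @export
delineate_grounds <- function(abundance, threshold = 20) {
  grid_map(abundance, function(v) (v >= threshold) * 1, variable = "fishing_ground")
}

#' Classify change in fishing grounds
#'
#' Cross-tabulates present-day and future fishing-ground indicators into the
#' four change classes: `retained` (ground in both), `gained` (future only),
#' `lost` (present only), `never` (neither). The classes partition the sea
#' mask exactly.
#'
#' @param current_grounds,future_grounds 0/1 [raster_grid()]s from
#'   [delineate_grounds()] on identical geometry.
#' @param threshold,decade,scenario,species Labels recorded on the result.
#' @return An object of class `fishing_ground_map`: a [raster_grid()] of
#'   integer codes (0 never, 1 lost, 2 gained, 3 retained) with a `counts`
#'   tibble attribute (`category`, `n_cells`).
#' @export
classify_change <- function(current_grounds, future_grounds, threshold = 20,
                            decade = NA, scenario = NA_character_,
                            species = NA_character_) {
  same_geometry_or_stop(current_grounds, future_grounds,
                        "current and future ground grids")
  cur <- current_grounds$values > 0
  fut <- future_grounds$values > 0
  code <- matrix(NA_real_, nrow(cur), ncol(cur))
  msk <- current_grounds$mask & future_grounds$mask
  code[msk] <- 0
  code[msk & cur & !fut] <- 1
  code[msk & !cur & fut] <- 2
  code[msk & cur & fut] <- 3
  g <- raster_grid(code, current_grounds$lon_origin, current_grounds$lat_origin,
                   current_grounds$resolution, mask = msk,
                   variable = "ground_change")
  labels <- c("never", "lost", "gained", "retained")
  counts <- tibble::tibble(
    category = factor(labels, levels = labels),
    n_cells = vapply(0:3, function(k) sum(code[msk] == k), 0L)
  )
  structure(c(g, list(counts = counts, threshold = threshold, decade = decade,
                      scenario = scenario, species = species)),
            class = c("fishing_ground_map", "raster_grid"))
}

#' @export
print.fishing_ground_map <- function(x, ...) {
  cat(sprintf("<fishing_ground_map> threshold %g /100m2%s%s\n", x$threshold,
              if (!is.na(x$decade)) sprintf(", decade %s", x$decade) else "",
              if (!is.na(x$scenario)) sprintf(", %s", x$scenario) else ""))
  print(x$counts)
  invisible(x)
}

#' Percent change in harvestable abundance
#'
#' Percentage change in total abundance summed over harvestable cells:
#' `100 * (sum of future abundance over cells at/above threshold in the
#' future - sum of current abundance over cells at/above threshold at
#' present) / (current harvestable sum)`.
#'
#' @param current,future Abundance [raster_grid()]s on identical geometry.
#' @param threshold Harvestability threshold (individuals per 100 m^2).
#' @return Percent change (scalar).
#' @export
percent_change_above_threshold <- function(current, future, threshold = 20) {
  same_geometry_or_stop(current, future, "current and future abundance grids")
  cur <- current$values[current$mask & current$values >= threshold]
  fut <- future$values[future$mask & future$values >= threshold]
  denom <- sum(cur)
  if (!is.finite(denom) || denom <= 0)
    stop("no harvestable abundance at present: percent change undefined",
         call. = FALSE)
  100 * (sum(fut) - denom) / denom
}

#' March-SST thermal-tolerance overlay
#'
#' Bins late-summer (March) SST into thermal-tolerance categories — below
#' 17 deg C, 17 to just under 20 deg C, and at/above 20 deg C (the
#' temperature causing order-of-magnitude increases in juvenile mortality) —
#' and reports the fraction of each region's sea cells per category. Typical
#' regions: the whole study area, a species' current distribution, and the
#' cells the abundance models predict the species would expand into.
#'
#' @param march_sst A [raster_grid()] of March SST.
#' @param regions Named list of logical matrices (cell masks) on the grid's
#'   geometry; each is intersected with the sea mask.
#' @param bin_edges Interior category boundaries in deg C (default
#'   `c(17, 20)`); bins are left-closed, right-open, the last closed above.
#' @param area_weighted Weight cells by the cosine of latitude (approximate
#'   cell area) instead of counting cells equally.
#' @return A tibble (`overlay_report`) with columns `region`, `bin`,
#'   `fraction`, `n_cells`; fractions sum to 1 within each region.
#' @export
march_overlay <- function(march_sst, regions, bin_edges = c(17, 20),
                          area_weighted = FALSE) {
  stopifnot(is.list(regions), length(regions) >= 1, !is.null(names(regions)))
  edges <- c(-Inf, sort(bin_edges), Inf)
  bin_labels <- c(sprintf("<%g", edges[2]),
                  if (length(edges) > 3)
                    sprintf("[%g,%g)", utils::head(edges[-1], -2),
                            utils::head(edges[-(1:2)], -1)),
                  sprintf(">=%g", edges[length(edges) - 1]))
  lat_w <- cos(grid_lats(march_sst) * pi / 180)
  purrr::imap_dfr(regions, function(reg, nm) {
    reg <- as.matrix(reg) & march_sst$mask
    if (!any(reg)) stop(sprintf("region '%s' is empty", nm), call. = FALSE)
    idx <- which(reg, arr.ind = TRUE)
    vals <- march_sst$values[idx]
    w <- if (area_weighted) lat_w[idx[, 1]] else rep(1, nrow(idx))
    b <- cut(vals, breaks = edges, right = FALSE, labels = bin_labels)
    frac <- vapply(bin_labels, function(l) sum(w[b == l]) / sum(w), 0)
    tibble::tibble(region = nm, bin = factor(bin_labels, levels = bin_labels),
                   fraction = unname(frac),
                   n_cells = vapply(bin_labels, function(l) sum(b == l), 0L))
  })
}

#' Survey density summarised by March-SST category
#'
#' Looks up the March SST of each survey's cell, bins records by SST
#' (left-closed, right-open, last bin closed above) and returns box-plot
#' style five-number summaries of density per bin (type-7 linear-interpolation
#' quantiles). Empty bins are reported with `n = 0` and `NA` statistics.
#'
#' @param surveys Survey tibble with `lon`, `lat`, `count_per_100m2`.
#' @param march_sst A [raster_grid()] of March SST covering every survey cell.
#' @param bin_edges Interior bin boundaries in deg C (default `c(17, 20)`).
#' @return A tibble with columns `bin`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
density_by_temperature_bins <- function(surveys, march_sst,
                                        bin_edges = c(17, 20)) {
  g <- march_sst
  j <- round((surveys$lon - g$lon_origin) / g$resolution) + 1
  i <- round((surveys$lat - g$lat_origin) / g$resolution) + 1
  if (any(i < 1 | i > nrow(g$values) | j < 1 | j > ncol(g$values)))
    stop("survey location outside the March SST grid", call. = FALSE)
  sst <- g$values[cbind(i, j)]
  if (anyNA(sst)) stop("survey cell has no March SST value", call. = FALSE)
  edges <- c(-Inf, sort(bin_edges), Inf)
  bin_labels <- c(sprintf("<%g", edges[2]),
                  if (length(edges) > 3)
                    sprintf("[%g,%g)", utils::head(edges[-1], -2),
                            utils::head(edges[-(1:2)], -1)),
                  sprintf(">=%g", edges[length(edges) - 1]))
  b <- cut(sst, breaks = edges, right = FALSE, labels = bin_labels)
  purrr::map_dfr(bin_labels, function(l) {
    d <- surveys$count_per_100m2[b == l]
    if (!length(d))
      return(tibble::tibble(bin = l, n = 0L, min = NA_real_, q1 = NA_real_,
                            median = NA_real_, q3 = NA_real_, max = NA_real_))
    q <- stats::quantile(d, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    tibble::tibble(bin = l, n = length(d), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5])
  }) |>
    dplyr::mutate(bin = factor(.data$bin, levels = bin_labels))
}

#' Plot a fishing-ground change map
#'
#' @param object A `fishing_ground_map` from [classify_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fishing_ground_map <- function(object, ...) {
  df <- as_tibble.raster_grid(object)
  labels <- c(`0` = "never", `1` = "lost", `2` = "gained", `3` = "retained")
  df$category <- factor(labels[as.character(df$value)],
                        levels = c("never", "lost", "gained", "retained"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(never = "grey85", lost = "#d7301f",
                                          gained = "#2b8cbe", retained = "#31a354"),
                               drop = FALSE, name = "Fishing ground") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude (deg E)", y = "Latitude (deg N)") +
    ggplot2::theme_minimal()
}

#' Bar chart of a March-SST overlay report
#'
#' @param report Tibble from [march_overlay()].
#' @return A ggplot object.
#' @export
plot_overlay_report <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$bin, y = 100 * .data$fraction,
                                       fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "March SST category (deg C)", y = "% of region") +
    ggplot2::theme_minimal()
}
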