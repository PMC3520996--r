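#' One-way ANOVA on tank-level mortality
#'
#' Tests for a temperature effect on juvenile mortality with tank as the
#' unit of replication (individuals within a tank are pseudo-replicates and
#' never enter the analysis). Computed via [stats::aov()] on the tank
#' percentages; with two groups of four tanks the test has df (1, 6).
#' Zero within-group variance with distinct group means yields an infinite F
#' (flagged) with p reported as 0.
#'
#' @param experiment A tibble with columns `temperature` (group label) and
#'   `mortality_pct`, e.g. from [generate_mortality()]; >= 2 groups with
#'   >= 2 tanks each.
#' @return An object of class `mortality_anova`: a one-row tibble-like list
#'   with `F`, `df_between`, `df_within`, `p`, `group_means`, `group_sds`,
#'   `infinite_F` flag.
#' @export
one_way_anova <- function(experiment) {
  stopifnot(all(c("temperature", "mortality_pct") %in% names(experiment)))
  grp <- factor(experiment$temperature)
  if (nlevels(grp) < 2) stop("need at least 2 temperature groups", call. = FALSE)
  if (any(table(grp) < 2)) stop("need at least 2 tanks per group", call. = FALSE)
  y <- experiment$mortality_pct
  k <- nlevels(grp); N <- length(y)
  fit <- stats::aov(y ~ grp)
  tab <- summary(fit)[[1]]
  ms_between <- tab["grp", "Mean Sq"]
  ms_within <- tab["Residuals", "Mean Sq"]
  if (ms_within <= .Machine$double.eps * max(1, ms_between)) {
    f <- if (ms_between > 0) Inf else 0
    p <- if (is.infinite(f)) 0 else 1
    inf_flag <- is.infinite(f)
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
    inf_flag <- FALSE
  }
  structure(list(F = f, df_between = k - 1L, df_within = N - k, p = p,
                 group_means = tapply(y, grp, mean),
                 group_sds = tapply(y, grp, stats::sd),
                 n_per_group = as.integer(table(grp)),
                 infinite_F = inf_flag),
            class = "mortality_anova")
}

#' @export
print.mortality_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %s, p = %s\n", x$df_between,
              x$df_within,
              if (x$infinite_F) "Inf (zero within-group variance)"
              else sprintf("%.4f", x$F),
              format(x$p, digits = 4)))
  invisible(x)
}

#' @rdname one_way_anova
#' @param x A `mortality_anova`.
#' @param ... Unused.
#' @export
tidy.mortality_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_between = x$df_between,
                 df_within = x$df_within, p.value = x$p)
}

#' @rdname one_way_anova
#' @export
glance.mortality_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, p.value = x$p, infinite_F = x$infinite_F,
                 n_groups = x$df_between + 1L,
                 n_total = x$df_between + x$df_within + 1L)
}

#' Reconstruct a one-way ANOVA from printed summary statistics
#'
#' Rebuilds the F statistic from group means, standard errors and group
#' sizes alone: SD = SE * sqrt(n), the within-group mean square is the
#' pooled variance, and the between-group mean square comes from the
#' dispersion of group means about the weighted grand mean. On any raw data
#' having exactly those summaries this is algebraically identical to
#' [one_way_anova()]. Useful for checking statistics reported only as
#' mean +/- SE in a results section.
#'
#' @param means Group means (%).
#' @param ses Group standard errors (%), >= 0.
#' @param n Group sizes (tanks per group, each >= 2); scalar recycled.
#' @return A `mortality_anova` (see [one_way_anova()]).
#' @export
anova_from_summary <- function(means, ses, n) {
  k <- length(means)
  stopifnot(k >= 2, length(ses) == k, all(ses >= 0))
  n <- rep_len(n, k)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  N <- sum(n)
  sds <- ses * sqrt(n)
  ss_within <- sum((n - 1) * sds^2)
  grand <- sum(n * means) / N
  ss_between <- sum(n * (means - grand)^2)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  if (ms_within <= .Machine$double.eps * max(1, ms_between)) {
    f <- if (ms_between > 0) Inf else 0
    p <- if (is.infinite(f)) 0 else 1
    inf_flag <- is.infinite(f)
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
    inf_flag <- FALSE
  }
  structure(list(F = f, df_between = k - 1L, df_within = as.integer(N - k),
                 p = p, group_means = stats::setNames(means, seq_len(k)),
                 group_sds = stats::setNames(sds, seq_len(k)),
                 n_per_group = as.integer(n), infinite_F = inf_flag),
            class = "mortality_anova")
}

#' Fold change between group means
#'
#' Ratio of the treatment mean to the control mean, e.g. mortality at the
#' warm temperature relative to ambient.
#'
#' @param mean_treatment,mean_control Group means; `mean_control` must be
#'   positive.
#' @return The ratio (scalar).
#' @export
fold_change <- function(mean_treatment, mean_control) {
  if (!is.finite(mean_control) || mean_control <= 0)
    stop("fold change undefined: control mean must be positive", call. = FALSE)
  mean_treatment / mean_control
}
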