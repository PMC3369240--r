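# Per-band three-group comparison of subband entropy features and
# selection of significantly different bands.

#' Per-band group comparison of subband entropy features
#'
#' For every band column of a wide feature table, compares the groups with
#' a one-way fixed-effects ANOVA (default) or a Kruskal-Wallis test.
#' Undefined feature cells (`NA`) are dropped bandwise; a band is testable
#' when at least two groups retain two or more values with positive
#' pooled within-group variance, otherwise its p-value is `NA`.
#'
#' @param features Wide feature table (`subject_id`, `group`, band
#'   columns), e.g. from [batch_extract()].
#' @param method `"anova"` (classic equal-variance one-way ANOVA, matching
#'   a mean/SD summary presentation) or `"kruskal"`.
#' @return A `band_group_stats` tibble: one row per band with `band`,
#'   `level`, `band_lo`, `band_hi`, per-group `n_*`, `mean_*`, `sd_*`
#'   columns, `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(features, method = c("anova", "kruskal")) {
  method <- match.arg(method)
  bands <- feature_bands(features)
  if (length(bands) == 0L) stop("no band columns in feature table", call. = FALSE)
  groups <- unique(features$group)
  if (length(groups) < 2L) {
    stop("need at least two groups to compare", call. = FALSE)
  }
  long <- tidyr::pivot_longer(features[, c("group", bands)],
                              cols = dplyr::all_of(bands),
                              names_to = "band", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  summ <- long |>
    dplyr::group_by(.data$band, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("n", "mean", "sd"))
  tests <- long |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(test = list(.band_test(.data$value, .data$group, method)),
                     .groups = "drop") |>
    tidyr::unnest_wider("test")
  out <- dplyr::left_join(parse_band_key(bands), summ, by = "band") |>
    dplyr::left_join(tests, by = "band") |>
    dplyr::arrange(.data$level, .data$band_lo)
  out$method <- method
  class(out) <- c("band_group_stats", class(out))
  out
}

.band_test <- function(value, group, method) {
  tab <- table(group)
  ok <- length(tab) >= 2L && all(tab >= 2L)
  if (ok && method == "anova") {
    fit <- tryCatch(stats::oneway.test(value ~ factor(group), var.equal = TRUE),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$statistic)) {
      return(list(statistic = unname(fit$statistic),
                  p_value = unname(fit$p.value)))
    }
  } else if (ok && method == "kruskal") {
    fit <- tryCatch(stats::kruskal.test(value ~ factor(group)),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$statistic)) {
      return(list(statistic = unname(fit$statistic),
                  p_value = unname(fit$p.value)))
    }
  }
  list(statistic = NA_real_, p_value = NA_real_)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Computes the fixed-effects one-way ANOVA F statistic and p-value from
#' group sizes, means and (sample) standard deviations alone, using the
#' between/within sum-of-squares identity. This reproduces exactly what a
#' full ANOVA on the raw data would give, so published tables that report
#' only per-group mean, SD and n can be checked without the underlying
#' observations.
#'
#' @param ns Integer vector of group sizes (all `>= 2`).
#' @param means Numeric vector of group means.
#' @param sds Numeric vector of group sample SDs (denominator `n - 1`).
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @examples
#' anova_from_summary(c(10, 10), c(1, 1), c(0.5, 0.5))  # F = 0, p = 1
#' @export
anova_from_summary <- function(ns, means, sds) {
  k <- length(ns)
  if (length(means) != k || length(sds) != k) {
    stop("ns, means, sds must have equal length", call. = FALSE)
  }
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (any(sds < 0)) stop("negative SD", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  f <- if (ms_within == 0) {
    if (ms_between == 0) 0 else Inf
  } else ms_between / ms_within
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  tibble::tibble(statistic = f, df1 = df1, df2 = df2, p_value = p)
}

#' Select bands whose entropy differs significantly between groups
#'
#' Screens the per-band comparison for bands with (optionally
#' BH-corrected) p-value strictly below `alpha`; bands with undefined
#' p-values are excluded. The selection is ordered level-major then by
#' ascending lower band edge.
#'
#' @param stats A `band_group_stats` tibble from [compare_groups()].
#' @param alpha Significance level, default 0.05.
#' @param correction `"none"` (default) or `"bh"`
#'   (Benjamini-Hochberg across all tested bands).
#' @return A `feature_selection` object: list with `selected` (tibble of
#'   the retained bands with their p-values), `n_selected`, `alpha`,
#'   `correction`.
#' @export
select_features <- function(stats, alpha = 0.05, correction = c("none", "bh")) {
  correction <- match.arg(correction)
  stopifnot(nrow(stats) >= 1, alpha > 0)
  p <- stats$p_value
  p_adj <- if (correction == "bh") p.adjust(p, method = "BH") else p
  keep <- !is.na(p_adj) & p_adj < alpha
  sel <- stats[keep, c("band", "level", "band_lo", "band_hi", "p_value")]
  sel$p_adjusted <- p_adj[keep]
  sel <- dplyr::arrange(sel, .data$level, .data$band_lo)
  structure(list(selected = sel, n_selected = nrow(sel), alpha = alpha,
                 correction = correction),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> ", x$n_selected, " band(s) at alpha = ", x$alpha,
      " (correction: ", x$correction, ")\n", sep = "")
  invisible(x)
}

#' @rdname select_features
#' @param x A `feature_selection`.
#' @param ... Unused.
#' @export
tidy.feature_selection <- function(x, ...) x$selected

#' Published clinical per-band summary statistics
#'
#' Per-group mean, SD and p-value for the 47 subbands reported as
#' significantly different (p < 0.05, one-way comparison across
#' qi-deficient, yin-deficient and healthy speakers) in the clinical study
#' of 181 sustained-vowel recordings that this method was developed on
#' (27 healthy, 116 qi-deficient, 38 yin-deficient; 16 kHz audio, db4,
#' 5 levels, m = 2, r = 0.2 SD). Shipped as reference data for checking
#' the summary-statistics ANOVA and the band bookkeeping; the raw
#' recordings themselves are not publicly available.
#'
#' @return Tibble with columns `level`, `band_lo_khz`, `band_hi_khz`,
#'   `mean_qi`, `sd_qi`, `mean_yin`, `sd_yin`, `mean_healthy`,
#'   `sd_healthy`, `p_value`, plus a derived `band` key column.
#' @export
clinical_band_summaries <- function() {
  path <- system.file("extdata", "clinical_band_summaries.csv",
                      package = "wpse", mustWork = TRUE)
  df <- tibble::as_tibble(read.csv(path))
  df$band <- band_key(df$level, df$band_lo_khz * 1000, df$band_hi_khz * 1000)
  df
}

#' Clinical cohort composition
#'
#' Group sizes of the clinical cohort the method was developed on.
#' @return Named integer vector (`healthy`, `qi_deficiency`,
#'   `yin_deficiency`).
#' @export
clinical_cohort_sizes <- function() {
  c(healthy = 27L, qi_deficiency = 116L, yin_deficiency = 38L)
}
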