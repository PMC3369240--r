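# ggplot2 views of the main result types.

#' Plot per-group mean subband entropy across bands of one level
#'
#' The classic per-level profile: mean sample entropy per band and group,
#' with one-SD ribbons. Healthy voices typically sit above the deficient
#' groups across most bands.
#'
#' @param features Wide feature table with `group` and band columns.
#' @param level Decomposition level to show (default 5).
#' @return A ggplot object.
#' @export
plot_band_profiles <- function(features, level = 5) {
  bands <- feature_bands(features)
  info <- parse_band_key(bands)
  keep <- info$band[info$level == level]
  if (length(keep) == 0L) stop("no bands at level ", level, call. = FALSE)
  long <- tidyr::pivot_longer(features[, c("group", keep)],
                              cols = dplyr::all_of(keep),
                              names_to = "band", values_to = "sampen")
  long <- dplyr::left_join(long, info, by = "band")
  summ <- long |>
    dplyr::group_by(.data$group, .data$band_lo) |>
    dplyr::summarise(mean = mean(.data$sampen, na.rm = TRUE),
                     sd = stats::sd(.data$sampen, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$band_lo / 1000,
                                     y = .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Band lower edge (kHz)", y = "Mean SampEn",
                  title = paste0("Level-", level, " subband sample entropy"))
}

#' @rdname compare_groups
#' @param object A `band_group_stats` tibble.
#' @param alpha Significance threshold drawn as a reference line.
#' @param ... Unused.
#' @export
autoplot.band_group_stats <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(object, !is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band_lo / 1000,
                                   y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_value < alpha)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(~.data$level, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Band lower edge (kHz)", y = "-log10 p",
                  colour = paste0("p < ", alpha),
                  title = "Between-group band screen")
}

#' @rdname sampen_sweep
#' @param object A sweep tibble from [sampen_sweep()].
#' @param ... Unused.
#' @export
autoplot.tbl_sampen_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_frac, y = .data$value,
                                       colour = factor(.data$m))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "r (fraction of SD)", y = "SampEn", colour = "m")
}

#' @rdname svm_evaluate
#' @param object An `svm_eval`.
#' @export
autoplot.svm_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Overall accuracy %.1f%%",
                                  100 * object$overall))
}
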