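# ggplot2 figures for the result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_abline geom_tile
#'   geom_density geom_hline facet_wrap labs autoplot stat_ecdf
#'   scale_fill_brewer theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Association-scan map
#'
#' Per-feature t-statistics, faceted by measure kind, significant features
#' highlighted.
#'
#' @param object A `mets_assoc` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mets_assoc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste(df$region, substr(df$hemisphere, 1, 1))
  ggplot(df, aes(x = .data$feature, y = .data$t,
                 fill = .data$significant)) +
    geom_col() +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    facet_wrap(~measure_kind, scales = "free_x") +
    scale_fill_brewer(palette = "Set1", direction = -1) +
    labs(
      title = paste0("Association with ", attr(object, "predictor")),
      x = NULL, y = "t statistic",
      fill = paste0("q ≤ ", attr(object, "level"))
    ) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Predicted versus chronological age
#'
#' Out-of-fold brain-age predictions against chronological age with the
#' identity line.
#'
#' @param object A `pls_age_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pls_age_fit <- function(object, ...) {
  ggplot(object$result, aes(x = .data$age, y = .data$brain_age)) +
    geom_point(alpha = 0.3, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    labs(
      x = "Chronological age (years)", y = "Predicted brain age (years)",
      title = sprintf("r = %.2f, RMSE = %.2f y, MAE = %.2f y (out-of-fold)",
                      object$metrics$r, object$metrics$rmse,
                      object$metrics$mae)
    ) +
    theme_minimal()
}

#' Winning-component map
#'
#' Tile map of the AIC winning component per feature.
#'
#' @param object An `aic_table` from [winner_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aic_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"measure_kind" %in% names(df)) df$measure_kind <- "feature"
  ggplot(df, aes(x = .data$feature, y = 1, fill = .data$winner)) +
    geom_tile() +
    facet_wrap(~measure_kind, ncol = 1, scales = "free_x") +
    labs(x = NULL, y = NULL, fill = "winner",
         title = "AIC winning component per feature") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Brain-age gap distributions by MetS severity
#'
#' Density of the corrected brain-age gap per severity level.
#'
#' @param result Brain-age result tibble (`id`, `gap_corrected`).
#' @param severity Severity tibble (`id`, `severity`).
#' @return A ggplot.
#' @export
plot_gap_by_severity <- function(result, severity) {
  df <- dplyr::inner_join(result[c("id", "gap_corrected")],
                          severity[c("id", "severity")], by = "id")
  df <- df[!is.na(df$severity), , drop = FALSE]
  df$severity <- factor(df$severity, levels = 0:5)
  ggplot(df, aes(x = .data$gap_corrected, colour = .data$severity)) +
    geom_density() +
    labs(x = "Corrected brain-age gap (years)", y = "Density",
         colour = "MetS severity") +
    theme_minimal()
}

#' Cumulative gap distributions per contrast
#'
#' Empirical CDFs of the corrected gaps in the groups of a contrast table
#' built from brain-age results.
#'
#' @param results Named list of brain-age result tibbles (e.g. aging plus
#'   disease cohorts).
#' @return A ggplot.
#' @export
plot_gap_ecdf <- function(results) {
  df <- dplyr::bind_rows(lapply(names(results), function(nm) {
    tibble::tibble(cohort = nm, gap = results[[nm]]$gap_corrected)
  }))
  ggplot(df, aes(x = .data$gap, colour = .data$cohort)) +
    stat_ecdf() +
    labs(x = "Corrected brain-age gap (years)",
         y = "Cumulative probability", colour = NULL) +
    theme_minimal()
}
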