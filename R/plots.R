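#' @title Plot methods
#' @description ggplot2 visualizations for the main result types:
#'   robust-trait presence, group-wise weight distributions, averaged
#'   MLR statistics and RSN block presence.
#' @name conntrait-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot robust-trait presence fractions
#'
#' @param object A `conn_traits` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conn_traits
#' @export
autoplot.conn_traits <- function(object, ...) {
  info <- object$info
  ggplot2::ggplot(info,
                  ggplot2::aes(x = stats::reorder(.data$trait_id,
                                                  -.data$presence_fraction),
                               y = .data$presence_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$params$presence_min %||% 0.75,
                        linetype = "dashed") +
    ggplot2::labs(x = "robust trait", y = "presence fraction across runs",
                  title = "Robust SC-traits") +
    ggplot2::theme_minimal()
}

#' Violin plot of trait weights by group
#'
#' The per-subject presence of each trait, split by family-history
#' group.
#'
#' @param weights Long weights tibble (see [trait_weights()]).
#' @param covariates Covariate tibble with `subject_id`,
#'   `family_history`.
#' @param trait_ids Optional subset of traits to show.
#' @return A ggplot.
#' @export
plot_trait_weights <- function(weights, covariates, trait_ids = NULL) {
  dat <- dplyr::inner_join(
    weights, dplyr::select(covariates, "subject_id", "family_history"),
    by = "subject_id")
  if (!is.null(trait_ids)) {
    dat <- dplyr::filter(dat, .data$trait_id %in% trait_ids)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$family_history,
                                    y = .data$weight,
                                    fill = .data$family_history)) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.5, 0.75), alpha = 0.7) +
    ggplot2::facet_wrap(~trait_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "trait weight (presence)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the averaged MLR per-predictor statistics
#'
#' @param object A `conn_mlr` object.
#' @param ... Unused.
#' @return A ggplot of the averaged t-statistic per predictor, with
#'   significant (FDR) predictors highlighted.
#' @method autoplot conn_mlr
#' @export
autoplot.conn_mlr <- function(object, ...) {
  terms <- object$terms
  terms$predictor <- factor(terms$predictor, levels = terms$predictor)
  ggplot2::ggplot(terms, ggplot2::aes(x = .data$predictor, y = .data$t_mean,
                                      fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "averaged t-statistic",
                  title = sprintf("Balanced MLR (R² = %.3f, %d samplings)",
                                  object$r_squared, object$n_samplings)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of RSN block presence
#'
#' @param object An `rsn_presence` tibble.
#' @param ... Unused.
#' @return A ggplot tile map of block presence values.
#' @method autoplot rsn_presence
#' @export
autoplot.rsn_presence <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$network_a, y = .data$network_b,
                               fill = .data$presence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s subtrait block presence",
                                  attr(object, "polarity"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
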