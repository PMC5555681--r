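# ggplot2 views of the intermediate and final results.

#' Histogram of the predictive-power distribution
#'
#' Mirrors the usual diagnostic for the good-predictor cut: the per-gene
#' predictive powers with the upper-tail cutoff marked when one has been
#' applied.
#'
#' @param object A `pgs_pp` or `pgs_good_predictors` tibble.
#' @param binwidth Histogram bin width (default one sample's worth of pp).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgs_pp <- function(object, binwidth = NULL, ...) {
  n_samples <- length(attr(object, "sample_ids"))
  if (is.null(binwidth)) binwidth <- if (n_samples > 0) 1 / n_samples else 0.01
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$pp)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35", colour = "white") +
    ggplot2::labs(x = "predictive power", y = "genes") +
    ggplot2::theme_minimal()
  cutoff <- attr(object, "cutoff")
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = 2, colour = "red")
  }
  p
}

#' @export
autoplot.pgs_good_predictors <- autoplot.pgs_pp

#' Tile view of the vote matrix
#'
#' Predictors by samples, class-0 columns first; hard samples (if supplied)
#' are outlined on the x axis.
#'
#' @param object A `pgs_vote_matrix`.
#' @param hard Optional `pgs_hard_samples` used to mark the hard columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgs_vote_matrix <- function(object, hard = NULL, ...) {
  long <- as_tibble(object$votes, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "vote") %>%
    mutate(
      sample_id = factor(.data$sample_id, levels = object$sample_ids),
      gene_id = factor(.data$gene_id, levels = rev(object$gene_ids))
    )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                          fill = factor(.data$vote))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey85", `1` = "grey20"),
                               name = "vote") +
    ggplot2::geom_vline(xintercept = object$n + 0.5, colour = "red") +
    ggplot2::labs(x = "sample (class 0 | class 1)", y = "good predictor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
  if (!is.null(hard)) {
    hard_ids <- c(hard$hard0, hard$hard1)
    p <- p + ggplot2::annotate(
      "point",
      x = match(hard_ids, object$sample_ids), y = 0.4,
      shape = 17, colour = "red", size = 2
    )
  }
  p
}

#' Cross-validation metric profile over the grid
#'
#' @param object A `pgs_cv` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot object: the optimised metric against cost, coloured by
#'   kernel and faceted by class-weight ratio.
#' @export
autoplot.pgs_cv <- function(object, ...) {
  res <- tidy(object) %>%
    filter(!.data$failed) %>%
    mutate(weights = paste0(.data$w0, ":", .data$w1))
  ycol <- paste0("mean_", object$metric)
  ggplot2::ggplot(res, ggplot2::aes(x = factor(.data$cost), y = .data[[ycol]],
                                    colour = .data$kernel,
                                    group = .data$kernel)) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = max, geom = "line") +
    ggplot2::facet_wrap(~weights) +
    ggplot2::labs(x = "cost", y = paste("mean", object$metric)) +
    ggplot2::theme_minimal()
}

#' Predictive-power view of a full pipeline fit
#'
#' @param object A `pgs_fit`.
#' @param ... Unused.
#' @return A ggplot object: the pp histogram with the good-predictor cutoff.
#' @export
autoplot.pgs_fit <- function(object, ...) {
  autoplot.pgs_pp(structure(object$pp,
                            cutoff = object$params$pp_cutoff,
                            sample_ids = attr(object$pp, "sample_ids")))
}
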