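#' Run the full peculiar-gene selection pipeline
#'
#' Chains the three selection steps: differential-expression screening
#' ([deg_test()] + [filter_degs()]), per-gene logistic predictive power with
#' an upper-quantile cut ([gene_predictive_power()] +
#' [select_good_predictors()]), and vote-matrix mining for the class-specific
#' peculiar genes ([build_vote_matrix()], [find_most_misclassified()],
#' [select_peculiar()], [finalize_signature()]).
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param labels Label tibble (`sample_id`, binary `label`).
#' @param alpha Adjusted-p-value cutoff for the DEG step (default 0.01);
#'   `NULL` skips the step.
#' @param deg_genes Optional precomputed DEG gene-id vector (e.g. from an
#'   external limma run); bypasses the internal test.
#' @param design,moderated Passed to [deg_test()].
#' @param pairing Passed to [deg_test()] for the paired design.
#' @param tau Probability threshold for [predict_labels()] (default 0.5).
#' @param quantile_level Upper-tail cut for the good predictors (default
#'   0.95: roughly the top 5% of the predictive-power distribution).
#' @param K0,K1 Hard-sample thresholds (see [find_most_misclassified()]).
#'   The defaults (0.8 and 0.2 in quantile mode) flag class-0 samples in the
#'   top fifth of the misclassification-count distribution and class-1
#'   samples in the bottom fifth of the correct-vote distribution.
#' @param k_mode `"quantile"` (default) or `"absolute"`.
#' @param tolerance Hard-sample misses a peculiar gene may make (default 0).
#' @param relax_schedule Optional data frame (`K0`, `K1`, `tolerance`) tried
#'   via [relax_until_nonempty()] when either peculiar set comes back empty.
#' @return A `pgs_fit` list with the intermediate results of every step
#'   (`deg`, `deg_expr`, `pp`, `good`, `vote_matrix`, `hard`, `signature`,
#'   `params`).
#' @examples
#' sim <- simulate_peculiar_data(genes = 300, g_common = 30, seed = 7)
#' fit <- pgs(sim$expression, sim$labels, quantile_level = 0.5)
#' fit$signature
#' @export
pgs <- function(expr, labels, alpha = 0.01, deg_genes = NULL,
                design = "two_group", pairing = NULL, moderated = TRUE,
                tau = 0.5, quantile_level = 0.95,
                K0 = 0.8, K1 = 0.2, k_mode = c("quantile", "absolute"),
                tolerance = 0, relax_schedule = NULL) {
  k_mode <- match.arg(k_mode)
  validate_expression(expr)

  deg <- NULL
  if (!is.null(deg_genes)) {
    deg_expr <- expr[expr$gene_id %in% deg_genes, , drop = FALSE]
    if (nrow(deg_expr) == 0) abort("none of `deg_genes` are present in `expr`.")
  } else if (!is.null(alpha)) {
    deg <- deg_test(expr, labels, design = design, pairing = pairing,
                    moderated = moderated)
    deg_expr <- filter_degs(expr, deg, alpha = alpha)
  } else {
    deg_expr <- expr
  }

  pp <- gene_predictive_power(deg_expr, labels, tau = tau)
  good <- select_good_predictors(pp, quantile_level = quantile_level)
  vm <- build_vote_matrix(good, labels)
  hard <- find_most_misclassified(vm, K0 = K0, K1 = K1, mode = k_mode)
  pec <- suppressWarnings(select_peculiar(vm, hard, tolerance = tolerance))

  params <- list(
    alpha = if (is.null(deg_genes)) alpha else NA_real_, tau = tau,
    quantile_level = quantile_level, pp_cutoff = attr(good, "cutoff"),
    K0 = hard$K0, K1 = hard$K1, k_mode = k_mode, tolerance = tolerance
  )
  if ((length(pec$G0) == 0 || length(pec$G1) == 0) && !is.null(relax_schedule)) {
    signature <- relax_until_nonempty(vm, relax_schedule, mode = k_mode)
    signature$params <- utils::modifyList(params, signature$params)
  } else {
    signature <- finalize_signature(pec, params = params)
  }

  structure(
    list(deg = deg, deg_expr = deg_expr, pp = pp, good = good,
         vote_matrix = vm, hard = hard, signature = signature,
         params = params),
    class = "pgs_fit"
  )
}

#' @export
print.pgs_fit <- function(x, ...) {
  cat(sprintf(
    "<pgs_fit> %d DEG(s) -> %d good predictor(s) (pp >= %.4g) -> |G0| = %d, |G1| = %d, |S| = %d\n",
    nrow(x$deg_expr), nrow(x$good), x$params$pp_cutoff,
    length(x$signature$G0), length(x$signature$G1), length(x$signature$S)
  ))
  cat(sprintf(
    "hard samples: %d class-0 (votes > %.4g), %d class-1 (votes < %.4g)\n",
    length(x$hard$hard0), x$hard$K0, length(x$hard$hard1), x$hard$K1
  ))
  invisible(x)
}

#' Per-gene summary of a pipeline fit
#'
#' @param x A `pgs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per DEG: effect, adjusted p, predictive
#'   power, and flags for good-predictor and signature membership.
#' @export
tidy.pgs_fit <- function(x, ...) {
  out <- x$pp %>%
    select("gene_id", "beta0", "beta_j", "pp") %>%
    as_tibble() %>%
    mutate(
      good_predictor = .data$gene_id %in% x$good$gene_id,
      in_G0 = .data$gene_id %in% x$signature$G0,
      in_G1 = .data$gene_id %in% x$signature$G1
    )
  if (!is.null(x$deg)) {
    out <- left_join(out,
                     select(x$deg, "gene_id", "effect", "adj_p"),
                     by = "gene_id") %>%
      select("gene_id", "effect", "adj_p", dplyr::everything())
  }
  out
}

#' One-row summary of a pipeline fit
#'
#' @param x A `pgs_fit`.
#' @param ... Unused.
#' @export
glance.pgs_fit <- function(x, ...) {
  tibble(
    n_deg = nrow(x$deg_expr), n_good = nrow(x$good),
    pp_cutoff = x$params$pp_cutoff,
    n_hard0 = length(x$hard$hard0), n_hard1 = length(x$hard$hard1),
    n_G0 = length(x$signature$G0), n_G1 = length(x$signature$G1),
    n_signature = length(x$signature$S),
    tau = x$params$tau, quantile_level = x$params$quantile_level,
    K0 = x$params$K0, K1 = x$params$K1, tolerance = x$params$tolerance
  )
}
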