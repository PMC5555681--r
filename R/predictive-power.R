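# Step 2: single-gene logistic predictive power.
#
# For each gene j a one-predictor logistic model
#   logit(p_i) = beta0 + beta_j * x_ji
# is fit by iteratively reweighted least squares; predicted probabilities are
# thresholded at tau into class labels and the predictive power pp_j is the
# fraction of samples classified correctly. Under complete or quasi-complete
# separation the likelihood has no finite maximiser: the fit then stops at
# `max_iter` with `converged = FALSE` but the fitted probabilities (pinned
# near 0/1 on the correct sides) remain well defined and usable.

ETA_CAP <- 30 # |linear predictor| beyond which plogis() is numerically 0/1

#' Fit a one-predictor logistic regression for a single gene
#'
#' @param x Numeric expression vector across samples.
#' @param labels Label tibble (`sample_id`, `label`) or a bare 0/1 vector in
#'   the same sample order as `x`.
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param tol Convergence tolerance on the coefficient update (default 1e-8).
#' @return A list with `beta0`, `beta_j`, `probs` (fitted probabilities),
#'   `converged` and `iterations`. Zero-variance `x` yields the intercept-only
#'   fit (`beta_j = 0`, all probabilities equal to the class-1 frequency).
#' @export
fit_single_gene_logistic <- function(x, labels, max_iter = 50, tol = 1e-8) {
  y <- if (is.data.frame(labels)) as.integer(labels$label) else as.integer(labels)
  if (length(x) != length(y)) abort("`x` and `labels` lengths differ.")
  if (length(y) < 2) abort("need at least 2 samples.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  if (!all(y %in% c(0L, 1L))) abort("labels must be 0/1.")
  if (length(unique(y)) < 2) abort("labels contain a single class; cannot fit a logistic model.")
  nms <- if (is.data.frame(labels)) labels$sample_id else names(x)

  if (var(x) == 0) {
    p1 <- mean(y)
    return(list(
      beta0 = qlogis(p1), beta_j = 0,
      probs = setNames(rep(p1, length(y)), nms),
      converged = TRUE, iterations = 0L
    ))
  }

  nll <- function(b) {
    eta <- pmin(pmax(b[1] + b[2] * x, -ETA_CAP), ETA_CAP)
    -sum(y * eta - log1p(exp(eta)))
  }
  beta <- c(qlogis(mean(y)), 0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- beta[1] + beta[2] * x
    p <- plogis(pmin(pmax(eta, -ETA_CAP), ETA_CAP))
    w <- p * (1 - p)
    r <- y - p
    # closed-form 2x2 Newton step
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
    det <- sw * swxx - swx^2
    if (!is.finite(det) || det <= .Machine$double.eps * sw * swxx) break
    g0 <- sum(r); g1 <- sum(r * x)
    delta <- c(swxx * g0 - swx * g1, sw * g1 - swx * g0) / det
    # step-halving keeps the Newton update ascent-safe on awkward genes
    f0 <- nll(beta)
    step <- 1
    for (h in seq_len(20)) {
      if (nll(beta + step * delta) <= f0 + 1e-12) break
      step <- step / 2
    }
    beta <- beta + step * delta
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- beta[1] + beta[2] * x
  list(
    beta0 = beta[1], beta_j = beta[2],
    probs = setNames(plogis(eta), nms),
    converged = converged, iterations = iter
  )
}

#' Threshold predicted probabilities into class labels
#'
#' A sample is assigned class 1 when its predicted probability reaches `tau`
#' (ties at exactly `tau` go to class 1). `tau` is raised above 0.5 to counter
#' strong class imbalance.
#'
#' @param fit A fit from [fit_single_gene_logistic()] or a bare probability
#'   vector.
#' @param tau Probability threshold in `(0, 1)`.
#' @return Integer 0/1 vector.
#' @export
predict_labels <- function(fit, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    abort("`tau` must be a single value in (0, 1).")
  }
  probs <- if (is.list(fit)) fit$probs else fit
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  out <- as.integer(probs >= tau)
  names(out) <- names(probs)
  out
}

#' Predictive power of a thresholded predictor
#'
#' The fraction of samples whose predicted label agrees with the true label.
#'
#' @param y_hat Predicted 0/1 labels.
#' @param labels Label tibble or bare 0/1 vector, same sample order.
#' @return A single value in `[0, 1]`.
#' @export
predictive_power <- function(y_hat, labels) {
  y <- if (is.data.frame(labels)) as.integer(labels$label) else as.integer(labels)
  if (length(y_hat) != length(y)) abort("`y_hat` and `labels` lengths differ.")
  sum(as.integer(y_hat) == y) / length(y)
}

#' Per-gene logistic fits and predictive power
#'
#' Runs [fit_single_gene_logistic()] for every gene of an expression matrix,
#' thresholds the fitted probabilities at `tau` and scores each gene's
#' predictive power.
#'
#' @param expr Expression tibble (typically the DEG-restricted matrix from
#'   [filter_degs()]).
#' @param labels Label tibble.
#' @param tau Probability threshold (default 0.5; raise under strong
#'   imbalance).
#' @inheritParams fit_single_gene_logistic
#' @return A `pgs_pp` tibble with one row per gene: `gene_id`, `beta0`,
#'   `beta_j`, `converged`, `iterations`, `pp`, and list-columns `probs` and
#'   `y_hat` (named by sample id). The threshold used is stored in
#'   `attr(, "tau")`.
#' @export
gene_predictive_power <- function(expr, labels, tau = 0.5, max_iter = 50, tol = 1e-8) {
  m <- expr_matrix(expr)
  y <- aligned_labels(labels, colnames(m))
  fits <- purrr::map(seq_len(nrow(m)), function(j) {
    f <- fit_single_gene_logistic(setNames(m[j, ], colnames(m)), y,
                                  max_iter = max_iter, tol = tol)
    yh <- predict_labels(f, tau)
    tibble(
      gene_id = rownames(m)[j], beta0 = f$beta0, beta_j = f$beta_j,
      converged = f$converged, iterations = f$iterations,
      pp = predictive_power(yh, y),
      probs = list(f$probs), y_hat = list(yh)
    )
  })
  out <- bind_rows(fits)
  attr(out, "tau") <- tau
  attr(out, "sample_ids") <- colnames(m)
  class(out) <- c("pgs_pp", class(out))
  out
}

#' Select the good predictors from the predictive-power distribution
#'
#' The cutoff is the empirical quantile (linear interpolation of order
#' statistics) of the per-gene predictive powers at `quantile_level`; all
#' genes with `pp >= cutoff` are retained, ties included, so the maximum
#' always qualifies.
#'
#' @param pp_tbl A `pgs_pp` tibble from [gene_predictive_power()].
#' @param quantile_level Lower bound of the retained upper tail, in `(0, 1)`:
#'   0.95 keeps roughly the top 5% of genes, 0.99 the top 1%.
#' @return The filtered `pgs_pp` tibble (class `pgs_good_predictors`) with
#'   attributes `quantile_level` and `cutoff`.
#' @export
select_good_predictors <- function(pp_tbl, quantile_level = 0.95) {
  if (!is.numeric(quantile_level) || length(quantile_level) != 1 ||
      quantile_level <= 0 || quantile_level >= 1) {
    abort("`quantile_level` must be in (0, 1).")
  }
  if (!is.data.frame(pp_tbl) || nrow(pp_tbl) == 0 || !"pp" %in% names(pp_tbl)) {
    abort("`pp_tbl` must be a non-empty result of gene_predictive_power().")
  }
  cutoff <- unname(quantile(pp_tbl$pp, probs = quantile_level, type = 7))
  # the 1e-12 guard keeps ties at the cutoff included despite interpolation
  # round-off
  out <- pp_tbl[pp_tbl$pp >= cutoff - 1e-12, , drop = FALSE]
  attr(out, "tau") <- attr(pp_tbl, "tau")
  attr(out, "sample_ids") <- attr(pp_tbl, "sample_ids")
  attr(out, "quantile_level") <- quantile_level
  attr(out, "cutoff") <- cutoff
  class(out) <- unique(c("pgs_good_predictors", class(out)))
  out
}
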