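# Step 1: differential expression screening.
#
# The moderated path shrinks per-gene variances toward a common prior before
# computing t statistics. The prior (d0, s0^2) is estimated by the method of
# moments on the log sample variances: with z = log(s^2) and d residual df,
# e = z - digamma(d/2) + log(d/2) has mean log(s0^2) + digamma(d0/2) -
# log(d0/2) and excess variance trigamma(d0/2) over trigamma(d/2). Posterior
# variances are s~^2 = (d0 s0^2 + d s^2) / (d0 + d) and the moderated t has
# d + d0 degrees of freedom.

trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# Empirical-Bayes variance shrinkage; returns the prior and posterior variances.
# Exact zeros are offset to a small fraction of the median variance so the log
# moments stay finite.
squeeze_variances <- function(s2, df) {
  med <- stats::median(s2)
  if (!is.finite(med) || med <= 0) {
    abort("most genes have zero within-group variance; cannot estimate a variance prior.")
  }
  s2 <- pmax(s2, 1e-5 * med)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s20 <- mean(s2)
    var_post <- rep(s20, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s20 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    var_post <- (d0 * s20 + df * s2) / (d0 + df)
  }
  list(df_prior = d0, var_prior = s20, var_post = var_post)
}

t_to_p <- function(t_stat, df) 2 * pt(-abs(t_stat), df = df)

#' Per-gene differential-expression tests
#'
#' Computes a per-gene t statistic and two-sided p-value contrasting the two
#' classes (`two_group`), paired samples (`paired`, via within-subject
#' differences), or per-subject differences against zero (`one_sample`). With
#' `moderated = TRUE` per-gene variances are shrunk toward a common prior by
#' empirical-Bayes moderation (method-of-moments prior on log variances, with
#' a pooled-variance statistic); with `moderated = FALSE` the two-group test
#' is the Welch unequal-variance t.
#'
#' @param expr Expression tibble (`gene_id` + sample columns). For
#'   `one_sample`, columns are per-subject differences.
#' @param labels Label tibble (`sample_id`, `label`); required for
#'   `two_group` and `paired`.
#' @param design One of `"two_group"`, `"paired"`, `"one_sample"`.
#' @param pairing For `paired`: tibble with columns `sample_0` and `sample_1`
#'   giving, per subject, the class-0 and class-1 sample ids.
#' @param moderated Shrink variances via empirical Bayes (default `TRUE`).
#' @param adjust Multiple-testing adjustment for `adj_p`: `"BH"` (default),
#'   `"bonferroni"` or `"none"`.
#' @return A tibble with one row per gene: `gene_id`, `effect` (class-1 minus
#'   class-0 mean, log units), `t_stat`, `df`, `p_value`, `adj_p`.
#' @seealso [filter_degs()] to subset the expression matrix to significant
#'   genes, [bh_adjust()].
#' @export
deg_test <- function(expr, labels = NULL,
                     design = c("two_group", "paired", "one_sample"),
                     pairing = NULL, moderated = TRUE,
                     adjust = c("BH", "bonferroni", "none")) {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  m <- expr_matrix(expr)
  if (anyNA(m)) abort("`expr` contains missing values; drop or re-load the matrix first.")

  if (design == "paired") {
    if (is.null(pairing) || !all(c("sample_0", "sample_1") %in% names(pairing))) {
      abort("`paired` design needs `pairing` with columns `sample_0` and `sample_1`.")
    }
    missing_ids <- setdiff(c(pairing$sample_0, pairing$sample_1), colnames(m))
    if (length(missing_ids) > 0) {
      abort(sprintf("pairing refers to unknown samples: %s",
                    paste(head(missing_ids, 5), collapse = ", ")))
    }
    if (nrow(pairing) < 2) abort("need at least 2 pairs.")
    m <- m[, pairing$sample_1, drop = FALSE] - m[, pairing$sample_0, drop = FALSE]
    design <- "one_sample"
  }

  if (design == "two_group") {
    y <- aligned_labels(labels, colnames(m))
    if (sum(y == 0) < 2 || sum(y == 1) < 2) abort("need at least 2 samples per group.")
    m0 <- m[, y == 0, drop = FALSE]
    m1 <- m[, y == 1, drop = FALSE]
    n0 <- ncol(m0); n1 <- ncol(m1)
    effect <- rowMeans(m1) - rowMeans(m0)
    v0 <- row_vars(m0); v1 <- row_vars(m1)
    if (moderated) {
      d <- n0 + n1 - 2
      s2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / d
      sq <- squeeze_variances(s2, d)
      se <- sqrt(sq$var_post * (1 / n0 + 1 / n1))
      # total df capped at the pooled residual df across genes
      df <- min(d + sq$df_prior, length(s2) * d)
      t_stat <- effect / se
    } else {
      se <- sqrt(v0 / n0 + v1 / n1)
      df <- se^4 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
      t_stat <- effect / se
    }
  } else { # one_sample
    n <- ncol(m)
    if (n < 2) abort("need at least 2 samples.")
    effect <- rowMeans(m)
    s2 <- row_vars(m)
    d <- n - 1
    if (moderated) {
      sq <- squeeze_variances(s2, d)
      se <- sqrt(sq$var_post / n)
      df <- min(d + sq$df_prior, length(s2) * d)
      t_stat <- effect / se
    } else {
      se <- sqrt(s2 / n)
      df <- rep(d, length(effect))
      t_stat <- effect / se
    }
  }

  df <- rep(df, length.out = length(effect))

  # Degenerate genes: zero variance. Non-zero effect goes to +-Inf (p -> 0);
  # zero effect is an exact tie (t = 0, p = 1).
  degen <- !is.finite(t_stat)
  if (all(degen)) abort("all genes have zero within-group variance.")
  if (any(degen)) {
    inform(sprintf("%d gene(s) with zero variance; t set by the limiting convention.", sum(degen)))
    t_stat[degen] <- ifelse(effect[degen] == 0, 0, sign(effect[degen]) * Inf)
    df[degen] <- Inf
  }
  p_value <- t_to_p(t_stat, df)
  p_value[degen & effect == 0] <- 1
  p_value[degen & effect != 0] <- 0

  adj_p <- switch(adjust,
    BH = bh_adjust(p_value),
    bonferroni = p.adjust(p_value, method = "bonferroni"),
    none = p_value
  )
  tibble(
    gene_id = rownames(m), effect = unname(effect), t_stat = unname(t_stat),
    df = unname(df), p_value = unname(p_value), adj_p = unname(adj_p)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone step-up), same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must be numeric in [0, 1] with no missing values.")
  }
  p.adjust(p_values, method = "BH")
}

#' Restrict an expression matrix to differentially expressed genes
#'
#' @param expr Expression tibble.
#' @param deg Result of [deg_test()].
#' @param alpha Adjusted-p-value cutoff in `(0, 1]` (default 0.01).
#' @return The expression tibble restricted to genes with `adj_p <= alpha`,
#'   preserving the input gene order.
#' @export
filter_degs <- function(expr, deg, alpha = 0.01) {
  validate_expression(expr)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be in (0, 1].")
  }
  keep_ids <- deg$gene_id[deg$adj_p <= alpha]
  out <- expr[expr$gene_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(sprintf("no genes pass adj_p <= %g; consider a larger `alpha`.", alpha))
  }
  out
}
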