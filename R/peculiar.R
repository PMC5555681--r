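# Step 3: vote-matrix analysis and peculiar-gene extraction.
#
# The vote matrix M (P good predictors x N samples, class-0 columns first)
# stacks the thresholded prediction vectors. For a class-0 sample a 1-vote is
# a misclassification, so its column sum counts the predictors that get it
# wrong; for a class-1 sample the column sum counts the predictors that get
# it right. The most-misclassified ("hard") samples are the class-0 columns
# with sum strictly above K0 and the class-1 columns with sum strictly below
# K1. The peculiar genes are the rows voting for the correct class of every
# hard sample (up to `tolerance` misses): G0 rows vote 0 on hard0, G1 rows
# vote 1 on hard1, and the signature is S = G0 u G1.

#' Stack good-predictor votes into a binary matrix
#'
#' @param good A `pgs_good_predictors` tibble (or any `pgs_pp` tibble) whose
#'   `y_hat` list-column holds the thresholded predictions.
#' @param labels Label tibble covering the same samples.
#' @return A `pgs_vote_matrix`: list with `votes` (P x N 0/1 matrix, columns
#'   ordered class-0 samples first), `gene_ids`, `sample_ids`, `labels`
#'   (reordered tibble), and class sizes `n` and `m`.
#' @export
build_vote_matrix <- function(good, labels) {
  if (!is.data.frame(good) || nrow(good) == 0 || !"y_hat" %in% names(good)) {
    abort("`good` must be a non-empty predictor table with a `y_hat` column.")
  }
  sample_ids <- names(good$y_hat[[1]])
  if (is.null(sample_ids)) abort("`y_hat` vectors must be named by sample id.")
  validate_labels(labels, sample_ids)
  ordered <- bind_rows(
    labels[labels$label == 0, , drop = FALSE],
    labels[labels$label == 1, , drop = FALSE]
  )
  votes <- do.call(rbind, lapply(good$y_hat, function(v) {
    if (!setequal(names(v), ordered$sample_id)) {
      abort("predictor and label sample ids do not match.")
    }
    as.integer(v[ordered$sample_id])
  }))
  rownames(votes) <- good$gene_id
  colnames(votes) <- ordered$sample_id
  structure(
    list(
      votes = votes, gene_ids = good$gene_id, sample_ids = ordered$sample_id,
      labels = ordered, n = sum(ordered$label == 0), m = sum(ordered$label == 1)
    ),
    class = "pgs_vote_matrix"
  )
}

#' @export
print.pgs_vote_matrix <- function(x, ...) {
  cat(sprintf(
    "<pgs_vote_matrix> %d predictors x %d samples (%d class-0, %d class-1)\n",
    nrow(x$votes), ncol(x$votes), x$n, x$m
  ))
  invisible(x)
}

#' Detect the most-misclassified samples of each class
#'
#' Column sums of the vote matrix are compared to the thresholds `K0`/`K1`
#' with strict inequalities: class-0 samples with more than `K0` 1-votes
#' (misclassifications) form `hard0`; class-1 samples with fewer than `K1`
#' 1-votes (correct votes) form `hard1`.
#'
#' @param vm A `pgs_vote_matrix`.
#' @param K0,K1 Thresholds. In `absolute` mode, vote counts in `[0, P]`. In
#'   `quantile` mode, probabilities in `(0, 1)` turned into vote counts via
#'   the empirical quantile of the per-class column-sum distribution.
#' @param mode `"absolute"` (vote counts, the primary reading) or
#'   `"quantile"`.
#' @return A `pgs_hard_samples`: list with `hard0`, `hard1` (sample ids),
#'   the vote-count thresholds actually applied (`K0`, `K1`), and a `counts`
#'   tibble (`sample_id`, `class`, `votes`, `hard`).
#' @export
find_most_misclassified <- function(vm, K0, K1, mode = c("absolute", "quantile")) {
  mode <- match.arg(mode)
  if (!inherits(vm, "pgs_vote_matrix")) abort("`vm` must be a `pgs_vote_matrix`.")
  P <- nrow(vm$votes)
  sums <- colSums(vm$votes)
  cls <- vm$labels$label
  sums0 <- sums[cls == 0]
  sums1 <- sums[cls == 1]
  if (mode == "quantile") {
    if (K0 <= 0 || K0 >= 1 || K1 <= 0 || K1 >= 1) {
      abort("in quantile mode `K0` and `K1` must be in (0, 1).")
    }
    k0 <- unname(quantile(sums0, probs = K0, type = 7))
    k1 <- unname(quantile(sums1, probs = K1, type = 7))
  } else {
    if (K0 < 0 || K0 > P || K1 < 0 || K1 > P) {
      abort(sprintf("in absolute mode `K0` and `K1` must lie in [0, %d].", P))
    }
    k0 <- K0
    k1 <- K1
  }
  hard0 <- names(sums0)[sums0 > k0]
  hard1 <- names(sums1)[sums1 < k1]
  counts <- tibble(
    sample_id = names(sums), class = as.integer(cls), votes = unname(sums),
    hard = names(sums) %in% c(hard0, hard1)
  )
  structure(
    list(hard0 = hard0, hard1 = hard1, K0 = k0, K1 = k1, mode = mode,
         counts = counts),
    class = "pgs_hard_samples"
  )
}

#' @export
print.pgs_hard_samples <- function(x, ...) {
  cat(sprintf(
    "<pgs_hard_samples> hard0: %d sample(s) (votes > %.6g); hard1: %d sample(s) (votes < %.6g)\n",
    length(x$hard0), x$K0, length(x$hard1), x$K1
  ))
  invisible(x)
}

#' Extract the peculiar genes for each class
#'
#' A gene enters `G0` when it votes 0 (the correct class) on every hard
#' class-0 sample except at most `tolerance` of them; `G1` analogously with
#' 1-votes on the hard class-1 samples. An empty hard set yields an empty
#' gene set with a warning.
#'
#' @param vm A `pgs_vote_matrix`.
#' @param hard A `pgs_hard_samples` from [find_most_misclassified()].
#' @param tolerance Number of hard samples a peculiar gene may miss
#'   (default 0).
#' @return A `pgs_peculiar`: list with gene-id vectors `G0` and `G1` and the
#'   `tolerance` used.
#' @export
select_peculiar <- function(vm, hard, tolerance = 0) {
  if (!inherits(vm, "pgs_vote_matrix")) abort("`vm` must be a `pgs_vote_matrix`.")
  if (!inherits(hard, "pgs_hard_samples")) abort("`hard` must be a `pgs_hard_samples`.")
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0) {
    abort("`tolerance` must be a non-negative integer.")
  }
  if (length(hard$hard0) == 0) {
    warn("no hard class-0 samples: G0 is empty.")
    G0 <- character(0)
  } else {
    miss0 <- rowSums(vm$votes[, hard$hard0, drop = FALSE] == 1)
    G0 <- vm$gene_ids[miss0 <= tolerance]
  }
  if (length(hard$hard1) == 0) {
    warn("no hard class-1 samples: G1 is empty.")
    G1 <- character(0)
  } else {
    miss1 <- rowSums(vm$votes[, hard$hard1, drop = FALSE] == 0)
    G1 <- vm$gene_ids[miss1 <= tolerance]
  }
  structure(list(G0 = G0, G1 = G1, tolerance = tolerance), class = "pgs_peculiar")
}

new_signature <- function(G0, G1, params = list()) {
  structure(
    list(G0 = unique(as.character(G0)), G1 = unique(as.character(G1)),
         S = union(unique(as.character(G0)), unique(as.character(G1))),
         params = params),
    class = "pgs_signature"
  )
}

#' Combine the class-specific peculiar sets into a signature
#'
#' @param G0 Either a `pgs_peculiar` from [select_peculiar()] or a character
#'   vector of class-0 peculiar genes.
#' @param G1 Character vector of class-1 peculiar genes (ignored when `G0`
#'   is a `pgs_peculiar`).
#' @param params Named list of provenance parameters (tau, quantile level,
#'   K0, K1, tolerance, ...) stored with the signature.
#' @return A `pgs_signature`: list with `G0`, `G1`, their union `S`, and
#'   `params`.
#' @export
finalize_signature <- function(G0, G1 = character(0), params = list()) {
  if (inherits(G0, "pgs_peculiar")) {
    params <- c(params[setdiff(names(params), "tolerance")],
                list(tolerance = G0$tolerance))
    G1 <- G0$G1
    G0 <- G0$G0
  }
  if (length(G0) == 0 && length(G1) == 0) {
    abort(paste(
      "both G0 and G1 are empty; relax the hard-sample thresholds or the",
      "tolerance (see relax_until_nonempty())."
    ))
  }
  if (length(G0) == 0) warn("G0 is empty; the signature covers class 1 only.")
  if (length(G1) == 0) warn("G1 is empty; the signature covers class 0 only.")
  new_signature(G0, G1, params)
}

#' @export
print.pgs_signature <- function(x, ...) {
  cat(sprintf(
    "<pgs_signature> |G0| = %d, |G1| = %d, |S| = %d\n",
    length(x$G0), length(x$G1), length(x$S)
  ))
  if (length(x$params) > 0) {
    cat("params:", paste(names(x$params),
                         vapply(x$params, function(p) paste(format(p), collapse = "/"),
                                character(1)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.pgs_signature <- function(x, ...) {
  tibble(
    gene_id = x$S,
    in_G0 = x$S %in% x$G0,
    in_G1 = x$S %in% x$G1
  )
}

#' Walk a relaxation schedule until both peculiar sets are non-empty
#'
#' When the strict thresholds leave `G0` or `G1` empty, the thresholds and/or
#' the tolerance can be relaxed. Each schedule row is tried in order; the
#' first one yielding non-empty `G0` and `G1` wins.
#'
#' @param vm A `pgs_vote_matrix`.
#' @param schedule Data frame with columns `K0`, `K1`, `tolerance`, one row
#'   per attempt.
#' @param mode Threshold mode passed to [find_most_misclassified()].
#' @return A `pgs_signature`; the attempt log is attached as
#'   `attr(, "attempts")`.
#' @export
relax_until_nonempty <- function(vm, schedule, mode = c("absolute", "quantile")) {
  mode <- match.arg(mode)
  if (!is.data.frame(schedule) || nrow(schedule) == 0 ||
      !all(c("K0", "K1", "tolerance") %in% names(schedule))) {
    abort("`schedule` must be a non-empty data frame with columns K0, K1, tolerance.")
  }
  attempts <- list()
  for (i in seq_len(nrow(schedule))) {
    K0 <- schedule$K0[i]; K1 <- schedule$K1[i]; tol <- schedule$tolerance[i]
    hard <- find_most_misclassified(vm, K0 = K0, K1 = K1, mode = mode)
    pec <- suppressWarnings(select_peculiar(vm, hard, tolerance = tol))
    attempts[[i]] <- tibble(
      K0 = K0, K1 = K1, tolerance = tol,
      n_hard0 = length(hard$hard0), n_hard1 = length(hard$hard1),
      n_G0 = length(pec$G0), n_G1 = length(pec$G1)
    )
    inform(sprintf(
      "relaxation attempt %d (K0=%.6g, K1=%.6g, tolerance=%g): |G0|=%d, |G1|=%d",
      i, K0, K1, tol, length(pec$G0), length(pec$G1)
    ))
    if (length(pec$G0) > 0 && length(pec$G1) > 0) {
      sig <- finalize_signature(pec, params = list(K0 = K0, K1 = K1, mode = mode))
      attr(sig, "attempts") <- bind_rows(attempts)
      return(sig)
    }
  }
  log_tbl <- bind_rows(attempts)
  abort(paste0(
    "relaxation schedule exhausted without non-empty G0 and G1; attempts:\n",
    paste(utils::capture.output(print(as.data.frame(log_tbl))), collapse = "\n")
  ))
}
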