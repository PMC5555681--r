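# Signature evaluation: SVM grid search under stratified k-fold CV.
#
# The SVM solver is an external contract (libsvm via e1071; kernlab for the
# unsquared gaussian variant); this file owns the folds, the metric
# bookkeeping and the grid walk. Kernel forms follow the usual conventions:
#   polynomial (<x, y> + coef0)^degree
#   gaussian   exp(-||x - y||^2 / scale^2)          ("squared", default)
#              exp(-||x - y||   / scale^2)          ("absolute" variant)
#   sigmoid    tanh(scale * <x, y> + coef0)

#' Stratified k-fold cross-validation folds
#'
#' Partitions the samples into `k` validation folds with per-class
#' round-robin assignment after a seeded shuffle, so every fold's class ratio
#' is within one sample of the global ratio.
#'
#' @param labels Label tibble (`sample_id`, `label`).
#' @param k Number of folds (default 10).
#' @param seed Optional integer making the folds reproducible.
#' @return A list of `k` elements, each `list(train =, validation =)` of
#'   integer row indices into `labels`.
#' @export
stratified_kfold <- function(labels, k = 10, seed = NULL) {
  validate_labels(labels)
  N <- nrow(labels)
  if (!is.numeric(k) || length(k) != 1 || k < 2) abort("`k` must be an integer >= 2.")
  if (k > N) abort(sprintf("k = %d exceeds the number of samples (%d).", k, N))
  if (min(table(labels$label)) < k) {
    warn(sprintf(
      "a class has fewer than k = %d samples; some validation folds will miss it.", k
    ))
  }
  assign_folds <- function() {
    fold_of <- integer(N)
    # continuous round-robin across the two classes keeps per-class counts
    # within 1 of proportional AND total fold sizes within 1 of N / k
    start <- 0L
    for (cl in c(0L, 1L)) {
      idx <- which(labels$label == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    lapply(seq_len(k), function(f) {
      list(train = which(fold_of != f), validation = which(fold_of == f))
    })
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity (class-1 recall) and specificity (class-0 recall).
#' A metric whose reference class is absent from `y_true` is `NA` and is
#' excluded from cross-validation averages.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) abort("`y_true` and `y_pred` lengths differ.")
  tibble(
    accuracy = mean(y_true == y_pred),
    sensitivity = if (any(y_true == 1)) mean(y_pred[y_true == 1] == 1) else NA_real_,
    specificity = if (any(y_true == 0)) mean(y_pred[y_true == 0] == 0) else NA_real_
  )
}

#' Build a grid of SVM configurations
#'
#' The default grid spans the dimensions usually explored for imbalanced
#' expression signatures: four kernel families, polynomial degrees 2-6 with
#' integer offsets, costs over four orders of magnitude and increasingly
#' asymmetric class weights (up to 300:1 in favour of the minority class 0).
#'
#' @param kernels Subset of `c("linear", "polynomial", "gaussian", "sigmoid")`.
#' @param cost Misclassification costs.
#' @param degree Polynomial degrees.
#' @param coef0 Offsets for the polynomial/sigmoid kernels.
#' @param scale Kernel scale `sigma` for gaussian (and slope for sigmoid).
#' @param class_weights List of `c(w0, w1)` pairs.
#' @return A tibble with columns `kernel`, `degree`, `coef0`, `scale`,
#'   `cost`, `w0`, `w1`, one row per configuration.
#' @export
svm_grid <- function(kernels = c("linear", "polynomial", "gaussian", "sigmoid"),
                     cost = c(0.1, 1, 10, 100, 1000),
                     degree = 2:6,
                     coef0 = -6:6,
                     scale = 1,
                     class_weights = list(c(1, 1), c(3, 1), c(10, 1),
                                          c(100, 1), c(300, 1))) {
  kernels <- match.arg(kernels, several.ok = TRUE)
  w <- tibble(
    w0 = vapply(class_weights, `[`, numeric(1), 1),
    w1 = vapply(class_weights, `[`, numeric(1), 2)
  )
  if (any(w$w0 <= 0 | w$w1 <= 0)) abort("class weights must be positive.")
  if (any(cost <= 0)) abort("`cost` must be positive.")
  base <- tidyr::crossing(cost = cost, w)
  per_kernel <- lapply(kernels, function(kn) {
    switch(kn,
      linear = tidyr::crossing(kernel = kn, degree = NA_integer_,
                               coef0 = NA_real_, scale = NA_real_, base),
      polynomial = tidyr::crossing(kernel = kn, degree = as.integer(degree),
                                   coef0 = as.numeric(coef0), scale = NA_real_, base),
      gaussian = tidyr::crossing(kernel = kn, degree = NA_integer_,
                                 coef0 = NA_real_, scale = as.numeric(scale), base),
      sigmoid = tidyr::crossing(kernel = kn, degree = NA_integer_,
                                coef0 = as.numeric(coef0), scale = as.numeric(scale), base)
    )
  })
  bind_rows(per_kernel)
}

fit_predict_svm <- function(xtr, ytr, xval, point, gaussian_form) {
  w <- c("0" = point$w0, "1" = point$w1)
  if (point$kernel == "gaussian" && gaussian_form == "absolute") {
    if (!requireNamespace("kernlab", quietly = TRUE)) {
      abort("the absolute gaussian form needs the kernlab package.")
    }
    fit <- kernlab::ksvm(
      xtr, factor(ytr, levels = c("0", "1")),
      type = "C-svc", C = point$cost, scaled = FALSE,
      kernel = "laplacedot", kpar = list(sigma = 1 / point$scale^2),
      class.weights = w
    )
    return(as.character(kernlab::predict(fit, xval)))
  }
  args <- list(
    x = xtr, y = factor(ytr, levels = c("0", "1")),
    type = "C-classification", cost = point$cost,
    class.weights = w, scale = FALSE
  )
  args <- switch(point$kernel,
    linear = c(args, list(kernel = "linear")),
    polynomial = c(args, list(kernel = "polynomial", degree = point$degree,
                              coef0 = point$coef0, gamma = 1)),
    gaussian = c(args, list(kernel = "radial", gamma = 1 / point$scale^2)),
    sigmoid = c(args, list(kernel = "sigmoid", gamma = point$scale,
                           coef0 = point$coef0))
  )
  fit <- do.call(e1071::svm, args)
  as.character(stats::predict(fit, xval))
}

#' Grid-search an SVM over a signature under cross-validation
#'
#' Every grid configuration is trained and evaluated on the same stratified
#' folds; the winner maximises the mean of the chosen metric, with ties
#' broken by higher mean accuracy, then smaller cost, then grid order.
#' Configurations for which the solver fails are recorded and skipped.
#'
#' @param expr Expression tibble, typically restricted to a signature's genes
#'   (rows are features, columns samples).
#' @param labels Label tibble.
#' @param grid Configuration tibble from [svm_grid()] (or hand-built with the
#'   same columns).
#' @param metric Metric to maximise: `"accuracy"`, `"sensitivity"` (class-1
#'   recall) or `"specificity"` (class-0 recall).
#' @param k Folds (default 10).
#' @param seed Fold-assignment seed.
#' @param gaussian_form `"squared"` for the conventional
#'   `exp(-||x-y||^2 / scale^2)` kernel, `"absolute"` for the
#'   `exp(-||x-y|| / scale^2)` variant.
#' @return A `pgs_cv`: list with `results` (one row per configuration with
#'   per-fold metrics in a list-column and the fold means), `best` (the
#'   winning row), and the fold definition.
#' @export
grid_search <- function(expr, labels, grid = svm_grid(),
                        metric = c("accuracy", "sensitivity", "specificity"),
                        k = 10, seed = NULL,
                        gaussian_form = c("squared", "absolute")) {
  metric <- match.arg(metric)
  gaussian_form <- match.arg(gaussian_form)
  if (!is.data.frame(grid) || nrow(grid) == 0) abort("`grid` must be non-empty.")
  m <- expr_matrix(expr)
  y <- aligned_labels(labels, colnames(m))
  x <- t(m)
  folds <- stratified_kfold(tibble(sample_id = colnames(m), label = y),
                            k = k, seed = seed)

  eval_point <- function(i) {
    point <- as.list(grid[i, , drop = FALSE])
    fold_metrics <- tryCatch({
      purrr::map(folds, function(f) {
        pred <- fit_predict_svm(
          x[f$train, , drop = FALSE], y[f$train],
          x[f$validation, , drop = FALSE], point, gaussian_form
        )
        compute_metrics(y[f$validation], as.integer(pred))
      }) %>% bind_rows()
    }, error = function(e) {
      inform(sprintf("grid point %d failed (%s); skipped.", i, conditionMessage(e)))
      NULL
    })
    row <- as_tibble(grid[i, , drop = FALSE])
    if (is.null(fold_metrics)) {
      row$failed <- TRUE
      row$fold_metrics <- list(tibble())
      row$mean_accuracy <- NA_real_
      row$mean_sensitivity <- NA_real_
      row$mean_specificity <- NA_real_
    } else {
      row$failed <- FALSE
      row$fold_metrics <- list(fold_metrics)
      row$mean_accuracy <- mean(fold_metrics$accuracy, na.rm = TRUE)
      row$mean_sensitivity <- mean(fold_metrics$sensitivity, na.rm = TRUE)
      row$mean_specificity <- mean(fold_metrics$specificity, na.rm = TRUE)
    }
    row
  }
  results <- bind_rows(lapply(seq_len(nrow(grid)), eval_point))
  ok <- which(!results$failed)
  if (length(ok) == 0) abort("every grid point failed.")
  score <- results[[paste0("mean_", metric)]][ok]
  ord <- order(-score, -results$mean_accuracy[ok], results$cost[ok], ok)
  best_idx <- ok[ord[1]]
  structure(
    list(
      results = results, best = results[best_idx, , drop = FALSE],
      metric = metric, k = k, seed = seed, folds = folds
    ),
    class = "pgs_cv"
  )
}

#' @export
print.pgs_cv <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<pgs_cv> %d grid point(s), %d-fold CV, optimising %s\nbest: %s kernel, cost %.4g, weights (%g, %g) -> mean %s = %.4f\n",
    nrow(x$results), x$k, x$metric, b$kernel, b$cost, b$w0, b$w1,
    x$metric, b[[paste0("mean_", x$metric)]]
  ))
  invisible(x)
}

#' @export
tidy.pgs_cv <- function(x, ...) {
  x$results %>% select(-"fold_metrics")
}

#' @export
glance.pgs_cv <- function(x, ...) {
  b <- x$best
  tibble(
    metric = x$metric, kernel = b$kernel, degree = b$degree, coef0 = b$coef0,
    scale = b$scale, cost = b$cost, w0 = b$w0, w1 = b$w1,
    mean_accuracy = b$mean_accuracy, mean_sensitivity = b$mean_sensitivity,
    mean_specificity = b$mean_specificity, k = x$k
  )
}
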