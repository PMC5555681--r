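# Internal helpers shared across the pipeline.
#
# Expression data travel as a tibble whose first column is `gene_id` and whose
# remaining columns are one numeric column per sample (log-scale expression or
# per-subject log differences). Labels travel as a tibble with `sample_id` and
# a binary `label` (0 = class C0, 1 = class C1).

validate_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr)) {
    abort(sprintf("`%s` must be a data frame with a `gene_id` column.", arg))
  }
  if (!"gene_id" %in% names(expr)) {
    abort(sprintf("`%s` must have a `gene_id` column.", arg))
  }
  sample_cols <- setdiff(names(expr), "gene_id")
  if (length(sample_cols) < 2) {
    abort(sprintf("`%s` must have at least 2 sample columns.", arg))
  }
  if (nrow(expr) < 1) {
    abort(sprintf("`%s` must have at least 1 gene.", arg))
  }
  dup_g <- unique(expr$gene_id[duplicated(expr$gene_id)])
  if (length(dup_g) > 0) {
    abort(sprintf(
      "duplicate gene_id in `%s`: %s", arg,
      paste0("'", head(dup_g, 5), "'", collapse = ", ")
    ))
  }
  not_num <- sample_cols[!vapply(expr[sample_cols], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(sprintf(
      "non-numeric sample column(s) in `%s`: %s", arg,
      paste0("'", head(not_num, 5), "'", collapse = ", ")
    ))
  }
  invisible(expr)
}

validate_labels <- function(labels, sample_ids = NULL, arg = "labels") {
  if (!is.data.frame(labels) || !all(c("sample_id", "label") %in% names(labels))) {
    abort(sprintf("`%s` must be a data frame with `sample_id` and `label` columns.", arg))
  }
  if (anyDuplicated(labels$sample_id)) {
    dup <- unique(labels$sample_id[duplicated(labels$sample_id)])
    abort(sprintf("duplicate sample_id in `%s`: '%s'", arg, dup[1]))
  }
  if (!all(labels$label %in% c(0L, 1L))) {
    abort(sprintf("`%s$label` must be binary (0/1).", arg))
  }
  if (!is.null(sample_ids)) {
    if (!setequal(labels$sample_id, sample_ids)) {
      missing_in_labels <- setdiff(sample_ids, labels$sample_id)
      extra <- setdiff(labels$sample_id, sample_ids)
      abort(sprintf(
        "`%s` sample_ids do not match the expression columns (missing: %s; extra: %s).",
        arg,
        paste(head(missing_in_labels, 3), collapse = ", "),
        paste(head(extra, 3), collapse = ", ")
      ))
    }
  }
  if (sum(labels$label == 0) < 1 || sum(labels$label == 1) < 1) {
    abort(sprintf("`%s` must contain both classes.", arg))
  }
  invisible(labels)
}

# genes x samples numeric matrix with gene_id rownames
expr_matrix <- function(expr) {
  validate_expression(expr)
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

matrix_to_expr <- function(m) {
  tbl <- as_tibble(m)
  dplyr::bind_cols(tibble(gene_id = rownames(m)), tbl)
}

# label vector aligned to a given sample-id order
aligned_labels <- function(labels, sample_ids) {
  validate_labels(labels, sample_ids)
  y <- labels$label[match(sample_ids, labels$sample_id)]
  as.integer(y)
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
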