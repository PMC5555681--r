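#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and one row per gene with the
#' gene identifier in the first column. Values are log-scale expression (or
#' per-subject log differences); rows containing missing values are dropped
#' with a message rather than imputed.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter. Defaults to `","` for `.csv` files and
#'   tab otherwise.
#' @return A tibble with a `gene_id` column followed by one numeric column per
#'   sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t0\t0.5\t1"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (ncol(raw) < 3) {
    abort(sprintf("'%s' must have a gene-id column and at least 2 sample columns.", path))
  }
  names(raw)[1] <- "gene_id"
  dup_s <- unique(names(raw)[duplicated(names(raw))])
  if (length(dup_s) > 0) {
    abort(sprintf("duplicate sample id in '%s': '%s'", path, dup_s[1]))
  }
  dup_g <- unique(raw$gene_id[duplicated(raw$gene_id)])
  if (length(dup_g) > 0) {
    abort(sprintf("duplicate gene id in '%s': '%s'", path, dup_g[1]))
  }

  sample_cols <- setdiff(names(raw), "gene_id")
  parsed <- raw
  for (cn in sample_cols) {
    cell <- raw[[cn]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "NA" & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric value '%s' at row %d (gene '%s'), column '%s' of '%s'",
        cell[bad[1]], bad[1], raw$gene_id[bad[1]], cn, path
      ))
    }
    parsed[[cn]] <- num
  }

  incomplete <- !stats::complete.cases(parsed[sample_cols])
  if (any(incomplete)) {
    inform(sprintf(
      "Dropped %d gene(s) with missing values: %s",
      sum(incomplete),
      paste(head(parsed$gene_id[incomplete], 5), collapse = ", ")
    ))
    parsed <- parsed[!incomplete, , drop = FALSE]
  }
  if (nrow(parsed) < 1) {
    abort(sprintf("no complete gene rows left after dropping missing values in '%s'", path))
  }
  validate_expression(parsed, arg = path)
  as_tibble(parsed)
}

#' Write an expression tibble back to delimited text
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delim = "\t") {
  validate_expression(expr)
  readr::write_delim(expr, path, delim = delim)
  invisible(path)
}

#' Read a two-column sample label file
#'
#' @param path Path to a delimited file with columns `sample_id` and `label`
#'   (0/1; a header row is expected).
#' @param delim Field delimiter, defaulting as in [read_expression()].
#' @return A tibble with `sample_id` (character) and `label` (integer).
#' @export
read_labels <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) abort(sprintf("'%s' must have two columns: sample id and label.", path))
  out <- tibble(
    sample_id = as.character(raw[[1]]),
    label = as.integer(raw[[2]])
  )
  validate_labels(out, arg = path)
  out
}

#' Per-subject difference of paired expression matrices
#'
#' Subtracts a pre-treatment matrix from a post-treatment matrix gene by gene
#' and subject by subject. On log-scale expression this difference is the log
#' fold-change, the predictor used for response-to-treatment classification.
#'
#' @param post,pre Expression tibbles with identical `gene_id` sets. Sample
#'   columns are paired through `pairing`.
#' @param pairing Optional tibble with columns `post_id`, `pre_id` and
#'   optionally `subject` naming the output columns. By default samples are
#'   paired by identical sample id in both matrices.
#' @return An expression tibble of differences whose sample columns are the
#'   subject keys.
#' @export
paired_log_difference <- function(post, pre, pairing = NULL) {
  mp <- expr_matrix(post)
  mq <- expr_matrix(pre)
  if (!identical(rownames(mp), rownames(mq))) {
    if (!setequal(rownames(mp), rownames(mq))) {
      off <- c(setdiff(rownames(mp), rownames(mq)), setdiff(rownames(mq), rownames(mp)))
      abort(sprintf("gene_ids differ between `post` and `pre`: %s",
                    paste(head(off, 5), collapse = ", ")))
    }
    mq <- mq[rownames(mp), , drop = FALSE]
  }
  if (is.null(pairing)) {
    unmatched <- c(setdiff(colnames(mp), colnames(mq)), setdiff(colnames(mq), colnames(mp)))
    if (length(unmatched) > 0) {
      abort(sprintf("unpaired subject(s): %s", paste(unmatched, collapse = ", ")))
    }
    pairing <- tibble(post_id = colnames(mp), pre_id = colnames(mp),
                      subject = colnames(mp))
  } else {
    if (!all(c("post_id", "pre_id") %in% names(pairing))) {
      abort("`pairing` must have columns `post_id` and `pre_id`.")
    }
    if (!"subject" %in% names(pairing)) pairing$subject <- pairing$post_id
    unmatched <- c(setdiff(pairing$post_id, colnames(mp)),
                   setdiff(pairing$pre_id, colnames(mq)))
    if (length(unmatched) > 0) {
      abort(sprintf("unpaired subject(s): %s", paste(unmatched, collapse = ", ")))
    }
  }
  d <- mp[, pairing$post_id, drop = FALSE] - mq[, pairing$pre_id, drop = FALSE]
  colnames(d) <- pairing$subject
  matrix_to_expr(d)
}

#' Label vaccine responders from antibody-titer records
#'
#' Applies the standard seroconversion rule: a subject is a high responder
#' (label 1) when the day-28 over baseline titer ratio reaches `fold` for at
#' least one antigen. Subjects whose baseline titer exceeds `baseline_cap` for
#' any antigen are excluded beforehand: pre-existing immunity at such levels
#' suppresses the fold-rise and would otherwise misclassify them as
#' non-responders.
#'
#' @param titers Tibble with columns `sample_id`, `antigen`, `baseline`,
#'   `day28` (one row per subject-antigen; titers must be positive).
#' @param fold Required titer ratio (default 4).
#' @param baseline_cap Baseline exclusion threshold (default 256); subjects
#'   with any baseline strictly above it are excluded.
#' @return A tibble with one row per subject: `sample_id`, `label` (integer,
#'   `NA` for excluded subjects) and `excluded` (logical).
#' @export
label_responders <- function(titers, fold = 4, baseline_cap = 256) {
  need <- c("sample_id", "antigen", "baseline", "day28")
  if (!is.data.frame(titers) || !all(need %in% names(titers))) {
    abort("`titers` must have columns sample_id, antigen, baseline, day28.")
  }
  if (any(!is.finite(titers$baseline) | titers$baseline <= 0) ||
      any(!is.finite(titers$day28) | titers$day28 <= 0)) {
    abort("titers must be positive and finite.")
  }
  if (!is.numeric(fold) || fold <= 0) abort("`fold` must be positive.")

  titers %>%
    group_by(.data$sample_id) %>%
    summarise(
      excluded = any(.data$baseline > baseline_cap),
      label = as.integer(any(.data$day28 / .data$baseline >= fold)),
      .groups = "drop"
    ) %>%
    mutate(label = ifelse(.data$excluded, NA_integer_, .data$label)) %>%
    select("sample_id", "label", "excluded")
}

#' Write a peculiar-gene signature to JSON
#'
#' Serialises the class-specific gene sets `G0` and `G1`, their union `S` and
#' the parameters that produced them. Round-trips through [read_signature()].
#'
#' @param sig A `pgs_signature` (see [finalize_signature()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  if (!inherits(sig, "pgs_signature")) abort("`sig` must be a `pgs_signature`.")
  if (length(sig$G0) == 0) warn("writing a signature with empty G0")
  if (length(sig$G1) == 0) warn("writing a signature with empty G1")
  payload <- list(
    G0 = as.list(sig$G0), G1 = as.list(sig$G1), S = as.list(sig$S),
    params = sig$params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  g0 <- as.character(unlist(payload$G0))
  g1 <- as.character(unlist(payload$G1))
  new_signature(g0, g1, params = payload$params)
}
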