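# Small in-code fixtures.

make_expr <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
}

make_labels <- function(n0, n1, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n0 + n1))
  tibble::tibble(sample_id = ids, label = c(rep(0L, n0), rep(1L, n1)))
}

# a pgs_pp-like predictor table built from explicit vote vectors
make_profiles <- function(y_hat_rows, sample_ids, pp = NULL) {
  y_hat <- lapply(y_hat_rows, function(v) stats::setNames(as.integer(v), sample_ids))
  tibble::tibble(
    gene_id = names(y_hat_rows),
    pp = if (is.null(pp)) vapply(y_hat, mean, numeric(1)) else pp,
    y_hat = y_hat
  )
}

new_sig_for_test <- function(g0, g1) {
  suppressWarnings(finalize_signature(g0, g1))
}

random_vote_matrix <- function(P, n, m) {
  ids <- c(sprintf("a%02d", seq_len(n)), sprintf("b%02d", seq_len(m)))
  votes <- matrix(rbinom(P * (n + m), 1, runif(1, 0.2, 0.8)), nrow = P,
                  dimnames = list(sprintf("g%02d", seq_len(P)), ids))
  rows <- stats::setNames(lapply(seq_len(P), function(p) votes[p, ]),
                          rownames(votes))
  list(
    vm = build_vote_matrix(make_profiles(rows, ids), make_labels(n, m, ids)),
    votes = votes,
    classes = c(rep(0L, n), rep(1L, m))
  )
}
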