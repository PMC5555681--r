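# Synthetic two-class expression data with planted structure.
#
# The generator emulates the situation the peculiar-gene method targets: a
# block of "common" markers separates the classes but systematically
# misclassifies a small planted subset of hard samples (their shifts are
# flipped), while a handful of "peculiar" markers classify every sample
# correctly, hard ones included. All remaining genes are pure noise. Values
# are on a log-expression-like scale: additive mean shifts plus gaussian
# noise, no gene-gene correlation.

#' Simulate an imbalanced expression dataset with planted peculiar markers
#'
#' @param n0,n1 Class sizes (class 0 is the minority by default: 15 vs 45).
#' @param genes Total number of genes.
#' @param g_common Number of common markers (shifted by `delta` in class 1,
#'   with the shift flipped on the hard samples so that they misclassify
#'   them).
#' @param g_pec0,g_pec1 Numbers of planted peculiar markers for class 0 and
#'   class 1 (shifted by `delta` in every class-1 sample, never flipped).
#' @param h0,h1 Numbers of planted hard samples per class.
#' @param delta Mean shift (log-expression units, default 4).
#' @param sigma_noise Noise standard deviation (default 1).
#' @param seed Optional integer seed; the output is deterministic given it.
#' @return A list with `expression` (tibble, `gene_id` + sample columns),
#'   `labels` (tibble `sample_id`, `label`), `truth` (list with per-gene
#'   `roles` tibble and the planted `hard0`/`hard1` sample ids) and `config`.
#' @export
simulate_peculiar_data <- function(n0 = 15, n1 = 45, genes = 2000,
                                   g_common = 40, g_pec0 = 5, g_pec1 = 5,
                                   h0 = 3, h1 = 5, delta = 4,
                                   sigma_noise = 1, seed = NULL) {
  if (h0 > n0 || h1 > n1) abort("`h0`/`h1` cannot exceed the class sizes.")
  if (g_common + g_pec0 + g_pec1 > genes) {
    abort("planted gene counts exceed `genes`.")
  }
  if (delta < 0) abort("`delta` must be non-negative.")
  if (sigma_noise <= 0) abort("`sigma_noise` must be positive.")
  if (n0 < 1 || n1 < 1) abort("both classes need at least one sample.")

  build <- function() {
    N <- n0 + n1
    sample_ids <- c(sprintf("C0_%03d", seq_len(n0)), sprintf("C1_%03d", seq_len(n1)))
    labels <- tibble(sample_id = sample_ids, label = c(rep(0L, n0), rep(1L, n1)))
    gene_ids <- sprintf("g%05d", seq_len(genes))
    roles <- sample(c(
      rep("common", g_common), rep("peculiar0", g_pec0), rep("peculiar1", g_pec1),
      rep("noise", genes - g_common - g_pec0 - g_pec1)
    ))
    hard0 <- sample(sample_ids[seq_len(n0)], h0)
    hard1 <- sample(sample_ids[n0 + seq_len(n1)], h1)

    class1 <- labels$label == 1
    is_hard0 <- sample_ids %in% hard0
    is_hard1 <- sample_ids %in% hard1

    mu <- matrix(0, nrow = genes, ncol = N,
                 dimnames = list(gene_ids, sample_ids))
    common_row <- as.numeric(class1)      # delta pattern for a clean marker
    common_row[is_hard0] <- 1             # hard class-0 samples look class-1
    common_row[is_hard1] <- 0             # hard class-1 samples look class-0
    mu[roles == "common", ] <- matrix(common_row * delta,
                                      nrow = sum(roles == "common"),
                                      ncol = N, byrow = TRUE)
    pec_row <- as.numeric(class1) * delta # peculiar markers are never flipped
    mu[roles %in% c("peculiar0", "peculiar1"), ] <-
      matrix(pec_row, nrow = g_pec0 + g_pec1, ncol = N, byrow = TRUE)

    values <- mu + matrix(rnorm(genes * N, sd = sigma_noise), nrow = genes)
    list(
      expression = matrix_to_expr(values),
      labels = labels,
      truth = list(
        roles = tibble(gene_id = gene_ids, role = roles),
        hard0 = hard0, hard1 = hard1
      ),
      config = list(
        n0 = n0, n1 = n1, genes = genes, g_common = g_common,
        g_pec0 = g_pec0, g_pec1 = g_pec1, h0 = h0, h1 = h1,
        delta = delta, sigma_noise = sigma_noise, seed = seed
      )
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Score recovery of the planted peculiar markers
#'
#' @param sig A `pgs_signature`.
#' @param truth The `truth` element of [simulate_peculiar_data()] output.
#' @return A one-row tibble: `recall0` (fraction of planted class-0 peculiar
#'   markers found in `G0`), `recall1` (analogous for `G1`), and
#'   `false_marker_rate` (fraction of the signature made of noise genes).
#'   Recalls are `NA` when no marker of that role was planted.
#' @export
score_recovery <- function(sig, truth) {
  if (!inherits(sig, "pgs_signature")) abort("`sig` must be a `pgs_signature`.")
  roles <- truth$roles
  pec0 <- roles$gene_id[roles$role == "peculiar0"]
  pec1 <- roles$gene_id[roles$role == "peculiar1"]
  noise <- roles$gene_id[roles$role == "noise"]
  tibble(
    recall0 = if (length(pec0) == 0) NA_real_ else length(intersect(sig$G0, pec0)) / length(pec0),
    recall1 = if (length(pec1) == 0) NA_real_ else length(intersect(sig$G1, pec1)) / length(pec1),
    false_marker_rate = if (length(sig$S) == 0) NA_real_ else
      length(intersect(sig$S, noise)) / length(sig$S)
  )
}
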