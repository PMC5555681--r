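test_that("perfect predictors yield the ideal block vote matrix", {
  n <- 4; m <- 6
  ids <- paste0("s", 1:(n + m))
  ideal <- c(rep(0L, n), rep(1L, m))
  prof <- make_profiles(list(gA = ideal, gB = ideal, gC = ideal), ids)
  vm <- build_vote_matrix(prof, make_labels(n, m, ids))
  expect_true(all(vm$votes[, 1:n] == 0))
  expect_true(all(vm$votes[, (n + 1):(n + m)] == 1))
  expect_equal(vm$n, n)
  expect_equal(vm$m, m)
})

test_that("a single predictor's matrix is its prediction vector", {
  ids <- paste0("s", 1:5)
  v <- c(1L, 0L, 1L, 1L, 0L)
  prof <- make_profiles(list(gX = v), ids)
  vm <- build_vote_matrix(prof, make_labels(2, 3, ids))
  expect_equal(unname(vm$votes[1, ids]), v)
})

test_that("vote matrix equals row stacking and orders class-0 columns first", {
  set.seed(301)
  ids <- sample(sprintf("x%02d", 1:8))
  labels <- tibble::tibble(sample_id = ids, label = c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 1L))
  rows <- stats::setNames(
    lapply(1:5, function(i) stats::setNames(rbinom(8, 1, 0.5), ids)),
    paste0("g", 1:5)
  )
  vm <- build_vote_matrix(make_profiles(rows, ids), labels)
  expect_equal(vm$sample_ids,
               c(ids[labels$label == 0], ids[labels$label == 1]))
  for (g in names(rows)) {
    for (s in ids) expect_equal(vm$votes[g, s], unname(rows[[g]][s]))
  }
})

test_that("hard-sample detection uses strict inequalities", {
  n <- 2; m <- 2
  ids <- c("c0a", "c0b", "c1a", "c1b")
  # column sums: c0a = 9, c0b = 8, c1a = 2, c1b = 5 out of P = 10
  rows <- stats::setNames(lapply(1:10, function(p) {
    stats::setNames(c(as.integer(p <= 9), as.integer(p <= 8),
                      as.integer(p <= 2), as.integer(p <= 5)), ids)
  }), paste0("g", 1:10))
  vm <- build_vote_matrix(make_profiles(rows, ids), make_labels(n, m, ids))
  hard <- find_most_misclassified(vm, K0 = 8, K1 = 5, mode = "absolute")
  expect_equal(hard$hard0, "c0a")  # 9 > 8 but 8 is not > 8
  expect_equal(hard$hard1, "c1a")  # 2 < 5 but 5 is not < 5
  expect_error(find_most_misclassified(vm, K0 = 11, K1 = 2), "\\[0, 10\\]")
})

test_that("the ideal matrix has no hard samples for positive thresholds", {
  ids <- paste0("s", 1:10)
  ideal <- c(rep(0L, 4), rep(1L, 6))
  prof <- make_profiles(list(gA = ideal, gB = ideal, gC = ideal), ids)
  vm <- build_vote_matrix(prof, make_labels(4, 6, ids))
  hard <- find_most_misclassified(vm, K0 = 1, K1 = 3, mode = "absolute")
  expect_length(hard$hard0, 0)
  expect_length(hard$hard1, 0)
})

test_that("hard sets match the exhaustive scan on random matrices", {
  set.seed(302)
  for (i in 1:25) {
    r <- random_vote_matrix(P = 20, n = 5, m = 7)
    K0 <- sample(0:20, 1); K1 <- sample(0:20, 1)
    hard <- find_most_misclassified(r$vm, K0, K1, mode = "absolute")
    o <- oracle_hard_sets(r$votes, r$classes, K0, K1)
    expect_setequal(hard$hard0, o$hard0)
    expect_setequal(hard$hard1, o$hard1)
  }
})

test_that("quantile mode thresholds come from the per-class column sums", {
  set.seed(303)
  r <- random_vote_matrix(P = 15, n = 6, m = 8)
  hard <- find_most_misclassified(r$vm, K0 = 0.75, K1 = 0.25, mode = "quantile")
  sums <- colSums(r$votes)
  k0 <- unname(quantile(sums[r$classes == 0], 0.75))
  k1 <- unname(quantile(sums[r$classes == 1], 0.25))
  expect_equal(hard$K0, k0)
  expect_equal(hard$K1, k1)
  o <- oracle_hard_sets(r$votes, r$classes, k0, k1)
  expect_setequal(hard$hard0, o$hard0)
  expect_setequal(hard$hard1, o$hard1)
  expect_error(find_most_misclassified(r$vm, K0 = 1.5, K1 = 0.2, mode = "quantile"),
               "\\(0, 1\\)")
})

test_that("column sums are conserved", {
  set.seed(304)
  r <- random_vote_matrix(P = 12, n = 4, m = 6)
  hard <- find_most_misclassified(r$vm, K0 = 6, K1 = 6, mode = "absolute")
  expect_equal(sum(hard$counts$votes), sum(r$votes))
  expect_equal(hard$counts$votes[match(colnames(r$votes), hard$counts$sample_id)],
               unname(colSums(r$votes)))
})

test_that("raising K0 shrinks hard0 and lowering K1 shrinks hard1", {
  set.seed(305)
  r <- random_vote_matrix(P = 18, n = 6, m = 9)
  prev0 <- r$vm$sample_ids
  for (K0 in c(2, 5, 8, 11, 14, 17)) {
    cur <- find_most_misclassified(r$vm, K0 = K0, K1 = 9, mode = "absolute")$hard0
    expect_true(all(cur %in% prev0))
    prev0 <- cur
  }
  prev1 <- r$vm$sample_ids
  for (K1 in c(17, 14, 11, 8, 5, 2)) {
    cur <- find_most_misclassified(r$vm, K0 = 9, K1 = K1, mode = "absolute")$hard1
    expect_true(all(cur %in% prev1))
    prev1 <- cur
  }
})

test_that("peculiar selection honours the tolerance counting rule", {
  ids <- c("s1", "s2", "s8", "s9")
  rows <- list(
    gA = c(0L, 0L, 1L, 1L),
    gB = c(0L, 1L, 1L, 1L),
    gC = c(1L, 1L, 0L, 1L)
  )
  rows <- lapply(rows, stats::setNames, ids)
  vm <- build_vote_matrix(make_profiles(rows, ids), make_labels(2, 2, ids))
  hard <- find_most_misclassified(vm, K0 = 0, K1 = 3, mode = "absolute")
  expect_setequal(hard$hard0, c("s1", "s2"))
  expect_true("s8" %in% hard$hard1)

  hard2 <- structure(list(hard0 = c("s1", "s2"), hard1 = "s9", K0 = 0, K1 = 2,
                          mode = "absolute", counts = hard$counts),
                     class = "pgs_hard_samples")
  pec0 <- select_peculiar(vm, hard2, tolerance = 0)
  expect_equal(pec0$G0, "gA")
  expect_setequal(pec0$G1, c("gA", "gB", "gC")) # all vote 1 on s9
  pec1 <- select_peculiar(vm, hard2, tolerance = 1)
  expect_setequal(pec1$G0, c("gA", "gB"))
})

test_that("peculiar selection matches the exhaustive row filter", {
  set.seed(306)
  for (i in 1:25) {
    r <- random_vote_matrix(P = 15, n = 4, m = 6)
    hard <- find_most_misclassified(r$vm, K0 = sample(3:10, 1),
                                    K1 = sample(5:12, 1), mode = "absolute")
    tol <- sample(0:2, 1)
    pec <- suppressWarnings(select_peculiar(r$vm, hard, tolerance = tol))
    o <- oracle_peculiar(r$votes, hard$hard0, hard$hard1, tol)
    expect_setequal(pec$G0, o$G0)
    expect_setequal(pec$G1, o$G1)
    # tolerance-0 members vote correctly on every hard sample
    if (tol == 0 && length(hard$hard0) > 0) {
      for (g in pec$G0) expect_true(all(r$votes[g, hard$hard0] == 0))
    }
  }
})

test_that("increasing tolerance weakly grows both peculiar sets", {
  set.seed(307)
  r <- random_vote_matrix(P = 14, n = 5, m = 7)
  hard <- find_most_misclassified(r$vm, K0 = 6, K1 = 8, mode = "absolute")
  prev <- suppressWarnings(select_peculiar(r$vm, hard, tolerance = 0))
  for (tol in 1:4) {
    cur <- suppressWarnings(select_peculiar(r$vm, hard, tolerance = tol))
    expect_true(all(prev$G0 %in% cur$G0))
    expect_true(all(prev$G1 %in% cur$G1))
    prev <- cur
  }
})

test_that("empty hard sets give empty peculiar sets with a warning", {
  ids <- paste0("s", 1:6)
  ideal <- c(rep(0L, 2), rep(1L, 4))
  vm <- build_vote_matrix(make_profiles(list(gA = ideal, gB = ideal), ids),
                          make_labels(2, 4, ids))
  hard <- find_most_misclassified(vm, K0 = 1, K1 = 1, mode = "absolute")
  expect_warning(expect_warning(select_peculiar(vm, hard), "G0"), "G1")
})

test_that("finalize_signature unions the sets and flags degenerate input", {
  sig <- finalize_signature(c("A", "B"), c("B", "C"))
  expect_setequal(sig$S, c("A", "B", "C"))
  expect_length(sig$S, 3)
  sig2 <- finalize_signature(paste0("a", 1:11), paste0("b", 1:19))
  expect_length(sig2$S, 30)
  expect_warning(one <- finalize_signature(c("A"), character(0)), "G1 is empty")
  expect_equal(one$S, "A")
  expect_error(finalize_signature(character(0), character(0)), "relax")
})

test_that("relaxation walks the schedule and reports exhaustion", {
  ids <- c("u1", "u2", "v1", "v2", "v3")
  rows <- list(
    gA = c(0L, 1L, 1L, 1L, 1L), # misses hard0 sample u2
    gB = c(1L, 0L, 1L, 1L, 0L),
    gC = c(1L, 1L, 0L, 1L, 1L)
  )
  rows <- lapply(rows, stats::setNames, ids)
  vm <- build_vote_matrix(make_profiles(rows, ids), make_labels(2, 3, ids))
  # u1, u2 both have 2 votes -> hard0 = {u1, u2} at K0 = 1; no row votes 0 on
  # both, so tolerance 0 fails and tolerance 1 succeeds.
  schedule <- tibble::tibble(K0 = c(1, 1), K1 = c(3, 3), tolerance = c(0, 1))
  direct <- find_most_misclassified(vm, 1, 3, mode = "absolute")
  expect_setequal(direct$hard0, c("u1", "u2"))
  sig <- suppressMessages(relax_until_nonempty(vm, schedule))
  expect_setequal(sig$G0, c("gA", "gB"))
  expect_equal(nrow(attr(sig, "attempts")), 2)
  expect_equal(sig$params$tolerance, 1)

  # a schedule whose only entry cannot produce non-empty sets
  bad <- tibble::tibble(K0 = 3, K1 = 0, tolerance = 0)
  expect_error(suppressMessages(relax_until_nonempty(vm, bad)), "exhausted")
})

test_that("a schedule whose first entry works matches the direct call", {
  set.seed(308)
  r <- random_vote_matrix(P = 10, n = 4, m = 5)
  schedule <- tibble::tibble(K0 = 4, K1 = 6, tolerance = 1)
  hard <- find_most_misclassified(r$vm, 4, 6, mode = "absolute")
  pec <- suppressWarnings(select_peculiar(r$vm, hard, tolerance = 1))
  if (length(pec$G0) > 0 && length(pec$G1) > 0) {
    sig <- suppressMessages(relax_until_nonempty(r$vm, schedule))
    expect_setequal(sig$G0, pec$G0)
    expect_setequal(sig$G1, pec$G1)
  }
})
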