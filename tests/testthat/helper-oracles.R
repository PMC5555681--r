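# Independent oracles used to validate the implementation. These are written
# directly from the definitions (textbook formulas, exhaustive scans) and
# share no code with the package internals.

# Full Newton-Raphson on the Bernoulli log-likelihood, generic matrix algebra,
# cold start at (0, 0).
oracle_newton_logistic <- function(x, y, max_iter = 200, tol = 1e-12) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- diag(p * (1 - p))
    H <- t(X) %*% W %*% X
    score <- t(X) %*% (y - p)
    delta <- drop(solve(H, score))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  unname(beta)
}

# Benjamini-Hochberg step-up from the definition: walk ranks from largest to
# smallest, adjusting and enforcing monotonicity.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (r in m:1) {
    val <- min(1, p[o[r]] * m / r)
    running_min <- min(running_min, val)
    adj[o[r]] <- running_min
  }
  adj
}

# Welch two-sample t from the textbook formula.
oracle_welch_t <- function(a, b) {
  va <- var(a); vb <- var(b)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exhaustive column scan for the hard-sample rule (strict inequalities).
oracle_hard_sets <- function(votes, classes, K0, K1) {
  hard0 <- character(0); hard1 <- character(0)
  for (i in seq_len(ncol(votes))) {
    s <- sum(votes[, i])
    if (classes[i] == 0 && s > K0) hard0 <- c(hard0, colnames(votes)[i])
    if (classes[i] == 1 && s < K1) hard1 <- c(hard1, colnames(votes)[i])
  }
  list(hard0 = hard0, hard1 = hard1)
}

# Exhaustive row filter for the peculiar-gene rule.
oracle_peculiar <- function(votes, hard0, hard1, tolerance) {
  G0 <- character(0); G1 <- character(0)
  for (p in seq_len(nrow(votes))) {
    if (length(hard0) > 0) {
      wrong <- sum(votes[p, hard0] != 0)
      if (wrong <= tolerance) G0 <- c(G0, rownames(votes)[p])
    }
    if (length(hard1) > 0) {
      wrong <- sum(votes[p, hard1] != 1)
      if (wrong <= tolerance) G1 <- c(G1, rownames(votes)[p])
    }
  }
  list(G0 = G0, G1 = G1)
}

# Bernoulli log-likelihood of a single-gene logistic model.
oracle_loglik <- function(beta0, beta1, x, y) {
  eta <- beta0 + beta1 * x
  sum(y * eta - log1p(exp(eta)))
}
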