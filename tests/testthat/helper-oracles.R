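# Independent oracles, written as explicit loops over the defining sums so
# they share no code path with the package implementations.

oracle_kappa <- function(m, weighted = FALSE) {
  k <- nrow(m)
  n <- sum(m)
  p <- m / n
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k)
    w[i, j] <- if (weighted) 1 - abs(i - j) / (k - 1) else as.numeric(i == j)
  po <- 0
  for (i in 1:k) for (j in 1:k) po <- po + w[i, j] * p[i, j]
  pe <- 0
  for (i in 1:k) for (j in 1:k)
    pe <- pe + w[i, j] * sum(p[i, ]) * sum(p[, j])
  (po - pe) / (1 - pe)
}

# ICC via stats::aov mean squares, a different computational route than the
# package's direct sums of squares
oracle_icc <- function(x, definition) {
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(score = as.vector(x),
                     unit = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(score ~ unit + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (definition == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
}

random_table <- function(k, n) {
  probs <- as.vector(stats::rexp(k * k))
  counts <- stats::rmultinom(1, n, probs / sum(probs))
  m <- matrix(as.numeric(counts), k, k)
  dimnames(m) <- list(a = paste0("c", 1:k), b = paste0("c", 1:k))
  m
}

# a random table guaranteed nondegenerate (both margins spread over >= 2
# categories)
random_table_nondeg <- function(k, n) {
  repeat {
    m <- random_table(k, n)
    if (sum(rowSums(m) > 0) >= 2 && sum(colSums(m) > 0) >= 2) return(m)
  }
}
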