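# Independent brute-force oracles used to pin the normalization and
# imputation implementations. Written as plain loops over the definitions,
# sharing no code with the package internals.

# CSS: exhaustive scan over every quantile level l, explicit per-sample sums.
css_oracle <- function(counts) {
  m <- nrow(counts); n <- ncol(counts)
  q <- matrix(NA_real_, m, n)
  for (j in seq_len(n)) {
    pos <- counts[counts[, j] > 0, j]
    for (l in seq_len(m)) q[l, j] <- unname(quantile(pos, l / m))
  }
  d <- numeric(m)
  for (l in seq_len(m)) {
    qbar <- median(q[l, ])
    d[l] <- median(abs(q[l, ] - qbar))
  }
  l_hat <- NA
  for (l in seq_len(m - 1)) if (d[l + 1] - d[l] >= 0.1 * d[l]) { l_hat <- l; break }
  if (is.na(l_hat)) l_hat <- which.min(abs(seq_len(m) / m - 0.5))
  s <- numeric(n)
  for (j in seq_len(n)) s[j] <- sum(counts[counts[, j] <= q[l_hat, j], j])
  K <- median(s)
  out <- counts
  for (j in seq_len(n)) out[, j] <- K * counts[, j] / s[j]
  list(normalized = out, l_hat = l_hat, s = s, K = K)
}

# TMM: explicit enumeration of retained features, then the weighted mean.
tmm_oracle <- function(counts, ref, trim_m = 0.30, trim_a = 0.05) {
  N <- colSums(counts)
  n <- ncol(counts)
  f <- rep(1, n)
  for (j in seq_len(n)) {
    if (j == ref) next
    M <- A <- w <- c()
    for (i in seq_len(nrow(counts))) {
      cj <- counts[i, j]; cr <- counts[i, ref]
      if (cj == 0 || cr == 0) next
      M <- c(M, log2((cj / N[j]) / (cr / N[ref])))
      A <- c(A, 0.5 * log2((cj / N[j]) * (cr / N[ref])))
      w <- c(w, 1 / ((N[j] - cj) / (N[j] * cj) + (N[ref] - cr) / (N[ref] * cr)))
    }
    nn <- length(M)
    loM <- floor(nn * trim_m) + 1; hiM <- nn + 1 - loM
    loA <- floor(nn * trim_a) + 1; hiA <- nn + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[j] <- if (sum(keep) < 10) 1 else
      2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# Median-of-ratios, feature-by-feature.
deseq_oracle <- function(counts) {
  n <- ncol(counts)
  keep <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[keep, , drop = FALSE]
  f <- numeric(n)
  for (j in seq_len(n)) {
    ratios <- c()
    for (i in seq_len(nrow(sub))) {
      geo <- prod(sub[i, ])^(1 / n)
      ratios <- c(ratios, sub[i, j] / geo)
    }
    f[j] <- median(ratios)
  }
  f
}

# GMPR: double loop over pairs and shared features.
gmpr_oracle <- function(counts) {
  n <- ncol(counts)
  f <- numeric(n)
  for (j in seq_len(n)) {
    logr <- c()
    for (k in seq_len(n)) {
      if (k == j) next
      ratios <- c()
      for (y in seq_len(nrow(counts))) {
        if (counts[y, j] > 0 && counts[y, k] > 0)
          ratios <- c(ratios, counts[y, j] / counts[y, k])
      }
      if (length(ratios) > 0) logr <- c(logr, log(median(ratios)))
    }
    f[j] <- exp(mean(logr))
  }
  f / median(f)
}

# Local least squares: explicit neighbour enumeration + normal equations.
lls_oracle <- function(counts, K) {
  out <- counts
  for (i in seq_len(nrow(counts))) {
    Ci <- which(counts[i, ] == 0)
    Di <- which(counts[i, ] != 0)
    if (length(Ci) == 0 || length(Di) < 2) next
    d <- c()
    others <- setdiff(seq_len(nrow(counts)), i)
    for (o in others) d <- c(d, sqrt(sum((counts[o, Di] - counts[i, Di])^2)))
    Ki <- others[order(d)[1:K]]
    A <- t(counts[Ki, Di, drop = FALSE])     # (n-q) x K
    b <- counts[i, Di]
    x <- solve(t(A) %*% A, t(A) %*% b)       # normal equations
    for (cix in seq_along(Ci))
      out[i, Ci[cix]] <- max(sum(counts[Ki, Ci[cix]] * x), 0)
  }
  out
}

# Aitchison distance by the double loop over part pairs.
aitchison_double_loop <- function(x, y) {
  m <- length(x)
  acc <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      acc <- acc + (log(x[i] / x[j]) - log(y[i] / y[j]))^2
    }
  }
  sqrt(acc / m)
}

# Small deterministic count fixture with staggered zeros.
toy_counts <- function(nr = 10, nc = 3, seed = 1, zero_frac = 0.2) {
  set.seed(seed)
  m <- matrix(rpois(nr * nc, lambda = 50) + 1, nr, nc)
  z <- sample(length(m), round(zero_frac * length(m)))
  m[z] <- 0
  # every sample keeps positives, every pair shares features
  m[1, ] <- 100 + seq_len(nc)
  m[2, ] <- 80 + seq_len(nc)
  dimnames(m) <- list(sprintf("F%02d", 1:nr), sprintf("S%d", 1:nc))
  m
}

# The reduced moderate-sparsity recovery dataset, simulated once per run.
.fixture_env <- new.env(parent = emptyenv())
get_scenario_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- simulate_dataset(scenario_moderate_preset(seed = 1L))
  .fixture_env$ds
}

median_smape_vs_truth <- function(truth, M) {
  tc <- unclass(cpm(truth)); pc <- unclass(cpm(M))
  median(vapply(seq_len(ncol(tc)), function(j)
    smape_per_sample(tc[, j], pc[, j]), numeric(1)))
}
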