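#' Total sum scaling (TSS)
#'
#' Divides each sample's counts by its library size, returning per-sample
#' proportions. Zeros are preserved; every column sums to 1.
#'
#' @param counts feature x sample nonnegative matrix.
#' @return matrix of proportions, layer `"processed"`.
#' @export
tss <- function(counts) {
  N <- colSums(counts)
  if (any(N <= 0))
    stop("all-zero sample(s): ", paste(colnames(counts)[N <= 0], collapse = ", "))
  retag(sweep(counts, 2, N, "/"), counts, "processed")
}

#' Counts per million (CPM)
#'
#' [tss()] scaled by 1e6; the common scale on which the evaluation metrics
#' compare matrices of different normalizations.
#'
#' @inheritParams tss
#' @return matrix with columns summing to 1e6.
#' @export
cpm <- function(counts) {
  out <- tss(counts)
  retag(out * 1e6, counts, "processed")
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Scales each sample by the cumulative sum of its counts up to a
#' data-driven quantile. Per sample j, `q_j^l` is the l-th quantile of the
#' sample's positive counts and `s_j^l` the sum of counts not exceeding it.
#' With `d_l` the median absolute deviation of the `q_j^l` around the
#' median (reference) quantile, the selected level `l_hat` is the smallest l
#' whose deviation sequence turns unstable, `d_{l+1} - d_l >= 0.1 d_l`.
#' Normalized counts are `K * c_ij / s_j^l_hat` with K the median of the
#' selected scaling factors across samples.
#'
#' The quantile grid has one level per feature, evaluated over positive
#' counts only. If the instability rule never fires, the median level
#' (0.50 quantile) is used and recorded in the returned stats.
#'
#' @inheritParams tss
#' @return list with `normalized` (matrix, layer `"processed"`) and `stats`
#'   (list: `quantiles`, `deviations d_l`, `l_hat`, per-sample scaling
#'   factors `s`, constant `K`, `fallback` flag).
#' @export
css <- function(counts) {
  if (ncol(counts) < 2) stop("CSS needs at least two samples")
  if (any(colSums(counts > 0) < 1)) stop("every sample needs a positive count")
  m <- nrow(counts)
  probs <- seq_len(m) / m
  # quantiles of positive counts, one column per sample
  q <- sapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[counts[, j] > 0, j], probs = probs, names = FALSE)
  })
  qbar <- apply(q, 1, stats::median)
  d <- apply(abs(q - qbar), 1, stats::median)
  fallback <- FALSE
  l_hat <- NA_integer_
  for (l in seq_len(m - 1)) {
    if (d[l + 1] - d[l] >= 0.1 * d[l]) { l_hat <- l; break }
  }
  if (is.na(l_hat)) {
    fallback <- TRUE
    l_hat <- which.min(abs(probs - 0.5))
  }
  s <- sapply(seq_len(ncol(counts)), function(j) {
    sum(counts[counts[, j] <= q[l_hat, j], j])
  })
  K <- stats::median(s)
  out <- sweep(counts, 2, s, "/") * K
  list(normalized = retag(out, counts, "processed"),
       stats = list(quantiles = q, reference = qbar, deviations = d,
                    l_hat = l_hat, s = stats::setNames(s, colnames(counts)),
                    K = K, fallback = fallback))
}

# Reference sample for TMM: the sample whose 75th percentile of
# positive-count CPM is closest to the mean such percentile.
tmm_reference <- function(counts) {
  p <- cpm(counts)
  f75 <- sapply(seq_len(ncol(p)), function(j)
    stats::quantile(p[p[, j] > 0, j], 0.75, names = FALSE))
  which.min(abs(f75 - mean(f75)))
}

#' Trimmed mean of M-values (TMM) size factors
#'
#' For each sample against a reference sample, computes per-feature
#' log2-fold-changes `M_i = log2((c_ij/N_j)/(c_ir/N_r))` and average
#' log-abundances `A_i = 0.5 log2((c_ij/N_j)(c_ir/N_r))` over features
#' nonzero in both; double-trims 30% of each M tail and 5% of each A tail;
#' and returns `2^(weighted mean of M)` with delta-method inverse-variance
#' weights `w_i = [(N_j - c_ij)/(N_j c_ij) + (N_r - c_ir)/(N_r c_ir)]^-1`.
#' Factors are rescaled to geometric mean 1. Zero counts in either sample
#' are trimmed up front: their log-fold-change is undefined.
#'
#' @inheritParams tss
#' @param trim_m,trim_a tail trim fractions for M and A values.
#' @return list with `factors` (named positive vector, geometric mean 1,
#'   plus attributes) and `stats` (per-sample list of M, A, weights and the
#'   retained feature set; `reference` sample index).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  N <- colSums(counts)
  r <- tmm_reference(counts)
  per_sample <- vector("list", ncol(counts))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == r) { f[j] <- 1; per_sample[[j]] <- list(reference = TRUE); next }
    ok <- counts[, j] > 0 & counts[, r] > 0
    cj <- counts[ok, j]; cr <- counts[ok, r]
    M <- log2((cj / N[j]) / (cr / N[r]))
    A <- 0.5 * log2((cj / N[j]) * (cr / N[r]))
    keep <- trim_keep(M, trim_m) & trim_keep(A, trim_a)
    if (sum(keep) < 10) {
      warning(sprintf("TMM: <10 features retained for sample %s; factor set to 1",
                      colnames(counts)[j]))
      f[j] <- 1
      per_sample[[j]] <- list(retained = which(ok)[keep])
      next
    }
    w <- 1 / ((N[j] - cj) / (N[j] * cj) + (N[r] - cr) / (N[r] * cr))
    f[j] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
    per_sample[[j]] <- list(M = M, A = A, w = w, keep = keep,
                            retained = which(ok)[keep])
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  list(factors = structure(f, method = "tmm", reference = colnames(counts)[r]),
       stats = list(reference = r, per_sample = per_sample,
                    trim_m = trim_m, trim_a = trim_a))
}

# keep values whose rank falls inside the two-sided trim window
trim_keep <- function(x, frac) {
  n <- length(x)
  lo <- floor(n * frac) + 1
  hi <- n + 1 - lo
  rk <- rank(x, ties.method = "first")
  rk >= lo & rk <= hi
}

#' Median-of-ratios size factors
#'
#' The classical pseudo-reference scaling: each sample's size factor is the
#' median, over features positive in every sample, of the ratio of that
#' sample's count to the feature's geometric mean across samples. Features
#' with any zero are excluded (their geometric mean degenerates).
#'
#' @inheritParams tss
#' @return named vector of positive size factors.
#' @export
deseq_factors <- function(counts) {
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop(paste("no feature is positive in all samples; pseudo-reference",
               "alternatives are out of scope"))
  sub <- counts[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  f <- apply(sweep(sub, 1, geo, "/"), 2, stats::median)
  structure(f, method = "deseq", names = colnames(counts))
}

#' Geometric mean of pairwise ratios (GMPR) size factors
#'
#' Designed for zero-inflated count tables: for every ordered sample pair
#' (j,k), `r_jk` is the median ratio `c_yj / c_yk` over features nonzero in
#' both samples; sample j's factor is the geometric mean of its `r_jk` over
#' all usable partners k. Pairs sharing no feature are skipped (recorded),
#' and the geometric-mean exponent shrinks accordingly. Factors are
#' rescaled to median 1.
#'
#' @inheritParams tss
#' @param min_shared minimum number of shared nonzero features for a pair
#'   to be used.
#' @return list with `factors` (named positive vector, median 1) and
#'   `stats` (matrix of pairwise ratios `r`, matrix of shared-feature
#'   counts, list of skipped pairs).
#' @export
gmpr_factors <- function(counts, min_shared = 1L) {
  n <- ncol(counts)
  if (n < 2) stop("GMPR needs at least two samples")
  r <- matrix(NA_real_, n, n, dimnames = list(colnames(counts), colnames(counts)))
  shared <- matrix(0L, n, n, dimnames = dimnames(r))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) { r[j, k] <- 1; shared[j, k] <- nrow(counts); next }
      ok <- counts[, j] > 0 & counts[, k] > 0
      shared[j, k] <- sum(ok)
      if (sum(ok) >= min_shared)
        r[j, k] <- stats::median(counts[ok, j] / counts[ok, k])
    }
  }
  f <- sapply(seq_len(n), function(j) {
    rj <- r[j, -j]
    rj <- rj[!is.na(rj)]
    if (length(rj) == 0)
      stop(sprintf("sample %s shares no nonzero features with any other sample",
                   colnames(counts)[j]))
    exp(mean(log(rj)))
  })
  f <- f / stats::median(f)
  names(f) <- colnames(counts)
  skipped <- which(is.na(r), arr.ind = TRUE)
  list(factors = structure(f, method = "gmpr"),
       stats = list(r = r, shared = shared, skipped = skipped))
}

#' Divide each sample by its size factor
#'
#' @inheritParams tss
#' @param sf positive numeric vector of per-sample size factors.
#' @return scaled matrix, layer `"processed"`.
#' @export
apply_factors <- function(counts, sf) {
  sf <- as.numeric(sf)
  if (length(sf) != ncol(counts)) stop("one size factor per sample required")
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("size factors must be positive")
  retag(sweep(counts, 2, sf, "/"), counts, "processed")
}

#' Stable ids of the registered normalization methods
#' @return character vector.
#' @export
norm_ids <- function() c("tss", "css", "tmm", "deseq", "gmpr")

#' Run a normalization method by id
#'
#' @inheritParams tss
#' @param id one of `"tss"`, `"css"`, `"tmm"`, `"deseq"`, `"gmpr"`.
#' @return normalized matrix (layer `"processed"`).
#' @export
normalize_counts <- function(counts, id) {
  switch(match.arg(id, norm_ids()),
         tss = tss(counts),
         css = css(counts)$normalized,
         tmm = apply_factors(counts, tmm_factors(counts)$factors),
         deseq = apply_factors(counts, deseq_factors(counts)),
         gmpr = apply_factors(counts, gmpr_factors(counts)$factors))
}
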