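# Imputed values below this are floored to zero so that denormal noise does
# not count as an imputed (recovered) entry.
.impute_floor <- 1e-9

floor_small <- function(x) { x[x < .impute_floor] <- 0; x }

#' Local least squares imputation of zero entries
#'
#' For each feature with at least one zero, finds the `K` features nearest
#' in Euclidean distance over the samples where the target is observed
#' (non-zero), regresses the target's observed values on those neighbours,
#' and predicts the target's zero entries from the neighbours' values
#' there, clamped at zero. Non-zero entries are never modified. Features
#' observed in fewer than two samples are left unimputed (recorded).
#'
#' @param counts feature x sample nonnegative matrix.
#' @param K positive integer, number of neighbour features.
#' @return matrix of the same shape, layer `"processed"`, with attribute
#'   `"skipped"` listing features left unimputed.
#' @export
llsimpute <- function(counts, K = 10L) {
  K <- as.integer(K)
  if (K <= 0) stop("K must be positive")
  if (K >= nrow(counts)) stop("K must be smaller than the number of features")
  out <- unclass(counts)
  skipped <- character(0)
  zero_rows <- which(rowSums(counts == 0) > 0)
  for (i in zero_rows) {
    Ci <- which(counts[i, ] == 0)
    Di <- which(counts[i, ] != 0)
    if (length(Di) < 2) {
      skipped <- c(skipped, rownames(counts)[i])
      next
    }
    others <- setdiff(seq_len(nrow(counts)), i)
    d2 <- colSums((t(counts[others, Di, drop = FALSE]) - counts[i, Di])^2)
    Ki <- others[order(d2)[seq_len(K)]]
    GKD <- counts[Ki, Di, drop = FALSE]
    fit <- stats::lm.fit(x = t(GKD), y = counts[i, Di])
    x <- fit$coefficients
    x[is.na(x)] <- 0
    pred <- as.numeric(crossprod(counts[Ki, Ci, drop = FALSE], x))
    out[i, Ci] <- pmax(pred, 0)
  }
  structure(retag(floor_small(out), counts, "processed"), skipped = skipped)
}

#' Square-root Bayesian multiplicative zero replacement
#'
#' Compositional zero replacement under a Dirichlet prior of total strength
#' `sqrt(n)` (n the sample total) split uniformly over the D parts: each
#' zero part of a sample is replaced by its posterior-expected proportion
#' `(sqrt(n)/D) / (n + sqrt(n))`, non-zero proportions are multiplied by
#' one minus the total replaced mass (so ratios between non-zero parts are
#' unchanged and the column still closes to 1), and the column is rescaled
#' to its original total. The output contains no zeros.
#'
#' The evidence total `n` is the sample's sequencing depth. For raw counts
#' that is simply the column sum (the default); for a matrix that has
#' already been rescaled by a normalization step, pass the original
#' library sizes via `depths` so that the prior strength keeps its
#' count-scale meaning.
#'
#' @inheritParams llsimpute
#' @param depths per-sample totals on the count scale; defaults to the
#'   column sums of `counts`.
#' @return same-shape positive matrix, layer `"processed"`.
#' @export
zcomp_sq <- function(counts, depths = colSums(counts)) {
  N <- colSums(counts)
  if (any(N <= 0))
    stop("all-zero sample(s): ", paste(colnames(counts)[N <= 0], collapse = ", "))
  if (length(depths) != ncol(counts) || any(depths <= 0))
    stop("`depths` must be one positive total per sample")
  D <- nrow(counts)
  out <- unclass(counts)
  for (j in seq_len(ncol(counts))) {
    n <- depths[j]
    z <- counts[, j] == 0
    if (!any(z)) next
    repl <- (sqrt(n) / D) / (n + sqrt(n))
    p <- counts[, j] / N[j]
    p[!z] <- p[!z] * (1 - sum(z) * repl)
    p[z] <- repl
    out[, j] <- p * N[j]
  }
  retag(out, counts, "processed")
}

#' Rounded-zero multiplicative replacement (CZM)
#'
#' Replaces each zero proportion of a sample by a fixed fraction of the
#' detection-limit proxy `1/(n+1)` (one read out of the sample's n), then
#' multiplies the non-zero proportions by one minus the total replaced
#' mass and rescales to the original total. Ratios between non-zero parts
#' are preserved and the output contains no zeros. As in [zcomp_sq()],
#' `n` is the count-scale depth; pass `depths` after normalization.
#'
#' @inheritParams zcomp_sq
#' @param frac fraction of the detection limit used as replacement,
#'   in (0, 1).
#' @return same-shape positive matrix, layer `"processed"`.
#' @export
zcomp_czm <- function(counts, frac = 0.65, depths = colSums(counts)) {
  if (frac <= 0 || frac >= 1) stop("`frac` must be in (0, 1)")
  N <- colSums(counts)
  if (any(N <= 0))
    stop("all-zero sample(s): ", paste(colnames(counts)[N <= 0], collapse = ", "))
  if (length(depths) != ncol(counts) || any(depths <= 0))
    stop("`depths` must be one positive total per sample")
  out <- unclass(counts)
  for (j in seq_len(ncol(counts))) {
    z <- counts[, j] == 0
    if (!any(z)) next
    delta <- frac / (depths[j] + 1)
    if (sum(z) * delta >= 1)
      stop(sprintf("degenerate sample %s: replaced mass >= 1", colnames(counts)[j]))
    p <- counts[, j] / N[j]
    p[!z] <- p[!z] * (1 - sum(z) * delta)
    p[z] <- delta
    out[, j] <- p * N[j]
  }
  retag(out, counts, "processed")
}

# --- dropout-model imputer ---------------------------------------------------

# Two-component Gamma (dropout, near zero) + Normal (expressed) mixture on a
# vector of log1p-CPM values, fitted by EM. Returns the posterior dropout
# probability at value 0, or NA on failure. Moment-based gamma M-step;
# init by 10th-percentile split.
fit_dropout_mixture <- function(y, max_iter = 200L, tol = 1e-6) {
  eps <- 1e-3
  ye <- pmax(y, eps)
  thr <- stats::quantile(y, 0.1, names = FALSE)
  low <- y <= max(thr, 0)
  if (sum(low) < 2 || sum(!low) < 2) low <- y <= stats::median(y)
  if (sum(low) < 2 || sum(!low) < 2) return(NA_real_)
  gmom <- function(v, w = rep(1, length(v))) {
    m <- sum(w * v) / sum(w)
    s2 <- max(sum(w * (v - m)^2) / sum(w), 1e-6)
    c(shape = m^2 / s2, rate = m / s2)
  }
  gp <- gmom(ye[low])
  mu <- mean(y[!low]); sg <- max(stats::sd(y[!low]), 1e-3)
  lambda <- mean(low)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    fg <- stats::dgamma(ye, shape = gp["shape"], rate = gp["rate"])
    fn <- stats::dnorm(y, mu, sg)
    num <- lambda * fg
    den <- num + (1 - lambda) * fn
    if (any(!is.finite(den)) || any(den <= 0)) return(NA_real_)
    g <- num / den
    lambda <- mean(g)
    if (lambda < 1e-6 || lambda > 1 - 1e-6) break
    gp <- gmom(ye, g)
    if (!all(is.finite(gp)) || any(gp <= 0)) return(NA_real_)
    mu <- sum((1 - g) * y) / sum(1 - g)
    sg <- max(sqrt(sum((1 - g) * (y - mu)^2) / sum(1 - g)), 1e-3)
    ll <- sum(log(den))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
    if (it == max_iter) return(NA_real_)  # non-convergence
  }
  fg0 <- lambda * stats::dgamma(eps, shape = gp["shape"], rate = gp["rate"])
  fn0 <- (1 - lambda) * stats::dnorm(0, mu, sg)
  if (!is.finite(fg0 + fn0) || fg0 + fn0 <= 0) return(NA_real_)
  fg0 / (fg0 + fn0)
}

#' Dropout-model zero imputation (scImpute-style)
#'
#' Works on log1p-CPM values. For every feature with both zeros and at
#' least two positive values, a two-component Gamma (dropout) + Normal
#' (expressed) mixture is fitted across all samples by EM; a feature's zero
#' entries whose posterior dropout probability exceeds `t` become
#' imputation candidates. Each sample's candidates are then predicted by a
#' nonnegative least-squares regression of the sample on its similar
#' samples (its group members when labels are given, otherwise clusters on
#' the leading principal directions), fitted over the sample's reliable
#' (non-candidate) features. Non-candidate entries are returned
#' bit-unchanged; predictions are back-transformed to the input count
#' scale.
#'
#' @inheritParams llsimpute
#' @param t dropout-probability threshold in (0, 1).
#' @param groups optional character vector of group labels per sample.
#' @param seed integer seed for the clustering fallback.
#' @return same-shape nonnegative matrix, layer `"processed"`, with
#'   attribute `"skipped_features"` (features whose mixture fit failed).
#' @export
scimpute_like <- function(counts, t = 0.5, groups = cm_groups(counts),
                          seed = 1L) {
  if (ncol(counts) < 4) stop("need at least 4 samples")
  x <- log1p(unclass(cpm(counts)))
  N <- colSums(counts)
  n <- ncol(counts)
  drop_p <- rep(0, nrow(counts))
  skipped <- character(0)
  for (i in seq_len(nrow(counts))) {
    yi <- x[i, ]
    if (!any(yi == 0) || sum(yi > 0) < 2) next
    d <- fit_dropout_mixture(yi)
    if (is.na(d)) {
      skipped <- c(skipped, rownames(counts)[i])
      next
    }
    drop_p[i] <- d
  }
  candidate <- (unclass(counts) == 0) & (drop_p > t)
  if (is.null(groups)) {
    set.seed(seed)
    pc <- stats::prcomp(t(x), rank. = min(5, n - 1))
    k <- max(2, min(5, n %/% 5))
    groups <- as.character(stats::kmeans(pc$x, centers = k, nstart = 5)$cluster)
  }
  out <- unclass(counts)
  for (j in seq_len(n)) {
    cand_j <- which(candidate[, j])
    if (length(cand_j) == 0) next
    members <- setdiff(which(groups == groups[j]), j)
    if (length(members) == 0) next
    reliable <- which(!candidate[, j])
    A <- x[reliable, members, drop = FALSE]
    b <- x[reliable, j]
    coef <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) NULL)
    if (is.null(coef)) next
    xhat <- as.numeric(x[cand_j, members, drop = FALSE] %*% coef)
    out[cand_j, j] <- pmax(expm1(xhat), 0) * N[j] / 1e6
  }
  structure(retag(floor_small(out), counts, "processed"),
            skipped_features = skipped, dropout_probability = drop_p)
}

#' Consensus-clustering zero imputation (DrImpute-style)
#'
#' Works on log1p-CPM values. For every combination of correlation metric
#' (Spearman, Pearson) and cluster number `k` in `ks`, samples are
#' clustered by average-linkage hierarchical clustering on the
#' 1 - correlation distance, and each zero entry is estimated as the mean
#' of that feature over the other samples of the entry's cluster. The
#' final imputed value is the average of the estimates over all
#' combinations, back-transformed to the input count scale. Non-zero
#' entries are returned bit-unchanged. Values of `k` not smaller than the
#' number of samples are skipped with a warning.
#'
#' @inheritParams llsimpute
#' @param ks integer vector of cluster numbers to average over.
#' @return same-shape nonnegative matrix, layer `"processed"`.
#' @export
drimpute_like <- function(counts, ks = 10:15) {
  n <- ncol(counts)
  usable <- ks[ks < n & ks >= 1]
  if (length(usable) < length(ks))
    warning("skipping k >= number of samples: ",
            paste(setdiff(ks, usable), collapse = ", "))
  if (length(usable) == 0) stop("no usable k in `ks`")
  x <- log1p(unclass(cpm(counts)))
  N <- colSums(counts)
  zero <- unclass(counts) == 0
  acc <- matrix(0, nrow(counts), n)
  combos <- 0L
  for (metric in c("spearman", "pearson")) {
    cm <- suppressWarnings(stats::cor(x, method = metric))
    cm[!is.finite(cm)] <- 0  # constant column: no usable ranking signal
    dmat <- stats::as.dist(1 - cm)
    hc <- stats::hclust(dmat, method = "average")
    for (k in usable) {
      cl <- stats::cutree(hc, k = k)
      est <- matrix(0, nrow(counts), n)
      for (g in unique(cl)) {
        members <- which(cl == g)
        if (length(members) < 2) next  # no other member: estimate stays 0
        tot <- rowSums(x[, members, drop = FALSE])
        # leave-self-out cluster mean; zero entries contribute 0 to tot
        est[, members] <- (tot - x[, members, drop = FALSE]) /
          (length(members) - 1)
      }
      acc <- acc + est
      combos <- combos + 1L
    }
  }
  xhat <- acc / combos
  out <- unclass(counts)
  out[zero] <- pmax(expm1(xhat[zero]), 0) * rep(N / 1e6, each = nrow(counts))[zero]
  structure(retag(floor_small(out), counts, "processed"),
            combinations = combos)
}

#' Stable ids of the registered zero-imputation methods
#' @return character vector.
#' @export
imp_ids <- function() c("llsimpute", "zcomp_sq", "zcomp_czm", "scimpute",
                        "drimpute")

#' Run a zero-imputation method by id
#'
#' @inheritParams llsimpute
#' @param id one of `"llsimpute"`, `"zcomp_sq"`, `"zcomp_czm"`,
#'   `"scimpute"`, `"drimpute"`.
#' @param params named list of per-method parameter overrides (`K`, `frac`,
#'   `t`, `groups`, `seed`, `ks`).
#' @return imputed matrix (layer `"processed"`).
#' @export
impute_counts <- function(counts, id, params = list()) {
  id <- match.arg(id, imp_ids())
  p <- function(name, default) params[[name]] %||% default
  switch(id,
         llsimpute = llsimpute(counts, K = p("K", 10L)),
         zcomp_sq = zcomp_sq(counts, depths = p("depths", colSums(counts))),
         zcomp_czm = zcomp_czm(counts, frac = p("frac", 0.65),
                               depths = p("depths", colSums(counts))),
         scimpute = scimpute_like(counts, t = p("t", 0.5),
                                  groups = p("groups", cm_groups(counts)),
                                  seed = p("seed", 1L)),
         drimpute = drimpute_like(counts, ks = p("ks", 10:15)))
}
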