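#' Total sparsity of a matrix, in percent
#'
#' @param M numeric matrix.
#' @return percentage of exactly-zero entries.
#' @export
total_sparsity <- function(M) {
  if (length(M) == 0) stop("empty matrix")
  100 * mean(M == 0)
}

#' Classify imputed zeros against the ground truth
#'
#' Over the entries that are zero in the raw matrix: a zero is *technical*
#' if the ground truth there is positive (the species was present but
#' unobserved) and *biological* if the ground truth is exactly zero. An
#' entry counts as imputed when the processed matrix is positive there.
#' TP = technical and imputed, FP = biological and imputed, FN = technical
#' and not imputed, TN = biological and not imputed.
#'
#' @param truth,raw,processed matrices of identical shape.
#' @return object of class `zero_confusion`: list with `TP`, `FP`, `FN`,
#'   `TN`, `sensitivity` (percent) and `specificity` (percent).
#' @export
zero_confusion <- function(truth, raw, processed) {
  stopifnot(all(dim(truth) == dim(raw)), all(dim(raw) == dim(processed)))
  z <- raw == 0
  technical <- z & truth > 0
  biological <- z & truth == 0
  imputed <- processed > 0
  TP <- sum(technical & imputed)
  FN <- sum(technical & !imputed)
  FP <- sum(biological & imputed)
  TN <- sum(biological & !imputed)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
                 specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_),
            class = "zero_confusion")
}

#' @method print zero_confusion
#' @export
print.zero_confusion <- function(x, ...) {
  cat(sprintf("zero_confusion: TP %d FP %d FN %d TN %d | sens %.2f%% spec %.2f%%\n",
              x$TP, x$FP, x$FN, x$TN, x$sensitivity, x$specificity))
  invisible(x)
}

#' Symmetric mean absolute percentage error between two vectors
#'
#' `100/m * sum |x_i - y_i| / (|x_i| + |y_i|)`, with the 0/0 convention
#' that an element where both vectors are zero contributes 0. Bounded in
#' \[0, 100\] and symmetric in its arguments.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return SMAPE in percent.
#' @export
smape_per_sample <- function(x, y) {
  stopifnot(length(x) == length(y))
  num <- abs(x - y)
  den <- abs(x) + abs(y)
  term <- ifelse(den == 0, 0, num / den)
  100 * mean(term)
}

# clr transform of a strictly positive vector
clr <- function(x) log(x) - mean(log(x))

#' Aitchison distance between two compositions
#'
#' `sqrt(1/m * sum_{i<j} (ln(x_i/x_j) - ln(y_i/y_j))^2)`, the natural
#' distance on the simplex; scale-invariant in each argument. Computed via
#' the centred-log-ratio identity (it equals the Euclidean distance
#' between clr vectors). Zeros are handled by a configurable replacement
#' rule applied before the transform; the default replaces zeros with half
#' the smallest positive value observed across the two vectors.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @param zero_rule function applied to `(x, y)` returning the repaired
#'   list `list(x, y)`; the default is half-minimum replacement.
#' @return nonnegative distance.
#' @export
aitchison_per_sample <- function(x, y, zero_rule = half_min_replace) {
  stopifnot(length(x) == length(y))
  r <- zero_rule(x, y)
  sqrt(sum((clr(r[[1]]) - clr(r[[2]]))^2))
}

#' Half-minimum zero replacement for a vector pair
#' @param x,y nonnegative numeric vectors.
#' @return list of the two vectors with zeros replaced by half the
#'   smallest positive value across both.
#' @export
half_min_replace <- function(x, y) {
  pos <- c(x[x > 0], y[y > 0])
  if (length(pos) == 0) stop("both vectors are all zero")
  repl <- 0.5 * min(pos)
  x[x == 0] <- repl
  y[y == 0] <- repl
  list(x, y)
}

#' Per-sample alpha diversity: observed richness, Shannon entropy, Pielou
#'
#' Richness is the number of positive entries; Shannon entropy `H` is
#' computed on the sample's proportions (the log of the order-1 Hill
#' number); Pielou evenness is `J = H / ln(S_obs)`, which is undefined
#' (returned as `NA`) for samples with a single observed species.
#'
#' @param M feature x sample matrix with positive column sums.
#' @return data.frame with columns `sample`, `richness`, `shannon`,
#'   `pielou`.
#' @export
alpha_indices <- function(M) {
  if (any(colSums(M) <= 0)) stop("all-zero sample(s)")
  S <- colSums(M > 0)
  H <- vegan::diversity(t(unclass(M)), index = "shannon")
  J <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(sample = colnames(M) %||% sprintf("S%03d", seq_len(ncol(M))),
             richness = as.integer(S), shannon = unname(H), pielou = unname(J),
             row.names = NULL)
}

#' Cohen's d with a magnitude label
#'
#' Standardized mean difference with pooled standard deviation, labelled
#' on the conventional scale: Negligible (< 0.01), Very small (>= 0.01),
#' Small (>= 0.20), Medium (>= 0.50), Large (>= 0.80), Very large
#' (>= 1.20), Huge (>= 2.0); labels are assigned on |d|.
#'
#' @param sample1,sample2 numeric vectors with at least two values each.
#' @return list with `d` and `magnitude`.
#' @export
cohens_d_magnitude <- function(sample1, sample2) {
  stopifnot(length(sample1) >= 2, length(sample2) >= 2)
  n1 <- length(sample1); n2 <- length(sample2)
  sp <- sqrt(((n1 - 1) * stats::var(sample1) + (n2 - 1) * stats::var(sample2)) /
               (n1 + n2 - 2))
  d <- if (sp == 0) 0 else (mean(sample1) - mean(sample2)) / sp
  cuts <- c(0.01, 0.20, 0.50, 0.80, 1.20, 2.0)
  labels <- c("Negligible", "Very small", "Small", "Medium", "Large",
              "Very large", "Huge")
  list(d = d, magnitude = labels[findInterval(abs(d), cuts) + 1])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped
#' at 1).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Jaccard index of two sets
#'
#' Intersection over union. Two empty sets are perfectly concordant
#' (index 1): neither analysis finds any feature.
#'
#' @param A,B vectors interpreted as sets.
#' @return value in \[0, 1\].
#' @export
jaccard <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) return(1)
  length(intersect(A, B)) / u
}

#' Pairwise Whittaker beta diversity matrix
#'
#' On presence/absence: `beta_w(a, b) = S_union / ((S_a + S_b)/2)`, the
#' number of species in the union of the two samples over their mean
#' richness. Identical presence sets give 1; disjoint sets give 2.
#'
#' @param M feature x sample matrix.
#' @return symmetric sample x sample matrix with unit diagonal.
#' @export
whittaker_matrix <- function(M) {
  P <- unclass(M) > 0
  S <- colSums(P)
  inter <- crossprod(P)          # shared species counts
  union_ <- outer(S, S, "+") - inter
  out <- union_ / (outer(S, S, "+") / 2)
  dimnames(out) <- list(colnames(M), colnames(M))
  out
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y)`.
#'
#' @param M feature x sample matrix with positive column sums.
#' @return symmetric sample x sample matrix in \[0, 1\], zero diagonal.
#' @export
bray_curtis_matrix <- function(M) {
  if (any(colSums(M) <= 0)) stop("all-zero sample(s)")
  as.matrix(vegan::vegdist(t(unclass(M)), method = "bray"))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Iterative stress minimization with monotone regression, restarted from
#' random configurations; the best (lowest-stress) solution is kept.
#' Deterministic given `seed`.
#'
#' @param dist_matrix symmetric nonnegative matrix or `dist`.
#' @param dims embedding dimension.
#' @param seed integer seed.
#' @param restarts number of random restarts.
#' @return list with `points` (samples x dims) and `stress` (final stress,
#'   proportion scale).
#' @export
nmds_embed <- function(dist_matrix, dims = 2, seed = 1L, restarts = 20L) {
  d <- stats::as.dist(dist_matrix)
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, trymax = restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  pts <- fit$points
  rownames(pts) <- attr(d, "Labels")
  list(points = pts, stress = fit$stress)
}

#' Differentially abundant features between two groups
#'
#' For each feature, a two-sided Mann-Whitney (Wilcoxon rank-sum) test
#' between the samples of the two groups; Benjamini-Hochberg correction
#' across features; features with adjusted p below `alpha_level` are
#' returned. Features all-zero in both groups are excluded from testing.
#'
#' @param M feature x sample matrix.
#' @param groups character vector of group labels per sample (exactly two
#'   distinct labels among the tested columns).
#' @param alpha_level significance level on adjusted p-values.
#' @return character vector of feature ids, with attribute `"table"`
#'   holding the per-feature p-values.
#' @export
da_features <- function(M, groups, alpha_level = 0.05) {
  stopifnot(length(groups) == ncol(M))
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  a <- which(groups == lv[1]); b <- which(groups == lv[2])
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 samples")
  keep <- rowSums(M[, c(a, b), drop = FALSE]) > 0
  ids <- rownames(M)[keep]
  p <- vapply(which(keep), function(i) {
    suppressWarnings(stats::wilcox.test(M[i, a], M[i, b], exact = FALSE,
                                        correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  padj <- benjamini_hochberg(p)
  tab <- data.frame(feature = ids, p = p, p_adj = padj, row.names = NULL)
  structure(ids[padj < alpha_level], table = tab)
}

#' Alpha-diversity group comparisons with direction
#'
#' For every ordered pair of groups and each alpha index, one-sided
#' Mann-Whitney tests in both directions decide whether the index is
#' significantly higher (`up`), lower (`down`) or not different (`ns`) in
#' the first group; p-values are Benjamini-Hochberg-corrected within each
#' index across group pairs.
#'
#' @param M feature x sample matrix.
#' @param groups character vector of group labels per sample.
#' @param alpha_level significance level on adjusted p-values.
#' @return data.frame with columns `index`, `group_a`, `group_b`,
#'   `p_greater`, `p_less` (adjusted) and `label`.
#' @export
alpha_group_comparisons <- function(M, groups, alpha_level = 0.05) {
  stopifnot(length(groups) == ncol(M))
  idx <- alpha_indices(M)
  lv <- unique(groups)
  if (length(lv) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- list()
  for (index in c("richness", "pielou")) {
    v <- idx[[index]]
    rows <- lapply(pairs, function(pr) {
      xa <- v[groups == pr[1]]; xb <- v[groups == pr[2]]
      pg <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = "greater",
                                                exact = FALSE)$p.value)
      pl <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = "less",
                                                exact = FALSE)$p.value)
      data.frame(index = index, group_a = pr[1], group_b = pr[2],
                 p_greater = pg, p_less = pl)
    })
    tab <- do.call(rbind, rows)
    tab$p_greater <- benjamini_hochberg(tab$p_greater)
    tab$p_less <- benjamini_hochberg(tab$p_less)
    tab$label <- ifelse(tab$p_greater < alpha_level, "up",
                        ifelse(tab$p_less < alpha_level, "down", "ns"))
    out[[index]] <- tab
  }
  do.call(rbind, out)
}

#' Compare a pipeline's alpha-index errors with raw data
#'
#' Computes per-sample relative errors of an alpha index against the
#' ground truth for the processed and the raw matrix, and tests whether
#' the processed errors are stochastically smaller using a one-sided
#' paired Wilcoxon signed-rank test. Intended to be called per pipeline
#' and corrected across pipelines by the caller ([evaluate_all()] does).
#'
#' @param truth,raw,processed matrices of identical shape.
#' @param index `"richness"` or `"pielou"`.
#' @return list with `rel_err_processed`, `rel_err_raw` (per sample), `p`
#'   (one-sided signed-rank p), `d` and `magnitude` (Cohen's d of the
#'   error distributions).
#' @export
alpha_error_test <- function(truth, raw, processed,
                             index = c("richness", "pielou")) {
  index <- match.arg(index)
  it <- alpha_indices(truth)[[index]]
  rel <- function(M) {
    ix <- alpha_indices(M)[[index]]
    abs(ix - it) / ifelse(it == 0, NA_real_, it)
  }
  ep <- rel(processed); er <- rel(raw)
  ok <- is.finite(ep) & is.finite(er)
  p <- if (all(ep[ok] == er[ok])) 1 else
    suppressWarnings(stats::wilcox.test(ep[ok], er[ok], paired = TRUE,
                                        alternative = "less",
                                        exact = FALSE)$p.value)
  es <- if (sum(ok) >= 2) cohens_d_magnitude(er[ok], ep[ok]) else
    list(d = NA_real_, magnitude = NA_character_)
  list(rel_err_processed = ep, rel_err_raw = er, p = p,
       d = es$d, magnitude = es$magnitude)
}
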