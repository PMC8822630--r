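#' Evaluate a set of preprocessed matrices against the ground truth
#'
#' Runs the full benchmark battery for every pipeline output: total
#' sparsity, technical/biological zero classification, per-sample SMAPE
#' and Aitchison distance on the CPM scale, alpha-diversity relative
#' errors (with one-sided paired signed-rank improvement tests,
#' Benjamini-Hochberg-corrected across pipelines, and Cohen's d), alpha
#' group-comparison disagreement, beta-diversity preservation (agreement
#' of Bray-Curtis and Whittaker matrices with the ground truth, NMDS
#' stress) and differential-abundance concordance (Jaccard index per
#' group pair, against the ground truth's DA feature sets).
#'
#' @param truth ground-truth matrix.
#' @param raw raw count matrix (same shape, with group labels).
#' @param processed_by_pipeline named list of processed matrices.
#' @param groups group labels per sample; defaults to the raw matrix's.
#' @param alpha_level significance level used throughout.
#' @param nmds logical: compute NMDS embeddings (the slowest step).
#' @param seed integer seed for NMDS restarts.
#' @return object of class `eval_report`: a named list of tidy
#'   data.frames (`sparsity`, `zero_classification`, `abundance_error`,
#'   `alpha_tests`, `alpha_comparisons`, `beta`, `da`, `summary`).
#' @export
evaluate_all <- function(truth, raw, processed_by_pipeline,
                         groups = cm_groups(raw), alpha_level = 0.05,
                         nmds = TRUE, seed = 1L) {
  stopifnot(all(dim(truth) == dim(raw)))
  pn <- names(processed_by_pipeline)
  if (is.null(pn)) stop("processed matrices must be named by pipeline")
  truth_cpm <- unclass(cpm(truth))
  raw_cpm <- unclass(cpm(raw))
  ns <- ncol(raw)

  per_sample_err <- function(P) {
    pc <- unclass(cpm(P))
    data.frame(
      sample = colnames(raw),
      smape = vapply(seq_len(ns), function(j)
        smape_per_sample(truth_cpm[, j], pc[, j]), numeric(1)),
      aitchison = vapply(seq_len(ns), function(j)
        aitchison_per_sample(truth_cpm[, j], pc[, j]), numeric(1)),
      row.names = NULL)
  }
  raw_err <- per_sample_err(raw)

  lower <- function(M) M[lower.tri(M)]
  truth_bc <- bray_curtis_matrix(truth_cpm)
  truth_wh <- whittaker_matrix(truth)

  pair_groups <- if (!is.null(groups) && length(unique(groups)) >= 2)
    utils::combn(unique(groups), 2, simplify = FALSE) else list()
  da_of <- function(M) {
    lapply(pair_groups, function(pr) {
      sel <- groups %in% pr
      da_features(M[, sel, drop = FALSE], groups[sel], alpha_level)
    })
  }
  truth_da <- da_of(truth)
  raw_da <- da_of(raw)
  pair_names <- vapply(pair_groups, paste, "", collapse = " vs ")

  truth_labels <- if (length(pair_groups) > 0)
    alpha_group_comparisons(truth, groups, alpha_level) else NULL

  sparsity <- data.frame(
    pipeline = c("ground_truth", "raw", pn),
    sparsity = c(total_sparsity(truth), total_sparsity(raw),
                 vapply(processed_by_pipeline, total_sparsity, numeric(1))),
    row.names = NULL)

  conf_rows <- lapply(pn, function(p) {
    zc <- zero_confusion(truth, raw, processed_by_pipeline[[p]])
    data.frame(pipeline = p, TP = zc$TP, FP = zc$FP, FN = zc$FN, TN = zc$TN,
               sensitivity = zc$sensitivity, specificity = zc$specificity)
  })
  zero_classification <- do.call(rbind, conf_rows)

  abundance_error <- do.call(rbind, c(
    list(cbind(pipeline = "raw", raw_err)),
    lapply(pn, function(p)
      cbind(pipeline = p, per_sample_err(processed_by_pipeline[[p]])))))

  alpha_tests <- do.call(rbind, lapply(pn, function(p) {
    do.call(rbind, lapply(c("richness", "pielou"), function(ix) {
      at <- alpha_error_test(truth, raw, processed_by_pipeline[[p]], ix)
      data.frame(pipeline = p, index = ix,
                 median_rel_err = stats::median(at$rel_err_processed, na.rm = TRUE),
                 median_rel_err_raw = stats::median(at$rel_err_raw, na.rm = TRUE),
                 p = at$p, d = at$d, magnitude = at$magnitude)
    }))
  }))
  for (ix in unique(alpha_tests$index)) {
    sel <- alpha_tests$index == ix
    alpha_tests$p_adj[sel] <- benjamini_hochberg(alpha_tests$p[sel])
  }

  alpha_comparisons <- if (!is.null(truth_labels)) {
    key <- function(tab) paste(tab$index, tab$group_a, tab$group_b)
    disagreement <- function(M) {
      lab <- alpha_group_comparisons(M, groups, alpha_level)
      stopifnot(identical(key(lab), key(truth_labels)))
      100 * mean(lab$label != truth_labels$label)
    }
    data.frame(pipeline = c("raw", pn),
               disagreement_pct = c(disagreement(raw),
                                    vapply(processed_by_pipeline, disagreement,
                                           numeric(1))),
               row.names = NULL)
  } else NULL

  beta_rows <- lapply(c(list(raw = raw), processed_by_pipeline), function(P) {
    pc <- unclass(cpm(P))
    bc <- bray_curtis_matrix(pc)
    wh <- whittaker_matrix(P)
    stress <- if (nmds) nmds_embed(bc, seed = seed)$stress else NA_real_
    # a constant dissimilarity matrix (e.g. zero-free output) has no
    # correlation with anything
    safe_cor <- function(a, b)
      if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
    data.frame(bray_curtis_cor = safe_cor(lower(bc), lower(truth_bc)),
               whittaker_cor = safe_cor(lower(wh), lower(truth_wh)),
               nmds_stress = stress)
  })
  beta <- cbind(pipeline = c("raw", pn), do.call(rbind, beta_rows))
  rownames(beta) <- NULL

  da <- if (length(pair_groups) > 0) {
    jacc <- function(sets) vapply(seq_along(sets), function(i)
      jaccard(truth_da[[i]], sets[[i]]), numeric(1))
    do.call(rbind, c(
      list(data.frame(pipeline = "raw", pair = pair_names,
                      jaccard = jacc(raw_da))),
      lapply(pn, function(p)
        data.frame(pipeline = p, pair = pair_names,
                   jaccard = jacc(da_of(processed_by_pipeline[[p]]))))))
  } else NULL

  report <- list(sparsity = sparsity,
                 zero_classification = zero_classification,
                 abundance_error = abundance_error,
                 alpha_tests = alpha_tests,
                 alpha_comparisons = alpha_comparisons,
                 beta = beta, da = da)
  report$summary <- summarize_report(report)
  structure(report, class = "eval_report", alpha_level = alpha_level)
}

# Qualitative per-pipeline grid: each metric labelled better / comparable /
# worse than the raw-data baseline (relative margin 2%).
summarize_report <- function(report, margin = 0.02) {
  pn <- setdiff(unique(report$zero_classification$pipeline),
                c("raw", "ground_truth"))
  truth_sp <- report$sparsity$sparsity[report$sparsity$pipeline == "ground_truth"]
  raw_sp <- report$sparsity$sparsity[report$sparsity$pipeline == "raw"]
  med <- function(tab, p, col) {
    stats::median(tab[[col]][tab$pipeline == p], na.rm = TRUE)
  }
  lab <- function(value, baseline, lower_better = TRUE) {
    if (!lower_better) { value <- -value; baseline <- -baseline }
    span <- max(abs(baseline), 1e-12)
    if (value < baseline - margin * span) "better"
    else if (value > baseline + margin * span) "worse"
    else "comparable"
  }
  rows <- lapply(pn, function(p) {
    sp <- report$sparsity$sparsity[report$sparsity$pipeline == p]
    data.frame(
      pipeline = p,
      sparsity = lab(abs(sp - truth_sp), abs(raw_sp - truth_sp)),
      smape = lab(med(report$abundance_error, p, "smape"),
                  med(report$abundance_error, "raw", "smape")),
      aitchison = lab(med(report$abundance_error, p, "aitchison"),
                      med(report$abundance_error, "raw", "aitchison")),
      da = if (is.null(report$da)) NA_character_ else
        lab(med(report$da, p, "jaccard"), med(report$da, "raw", "jaccard"),
            lower_better = FALSE))
  })
  do.call(rbind, rows)
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report with tables:",
      paste(names(Filter(Negate(is.null), x)), collapse = ", "), "\n")
  cat("pipelines evaluated:", nrow(x$summary), "\n")
  invisible(x)
}
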