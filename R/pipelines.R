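#' Specify one preprocessing pipeline
#'
#' An ordered pair of an optional normalization and an optional
#' zero-imputation method (not both absent). Execution order is always
#' normalization first, then imputation.
#'
#' @param normalization normalization id or `NULL`.
#' @param imputation imputation id or `NULL`.
#' @return object of class `pipeline_spec` with a display `name` such as
#'   `"gmpr + scimpute"`.
#' @export
pipeline_spec <- function(normalization = NULL, imputation = NULL) {
  if (is.null(normalization) && is.null(imputation))
    stop("a pipeline needs at least one stage")
  if (!is.null(normalization) && !normalization %in% norm_ids())
    stop("unknown normalization id: ", normalization)
  if (!is.null(imputation) && !imputation %in% imp_ids())
    stop("unknown imputation id: ", imputation)
  name <- paste(c(normalization, imputation), collapse = " + ")
  structure(list(normalization = normalization, imputation = imputation,
                 name = name), class = "pipeline_spec")
}

#' @method print pipeline_spec
#' @export
print.pipeline_spec <- function(x, ...) {
  cat("pipeline_spec:", x$name, "\n")
  invisible(x)
}

#' Enumerate the preprocessing pipeline registry
#'
#' All normalization-only pipelines, then all imputation-only pipelines,
#' then every (normalization, imputation) pair. With the default five
#' methods on each side this yields the full set of 35 pipelines.
#'
#' @param norm_ids character vector of normalization ids.
#' @param imp_ids character vector of imputation ids.
#' @return named list of [pipeline_spec()] objects,
#'   length `|N| + |I| + |N|*|I|`.
#' @export
build_registry <- function(norm_ids = zibench16S::norm_ids(),
                           imp_ids = zibench16S::imp_ids()) {
  if (length(norm_ids) == 0 || length(imp_ids) == 0)
    stop("both method sets must be non-empty")
  specs <- c(
    lapply(norm_ids, function(n) pipeline_spec(normalization = n)),
    lapply(imp_ids, function(i) pipeline_spec(imputation = i)),
    unlist(lapply(norm_ids, function(n)
      lapply(imp_ids, function(i)
        pipeline_spec(normalization = n, imputation = i))),
      recursive = FALSE)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Run one preprocessing pipeline
#'
#' Applies the pipeline's normalization (if any) and then its imputation
#' (if any) to a raw count matrix. The output carries the layer tag
#' `"processed"` and a `provenance` attribute recording the pipeline,
#' parameters and seed.
#'
#' @param raw raw-layer [count_matrix()].
#' @param spec a [pipeline_spec()].
#' @param config named list of per-method parameter overrides, passed to
#'   [impute_counts()]; a `seed` entry governs stochastic stages.
#' @return processed matrix.
#' @export
run_pipeline <- function(raw, spec, config = list()) {
  stopifnot(inherits(spec, "pipeline_spec"))
  t0 <- proc.time()[["elapsed"]]
  out <- raw
  if (!is.null(spec$normalization)) {
    out <- tryCatch(
      normalize_counts(out, spec$normalization),
      error = function(e) stop(sprintf("[%s] %s", spec$name, conditionMessage(e)),
                               call. = FALSE))
  }
  if (!is.null(spec$imputation)) {
    params <- config[[spec$imputation]] %||% list()
    if (is.null(params$groups)) params$groups <- cm_groups(raw)
    if (is.null(params$depths)) params$depths <- colSums(raw)
    if (is.null(params$seed) && !is.null(config$seed))
      params$seed <- config$seed
    out <- tryCatch(
      impute_counts(out, spec$imputation, params),
      error = function(e) stop(sprintf("[%s] %s", spec$name, conditionMessage(e)),
                               call. = FALSE))
  }
  attr(out, "provenance") <- list(
    pipeline = spec$name, normalization = spec$normalization,
    imputation = spec$imputation, config = config,
    elapsed = proc.time()[["elapsed"]] - t0)
  out
}
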