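#' Read a feature x sample count table
#'
#' Dense TSV: header row of sample ids, first column of feature ids,
#' numeric body. Alternatively a MatrixMarket triplet file accompanied by
#' `<stem>.features.txt` and `<stem>.samples.txt` id files (one id per
#' line). Negative values, duplicated ids and ragged rows are rejected
#' with messages naming the offender.
#'
#' @param path path to a `.tsv` or `.mtx` file.
#' @param layer layer tag for the returned matrix.
#' @param groups optional group labels (see [count_matrix()]).
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, layer = "raw", groups = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".features.txt"))
    colnames(m) <- readLines(paste0(stem, ".samples.txt"))
    return(count_matrix(m, layer = layer, groups = groups))
  }
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty or header-only file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  bad <- which(vapply(fields, length, 0L) != ncols)
  if (length(bad) > 0)
    stop(sprintf("ragged row at line %d of %s", bad[1], path))
  header <- fields[[1]][-1]
  ids <- vapply(fields[-1], `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicated feature id: ", ids[duplicated(ids)][1])
  if (anyDuplicated(header))
    stop("duplicated sample id: ", header[duplicated(header)][1])
  body <- t(vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(ncols - 1)))
  if (ncols == 2) body <- matrix(body, ncol = 1)
  if (anyNA(body)) {
    at <- which(is.na(body), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at feature %s, sample %s",
                 ids[at[1]], header[at[2]]))
  }
  if (any(body < 0)) {
    at <- which(body < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at feature %s, sample %s",
                 ids[at[1]], header[at[2]]))
  }
  dimnames(body) <- list(ids, header)
  count_matrix(body, layer = layer, groups = groups)
}

#' Write a count table as dense TSV
#'
#' Tab-separated, UTF-8, '.' decimal, no quoting; values at full precision
#' (shortest round-tripping representation). Inverse of [read_counts()].
#'
#' @param counts matrix to write.
#' @param path destination path.
#' @export
write_counts <- function(counts, path) {
  m <- unclass(counts)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample-to-group metadata table
#'
#' Two-column TSV (`sample_id`, `group`). When `counts` is supplied the
#' mapping must cover exactly its samples; unknown or missing samples are
#' reported by name.
#'
#' @param path path to the TSV.
#' @param counts optional count matrix to validate against.
#' @return named character vector (sample id -> group).
#' @export
read_metadata <- function(path, counts = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("metadata needs columns sample_id and group")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate sample_id: ", tab[[1]][duplicated(tab[[1]])][1])
  map <- stats::setNames(tab[[2]], tab[[1]])
  if (!is.null(counts)) {
    extra <- setdiff(names(map), colnames(counts))
    missing <- setdiff(colnames(counts), names(map))
    if (length(extra) > 0)
      stop("metadata samples not in counts: ", paste(extra, collapse = ", "))
    if (length(missing) > 0)
      stop("counts samples not in metadata: ", paste(missing, collapse = ", "))
    map <- map[colnames(counts)]
  }
  map
}

#' Write sample metadata as TSV
#' @param groups named character vector (sample id -> group).
#' @param path destination path.
#' @export
write_metadata <- function(groups, path) {
  utils::write.table(data.frame(sample_id = names(groups), group = groups),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset as plain-text artifacts
#'
#' Emits `ground_truth.tsv`, `raw.tsv`, `metadata.tsv` and `depths.tsv`
#' under `dir`.
#'
#' @param ds a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(ds$ground_truth, file.path(dir, "ground_truth.tsv"))
  write_counts(ds$raw, file.path(dir, "raw.tsv"))
  write_metadata(cm_groups(ds$raw), file.path(dir, "metadata.tsv"))
  utils::write.table(data.frame(sample_id = names(ds$depths),
                                depth = as.integer(ds$depths)),
                     file.path(dir, "depths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Read a simulated dataset written by [write_dataset()]
#' @param dir the dataset directory.
#' @return a `simulated_dataset`.
#' @export
read_dataset <- function(dir) {
  groups <- read_metadata(file.path(dir, "metadata.tsv"))
  truth <- read_counts(file.path(dir, "ground_truth.tsv"),
                       layer = "ground_truth", groups = groups)
  raw <- read_counts(file.path(dir, "raw.tsv"), layer = "raw",
                     groups = groups)
  dep <- utils::read.delim(file.path(dir, "depths.tsv"))
  structure(list(ground_truth = truth, raw = raw,
                 depths = stats::setNames(as.integer(dep$depth),
                                          dep$sample_id),
                 structural_zero_mask = unclass(truth) == 0),
            class = "simulated_dataset")
}

#' Write an evaluation report as a directory of TSV tables + JSON summary
#'
#' One TSV per metric table, plus `summary.json` with the qualitative grid
#' and a `provenance.json` sufficient to re-run the job.
#'
#' @param report an `eval_report`.
#' @param dir destination directory.
#' @param provenance named list recorded alongside the tables.
#' @export
write_report <- function(report, dir, provenance = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    tab <- report[[nm]]
    if (is.null(tab)) next
    utils::write.table(tab, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(provenance, list(package = "zibench16S",
                                          r_version = R.version.string)),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an evaluation report directory back into tables
#' @param dir the report directory.
#' @return named list of data.frames.
#' @export
read_report <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tabs <- lapply(files, utils::read.delim, sep = "\t",
                 stringsAsFactors = FALSE)
  names(tabs) <- sub("\\.tsv$", "", basename(files))
  tabs
}

#' Read a benchmark configuration file
#'
#' YAML layout. Recognized keys: `preset` (builtin preset id) or
#' `simulation` (inline preset fields `n_features`, `n_conditions`,
#' `present_frac`, `variability`, `replicates`, `depth_range`,
#' `pool_scale`, `intensity_seed`), `normalizations`, `imputations`,
#' per-method parameter blocks (e.g. `drimpute: {ks: [2, 3]}`), `seed`
#' (required), `out_dir`, `alpha_level`, `nmds`. Unknown top-level keys
#' are errors.
#'
#' @param path path to the YAML config.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("preset", "simulation", "normalizations", "imputations",
               "seed", "out_dir", "alpha_level", "nmds", imp_ids())
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set `seed` (reproducibility)")
  cfg$normalizations <- cfg$normalizations %||% norm_ids()
  cfg$imputations <- cfg$imputations %||% imp_ids()
  bad <- setdiff(cfg$normalizations, norm_ids())
  if (length(bad) > 0) stop("unknown normalization id: ", bad[1])
  bad <- setdiff(cfg$imputations, imp_ids())
  if (length(bad) > 0) stop("unknown imputation id: ", bad[1])
  cfg$alpha_level <- cfg$alpha_level %||% 0.05
  cfg$nmds <- cfg$nmds %||% TRUE
  cfg
}

# Build the simulation preset a config describes.
config_preset <- function(cfg) {
  if (!is.null(cfg$preset)) {
    presets <- builtin_presets(seed = cfg$seed)
    if (!cfg$preset %in% names(presets))
      stop("unknown preset id: ", cfg$preset)
    return(presets[[cfg$preset]])
  }
  s <- cfg$simulation
  if (is.null(s)) stop("config needs `preset` or `simulation`")
  phi <- make_intensities(s$n_features, s$n_conditions,
                          present_frac = s$present_frac %||% 0.4,
                          sdlog = s$sdlog %||% 2,
                          seed = s$intensity_seed %||% 7L)
  vr <- s$variability %||% c(0.1, 0.5)
  set.seed((s$intensity_seed %||% 7L) + 1L)
  v <- stats::runif(s$n_features, vr[1], vr[length(vr)])
  simulation_preset(phi, v, replicates = s$replicates %||% 10L,
                    depth_range = unlist(s$depth_range %||% c(5000L, 20000L)),
                    pool_scale = s$pool_scale, seed = cfg$seed)
}

# Timestamped leveled logging to stderr.
zi_log <- function(..., level = "info") {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}
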