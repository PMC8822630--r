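#' Define a simulation preset
#'
#' A preset fully specifies one synthetic 16S experiment for the two-step
#' simulator: per-condition mean relative intensities (step 1, biological),
#' per-feature dispersions of the gamma replicate-variability model, the
#' number of biological replicates per condition, the range of sequencing
#' depths, and the size of the discretized community pool that the
#' sequencing step samples without replacement (step 2, technical).
#'
#' @param condition_intensities numeric matrix, features x conditions, of
#'   nonnegative mean intensities phi. A zero marks a species structurally
#'   absent from that condition.
#' @param variability numeric vector, one nonnegative value per feature: the
#'   squared coefficient of variation of the gamma draw across biological
#'   replicates.
#' @param replicates integer >= 2, biological replicates per condition.
#' @param depth_range integer length-2 vector (min, max) of reads per sample.
#' @param pool_scale integer size P of the discretized pool each sample's
#'   reads are drawn from without replacement; defaults to 10 x max depth.
#' @param seed integer master seed; every random draw in the simulation is
#'   derived from it.
#' @return an object of class `simulation_preset`.
#' @export
simulation_preset <- function(condition_intensities, variability, replicates,
                              depth_range, pool_scale = NULL, seed = 1L) {
  phi <- as.matrix(condition_intensities)
  if (any(phi < 0) || anyNA(phi)) stop("intensities must be nonnegative")
  if (any(colSums(phi) <= 0)) stop("every condition needs at least one phi > 0")
  variability <- as.numeric(variability)
  if (length(variability) == 1L) variability <- rep(variability, nrow(phi))
  if (length(variability) != nrow(phi))
    stop("`variability` must have one value per feature")
  if (any(variability < 0) || anyNA(variability))
    stop("variability must be nonnegative")
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("need at least 2 replicates per condition")
  depth_range <- as.integer(depth_range)
  if (length(depth_range) != 2L || any(depth_range <= 0L) ||
      depth_range[1] > depth_range[2])
    stop("`depth_range` must be positive (min, max)")
  if (is.null(pool_scale)) pool_scale <- 10L * depth_range[2]
  pool_scale <- as.integer(pool_scale)
  if (pool_scale < depth_range[2])
    stop("pool_scale must be >= the maximum depth")
  if (is.null(rownames(phi))) rownames(phi) <- sprintf("F%04d", seq_len(nrow(phi)))
  if (is.null(colnames(phi))) colnames(phi) <- sprintf("G%02d", seq_len(ncol(phi)))
  structure(list(condition_intensities = phi, variability = variability,
                 replicates = replicates, depth_range = depth_range,
                 pool_scale = pool_scale, seed = as.integer(seed)),
            class = "simulation_preset")
}

#' @method print simulation_preset
#' @export
print.simulation_preset <- function(x, ...) {
  phi <- x$condition_intensities
  cat(sprintf(paste0("simulation_preset: %d features, %d conditions x %d",
                     " replicates, depths %d-%d, pool %d, seed %d\n"),
              nrow(phi), ncol(phi), x$replicates, x$depth_range[1],
              x$depth_range[2], x$pool_scale, x$seed))
  invisible(x)
}

# Sample ids and group labels implied by a preset; condition-major order.
preset_samples <- function(preset) {
  conds <- colnames(preset$condition_intensities)
  grp <- rep(conds, each = preset$replicates)
  ids <- paste0(grp, "_r", sprintf("%02d", rep(seq_len(preset$replicates),
                                               times = length(conds))))
  list(ids = ids, groups = grp)
}

#' Step 1: gamma-distributed biological replicate abundances
#'
#' Draws, for every condition and replicate, per-feature abundances from a
#' gamma law with mean `phi_i` and squared coefficient of variation `v_i`
#' (shape `1/v_i`, scale `phi_i * v_i`). Features with `phi_i = 0` are
#' structural zeros and come out exactly 0. A feature with positive mean but
#' nonpositive dispersion is floored at `v = 1e-6` rather than rejected.
#'
#' @param preset a [simulation_preset()].
#' @param seed integer; per-sample substreams use `seed + sample index` so
#'   that column `j` is reproducible in isolation. Defaults to the preset's
#'   seed.
#' @return feature x sample numeric matrix of nonnegative abundances, in
#'   condition-major sample order.
#' @export
gamma_abundances <- function(preset, seed = preset$seed) {
  phi <- preset$condition_intensities
  v <- preset$variability
  v[v <= 0] <- 1e-6
  smp <- preset_samples(preset)
  out <- matrix(0, nrow(phi), length(smp$ids),
                dimnames = list(rownames(phi), smp$ids))
  for (j in seq_along(smp$ids)) {
    mu <- phi[, smp$groups[j]]
    pos <- mu > 0
    set.seed(seed + j)
    out[pos, j] <- stats::rgamma(sum(pos), shape = 1 / v[pos],
                                 scale = mu[pos] * v[pos])
  }
  out
}

#' Step 2 primitive: one multivariate hypergeometric draw
#'
#' Samples `depth` reads without replacement from a finite pool of
#' discretized community members, by exact sequential univariate
#' hypergeometric conditioning (category i is drawn against the pooled
#' remainder, then removed). The draw sums exactly to `depth`, never exceeds
#' the pool in any category, and is zero wherever the pool is zero.
#'
#' @param pool_counts nonnegative integer vector, the per-feature pool.
#' @param depth integer number of reads; must not exceed `sum(pool_counts)`.
#' @param seed optional integer; if given, `set.seed(seed)` is applied first.
#' @return integer vector, same length as `pool_counts`.
#' @export
mhg_draw <- function(pool_counts, depth, seed = NULL) {
  pool <- as.numeric(pool_counts)
  if (any(pool < 0) || any(pool != floor(pool)))
    stop("pool counts must be nonnegative integers")
  depth <- as.numeric(depth)
  total <- sum(pool)
  if (depth > total)
    stop(sprintf("depth %d exceeds pool total %d: inconsistent preset",
                 depth, total))
  if (!is.null(seed)) set.seed(seed)
  m <- length(pool)
  out <- numeric(m)
  remaining <- depth
  rest <- total
  for (i in seq_len(m)) {
    if (remaining == 0) break
    rest <- rest - pool[i]
    if (i == m) {
      out[i] <- remaining  # forced: only this category is left
      break
    }
    x <- stats::rhyper(1, pool[i], rest, remaining)
    out[i] <- x
    remaining <- remaining - x
  }
  as.integer(out)
}

# Discretize a nonnegative vector into an integer pool summing exactly to P,
# proportional to x, by the largest-remainder rule. Zeros stay zero.
discretize_pool <- function(x, P) {
  ideal <- x * P / sum(x)
  base <- floor(ideal)
  rem <- ideal - base
  deficit <- P - sum(base)
  if (deficit > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    base[take] <- base[take] + 1
  }
  base
}

#' Simulate a paired ground-truth / raw 16S dataset
#'
#' Runs the two-step model: step 1 draws pre-sequencing abundances per
#' biological replicate ([gamma_abundances()]); step 2 discretizes each
#' sample's abundance vector into an integer pool of total `pool_scale` and
#' draws that sample's sequencing depth without replacement from it
#' ([mhg_draw()]). Depths are drawn uniformly on the preset's depth range.
#' The run is fully determined by the preset's seed.
#'
#' @param preset a [simulation_preset()].
#' @return an object of class `simulated_dataset`: a list with elements
#'   `ground_truth` and `raw` (tagged [count_matrix()] layers), `depths`
#'   (named integer vector of per-sample read totals) and
#'   `structural_zero_mask` (logical matrix, `TRUE` where the ground truth
#'   is exactly zero).
#' @export
simulate_dataset <- function(preset) {
  abund <- gamma_abundances(preset)
  if (any(colSums(abund) <= 0))
    stop("a simulated sample has an all-zero abundance vector")
  smp <- preset_samples(preset)
  set.seed(preset$seed)
  depth_grid <- seq.int(preset$depth_range[1], preset$depth_range[2])
  depths <- depth_grid[sample.int(length(depth_grid), ncol(abund),
                                  replace = TRUE)]
  names(depths) <- smp$ids
  raw <- matrix(0L, nrow(abund), ncol(abund), dimnames = dimnames(abund))
  for (j in seq_len(ncol(abund))) {
    pool <- discretize_pool(abund[, j], preset$pool_scale)
    raw[, j] <- mhg_draw(pool, depths[j], seed = preset$seed + 500009L + j)
  }
  structure(list(
    ground_truth = count_matrix(abund, layer = "ground_truth",
                                groups = smp$groups),
    raw = count_matrix(raw, layer = "raw", groups = smp$groups),
    depths = depths,
    structural_zero_mask = abund == 0
  ), class = "simulated_dataset")
}

#' @method print simulated_dataset
#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(paste0("simulated_dataset: %d features x %d samples | truth",
                     " sparsity %.2f%%, raw sparsity %.2f%%\n"),
              nrow(x$raw), ncol(x$raw), 100 * mean(x$ground_truth == 0),
              100 * mean(x$raw == 0)))
  invisible(x)
}

# Deterministic construction of a condition-intensity matrix with a target
# structural-zero fraction. Feature base intensities follow a heavy-tailed
# log-normal (many rare species, few dominant ones); per-feature occupancy is
# beta-distributed so that some species are core (present in all conditions)
# and others condition-specific; per-condition log-normal fold effects create
# group differences for the diversity and differential-abundance analyses.
make_intensities <- function(n_features, n_conditions, present_frac,
                             sdlog = 2, occupancy_conc = 1.2, seed = 7L) {
  set.seed(seed)
  base <- stats::rlnorm(n_features, meanlog = 0, sdlog = sdlog)
  occ <- stats::rbeta(n_features, occupancy_conc * present_frac,
                      occupancy_conc * (1 - present_frac))
  phi <- matrix(0, n_features, n_conditions)
  for (cc in seq_len(n_conditions)) {
    present <- stats::runif(n_features) < occ
    if (!any(present)) present[which.max(occ)] <- TRUE
    fc <- stats::rlnorm(n_features, 0, 0.6)
    phi[present, cc] <- base[present] * fc[present]
  }
  rownames(phi) <- sprintf("F%04d", seq_len(n_features))
  colnames(phi) <- sprintf("G%02d", seq_len(n_conditions))
  phi
}

#' Reduced benchmark scenario: moderate sparsity, low variability
#'
#' A small fixed-design preset used for recovery experiments: 4 conditions
#' x 5 replicates x 300 features, exactly 40% structural zeros per
#' condition, heavy-tailed log-normal intensities, gamma dispersions
#' uniform on (0.1, 0.4), depths 5,000-20,000 and the default pool of 10 x
#' the maximum depth.
#'
#' @param seed integer seed for the simulation draws (the design itself is
#'   fixed).
#' @return a [simulation_preset()].
#' @export
scenario_moderate_preset <- function(seed = 1L) {
  n_feat <- 300L; n_cond <- 4L
  set.seed(9001L)
  base <- stats::rlnorm(n_feat, 0, 2)
  phi <- matrix(0, n_feat, n_cond,
                dimnames = list(sprintf("F%04d", seq_len(n_feat)),
                                sprintf("G%02d", seq_len(n_cond))))
  n_absent <- round(0.40 * n_feat)
  for (cc in seq_len(n_cond)) {
    absent <- sample(n_feat, n_absent)
    fc <- stats::rlnorm(n_feat, 0, 0.6)
    phi[, cc] <- base * fc
    phi[absent, cc] <- 0
  }
  v <- stats::runif(n_feat, 0.1, 0.4)
  simulation_preset(phi, v, replicates = 5L, depth_range = c(5000L, 20000L),
                    seed = seed)
}

#' Built-in reduced-scale presets
#'
#' Three presets mirroring the contrasts of the full-scale study scenarios,
#' at desk scale: (1) moderate sparsity and low biological variability
#' (animal-gut-like; raw sparsity targeted at the 60-80% band), (2) low
#' sparsity but high between-replicate variability (human-microbiome-like),
#' and (3) high sparsity with high sequencing depth (food-microbiota-like;
#' raw sparsity targeted at the 88-96% band; little technical loss, so
#' unnecessary imputation can only hurt). All use 10 biological replicates
#' per condition.
#'
#' @param seed integer master seed passed to each preset (the intensity
#'   structure itself is fixed; the seed governs the simulation draws).
#' @return named list of three [simulation_preset()] objects.
#' @export
builtin_presets <- function(seed = 1L) {
  vfix <- function(n, lo, hi, s) { set.seed(s); stats::runif(n, lo, hi) }
  list(
    preset1 = simulation_preset(
      make_intensities(332, 14, present_frac = 0.34, sdlog = 2.2, seed = 101L),
      variability = vfix(332, 0.05, 0.30, 111L),
      replicates = 10, depth_range = c(1500L, 10000L), seed = seed),
    preset2 = simulation_preset(
      make_intensities(252, 8, present_frac = 0.40, sdlog = 1.8, seed = 202L),
      variability = vfix(252, 0.5, 2.0, 222L),
      replicates = 10, depth_range = c(1000L, 12000L), seed = seed),
    preset3 = simulation_preset(
      make_intensities(380, 12, present_frac = 0.085, sdlog = 3.0, seed = 303L),
      variability = vfix(380, 0.2, 0.8, 333L),
      replicates = 10, depth_range = c(5000L, 40000L), seed = seed)
  )
}
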