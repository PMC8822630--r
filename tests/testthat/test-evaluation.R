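test_that("total sparsity counts zero entries as a percentage", {
  expect_equal(total_sparsity(matrix(c(0, 1, 2, 3), 2)), 25)
  expect_equal(total_sparsity(matrix(0, 3, 3)), 100)
  expect_error(total_sparsity(matrix(numeric(0), 0, 0)), "empty")
})

test_that("zero classification hits the three anchor points", {
  ds <- get_scenario_dataset()
  truth <- unclass(ds$ground_truth); raw <- unclass(ds$raw)
  # identity pipeline: nothing recovered, nothing falsely imputed
  id <- zero_confusion(truth, raw, raw)
  expect_equal(id$sensitivity, 0)
  expect_equal(id$specificity, 100)
  # impute-everything
  all_pos <- raw; all_pos[all_pos == 0] <- 1
  ae <- zero_confusion(truth, raw, all_pos)
  expect_equal(ae$sensitivity, 100)
  expect_equal(ae$specificity, 0)
  # oracle imputer
  oracle <- raw; oracle[raw == 0 & truth > 0] <- 1
  or <- zero_confusion(truth, raw, oracle)
  expect_equal(or$sensitivity, 100)
  expect_equal(or$specificity, 100)
  expect_equal(or$TP + or$FP + or$FN + or$TN, sum(raw == 0))
})

test_that("SMAPE follows the hand evaluation and its 0/0 convention", {
  expect_equal(smape_per_sample(c(1, 3), c(3, 1)), 50)
  expect_equal(smape_per_sample(c(0, 0), c(0, 0)), 0)
  expect_equal(smape_per_sample(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(2)
  for (i in 1:10) {
    x <- rpois(30, 5); y <- rpois(30, 5)
    expect_equal(smape_per_sample(x, y), smape_per_sample(y, x))
    expect_lte(smape_per_sample(x, y), 100)
  }
})

test_that("Aitchison distance: hand value, scale invariance, clr identity", {
  expect_equal(aitchison_per_sample(c(1, exp(1)), c(1, 1)), sqrt(0.5),
               tolerance = 1e-10)
  expect_equal(aitchison_per_sample(c(1, exp(1)), c(1, 1)), 0.70711,
               tolerance = 1e-5)
  set.seed(3)
  for (m in c(5, 50, 200)) {
    x <- rlnorm(m); y <- rlnorm(m)
    expect_equal(aitchison_per_sample(x, y), aitchison_double_loop(x, y),
                 tolerance = 1e-8)
    expect_equal(aitchison_per_sample(7.3 * x, y), aitchison_per_sample(x, y),
                 tolerance = 1e-10)
    expect_equal(aitchison_per_sample(x, x), 0, tolerance = 1e-12)
  }
  # metric axioms on random triples
  set.seed(4)
  for (i in 1:10) {
    x <- rlnorm(20); y <- rlnorm(20); z <- rlnorm(20)
    dxy <- aitchison_per_sample(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, aitchison_per_sample(y, x), tolerance = 1e-12)
    expect_lte(dxy, aitchison_per_sample(x, z) + aitchison_per_sample(z, y) + 1e-12)
  }
})

test_that("alpha indices reproduce the hand Shannon/Pielou values", {
  m <- cbind(s1 = c(0.5, 0.25, 0.25), s2 = c(1/3, 1/3, 1/3), s3 = c(1, 0, 0))
  rownames(m) <- paste0("f", 1:3)
  a <- alpha_indices(m)
  expect_equal(a$richness, c(3L, 3L, 1L))
  expect_equal(a$shannon[1], 1.03972, tolerance = 1e-5)
  expect_equal(a$pielou[1], 0.94640, tolerance = 1e-5)
  expect_equal(a$pielou[2], 1)
  expect_true(is.na(a$pielou[3]))
})

test_that("Whittaker and Bray-Curtis matrices match hand counts", {
  m <- cbind(a = c(1, 1, 1, 0), b = c(1, 0, 0, 0))
  expect_equal(whittaker_matrix(m)["a", "b"], 3 / 2)
  same <- cbind(x = c(1, 1, 0), y = c(2, 5, 0))
  expect_equal(whittaker_matrix(same)["x", "y"], 1)
  disj <- cbind(x = c(1, 1, 0, 0), y = c(0, 0, 2, 2))
  expect_equal(whittaker_matrix(disj)["x", "y"], 2)

  bc <- bray_curtis_matrix(cbind(x = c(2, 2, 0), y = c(0, 2, 2)))
  expect_equal(bc["x", "y"], 0.5)
  expect_equal(bray_curtis_matrix(cbind(x = c(1, 2), y = c(1, 2)))["x", "y"], 0)
  expect_equal(bray_curtis_matrix(disj)["x", "y"], 1)
})

test_that("NMDS recovers embeddable configurations with near-zero stress", {
  three <- matrix(1, 3, 3) - diag(3)
  dimnames(three) <- list(letters[1:3], letters[1:3])
  fit <- nmds_embed(three, seed = 1)
  expect_lt(fit$stress, 1e-3)
  d12 <- dist(fit$points)
  expect_lt(sd(d12) / mean(d12), 0.01)   # equilateral

  set.seed(7)
  pts <- matrix(rnorm(20), 10, 2)
  fit2 <- nmds_embed(as.matrix(dist(pts)), seed = 2)
  expect_lt(fit2$stress, 0.01)
})

test_that("differential abundance calls separate exactly the separated feature", {
  set.seed(11)
  n <- 10
  m <- matrix(rep(rpois(20, 50) + 10, 2 * n), 20, 2 * n)
  dimnames(m) <- list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:(2 * n)))
  groups <- rep(c("A", "B"), each = n)
  expect_length(da_features(m, groups), 0)         # identical sample-for-sample

  m2 <- m
  m2[7, groups == "A"] <- 100 + seq_len(n)         # complete separation
  m2[7, groups == "B"] <- 1 + seq_len(n)
  expect_identical(as.character(da_features(m2, groups)), "f07")
  expect_length(da_features(m2, groups, alpha_level = 0), 0)
})

test_that("differential abundance is calibrated under the null", {
  set.seed(13)
  n_feat <- 500
  lam <- rlnorm(n_feat, 3, 1)
  m <- sapply(1:20, function(j) rpois(n_feat, lam))
  dimnames(m) <- list(sprintf("f%03d", 1:n_feat), sprintf("s%02d", 1:20))
  groups <- rep(c("A", "B"), each = 10)
  hits <- da_features(m, groups)
  tested <- sum(rowSums(m) > 0)
  se <- sqrt(0.05 * 0.95 / tested)
  expect_lte(length(hits) / tested, 0.05 + 3 * se)
})

test_that("BH adjustment and Jaccard follow their definitions", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(benjamini_hochberg(0.7), 0.7)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard("x", "y"), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "a")), 1)
})

test_that("Cohen's d magnitudes map onto the conventional cut-offs", {
  expect_equal(cohens_d_magnitude(c(1, 2, 3), c(1, 2, 3)),
               list(d = 0, magnitude = "Negligible"))
  shifted <- function(d) cohens_d_magnitude(c(-1, 0, 1) + d, c(-1, 0, 1))
  expect_equal(shifted(0.5)$magnitude, "Medium")   # pooled sd = 1 exactly
  expect_equal(shifted(0.15)$magnitude, "Very small")
  expect_equal(shifted(0.9)$magnitude, "Large")
  expect_equal(shifted(2.0)$magnitude, "Huge")
  expect_equal(cohens_d_magnitude(c(10, 11, 12), c(0, 1, 2))$magnitude, "Huge")
})

test_that("alpha error tests flag constructed improvements", {
  ds <- get_scenario_dataset()
  truth <- ds$ground_truth; raw <- ds$raw
  perfect <- count_matrix(unclass(truth), layer = "processed",
                          groups = cm_groups(raw))
  at <- alpha_error_test(truth, raw, perfect, "richness")
  expect_true(all(at$rel_err_processed == 0))
  expect_lt(at$p, 0.05)

  same <- alpha_error_test(truth, raw, raw, "richness")
  expect_identical(same$rel_err_processed, same$rel_err_raw)
  expect_equal(same$p, 1)
})

test_that("group comparisons label direction of richness shifts", {
  set.seed(19)
  rich <- matrix(rpois(40 * 10, 30) + 1, 40, 10)
  poor <- rbind(matrix(rpois(10 * 10, 30) + 1, 10, 10), matrix(0, 30, 10))
  m <- cbind(rich, poor)
  dimnames(m) <- list(sprintf("f%02d", 1:40), sprintf("s%02d", 1:20))
  groups <- rep(c("hi", "lo"), each = 10)
  tab <- alpha_group_comparisons(m, groups)
  r <- tab[tab$index == "richness", ]
  expect_equal(r$label, "up")   # hi listed first in the pair
  mm <- cbind(rich, rich)
  dimnames(mm) <- dimnames(m)
  tab2 <- alpha_group_comparisons(mm, groups)
  expect_true(all(tab2$label == "ns"))
})

test_that("evaluate_all hits its fixed points and round-trips as a report", {
  ds <- get_scenario_dataset()
  truth <- ds$ground_truth; raw <- ds$raw
  perfect <- count_matrix(unclass(truth), layer = "processed",
                          groups = cm_groups(raw))
  rep <- evaluate_all(truth, raw,
                      list(perfect = perfect, identity = raw),
                      nmds = FALSE)
  zc <- rep$zero_classification
  expect_equal(zc$sensitivity[zc$pipeline == "perfect"], 100)
  expect_equal(zc$specificity[zc$pipeline == "perfect"], 100)
  expect_equal(zc$sensitivity[zc$pipeline == "identity"], 0)
  expect_equal(zc$specificity[zc$pipeline == "identity"], 100)

  ae <- rep$abundance_error
  expect_true(all(ae$smape[ae$pipeline == "perfect"] == 0))
  expect_true(all(ae$aitchison[ae$pipeline == "perfect"] < 1e-10))
  expect_equal(ae$smape[ae$pipeline == "identity"],
               ae$smape[ae$pipeline == "raw"])
  expect_true(all(rep$da$jaccard[rep$da$pipeline == "perfect"] == 1))

  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_report(dir)
  expect_equal(back$sparsity$sparsity, rep$sparsity$sparsity, tolerance = 1e-6)
  expect_identical(nrow(back$summary), nrow(rep$summary))
})
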