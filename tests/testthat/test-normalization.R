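test_that("tss yields per-sample proportions and is idempotent", {
  m <- cbind(a = c(2, 3, 5), b = c(0, 7, 0))
  rownames(m) <- paste0("f", 1:3)
  p <- tss(m)
  expect_equal(unname(unclass(p)[, "a"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(unclass(p)[, "b"]), c(0, 1, 0))
  expect_equal(unclass(tss(p)), unclass(p))
  expect_identical(cm_layer(p), "processed")
  m0 <- m; m0[, 2] <- 0
  expect_error(tss(m0), "b")
})

test_that("cpm columns sum to 1e6 and preserve zeros", {
  m <- toy_counts(12, 4, seed = 2)
  x <- cpm(m)
  expect_equal(unname(colSums(x)), rep(1e6, 4))
  expect_identical(unclass(x) == 0, m == 0)
  expect_equal(unname(unclass(cpm(cbind(c(2, 3, 5))))[, 1]), c(2e5, 3e5, 5e5))
})

test_that("css matches the exhaustive l-scan oracle on a toy matrix", {
  m <- toy_counts(5, 4, seed = 31, zero_frac = 0.15)
  got <- css(m)
  ora <- css_oracle(m)
  expect_identical(got$stats$l_hat, as.integer(ora$l_hat))
  expect_equal(unname(got$stats$s), ora$s)
  expect_equal(unclass(got$normalized), ora$normalized, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("css treats identical and duplicated samples coherently", {
  col <- c(3, 8, 0, 21, 5)
  m <- matrix(col, 5, 4)
  dimnames(m) <- list(paste0("f", 1:5), paste0("s", 1:4))
  got <- css(m)
  s <- got$stats$s
  expect_true(all(s == s[1]))
  # identical columns stay identical
  expect_equal(unclass(got$normalized)[, 1], unclass(got$normalized)[, 3],
               ignore_attr = TRUE)

  m2 <- toy_counts(8, 3, seed = 7)
  m2 <- cbind(m2, dup = m2[, 2])
  got2 <- css(m2)
  expect_equal(unname(unclass(got2$normalized)[, 2]),
               unname(unclass(got2$normalized)[, "dup"]))
})

test_that("tmm factors are 1 for identical or proportional samples", {
  m <- toy_counts(20, 2, seed = 5, zero_frac = 0)
  m[, 2] <- m[, 1]
  expect_equal(as.numeric(tmm_factors(m)$factors), c(1, 1))
  m[, 2] <- 2 * m[, 1]
  expect_equal(as.numeric(tmm_factors(m)$factors), c(1, 1))
})

test_that("tmm matches the brute-force trim-then-weighted-mean oracle", {
  set.seed(17)
  m <- matrix(rpois(20 * 2, 60) + 1, 20, 2)
  m[sample(40, 5)] <- 0
  dimnames(m) <- list(sprintf("f%02d", 1:20), c("s1", "s2"))
  got <- tmm_factors(m)
  ora <- tmm_oracle(m, ref = got$stats$reference)
  expect_equal(as.numeric(got$factors), ora, tolerance = 1e-10)

  # and on a wider matrix
  m5 <- toy_counts(20, 5, seed = 23, zero_frac = 0.2)
  got5 <- suppressWarnings(tmm_factors(m5))
  expect_equal(as.numeric(got5$factors), tmm_oracle(m5, got5$stats$reference),
               tolerance = 1e-10)

  # large enough that every sample clears the retention threshold
  set.seed(19)
  m60 <- matrix(rpois(60 * 5, 80) + 1, 60, 5)
  m60[sample(300, 30)] <- 0
  dimnames(m60) <- list(sprintf("f%02d", 1:60), paste0("s", 1:5))
  got60 <- tmm_factors(m60)
  expect_false(all(as.numeric(got60$factors) == 1))
  expect_equal(as.numeric(got60$factors),
               tmm_oracle(m60, got60$stats$reference), tolerance = 1e-10)
})

test_that("median-of-ratios factors match hand and brute-force evaluation", {
  m <- toy_counts(8, 3, seed = 3, zero_frac = 0)
  expect_equal(as.numeric(deseq_factors(cbind(m[, 1], m[, 1], m[, 1]))), rep(1, 3))
  two <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(as.numeric(deseq_factors(two)), c(1 / sqrt(2), sqrt(2)))
  m2 <- toy_counts(12, 3, seed = 13, zero_frac = 0.25)
  expect_equal(as.numeric(deseq_factors(m2)), deseq_oracle(m2), tolerance = 1e-10)
  all_zero_rows <- rbind(c(1, 0, 2), c(0, 1, 1))
  expect_error(deseq_factors(all_zero_rows), "pseudo-reference")
})

test_that("gmpr handles proportional samples and matches its oracle", {
  m <- toy_counts(10, 3, seed = 41, zero_frac = 0)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(as.numeric(gmpr_factors(same)$factors), rep(1, 3))

  twoc <- cbind(A = m[, 1], B = 3 * m[, 1])
  st <- gmpr_factors(twoc)$stats
  expect_equal(st$r["A", "B"], 1 / 3)
  expect_equal(st$r["B", "A"], 3)

  m3 <- toy_counts(10, 3, seed = 43, zero_frac = 0.3)
  expect_equal(as.numeric(gmpr_factors(m3)$factors), gmpr_oracle(m3),
               tolerance = 1e-10)
})

test_that("apply_factors scales, inverts and rejects bad factors", {
  m <- toy_counts(6, 3, seed = 9)
  expect_equal(unclass(apply_factors(m, c(1, 1, 1))), unclass(m),
               ignore_attr = TRUE)
  half <- apply_factors(m, c(2, 1, 1))
  expect_equal(unclass(half)[, 1], m[, 1] / 2)
  back <- apply_factors(half, c(1 / 2, 1, 1))
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  expect_error(apply_factors(m, c(0, 1, 1)), "positive")
})

test_that("size-factor methods are scale-equivariant in a sample", {
  m <- toy_counts(15, 4, seed = 51, zero_frac = 0.2)
  f <- 2.5
  m2 <- m; m2[, 3] <- f * m[, 3]
  d1 <- deseq_factors(m); d2 <- deseq_factors(m2)
  rd <- as.numeric(d2 / d1)   # up to the pseudo-reference's global rescaling
  expect_equal(rd / rd[1], c(1, 1, f, 1), tolerance = 1e-10)
  # GMPR: exact equivariance lives at the pairwise-ratio level; the scaled
  # sample's partners each pick up f^(-1/(n-1)), so the factor ratio is
  # f^(n/(n-1)) after the global rescale
  s1 <- gmpr_factors(m)$stats; s2 <- gmpr_factors(m2)$stats
  expect_equal(s2$r[3, -3], f * s1$r[3, -3], tolerance = 1e-10)
  expect_equal(s2$r[-3, 3], s1$r[-3, 3] / f, tolerance = 1e-10)
  g1 <- gmpr_factors(m)$factors; g2 <- gmpr_factors(m2)$factors
  r <- as.numeric(g2 / g1)
  expect_equal(r / r[1], c(1, 1, f^(4 / 3), 1), tolerance = 1e-10)
})

test_that("no normalization creates or destroys zeros", {
  m <- count_matrix(toy_counts(18, 5, seed = 61, zero_frac = 0.3))
  for (id in norm_ids()) {
    out <- normalize_counts(m, id)
    expect_identical(unclass(out) == 0, unclass(m) == 0, label = id)
  }
})

test_that("permuting samples permutes normalization outputs identically", {
  m <- count_matrix(toy_counts(15, 5, seed = 71, zero_frac = 0.2))
  perm <- c(3, 1, 5, 2, 4)
  mp <- count_matrix(unclass(m)[, perm])
  for (id in c("tss", "deseq", "gmpr")) {
    out <- unclass(normalize_counts(m, id))
    outp <- unclass(normalize_counts(mp, id))
    expect_equal(outp, out[, perm], tolerance = 1e-12, label = id,
                 ignore_attr = TRUE)
  }
})

test_that("deseq factors agree with the Bioconductor median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  m <- toy_counts(15, 5, seed = 81, zero_frac = 0.15)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(as.numeric(deseq_factors(m)), unname(ref), tolerance = 1e-8)
})
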