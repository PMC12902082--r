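toy_study <- function(counts, n = ncol(counts)) {
  design <- expression_design(max(2, ceiling(n / 6)))[seq_len(n), ]
  colnames(counts) <- design$sample
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  expression_study(counts, design)
}

test_that("low-count filter keeps genes exceeding 10 in two samples", {
  m <- rbind(g1 = c(11, 11, 0, 0, 0, 0),
             g2 = c(11, 10, 10, 10, 10, 10),
             g3 = rep(0, 6),
             g4 = rep(100, 6))
  st <- filter_low_counts(toy_study(m))
  expect_equal(rownames(st$counts), c("g1", "g4"))
})

test_that("size factors follow the median-of-ratios definition", {
  # identical columns give unit factors
  m <- matrix(rep(c(10, 20, 30), 4), ncol = 4,
              dimnames = list(paste0("g", 1:3), NULL))
  st <- size_factors(toy_study(m))
  expect_equal(unname(st$size_factors), rep(1, 4), tolerance = 1e-12)

  # a doubled library: factors proportional to (1, 2)
  design2 <- expression_design(2)[1:2, ]
  m2 <- cbind(c(10, 20, 30), c(20, 40, 60))
  dimnames(m2) <- list(paste0("g", 1:3), design2$sample)
  st2 <- size_factors(expression_study(m2, design2))
  f <- st2$size_factors
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-8)

  # random NB fixture equals the brute-force oracle
  set.seed(31)
  m3 <- matrix(rnbinom(50 * 6, mu = 100, size = 5), ncol = 6,
               dimnames = list(sprintf("g%02d", 1:50), NULL))
  st3 <- size_factors(toy_study(m3))
  expect_equal(unname(st3$size_factors), unname(oracle_size_factors(
    st3$counts)), tolerance = 1e-12)

  # scaling one library by c multiplies its factor relative to every
  # other sample's by exactly c
  m4 <- m3; m4[, 3] <- m4[, 3] * 5L
  st4 <- size_factors(toy_study(m4))
  r3 <- st3$size_factors; r4 <- st4$size_factors
  expect_equal(unname(r4[3] / r4[1]), unname(5 * r3[3] / r3[1]),
               tolerance = 1e-12)
  # and leaves every normalized count ratio unchanged
  n3 <- sweep(st3$counts, 2, st3$size_factors, "/")
  n4 <- sweep(st4$counts, 2, st4$size_factors, "/")
  expect_equal(n4 / n4[, 1], n3 / n3[, 1], tolerance = 1e-12)

  # no all-positive gene: error, pseudo-reference fallback works
  m5 <- rbind(g1 = c(0, 5, 5, 5, 5, 5), g2 = c(5, 0, 5, 5, 5, 5))
  expect_error(size_factors(toy_study(m5)), "pseudo_reference")
  st5 <- size_factors(toy_study(m5), pseudo_reference = TRUE)
  expect_true(all(st5$size_factors > 0))
})

test_that("covariance PCA has the expected algebraic properties", {
  set.seed(7)
  m <- matrix(rnbinom(200 * 6, mu = 200, size = 10), ncol = 6)
  st <- size_factors(toy_study(m))
  # duplicate a sample exactly
  st$counts[, 2] <- st$counts[, 1]
  st$size_factors <- NULL
  pc <- pca_expression(st)
  expect_equal(pc$scores[1, ], pc$scores[2, ], tolerance = 1e-9)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-10)
  # full reconstruction of the centered matrix
  rec <- pc$scores %*% t(pc$rotation)
  expect_equal(unname(rec), unname(pc$centered), tolerance = 1e-8)
  # leading eigenvalue fraction matches a direct eigen decomposition of
  # the sample-space covariance of the same transformed matrix
  lm2 <- log2(sweep(st$counts, 2, size_factors(st)$size_factors, "/") + 1)
  x <- t(lm2 - rowMeans(lm2))
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(pc$var_explained[1], ev[1] / sum(ev), tolerance = 1e-8)
  expect_error(pca_expression(toy_study(m[, 1, drop = FALSE], n = 1)),
               "2 samples")
})

test_that("duration LRT behaves on degenerate and strong-signal genes", {
  design <- expression_design(5)
  set.seed(11)
  truth <- simulate_expr_truth(n_genes = 60, frac_increasing = 0.2,
                               frac_decreasing = 0, frac_low = 0,
                               slope_range = c(2, 2), seed = 11)
  counts <- simulate_expression_counts(design, truth, seed = 12)
  counts["gene0001", ] <- 50L       # constant gene, identical counts
  study <- expression_study(counts, design)
  # equal library sizes: unit normalization, so the constant gene is an
  # exact null case
  study$size_factors <- stats::setNames(rep(1, ncol(counts)),
                                        colnames(counts))
  res <- lrt_duration(study)
  expect_true(all(res$stat >= 0, na.rm = TRUE))
  cst <- res[res$gene == "gene0001", ]
  expect_lt(cst$stat, 1e-6)
  expect_gt(cst$p, 0.99)
  # strong slope (4-fold per decade): overwhelming evidence at n = 30
  strong <- merge(res, truth, by = "gene")
  strong <- strong[strong$pattern == "increasing" &
                     strong$gene != "gene0001", ]
  expect_true(all(strong$p < 1e-4))
  # slope estimate sign follows the truth
  expect_true(all(strong$slope > 0))
  # adjusted p-values are monotone and match the brute-force BH oracle
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
  expect_equal(res$padj, oracle_bh(res$p), tolerance = 1e-12)
  # fewer than 3 distinct durations is an error
  d2 <- design[design$cohort == "parentA", ]
  st2 <- expression_study(counts[, d2$sample], d2)
  expect_error(lrt_duration(st2), "distinct")
})

test_that("BH adjustment matches the oracle on random p-vectors", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("pattern clustering recovers monotone templates", {
  design <- expression_design(5)
  truth <- simulate_expr_truth(n_genes = 40, frac_increasing = 0.5,
                               frac_decreasing = 0.5, frac_low = 0,
                               slope_range = c(2, 3), seed = 13)
  counts <- simulate_expression_counts(design, truth, seed = 14)
  study <- size_factors(expression_study(counts, design))
  cl <- cluster_patterns(study, truth$gene, k = 2)
  m <- merge(cl, truth, by = "gene")
  expect_true(all(m$direction[m$pattern == "increasing"] == "increasing"))
  expect_true(all(m$direction[m$pattern == "decreasing"] == "decreasing"))

  # a flat gene (constant profile) gets the non-monotone label
  flat <- truth$gene[1]
  inc <- setdiff(truth$gene[truth$pattern == "increasing"], flat)[1]
  dec <- setdiff(truth$gene[truth$pattern == "decreasing"], flat)[1]
  counts2 <- counts
  counts2[1, ] <- 100L
  study2 <- expression_study(counts2, design)
  # unit normalization keeps the flat gene's profile exactly constant
  study2$size_factors <- stats::setNames(rep(1, ncol(counts2)),
                                         colnames(counts2))
  cl2 <- cluster_patterns(study2, c(inc, dec, flat), k = 3)
  expect_equal(cl2$direction[cl2$gene == flat], "non-monotone")
  expect_equal(cl2$direction[cl2$gene == inc], "increasing")
  expect_equal(cl2$direction[cl2$gene == dec], "decreasing")

  # permuting gene order leaves the grouping invariant
  perm <- sample(truth$gene)
  clp <- cluster_patterns(study, perm, k = 2)
  expect_equal(clp$gene, cl$gene)
  expect_equal(clp$direction, cl$direction)

  expect_error(cluster_patterns(study, truth$gene[1:3], k = 5), "exceeds")
})
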