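# One crafted VCF exercising each fixed-difference filter.
filter_fixture <- function() {
  sheet <- toy_sheet()
  hybcols <- c(HJ1 = "0/1:20,20", HJ2 = "0/1:15,25",
               HA1 = "0/1:18,22", HA2 = "0/1:30,10")
  mk <- function(pos, qual, pa1, pa2, pb1, pb2) {
    r <- data.frame(chrom = "c1", pos = pos, ref = "A", alt = "G",
                    qual = qual, stringsAsFactors = FALSE)
    r$PA1 <- pa1; r$PA2 <- pa2; r$PB1 <- pb1; r$PB2 <- pb2
    for (s in names(hybcols)) r[[s]] <- hybcols[[s]]
    r
  }
  rec <- rbind(
    mk(10L, "90",    "0/0:30,0", "0/0:30,0", "1/1:0,30", "1/1:0,30"),
    mk(20L, "69.5",  "0/0:30,0", "0/0:30,0", "1/1:0,30", "1/1:0,30"),
    mk(30L, "90",    "0/0:30,0", "0/1:15,15", "1/1:0,30", "1/1:0,30"),
    mk(40L, "90",    "0/0:30,0", "0/0:30,0", "0/0:30,0", "0/0:30,0"),
    mk(50L, "90",    "0/0:30,0", "./.:.",    "1/1:0,30", "1/1:0,30"),
    mk(60L, "90",    "1/1:0,30", "1/1:0,30", "0/0:30,0", "0/0:30,0"))
  path <- toy_vcf(tempfile(fileext = ".vcf"), sheet$sample, rec)
  list(sheet = sheet, vcf = read_vcf(path, sheet))
}

test_that("fixed-difference discovery applies genotype and QUAL rules", {
  fx <- filter_fixture()
  found <- find_fixed_differences(fx$vcf, fx$sheet)
  expect_equal(found$pos, c(10L, 60L))
  # parent-of-origin allele labels follow the cohorts
  expect_equal(found$parentA_allele, c("ref", "alt"))
  # QUAL exactly at the threshold is retained
  found69 <- find_fixed_differences(fx$vcf, fx$sheet, qual_min = 69.5)
  expect_true(20L %in% found69$pos)
  # one missing parental genotype tolerated only when asked
  found_m <- find_fixed_differences(fx$vcf, fx$sheet, max_missing = 1)
  expect_true(50L %in% found_m$pos)
  # empty parental cohort errors
  expect_error(
    find_fixed_differences(fx$vcf,
                           fx$sheet[fx$sheet$cohort != "parentA", ]),
    "empty parental cohort")
})

test_that("discovery on simulated noise recovers the truth set exactly", {
  b <- small_bundle()
  v <- read_vcf(b$paths$vcf, b$sim$sheet)
  found <- find_fixed_differences(v, b$sim$sheet)
  truth_fixed <- b$sim$sites[b$sim$sites$class == "fixed", ]
  expect_equal(paste(found$chrom, found$pos),
               paste(truth_fixed$chrom, truth_fixed$pos))
  expect_equal(ifelse(found$parentA_allele == "ref", "ref", "alt"),
               truth_fixed$parentA_allele)
})

test_that("raising the filters never enlarges the retained set", {
  b <- small_bundle()
  v <- read_vcf(b$paths$vcf, b$sim$sheet)
  f70 <- find_fixed_differences(v, b$sim$sheet, qual_min = 70)
  f90 <- find_fixed_differences(v, b$sim$sheet, qual_min = 90)
  expect_true(all(paste(f90$chrom, f90$pos) %in%
                    paste(f70$chrom, f70$pos)))
  p10 <- site_proportions(v, f70, b$sim$sheet, depth_min = 10)
  p40 <- site_proportions(v, f70, b$sim$sheet, depth_min = 40)
  expect_true(all(paste(p40$sample, p40$chrom, p40$pos) %in%
                    paste(p10$sample, p10$chrom, p10$pos)))
})

test_that("site proportions compute the parental ratio and depth filter", {
  sheet <- toy_sheet()
  mkr <- function(pos, hj1) {
    r <- data.frame(chrom = "c1", pos = pos, ref = "A", alt = "G",
                    qual = "90", stringsAsFactors = FALSE)
    r$PA1 <- "0/0:30,0"; r$PA2 <- "0/0:30,0"
    r$PB1 <- "1/1:0,30"; r$PB2 <- "1/1:0,30"
    r$HJ1 <- hj1
    for (s in c("HJ2", "HA1", "HA2")) r[[s]] <- "0/1:20,20"
    r
  }
  rec <- rbind(mkr(10L, "0/1:30,70"),   # proportion 0.30
               mkr(20L, "0/1:4,5"),     # total 9 -> dropped
               mkr(30L, "0/1:10,0"))    # proportion 1.0, boundary depth
  v <- read_vcf(toy_vcf(tempfile(fileext = ".vcf"), sheet$sample, rec),
                sheet)
  fixed <- find_fixed_differences(v, sheet)
  props <- site_proportions(v, fixed, sheet)
  hj1 <- props[props$sample == "HJ1", ]
  expect_equal(hj1$prop[hj1$pos == 10], 0.30)
  expect_false(20L %in% hj1$pos)
  expect_equal(hj1$prop[hj1$pos == 30], 1.0)
  expect_equal(unname(attr(props, "drops")["low_depth"]), 1)
})

test_that("gene aggregation averages SNP proportions per sample", {
  props <- data.frame(sample = "H1", stage = "juvenile",
                      chrom = c("c1", "c1", "c2"), pos = c(1L, 2L, 1L),
                      depth = c(50L, 50L, 40L), prop = c(0.2, 0.4, 0.7),
                      stringsAsFactors = FALSE)
  map <- data.frame(chrom = c("c1", "c1", "c2"), pos = c(1L, 2L, 1L),
                    gene = c("gA", "gA", "gB"), stringsAsFactors = FALSE)
  agg <- aggregate_gene(props, map)
  expect_equal(agg$prop[agg$gene == "gA"], 0.3)
  expect_equal(agg$n_snps[agg$gene == "gA"], 2L)
  # single-SNP gene: identity
  expect_equal(agg$prop[agg$gene == "gB"], 0.7)
  # depth-weighted equals unweighted under equal weights
  aggw <- aggregate_gene(props, map, weighted = TRUE)
  expect_equal(aggw$prop, agg$prop)
  # unmapped site is an error
  expect_error(aggregate_gene(props, map[-1, ]), "without a gene")
})

test_that("balance classification respects the inclusive band", {
  expect_equal(classify_balance(0.50), "balanced")
  expect_equal(classify_balance(0.45), "balanced")
  expect_equal(classify_balance(0.55), "balanced")
  expect_equal(classify_balance(0.20), "parentB_dominant")
  expect_equal(classify_balance(0.5501), "parentA_dominant")
  expect_equal(classify_balance(c(0.1, NA)), c("parentB_dominant", NA))
  expect_error(classify_balance(1.2), "\\[0, 1\\]")
})

test_that("shift detection uses a strict threshold by default", {
  s <- detect_shift(0.55, 0.67)
  expect_equal(s$magnitude, 0.12)
  expect_true(s$flag)
  # a change of exactly 0.10 is not "over 0.1" under the strict rule
  s2 <- detect_shift(0.30, 0.20)
  expect_equal(s2$magnitude, 0.10)
  expect_false(s2$flag)
  expect_true(detect_shift(0.30, 0.20, strict = FALSE)$flag)
  expect_equal(detect_shift(0.4, 0.4)$magnitude, 0)
  expect_false(detect_shift(0.4, 0.4)$flag)
  expect_true(is.na(detect_shift(NA, 0.4)$flag))
})

test_that("the stage test equals an independent Welch computation", {
  z <- stage_test(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)

  juv <- c(0.48, 0.52, 0.50); adult <- c(0.88, 0.90, 0.92)
  got <- stage_test(juv, adult)
  want <- oracle_welch(asin(sqrt(adult)), asin(sqrt(juv)))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # label swap leaves |t| and p unchanged
  sw <- stage_test(1 - juv, 1 - adult)
  expect_equal(abs(sw$t), abs(got$t), tolerance = 1e-12)
  expect_equal(sw$p, got$p, tolerance = 1e-12)

  expect_true(stage_test(0.5, c(0.7, 0.8))$untestable)
})

test_that("run_ase is exactly equivariant under a parental label swap", {
  b <- small_bundle()
  sheet <- b$sim$sheet
  fit <- run_ase(b$paths$vcf, sheet, b$sim$site_gene)

  swapped <- sheet
  swapped$cohort[sheet$cohort == "parentA"] <- "parentB"
  swapped$cohort[sheet$cohort == "parentB"] <- "parentA"
  fit2 <- run_ase(b$paths$vcf, swapped, b$sim$site_gene)

  g1 <- fit$genes; g2 <- fit2$genes
  expect_equal(g2$gene, g1$gene)
  expect_equal(g2$juv_mean, 1 - g1$juv_mean, tolerance = 1e-12)
  expect_equal(g2$adult_mean, 1 - g1$adult_mean, tolerance = 1e-12)
  flip <- c(parentA_dominant = "parentB_dominant", balanced = "balanced",
            parentB_dominant = "parentA_dominant")
  expect_equal(unname(flip[g1$balance_juv]), g2$balance_juv)
  expect_equal(unname(flip[g1$balance_adult]), g2$balance_adult)
  expect_equal(g2$shift_mag, g1$shift_mag, tolerance = 1e-12)
  expect_identical(g2$shift_flag, g1$shift_flag)
  expect_equal(abs(g2$t), abs(g1$t), tolerance = 1e-10)
  expect_equal(g2$p, g1$p, tolerance = 1e-10)
  s1 <- summary(fit); s2 <- summary(fit2)
  expect_equal(unname(s2$class_counts_juv[["balanced"]]),
               unname(s1$class_counts_juv[["balanced"]]))
  expect_equal(unname(s2$class_counts_juv[["parentA_dominant"]]),
               unname(s1$class_counts_juv[["parentB_dominant"]]))
  expect_identical(s2$shifted_genes, s1$shifted_genes)

  # complement conservation: parent-B proportion is 1 - parent-A at the
  # per-sample gene level
  expect_equal(fit2$sample_props$prop, 1 - fit$sample_props$prop,
               tolerance = 1e-12)
})

test_that("estimated gene proportions sit in the analytic 99% interval", {
  b <- recovery_bundle()
  g <- merge(b$fit$genes, b$sim$truth, by = "gene")
  cfg <- b$cfg
  n_sites <- vapply(g$gene, function(gg)
    sum(b$sim$sites$gene == gg & b$sim$sites$class == "fixed"), 1L)
  rho <- cfg$overdispersion_rho
  # analytic stage-mean variance of a beta-binomial proportion averaged
  # over S sites and m samples: p(1-p) (rho + (1-rho) E[1/depth]) / (S m)
  e_inv_depth <- local({       # zero-truncated Poisson E[1/N]
    n <- 1:300
    sum(stats::dpois(n, cfg$depth_mean) / n) /
      (1 - exp(-cfg$depth_mean))
  })
  ok <- function(est, p, n_samp) {
    se <- sqrt(p * (1 - p) * (rho + (1 - rho) * e_inv_depth) /
                 (n_sites * n_samp))
    abs(est - p) <= stats::qnorm(0.995) * se
  }
  cover <- c(ok(g$juv_mean, g$p_juv, cfg$n_hybrid_juv),
             ok(g$adult_mean, g$p_adult, cfg$n_hybrid_adult))
  # under correct 99% coverage, misses are Binomial(n, 0.01): accept up
  # to the exact binomial 99.9% quantile so the test's own false-alarm
  # rate is 0.1%
  n_val <- length(cover)
  expect_lte(sum(!cover), stats::qbinom(0.999, n_val, 0.01))
})
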