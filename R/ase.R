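# Allele-specific expression pipeline: fixed-difference discovery between
# the parental cohorts, per-site allelic proportions in the hybrids,
# gene-level aggregation, balance classification, ontogenetic shift
# detection and the arcsine-transformed stage test.

#' Find fixed biallelic differences between the parental cohorts
#'
#' A site is retained iff it is a biallelic SNV at which every parent-A
#' sample is homozygous for one allele and every parent-B sample is
#' homozygous for the other (no missing parental genotypes by default),
#' and its QUAL is at least `qual_min`. The retained sites carry the
#' parent-of-origin label for each allele, which is what allows hybrid
#' reads to be assigned to a parental subgenome downstream.
#'
#' @param vcf A `vcf_sites` object from [read_vcf()].
#' @param sheet Sample sheet with at least one sample per parental cohort.
#' @param qual_min Minimum QUAL (default 70; sites below are filtered).
#' @param max_missing Maximum number of missing parental genotypes
#'   tolerated per cohort (default 0, the strict "fixed" criterion).
#' @param site_gene Optional site-to-gene map; when given, the owning gene
#'   is attached to each retained site.
#' @return Data frame of fixed-difference sites: `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `parentA_allele` (`"ref"` or `"alt"`), and `gene` if a
#'   map was supplied.
#' @export
find_fixed_differences <- function(vcf, sheet, qual_min = 70,
                                   max_missing = 0L, site_gene = NULL) {
  stopifnot(inherits(vcf, "vcf_sites"))
  sA <- sheet$sample[sheet$cohort == "parentA"]
  sB <- sheet$sample[sheet$cohort == "parentB"]
  if (length(sA) == 0L || length(sB) == 0L)
    stop("empty parental cohort: need >= 1 parentA and >= 1 parentB sample")
  gA <- vcf$gt[, sA, drop = FALSE]
  gB <- vcf$gt[, sB, drop = FALSE]

  cohort_hom <- function(g) {
    # per site: "ref"/"alt" if all non-missing calls are the same
    # homozygote and missing count is within tolerance, else NA
    n_missing <- rowSums(g == "missing")
    all_ref <- rowSums(g == "hom_ref") + n_missing == ncol(g)
    all_alt <- rowSums(g == "hom_alt") + n_missing == ncol(g)
    ok <- n_missing <= max_missing & ncol(g) - n_missing >= 1L
    out <- rep(NA_character_, nrow(g))
    out[ok & all_ref] <- "ref"
    out[ok & all_alt] <- "alt"
    out
  }
  homA <- cohort_hom(gA)
  homB <- cohort_hom(gB)
  keep <- !is.na(homA) & !is.na(homB) & homA != homB &
    !is.na(vcf$sites$qual) & vcf$sites$qual >= qual_min
  out <- vcf$sites[keep, , drop = FALSE]
  out$parentA_allele <- homA[keep]
  rownames(out) <- NULL
  if (!is.null(site_gene)) {
    idx <- match(paste(out$chrom, out$pos),
                 paste(site_gene$chrom, site_gene$pos))
    out$gene <- site_gene$gene[idx]
  }
  out
}

#' Per-sample, per-site parent-A allelic proportions
#'
#' For each hybrid sample and fixed-difference site, the informative total
#' is the sum of the two parental-allele depths; observations below
#' `depth_min` or with missing allelic depth are dropped (counted, not
#' erred on) and the proportion is the parent-A depth over the total.
#'
#' @param vcf A `vcf_sites` object carrying `AD` for the hybrid samples.
#' @param fixed_sites Output of [find_fixed_differences()].
#' @param sheet Sample sheet identifying the hybrid samples.
#' @param depth_min Minimum total allelic depth per observation
#'   (default 10).
#' @return Long data frame `sample`, `stage`, `chrom`, `pos`, `depth`,
#'   `prop` (parent-A proportion); attribute `drops` records how many
#'   observations were removed for missing AD and for low depth.
#' @export
site_proportions <- function(vcf, fixed_sites, sheet, depth_min = 10L) {
  stopifnot(inherits(vcf, "vcf_sites"))
  hyb <- sheet[sheet$cohort == "hybrid", , drop = FALSE]
  idx <- match(paste(fixed_sites$chrom, fixed_sites$pos),
               paste(vcf$sites$chrom, vcf$sites$pos))
  if (any(is.na(idx)))
    stop("fixed site(s) not present in VCF")
  rd <- vcf$ref_depth[idx, hyb$sample, drop = FALSE]
  ad <- vcf$alt_depth[idx, hyb$sample, drop = FALSE]
  a_is_ref <- fixed_sites$parentA_allele == "ref"
  dA <- rd; dA[!a_is_ref, ] <- ad[!a_is_ref, , drop = FALSE]
  dB <- ad; dB[!a_is_ref, ] <- rd[!a_is_ref, , drop = FALSE]
  total <- dA + dB
  out <- data.frame(
    sample = rep(hyb$sample, each = nrow(fixed_sites)),
    stage = rep(hyb$stage, each = nrow(fixed_sites)),
    chrom = rep(fixed_sites$chrom, times = nrow(hyb)),
    pos = rep(fixed_sites$pos, times = nrow(hyb)),
    depth = as.vector(total),
    prop = as.vector(dA) / as.vector(total),
    stringsAsFactors = FALSE)
  n_missing <- sum(is.na(out$depth))
  keep <- !is.na(out$depth) & out$depth >= depth_min
  n_low <- sum(!keep) - n_missing
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- c(missing_ad = n_missing, low_depth = n_low)
  out
}

#' Aggregate site proportions to gene level
#'
#' The gene-level parental proportion of a sample is the unweighted mean
#' of that sample's retained SNP proportions within the gene (the
#' convention used throughout the pipeline); a depth-weighted mean is
#' available as an option. A gene is absent for a sample with no retained
#' SNP observation.
#'
#' @param props Site proportions from [site_proportions()].
#' @param site_gene Site-to-gene map (`chrom`, `pos`, `gene`).
#' @param weighted Use depth-weighted means instead of unweighted.
#' @return Data frame `gene`, `sample`, `stage`, `prop`, `n_snps`.
#' @export
aggregate_gene <- function(props, site_gene, weighted = FALSE) {
  idx <- match(paste(props$chrom, props$pos),
               paste(site_gene$chrom, site_gene$pos))
  if (any(is.na(idx)))
    stop("site(s) without a gene assignment: ",
         paste(utils::head(unique(
           paste(props$chrom, props$pos)[is.na(idx)]), 5), collapse = "; "))
  props$gene <- site_gene$gene[idx]
  key <- interaction(props$gene, props$sample, drop = TRUE)
  prop <- if (weighted) {
    as.vector(tapply(seq_len(nrow(props)), key, function(i)
      stats::weighted.mean(props$prop[i], props$depth[i])))
  } else {
    as.vector(tapply(props$prop, key, mean))
  }
  first <- match(levels(key), key)
  out <- data.frame(gene = props$gene[first],
                    sample = props$sample[first],
                    stage = props$stage[first],
                    prop = prop,
                    n_snps = as.vector(tapply(props$prop, key, length)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a stage-mean proportion as balanced or parent-dominant
#'
#' Equal expression of both parental alleles is defined by the balance
#' band (default `[0.45, 0.55]`, inclusive at both ends). Proportions
#' above the band are parent-A dominant, below it parent-B dominant.
#'
#' @param p Proportion(s) in `[0, 1]` (`NA` passes through).
#' @param band Numeric pair, the inclusive balance band.
#' @return Character vector in
#'   `{"parentB_dominant", "balanced", "parentA_dominant"}`.
#' @export
classify_balance <- function(p, band = c(0.45, 0.55)) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("proportions must lie in [0, 1]")
  out <- rep(NA_character_, length(p))
  out[!is.na(p) & p > band[2]] <- "parentA_dominant"
  out[!is.na(p) & p < band[1]] <- "parentB_dominant"
  out[!is.na(p) & p >= band[1] & p <= band[2]] <- "balanced"
  out
}

#' Ontogenetic allelic shift between stage means
#'
#' The shift magnitude is `|adult - juvenile|`; a gene is flagged when the
#' magnitude exceeds the threshold (strictly, by default — "over 0.1").
#' Genes missing a stage mean get `NA` (excluded, never flagged).
#'
#' @param juv,adult Stage-mean proportions (vectors).
#' @param threshold Shift threshold (default 0.1).
#' @param strict Flag only magnitudes strictly greater than the threshold
#'   (default); `FALSE` flags `>=`. Comparisons carry a `1e-9` numerical
#'   tolerance so that decimally-equal magnitudes (e.g. `|0.20 - 0.30|`)
#'   sit exactly on the boundary despite binary floating point.
#' @return List with `magnitude` and logical `flag`.
#' @export
detect_shift <- function(juv, adult, threshold = 0.1, strict = TRUE) {
  magnitude <- abs(adult - juv)
  eps <- 1e-9
  flag <- if (strict) magnitude > threshold + eps
          else magnitude >= threshold - eps
  list(magnitude = magnitude, flag = flag)
}

#' Stage comparison of arcsine-transformed proportions
#'
#' Applies the variance-stabilizing transform `asin(sqrt(p))` to each
#' per-sample gene proportion and compares juveniles and adults with a
#' two-sided Welch t-test. With fewer than two samples in a stage the
#' gene is untestable and both statistics are `NA`.
#'
#' @param juv,adult Per-sample gene-level proportions for each stage.
#' @param transform `"asin_sqrt"` (default, variance-stabilizing) or
#'   `"asin"` (plain arcsine of the proportion).
#' @return List with `t`, `p`, and logical `untestable`.
#' @export
stage_test <- function(juv, adult, transform = c("asin_sqrt", "asin")) {
  transform <- match.arg(transform)
  juv <- juv[!is.na(juv)]; adult <- adult[!is.na(adult)]
  if (length(juv) < 2L || length(adult) < 2L)
    return(list(t = NA_real_, p = NA_real_, untestable = TRUE))
  f <- if (transform == "asin_sqrt") function(x) asin(sqrt(x)) else asin
  tj <- f(juv); ta <- f(adult)
  if (stats::sd(c(tj, ta)) == 0)
    return(list(t = 0, p = 1, untestable = FALSE))
  tt <- tryCatch(stats::t.test(ta, tj, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt))
    return(list(t = NA_real_, p = NA_real_, untestable = TRUE))
  list(t = unname(tt$statistic), p = tt$p.value, untestable = FALSE)
}

#' Run the full allele-specific-expression pipeline
#'
#' Chains fixed-difference discovery, depth filtering, per-site
#' proportions, gene aggregation, balance classification per stage,
#' ontogenetic shift detection and the arcsine stage test, and summarizes
#' per-stage class counts. Genes enter the stage-comparison columns only
#' when observed in at least one sample of each stage; the per-stage
#' classifications use all genes observed in that stage.
#'
#' @param vcf A `vcf_sites` object (or a VCF path).
#' @param sheet Sample sheet (or path).
#' @param site_gene Site-to-gene map (or path).
#' @param qual_min,depth_min,band,shift_threshold,strict_shift Stage
#'   parameters; see the individual stage functions.
#' @param max_missing Missing-parental-genotype tolerance for
#'   [find_fixed_differences()].
#' @param weighted Depth-weighted gene aggregation.
#' @param transform Arcsine variant for [stage_test()].
#' @param p_adjust Multiple-testing adjustment for the stage-test
#'   p-values (`"none"`, the default, or any [stats::p.adjust()] method).
#' @return An object of class `ase_fit`; see [summary.ase_fit()].
#' @export
run_ase <- function(vcf, sheet, site_gene, qual_min = 70, depth_min = 10L,
                    band = c(0.45, 0.55), shift_threshold = 0.1,
                    strict_shift = TRUE, max_missing = 0L,
                    weighted = FALSE, transform = "asin_sqrt",
                    p_adjust = "none") {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(vcf)) vcf <- read_vcf(vcf, sheet)
  if (is.character(site_gene)) site_gene <- read_site_gene_map(site_gene)

  fixed <- find_fixed_differences(vcf, sheet, qual_min = qual_min,
                                  max_missing = max_missing,
                                  site_gene = site_gene)
  props <- site_proportions(vcf, fixed, sheet, depth_min = depth_min)
  gene_props <- aggregate_gene(props, site_gene, weighted = weighted)

  genes <- sort(unique(gene_props$gene))
  stage_mean <- function(g, st) {
    x <- gene_props$prop[gene_props$gene == g & gene_props$stage == st]
    if (length(x) == 0L) NA_real_ else mean(x)
  }
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  tab$n_snps <- vapply(genes, function(g)
    max(gene_props$n_snps[gene_props$gene == g]), 1L)
  tab$juv_mean <- vapply(genes, stage_mean, 1, st = "juvenile")
  tab$adult_mean <- vapply(genes, stage_mean, 1, st = "adult")
  tab$n_juv <- vapply(genes, function(g)
    sum(gene_props$gene == g & gene_props$stage == "juvenile"), 1L)
  tab$n_adult <- vapply(genes, function(g)
    sum(gene_props$gene == g & gene_props$stage == "adult"), 1L)
  tab$balance_juv <- classify_balance(tab$juv_mean, band)
  tab$balance_adult <- classify_balance(tab$adult_mean, band)

  both <- !is.na(tab$juv_mean) & !is.na(tab$adult_mean)
  sh <- detect_shift(tab$juv_mean, tab$adult_mean,
                     threshold = shift_threshold, strict = strict_shift)
  tab$shift_mag <- ifelse(both, sh$magnitude, NA_real_)
  tab$shift_flag <- ifelse(both, sh$flag, NA)

  tests <- lapply(genes, function(g) {
    stage_test(gene_props$prop[gene_props$gene == g &
                                 gene_props$stage == "juvenile"],
               gene_props$prop[gene_props$gene == g &
                                 gene_props$stage == "adult"],
               transform = transform)
  })
  tab$t <- vapply(tests, `[[`, 1, "t")
  tab$p <- vapply(tests, `[[`, 1, "p")
  if (p_adjust != "none")
    tab$padj <- stats::p.adjust(tab$p, method = p_adjust)

  class_counts <- function(cls) {
    lv <- c("parentB_dominant", "balanced", "parentA_dominant")
    table(factor(cls, levels = lv))
  }
  summary <- list(
    n_sites_total = nrow(vcf$sites),
    n_fixed_sites = nrow(fixed),
    n_genes = length(genes),
    drops = attr(props, "drops"),
    class_counts_juv = class_counts(tab$balance_juv),
    class_counts_adult = class_counts(tab$balance_adult),
    shifted_genes = tab$gene[!is.na(tab$shift_flag) & tab$shift_flag])

  structure(list(genes = tab, sample_props = gene_props,
                 fixed_sites = fixed, summary = summary,
                 params = list(qual_min = qual_min, depth_min = depth_min,
                               band = band,
                               shift_threshold = shift_threshold,
                               strict_shift = strict_shift,
                               max_missing = max_missing,
                               weighted = weighted, transform = transform,
                               p_adjust = p_adjust)),
            class = "ase_fit")
}

#' @export
print.ase_fit <- function(x, ...) {
  s <- x$summary
  cat("Allele-specific expression fit\n")
  cat(sprintf("  fixed-difference SNPs: %d (of %d sites) in %d genes\n",
              s$n_fixed_sites, s$n_sites_total, s$n_genes))
  cat(sprintf("  dropped observations: %d missing AD, %d below depth\n",
              s$drops[["missing_ad"]], s$drops[["low_depth"]]))
  cat("  juvenile classes: ",
      paste(names(s$class_counts_juv), s$class_counts_juv,
            collapse = ", "), "\n")
  cat("  adult classes:    ",
      paste(names(s$class_counts_adult), s$class_counts_adult,
            collapse = ", "), "\n")
  cat(sprintf("  ontogenetic shifts (> %.2f): %d gene(s)\n",
              x$params$shift_threshold, length(s$shifted_genes)))
  invisible(x)
}

#' Summarize an ASE fit
#'
#' @param object An `ase_fit`.
#' @param ... Unused.
#' @return The summary list: site/gene counts, filter drop counts,
#'   per-stage balance-class counts and the shifted-gene list.
#' @export
summary.ase_fit <- function(object, ...) object$summary

#' Plot stage histograms of parental-allele proportions
#'
#' Gene-density histograms of the parent-A allelic proportion per life
#' stage, with the balance band marked — the package's analogue of the
#' stage-wise allelic-proportion overview plot.
#'
#' @param x An `ase_fit`.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @param ... Further arguments to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.ase_fit <- function(x, breaks = seq(0, 1, 0.05), ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (st in c("juv", "adult")) {
    v <- x$genes[[paste0(st, "_mean")]]
    graphics::hist(v[!is.na(v)], breaks = breaks,
                   main = ifelse(st == "juv", "Juvenile", "Adult"),
                   xlab = "parent-A allele proportion", ...)
    graphics::abline(v = x$params$band, lty = 2)
  }
  invisible(x)
}
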