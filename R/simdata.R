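# Synthetic-data generator: parental genotypes, hybrid allelic counts, and
# NB expression matrices with known ground truth. Every downstream stage of
# the package can be exercised against the truth tables produced here.

#' Simulation configuration
#'
#' Collects and validates all knobs of the synthetic-data generator. The
#' defaults emulate the study design the package targets: two parental
#' species cohorts and their F1 hybrid, five individuals per cohort and
#' stage, overdispersed allelic read counts at moderate sequencing depth.
#'
#' @param n_genes Number of genes carrying variant sites.
#' @param snps_per_gene_mean Poisson mean of the per-gene SNP count
#'   (each gene is guaranteed at least one site).
#' @param frac_fixed_sites Expected fraction of sites that are fixed
#'   differences between the parental cohorts (each parental cohort
#'   homozygous for alternate alleles). The remainder are confounder sites
#'   drawn from `confounder_mix`.
#' @param n_parentA_samples,n_parentB_samples Parental cohort sizes.
#' @param n_hybrid_juv,n_hybrid_adult Hybrid sample sizes per life stage
#'   (at least 2 each, so stage comparisons are testable).
#' @param depth_mean Mean total allelic depth per hybrid sample and site
#'   (Poisson; zero totals are resampled unless `allow_zero_depth`).
#' @param qual_range Range of the variant QUAL score for ordinary sites;
#'   low-QUAL confounder sites are forced below 70 regardless.
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   `[0, 1)`; 0 reduces exactly to binomial sampling.
#' @param confounder_mix Named non-negative weights for the three
#'   confounder site classes `shared_hom` (both cohorts the same
#'   homozygote), `het_parent` (one parental sample heterozygous) and
#'   `low_qual` (fixed-like genotypes, QUAL below 70).
#' @param allow_zero_depth If `TRUE`, zero total depths are emitted rather
#'   than resampled (useful to exercise the depth filter).
#' @param seed Integer seed; all generator functions derive their RNG
#'   state from it, making outputs reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200L,
                       snps_per_gene_mean = 25,
                       frac_fixed_sites = 0.7,
                       n_parentA_samples = 5L,
                       n_parentB_samples = 5L,
                       n_hybrid_juv = 5L,
                       n_hybrid_adult = 5L,
                       depth_mean = 50,
                       qual_range = c(75, 110),
                       overdispersion_rho = 0.1,
                       confounder_mix = c(shared_hom = 1, het_parent = 1,
                                          low_qual = 1),
                       allow_zero_depth = FALSE,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              snps_per_gene_mean = snps_per_gene_mean,
              frac_fixed_sites = frac_fixed_sites,
              n_parentA_samples = as.integer(n_parentA_samples),
              n_parentB_samples = as.integer(n_parentB_samples),
              n_hybrid_juv = as.integer(n_hybrid_juv),
              n_hybrid_adult = as.integer(n_hybrid_adult),
              depth_mean = depth_mean,
              qual_range = as.numeric(qual_range),
              overdispersion_rho = overdispersion_rho,
              confounder_mix = confounder_mix,
              allow_zero_depth = isTRUE(allow_zero_depth),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L)
    stop("configuration error: n_genes must be >= 1")
  if (cfg$snps_per_gene_mean < 1)
    stop("configuration error: snps_per_gene_mean must be >= 1")
  if (frac_fixed_sites < 0 || frac_fixed_sites > 1)
    stop("configuration error: frac_fixed_sites must lie in [0, 1]")
  if (cfg$n_parentA_samples < 1L || cfg$n_parentB_samples < 1L)
    stop("configuration error: parental cohorts need >= 1 sample")
  if (cfg$n_hybrid_juv < 2L || cfg$n_hybrid_adult < 2L)
    stop("configuration error: hybrid stages need >= 2 samples each")
  if (depth_mean <= 0)
    stop("configuration error: depth_mean must be positive")
  if (length(cfg$qual_range) != 2L || diff(cfg$qual_range) < 0)
    stop("configuration error: qual_range must be an increasing pair")
  if (overdispersion_rho < 0 || overdispersion_rho >= 1)
    stop("configuration error: overdispersion_rho must lie in [0, 1)")
  mix <- cfg$confounder_mix
  if (is.null(names(mix)) ||
      !setequal(names(mix), c("shared_hom", "het_parent", "low_qual")) ||
      any(mix < 0) || sum(mix) <= 0)
    stop("configuration error: confounder_mix needs non-negative weights ",
         "named shared_hom, het_parent, low_qual")
  structure(cfg, class = "sim_config")
}

#' Sample sheet for the allele-specific-expression design
#'
#' Builds the sample metadata for the ASE arm of the simulation: parental
#' cohort samples (used only for genotyping) plus juvenile and adult
#' hybrids. EOD durations follow the emulated design: the parent-A species
#' keeps a 0.4 ms discharge throughout ontogeny, the parent-B species
#' elongates to 40 ms, and the hybrid elongates from 0.4 to 4 ms.
#'
#' @param cfg A [sim_config()].
#' @return A data frame with columns `sample`, `cohort`
#'   (`parentA`/`parentB`/`hybrid`), `stage` and `duration_ms`.
#' @export
ase_sample_sheet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  data.frame(
    sample = c(sprintf("PA%d", seq_len(cfg$n_parentA_samples)),
               sprintf("PB%d", seq_len(cfg$n_parentB_samples)),
               sprintf("HJ%d", seq_len(cfg$n_hybrid_juv)),
               sprintf("HA%d", seq_len(cfg$n_hybrid_adult))),
    cohort = c(rep("parentA", cfg$n_parentA_samples),
               rep("parentB", cfg$n_parentB_samples),
               rep("hybrid", cfg$n_hybrid_juv + cfg$n_hybrid_adult)),
    stage = c(rep("adult", cfg$n_parentA_samples + cfg$n_parentB_samples),
              rep("juvenile", cfg$n_hybrid_juv),
              rep("adult", cfg$n_hybrid_adult)),
    duration_ms = c(rep(0.4, cfg$n_parentA_samples),
                    rep(40, cfg$n_parentB_samples),
                    rep(0.4, cfg$n_hybrid_juv),
                    rep(4, cfg$n_hybrid_adult)),
    stringsAsFactors = FALSE)
}

#' Expression study design
#'
#' Sample metadata for the expression arm: three cohorts (parent-A
#' species, parent-B species, hybrid) at two life stages with the
#' cohort-and-stage-specific EOD durations of the emulated design
#' (parent A 0.4/0.4 ms, parent B 5/40 ms, hybrid 0.4/4 ms).
#'
#' @param n_per_group Individuals per cohort-stage cell.
#' @return Data frame with `sample`, `cohort`, `stage`, `duration_ms`.
#' @export
expression_design <- function(n_per_group = 5L) {
  n <- as.integer(n_per_group)
  if (n < 2L) stop("configuration error: need >= 2 samples per group")
  grp <- expand.grid(stage = c("juvenile", "adult"),
                     cohort = c("parentA", "parentB", "hybrid"),
                     stringsAsFactors = FALSE)
  dur <- c(parentA.juvenile = 0.4, parentA.adult = 0.4,
           parentB.juvenile = 5,   parentB.adult = 40,
           hybrid.juvenile = 0.4,  hybrid.adult = 4)
  out <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    key <- paste(grp$cohort[i], grp$stage[i], sep = ".")
    tag <- paste0(sub("parent", "P", grp$cohort[i]),
                  ifelse(grp$stage[i] == "juvenile", "J", "A"))
    data.frame(sample = sprintf("%s%d", tag, seq_len(n)),
               cohort = grp$cohort[i], stage = grp$stage[i],
               duration_ms = unname(dur[key]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Ground-truth allelic proportions
#'
#' Draws per-gene latent parent-A allelic proportions for the juvenile and
#' adult stage. A configurable fraction of genes undergoes an ontogenetic
#' shift of fixed magnitude `shift_delta`; all true proportions are kept
#' at least `band_margin` away from the balance-band edges so the truth
#' labels are well separated from the classifier boundaries.
#'
#' @param cfg A [sim_config()].
#' @param frac_balanced Fraction of genes with balanced true proportions.
#' @param frac_shifted Fraction of genes whose adult proportion differs
#'   from the juvenile one by exactly `shift_delta`.
#' @param shift_delta True shift magnitude for shifted genes.
#' @param band Balance band used to derive truth labels.
#' @param band_margin Minimum distance of any true proportion from either
#'   band edge.
#' @return Data frame of class `ase_truth` with per-gene `p_juv`,
#'   `p_adult`, stage balance labels, `shift_mag` and `shifted` flag; the
#'   labels are recomputed from the proportions with [classify_balance()]
#'   and [detect_shift()], so they are consistent by construction.
#' @export
simulate_ase_truth <- function(cfg, frac_balanced = 0.6, frac_shifted = 0.1,
                               shift_delta = 0.15, band = c(0.45, 0.55),
                               band_margin = 0.04) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("gene%04d", seq_len(n))
  lo <- band[1]; hi <- band[2]
  away <- function(p) {
    p >= 0.05 & p <= 0.95 &
      abs(p - lo) >= band_margin & abs(p - hi) >= band_margin
  }
  draw_p <- function() {
    if (runif(1) < frac_balanced)
      runif(1, lo + band_margin, hi - band_margin)
    else if (runif(1) < 0.5)
      runif(1, 0.10, lo - band_margin)
    else
      runif(1, hi + band_margin, 0.90)
  }
  shifted <- rep(FALSE, n)
  if (frac_shifted > 0)
    shifted[sample.int(n, max(1L, round(frac_shifted * n)))] <- TRUE
  p_juv <- p_adult <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      pj <- draw_p()
      pa <- if (shifted[i]) pj + sample(c(-1, 1), 1) * shift_delta else pj
      if (away(pj) && away(pa)) break
    }
    p_juv[i] <- pj; p_adult[i] <- pa
  }
  truth <- data.frame(gene = genes, p_juv = p_juv, p_adult = p_adult,
                      stringsAsFactors = FALSE)
  truth$balance_juv <- classify_balance(truth$p_juv, band)
  truth$balance_adult <- classify_balance(truth$p_adult, band)
  sh <- detect_shift(truth$p_juv, truth$p_adult)
  truth$shift_mag <- sh$magnitude
  truth$shifted <- sh$flag
  class(truth) <- c("ase_truth", "data.frame")
  truth
}

#' Simulate parental genotypes at fixed and confounder sites
#'
#' Emits a site table, parental genotype matrix, site-to-gene map and
#' allelic ground truth. In expectation `frac_fixed_sites` of the sites
#' are fixed differences (every parent-A sample homozygous for one allele,
#' every parent-B sample homozygous for the other, QUAL in `qual_range`);
#' the rest are confounders that downstream filters must reject: shared
#' homozygotes, sites with a heterozygous parental sample, and fixed-like
#' sites with QUAL forced below 70.
#'
#' @param cfg A [sim_config()].
#' @param truth Optional [simulate_ase_truth()] result; generated with the
#'   configuration defaults when omitted.
#' @param ... Passed on to [simulate_ase_truth()] when `truth` is missing.
#' @return A list of class `ase_sim`: `sites` (chrom, pos, ref, alt, qual,
#'   class, parentA_allele, gene), `gt` (site-by-parental-sample genotype
#'   strings), `site_gene` map, `truth`, `sheet` and `cfg`.
#' @export
simulate_parental_genotypes <- function(cfg, truth = NULL, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L ||
      cfg$n_parentA_samples < 1L || cfg$n_parentB_samples < 1L)
    stop("configuration error: need >= 1 gene and >= 1 sample per cohort")
  if (is.null(truth)) truth <- simulate_ase_truth(cfg, ...)
  sheet <- ase_sample_sheet(cfg)
  set.seed(cfg$seed + 1L)

  n_sites_gene <- 1L + stats::rpois(cfg$n_genes, cfg$snps_per_gene_mean - 1)
  gene_of_site <- rep(truth$gene, n_sites_gene)
  n_sites <- length(gene_of_site)
  within_idx <- sequence(n_sites_gene)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

  classes <- ifelse(stats::runif(n_sites) < cfg$frac_fixed_sites, "fixed",
                    NA_character_)
  n_conf <- sum(is.na(classes))
  if (n_conf > 0) {
    w <- cfg$confounder_mix[c("shared_hom", "het_parent", "low_qual")]
    classes[is.na(classes)] <- sample(names(w), n_conf, replace = TRUE,
                                      prob = w / sum(w))
  }

  qual <- round(stats::runif(n_sites, cfg$qual_range[1], cfg$qual_range[2]), 2)
  low <- classes == "low_qual"
  qual[low] <- round(stats::runif(sum(low), 40, 69.98), 2)

  # which allele belongs to parent A (shared-homozygote sites have none)
  parentA_allele <- ifelse(classes == "shared_hom", NA_character_,
                           ifelse(stats::runif(n_sites) < 0.5, "ref", "alt"))

  nA <- cfg$n_parentA_samples; nB <- cfg$n_parentB_samples
  samplesP <- sheet$sample[sheet$cohort != "hybrid"]
  gt <- matrix(NA_character_, n_sites, nA + nB,
               dimnames = list(NULL, samplesP))
  hom <- c(ref = "0/0", alt = "1/1")
  for (i in seq_len(n_sites)) {
    cl <- classes[i]
    if (cl == "shared_hom") {
      gt[i, ] <- "0/0"
    } else {
      aA <- parentA_allele[i]
      aB <- if (aA == "ref") "alt" else "ref"
      gt[i, seq_len(nA)] <- hom[[aA]]
      gt[i, nA + seq_len(nB)] <- hom[[aB]]
      if (cl == "het_parent")
        gt[i, sample.int(nA + nB, 1L)] <- "0/1"
    }
  }

  sites <- data.frame(chrom = sprintf("ctg%04d", match(gene_of_site,
                                                       truth$gene)),
                      pos = (within_idx - 1L) * 100L + 1L,
                      ref = ref, alt = alt, qual = qual,
                      class = classes, parentA_allele = parentA_allele,
                      gene = gene_of_site, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt,
                 site_gene = sites[, c("chrom", "pos", "gene")],
                 truth = truth, sheet = sheet, cfg = cfg),
            class = "ase_sim")
}

#' Beta-binomial random counts
#'
#' Parameterized by success probability `prob` and intra-class correlation
#' `rho`; `rho = 0` reduces exactly to [stats::rbinom()].
#'
#' @param n Number of draws.
#' @param size Vector of totals.
#' @param prob Success probability (scalar or vector).
#' @param rho Intra-class correlation in `[0, 1)`.
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  prob <- rep_len(prob, n)
  size <- rep_len(size, n)
  if (rho == 0) return(stats::rbinom(n, size, prob))
  p <- numeric(n)
  inner <- prob > 0 & prob < 1
  a <- prob[inner] * (1 - rho) / rho
  b <- (1 - prob[inner]) * (1 - rho) / rho
  p[inner] <- stats::rbeta(sum(inner), a, b)
  p[prob >= 1] <- 1
  stats::rbinom(n, size, p)
}

#' Simulate hybrid allelic depths at variant sites
#'
#' For every hybrid sample and site, the total depth is Poisson with mean
#' `depth_mean` (zeros resampled unless the configuration allows them) and
#' the parent-A allele count is beta-binomial around the gene's true
#' stage-specific proportion. Sites without a parent-A allele (shared
#' homozygotes) receive all depth on their shared allele.
#'
#' @param sites Site table as produced by [simulate_parental_genotypes()]
#'   (requires `chrom`, `pos`, `gene`, `parentA_allele`).
#' @param truth An `ase_truth` table covering every gene in `sites`.
#' @param cfg A [sim_config()].
#' @return Long data frame with one row per hybrid sample and site:
#'   `chrom`, `pos`, `gene`, `sample`, `stage`, `total`, `count_a`
#'   (parent-A allele depth; `NA` where no parental allele is defined).
#' @export
simulate_hybrid_allelic_counts <- function(sites, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  miss <- setdiff(unique(sites$gene), truth$gene)
  if (length(miss))
    stop("sites reference unknown gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  sheet <- ase_sample_sheet(cfg)
  hyb <- sheet[sheet$cohort == "hybrid", ]
  set.seed(cfg$seed + 2L)
  n_obs <- nrow(sites) * nrow(hyb)
  out <- data.frame(
    chrom = rep(sites$chrom, times = nrow(hyb)),
    pos = rep(sites$pos, times = nrow(hyb)),
    gene = rep(sites$gene, times = nrow(hyb)),
    sample = rep(hyb$sample, each = nrow(sites)),
    stage = rep(hyb$stage, each = nrow(sites)),
    stringsAsFactors = FALSE)
  total <- stats::rpois(n_obs, cfg$depth_mean)
  if (!cfg$allow_zero_depth) {
    while (any(total == 0L))
      total[total == 0L] <- stats::rpois(sum(total == 0L), cfg$depth_mean)
  }
  gi <- match(out$gene, truth$gene)
  p <- ifelse(out$stage == "juvenile", truth$p_juv[gi], truth$p_adult[gi])
  count_a <- rbetabinom(n_obs, total, p, cfg$overdispersion_rho)
  no_parent <- rep(is.na(sites$parentA_allele), times = nrow(hyb))
  count_a[no_parent] <- NA_integer_
  out$total <- total
  out$count_a <- count_a
  out
}

#' Ground-truth expression patterns
#'
#' Per-gene latent structure for the expression simulator: a pattern label
#' (increasing, decreasing or flat with respect to EOD duration), a
#' baseline mean, a log2 fold-change per duration decade (exactly 0 for
#' flat genes) and an NB dispersion. A configurable fraction of genes is
#' given a near-zero baseline so the low-count filter has work to do.
#'
#' @param n_genes Number of genes.
#' @param frac_increasing,frac_decreasing Fractions of monotone genes.
#' @param frac_low Fraction of flat genes with near-zero baseline.
#' @param slope_range Magnitude range of the log2 fold change per decade
#'   of EOD duration for monotone genes.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @return Data frame of class `expr_truth` with columns `gene`,
#'   `pattern`, `baseline`, `slope`, `dispersion`.
#' @export
simulate_expr_truth <- function(n_genes = 1000L, frac_increasing = 0.15,
                                frac_decreasing = 0.15, frac_low = 0.05,
                                slope_range = c(1, 3),
                                baseline_meanlog = log(100),
                                baseline_sdlog = 1,
                                dispersion = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  n <- as.integer(n_genes)
  pattern <- sample(c("increasing", "decreasing", "flat"), n, replace = TRUE,
                    prob = c(frac_increasing, frac_decreasing,
                             1 - frac_increasing - frac_decreasing))
  slope <- numeric(n)
  mono <- pattern != "flat"
  slope[mono] <- stats::runif(sum(mono), slope_range[1], slope_range[2]) *
    ifelse(pattern[mono] == "increasing", 1, -1)
  baseline <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
  low <- pattern == "flat" & stats::runif(n) < frac_low / max(1e-9, 1 -
    frac_increasing - frac_decreasing)
  baseline[low] <- stats::runif(sum(low), 0.01, 0.5)
  structure(data.frame(gene = sprintf("gene%04d", seq_len(n)),
                       pattern = pattern, baseline = baseline, slope = slope,
                       dispersion = dispersion, stringsAsFactors = FALSE),
            class = c("expr_truth", "data.frame"))
}

#' Simulate an expression count matrix
#'
#' Counts are negative-binomial with per-gene mean
#' `baseline * 2^(slope * log10(duration / d0))`, where `d0` is the
#' geometric mean duration across samples, so `slope` is the log2 fold
#' change per decade of EOD duration; flat genes (slope 0) have a constant
#' mean. Dispersion 0 falls back to Poisson sampling.
#'
#' @param design Sample metadata with positive `duration_ms` (e.g.
#'   [expression_design()]).
#' @param truth An `expr_truth` table ([simulate_expr_truth()]).
#' @param seed Integer seed.
#' @return Integer count matrix, genes in rows, samples in columns.
#' @export
simulate_expression_counts <- function(design, truth, seed = 1L) {
  if (any(!is.finite(design$duration_ms)) || any(design$duration_ms <= 0))
    stop("every sample needs a positive EOD duration")
  set.seed(as.integer(seed))
  d0 <- exp(mean(log(design$duration_ms)))
  dec <- log10(design$duration_ms / d0)
  mu <- outer(truth$baseline, rep(1, nrow(design))) *
    2^(outer(truth$slope, dec))
  n <- length(mu)
  disp <- rep(truth$dispersion, nrow(design))
  counts <- integer(n)
  pois <- disp < 1e-12
  counts[pois] <- stats::rpois(sum(pois), mu[pois])
  counts[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                  size = 1 / disp[!pois])
  matrix(counts, nrow = nrow(truth),
         dimnames = list(truth$gene, design$sample))
}

#' Write a complete simulation bundle to disk
#'
#' Persists an `ase_sim` (VCF with parental genotypes and hybrid allelic
#' depths, site-to-gene map, ASE sample sheet, allelic truth) and
#' optionally an expression arm (count matrix, design, expression truth)
#' as plain-text files that round-trip through the package's readers.
#'
#' @param sim An `ase_sim` from [simulate_parental_genotypes()].
#' @param dir Output directory (created if missing).
#' @param allelic Hybrid allelic counts; generated from `sim` if omitted.
#' @param counts,design,expr_truth Optional expression arm.
#' @return Named list of the written file paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir, allelic = NULL, counts = NULL,
                                 design = NULL, expr_truth = NULL) {
  stopifnot(inherits(sim, "ase_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  if (is.null(allelic))
    allelic <- simulate_hybrid_allelic_counts(sim$sites, sim$truth, sim$cfg)
  paths <- list(vcf = file.path(dir, "sites.vcf"),
                site_gene = file.path(dir, "site_gene_map.tsv"),
                ase_sheet = file.path(dir, "ase_samples.tsv"),
                ase_truth = file.path(dir, "ase_truth.tsv"))
  write_sim_vcf(paths$vcf, sim, allelic)
  write_tsv(sim$site_gene, paths$site_gene)
  write_tsv(sim$sheet, paths$ase_sheet)
  write_tsv(as.data.frame(sim$truth), paths$ase_truth)
  if (!is.null(counts)) {
    stopifnot(!is.null(design))
    paths$counts <- file.path(dir, "counts.tsv")
    paths$expr_sheet <- file.path(dir, "expr_samples.tsv")
    write_counts(counts, paths$counts)
    write_tsv(design, paths$expr_sheet)
    if (!is.null(expr_truth)) {
      paths$expr_truth <- file.path(dir, "expr_truth.tsv")
      write_tsv(as.data.frame(expr_truth), paths$expr_truth)
    }
  }
  invisible(paths)
}

# VCF v4.2 emit: parental genotypes carry deterministic depths consistent
# with the call; hybrids are het at parent-informative sites with AD taken
# from the simulated allelic counts.
write_sim_vcf <- function(path, sim, allelic) {
  sites <- sim$sites
  sheet <- sim$sheet
  hyb_samples <- sheet$sample[sheet$cohort == "hybrid"]
  key <- paste(allelic$chrom, allelic$pos, allelic$sample, sep = "\r")
  a_tot <- allelic$total[match(
    paste(rep(sites$chrom, length(hyb_samples)),
          rep(sites$pos, length(hyb_samples)),
          rep(hyb_samples, each = nrow(sites)), sep = "\r"), key)]
  a_cnt <- allelic$count_a[match(
    paste(rep(sites$chrom, length(hyb_samples)),
          rep(sites$pos, length(hyb_samples)),
          rep(hyb_samples, each = nrow(sites)), sep = "\r"), key)]
  tot <- matrix(a_tot, nrow(sites), length(hyb_samples))
  cnt <- matrix(a_cnt, nrow(sites), length(hyb_samples))

  gt_field <- function(g) {
    # depth 30 split per call; missing stays ./.
    switch(g,
           "0/0" = "0/0:30,0", "1/1" = "1/1:0,30", "0/1" = "0/1:15,15",
           "./." = "./.:.")
  }
  lines <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pa <- sites$parentA_allele[i]
    if (is.na(pa)) {                       # shared homozygote: all ref depth
      hyb_cols <- sprintf("0/0:%d,0", tot[i, ])
    } else if (pa == "ref") {
      hyb_cols <- sprintf("0/1:%d,%d", cnt[i, ], tot[i, ] - cnt[i, ])
    } else {
      hyb_cols <- sprintf("0/1:%d,%d", tot[i, ] - cnt[i, ], cnt[i, ])
    }
    par_cols <- vapply(sim$gt[i, ], gt_field, "")
    lines[i] <- paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i],
                        sites$alt[i], format_qual(sites$qual[i]), "PASS",
                        ".", "GT:AD", par_cols, hyb_cols), collapse = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=eodase-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sheet$sample), collapse = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

format_qual <- function(q) {
  s <- formatC(q, format = "f", digits = 2)
  sub("\\.?0+$", "", s)
}
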