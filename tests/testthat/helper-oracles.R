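# Shared fixtures and independent oracle implementations. The oracles are
# deliberately straight-line re-implementations that do not touch the
# package's code paths (nor vcfR), so agreement is informative.

# Write a crafted VCF from a record data frame with one "GT:AD" string per
# sample column.
toy_vcf <- function(path, samples, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], records$qual[i], "PASS", ".", "GT:AD",
            unlist(records[i, samples])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# Minimal 2+2 parents / 2+2 hybrids sheet used by crafted fixtures.
toy_sheet <- function() {
  data.frame(
    sample = c("PA1", "PA2", "PB1", "PB2", "HJ1", "HJ2", "HA1", "HA2"),
    cohort = c("parentA", "parentA", "parentB", "parentB",
               "hybrid", "hybrid", "hybrid", "hybrid"),
    stage = c(rep("adult", 4), "juvenile", "juvenile", "adult", "adult"),
    duration_ms = c(0.4, 0.4, 40, 40, 0.4, 0.4, 4, 4),
    stringsAsFactors = FALSE)
}

# Welch two-sample t-test from first principles.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Benjamini-Hochberg by the textbook definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  adj[o] <- rev(cummin(rev(pmin(ranked, 1))))
  adj
}

# Two-sided Fisher exact p by hypergeometric summation over all tables
# with the observed margins, including every table whose probability does
# not exceed the observed one (with a relative tolerance, as in the
# conventional definition).
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# Median-of-ratios size factors, brute force, geometric mean 1.
oracle_size_factors <- function(m) {
  use <- apply(m, 1, function(r) all(r > 0))
  ref <- apply(m[use, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  f <- apply(m[use, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
  f / exp(mean(log(f)))
}

# Straight-line re-computation of the whole ASE pipeline from the VCF
# text. Parses lines with strsplit, applies the filters, averages SNP
# proportions per gene/sample, classifies, and tests, independently of
# every package function.
oracle_ase <- function(vcf_path, sheet, map, qual_min = 70,
                       depth_min = 10, band = c(0.45, 0.55),
                       shift_threshold = 0.1) {
  ln <- readLines(vcf_path)
  ln <- ln[!startsWith(ln, "##")]
  hdr <- strsplit(ln[1], "\t", fixed = TRUE)[[1]]
  samples <- hdr[-(1:9)]
  pa <- sheet$sample[sheet$cohort == "parentA"]
  pb <- sheet$sample[sheet$cohort == "parentB"]
  hyb <- sheet[sheet$cohort == "hybrid", ]
  acc <- list()
  for (line in ln[-1]) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5], fixed = TRUE)) next
    if (nchar(f[4]) > 1 || nchar(f[5]) > 1) next
    if (as.numeric(f[6]) < qual_min) next
    cols <- f[-(1:9)]
    names(cols) <- samples
    gts <- sub(":.*", "", cols)
    fixedA_ref <- all(gts[pa] == "0/0") && all(gts[pb] == "1/1")
    fixedA_alt <- all(gts[pa] == "1/1") && all(gts[pb] == "0/0")
    if (!fixedA_ref && !fixedA_alt) next
    gene <- map$gene[map$chrom == f[1] & map$pos == as.integer(f[2])]
    for (k in seq_len(nrow(hyb))) {
      ad <- sub("^[^:]*:", "", cols[[hyb$sample[k]]])
      if (ad %in% c(".", "")) next
      dp <- suppressWarnings(
        as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
      if (length(dp) < 2 || any(is.na(dp))) next
      tot <- dp[1] + dp[2]
      if (tot < depth_min) next
      pA <- if (fixedA_ref) dp[1] / tot else dp[2] / tot
      key <- paste(gene, hyb$sample[k], hyb$stage[k], sep = "|")
      acc[[key]] <- c(acc[[key]], pA)
    }
  }
  if (!length(acc)) return(NULL)
  parts <- do.call(rbind, strsplit(names(acc), "|", fixed = TRUE))
  per_sample <- data.frame(gene = parts[, 1], sample = parts[, 2],
                           stage = parts[, 3],
                           prop = vapply(acc, mean, 1),
                           stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL
  genes <- sort(unique(per_sample$gene))
  classify <- function(p) {
    if (is.na(p)) NA_character_
    else if (p > band[2]) "parentA_dominant"
    else if (p < band[1]) "parentB_dominant"
    else "balanced"
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    pj <- per_sample$prop[per_sample$gene == g &
                            per_sample$stage == "juvenile"]
    pa_ <- per_sample$prop[per_sample$gene == g &
                             per_sample$stage == "adult"]
    jm <- if (length(pj)) mean(pj) else NA_real_
    am <- if (length(pa_)) mean(pa_) else NA_real_
    shift <- if (is.na(jm) || is.na(am)) NA_real_ else abs(am - jm)
    tt <- if (length(pj) >= 2 && length(pa_) >= 2 &&
              stats::sd(asin(sqrt(c(pj, pa_)))) > 0)
      oracle_welch(asin(sqrt(pa_)), asin(sqrt(pj)))
    else list(t = NA_real_, p = NA_real_)
    data.frame(gene = g, juv_mean = jm, adult_mean = am,
               balance_juv = classify(jm), balance_adult = classify(am),
               shift_mag = shift,
               shift_flag = if (is.na(shift)) NA else
                 shift > shift_threshold,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Default-condition recovery bundle (200 genes, depth 50, rho 0.1,
# 5 hybrids/stage), built once per run and shared between the
# parameter-recovery tests.
recovery_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 200, seed = 1)
      sim <- simulate_parental_genotypes(cfg)
      al <- simulate_hybrid_allelic_counts(sim$sites, sim$truth, cfg)
      dir <- file.path(tempdir(), "eodase-recovery-bundle")
      paths <- write_fixture_bundle(sim, dir, allelic = al)
      fit <- run_ase(paths$vcf, sim$sheet, sim$site_gene)
      cache <<- list(cfg = cfg, sim = sim, allelic = al, paths = paths,
                     fit = fit)
    }
    cache
  }
})

# Small simulated ASE bundle shared by several tests (built once per run).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 30, snps_per_gene_mean = 4, seed = 42)
      sim <- simulate_parental_genotypes(cfg)
      al <- simulate_hybrid_allelic_counts(sim$sites, sim$truth, cfg)
      dir <- file.path(tempdir(), "eodase-small-bundle")
      paths <- write_fixture_bundle(sim, dir, allelic = al)
      cache <<- list(cfg = cfg, sim = sim, allelic = al, paths = paths)
    }
    cache
  }
})
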