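# End-to-end orchestration: a serializable run configuration holding
# every stage threshold, and run_all(), which executes the expression,
# DEG-set and ASE stages against a set of input files and writes a
# deterministic report.

#' Build a run configuration
#'
#' Single home for every pipeline threshold, serializable to YAML and
#' round-trippable, so a run is fully described by one file.
#'
#' @param vcf,sample_sheet,site_gene_map,counts Input file paths (the ASE
#'   arm needs the first three; the expression arm needs `counts` plus a
#'   sheet covering its samples).
#' @param expr_sample_sheet Optional separate sheet for the expression
#'   arm; defaults to `sample_sheet`.
#' @param list_iv,list_v Optional paths to external evidence gene lists
#'   (one id per line).
#' @param annotation Optional path to a two-column gene/term TSV for
#'   enrichment.
#' @param out_dir Output directory.
#' @param qual_min,depth_min,band,shift_threshold ASE parameters.
#' @param lfc_threshold,p_threshold Pairwise-DE thresholds.
#' @param lrt_alpha Adjusted-p cutoff for LRT-significant genes.
#' @param k Number of pattern clusters.
#' @param min_evidence Candidate-triage evidence threshold.
#' @param seed Integer seed recorded in the report.
#' @return Object of class `run_config`.
#' @export
run_config <- function(vcf = NULL, sample_sheet = NULL,
                       site_gene_map = NULL, counts = NULL,
                       expr_sample_sheet = NULL,
                       list_iv = NULL, list_v = NULL, annotation = NULL,
                       out_dir = "eodase_out",
                       qual_min = 70, depth_min = 10L,
                       band = c(0.45, 0.55), shift_threshold = 0.1,
                       lfc_threshold = 1, p_threshold = 0.05,
                       lrt_alpha = 0.05, k = 14L, min_evidence = 3L,
                       seed = 1L) {
  cfg <- list(vcf = vcf, sample_sheet = sample_sheet,
              site_gene_map = site_gene_map, counts = counts,
              expr_sample_sheet = expr_sample_sheet,
              list_iv = list_iv, list_v = list_v, annotation = annotation,
              out_dir = out_dir, qual_min = qual_min,
              depth_min = as.integer(depth_min), band = as.numeric(band),
              shift_threshold = shift_threshold,
              lfc_threshold = lfc_threshold, p_threshold = p_threshold,
              lrt_alpha = lrt_alpha, k = as.integer(k),
              min_evidence = as.integer(min_evidence),
              seed = as.integer(seed))
  if (cfg$qual_min < 0 || cfg$depth_min < 0)
    stop("qual_min and depth_min must be non-negative")
  if (length(cfg$band) != 2L || cfg$band[1] > cfg$band[2] ||
      cfg$band[1] < 0 || cfg$band[2] > 1)
    stop("band must be an increasing pair within [0, 1]")
  if (cfg$shift_threshold < 0 || cfg$shift_threshold > 1)
    stop("shift_threshold must lie in [0, 1]")
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1 ||
      cfg$lrt_alpha <= 0 || cfg$lrt_alpha > 1)
    stop("p thresholds must lie in (0, 1]")
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Executes expression stages (low-count filter, size factors, PCA, LRT
#' against EOD duration, pattern clustering), DEG-set stages (pairwise DE
#' per cohort, Venn sets, triage, optional enrichment) and the ASE arm,
#' writing per-stage TSVs and a plain-text report of every count the run
#' produced. Reruns with the same configuration and inputs are
#' byte-identical.
#'
#' @param cfg A [run_config()].
#' @return The report, as a named list, invisibly. Files are written
#'   under `cfg$out_dir`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed)
  set.seed(cfg$seed)

  # --- expression arm ---
  expr_done <- !is.null(cfg$counts)
  if (expr_done) {
    sheet <- read_sample_sheet(
      if (is.null(cfg$expr_sample_sheet)) cfg$sample_sheet
      else cfg$expr_sample_sheet)
    counts <- read_counts(cfg$counts)
    esheet <- sheet[sheet$sample %in% colnames(counts), , drop = FALSE]
    study <- expression_study(counts, esheet)
    n0 <- nrow(study$counts)
    study <- filter_low_counts(study)
    report$genes_input <- n0
    report$genes_after_low_count_filter <- nrow(study$counts)
    study <- size_factors(study, pseudo_reference = TRUE)
    pca <- pca_expression(study)
    write_tsv(data.frame(sample = rownames(pca$scores),
                         round(pca$scores[, seq_len(min(5,
                           ncol(pca$scores))), drop = FALSE], 6)),
              file.path(cfg$out_dir, "pca_scores.tsv"))
    report$pc1_var_pct <- round(100 * pca$var_explained[1], 2)

    lrt <- lrt_duration(study)
    write_tsv(as.data.frame(lrt), file.path(cfg$out_dir,
                                            "lrt_results.tsv"))
    sig <- lrt$gene[!is.na(lrt$padj) & lrt$padj < cfg$lrt_alpha]
    report$lrt_significant <- length(sig)

    patterns <- NULL
    if (length(sig) >= max(2L, cfg$k)) {
      patterns <- cluster_patterns(study, sig, k = cfg$k)
      write_tsv(as.data.frame(patterns),
                file.path(cfg$out_dir, "clusters.tsv"))
      cs <- attr(patterns, "cluster_summary")
      report$clusters_increasing <- sum(cs$direction == "increasing")
      report$clusters_decreasing <- sum(cs$direction == "decreasing")
      report$genes_monotone <- sum(patterns$direction %in%
                                     c("increasing", "decreasing"))
    }

    de <- lapply(c(parentA = "parentA", parentB = "parentB",
                   hybrid = "hybrid"), function(ch)
      pairwise_de(study, ch, lfc_threshold = cfg$lfc_threshold,
                  p_threshold = cfg$p_threshold))
    for (ch in names(de))
      write_tsv(as.data.frame(de[[ch]]),
                file.path(cfg$out_dir, paste0("de_", ch, ".tsv")))
    flags <- lapply(de, function(d) stats::setNames(d$deg, d$gene))
    vs <- venn_sets(flags$parentA, flags$parentB, flags$hybrid)
    report$deg_parentA <- sum(flags$parentA)
    report$deg_parentB <- sum(flags$parentB)
    report$deg_hybrid <- sum(flags$hybrid)
    report$setA <- vs$counts[["A"]]
    report$setB <- vs$counts[["B"]]
    report$setC <- vs$counts[["C"]]
    write_tsv(data.frame(
      gene = c(vs$A, vs$B, vs$C),
      set = rep(c("A", "B", "C"), c(length(vs$A), length(vs$B),
                                    length(vs$C)))),
      file.path(cfg$out_dir, "venn_sets.tsv"))

    if (!is.null(patterns)) {
      l4 <- if (!is.null(cfg$list_iv)) readLines(cfg$list_iv)
            else character()
      l5 <- if (!is.null(cfg$list_v)) readLines(cfg$list_v)
            else character()
      ledger <- triage(patterns, vs$A, vs$B, vs$C, l4, l5,
                       min_evidence = cfg$min_evidence)
      write_tsv(as.data.frame(ledger),
                file.path(cfg$out_dir, "candidate_ledger.tsv"))
      report$candidates <- sum(ledger$candidate)
      if (!is.null(cfg$annotation)) {
        ann <- read_table_auto(cfg$annotation)
        enr <- fisher_enrichment(ledger$gene[ledger$candidate],
                                 rownames(study$counts), ann)
        write_tsv(enr, file.path(cfg$out_dir, "enrichment.tsv"))
        report$enriched_terms_p05 <- sum(enr$p < 0.05)
      }
    }
  }

  # --- ASE arm ---
  if (!is.null(cfg$vcf)) {
    fit <- run_ase(cfg$vcf, cfg$sample_sheet, cfg$site_gene_map,
                   qual_min = cfg$qual_min, depth_min = cfg$depth_min,
                   band = cfg$band, shift_threshold = cfg$shift_threshold)
    g <- fit$genes
    g$juv_mean <- round(g$juv_mean, 6)
    g$adult_mean <- round(g$adult_mean, 6)
    g$shift_mag <- round(g$shift_mag, 6)
    g$t <- round(g$t, 6); g$p <- signif(g$p, 6)
    write_tsv(g, file.path(cfg$out_dir, "ase_genes.tsv"))
    s <- fit$summary
    write_tsv(data.frame(stage = rep(c("juvenile", "adult"), each = 3),
                         class = rep(names(s$class_counts_juv), 2),
                         n = c(as.integer(s$class_counts_juv),
                               as.integer(s$class_counts_adult))),
              file.path(cfg$out_dir, "ase_class_counts.tsv"))
    report$ase_sites_total <- s$n_sites_total
    report$ase_fixed_sites <- s$n_fixed_sites
    report$ase_genes <- s$n_genes
    report$ase_dropped_missing_ad <- unname(s$drops[["missing_ad"]])
    report$ase_dropped_low_depth <- unname(s$drops[["low_depth"]])
    report$ase_balanced_juv <-
      unname(s$class_counts_juv[["balanced"]])
    report$ase_balanced_adult <-
      unname(s$class_counts_adult[["balanced"]])
    report$ase_shifted_genes <- length(s$shifted_genes)
    writeLines(s$shifted_genes,
               file.path(cfg$out_dir, "shifted_genes.txt"))
  }

  lines <- vapply(names(report), function(k)
    paste0(k, "\t", format(report[[k]], scientific = FALSE)), "")
  writeLines(lines, file.path(cfg$out_dir, "report.tsv"))
  invisible(report)
}
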