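# DEG-set stages: pairwise adult-vs-juvenile differential expression
# (NB Wald stand-in or pass-through of an external table), Venn set A/B/C
# construction, five-list candidate triage, and Fisher's exact enrichment
# against a user-supplied annotation.

#' Pairwise adult-versus-juvenile differential expression within a cohort
#'
#' A self-contained NB Wald stand-in: per gene, a two-group
#' negative-binomial GLM (stage contrast, size-factor offsets, shared
#' method-of-moments dispersion) gives the p-value; the reported log2
#' fold change (adult over juvenile) comes from the normalized stage
#' means, with a pseudo-mean of `eps` added to zero-mean groups so it is
#' always finite. A gene is flagged as a DEG iff `|log2FC| >` the fold
#' threshold and `p <` the p threshold (raw p-values by default, as in
#' the emulated workflow; BH-adjusted flags are available).
#'
#' @param study An `expression_study`.
#' @param cohort Cohort to contrast (`parentA`, `parentB` or `hybrid`).
#' @param lfc_threshold,p_threshold DEG thresholds (defaults 1 and 0.05).
#' @param eps Pseudo-mean added to a zero stage mean (default 0.5).
#' @param use_padj Apply the thresholds to BH-adjusted p-values.
#' @return Object of class `de_result` (data frame): `gene`, `log2fc`,
#'   `p`, `padj`, `deg`.
#' @export
pairwise_de <- function(study, cohort, lfc_threshold = 1,
                        p_threshold = 0.05, eps = 0.5, use_padj = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  sub <- study$sheet[study$sheet$cohort == cohort, , drop = FALSE]
  if (!all(c("juvenile", "adult") %in% sub$stage) ||
      min(table(sub$stage)) < 2L)
    stop("cohort '", cohort, "' needs >= 2 samples in each stage")
  sstudy <- expression_study(study$counts[, sub$sample, drop = FALSE], sub)
  sstudy <- size_factors(sstudy, pseudo_reference = TRUE)
  norm <- normalized_counts(sstudy)
  stage <- factor(sub$stage, levels = c("juvenile", "adult"))
  off <- log(sstudy$size_factors)
  m_juv <- rowMeans(norm[, stage == "juvenile", drop = FALSE])
  m_adu <- rowMeans(norm[, stage == "adult", drop = FALSE])
  log2fc <- log2(ifelse(m_adu == 0, eps, m_adu) /
                 ifelse(m_juv == 0, eps, m_juv))
  p <- vapply(seq_len(nrow(norm)), function(i) {
    y <- sstudy$counts[i, ]
    tryCatch(suppressWarnings({
      pois <- stats::glm(y ~ stage + offset(off),
                         family = stats::poisson())
      alpha <- mom_dispersion(y, stats::fitted(pois), 2L)
      fam <- MASS::negative.binomial(theta = 1 / alpha)
      fit <- stats::glm(y ~ stage + offset(off), family = fam)
      stats::coef(summary(fit))["stageadult", 4]
    }), error = function(e) NA_real_)
  }, 1)
  out <- data.frame(gene = rownames(study$counts), log2fc = log2fc,
                    p = p, padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  pv <- if (use_padj) out$padj else out$p
  out$deg <- !is.na(pv) & abs(out$log2fc) > lfc_threshold &
    pv < p_threshold
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  attr(out, "cohort") <- cohort
  attr(out, "thresholds") <- c(lfc = lfc_threshold, p = p_threshold)
  out
}

#' Recompute DEG flags from an externally computed DE table
#'
#' Pass-through contract for DE results computed elsewhere: the table
#' must carry `gene`, `log2fc` and `p` columns; flags are recomputed from
#' those columns with the same thresholds as [pairwise_de()].
#'
#' @param tab Data frame with `gene`, `log2fc`, `p` (and optionally
#'   `padj`).
#' @param lfc_threshold,p_threshold,use_padj As in [pairwise_de()].
#' @return A `de_result` with recomputed `deg` flags.
#' @export
de_from_table <- function(tab, lfc_threshold = 1, p_threshold = 0.05,
                          use_padj = FALSE) {
  need <- c("gene", "log2fc", "p")
  if (!all(need %in% names(tab)))
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  if (is.null(tab$padj)) tab$padj <- stats::p.adjust(tab$p, method = "BH")
  pv <- if (use_padj) tab$padj else tab$p
  tab$deg <- !is.na(pv) & abs(tab$log2fc) > lfc_threshold &
    pv < p_threshold
  class(tab) <- c("de_result", "data.frame")
  attr(tab, "thresholds") <- c(lfc = lfc_threshold, p = p_threshold)
  tab
}

#' @export
print.de_result <- function(x, ...) {
  cat("Adult-vs-juvenile DE:", nrow(x), "genes,", sum(x$deg), "DEGs\n")
  invisible(x)
}

#' Venn sets A, B and C of adult-versus-juvenile DEGs
#'
#' Given DEG flags over a common gene universe for the EOD-constant
#' species (com), the EOD-elongating species (rhy) and the hybrid:
#' set A = DEGs shared by rhy and the hybrid but not com (EOD change
#' during ontogeny), set B = DEGs unique to com (EOD constancy), set C =
#' DEGs shared by all three (general electric-organ development). The
#' three sets are pairwise disjoint by construction.
#'
#' @param com,rhy,hybrid Named logical DEG-flag vectors over the same
#'   gene universe (names are gene ids).
#' @return List with character vectors `A`, `B`, `C` (sorted) and a
#'   `counts` vector.
#' @export
venn_sets <- function(com, rhy, hybrid) {
  u <- names(com)
  if (is.null(u) || is.null(names(rhy)) || is.null(names(hybrid)) ||
      !setequal(u, names(rhy)) || !setequal(u, names(hybrid)))
    stop("DEG flag vectors must share one named gene universe")
  rhy <- rhy[u]; hybrid <- hybrid[u]
  A <- sort(u[rhy & hybrid & !com])
  B <- sort(u[com & !rhy & !hybrid])
  C <- sort(u[com & rhy & hybrid])
  list(A = A, B = B, C = C,
       counts = c(A = length(A), B = length(B), C = length(C)))
}

#' Candidate triage across the five evidence lists
#'
#' For every gene in a monotone (increasing or decreasing) expression
#' cluster, membership is recorded in the five evidence lists — Venn sets
#' A, B and C, the adult-EO-upregulated list (iv) and the EOD-duration
#' candidate list (v) — and a gene is called a candidate when its
#' evidence count reaches `min_evidence` (default 3).
#'
#' @param patterns A `pattern_result` (or data frame with `gene` and
#'   `direction`).
#' @param setA,setB,setC Character vectors of gene ids (e.g. from
#'   [venn_sets()]).
#' @param list_iv,list_v External evidence lists (gene-id vectors; the
#'   emulated workflow takes these from a prior adult-stage study).
#' @param min_evidence Evidence count required for the candidate flag.
#' @return Object of class `candidate_ledger` (data frame) ordered by
#'   evidence count (descending) then gene id: per-list membership flags,
#'   `direction`, `evidence` and `candidate`.
#' @export
triage <- function(patterns, setA, setB, setC, list_iv = character(),
                   list_v = character(), min_evidence = 3L) {
  monotone <- patterns$direction %in% c("increasing", "decreasing")
  genes <- sort(unique(patterns$gene[monotone]))
  out <- data.frame(gene = genes,
                    direction = patterns$direction[match(genes,
                                                         patterns$gene)],
                    in_setA = genes %in% setA,
                    in_setB = genes %in% setB,
                    in_setC = genes %in% setC,
                    in_list_iv = genes %in% list_iv,
                    in_list_v = genes %in% list_v,
                    stringsAsFactors = FALSE)
  out$evidence <- rowSums(out[, c("in_setA", "in_setB", "in_setC",
                                  "in_list_iv", "in_list_v")])
  out$candidate <- out$evidence >= min_evidence
  out <- out[order(-out$evidence, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_ledger", "data.frame")
  attr(out, "min_evidence") <- min_evidence
  out
}

#' @export
print.candidate_ledger <- function(x, ...) {
  cat("Candidate triage:", nrow(x), "clustered monotone genes,",
      sum(x$candidate), "candidate(s) with evidence >=",
      attr(x, "min_evidence"), "\n")
  invisible(x)
}

# Two-sided Fisher exact p for one 2x2 table (hypergeometric summation,
# via stats::fisher.test).
fisher_p_2x2 <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2L), alternative =
                       "two.sided")$p.value
}

#' Fisher's exact enrichment of a gene set against an annotation
#'
#' Per annotation term, a 2x2 table of set membership against term
#' membership over the background is tested with a two-sided Fisher exact
#' test. Terms annotating no background gene are skipped and counted.
#'
#' @param genes Gene set (must be a subset of `background`).
#' @param background Background gene universe.
#' @param annotation Data frame with columns `gene` and `term`.
#' @return Data frame per term: `term`, `n_set`, `n_term`, `odds_ratio`,
#'   `p`; attribute `n_skipped_terms`.
#' @export
fisher_enrichment <- function(genes, background, annotation) {
  if (!all(genes %in% background))
    stop("gene set must be a subset of the background")
  if (!all(c("gene", "term") %in% names(annotation)))
    stop("annotation needs columns 'gene' and 'term'")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  skipped <- setdiff(unique(annotation$term), unique(ann$term))
  terms <- sort(unique(ann$term))
  genes <- unique(genes)
  background <- unique(background)
  out <- do.call(rbind, lapply(terms, function(tm) {
    tg <- unique(ann$gene[ann$term == tm])
    a <- sum(genes %in% tg)
    b <- length(genes) - a
    c <- length(setdiff(tg, genes))
    d <- length(background) - a - b - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2L))
    data.frame(term = tm, n_set = a, n_term = length(tg),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(term = character(), n_set = integer(),
                      n_term = integer(), odds_ratio = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped_terms") <- length(skipped)
  out
}
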