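# Expression-side stages: low-count filtering, median-of-ratios size
# factors, covariance PCA on log counts, the negative-binomial
# likelihood-ratio test of association with EOD duration, and monotone
# expression-pattern clustering. The LRT and the clustering are documented
# stand-ins written in-package (shared method-of-moments dispersion per
# gene, z-score profiles + hierarchical clustering), not wrappers around
# an external DE engine.

#' Bundle a count matrix with its sample metadata
#'
#' @param counts Non-negative integer matrix, genes in rows; column names
#'   must match the sheet's sample ids (any order; columns are reordered
#'   to the sheet).
#' @param sheet Sample sheet (`sample`, `cohort`, `stage`, `duration_ms`).
#' @return Object of class `expression_study` with elements `counts`,
#'   `sheet` and (once computed) `size_factors`.
#' @export
expression_study <- function(counts, sheet) {
  validate_sample_sheet(sheet)
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), sheet$sample))
    stop("count matrix columns must match sample sheet ids")
  counts <- counts[, sheet$sample, drop = FALSE]
  if (any(counts < 0)) stop("negative counts")
  structure(list(counts = counts, sheet = sheet, size_factors = NULL),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples;",
      if (is.null(x$size_factors)) "size factors not yet computed"
      else "normalized", "\n")
  invisible(x)
}

#' Remove low-count genes
#'
#' Keeps a gene iff its count exceeds `min_count` in at least
#' `min_samples` samples (the "low count (<= 10) in fewer than two
#' replicates" cleaning rule).
#'
#' @param study An `expression_study`.
#' @param min_count Count that must be exceeded (strictly).
#' @param min_samples Minimum number of samples exceeding it.
#' @return The filtered study.
#' @export
filter_low_counts <- function(study, min_count = 10L, min_samples = 2L) {
  stopifnot(inherits(study, "expression_study"))
  keep <- rowSums(study$counts > min_count) >= min_samples
  study$counts <- study$counts[keep, , drop = FALSE]
  study$size_factors <- NULL
  study
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over reference genes of the ratio between the
#' sample's count and the gene's geometric mean across samples; factors
#' are rescaled to geometric mean 1. Reference genes are those with
#' strictly positive counts in every sample; with none, the
#' `pseudo_reference` fallback uses genes whose geometric mean over the
#' positive samples is positive (zeros ignored).
#'
#' Scaling one library by a constant multiplies its factor *relative to
#' every other sample's* by exactly that constant; the absolute factors
#' move only up to the overall geometric-mean convention.
#'
#' @param study An `expression_study`.
#' @param pseudo_reference Enable the zero-tolerant fallback reference.
#' @return The study with `size_factors` filled (positive, geometric
#'   mean 1).
#' @export
size_factors <- function(study, pseudo_reference = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$counts
  if (pseudo_reference) {
    logref <- apply(m, 1L, function(r) {
      pos <- r > 0
      if (!any(pos)) -Inf else mean(log(r[pos]))
    })
    use <- is.finite(logref)
  } else {
    use <- rowSums(m > 0) == ncol(m)
    if (!any(use))
      stop("no gene with positive counts in all samples; ",
           "set pseudo_reference = TRUE to use a zero-tolerant reference")
    logref <- rowMeans(log(m[use, , drop = FALSE]))
    logref <- replace(rep(-Inf, nrow(m)), which(use), logref)
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    r <- m[use, j] / exp(logref[use])
    r <- r[is.finite(r) & r > 0]
    if (!length(r)) stop("sample ", colnames(m)[j],
                         " shares no positive gene with the reference")
    stats::median(r)
  }, 1)
  f <- f / exp(mean(log(f)))
  study$size_factors <- stats::setNames(f, colnames(m))
  study
}

normalized_counts <- function(study) {
  if (is.null(study$size_factors)) study <- size_factors(study)
  sweep(study$counts, 2L, study$size_factors, "/")
}

#' Covariance PCA of log-transformed normalized counts
#'
#' Computes `log2(normalized count + offset)`, centers each gene across
#' samples, and eigen-decomposes the sample-space covariance (no
#' per-gene variance scaling). Sample scores and the fraction of variance
#' per component are returned.
#'
#' @param study An `expression_study` (size factors computed on demand).
#' @param log_offset Pseudo-count added before the log (default 1).
#' @return Object of class `expr_pca`: `scores` (samples by components),
#'   `var_explained` (fractions summing to 1), `rotation`, `sdev`.
#' @export
pca_expression <- function(study, log_offset = 1) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$counts) < 2L) stop("PCA needs at least 2 samples")
  lm2 <- log2(normalized_counts(study) + log_offset)
  centered <- lm2 - rowMeans(lm2)
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  structure(list(scores = pc$x,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 rotation = pc$rotation, sdev = pc$sdev,
                 centered = t(centered)),
            class = "expr_pca")
}

#' @export
print.expr_pca <- function(x, ...) {
  ve <- round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))])
  cat("Covariance PCA:", nrow(x$scores), "samples;",
      paste0("PC", seq_along(ve), " ", ve, "%", collapse = ", "), "\n")
  invisible(x)
}

# Per-gene NB fit machinery -------------------------------------------------

# Moment dispersion: alpha solving the Pearson chi-square matching
# equation sum((y-mu)^2 / (mu + alpha*mu^2)) = n - k, where k is the
# number of fitted mean parameters. Accounts for the residual degrees of
# freedom, unlike the naive (y-mu)^2 moment estimator, which is biased
# low when mu is fitted to the same data. Floored at 1e-8.
mom_dispersion <- function(y, mu, k = 1L, floor = 1e-8) {
  if (sum(mu^2) <= 0) return(floor)
  f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - (length(y) - k)
  if (!is.finite(f(floor)) || f(floor) <= 0) return(floor)
  tryCatch(stats::uniroot(f, c(floor, 100), extendInt = "downX")$root,
           error = function(e) floor)
}

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

#' Likelihood-ratio test of association with EOD duration
#'
#' Per gene, negative-binomial GLMs (log link, size-factor offsets) are
#' fitted for a full model with intercept plus `log10(duration)` and an
#' intercept-only reduced model, using one shared dispersion per gene
#' estimated by moments (Pearson chi-square matching with residual
#' degrees of freedom) under the full model, floored at `1e-8`. The
#' statistic is twice the log-likelihood difference. Because the
#' dispersion is estimated from the same few samples, the statistic is
#' referred by default to an F distribution with the residual degrees of
#' freedom in the denominator (quasi-likelihood style), which keeps the
#' test calibrated at small n; the asymptotic chi-squared reference is
#' available via `ref = "chisq"`. BH adjustment across genes. This is a
#' self-contained stand-in for a full DE engine: no dispersion shrinkage
#' across genes is attempted.
#'
#' @param study An `expression_study` with at least 3 distinct durations.
#' @param duration_factor Treat duration as an unordered factor instead
#'   of a numeric log10 covariate (df = number of levels - 1).
#' @param ref Null reference for the statistic: `"f"` (default,
#'   `stat/df ~ F(df, n - p)`) or `"chisq"` (`stat ~ chi-squared(df)`).
#' @return Object of class `lrt_result` (a data frame): `gene`, `slope`
#'   (log2 fold change per duration decade; `NA` in factor mode), `stat`,
#'   `df`, `p`, `padj`, `dispersion`.
#' @export
lrt_duration <- function(study, duration_factor = FALSE,
                         ref = c("f", "chisq")) {
  stopifnot(inherits(study, "expression_study"))
  ref <- match.arg(ref)
  dur <- study$sheet$duration_ms
  if (length(unique(dur)) < 3L)
    stop("need >= 3 distinct EOD durations")
  if (is.null(study$size_factors)) study <- size_factors(study)
  off <- log(study$size_factors)
  x <- if (duration_factor) factor(dur) else log10(dur)
  k_full <- if (duration_factor) nlevels(factor(dur)) else 2L
  df_test <- k_full - 1L
  m <- study$counts
  n <- ncol(m)
  res <- t(vapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    tryCatch(suppressWarnings({
      pois <- stats::glm(y ~ x + offset(off), family = stats::poisson())
      alpha <- mom_dispersion(y, stats::fitted(pois), k_full)
      fam <- MASS::negative.binomial(theta = 1 / alpha)
      full <- stats::glm(y ~ x + offset(off), family = fam)
      alpha <- mom_dispersion(y, stats::fitted(full), k_full)
      fam <- MASS::negative.binomial(theta = 1 / alpha)
      full <- stats::glm(y ~ x + offset(off), family = fam)
      red <- stats::glm(y ~ 1 + offset(off), family = fam)
      ll_full <- nb_loglik(y, stats::fitted(full), alpha)
      ll_red <- nb_loglik(y, stats::fitted(red), alpha)
      stat <- max(0, 2 * (ll_full - ll_red))
      slope <- if (duration_factor) NA_real_ else
        unname(stats::coef(full)[2]) / log(2)
      c(slope, stat, alpha)
    }), error = function(e) c(NA_real_, NA_real_, NA_real_))
  }, numeric(3)))
  out <- data.frame(gene = rownames(m), slope = res[, 1], stat = res[, 2],
                    df = df_test, dispersion = res[, 3],
                    stringsAsFactors = FALSE)
  out$p <- if (ref == "f")
    stats::pf(out$stat / df_test, df_test, n - k_full, lower.tail = FALSE)
  else
    stats::pchisq(out$stat, df = df_test, lower.tail = FALSE)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("lrt_result", "data.frame")
  out
}

#' @export
print.lrt_result <- function(x, alpha = 0.05, ...) {
  cat("NB likelihood-ratio test vs EOD duration:", nrow(x), "genes;",
      sum(x$padj < alpha, na.rm = TRUE),
      sprintf("with adjusted p < %.2g\n", alpha))
  invisible(x)
}

#' Cluster expression patterns across conditions
#'
#' For the selected genes, mean `log2(normalized count + offset)` is
#' computed per cohort-stage condition and z-scored across conditions per
#' gene. Genes are clustered hierarchically (correlation distance,
#' average linkage) and the tree is cut into `k` groups. Each group gets
#' a direction label from the Spearman correlation between its medoid
#' profile and the conditions' EOD durations: `increasing` at >= +0.8,
#' `decreasing` at <= -0.8, otherwise `non-monotone`. Group numbering is
#' arbitrary (tree order), so only the direction labels are meaningful
#' across runs.
#'
#' @param study An `expression_study`.
#' @param genes Gene ids to cluster (typically LRT-significant genes).
#' @param k Number of groups to cut the tree into (default 14).
#' @param cor_threshold Absolute Spearman threshold for a monotone label.
#' @param log_offset Pseudo-count for the log transform.
#' @return Object of class `pattern_result`: data frame `gene`,
#'   `cluster`, `direction`; attributes `cluster_summary` (size, Spearman
#'   rho, direction per cluster), `profiles` (gene-by-condition z-scores)
#'   and `condition_duration`.
#' @export
cluster_patterns <- function(study, genes, k = 14L, cor_threshold = 0.8,
                             log_offset = 1) {
  stopifnot(inherits(study, "expression_study"))
  genes <- intersect(genes, rownames(study$counts))
  if (length(genes) < 2L) stop("need >= 2 genes to cluster")
  if (k > length(genes))
    stop("k (", k, ") exceeds the number of genes (", length(genes), ")")
  lm2 <- log2(normalized_counts(study)[genes, , drop = FALSE] + log_offset)
  cond <- interaction(study$sheet$cohort, study$sheet$stage, drop = TRUE)
  prof <- t(apply(lm2, 1L, function(r) tapply(r, cond, mean)))
  cond_dur <- tapply(study$sheet$duration_ms, cond, mean)
  z <- t(apply(prof, 1L, function(r) {
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(prof)
  cm <- suppressWarnings(stats::cor(t(z)))
  cm[!is.finite(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  dmat <- as.matrix(d)
  clusters <- sort(unique(cl))
  summary <- do.call(rbind, lapply(clusters, function(g) {
    idx <- which(cl == g)
    medoid <- idx[which.min(colSums(dmat[idx, idx, drop = FALSE]))]
    rho <- suppressWarnings(
      stats::cor(z[medoid, ], cond_dur, method = "spearman"))
    dir <- if (is.na(rho)) "non-monotone"
      else if (rho >= cor_threshold) "increasing"
      else if (rho <= -cor_threshold) "decreasing"
      else "non-monotone"
    data.frame(cluster = g, size = length(idx), rho = rho,
               direction = dir, stringsAsFactors = FALSE)
  }))
  out <- data.frame(gene = genes, cluster = unname(cl),
                    direction = summary$direction[match(cl,
                                                        summary$cluster)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cluster_summary") <- summary
  attr(out, "profiles") <- z
  attr(out, "condition_duration") <- cond_dur
  class(out) <- c("pattern_result", "data.frame")
  out
}

#' @export
print.pattern_result <- function(x, ...) {
  s <- attr(x, "cluster_summary")
  cat("Expression-pattern clustering:", nrow(x), "genes in", nrow(s),
      "groups;", sum(s$direction == "increasing"), "increasing,",
      sum(s$direction == "decreasing"), "decreasing group(s)\n")
  invisible(x)
}
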