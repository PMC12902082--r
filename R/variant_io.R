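# Readers/writers for the standard formats the pipeline touches: VCF v4.2
# (via vcfR), TSV count matrices, sample sheets and site-to-gene maps.
# Everything is normalized into the internal data model used by the ASE
# and expression stages.

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Read a VCF into the internal site model
#'
#' Parses a VCF v4.2 (plain or gzipped) with `GT` and `AD` FORMAT fields.
#' Multi-allelic records and indels are skipped and counted. Missing `AD`
#' entries are recorded as missing observations (`NA`), never as zero
#' depth, so they cannot silently pass or fail depth filters downstream.
#'
#' @param path VCF file path.
#' @param sample_sheet Optional sample sheet; every sample listed there
#'   must be present in the VCF header, otherwise an error names the
#'   offenders.
#' @return An object of class `vcf_sites`: `sites` (data frame `chrom`,
#'   `pos` 1-based, `ref`, `alt`, `qual`), genotype matrix `gt` coded as
#'   `hom_ref`/`het`/`hom_alt`/`missing`, integer matrices `ref_depth` and
#'   `alt_depth`, and `n_skipped` (multi-allelic or indel records).
#' @export
read_vcf <- function(path, sample_sheet = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)        # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  n_skipped <- sum(!keep)
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ad_raw <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  if (!is.null(sample_sheet)) {
    missing <- setdiff(sample_sheet$sample, colnames(gt_raw))
    if (length(missing))
      stop("sample sheet entries absent from VCF: ",
           paste(missing, collapse = ", "))
  }

  code_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep("missing", length(g))
    out[g %in% "0/0"] <- "hom_ref"
    out[g %in% c("0/1", "1/0")] <- "het"
    out[g %in% "1/1"] <- "hom_alt"
    out
  }
  gt <- matrix(code_gt(gt_raw), nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))

  parse_ad <- function(x, field) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & x != "." & grepl(",", x, fixed = TRUE)
    parts <- strsplit(x[ok], ",", fixed = TRUE)
    val <- vapply(parts, function(p) {
      p <- p[field]
      if (is.na(p) || p == ".") NA_integer_ else as.integer(p)
    }, 1L)
    out[ok] <- val
    out
  }
  ref_depth <- matrix(parse_ad(ad_raw, 1L), nrow(ad_raw), ncol(ad_raw),
                      dimnames = dimnames(ad_raw))
  alt_depth <- matrix(parse_ad(ad_raw, 2L), nrow(ad_raw), ncol(ad_raw),
                      dimnames = dimnames(ad_raw))

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      qual = as.numeric(fix$QUAL), stringsAsFactors = FALSE)
  if (any(!is.finite(sites$pos)) || any(sites$pos < 1L))
    stop("malformed VCF: POS must be a 1-based integer")
  ord <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[ord, , drop = FALSE],
                 gt = gt[ord, , drop = FALSE],
                 ref_depth = ref_depth[ord, , drop = FALSE],
                 alt_depth = alt_depth[ord, , drop = FALSE],
                 n_skipped = n_skipped),
            class = "vcf_sites")
}

#' @export
print.vcf_sites <- function(x, ...) {
  cat("VCF sites:", nrow(x$sites), "biallelic SNVs,",
      ncol(x$gt), "samples,", x$n_skipped,
      "record(s) skipped (multi-allelic/indel)\n")
  invisible(x)
}

#' Read a gene-by-sample count matrix
#'
#' Expects a TSV/CSV with a header row; the first column holds gene ids.
#' Counts must be non-negative and integer-valued; duplicate gene ids are
#' an error. Rows are returned in sorted gene order.
#'
#' @param path File path (gzip accepted); comma or tab separated.
#' @return Integer matrix, genes in rows.
#' @export
read_counts <- function(path) {
  tab <- read_table_auto(path)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("counts must be finite numbers")
  if (any(m < 0)) stop("negative count encountered")
  if (any(abs(m - round(m)) > 1e-8)) stop("counts must be integer-valued")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m[order(ids), , drop = FALSE]
}

#' Read a site-to-gene assignment table
#'
#' TSV with columns `chrom`, `pos`, `gene`. A site assigned to more than
#' one gene is an error by default because per-gene proportion averaging
#' is ill-defined under double counting; `allow_multi = TRUE` keeps the
#' duplicates with a warning.
#'
#' @param path File path.
#' @param allow_multi Keep sites mapping to several genes (with warning).
#' @return Data frame `chrom`, `pos`, `gene`, sorted by site.
#' @export
read_site_gene_map <- function(path, allow_multi = FALSE) {
  tab <- read_table_auto(path)
  need <- c("chrom", "pos", "gene")
  if (!all(need %in% names(tab)))
    stop("site-gene map needs columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  tab$pos <- as.integer(tab$pos)
  key <- paste(tab$chrom, tab$pos)
  multi <- unique(key[duplicated(key)])
  if (length(multi)) {
    if (!allow_multi)
      stop("site(s) assigned to more than one gene: ",
           paste(utils::head(multi, 5), collapse = "; "))
    warning(length(multi), " site(s) map to multiple genes; keeping all")
  }
  tab[order(tab$chrom, tab$pos, tab$gene), , drop = FALSE]
}

#' Read a sample sheet
#'
#' TSV with columns `sample`, `cohort` (`parentA`, `parentB`, `hybrid`),
#' `stage` and `duration_ms`. Ids must be unique, every hybrid sample must
#' carry a stage, and durations must be positive.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- read_table_auto(path)
  need <- c("sample", "cohort", "stage", "duration_ms")
  if (!all(need %in% names(tab)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  validate_sample_sheet(tab)
  tab
}

validate_sample_sheet <- function(tab) {
  if (anyDuplicated(tab$sample))
    stop("duplicate sample id(s) in sheet")
  bad <- setdiff(unique(tab$cohort), c("parentA", "parentB", "hybrid"))
  if (length(bad))
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  hyb <- tab[tab$cohort == "hybrid", ]
  if (any(is.na(hyb$stage)) ||
      !all(hyb$stage %in% c("juvenile", "adult")))
    stop("every hybrid sample needs stage 'juvenile' or 'adult'")
  if (any(!is.finite(tab$duration_ms)) || any(tab$duration_ms <= 0))
    stop("EOD durations must be positive")
  invisible(tab)
}

# Shared table reader: sniffs tab vs comma, transparent gzip via file().
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Write a data frame as TSV (header, no quoting, no row names)
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a count matrix as TSV with a leading `gene` column
#' @param m Matrix with gene row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
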