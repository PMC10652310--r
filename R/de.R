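#' Median-of-ratios size factors
#'
#' Per-sample scale factors by the geometric-mean-reference method: each
#' sample's factor is the median over genes of the ratio of its count to the
#' gene's geometric mean across samples (computed over genes with nonzero
#' counts in all samples). When no gene is expressed everywhere, ratios are
#' taken over positive entries only, with a warning.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    DESeq2::estimateSizeFactorsForMatrix(counts)
  } else {
    warning("no gene with nonzero counts in every sample; ",
            "using positive-count geometric means")
    geo <- apply(counts, 1, function(x) {
      px <- x[x > 0]
      if (!length(px)) 0 else exp(mean(log(px)))
    })
    DESeq2::estimateSizeFactorsForMatrix(counts, geoMeans = pmax(geo, 1e-8))
  }
}

#' Normalized counts and the pipeline's log expression transform
#'
#' @param counts genes x samples count matrix.
#' @param sf size factors, computed by [size_factors()] when `NULL`.
#' @return `normalized_counts()`: matrix of counts divided by size factors.
#'   `log_norm()`: `log2(normalized + 1)` -- the expression scale used by all
#'   downstream linear models, correlations and noise statistics.
#' @export
normalized_counts <- function(counts, sf = NULL) {
  sf <- sf %||% size_factors(counts)
  sweep(as.matrix(counts), 2, sf, "/")
}

#' @rdname normalized_counts
#' @export
log_norm <- function(counts, sf = NULL) {
  log2(normalized_counts(counts, sf) + 1)
}

.check_de_inputs <- function(counts, metadata, contrast) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- metadata$sample
  if (nrow(metadata) != ncol(counts))
    stop("metadata rows must match count columns")
  if (!contrast %in% names(metadata))
    stop("contrast column `", contrast, "` not found in metadata")
  grp <- factor(metadata[[contrast]])
  if (nlevels(grp) != 2) stop("contrast must have exactly two levels")
  if (any(table(grp) < 2)) stop("need >= 2 samples per contrast level")
  list(counts = counts, grp = grp)
}

.de_result <- function(gene, baseMean, tested, log2FC, se, stat, p, contrast) {
  res <- data.frame(gene = gene, log2FC = log2FC, se = se, stat = stat,
                    p = p, q = bh_adjust(p), baseMean = baseMean,
                    tested = tested, stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

#' Negative-binomial Wald differential expression (primary estimator)
#'
#' Fits a per-gene negative-binomial GLM (log link) with the contrast factor
#' and optional additive covariates via DESeq2 and tests the contrast
#' coefficient with a Wald test. Fold changes are unshrunken maximum
#' likelihood estimates with their standard errors. Genes with mean
#' normalized count below `min_base_mean` are flagged `tested = FALSE` and
#' excluded from the Benjamini-Hochberg family (their `p` and `q` are `NA`,
#' not 1).
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param metadata data.frame of per-sample covariates; rows parallel to the
#'   count columns. The contrast column must have two levels; the reported
#'   log2 fold change is second level over first (e.g. Smurf over non-Smurf
#'   for a 0/1 `smurf` column).
#' @param contrast name of the metadata column to test.
#' @param covariates optional character vector of additive covariate columns.
#' @param min_base_mean independent-filter threshold on mean normalized
#'   count.
#' @param sf optional externally computed size factors.
#' @return A `de_result` data.frame: `gene`, `log2FC`, `se`, `stat`, `p`,
#'   `q`, `baseMean`, `tested`.
#' @export
nb_wald_test <- function(counts, metadata, contrast = "smurf",
                         covariates = NULL, min_base_mean = 1, sf = NULL) {
  ck <- .check_de_inputs(counts, metadata, contrast)
  counts <- ck$counts
  sf <- sf %||% size_factors(counts)
  baseMean <- rowMeans(normalized_counts(counts, sf))
  tested <- baseMean >= min_base_mean
  gene <- rownames(counts) %||% sprintf("g%05d", seq_len(nrow(counts)))

  cd <- data.frame(.grp = ck$grp)
  for (cv in covariates) cd[[cv]] <- metadata[[cv]]
  design <- stats::as.formula(paste("~", paste(c(covariates, ".grp"),
                                               collapse = " + ")))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = counts[tested, , drop = FALSE], colData = cd,
    design = design))
  DESeq2::sizeFactors(dds) <- sf
  dds <- tryCatch(
    suppressMessages(DESeq2::DESeq(dds, test = "Wald", quiet = TRUE,
                                   minReplicatesForReplace = Inf)),
    error = function(e) {
      # the dispersion-mean trend cannot be fit when every gene-wise
      # estimate sits at the lower bound (tiny, dispersion-homogeneous
      # matrices); use the gene-wise estimates as final dispersions
      if (!grepl("dispersion", conditionMessage(e))) stop(e)
      dds <- suppressMessages(DESeq2::estimateDispersionsGeneEst(dds))
      DESeq2::dispersions(dds) <- SummarizedExperiment::mcols(dds)$dispGeneEst
      suppressMessages(DESeq2::nbinomWaldTest(dds))
    })
  rn <- DESeq2::resultsNames(dds)
  res <- DESeq2::results(dds, name = rn[length(rn)],
                         independentFiltering = FALSE, cooksCutoff = FALSE)

  lfc <- se <- stat <- p <- rep(NA_real_, nrow(counts))
  lfc[tested] <- res$log2FoldChange
  se[tested] <- res$lfcSE
  stat[tested] <- res$stat
  p[tested] <- res$pvalue
  .de_result(gene, baseMean, tested, lfc, se, stat, p, contrast)
}

#' Quasi-likelihood differential expression (independent second estimator)
#'
#' Same contract as [nb_wald_test()] but estimated with edgeR's
#' quasi-likelihood negative-binomial pipeline (TMM normalization, QL
#' dispersion, F-type test). Used to check call concordance between two
#' independent estimators of the same contrast; agreement of ~90% of calls
#' and near-unity fold-change correlation is the expected behaviour on a
#' well-behaved data set.
#'
#' @inheritParams nb_wald_test
#' @return A `de_result` data.frame (the `stat` column holds the
#'   quasi-likelihood F statistic; `se` is `NA`).
#' @export
nb_quasi_test <- function(counts, metadata, contrast = "smurf",
                          covariates = NULL, min_base_mean = 1, sf = NULL) {
  ck <- .check_de_inputs(counts, metadata, contrast)
  counts <- ck$counts
  sf <- sf %||% size_factors(counts)
  baseMean <- rowMeans(normalized_counts(counts, sf))
  tested <- baseMean >= min_base_mean
  gene <- rownames(counts) %||% sprintf("g%05d", seq_len(nrow(counts)))

  mm_terms <- c(covariates, ".grp")
  mf <- data.frame(.grp = ck$grp)
  for (cv in covariates) mf[[cv]] <- metadata[[cv]]
  design <- stats::model.matrix(
    stats::as.formula(paste("~", paste(mm_terms, collapse = " + "))), mf)

  y <- edgeR::DGEList(counts = counts[tested, , drop = FALSE])
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qlf <- edgeR::glmQLFTest(fit, coef = ncol(design))
  tt <- qlf$table

  lfc <- stat <- p <- rep(NA_real_, nrow(counts))
  lfc[tested] <- tt$logFC
  stat[tested] <- tt$F
  p[tested] <- tt$PValue
  .de_result(gene, baseMean, tested, lfc, rep(NA_real_, nrow(counts)),
             stat, p, contrast)
}

#' Differentially expressed gene counts per age-matched contrast
#'
#' Runs the Smurf vs non-Smurf contrast separately at each age and counts
#' genes at `q < q_max`. In biphasic cohorts where the Smurf signature
#' attenuates with age (old non-Smurfs resembling old Smurfs), the count
#' decreases with chronological age.
#'
#' @inheritParams nb_wald_test
#' @param q_max FDR threshold for the DEG count.
#' @return list with `summary` (data.frame `age_days`, `n_samples`,
#'   `n_deg`) and `results` (one `de_result` per age).
#' @export
deg_count_by_age <- function(counts, metadata, contrast = "smurf",
                             q_max = 0.05, min_base_mean = 1) {
  counts <- as.matrix(counts)
  ages <- sort(unique(metadata$age_days))
  results <- list()
  summary <- data.frame(age_days = numeric(0), n_samples = integer(0),
                        n_deg = integer(0))
  for (a in ages) {
    keep <- metadata$age_days == a
    tab <- table(factor(metadata[[contrast]][keep]))
    if (length(tab) < 2 || any(tab < 2)) {
      warning("age ", a, ": missing or underpowered stratum, skipped")
      next
    }
    de <- nb_wald_test(counts[, keep, drop = FALSE],
                       metadata[keep, , drop = FALSE],
                       contrast = contrast, min_base_mean = min_base_mean)
    results[[as.character(a)]] <- de
    summary <- rbind(summary, data.frame(
      age_days = a, n_samples = sum(keep),
      n_deg = sum(de$q < q_max, na.rm = TRUE)))
  }
  list(summary = summary, results = results)
}
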