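# Differential metabolomics on litter-paired designs: paired t-tests on
# log abundances, multiple-testing adjustment, fold changes, volcano
# classification, plus PCA / hierarchical-clustering plumbing.

#' Assemble a paired abundance table
#'
#' @param abundances Numeric matrix, samples in rows, metabolites in columns
#'   (positive intensities; `NA` marks missing values). Row names are sample
#'   ids, column names metabolite ids.
#' @param sample_meta `data.frame` with columns `sample_id`, `litter`,
#'   `genotype` (`"cystic"` or `"control"`) and optionally `sex`. Every
#'   litter must contribute at least one sample of each genotype.
#' @param metabolite_meta Optional `data.frame` with columns `metabolite_id`
#'   and optionally `name`, `kegg_id`, `super_pathway`.
#' @return A list of class `"paired_abundance_table"`.
#' @export
paired_abundance_table <- function(abundances, sample_meta,
                                   metabolite_meta = NULL) {
  stopifnot(is.matrix(abundances), is.data.frame(sample_meta))
  if (is.null(rownames(abundances))) {
    rownames(abundances) <- sample_meta$sample_id
  }
  if (!all(sample_meta$sample_id %in% rownames(abundances))) {
    stop("sample_meta lists sample(s) absent from the abundance matrix")
  }
  if (!all(sample_meta$genotype %in% c("cystic", "control"))) {
    stop("genotype must be 'cystic' or 'control'")
  }
  tab <- table(sample_meta$litter, sample_meta$genotype)
  bad <- rownames(tab)[tab[, "cystic"] < 1 | tab[, "control"] < 1]
  if (length(bad)) {
    stop("litter(s) without both genotypes: ", paste(bad, collapse = ", "))
  }
  if (any(abundances <= 0, na.rm = TRUE)) {
    stop("abundances must be positive (use NA for missing values)")
  }
  if (is.null(metabolite_meta)) {
    metabolite_meta <- data.frame(metabolite_id = colnames(abundances),
                                  kegg_id = NA_character_,
                                  stringsAsFactors = FALSE)
  }
  structure(list(abundances = abundances, sample_meta = sample_meta,
                 metabolite_meta = metabolite_meta),
            class = "paired_abundance_table")
}

#' Paired t-test per metabolite on a litter-matched design
#'
#' Each litter's same-genotype replicates are collapsed to their mean log
#' abundance, yielding one (cystic, control) pair per litter; a classical
#' two-sided paired t-test is then run on the per-litter differences of log
#' abundances. Metabolites with any missing value are excluded from testing
#' (`NA` statistics, `tested = FALSE`). Zero-variance differences yield
#' `p = 1` with `degenerate = TRUE` rather than an error, keeping batch runs
#' alive; degenerate rows are excluded from volcano counts downstream.
#'
#' @param table A [paired_abundance_table()] with at least 2 litters.
#' @param pairing Collapse rule; only `"litter_mean"` is implemented.
#' @return A `data.frame`: `metabolite_id`, `t`, `p_raw`, `degenerate`,
#'   `tested`.
#' @export
paired_ttest <- function(table, pairing = "litter_mean") {
  pairing <- match.arg(pairing, "litter_mean")
  meta <- table$sample_meta
  litters <- sort(unique(meta$litter))
  if (length(litters) < 2L) stop("paired t-test needs at least 2 litters")
  logs <- log(table$abundances[meta$sample_id, , drop = FALSE])
  pair_diff <- function(lt) {
    cys <- colMeans(logs[meta$litter == lt & meta$genotype == "cystic", ,
                         drop = FALSE])
    ctl <- colMeans(logs[meta$litter == lt & meta$genotype == "control", ,
                         drop = FALSE])
    cys - ctl
  }
  d <- t(matrix(vapply(litters, pair_diff, numeric(ncol(logs))),
                nrow = ncol(logs)))                       # litters x mets
  n <- nrow(d)
  mbar <- colMeans(d)
  sdev <- apply(d, 2, stats::sd)
  tested <- !apply(d, 2, anyNA)
  tstat <- ifelse(sdev > 0, mbar / (sdev / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  degen <- tested & !is.na(sdev) & sdev == 0
  p[degen] <- 1
  tstat[degen] <- 0
  p[!tested] <- NA_real_
  tstat[!tested] <- NA_real_
  data.frame(metabolite_id = colnames(table$abundances),
             t = unname(tstat), p_raw = unname(p),
             degenerate = unname(degen), tested = unname(tested),
             stringsAsFactors = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @param method `"BH"` (Benjamini-Hochberg step-up, default) or
#'   `"bonferroni"`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_raw, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_raw, method = method)
}

#' Per-metabolite fold change (cystic over control)
#'
#' `FC = mean(cystic abundances) / mean(control abundances)` on the raw
#' intensity scale, with `log2_fc = log2(FC)`. A down-change of "absolute
#' fold change > 2" corresponds to `FC < 1/2`.
#'
#' @param table A [paired_abundance_table()].
#' @return A `data.frame`: `metabolite_id`, `fold_change`, `log2_fc`.
#' @export
fold_change <- function(table) {
  meta <- table$sample_meta
  cys <- colMeans(table$abundances[meta$sample_id[meta$genotype == "cystic"], ,
                                   drop = FALSE])
  ctl <- colMeans(table$abundances[meta$sample_id[meta$genotype == "control"], ,
                                   drop = FALSE])
  bad <- which(!is.na(cys) & !is.na(ctl) & (cys <= 0 | ctl <= 0))
  if (length(bad)) {
    stop("non-positive group mean for metabolite(s): ",
         paste(names(cys)[bad], collapse = ", "))
  }
  fc <- cys / ctl
  data.frame(metabolite_id = colnames(table$abundances),
             fold_change = unname(fc), log2_fc = unname(log2(fc)),
             stringsAsFactors = FALSE)
}

#' Volcano classification of differential records
#'
#' `up` when `p_adj < alpha` and `FC > fc_threshold`; `down` when
#' `p_adj < alpha` and `FC < 1/fc_threshold`; `ns` otherwise. `n_sig` counts
#' every metabolite with `p_adj < alpha` regardless of fold change.
#' Degenerate (zero-variance) records are classed `ns` and excluded from all
#' counts.
#'
#' @param records `data.frame` carrying `p_adj`, `fold_change` and optionally
#'   `degenerate`.
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 2).
#' @return `records` with a `volcano_class` column, plus a `"summary"`
#'   attribute: list `n_sig`, `n_up`, `n_down`.
#' @export
volcano_classify <- function(records, alpha = 0.05, fc_threshold = 2) {
  stopifnot(all(c("p_adj", "fold_change") %in% names(records)))
  degen <- if ("degenerate" %in% names(records)) records$degenerate else FALSE
  degen <- degen | is.na(records$p_adj)
  sig <- !degen & records$p_adj < alpha
  up <- sig & records$fold_change > fc_threshold
  down <- sig & records$fold_change < 1 / fc_threshold
  records$volcano_class <- ifelse(up, "up", ifelse(down, "down", "ns"))
  attr(records, "summary") <- list(n_sig = sum(sig), n_up = sum(up),
                                   n_down = sum(down))
  records
}

#' Full differential-metabolomics pass
#'
#' Paired t-test, BH adjustment, fold change and volcano classification in
#' one call.
#'
#' @inheritParams paired_ttest
#' @inheritParams volcano_classify
#' @param method Multiple-testing adjustment, see [adjust_pvalues()].
#' @return A `data.frame` of `DifferentialMetaboliteRecord`s (one row per
#'   metabolite: id, kegg id, fold change, log2 fc, t, raw and adjusted p,
#'   flags, volcano class) with the volcano `"summary"` attribute.
#' @export
differential_metabolomics <- function(table, alpha = 0.05, fc_threshold = 2,
                                      method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  tt <- paired_ttest(table)
  fc <- fold_change(table)
  rec <- merge(tt, fc, by = "metabolite_id", sort = FALSE)
  rec$p_adj <- adjust_pvalues(rec$p_raw, method = method)
  mm <- table$metabolite_meta
  rec$kegg_id <- mm$kegg_id[match(rec$metabolite_id, mm$metabolite_id)]
  rec <- rec[match(colnames(table$abundances), rec$metabolite_id), ]
  rownames(rec) <- NULL
  volcano_classify(rec, alpha = alpha, fc_threshold = fc_threshold)
}

#' PCA scores of the samples
#'
#' Log-transforms, centres each metabolite, and runs a standard SVD-based
#' PCA over the samples.
#'
#' @param table A [paired_abundance_table()] (metabolites with missing values
#'   are dropped first).
#' @param n_components Number of components to return.
#' @return A list with `scores` (samples x components), `explained` (variance
#'   proportions, non-increasing), `genotype` (aligned labels).
#' @export
pca_scores <- function(table, n_components = 2) {
  X <- log(table$abundances)
  X <- X[, !apply(X, 2, anyNA), drop = FALSE]
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  meta <- table$sample_meta
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       genotype = meta$genotype[match(rownames(X), meta$sample_id)])
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering on euclidean distances between log-abundance
#' profiles; tie handling is `stats::hclust`'s deterministic input-order
#' rule.
#'
#' @param table A [paired_abundance_table()].
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"complete"`).
#' @return An object of class `"hclust"`.
#' @export
hclust_linkage <- function(table, linkage = "complete") {
  X <- log(table$abundances)
  X <- X[, !apply(X, 2, anyNA), drop = FALSE]
  if (nrow(X) < 2L) stop("clustering needs at least 2 samples")
  stats::hclust(stats::dist(X), method = linkage)
}
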