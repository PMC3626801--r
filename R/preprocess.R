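#' Detect outlier arrays by mean inter-array correlation
#'
#' Computes every pairwise Pearson correlation between arrays on the
#' un-normalized matrix and flags arrays whose mean inter-array correlation
#' (IAC) falls below `grand mean - sd_multiplier * SD`. A single-linkage
#' clustering of `1 - IAC` is returned for manual inspection; the input is
#' never mutated. The threshold rule is a deterministic stand-in for
#' cluster-plus-RNA-quality review, which needs metadata a matrix does not
#' carry.
#'
#' @param expression numeric matrix, rows = probes/genes, columns = samples
#' @param sd_multiplier how many SDs below the mean IAC to flag (default 2)
#' @return an `outlier_report` list: `mean_iac` (named per sample),
#'   `flagged_samples`, `threshold_used`, and `dendrogram` (hclust,
#'   single linkage on 1 - IAC)
#' @export
detect_outlier_arrays <- function(expression, sd_multiplier = 2) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 3) stop_("need at least 3 samples, got %d", ncol(expression))
  v <- apply(expression, 2, stats::var)
  if (any(v == 0))
    stop_("zero-variance sample(s): %s",
          paste(colnames(expression)[v == 0], collapse = ", "))
  iac <- stats::cor(expression)
  mean_iac <- (colSums(iac) - 1) / (ncol(iac) - 1)  # exclude self-correlation
  thr <- mean(mean_iac) - sd_multiplier * stats::sd(mean_iac)
  hc <- stats::hclust(stats::as.dist(1 - iac), method = "single")
  structure(list(mean_iac = mean_iac,
                 flagged_samples = names(mean_iac)[mean_iac < thr],
                 threshold_used = thr,
                 dendrogram = hc),
            class = "outlier_report")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column to share one distribution: the per-rank cross-column
#' means. Delegates to the standard limma implementation; row and column
#' labels are preserved. Missing values are rejected — normalize before any
#' filtering that introduces them.
#'
#' @param expression numeric matrix (no NAs)
#' @return matrix of the same shape and dimnames
#' @export
quantile_normalize <- function(expression) {
  expression <- as.matrix(expression)
  if (anyNA(expression)) stop_("expression contains missing values")
  out <- limma::normalizeQuantiles(expression)
  dimnames(out) <- dimnames(expression)
  out
}

#' Drop rows absent in more than a fraction of samples
#'
#' A row is removed when its absent fraction strictly exceeds
#' `max_absent_fraction`; a row absent in exactly the threshold fraction is
#' retained. Default 0.90 (exclude probes absent in more than 90% of samples).
#'
#' @param expression numeric matrix
#' @param presence logical matrix aligned to `expression` (TRUE = present)
#' @param max_absent_fraction proportion in [0, 1]
#' @return the filtered expression matrix
#' @export
filter_absent <- function(expression, presence, max_absent_fraction = 0.90) {
  expression <- as.matrix(expression)
  if (!identical(dim(presence), dim(expression)))
    stop_("presence matrix shape differs from expression")
  absent_frac <- rowMeans(!presence)
  expression[absent_frac <= max_absent_fraction, , drop = FALSE]
}

#' Keep rows present in at least a minimum number of samples
#'
#' Independent, stricter presence filter used ahead of network construction
#' (default: present in at least 6 samples).
#'
#' @inheritParams filter_absent
#' @param min_present_samples minimum count of present calls per row
#' @return the filtered expression matrix
#' @export
filter_min_present <- function(expression, presence, min_present_samples = 6) {
  expression <- as.matrix(expression)
  if (!identical(dim(presence), dim(expression)))
    stop_("presence matrix shape differs from expression")
  expression[rowSums(presence) >= min_present_samples, , drop = FALSE]
}

#' Collapse probes to one row per gene
#'
#' For each gene symbol, keeps the probe with the highest average expression
#' across samples (the most reproducible representative); probes without a
#' gene mapping are dropped. Exact ties are broken by the lexicographically
#' smallest probe id, which keeps the choice stable under row reordering.
#'
#' @param expression numeric matrix with probe row names
#' @param probe_map data.frame with columns `probe`, `gene`
#' @return list: `expression` (one row per gene, gene-symbol row names) and
#'   `collapse_map` (data.frame probe/gene/chosen)
#' @export
collapse_probes <- function(expression, probe_map) {
  expression <- as.matrix(expression)
  if (is.null(probe_map) || nrow(probe_map) == 0) stop_("empty probe map")
  pm <- probe_map[probe_map$probe %in% rownames(expression) &
                  !is.na(probe_map$gene) & nzchar(probe_map$gene), , drop = FALSE]
  if (nrow(pm) == 0) stop_("probe map covers no rows of the matrix")
  means <- rowMeans(expression)[pm$probe]
  # order: by gene, then decreasing mean, then probe id for exact ties
  ord <- order(pm$gene, -means, pm$probe)
  pm <- pm[ord, , drop = FALSE]
  chosen <- pm[!duplicated(pm$gene), , drop = FALSE]
  out <- expression[chosen$probe, , drop = FALSE]
  rownames(out) <- chosen$gene
  out <- out[order(rownames(out)), , drop = FALSE]
  cmap <- data.frame(probe = pm$probe, gene = pm$gene,
                     chosen = pm$probe %in% chosen$probe,
                     stringsAsFactors = FALSE)
  list(expression = out, collapse_map = cmap)
}
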