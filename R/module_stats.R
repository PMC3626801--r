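#' Module eigengenes
#'
#' The eigengene (ME) of a module is the first principal component of its
#' per-gene z-scored expression submatrix: the single sample-level profile
#' capturing the largest share of module variance. Eigengenes are scaled to
#' unit variance and sign-oriented so the mean correlation with the module's
#' genes (mean kME) is non-negative; "grey" is excluded. Genes that are
#' constant across samples cannot be z-scored: they are dropped with a
#' warning, and a module consisting only of constant genes is an error.
#'
#' @param expression numeric matrix, rows = genes, columns = samples
#' @param assignment a `module_assignment` covering the rows
#' @return a `module_eigengenes` object: `eigengenes` (samples x modules
#'   matrix), `variance_explained` (named proportion), `orientation` (named
#'   +1/-1 applied to the raw first PC)
#' @export
module_eigengenes <- function(expression, assignment) {
  expression <- as.matrix(expression)
  labels <- assignment$labels[rownames(expression)]
  if (anyNA(labels)) stop_("assignment does not cover all expression rows")
  mods <- setdiff(unique(labels), "grey")
  mods <- names(sort(table(labels[labels %in% mods]), decreasing = TRUE))
  mes <- matrix(NA_real_, ncol(expression), length(mods),
                dimnames = list(colnames(expression), mods))
  varexp <- stats::setNames(numeric(length(mods)), mods)
  orient <- stats::setNames(integer(length(mods)), mods)
  for (m in mods) {
    sub <- expression[labels == m, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (all(sds == 0)) stop_("module '%s' consists only of constant genes", m)
    if (any(sds == 0)) {
      warn_("module '%s': dropping %d constant gene(s) from eigengene computation",
            m, sum(sds == 0))
      sub <- sub[sds > 0, , drop = FALSE]
    }
    z <- t(scale(t(sub)))                       # z-score each gene
    sv <- svd(t(z))                             # samples x genes
    me <- sv$u[, 1]
    me <- me / stats::sd(me)                    # unit variance
    s <- sign(mean(stats::cor(t(sub), me)))
    if (s == 0) s <- 1
    mes[, m] <- s * me
    varexp[m] <- sv$d[1]^2 / sum(sv$d^2)
    orient[m] <- s
  }
  structure(list(eigengenes = mes, variance_explained = varexp,
                 orientation = orient),
            class = "module_eigengenes")
}

#' Module membership (kME)
#'
#' kME of a gene in a module is the Pearson correlation between the gene's
#' profile and that module's eigengene, computed for every gene against every
#' module so any gene can be screened for intramodular hub character. Genes
#' with zero variance get NA with a warning.
#'
#' @param expression numeric matrix, rows = genes, columns = samples
#' @param eigengenes a [module_eigengenes()] result with matching samples
#' @return genes x modules matrix of kME values in [-1, 1]
#' @export
module_membership <- function(expression, eigengenes) {
  expression <- as.matrix(expression)
  me <- eigengenes$eigengenes
  if (nrow(me) != ncol(expression)) stop_("sample dimensions do not align")
  sds <- apply(expression, 1, stats::sd)
  kme <- suppressWarnings(stats::cor(t(expression), me))
  if (any(sds == 0)) {
    warn_("%d zero-variance gene(s): kME set to NA", sum(sds == 0))
    kme[sds == 0, ] <- NA_real_
  }
  kme
}

#' Scaled intramodular connectivity (kIN / max kIN)
#'
#' kIN of a gene is the sum of its adjacencies to the other genes of its own
#' module (diagonal excluded); scaling by the module maximum puts the top hub
#' of every module at exactly 1.0. Grey genes and singleton modules (kIN = 0,
#' scaled undefined) are reported with NA scaled values.
#'
#' @param adjacency an [signed_adjacency()] matrix
#' @param assignment a `module_assignment` covering the adjacency genes
#' @return data.frame: gene, module, kIN, scaled_kIN
#' @export
scaled_intramodular_connectivity <- function(adjacency, assignment) {
  a <- unclass(as.matrix(adjacency))
  genes <- rownames(a)
  labels <- assignment$labels[genes]
  if (anyNA(labels)) stop_("assignment does not cover all adjacency genes")
  kin <- stats::setNames(rep(NA_real_, length(genes)), genes)
  scaled <- kin
  for (m in setdiff(unique(labels), "grey")) {
    idx <- which(labels == m)
    sub <- a[idx, idx, drop = FALSE]
    k <- rowSums(sub) - diag(sub)
    kin[idx] <- k
    mx <- max(k)
    scaled[idx] <- if (mx > 0) k / mx else NA_real_
  }
  data.frame(gene = genes, module = unname(labels), kIN = unname(kin),
             scaled_kIN = unname(scaled), stringsAsFactors = FALSE)
}

.filter_samples <- function(phenotypes, samples) {
  if (is.null(samples)) return(rep(TRUE, nrow(phenotypes)))
  if (is.logical(samples)) {
    if (length(samples) != nrow(phenotypes))
      stop_("logical sample filter has wrong length")
    return(samples)
  }
  phenotypes$sample_id %in% as.character(samples)
}

#' Correlate module eigengenes with a clinical trait
#'
#' Pearson correlation of each eigengene with a numeric trait, with a
#' two-sided p-value from the t-distribution. Missing trait values are
#' dropped pairwise; p-values are reported raw (no multiple-testing
#' adjustment), matching trend-level reporting at p < 0.05. An optional
#' sample filter supports restrictions such as "impairment scores in
#' disease-positive cases only".
#'
#' @param eigengenes a [module_eigengenes()] result
#' @param phenotypes data.frame with `sample_id` and the trait column
#' @param trait name of the trait column
#' @param samples optional sample filter: character vector of sample ids or
#'   logical vector over phenotype rows
#' @return data.frame: module, trait, n, R, p
#' @export
module_trait_correlation <- function(eigengenes, phenotypes, trait,
                                     samples = NULL) {
  me <- eigengenes$eigengenes
  if (!trait %in% names(phenotypes)) stop_("trait '%s' not in phenotypes", trait)
  keep <- .filter_samples(phenotypes, samples)
  tv <- phenotypes[[trait]][keep]
  mesub <- me[keep, , drop = FALSE]
  ok <- !is.na(tv)
  if (sum(ok) < 4) stop_("trait '%s' has fewer than 4 non-missing values after filtering", trait)
  if (stats::sd(tv[ok]) == 0) stop_("trait '%s' is constant after filtering", trait)
  res <- lapply(colnames(mesub), function(m) {
    x <- mesub[ok, m]; y <- tv[ok]
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(module = m, trait = trait, n = sum(ok),
               R = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare module eigengenes across sample groups
#'
#' Runs both one-way ANOVA and the Kruskal-Wallis rank test of each eigengene
#' across the grouping, reporting both, since parametric and rank-based
#' answers can differ at small n.
#'
#' @param eigengenes a [module_eigengenes()] result
#' @param phenotypes data.frame with `sample_id` and the grouping column
#' @param grouping name of the grouping column (default "group")
#' @param samples optional sample filter as in [module_trait_correlation()]
#' @return data.frame: module, anova_F, anova_p, kruskal_H, kruskal_p
#' @export
module_group_test <- function(eigengenes, phenotypes, grouping = "group",
                              samples = NULL) {
  me <- eigengenes$eigengenes
  if (!grouping %in% names(phenotypes)) stop_("grouping '%s' not in phenotypes", grouping)
  keep <- .filter_samples(phenotypes, samples)
  g <- factor(phenotypes[[grouping]][keep])
  mesub <- me[keep, , drop = FALSE]
  sizes <- table(g)
  if (length(sizes) < 2) stop_("need at least 2 groups")
  if (any(sizes < 2))
    stop_("group(s) with fewer than 2 samples: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  res <- lapply(colnames(mesub), function(m) {
    y <- mesub[, m]
    if (stats::sd(y) == 0) {
      # all eigengene values identical: no between-group signal by definition
      return(data.frame(module = m, anova_F = 0, anova_p = 1,
                        kruskal_H = 0, kruskal_p = 1, stringsAsFactors = FALSE))
    }
    av <- stats::anova(stats::lm(y ~ g))
    kw <- stats::kruskal.test(y, g)
    data.frame(module = m, anova_F = av$`F value`[1], anova_p = av$`Pr(>F)`[1],
               kruskal_H = unname(kw$statistic), kruskal_p = kw$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Permutation-based module preservation between two datasets
#'
#' A reduced two-statistic preservation composite. For every non-grey
#' reference module, computed over the genes shared by both datasets:
#' density = mean intramodular adjacency in the test data, and
#' connectivity = Fisher z-transformed correlation between the genes'
#' intramodular connectivity (kIN) in the reference and in the test data
#' (the transform stabilizes variance and keeps the statistic informative as
#' the correlation approaches 1; it is clipped at |r| = 1 - 1e-12). Each
#' observed statistic is compared to a permutation null,
#' `Z = (obs - mean_perm) / sd_perm`, with `Z_summary` the mean of the two
#' Z scores; reproducible from `seed`. The density null draws random gene
#' sets of equal size from the common genes; the connectivity null permutes
#' the gene correspondence between the two kIN vectors (a random-gene-set
#' null is degenerate for this statistic whenever the two datasets are
#' highly similar: any set then yields cor = 1, with zero null variance).
#'
#' @param ref_expression reference expression matrix (genes x samples)
#' @param assignment `module_assignment` on the reference genes
#' @param test_expression test expression matrix (genes x samples; sample
#'   sets may differ)
#' @param n_permutations number of random gene sets (>= 20, default 200)
#' @param seed integer seed for the permutation draws
#' @param beta soft-threshold power for both networks (default 12)
#' @return data.frame: module, n_genes, Z_density, Z_connectivity, Z_summary;
#'   modules with no genes in the test data yield NA rows
#' @export
module_preservation <- function(ref_expression, assignment, test_expression,
                                n_permutations = 200, seed = 1, beta = 12) {
  if (n_permutations < 20) stop_("n_permutations must be >= 20")
  common <- intersect(rownames(ref_expression), rownames(test_expression))
  if (length(common) < assignment$min_module_size %||% 2)
    stop_("too few common genes")
  aref <- unclass(signed_adjacency(ref_expression[common, , drop = FALSE], beta))
  atest <- unclass(signed_adjacency(test_expression[common, , drop = FALSE], beta))
  labels <- assignment$labels[common]
  mods <- setdiff(unique(assignment$labels), "grey")
  set.seed(substream_seed(seed, "preservation"))
  density_of <- function(idx) {
    st <- atest[idx, idx, drop = FALSE]
    (sum(st) - sum(diag(st))) / (length(idx) * (length(idx) - 1))
  }
  kin_pair <- function(idx) {
    sr <- aref[idx, idx, drop = FALSE]; st <- atest[idx, idx, drop = FALSE]
    list(r = rowSums(sr) - diag(sr), t = rowSums(st) - diag(st))
  }
  # Fisher z of the kIN correlation; clipped so identical networks stay finite
  safe_cor <- function(x, y) {
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)
    atanh(max(-1 + 1e-12, min(1 - 1e-12, r)))
  }
  res <- lapply(mods, function(m) {
    idx <- which(labels == m)
    if (length(idx) < 3)
      return(data.frame(module = m, n_genes = length(idx), Z_density = NA_real_,
                        Z_connectivity = NA_real_, Z_summary = NA_real_,
                        stringsAsFactors = FALSE))
    dens_obs <- density_of(idx)
    kp <- kin_pair(idx)
    conn_obs <- safe_cor(kp$r, kp$t)
    dens_perm <- replicate(n_permutations,
                           density_of(sample.int(length(common), length(idx))))
    conn_perm <- replicate(n_permutations, safe_cor(kp$r, sample(kp$t)))
    z <- c((dens_obs - mean(dens_perm)) / stats::sd(dens_perm),
           (conn_obs - mean(conn_perm)) / stats::sd(conn_perm))
    data.frame(module = m, n_genes = length(idx), Z_density = z[1],
               Z_connectivity = z[2], Z_summary = mean(z),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
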