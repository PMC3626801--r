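#' Signed weighted coexpression adjacency
#'
#' Transforms the gene-gene Pearson correlation matrix as
#' `a_ij = ((cor_ij + 1) / 2)^beta`, so a correlation of -1 maps to adjacency
#' 0 and +1 maps to 1, preserving correlation sign information. The default
#' soft-threshold power is 12, the conventional choice for signed networks.
#' Correlations use pairwise-complete observations; any gene pair whose
#' correlation is undefined after that is an error.
#'
#' @param expression numeric matrix, rows = genes, columns = samples (>= 3)
#' @param beta soft-threshold power (> 0, default 12)
#' @return an `adjacency_matrix`: symmetric genes x genes matrix in [0, 1]
#'   with unit diagonal and attribute `beta`
#' @export
signed_adjacency <- function(expression, beta = 12) {
  expression <- as.matrix(expression)
  if (beta <= 0) stop_("beta must be positive")
  if (ncol(expression) < 3) stop_("need at least 3 samples")
  v <- apply(expression, 1, stats::var, na.rm = TRUE)
  if (any(!is.finite(v) | v == 0))
    stop_("zero-variance gene(s): %s",
          paste(rownames(expression)[!is.finite(v) | v == 0], collapse = ", "))
  r <- stats::cor(t(expression), use = "pairwise.complete.obs")
  if (anyNA(r))
    stop_("undefined correlations after pairwise-complete handling; remove genes with excessive missingness")
  a <- ((r + 1) / 2)^beta
  a <- (a + t(a)) / 2  # enforce exact symmetry against FP asymmetry
  diag(a) <- 1
  structure(a, beta = beta, class = c("adjacency_matrix", "matrix", "array"))
}

#' Topological overlap matrix
#'
#' Standard (unsigned-formula) topological overlap applied to a signed
#' adjacency: `t_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i` is the connectivity
#' `sum_{u != i} a_iu` (diagonal excluded). Diagonal of the result is 1.
#'
#' @param adjacency symmetric matrix with entries in [0, 1]
#' @return a `to_matrix`: symmetric matrix of topological overlaps in [0, 1]
#' @export
topological_overlap <- function(adjacency) {
  a <- unclass(as.matrix(adjacency))
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-12)))
    stop_("adjacency matrix is not symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # l_ij = sum_u a_iu a_uj, u != i,j since diag 0
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  structure(tom, class = c("to_matrix", "matrix", "array"))
}

# Collect leaf indices under each merge node of an hclust tree.
.merge_members <- function(merge) {
  n <- nrow(merge) + 1L
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    left <- merge[i, 1]; right <- merge[i, 2]
    lm <- if (left < 0) -left else members[[left]]
    rm_ <- if (right < 0) -right else members[[right]]
    members[[i]] <- c(lm, rm_)
  }
  members
}

# Tree-shaped branch decomposition: cut the dendrogram at `cut_h`; every
# maximal subtree below the cut is a candidate branch. With deep_split, a
# branch whose top merge joins two children that are each large enough and
# clearly tighter than the join (child height < split_ratio * join height)
# is split recursively. Branches below min size are left unassigned.
.cut_branches <- function(hc, cut_h, min_size, deep_split, split_ratio = 0.9) {
  n <- length(hc$order)
  members <- .merge_members(hc$merge)
  heights <- hc$height
  branches <- list()

  descend <- function(node) {
    # node > 0: merge index; node < 0: singleton leaf
    if (node < 0) { branches[[length(branches) + 1L]] <<- -node; return(invisible()) }
    if (heights[node] > cut_h) {
      descend(hc$merge[node, 1]); descend(hc$merge[node, 2])
      return(invisible())
    }
    if (deep_split) {
      l <- hc$merge[node, 1]; r <- hc$merge[node, 2]
      lsize <- if (l < 0) 1L else length(members[[l]])
      rsize <- if (r < 0) 1L else length(members[[r]])
      lh <- if (l < 0) 0 else heights[l]
      rh <- if (r < 0) 0 else heights[r]
      if (lsize >= min_size && rsize >= min_size &&
          max(lh, rh) < split_ratio * heights[node]) {
        descend(l); descend(r)
        return(invisible())
      }
    }
    branches[[length(branches) + 1L]] <<- members[[node]]
  }
  root <- nrow(hc$merge)
  descend(root)
  branches
}

#' Cluster genes on topological-overlap dissimilarity and cut modules
#'
#' Average-linkage hierarchical clustering of `1 - TO`, followed by a
#' tree-shaped branch decomposition: branches below `cut_height` (a fraction
#' of the maximum merge height) become modules when they hold at least
#' `min_module_size` genes; all other genes are labeled "grey". Module labels
#' are assigned by decreasing size in a fixed color order, so results are
#' reproducible; module counts are sensitive to the cut parameters.
#'
#' @param tom topological overlap matrix from [topological_overlap()]
#' @param min_module_size smallest admissible module (>= 2, default 30)
#' @param cut_height branch cut as a fraction of the maximum merge height
#'   (default 0.99)
#' @param deep_split logical; when TRUE, branches joining two well-separated
#'   large sub-branches are split further (more, smaller modules)
#' @return a `module_assignment`: `labels` (named character, "grey" =
#'   unassigned), `dendrogram` (hclust), `min_module_size`
#' @export
cluster_and_cut <- function(tom, min_module_size = 30, cut_height = 0.99,
                            deep_split = FALSE) {
  if (min_module_size < 2) stop_("min_module_size must be >= 2")
  tom <- as.matrix(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  if (nrow(tom) < 2 * min_module_size) {
    # fewer genes than two minimal modules: nothing can qualify
    warn_("fewer than 2 * min_module_size genes; all genes labeled grey")
    labels <- stats::setNames(rep("grey", length(genes)), genes)
    hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
    return(structure(list(labels = labels, dendrogram = hc,
                          min_module_size = as.integer(min_module_size)),
                     class = "module_assignment"))
  }
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cut_h <- cut_height * max(hc$height)
  branches <- .cut_branches(hc, cut_h, min_module_size, deep_split)
  keep <- branches[vapply(branches, length, 1L) >= min_module_size]
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  if (length(keep)) {
    keep <- keep[order(vapply(keep, length, 1L), decreasing = TRUE)]
    cols <- module_labels_for(length(keep))
    for (i in seq_along(keep)) labels[keep[[i]]] <- cols[i]
  }
  structure(list(labels = labels, dendrogram = hc,
                 min_module_size = as.integer(min_module_size)),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tb <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("module_assignment: %d genes, %d modules (+grey)\n",
              length(x$labels), sum(names(tb) != "grey")))
  print(tb)
  invisible(x)
}

#' Relabel a module assignment to match a reference
#'
#' For every non-grey target module, tests the overlap with each reference
#' module by a one-tailed hypergeometric test over the common gene universe.
#' A target module takes the reference label of its most significant overlap
#' when the Bonferroni-adjusted p (over reference modules) is below `alpha`;
#' competing claims on one reference label are resolved in order of
#' increasing p. Unmatched modules receive fresh labels unused by the
#' reference; "grey" is never remapped.
#'
#' @param reference,target `module_assignment` objects with overlapping
#'   gene universes
#' @param alpha significance level after Bonferroni (default 0.05)
#' @return `target` with relabeled modules
#' @export
match_labels <- function(reference, target, alpha = 0.05) {
  common <- intersect(names(reference$labels), names(target$labels))
  if (length(common) == 0) stop_("gene universes do not intersect")
  ref <- reference$labels[common]; tar <- target$labels[common]
  ref_mods <- setdiff(unique(ref), "grey")
  tar_mods <- setdiff(unique(target$labels), "grey")
  N <- length(common)
  hits <- expand.grid(tar = tar_mods, ref = ref_mods, stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hits$p <- mapply(function(tm, rm_) {
      ov <- sum(tar == tm & ref == rm_)
      stats::phyper(ov - 1, sum(ref == rm_), N - sum(ref == rm_),
                    sum(tar == tm), lower.tail = FALSE)
    }, hits$tar, hits$ref)
    hits$p_adj <- pmin(1, hits$p * length(ref_mods))
  }
  new_labels <- target$labels
  mapping <- character(0)
  if (nrow(hits)) {
    hits <- hits[order(hits$p), , drop = FALSE]
    taken_ref <- character(0); done_tar <- character(0)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      if (h$p_adj >= alpha) break
      if (h$tar %in% done_tar || h$ref %in% taken_ref) next
      mapping[h$tar] <- h$ref
      done_tar <- c(done_tar, h$tar); taken_ref <- c(taken_ref, h$ref)
    }
  }
  unmatched <- setdiff(tar_mods, names(mapping))
  fresh <- setdiff(module_labels_for(length(ref_mods) + length(tar_mods) + 5L),
                   c(ref_mods, mapping))
  for (i in seq_along(unmatched)) mapping[unmatched[i]] <- fresh[i]
  is_mod <- new_labels != "grey"
  new_labels[is_mod] <- unname(mapping[new_labels[is_mod]])
  out <- target
  out$labels <- new_labels
  out
}

#' Write a module assignment as a two-column TSV
#'
#' @param assignment a `module_assignment`
#' @param path output file
#' @return the path, invisibly
#' @export
write_assignment <- function(assignment, path) {
  utils::write.table(data.frame(gene = names(assignment$labels),
                                module = unname(assignment$labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
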