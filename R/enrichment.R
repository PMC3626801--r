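#' Read a GMT gene-set file
#'
#' Tab-delimited: category name, description, then member gene symbols.
#' Symbols are canonicalized (uppercased, trimmed); empty categories are
#' dropped.
#'
#' @param path GMT file path
#' @param source_tag optional label for the collection (GO/KEGG/markers/...)
#' @return named list of character vectors with attribute `source`
#' @export
read_gmt <- function(path, source_tag = NA_character_) {
  if (!file.exists(path)) stop_("GMT file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) return(NULL)
    unique(canonical_gene(parts[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets <- Filter(function(s) length(s) > 0, sets)
  attr(sets, "source") <- source_tag
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors
#' @param path output file
#' @return the path, invisibly
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Per-gene trait correlations
#'
#' Pearson correlation of every gene with a numeric clinical trait, with
#' two-sided t-distribution p-values. Missing values are dropped pairwise per
#' gene; genes with fewer than 4 paired observations get NA with a warning.
#' No multiple-testing adjustment is applied — downstream list building uses
#' the raw p-values.
#'
#' @param expression numeric matrix, rows = genes, columns = samples
#' @param phenotypes data.frame with `sample_id` and the trait column
#' @param trait name of the trait column
#' @param samples optional sample filter (ids or logical)
#' @return data.frame: gene, n, R, p
#' @export
gene_trait_correlations <- function(expression, phenotypes, trait,
                                    samples = NULL) {
  expression <- as.matrix(expression)
  if (!trait %in% names(phenotypes)) stop_("trait '%s' not in phenotypes", trait)
  keep <- .filter_samples(phenotypes, samples)
  tv <- phenotypes[[trait]][keep]
  ex <- expression[, keep, drop = FALSE]
  ok_t <- !is.na(tv)
  if (stats::sd(tv[ok_t]) == 0) stop_("trait '%s' is constant after filtering", trait)
  n_pair <- rowSums(!is.na(ex[, ok_t, drop = FALSE]))
  r <- suppressWarnings(as.vector(stats::cor(t(ex), tv,
                                             use = "pairwise.complete.obs")))
  few <- n_pair < 4
  if (any(few)) {
    warn_("%d gene(s) with fewer than 4 paired observations: set to NA", sum(few))
    r[few] <- NA_real_
  }
  tstat <- r * sqrt((n_pair - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n_pair - 2, lower.tail = FALSE)
  p[!is.na(r) & abs(r) == 1] <- 0
  data.frame(gene = rownames(ex), n = n_pair, R = r, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top gene table by absolute correlation
#'
#' Rows with `|R| >= r_threshold` (default 0.75), sorted by descending |R|.
#'
#' @param table a [gene_trait_correlations()] result
#' @param r_threshold absolute-correlation cutoff
#' @return the filtered, sorted data.frame
#' @export
top_gene_table <- function(table, r_threshold = 0.75) {
  keep <- !is.na(table$R) & abs(table$R) >= r_threshold
  out <- table[keep, , drop = FALSE]
  out[order(-abs(out$R)), , drop = FALSE]
}

# EASE score: one-tailed Fisher exact probability after jackknifing one gene
# out of the category's list hits (both the hit count and the list size lose
# that gene; population margins are unchanged):
#   EASE = P(X >= LH - 1),  X ~ Hypergeom(PH, PT - PH, LT - 1)
# This reproduces published EASE values where the plain Fisher p does not,
# and makes a single-hit category maximally non-significant (EASE = 1).
ease_score <- function(lh, lt, ph, pt) {
  stats::phyper(lh - 2, ph, pt - ph, lt - 1, lower.tail = FALSE)
}

#' EASE-style gene-set enrichment (jackknifed Fisher exact)
#'
#' For each category, counts list hits (LH), list total (LT), population hits
#' (PH) and population total (PT) over the supplied universe, then scores the
#' overlap with the EASE score: the one-tailed Fisher exact probability after
#' removing one gene from the category's list hits. This penalizes categories
#' supported by very few genes (a single-hit category scores 1). Categories
#' with no list hits are omitted; the Bonferroni column multiplies by the
#' number of categories actually tested.
#'
#' @param list_genes character vector of gene symbols (the hit list)
#' @param universe character vector of all assayable gene symbols; the
#'   population total is its size, so run per annotation source when sources
#'   have different annotated universes
#' @param sets named list of gene sets (e.g. from [read_gmt()])
#' @return data.frame sorted by EASE score: category, list_hits, list_total,
#'   pop_hits, pop_total, ease, bonferroni
#' @export
ease_enrichment <- function(list_genes, universe, sets) {
  universe <- unique(canonical_gene(universe))
  list_genes <- unique(canonical_gene(list_genes))
  if (length(universe) == 0) stop_("empty universe")
  if (length(list_genes) == 0) stop_("empty gene list")
  outside <- setdiff(list_genes, universe)
  if (length(outside)) {
    warn_("%d list gene(s) outside the universe were dropped", length(outside))
    list_genes <- intersect(list_genes, universe)
    if (length(list_genes) == 0) stop_("empty gene list after universe intersection")
  }
  lt <- length(list_genes); pt <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    cat_genes <- intersect(canonical_gene(sets[[nm]]), universe)
    ph <- length(cat_genes)
    lh <- length(intersect(list_genes, cat_genes))
    if (lh == 0) return(NULL)
    data.frame(category = nm, list_hits = lh, list_total = lt,
               pop_hits = ph, pop_total = pt,
               ease = ease_score(lh, lt, ph, pt), stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    return(data.frame(category = character(0), list_hits = integer(0),
                      list_total = integer(0), pop_hits = integer(0),
                      pop_total = integer(0), ease = numeric(0),
                      bonferroni = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$bonferroni <- pmin(1, out$ease * nrow(out))
  out[order(out$ease), , drop = FALSE]
}

#' Module enrichment for user-supplied marker lists
#'
#' One-tailed hypergeometric test of the overlap between every non-grey
#' module and every marker set (e.g. cell-type markers), over the assayed
#' gene universe. Bonferroni adjusts over all (module, set) pairs tested.
#'
#' @param assignment a `module_assignment`
#' @param marker_sets named list of gene sets
#' @param universe gene universe; defaults to all assigned genes
#' @return data.frame: module, category, overlap, module_size, set_size,
#'   universe_size, p, bonferroni
#' @export
user_list_enrichment <- function(assignment, marker_sets, universe = NULL) {
  genes <- canonical_gene(names(assignment$labels))
  labels <- assignment$labels
  names(labels) <- genes
  if (is.null(universe)) universe <- genes
  universe <- unique(canonical_gene(universe))
  labels <- labels[names(labels) %in% universe]
  pt <- length(universe)
  mods <- setdiff(unique(labels), "grey")
  rows <- list()
  for (m in mods) {
    mg <- names(labels)[labels == m]
    if (length(mg) == 0) { warn_("module '%s' empty after universe intersection; skipped", m); next }
    for (nm in names(marker_sets)) {
      sg <- intersect(canonical_gene(marker_sets[[nm]]), universe)
      if (length(sg) == 0) next
      ov <- length(intersect(mg, sg))
      p <- stats::phyper(ov - 1, length(sg), pt - length(sg), length(mg),
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, category = nm, overlap = ov,
                   module_size = length(mg), set_size = length(sg),
                   universe_size = pt, p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(module = character(0), category = character(0),
                      overlap = integer(0), module_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      p = numeric(0), bonferroni = numeric(0)))
  out <- do.call(rbind, rows)
  out$bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), , drop = FALSE]
}
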