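#' Align two studies on their common genes
#'
#' Intersects the (canonicalized) gene universes of two gene-collapsed
#' studies and restricts both expression matrices to the common genes in the
#' same sorted order.
#'
#' @param study1,study2 [expression_study()] objects whose expression rows
#'   are gene symbols (after probe collapse)
#' @return list: `genes` (sorted common symbols), `study1`, `study2`
#'   (row-subsetted and aligned)
#' @export
align_common_genes <- function(study1, study2) {
  g1 <- canonical_gene(rownames(study1$expression))
  g2 <- canonical_gene(rownames(study2$expression))
  common <- sort(intersect(g1, g2))
  if (length(common) == 0) stop_("no genes common to both studies")
  sub <- function(study, g) {
    idx <- match(common, g)
    study$expression <- study$expression[idx, , drop = FALSE]
    rownames(study$expression) <- common
    if (!is.null(study$presence)) {
      study$presence <- study$presence[idx, , drop = FALSE]
      rownames(study$presence) <- common
    }
    study
  }
  list(genes = common, study1 = sub(study1, g1), study2 = sub(study2, g2))
}

#' Per-gene impairment correlations
#'
#' Orients per-gene trait correlations so that positive always means "up
#' with impairment": GCR (higher = more impaired) is used directly, MMSE
#' (lower = more impaired) is sign-flipped. GCR analyses conventionally
#' restrict to disease-positive cases via `samples`.
#'
#' @param study an [expression_study()]
#' @param trait "GCR" or "MMSE"
#' @param samples optional sample filter (ids or logical)
#' @return data.frame: gene, n, R (impairment-oriented), p
#' @export
impairment_correlations <- function(study, trait = c("GCR", "MMSE"),
                                    samples = NULL) {
  trait <- match.arg(trait)
  tab <- gene_trait_correlations(study$expression, study$phenotypes, trait,
                                 samples = samples)
  if (trait == "MMSE") tab$R <- -tab$R
  tab
}

#' Build the paired cross-disease correlation table
#'
#' Joins impairment-oriented correlations from the AD study and the two HIV
#' regions on gene symbol and classifies each gene: "up" when all three
#' correlations exceed `threshold`, "down" when all three fall below
#' `-threshold` (strict inequalities), otherwise "none".
#'
#' @param r_ad,r_fc,r_bg [impairment_correlations()] tables for AD
#'   hippocampus, HIV frontal cortex, HIV basal ganglia
#' @param threshold quadrant threshold (default 0.25)
#' @return data.frame: gene, R_ad, R_fc, R_bg, class
#' @export
paired_correlation_table <- function(r_ad, r_fc, r_bg, threshold = 0.25) {
  genes <- Reduce(intersect, list(canonical_gene(r_ad$gene),
                                  canonical_gene(r_fc$gene),
                                  canonical_gene(r_bg$gene)))
  if (length(genes) == 0) stop_("no genes common to the three tables")
  genes <- sort(genes)
  pick <- function(tab) tab$R[match(genes, canonical_gene(tab$gene))]
  out <- data.frame(gene = genes, R_ad = pick(r_ad), R_fc = pick(r_fc),
                    R_bg = pick(r_bg), stringsAsFactors = FALSE)
  up <- out$R_ad > threshold & out$R_fc > threshold & out$R_bg > threshold
  down <- out$R_ad < -threshold & out$R_fc < -threshold & out$R_bg < -threshold
  out$class <- ifelse(!is.na(up) & up, "up",
                      ifelse(!is.na(down) & down, "down", "none"))
  attr(out, "threshold") <- threshold
  out
}

#' Extract the up/down impairment gene sets
#'
#' @param paired a [paired_correlation_table()]; its stored threshold is
#'   reused unless `threshold` is given
#' @param threshold optional override of the quadrant threshold
#' @return list: `up`, `down` (character vectors), `counts` (named integer)
#' @export
classify_impairment_genes <- function(paired, threshold = NULL) {
  if (!is.null(threshold)) {
    paired <- paired_correlation_table(
      data.frame(gene = paired$gene, R = paired$R_ad),
      data.frame(gene = paired$gene, R = paired$R_fc),
      data.frame(gene = paired$gene, R = paired$R_bg), threshold)
  }
  list(up = paired$gene[paired$class == "up"],
       down = paired$gene[paired$class == "down"],
       counts = c(up = sum(paired$class == "up"),
                  down = sum(paired$class == "down"),
                  none = sum(paired$class == "none")))
}

#' Enrichment of common impairment genes
#'
#' Runs EASE enrichment separately on the up- and down-regulated common
#' impairment gene sets against the common-gene universe.
#'
#' @param up,down character vectors of impairment genes
#' @param universe common-gene universe
#' @param sets named list of gene sets
#' @return list of two enrichment data.frames: `up`, `down` (empty input
#'   yields an empty result with a warning)
#' @export
common_impairment_enrichment <- function(up, down, universe, sets) {
  run <- function(g, lab) {
    if (length(g) == 0) {
      warn_("empty %s impairment set; returning empty enrichment", lab)
      return(data.frame(category = character(0), list_hits = integer(0),
                        list_total = integer(0), pop_hits = integer(0),
                        pop_total = integer(0), ease = numeric(0),
                        bonferroni = numeric(0)))
    }
    ease_enrichment(g, universe, sets)
  }
  list(up = run(up, "up"), down = run(down, "down"))
}

#' Flag modules enriched for the other disease's impairment genes
#'
#' One-tailed hypergeometric test of each non-grey module against the up and
#' down impairment gene sets from the second disease, over the common-gene
#' universe; a module is flagged "up"/"down" when the corresponding p falls
#' below `alpha` (default 2e-5).
#'
#' @param assignment a `module_assignment` (first disease's network)
#' @param ad_impair_up,ad_impair_down impairment gene sets from the second
#'   disease
#' @param universe gene universe (default: the assigned genes)
#' @param alpha flagging threshold (default 0.00002)
#' @return data.frame: module, p_up, p_down, flag ("up", "down", or "")
#' @export
module_ad_enrichment <- function(assignment, ad_impair_up, ad_impair_down,
                                 universe = NULL, alpha = 0.00002) {
  genes <- canonical_gene(names(assignment$labels))
  labels <- stats::setNames(assignment$labels, genes)
  if (is.null(universe)) universe <- genes
  universe <- unique(canonical_gene(universe))
  labels <- labels[names(labels) %in% universe]
  pt <- length(universe)
  up <- intersect(canonical_gene(ad_impair_up), universe)
  down <- intersect(canonical_gene(ad_impair_down), universe)
  mods <- setdiff(unique(labels), "grey")
  hyp <- function(mg, set) {
    if (length(set) == 0) return(NA_real_)
    ov <- length(intersect(mg, set))
    stats::phyper(ov - 1, length(set), pt - length(set), length(mg),
                  lower.tail = FALSE)
  }
  rows <- lapply(mods, function(m) {
    mg <- names(labels)[labels == m]
    pu <- hyp(mg, up); pd <- hyp(mg, down)
    flag <- ""
    if (!is.na(pu) && pu < alpha) flag <- "up"
    if (!is.na(pd) && pd < alpha && (is.na(pu) || pd < pu)) flag <- "down"
    data.frame(module = m, p_up = pu, p_down = pd, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-disease common hub table
#'
#' Genes whose scaled intramodular connectivity exceeds `threshold` in the AD
#' network and in at least one HIV region (or all regions when
#' `require_all_regions`), grouped by impairment direction. Scaled kIN is
#' non-negative, so the threshold applies within the up- and down-direction
#' gene groups separately; missing module membership renders as "--".
#'
#' @param connectivity_ad,connectivity_fc,connectivity_bg
#'   [scaled_intramodular_connectivity()] tables for AD hippocampus, HIV
#'   frontal cortex, HIV basal ganglia
#' @param directions named vector mapping gene -> "up"/"down" (e.g. from
#'   [classify_impairment_genes()])
#' @param threshold scaled-kIN hub cutoff, strict (default 0.70)
#' @param require_all_regions require hub status in both HIV regions
#' @return data.frame: gene, direction, kin_ad, kin_fc, kin_bg (characters,
#'   "--" where the gene has no module membership in that network)
#' @export
common_hub_table <- function(connectivity_ad, connectivity_fc,
                             connectivity_bg, directions, threshold = 0.70,
                             require_all_regions = FALSE) {
  dir_genes <- canonical_gene(names(directions))
  lookup <- function(tab, g) {
    i <- match(g, canonical_gene(tab$gene))
    ifelse(is.na(i), NA_real_, tab$scaled_kIN[i])
  }
  kad <- lookup(connectivity_ad, dir_genes)
  kfc <- lookup(connectivity_fc, dir_genes)
  kbg <- lookup(connectivity_bg, dir_genes)
  hub <- function(x) !is.na(x) & x > threshold
  hiv_ok <- if (require_all_regions) hub(kfc) & hub(kbg) else hub(kfc) | hub(kbg)
  keep <- hub(kad) & hiv_ok
  fmt <- function(x) ifelse(is.na(x), "--", formatC(x, digits = 2, format = "f"))
  out <- data.frame(gene = dir_genes[keep],
                    direction = unname(directions[keep]),
                    kin_ad = fmt(kad[keep]), kin_fc = fmt(kfc[keep]),
                    kin_bg = fmt(kbg[keep]), stringsAsFactors = FALSE)
  out[order(out$direction, out$gene), , drop = FALSE]
}
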