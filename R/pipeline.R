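# Pipeline defaults. Every constant is either a field convention carried by
# the methods this pipeline reimplements or a documented package decision;
# see the methods vignette for the provenance of each.
pipeline_defaults <- function() {
  list(beta = 12, min_module_size = 30, cut_height = 0.99,
       max_absent_fraction = 0.90, min_present_samples = 6,
       r_top = 0.75, de_alpha = 0.05, impair_threshold = 0.25,
       hub_threshold = 0.70, module_ad_alpha = 0.00002,
       n_permutations = 200, sd_multiplier = 2, seed = 1)
}

.known_keys <- list(
  inputs = c("phenotypes", "probe_map", "gmt", "markers_gmt",
             "ad_expression", "ad_phenotypes", "ad_probe_map"),
  inputs_prefix = c("expression_", "presence_"),
  params = names(pipeline_defaults()),
  run = c("regions", "trait", "group_column", "cross_disease",
          "cross_regions", "trait_filter_groups")
)

#' Read a plain-text pipeline configuration
#'
#' Flat `key = value` lines grouped under `[section]` headers; sections are
#' `inputs`, `params`, and `run`. Unknown sections or keys are errors (fail
#' fast), `#` starts a comment. Region-specific inputs use the key prefixes
#' `expression_<REGION>` and `presence_<REGION>`.
#'
#' @param path configuration file
#' @return a `pipeline_config` list with `inputs`, `params` (defaults merged
#'   in), `run`
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  conf <- list(inputs = list(), params = list(), run = list())
  for (l in lines) {
    if (grepl("^\\[.*\\]$", l)) {
      section <- gsub("^\\[|\\]$", "", l)
      if (!section %in% names(conf)) stop_("unknown config section '%s'", section)
      next
    }
    if (is.na(section)) stop_("key outside of any [section]: '%s'", l)
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_("malformed line '%s'", l)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    ok <- if (section == "inputs") {
      key %in% .known_keys$inputs ||
        any(startsWith(key, .known_keys$inputs_prefix))
    } else key %in% .known_keys[[section]]
    if (!ok) stop_("unknown key '%s' in section [%s]", key, section)
    conf[[section]][[key]] <- val
  }
  defaults <- pipeline_defaults()
  for (k in names(conf$params)) defaults[[k]] <- as.numeric(conf$params[[k]])
  conf$params <- defaults
  bad <- c(
    if (defaults$beta <= 0) "beta",
    if (defaults$min_module_size < 2) "min_module_size",
    if (defaults$max_absent_fraction < 0 || defaults$max_absent_fraction > 1) "max_absent_fraction",
    if (defaults$impair_threshold < 0 || defaults$impair_threshold > 1) "impair_threshold",
    if (defaults$hub_threshold < 0 || defaults$hub_threshold > 1) "hub_threshold",
    if (defaults$de_alpha <= 0 || defaults$de_alpha > 1) "de_alpha")
  if (length(bad)) stop_("parameter(s) out of range: %s", paste(bad, collapse = ", "))
  structure(conf, class = "pipeline_config")
}

.read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_("missing input file '%s'", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, id_col = "gene") {
  d <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stage order per region: outlier removal, quantile normalization, presence
#' filtering, probe collapse, signed network and module detection (labels
#' matched across regions to the first region's), eigengenes, module-trait
#' and module-group statistics, per-gene trait correlations with top tables
#' and EASE enrichment of the p < de_alpha up/down lists; then, when a second
#' disease's inputs are configured, the cross-disease comparison. Every
#' output is deterministic given the config and its seed; a manifest records
#' all parameters used. Inputs are never mutated.
#'
#' @param config a [read_pipeline_config()] result (or path to one)
#' @param out_dir output directory; all artifacts are written beneath it
#' @param stages subset of c("preprocess", "network", "stats", "enrich",
#'   "cross") to run; later stages imply their prerequisites
#' @return invisibly, a named list of written file paths
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("preprocess", "network", "stats",
                                    "enrich", "cross")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(config)) config <- read_pipeline_config(config)
  p <- config$params
  regions <- trimws(strsplit(config$run$regions %||% "R1", ",")[[1]])
  # validate inputs before any computation
  for (rg in regions) {
    key <- paste0("expression_", rg)
    if (is.null(config$inputs[[key]])) stop_("missing input '%s'", key)
    if (!file.exists(config$inputs[[key]]))
      stop_("missing input file '%s'", config$inputs[[key]])
  }
  if (is.null(config$inputs$phenotypes)) stop_("missing input 'phenotypes'")
  if (!file.exists(config$inputs$phenotypes))
    stop_("missing input file '%s'", config$inputs$phenotypes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  cat("", file = logf)
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  written <- list()
  emit <- function(tag, path) { written[[tag]] <<- path; path }

  log("pipeline start; parameters: %s",
      paste(sprintf("%s=%g", names(p), unlist(p)), collapse = " "))
  pheno <- utils::read.csv(config$inputs$phenotypes,
                           stringsAsFactors = FALSE, na.strings = "")
  pheno$sample_id <- as.character(pheno$sample_id)
  probe_map <- NULL
  if (!is.null(config$inputs$probe_map))
    probe_map <- utils::read.delim(config$inputs$probe_map,
                                   stringsAsFactors = FALSE)
  trait <- config$run$trait %||% "GCR"
  group_col <- config$run$group_column %||% "group"
  tf_groups <- config$run$trait_filter_groups
  gmt <- if (!is.null(config$inputs$gmt)) read_gmt(config$inputs$gmt)
  markers <- if (!is.null(config$inputs$markers_gmt))
    read_gmt(config$inputs$markers_gmt)

  assignments <- list(); adjacencies <- list(); processed <- list()
  connectivities <- list()
  for (rg in regions) {
    log("[%s] preprocess", rg)
    expr <- .read_matrix_tsv(config$inputs[[paste0("expression_", rg)]])
    orep <- detect_outlier_arrays(expr, p$sd_multiplier)
    emit(paste0(rg, "_outliers"),
         .write_csv(data.frame(sample = names(orep$mean_iac),
                               mean_iac = unname(orep$mean_iac),
                               flagged = names(orep$mean_iac) %in% orep$flagged_samples),
                    file.path(out_dir, paste0(rg, "_outliers.csv"))))
    if (length(orep$flagged_samples)) {
      log("[%s] dropping %d outlier array(s): %s", rg,
          length(orep$flagged_samples), paste(orep$flagged_samples, collapse = ", "))
      expr <- expr[, !colnames(expr) %in% orep$flagged_samples, drop = FALSE]
    }
    expr <- quantile_normalize(expr)
    pres_key <- paste0("presence_", rg)
    if (!is.null(config$inputs[[pres_key]])) {
      pres <- .read_matrix_tsv(config$inputs[[pres_key]]) == 1
      pres <- pres[rownames(expr), colnames(expr), drop = FALSE]
      expr <- filter_absent(expr, pres, p$max_absent_fraction)
      pres <- pres[rownames(expr), , drop = FALSE]
      expr <- filter_min_present(expr, pres, p$min_present_samples)
      log("[%s] presence filters kept %d rows", rg, nrow(expr))
    }
    if (!is.null(probe_map)) {
      cp <- collapse_probes(expr, probe_map)
      expr <- cp$expression
      log("[%s] collapsed to %d genes", rg, nrow(expr))
    }
    processed[[rg]] <- expr
    emit(paste0(rg, "_processed"),
         .write_matrix_tsv(expr, file.path(out_dir, paste0(rg, "_processed.tsv"))))

    if (!any(c("network", "stats", "enrich", "cross") %in% stages)) next
    log("[%s] network (beta=%g, min_module_size=%d)", rg, p$beta,
        as.integer(p$min_module_size))
    adj <- signed_adjacency(expr, p$beta)
    tom <- topological_overlap(adj)
    asg <- cluster_and_cut(tom, p$min_module_size, p$cut_height)
    if (length(assignments)) asg <- match_labels(assignments[[1]], asg)
    assignments[[rg]] <- asg
    adjacencies[[rg]] <- adj
    emit(paste0(rg, "_modules"),
         write_assignment(asg, file.path(out_dir, paste0(rg, "_modules.tsv"))))
    emit(paste0(rg, "_dendrogram"),
         .write_csv(data.frame(merge_height = asg$dendrogram$height),
                    file.path(out_dir, paste0(rg, "_dendrogram_heights.csv"))))

    if (!any(c("stats", "enrich", "cross") %in% stages)) next
    log("[%s] module statistics", rg)
    ph_rg <- pheno[match(colnames(expr), pheno$sample_id), , drop = FALSE]
    mes <- module_eigengenes(expr, asg)
    emit(paste0(rg, "_eigengenes"),
         .write_csv(data.frame(sample_id = rownames(mes$eigengenes),
                               mes$eigengenes, check.names = FALSE),
                    file.path(out_dir, paste0(rg, "_eigengenes.csv"))))
    filt <- if (!is.null(tf_groups))
      ph_rg[[group_col]] %in% trimws(strsplit(tf_groups, ",")[[1]]) else NULL
    if (!is.null(filt))
      log("[%s] trait correlations restricted to groups: %s", rg, tf_groups)
    stats_rows <- list()
    if (trait %in% names(ph_rg))
      stats_rows$trait <- module_trait_correlation(mes, ph_rg, trait,
                                                   samples = filt)
    if (group_col %in% names(ph_rg)) {
      gt <- module_group_test(mes, ph_rg, group_col)
      stats_rows$group <- data.frame(module = gt$module, trait = group_col,
                                     n = nrow(ph_rg), R = NA_real_,
                                     p = gt$anova_p, stringsAsFactors = FALSE)
      emit(paste0(rg, "_group_tests"),
           .write_csv(gt, file.path(out_dir, paste0(rg, "_group_tests.csv"))))
    }
    if (length(stats_rows))
      emit(paste0(rg, "_module_trait"),
           .write_csv(do.call(rbind, stats_rows),
                      file.path(out_dir, paste0(rg, "_module_trait.csv"))))
    conn <- scaled_intramodular_connectivity(adj, asg)
    connectivities[[rg]] <- conn
    emit(paste0(rg, "_connectivity"),
         .write_csv(conn, file.path(out_dir, paste0(rg, "_connectivity.csv"))))

    if (!any(c("enrich", "cross") %in% stages)) next
    if (trait %in% names(ph_rg)) {
      log("[%s] differential expression vs %s", rg, trait)
      gtc <- gene_trait_correlations(expr, ph_rg, trait, samples = filt)
      emit(paste0(rg, "_gene_trait"),
           .write_csv(gtc, file.path(out_dir, paste0(rg, "_gene_trait.csv"))))
      emit(paste0(rg, "_top_genes"),
           .write_csv(top_gene_table(gtc, p$r_top),
                      file.path(out_dir, paste0(rg, "_top_genes.csv"))))
      if (!is.null(gmt)) {
        sig <- gtc[!is.na(gtc$p) & gtc$p < p$de_alpha, , drop = FALSE]
        for (dir_ in c("up", "down")) {
          gl <- sig$gene[if (dir_ == "up") sig$R > 0 else sig$R < 0]
          if (length(gl) == 0) next
          enr <- ease_enrichment(gl, rownames(expr), gmt)
          emit(paste0(rg, "_enrichment_", dir_),
               .write_csv(enr, file.path(out_dir,
                                         paste0(rg, "_enrichment_", dir_, ".csv"))))
        }
      }
    }
    if (!is.null(markers)) {
      emit(paste0(rg, "_marker_enrichment"),
           .write_csv(user_list_enrichment(asg, markers),
                      file.path(out_dir, paste0(rg, "_marker_enrichment.csv"))))
    }
  }

  do_cross <- "cross" %in% stages &&
    isTRUE(tolower(config$run$cross_disease %||% "false") %in%
             c("true", "yes", "1")) &&
    !is.null(config$inputs$ad_expression)
  if (do_cross) {
    log("cross-disease comparison")
    cross_regions <- trimws(strsplit(config$run$cross_regions %||%
                                       paste(regions[1:min(2, length(regions))],
                                             collapse = ","), ",")[[1]])
    ad_expr <- .read_matrix_tsv(config$inputs$ad_expression)
    ad_ph <- utils::read.csv(config$inputs$ad_phenotypes,
                             stringsAsFactors = FALSE, na.strings = "")
    ad_ph$sample_id <- as.character(ad_ph$sample_id)
    ad_study <- expression_study(ad_expr, ad_ph)
    hiv1 <- expression_study(processed[[cross_regions[1]]],
                             pheno[match(colnames(processed[[cross_regions[1]]]),
                                         pheno$sample_id), , drop = FALSE])
    hiv2 <- expression_study(processed[[cross_regions[2]]],
                             pheno[match(colnames(processed[[cross_regions[2]]]),
                                         pheno$sample_id), , drop = FALSE])
    al1 <- align_common_genes(hiv1, ad_study)
    common <- intersect(al1$genes, canonical_gene(rownames(hiv2$expression)))
    log("common genes across the three matrices: %d", length(common))
    filt1 <- if (!is.null(tf_groups))
      hiv1$phenotypes[[group_col]] %in% trimws(strsplit(tf_groups, ",")[[1]]) else NULL
    filt2 <- if (!is.null(tf_groups))
      hiv2$phenotypes[[group_col]] %in% trimws(strsplit(tf_groups, ",")[[1]]) else NULL
    r_fc <- impairment_correlations(hiv1, "GCR", samples = filt1)
    r_bg <- impairment_correlations(hiv2, "GCR", samples = filt2)
    r_ad <- impairment_correlations(ad_study, "MMSE")
    keep <- function(tab) tab[canonical_gene(tab$gene) %in% common, , drop = FALSE]
    paired <- paired_correlation_table(keep(r_ad), keep(r_fc), keep(r_bg),
                                       p$impair_threshold)
    emit("paired_correlations",
         .write_csv(paired, file.path(out_dir, "paired_correlations.csv")))
    cls <- classify_impairment_genes(paired)
    log("impairment genes: %d up, %d down", cls$counts[["up"]], cls$counts[["down"]])
    emit("impairment_counts",
         .write_csv(data.frame(class = names(cls$counts),
                               n = as.integer(cls$counts)),
                    file.path(out_dir, "impairment_counts.csv")))
    if (!is.null(gmt)) {
      enr <- common_impairment_enrichment(cls$up, cls$down, common, gmt)
      emit("impairment_enrichment_up",
           .write_csv(enr$up, file.path(out_dir, "impairment_enrichment_up.csv")))
      emit("impairment_enrichment_down",
           .write_csv(enr$down, file.path(out_dir, "impairment_enrichment_down.csv")))
    }
    asg1 <- assignments[[cross_regions[1]]]
    ad_up <- paired$gene[paired$R_ad > p$impair_threshold]
    ad_down <- paired$gene[paired$R_ad < -p$impair_threshold]
    emit("module_ad_enrichment",
         .write_csv(module_ad_enrichment(asg1, ad_up, ad_down, common,
                                         p$module_ad_alpha),
                    file.path(out_dir, "module_ad_enrichment.csv")))
    # hub comparison: AD network built on its common genes
    ad_sub <- ad_study$expression[match(common, canonical_gene(rownames(ad_study$expression))), ,
                                  drop = FALSE]
    rownames(ad_sub) <- common
    ad_adj <- signed_adjacency(ad_sub, p$beta)
    ad_asg <- cluster_and_cut(topological_overlap(ad_adj), p$min_module_size,
                              p$cut_height)
    conn_ad <- scaled_intramodular_connectivity(ad_adj, ad_asg)
    dirs <- stats::setNames(paired$class[paired$class != "none"],
                            paired$gene[paired$class != "none"])
    hubs <- common_hub_table(conn_ad, connectivities[[cross_regions[1]]],
                             connectivities[[cross_regions[2]]], dirs,
                             p$hub_threshold)
    emit("common_hubs",
         .write_csv(hubs, file.path(out_dir, "common_hubs.csv")))
  }

  manifest <- c(sprintf("coexnet %s", as.character(utils::packageVersion("coexnet"))),
                sprintf("regions: %s", paste(regions, collapse = ",")),
                sprintf("%s = %g", names(p), unlist(p)),
                sprintf("output: %s", names(written)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  log("pipeline complete; %d artifacts", length(written))
  invisible(written)
}
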