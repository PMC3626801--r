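#' Specify a planted coexpression module
#'
#' A module is driven by one latent factor shared by its genes. Each gene is
#' `group_shift + factor_loading * factor + N(0, noise_sd)`, so the module
#' summarizes to a first principal component by construction and eigengene
#' recovery is analytically predictable.
#'
#' @param module_id short label; used as a prefix for member gene symbols
#' @param size number of genes in the module (>= 1)
#' @param factor_loading strength of the shared latent factor, in [0, 1]
#' @param trait_effect target population correlation between the module's
#'   latent factor and the continuous impairment trait, in [-1, 1]
#' @param group_shifts named numeric vector of per-group mean offsets
#'   (expression units); must name every declared group
#' @return a `module_spec` list
#' @export
module_spec <- function(module_id, size, factor_loading,
                        trait_effect = 0,
                        group_shifts = c(A = 0, B = 0, C = 0, D = 0)) {
  if (size < 1) stop_("module '%s': size must be >= 1", module_id)
  if (abs(factor_loading) > 1) stop_("module '%s': |factor_loading| must be <= 1", module_id)
  if (abs(trait_effect) > 1) stop_("module '%s': |trait_effect| must be <= 1", module_id)
  structure(list(module_id = as.character(module_id), size = as.integer(size),
                 factor_loading = factor_loading, trait_effect = trait_effect,
                 group_shifts = group_shifts),
            class = "module_spec")
}

#' Specify a synthetic expression study
#'
#' @param modules list of [module_spec()] objects
#' @param n_background_genes number of trait- and module-independent genes
#' @param samples_per_group named integer vector of sample counts per group
#'   (defaults name groups A-D)
#' @param noise_sd per-gene Gaussian noise SD, expression units (>= 0)
#' @param probes_per_gene integer; when > 1, each gene is emitted as that many
#'   probes offset by a per-probe constant, to exercise probe collapse
#' @param absent_fraction probability in [0, 1] that any expression cell is
#'   called "absent" (independent Bernoulli draws; no probe-level chemistry)
#' @param traits which phenotype scores to emit: subset of
#'   c("GCR", "CPE", "MMSE")
#' @param seed integer; fully determines the generated study
#' @return a `synthetic_design` list
#' @export
synthetic_design <- function(modules = list(), n_background_genes = 0,
                             samples_per_group = c(A = 6, B = 5, C = 5, D = 5),
                             noise_sd = 0.5, probes_per_gene = 1,
                             absent_fraction = 0, traits = c("GCR", "CPE"),
                             seed = 1) {
  if (noise_sd < 0) stop_("noise_sd must be non-negative")
  if (absent_fraction < 0 || absent_fraction > 1)
    stop_("absent_fraction must be in [0, 1]")
  if (probes_per_gene < 1) stop_("probes_per_gene must be >= 1")
  if (is.null(names(samples_per_group)))
    stop_("samples_per_group must be a named vector")
  for (m in modules) {
    miss <- setdiff(names(samples_per_group), names(m$group_shifts))
    if (length(miss))
      stop_("module '%s': group_shifts missing groups: %s",
            m$module_id, paste(miss, collapse = ", "))
    bad <- names(m$group_shifts)[m$group_shifts != 0 &
                                 names(m$group_shifts) %in% names(samples_per_group) &
                                 samples_per_group[names(m$group_shifts)] == 0]
    bad <- bad[!is.na(bad)]
    if (length(bad))
      stop_("module '%s': nonzero group_shift for empty group(s): %s",
            m$module_id, paste(bad, collapse = ", "))
  }
  structure(list(modules = modules,
                 n_background_genes = as.integer(n_background_genes),
                 samples_per_group = samples_per_group,
                 noise_sd = noise_sd,
                 probes_per_gene = as.integer(probes_per_gene),
                 absent_fraction = absent_fraction,
                 traits = match.arg(traits, c("GCR", "CPE", "MMSE"),
                                    several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Construct an expression study container
#'
#' The unit every pipeline stage consumes and produces: a probes-or-genes by
#' samples log-intensity matrix, sample phenotypes, an optional presence-call
#' matrix aligned to the expression matrix, and a probe-to-gene map.
#'
#' @param expression numeric matrix, rows = probes or genes, columns = samples
#' @param phenotypes data.frame with `sample_id` plus optional `group`,
#'   `GCR` (1-9), `CPE` (>= 0), `MMSE` (0-30); one row per sample
#' @param probe_map data.frame with columns `probe`, `gene` (may be NULL when
#'   rows already are gene symbols)
#' @param presence logical matrix aligned to `expression`, or NULL
#' @param truth optional list of generator ground truth (planted module per
#'   gene, latent impairment, shared-gene directions); NULL for real data
#' @return an `expression_study` object
#' @export
expression_study <- function(expression, phenotypes, probe_map = NULL,
                             presence = NULL, truth = NULL) {
  expression <- as.matrix(expression)
  if (ncol(expression) != nrow(phenotypes))
    stop_("expression has %d columns but phenotypes has %d rows",
          ncol(expression), nrow(phenotypes))
  if (!identical(colnames(expression), as.character(phenotypes$sample_id)))
    stop_("expression column names must equal phenotypes$sample_id, in order")
  if (!is.null(presence)) {
    if (!identical(dim(presence), dim(expression)))
      stop_("presence matrix shape differs from expression")
    dimnames(presence) <- dimnames(expression)
  }
  if ("GCR" %in% names(phenotypes)) {
    g <- phenotypes$GCR
    if (any(!is.na(g) & (g < 1 | g > 9))) stop_("GCR values must lie in 1-9")
  }
  if ("MMSE" %in% names(phenotypes)) {
    m <- phenotypes$MMSE
    if (any(!is.na(m) & (m < 0 | m > 30))) stop_("MMSE values must lie in 0-30")
  }
  structure(list(expression = expression, phenotypes = phenotypes,
                 probe_map = probe_map, presence = presence, truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d rows x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  presence calls: %s; probe map: %s; ground truth: %s\n",
              if (is.null(x$presence)) "no" else "yes",
              if (is.null(x$probe_map)) "no" else "yes",
              if (is.null(x$truth)) "no" else "yes"))
  if ("group" %in% names(x$phenotypes))
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$phenotypes$group)),
                                   table(x$phenotypes$group)), collapse = " "), "\n")
  invisible(x)
}

# Latent algebra, documented once:
#   z        ~ N(0,1)                        per-sample impairment latent
#   f_m      = rho_m * z + sqrt(1-rho_m^2) * e_m,  e_m ~ N(0,1)
#     so cor(f_m, z) = rho_m (population), rho_m = trait_effect of module m
#   gene i in m: x_i = base + shift[group] + loading_m * f_m + N(0, noise_sd)
#   background:  x   = base + N(0, noise_sd)
# Trait scores are clipped linear transforms of z: GCR = 5 + 2z in [1,9]
# (higher = more impaired), MMSE = 21 - 6z in [0,30] (lower = more impaired).
# CPE is an independent N(7, 2) score clipped at 0. Clipping at ~2 SD
# attenuates cor(trait, z) by well under the 0.05 recovery tolerance.
.base_intensity <- 7

generate_phenotypes <- function(design, z) {
  n <- length(z)
  ph <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                   group = rep(names(design$samples_per_group),
                               times = design$samples_per_group),
                   stringsAsFactors = FALSE)
  if ("GCR" %in% design$traits)  ph$GCR  <- pmin(9, pmax(1, 5 + 2 * z))
  if ("CPE" %in% design$traits)  ph$CPE  <- pmax(0, 7 + 2 * stats::rnorm(n))
  if ("MMSE" %in% design$traits) ph$MMSE <- pmin(30, pmax(0, 21 - 6 * z))
  ph
}

#' Generate a synthetic expression study
#'
#' Plants coexpression modules driven by latent factors, a continuous
#' impairment trait correlated with those factors, per-group mean shifts,
#' optional probe multiplicity and Bernoulli presence calls. Output is fully
#' determined by `design$seed`.
#'
#' @param design a [synthetic_design()]
#' @return an [expression_study()] with `truth` holding the planted module of
#'   every gene ("background" for noise genes) and the latent impairment
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  if (design$noise_sd < 0) stop_("noise_sd must be non-negative")
  set.seed(substream_seed(design$seed, "study"))
  n <- sum(design$samples_per_group)
  if (n < 1) stop_("design has no samples")

  z <- stats::rnorm(n)
  ph <- generate_phenotypes(design, z)
  grp <- ph$group

  gene_rows <- list(); gene_names <- character(0); truth_mod <- character(0)
  factors <- matrix(numeric(0), n, 0)
  for (m in design$modules) {
    e <- stats::rnorm(n)
    f <- m$trait_effect * z + sqrt(1 - m$trait_effect^2) * e
    factors <- cbind(factors, f)
    colnames(factors)[ncol(factors)] <- m$module_id
    shift <- unname(m$group_shifts[grp])
    noise <- matrix(stats::rnorm(m$size * n, sd = design$noise_sd), m$size, n)
    block <- .base_intensity +
      matrix(shift, m$size, n, byrow = TRUE) +
      m$factor_loading * matrix(f, m$size, n, byrow = TRUE) + noise
    gene_rows[[length(gene_rows) + 1L]] <- block
    gene_names <- c(gene_names,
                    sprintf("%sG%03d", canonical_gene(m$module_id), seq_len(m$size)))
    truth_mod <- c(truth_mod, rep(m$module_id, m$size))
  }
  if (design$n_background_genes > 0) {
    nb <- design$n_background_genes
    gene_rows[[length(gene_rows) + 1L]] <- .base_intensity +
      matrix(stats::rnorm(nb * n, sd = design$noise_sd), nb, n)
    gene_names <- c(gene_names, sprintf("GENE%04d", seq_len(nb)))
    truth_mod <- c(truth_mod, rep("background", nb))
  }
  expr <- do.call(rbind, gene_rows)
  rownames(expr) <- gene_names
  colnames(expr) <- ph$sample_id
  names(truth_mod) <- gene_names

  # probe multiplicity: per-probe constant offsets on top of the gene profile
  if (design$probes_per_gene > 1) {
    k <- design$probes_per_gene
    off <- matrix(stats::rnorm(nrow(expr) * k), nrow(expr), k)
    probe_ids <- as.vector(t(outer(gene_names, seq_len(k),
                                   function(g, j) sprintf("%s_P%d", g, j))))
    expr <- expr[rep(seq_len(nrow(expr)), each = k), , drop = FALSE] +
      as.vector(t(off))
    rownames(expr) <- probe_ids
    probe_map <- data.frame(probe = probe_ids,
                            gene = rep(gene_names, each = k),
                            stringsAsFactors = FALSE)
  } else {
    probe_map <- data.frame(probe = gene_names, gene = gene_names,
                            stringsAsFactors = FALSE)
  }

  presence <- NULL
  if (design$absent_fraction > 0) {
    presence <- matrix(stats::runif(length(expr)) >= design$absent_fraction,
                       nrow(expr), ncol(expr), dimnames = dimnames(expr))
  }

  expression_study(expr, ph, probe_map = probe_map, presence = presence,
                   truth = list(modules = truth_mod, impairment = z,
                                factors = factors))
}

#' Generate a paired two-disease design with a shared impairment signature
#'
#' Produces two independent studies (distinct sample cohorts) in which a
#' designated set of gene symbols, present in both gene universes, carries an
#' impairment correlation of magnitude `shared_effect` in both: with GCR
#' (higher = more impaired) in the first study and with inverted MMSE (lower
#' MMSE = more impaired) in the second. Shared genes are regenerated as
#' `base + d * a * z + sqrt(1 - a^2) * e` with `a = shared_effect` and
#' direction `d` in {+1, -1}, so their population trait correlation is
#' `d * a` exactly (before trait clipping). All other genes follow their
#' design specs.
#'
#' @param design_hiv design for study 1 (GCR is added to its traits)
#' @param design_ad design for study 2 (MMSE is added to its traits)
#' @param shared_impairment_genes character vector of gene symbols planted in
#'   both universes (typically background genes)
#' @param shared_effect magnitude in [0, 1] of the planted impairment
#'   correlation
#' @param shared_directions optional vector of +1/-1 per shared gene; default
#'   alternates up/down (first half up, second half down)
#' @return list with elements `hiv` and `ad` ([expression_study()] objects);
#'   each `truth` gains `shared_genes` and `shared_direction`
#' @export
generate_paired_disease_studies <- function(design_hiv, design_ad,
                                            shared_impairment_genes,
                                            shared_effect,
                                            shared_directions = NULL) {
  if (shared_effect < 0 || shared_effect > 1)
    stop_("shared_effect must be in [0, 1]")
  design_hiv$traits <- union(design_hiv$traits, "GCR")
  design_ad$traits <- union(design_ad$traits, "MMSE")
  s1 <- generate_study(design_hiv)
  s2 <- generate_study(design_ad)
  u1 <- canonical_gene(s1$probe_map$gene); u2 <- canonical_gene(s2$probe_map$gene)
  if (length(intersect(u1, u2)) == 0)
    stop_("gene universes of the two designs are disjoint")
  shared <- canonical_gene(shared_impairment_genes)
  if (length(shared)) {
    missing1 <- setdiff(shared, u1); missing2 <- setdiff(shared, u2)
    if (length(missing1) || length(missing2))
      stop_("shared genes absent from a design's universe: %s",
            paste(union(missing1, missing2), collapse = ", "))
    if (is.null(shared_directions)) {
      shared_directions <- rep(c(1, -1),
                               c(ceiling(length(shared) / 2),
                                 floor(length(shared) / 2)))
    }
    if (length(shared_directions) != length(shared))
      stop_("shared_directions must have one entry per shared gene")
    names(shared_directions) <- shared

    plant <- function(study, design, tag) {
      set.seed(substream_seed(design$seed, paste0("shared-", tag)))
      z <- study$truth$impairment
      n <- length(z)
      rows <- which(canonical_gene(study$probe_map$gene) %in% shared)
      for (i in rows) {
        g <- canonical_gene(study$probe_map$gene[i])
        d <- shared_directions[[g]]
        study$expression[i, ] <- .base_intensity +
          d * shared_effect * z + sqrt(1 - shared_effect^2) * stats::rnorm(n)
      }
      study$truth$shared_genes <- shared
      study$truth$shared_direction <- shared_directions
      study
    }
    s1 <- plant(s1, design_hiv, "hiv")
    s2 <- plant(s2, design_ad, "ad")
  } else {
    s1$truth$shared_genes <- character(0)
    s2$truth$shared_genes <- character(0)
  }
  list(hiv = s1, ad = s2)
}

#' Write a study to plain-text fixtures
#'
#' Emits `expression.tsv` (first column `probe`, header = sample ids),
#' `phenotypes.csv` (empty cell = missing), `probe_map.tsv`, and, only when
#' presence calls exist, `presence.tsv`. Round-trips through [read_study()].
#'
#' @param study an [expression_study()]
#' @param directory target directory (created if needed)
#' @return named character vector of written file paths
#' @export
write_fixtures <- function(study, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop_("cannot create directory '%s'", directory)
  paths <- c(expression = file.path(directory, "expression.tsv"),
             phenotypes = file.path(directory, "phenotypes.csv"))
  ed <- data.frame(probe = rownames(study$expression),
                   study$expression, check.names = FALSE)
  utils::write.table(ed, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$phenotypes, paths[["phenotypes"]], sep = ",",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(study$probe_map)) {
    paths[["probe_map"]] <- file.path(directory, "probe_map.tsv")
    utils::write.table(study$probe_map, paths[["probe_map"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(study$presence)) {
    paths[["presence"]] <- file.path(directory, "presence.tsv")
    pd <- data.frame(probe = rownames(study$presence),
                     study$presence * 1L, check.names = FALSE)
    utils::write.table(pd, paths[["presence"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}

#' Read a study from plain-text fixtures
#'
#' Counterpart of [write_fixtures()]. The presence and probe-map files are
#' optional; their absence is tolerated.
#'
#' @param directory directory holding `expression.tsv` and `phenotypes.csv`
#' @return an [expression_study()] (without generator ground truth)
#' @export
read_study <- function(directory) {
  fe <- file.path(directory, "expression.tsv")
  fp <- file.path(directory, "phenotypes.csv")
  if (!file.exists(fe)) stop_("missing expression file '%s'", fe)
  if (!file.exists(fp)) stop_("missing phenotype file '%s'", fp)
  ed <- utils::read.delim(fe, check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(ed[, -1, drop = FALSE])
  rownames(expr) <- ed[[1]]
  ph <- utils::read.csv(fp, stringsAsFactors = FALSE, na.strings = "")
  ph$sample_id <- as.character(ph$sample_id)
  pm <- NULL
  fm <- file.path(directory, "probe_map.tsv")
  if (file.exists(fm))
    pm <- utils::read.delim(fm, stringsAsFactors = FALSE)
  pres <- NULL
  fpr <- file.path(directory, "presence.tsv")
  if (file.exists(fpr)) {
    pd <- utils::read.delim(fpr, check.names = FALSE, stringsAsFactors = FALSE)
    pres <- as.matrix(pd[, -1, drop = FALSE]) == 1
    rownames(pres) <- pd[[1]]
  }
  expression_study(expr, ph, probe_map = pm, presence = pres)
}
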