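toy_study <- function(genes, n = 8, seed = 1, traits = "GCR") {
  set.seed(seed)
  expr <- matrix(rnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, paste0("S", 1:n)))
  ph <- data.frame(sample_id = colnames(expr))
  if ("GCR" %in% traits) ph$GCR <- pmin(9, pmax(1, 5 + 2 * rnorm(n)))
  if ("MMSE" %in% traits) ph$MMSE <- pmin(30, pmax(0, 21 - 6 * rnorm(n)))
  expression_study(expr, ph)
}

test_that("common-gene alignment matches the set-intersection oracle", {
  s1 <- toy_study(c("B", "A", "C", "D"), seed = 1)
  s2 <- toy_study(c("c", "E", "a", "F"), seed = 2, traits = "MMSE")
  al <- align_common_genes(s1, s2)
  expect_identical(al$genes, sort(intersect(c("B", "A", "C", "D"),
                                            toupper(c("c", "E", "a", "F")))))
  expect_identical(rownames(al$study1$expression), al$genes)
  expect_identical(rownames(al$study2$expression), al$genes)
  # identical universes: all genes retained
  al2 <- align_common_genes(s1, toy_study(c("A", "B", "C", "D"), seed = 3))
  expect_length(al2$genes, 4)
  expect_error(align_common_genes(s1, toy_study(c("X", "Y"), seed = 4)),
               "common")
})

test_that("impairment correlations orient GCR directly and MMSE flipped", {
  n <- 10
  ph <- data.frame(sample_id = paste0("S", 1:n),
                   GCR = seq(1, 9, length.out = n),
                   MMSE = seq(30, 0, length.out = n))
  expr <- rbind(up_gene = seq_len(n),         # rises with impairment
                down_gene = -seq_len(n))
  colnames(expr) <- ph$sample_id
  s <- expression_study(expr, ph)
  r_gcr <- impairment_correlations(s, "GCR")
  expect_equal(r_gcr$R[r_gcr$gene == "up_gene"], 1, tolerance = 1e-12)
  r_mmse <- impairment_correlations(s, "MMSE")
  # expression falling as MMSE falls = down with impairment
  expect_equal(r_mmse$R[r_mmse$gene == "up_gene"], 1, tolerance = 1e-12)
  expect_equal(r_mmse$R[r_mmse$gene == "down_gene"], -1, tolerance = 1e-12)
})

test_that("null impairment correlations are symmetric about zero", {
  s <- toy_study(sprintf("G%03d", 1:400), n = 30, seed = 5)
  r <- impairment_correlations(s, "GCR")
  expect_lt(abs(mean(r$R > 0) - 0.5), 0.1)
  expect_lt(abs(median(r$R)), 0.05)
})

test_that("quadrant classification uses strict thresholds in all datasets", {
  mk <- function(g, ad, fc, bg) data.frame(gene = g, R = c(ad, fc, bg))
  tab <- function(ad, fc, bg)
    paired_correlation_table(data.frame(gene = "g", R = ad),
                             data.frame(gene = "g", R = fc),
                             data.frame(gene = "g", R = bg))
  expect_identical(tab(0.3, 0.3, 0.3)$class, "up")
  expect_identical(tab(0.25, 0.3, 0.3)$class, "none")   # boundary is strict
  expect_identical(tab(0.3, -0.3, 0.3)$class, "none")   # mixed signs
  expect_identical(tab(-0.3, -0.26, -0.9)$class, "down")
})

test_that("classification counts are monotone non-increasing in threshold", {
  set.seed(66)
  n <- 500
  mk <- function() data.frame(gene = sprintf("G%03d", 1:n),
                              R = runif(n, -1, 1) * 0.6)
  r_ad <- mk(); r_fc <- mk(); r_bg <- mk()
  counts <- sapply(c(0.1, 0.25, 0.4, 0.6), function(th) {
    cls <- classify_impairment_genes(
      paired_correlation_table(r_ad, r_fc, r_bg, th))
    cls$counts[["up"]] + cls$counts[["down"]]
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("sign coherence: flipping MMSE and GCR interpretation together", {
  s <- toy_study(sprintf("G%02d", 1:50), n = 20, seed = 7,
                 traits = c("GCR", "MMSE"))
  r1 <- impairment_correlations(s, "MMSE")
  s_flipped <- s
  s_flipped$phenotypes$MMSE <- 30 - s_flipped$phenotypes$MMSE
  # flipped MMSE behaves like a GCR-style score: direct correlation
  r2 <- gene_trait_correlations(s_flipped$expression, s_flipped$phenotypes,
                                "MMSE")
  expect_equal(r1$R, r2$R, tolerance = 1e-12)
})

test_that("planted shared genes are recovered in the correct quadrant", {
  mk <- function(seed) synthetic_design(
    n_background_genes = 250,
    samples_per_group = c(A = 15, B = 15, C = 15, D = 15),
    noise_sd = 1, seed = seed)
  shared <- sprintf("GENE%04d", 1:100)
  recov <- sapply(1:5, function(i) {
    ps1 <- generate_paired_disease_studies(mk(100 + i), mk(200 + i), shared, 0.6)
    ps2 <- generate_paired_disease_studies(mk(300 + i), mk(400 + i), shared, 0.6)
    r_fc <- impairment_correlations(ps1$hiv, "GCR")
    r_bg <- impairment_correlations(ps2$hiv, "GCR")
    r_ad <- impairment_correlations(ps1$ad, "MMSE")
    cls <- classify_impairment_genes(
      paired_correlation_table(r_ad, r_fc, r_bg))
    dirs <- ps1$hiv$truth$shared_direction
    mean(c(names(dirs)[dirs == 1] %in% cls$up,
           names(dirs)[dirs == -1] %in% cls$down))
  })
  expect_gte(median(recov), 0.8)
})

test_that("planted category enrichment ranks first in the down set", {
  set.seed(68)
  universe <- sprintf("G%03d", 1:300)
  mito <- universe[1:40]
  down <- c(universe[1:30], universe[100:110])  # mostly mito genes
  sets <- list(MITOCHONDRION = mito,
               OTHER1 = universe[150:200], OTHER2 = universe[201:260])
  enr <- common_impairment_enrichment(up = character(0), down = down,
                                      universe = universe, sets = sets) |>
    suppressWarnings()
  expect_identical(enr$down$category[1], "MITOCHONDRION")
  expect_identical(nrow(enr$up), 0L)
})

test_that("module AD-enrichment flags planted overlap; enumeration oracle", {
  genes <- sprintf("G%02d", 1:30)
  labels <- setNames(rep("grey", 30), genes)
  labels[1:10] <- "turquoise"
  asg <- structure(list(labels = labels, min_module_size = 2L),
                   class = "module_assignment")
  up <- genes[1:9]  # 9 of 10 module genes
  res <- module_ad_enrichment(asg, up, character(0), alpha = 0.001)
  expect_identical(res$flag, "up")
  expect_equal(res$p_up, hyper_tail_oracle(9, 9, 30, 10), tolerance = 1e-12)
  # zero overlap: not flagged
  res2 <- module_ad_enrichment(asg, genes[25:30], character(0), alpha = 0.05)
  expect_identical(res2$flag, "")
  res3 <- module_ad_enrichment(asg, character(0), character(0))
  expect_identical(res3$flag, "")
})

test_that("common hub table applies strict thresholds and region logic", {
  conn <- function(g, k) data.frame(gene = g, module = "m", kIN = k,
                                    scaled_kIN = k)
  genes <- c("HUB", "EDGE", "ADONLY", "NOAD")
  ad <- conn(genes, c(1.0, 0.70, 0.9, 0.2))
  fc <- conn(genes, c(1.0, 0.9, 0.3, 0.95))
  bg <- conn(c("HUB", "EDGE", "NOAD"), c(1.0, 0.9, 0.9))  # ADONLY missing
  dirs <- setNames(rep("up", 4), genes)
  tab <- common_hub_table(ad, fc, bg, dirs, threshold = 0.70)
  expect_setequal(tab$gene, "HUB")          # EDGE at exactly 0.70 excluded
  expect_identical(tab$kin_ad, "1.00")
  # ADONLY: hub in AD but neither HIV region above threshold -> excluded
  tab2 <- common_hub_table(ad, fc, bg, dirs, threshold = 0.25)
  expect_true("ADONLY" %in% tab2$gene)
  expect_identical(tab2$kin_bg[tab2$gene == "ADONLY"], "--")
  tab3 <- common_hub_table(ad, fc, bg, dirs, threshold = 0.25,
                           require_all_regions = TRUE)
  expect_false("ADONLY" %in% tab3$gene)
})
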