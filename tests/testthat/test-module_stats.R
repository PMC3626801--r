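make_assignment <- function(labels) {
  structure(list(labels = labels, min_module_size = 2L),
            class = "module_assignment")
}

test_that("eigengene of identical profiles explains all variance", {
  prof <- rnorm(12)
  expr <- matrix(rep(prof, each = 6), 6, 12,
                 dimnames = list(paste0("g", 1:6), paste0("S", 1:12)))
  asg <- make_assignment(setNames(rep("turquoise", 6), rownames(expr)))
  mes <- module_eigengenes(expr, asg)
  expect_equal(unname(mes$variance_explained), 1, tolerance = 1e-12)
  expect_equal(abs(cor(mes$eigengenes[, 1], prof)), 1, tolerance = 1e-12)
  expect_equal(sd(mes$eigengenes[, 1]), 1, tolerance = 1e-12)
})

test_that("eigengene matches the leading eigenvector oracle", {
  set.seed(41)
  expr <- matrix(rnorm(10 * 20), 10, 20,
                 dimnames = list(paste0("g", 1:10), paste0("S", 1:20)))
  asg <- make_assignment(setNames(rep("blue", 10), rownames(expr)))
  mes <- module_eigengenes(expr, asg)
  z <- t(scale(t(expr)))
  ev <- eigen(cor(t(expr)), symmetric = TRUE)
  me_oracle <- as.vector(t(z) %*% ev$vectors[, 1])
  expect_equal(abs(cor(mes$eigengenes[, 1], me_oracle)), 1, tolerance = 1e-8)
  expect_equal(unname(mes$variance_explained), ev$values[1] / sum(ev$values),
               tolerance = 1e-8)
})

test_that("eigengene orientation makes mean kME non-negative; scaling-invariant", {
  set.seed(42)
  s <- generate_study(three_module_design(42))
  tom <- topological_overlap(signed_adjacency(s$expression))
  asg <- cluster_and_cut(tom, 30)
  mes <- module_eigengenes(s$expression, asg)
  kme <- module_membership(s$expression, mes)
  for (m in colnames(mes$eigengenes)) {
    expect_gte(mean(kme[names(asg$labels)[asg$labels == m], m]), 0)
  }
  # positive per-gene scaling leaves the ME unchanged (genes are z-scored)
  expr2 <- s$expression * runif(nrow(s$expression), 0.5, 3)
  mes2 <- module_eigengenes(expr2, asg)
  expect_equal(mes2$eigengenes, mes$eigengenes, tolerance = 1e-8)
})

test_that("eigengene errors and warnings on degenerate genes", {
  expr <- rbind(g1 = rep(1, 5), g2 = rep(2, 5))
  colnames(expr) <- paste0("S", 1:5)
  asg <- make_assignment(setNames(rep("red", 2), rownames(expr)))
  expect_error(module_eigengenes(expr, asg), "red")
  expr2 <- rbind(expr, g3 = rnorm(5), g4 = rnorm(5))
  asg2 <- make_assignment(setNames(rep("red", 4), rownames(expr2)))
  expect_warning(mes <- module_eigengenes(expr2, asg2), "constant")
  expect_equal(ncol(mes$eigengenes), 1)
})

test_that("kME equals direct Pearson correlation; constant gene flagged", {
  set.seed(43)
  expr <- matrix(rnorm(8 * 15), 8, 15,
                 dimnames = list(paste0("g", 1:8), paste0("S", 1:15)))
  asg <- make_assignment(setNames(rep(c("turquoise", "blue"), each = 4),
                                  rownames(expr)))
  mes <- module_eigengenes(expr, asg)
  kme <- module_membership(expr, mes)
  for (g in rownames(expr)) for (m in colnames(kme))
    expect_equal(kme[g, m], cor(expr[g, ], mes$eigengenes[, m]),
                 tolerance = 1e-12)
  # gene identical to the ME gets kME 1
  expr2 <- rbind(expr, me_copy = mes$eigengenes[, "turquoise"])
  expect_equal(module_membership(expr2, mes)["me_copy", "turquoise"], 1,
               tolerance = 1e-12)
  expr3 <- rbind(expr, flat = rep(1, 15))
  expect_warning(kme3 <- module_membership(expr3, mes), "zero-variance")
  expect_true(all(is.na(kme3["flat", ])))
})

test_that("scaled intramodular connectivity matches hand-computed values", {
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 0.5
  a[1, 3] <- a[3, 1] <- 0.3
  a[2, 3] <- a[3, 2] <- 0.2
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  asg <- make_assignment(setNames(rep("turquoise", 3), rownames(a)))
  ct <- scaled_intramodular_connectivity(a, asg)
  expect_equal(ct$kIN, c(0.8, 0.7, 0.5))
  expect_equal(ct$scaled_kIN, c(1.0, 0.875, 0.625))
  expect_equal(sum(ct$scaled_kIN == 1), 1)
})

test_that("two-gene modules both scale to 1; grey gets NA", {
  a <- diag(4)
  a[1, 2] <- a[2, 1] <- 0.4
  dimnames(a) <- list(paste0("g", 1:4), paste0("g", 1:4))
  asg <- make_assignment(setNames(c("blue", "blue", "grey", "grey"),
                                  rownames(a)))
  ct <- scaled_intramodular_connectivity(a, asg)
  expect_equal(ct$scaled_kIN[1:2], c(1, 1))
  expect_true(all(is.na(ct$scaled_kIN[3:4])))
})

test_that("module-trait correlation recovers a planted effect and matches a permutation p", {
  d <- synthetic_design(modules = list(module_spec("M1", 30, 0.9,
                                                   trait_effect = 0.6)),
                        samples_per_group = c(A = 50, B = 50, C = 50, D = 50),
                        noise_sd = 0.5, seed = 44)
  s <- generate_study(d)
  asg <- make_assignment(s$truth$modules)
  names(asg$labels) <- rownames(s$expression)
  asg$labels[asg$labels == "M1"] <- "turquoise"
  mes <- module_eigengenes(s$expression, asg)
  res <- module_trait_correlation(mes, s$phenotypes, "GCR")
  expect_equal(abs(res$R), 0.6, tolerance = 0.1)
  # permutation oracle for the t-based p at a moderate effect size
  # (a strong effect saturates any permutation p at 1/(B+1))
  set.seed(1)
  me <- mes$eigengenes[, 1]
  tr <- 0.15 * scale(me)[, 1] + rnorm(length(me))
  ph2 <- s$phenotypes; ph2$noisy <- tr
  res2 <- module_trait_correlation(mes, ph2, "noisy")
  robs <- abs(cor(me, tr))
  rperm <- replicate(10000, abs(cor(me, sample(tr))))
  p_perm <- (1 + sum(rperm >= robs)) / 10001
  mc_err <- 4 * sqrt(max(p_perm, res2$p) / 10000) + 2e-4
  expect_lt(abs(res2$p - p_perm), mc_err)
})

test_that("module-trait correlation handles exact and degenerate traits", {
  set.seed(45)
  expr <- matrix(rnorm(6 * 10), 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("S", 1:10)))
  asg <- make_assignment(setNames(rep("blue", 6), rownames(expr)))
  mes <- module_eigengenes(expr, asg)
  ph <- data.frame(sample_id = paste0("S", 1:10),
                   me_trait = mes$eigengenes[, 1],
                   flat = 1, mostly_na = c(1, 2, NA, NA, NA, NA, NA, NA, NA, NA))
  res <- module_trait_correlation(mes, ph, "me_trait")
  expect_equal(res$R, 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(mes, ph, "flat"), "constant")
  expect_error(module_trait_correlation(mes, ph, "mostly_na"), "4 non-missing")
})

test_that("group tests: planted shift rejects; F matches the textbook oracle", {
  d <- synthetic_design(modules = list(module_spec("M1", 20, 0.9,
      group_shifts = c(A = 0, B = 0, C = 0, D = 3))),
      samples_per_group = c(A = 10, B = 10, C = 10, D = 10),
      noise_sd = 0.5, seed = 46)
  s <- generate_study(d)
  asg <- make_assignment(setNames(rep("turquoise", nrow(s$expression)),
                                  rownames(s$expression)))
  mes <- module_eigengenes(s$expression, asg)
  gt <- module_group_test(mes, s$phenotypes)
  expect_lt(gt$anova_p, 0.05)
  expect_lt(gt$kruskal_p, 0.05)
  # textbook between/within variance ratio
  y <- mes$eigengenes[, 1]; g <- factor(s$phenotypes$group)
  k <- nlevels(g); n <- length(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(gt$anova_F, f_oracle, tolerance = 1e-10)
})

test_that("two-group ANOVA F equals the squared t statistic", {
  set.seed(47)
  expr <- matrix(rnorm(5 * 16), 5, 16,
                 dimnames = list(paste0("g", 1:5), paste0("S", 1:16)))
  asg <- make_assignment(setNames(rep("blue", 5), rownames(expr)))
  mes <- module_eigengenes(expr, asg)
  ph <- data.frame(sample_id = paste0("S", 1:16),
                   group = rep(c("A", "B"), each = 8))
  gt <- module_group_test(mes, ph)
  tt <- t.test(mes$eigengenes[, 1] ~ ph$group, var.equal = TRUE)
  expect_equal(gt$anova_F, unname(tt$statistic)^2, tolerance = 1e-10)
  ph_bad <- data.frame(sample_id = paste0("S", 1:16),
                       group = c(rep("A", 15), "B"))
  expect_error(module_group_test(mes, ph_bad), "B")
})

test_that("kME tracks scaled kIN within planted modules", {
  s <- generate_study(three_module_design(48))
  adj <- signed_adjacency(s$expression)
  tom <- topological_overlap(adj)
  asg <- cluster_and_cut(tom, 30)
  mes <- module_eigengenes(s$expression, asg)
  kme <- module_membership(s$expression, mes)
  conn <- scaled_intramodular_connectivity(adj, asg)
  for (m in colnames(mes$eigengenes)) {
    genes <- conn$gene[conn$module == m]
    rho <- cor(kme[genes, m], conn$scaled_kIN[conn$module == m],
               method = "spearman")
    expect_gt(rho, 0.5)
  }
})

test_that("self-preservation is strong, random gene sets are null", {
  d <- synthetic_design(modules = list(module_spec("M1", 50, 0.9),
                                       module_spec("M2", 40, 0.9)),
                        n_background_genes = 100,
                        samples_per_group = c(A = 20, B = 20, C = 0, D = 0),
                        noise_sd = 0.5, seed = 49)
  s <- generate_study(d)
  tom <- topological_overlap(signed_adjacency(s$expression))
  asg <- cluster_and_cut(tom, 20)
  pres <- module_preservation(s$expression, asg, s$expression,
                              n_permutations = 200, seed = 50)
  expect_true(all(pres$Z_summary > 10))
  # identical seed reproduces identical Z values
  pres2 <- module_preservation(s$expression, asg, s$expression,
                               n_permutations = 200, seed = 50)
  expect_identical(pres, pres2)
  # a fake module of background genes in an independent study is null
  set.seed(51)
  fake <- sample(names(asg$labels)[s$truth$modules == "background"], 30)
  asg_fake <- asg
  asg_fake$labels[] <- "grey"
  asg_fake$labels[fake] <- "fakemod"
  d2 <- d; d2$seed <- 52
  s2 <- generate_study(d2)
  pres_null <- module_preservation(s$expression, asg_fake, s2$expression,
                                   n_permutations = 200, seed = 53)
  expect_lt(abs(pres_null$Z_summary), 2)
  expect_error(module_preservation(s$expression, asg, s$expression,
                                   n_permutations = 5), "n_permutations")
})
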