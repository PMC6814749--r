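test_that("specificity scores clip, threshold, and stay anti-monotone", {
  tiny <- tiny_dataset()
  genes <- c(tiny$ds$true_markers$macroglia, sprintf("GENE%04d", 1:20))
  sp <- specificity_scores(tiny$nm, tiny$truth, genes)
  expect_true(all(sp$score >= 0 & sp$score <= 300))
  expect_identical(sp$significant, sp$adj_p < 1e-10)
  expect_equal(sp$score, -log10(sp$adj_p), tolerance = 1e-12)
  o <- order(sp$adj_p)
  expect_true(all(diff(sp$score[o]) <= 1e-12))
  expect_true(all(sp$adj_p >= 1e-300))
  # the planted macroglial genes are the specific ones
  agg <- tapply(sp$significant, sp$type, mean)
  expect_equal(names(which.max(agg)), "macroglia")
  # absent genes are reported, not fatal
  sp2 <- specificity_scores(tiny$nm, tiny$truth, c("NOTAGENE", genes[1]))
  expect_equal(attr(sp2, "skipped"), "NOTAGENE")
  expect_error(specificity_scores(tiny$nm, tiny$truth, "NOTAGENE"),
               "no locus gene")
})

test_that("gene sets respect the FDR and detection rules", {
  tiny <- tiny_dataset()
  sets <- build_gene_sets(tiny$nm, tiny$qc, tiny$truth)
  # planted markers are detected in nearly all member cells -> included
  for (t in names(tiny$ds$true_markers)) {
    present <- intersect(tiny$ds$true_markers[[t]], tiny$nm$gene_ids)
    expect_gte(mean(present %in% sets[[t]]), 0.8)
  }
  # a gene passing the test but detected in few cells is excluded
  X <- matrix(1, 30, 60)
  X[2, ] <- rpois(60, 3) + 1
  X[1, ] <- 0
  X[1, 1:5] <- 50  # huge in 5/30 type-1 cells: detection 1/6 < 25%
  cm <- count_matrix(Matrix::Matrix(X, sparse = TRUE),
                     gene_ids = paste0("g", 1:30),
                     cell_ids = paste0("c", 1:60))
  labels <- rep(c("t1", "t2"), each = 30)
  suppressWarnings(
    sets2 <- build_gene_sets(depth_normalize(cm), cm, labels,
                             fdr = 0.05, min_detect = 0.25))
  expect_false("g1" %in% sets2$t1)
})

test_that("gene-set regression matches the closed form and refuses collinearity", {
  genes <- sprintf("G%04d", 1:600)
  st <- generate_gwas_stats(genes, genes[1:80], effect = 0.4, seed = 2)
  r <- geneset_regression(st, genes[1:80], covariates = character(0))
  expect_equal(r$beta, mean(st$z[1:80]) - mean(st$z[-(1:80)]),
               tolerance = 1e-10)
  expect_error(geneset_regression(st, genes), "collinear")
  expect_error(geneset_regression(st, "ZZZ"), "overlap")
  expect_error(geneset_regression(st[1:20, ], genes[1:5]), "at least 50")
  # membership collinear with a covariate
  st$dup <- as.numeric(st$member)
  expect_error(geneset_regression(st, genes[1:80], covariates = "dup"),
               "collinear")
})

test_that("gene-set regression is calibrated and powered", {
  set.seed(17)
  genes <- sprintf("G%04d", 1:1000)
  rej0 <- replicate(200, {
    st <- generate_gwas_stats(genes, sample(genes, 100), effect = 0,
                              seed = sample.int(1e6, 1))
    geneset_regression(st, st$gene[st$member])$p < 0.05
  })
  expect_gte(mean(rej0), 0.02)
  expect_lte(mean(rej0), 0.09)
  rej1 <- replicate(100, {
    st <- generate_gwas_stats(genes, sample(genes, 100), effect = 0.5,
                              seed = sample.int(1e6, 1))
    geneset_regression(st, st$gene[st$member])$p < 0.05
  })
  expect_gte(mean(rej1), 0.9)
})

test_that("the trait panel separates planted from null traits", {
  tiny <- tiny_dataset()
  sets <- build_gene_sets(tiny$nm, tiny$qc, tiny$truth)
  members <- intersect(sets$macroglia, tiny$nm$gene_ids)
  stats_list <- list(
    planted = generate_gwas_stats(tiny$nm$gene_ids, members,
                                  effect = 0.8, seed = 5),
    null = generate_gwas_stats(tiny$nm$gene_ids, members,
                               effect = 0, seed = 6))
  pan <- negative_control_panel(stats_list, sets)
  expect_true(pan$significant["planted", "macroglia"])
  expect_false(pan$significant["null", "macroglia"])
  # identical stats tables give identical rows
  pan2 <- negative_control_panel(
    list(a = stats_list$planted, b = stats_list$planted), sets)
  expect_equal(pan2$neglog10p["a", ], pan2$neglog10p["b", ])
  # a trait with no overlapping genes yields missing values
  st0 <- data.frame(gene = sprintf("OTHER%03d", 1:100),
                    z = rnorm(100), gene_size = 1)
  pan3 <- negative_control_panel(
    list(x = stats_list$planted, none = st0), sets)
  expect_true(all(is.na(pan3$neglog10p["none", ])))
  expect_error(negative_control_panel(stats_list["planted"], sets),
               "at least 2")
})
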