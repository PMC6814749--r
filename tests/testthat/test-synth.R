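types2 <- function(n_cells = 500L, marker_fold = 8) {
  data.frame(name = c("rods", "bipolar"), n_cells = n_cells,
             n_markers = 3L, marker_fold = marker_fold,
             stringsAsFactors = FALSE)
}

test_that("generation is reproducible and respects the doublet rate", {
  cfg <- sim_config(n_genes = 200, cell_types = types2(80L),
                    doublet_rate = 0, subtype_spec = NULL, seed = 5)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(as.matrix(a$counts$values), as.matrix(b$counts$values))
  expect_false(any(a$is_doublet))

  cfg2 <- sim_config(n_genes = 200, cell_types = types2(100L),
                     doublet_rate = 0.1, subtype_spec = NULL, seed = 5)
  d <- generate_counts(cfg2)
  expect_equal(sum(d$is_doublet), 20)
  expect_true(all(!is.na(d$doublet_type2[d$is_doublet])))
  expect_equal(length(d$true_type), ncol(d$counts$values))
})

test_that("planted markers show the configured fold elevation", {
  cfg <- sim_config(n_genes = 300, cell_types = types2(500L, 8),
                    n_batches = 1, doublet_rate = 0, libsize_cv = 0,
                    subtype_spec = NULL, seed = 9)
  ds <- generate_counts(cfg)
  X <- as.matrix(ds$counts$values)
  for (t in names(ds$true_markers)) {
    inb <- ds$true_type == t
    ratios <- vapply(ds$true_markers[[t]], function(g)
      mean(X[g, inb]) / mean(X[g, !inb]), numeric(1))
    # per-gene Monte-Carlo ratios are noisy for low-baseline genes; the
    # panel average concentrates near the planted fold of 8
    expect_gt(mean(ratios), 6)
    expect_lt(mean(ratios), 10)
    expect_true(all(ratios > 4 & ratios < 16))
  }
})

test_that("marker sets are pairwise disjoint and invalid configs rejected", {
  ds <- generate_counts(sim_config(n_genes = 300, cell_types = types2(50L),
                                   subtype_spec = NULL, seed = 1))
  mk <- unlist(ds$true_markers)
  expect_equal(anyDuplicated(mk), 0L)
  expect_error(sim_config(doublet_rate = 1), "doublet_rate")
  big <- data.frame(name = c("a", "b"), n_cells = 10L, n_markers = 30L,
                    marker_fold = 8)
  expect_error(sim_config(n_genes = 50, cell_types = big,
                          subtype_spec = NULL), "markers")
})

test_that("without batch effects no excess batch-differential genes appear", {
  cfg <- sim_config(n_genes = 400, cell_types = types2(200L),
                    n_batches = 2, batch_shift_sd = 0, doublet_rate = 0,
                    subtype_spec = NULL, seed = 21)
  ds <- generate_counts(cfg)
  X <- log1p(as.matrix(ds$counts$values))
  b <- ds$batch
  pv <- apply(X, 1, function(v) {
    if (stats::sd(v) == 0) return(1)
    stats::t.test(v[b == unique(b)[1]], v[b == unique(b)[2]])$p.value
  })
  # true-null 5% expected rate plus two binomial standard errors
  expect_lte(mean(pv < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / length(pv)))
})

test_that("gwas statistics follow the planted effect model", {
  genes <- sprintf("G%03d", 1:500)
  st0 <- generate_gwas_stats(genes, genes[1:100], effect = 0, seed = 4)
  expect_lt(abs(mean(st0$z[st0$member])), 3 / sqrt(100))
  st <- generate_gwas_stats(genes, genes[1:100], effect = 0.5, seed = 4)
  expect_lt(abs(mean(st$z[st$member]) - 0.5), 0.3)
  # gene size independent of membership
  expect_gt(stats::t.test(st$gene_size ~ st$member)$p.value, 0.001)
  # full-universe membership generates but downstream regression refuses
  stall <- generate_gwas_stats(genes, genes, effect = 0.2, seed = 4)
  expect_s3_class(stall, "data.frame")
  expect_error(geneset_regression(stall, genes), "collinear")
  expect_error(generate_gwas_stats(character(0), character(0)), "empty")
  expect_error(generate_gwas_stats(genes, "NOTAGENE"), "subset")
})
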