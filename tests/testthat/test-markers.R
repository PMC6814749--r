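test_that("rank-sum p equals exhaustive enumeration for all small sizes", {
  set.seed(14)
  for (n1 in 2:8) {
    for (n2 in c(2, 5, 8)) {
      vals <- sample(100, n1 + n2)  # distinct values, no ties
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      got <- retinet:::.wilcox_greater(x, y)
      expect_equal(got$p, enum_wilcox_p(x, y), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
  # the worked example: A = {5,6,7} vs B = {1,2,3}
  got <- retinet:::.wilcox_greater(c(5, 6, 7), c(1, 2, 3))
  expect_equal(got$p, 0.05, tolerance = 1e-12)
  expect_equal(got$auc, 1.0)
  expect_equal(got$U, 9)
})

test_that("marker selection applies the p/AUC/fold-change criteria", {
  X <- rbind(gA = c(5, 6, 7, 1, 2, 3), gB = c(1, 2, 3, 1.5, 2.5, 3.5),
             gC = c(2, 2, 2, 2, 2, 2))
  labels <- rep(c("t1", "t2"), each = 3)
  res <- wilcoxon_markers(make_nm(X), labels, p_thresh = 0.2)
  r_a1 <- res[res$gene == "gA" & res$type == "t1", ]
  expect_equal(r_a1$auc, 1.0)
  expect_equal(r_a1$p, 0.05, tolerance = 1e-12)
  # AUC(type vs rest) + AUC(rest vs type) = 1
  r_a2 <- res[res$gene == "gA" & res$type == "t2", ]
  expect_equal(r_a1$auc + r_a2$auc, 1)
  # identical distributions are not selected
  expect_false(any(res$passes[res$gene == "gB"]))
  # constant gene gets p = 1
  expect_true(all(res$p[res$gene == "gC"] == 1))
  # BH adjustment is monotone and never below the raw p
  expect_true(all(res$adj_p >= res$p - 1e-15))
  o <- order(res$p)
  expect_true(all(diff(res$adj_p[o]) >= -1e-12))
})

test_that("signature profiles expose planted discriminative genes", {
  set.seed(6)
  # two types differing only in gene 3
  X <- matrix(rnorm(20 * 40), 20, 40)
  X[3, 1:20] <- X[3, 1:20] + 5
  rownames(X) <- paste0("g", 1:20)
  labels <- rep(c("t1", "t2"), each = 20)
  rp <- reduce_profile(X, d = 10)
  sig <- signature_profiles(rp, labels)
  gap <- abs(sig$power[, "t1"] - sig$power[, "t2"])
  expect_equal(names(which.max(gap)), "g3")
  # identity basis: signature = centered per-type mean expression
  rp_id <- structure(list(
    scores = t(X), basis = diag(20), sv = rep(1, 20),
    center = rep(0, 20), gene_ids = rownames(X),
    cell_ids = as.character(1:40)), class = "reduced_profile")
  sig_id <- signature_profiles(rp_id, labels)
  ref <- cbind(t1 = rowMeans(X[, 1:20]), t2 = rowMeans(X[, 21:40]))
  ref <- ref - rowMeans(ref)
  expect_equal(unname(sig_id$power), unname(ref), tolerance = 1e-10)
  # small types excluded with a warning
  expect_warning(
    sig3 <- signature_profiles(
      rp, c(rep("t1", 19), rep("t2", 19), "t3", "t3"), min_cells = 3),
    "t3")
  expect_equal(colnames(sig3$power), c("t1", "t2"))
})

test_that("top-marker ranking orders by power with lexicographic ties", {
  pw <- cbind(t1 = c(3, 2, 2, 1), t2 = c(-3, -2, -2, -1))
  rownames(pw) <- c("gD", "gC", "gB", "gA")
  sig <- structure(list(power = pw, baseline = stats::setNames(
    rep(0, 4), rownames(pw)), raw = pw, gene_ids = rownames(pw),
    types = c("t1", "t2")), class = "signature_profile")
  res <- data.frame(
    gene = c("gD", "gC", "gB", "gA"), type = "t1",
    U = 1, auc = 1, lfc = 1, p = 0.001, adj_p = 0.001,
    passes = TRUE, exclusive = c(TRUE, TRUE, TRUE, FALSE))
  class(res) <- c("marker_test", "data.frame")
  top <- rank_top(sig, res, n = 10)
  expect_equal(top$t1$gene, c("gD", "gB", "gC"))  # tie gB/gC by symbol
  top2 <- rank_top(sig, res, n = 2)
  expect_equal(nrow(top2$t1), 2)
  expect_equal(attr(top2$t1, "n_available"), 3)
})

test_that("partial correlation agrees with the recursion formula", {
  # single control with r_xy = r_xz = r_yz = 0.5 gives 1/3
  S <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3)
  L <- chol(S)
  set.seed(9)
  M <- matrix(rnorm(3 * 20000), 20000, 3) %*% L
  pc <- retinet:::.pcor_resid(M[, 1], M[, 2], M[, 3, drop = FALSE])
  rxy <- stats::cor(M[, 1], M[, 2]); rxz <- stats::cor(M[, 1], M[, 3])
  ryz <- stats::cor(M[, 2], M[, 3])
  ref <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc, ref, tolerance = 1e-10)
  expect_equal(ref, 1 / 3, tolerance = 0.03)
  # perfectly correlated signals with independent controls give 1
  z <- rnorm(500)
  x <- rnorm(500)
  pc1 <- retinet:::.pcor_resid(x, x, cbind(z))
  expect_equal(pc1, 1, tolerance = 1e-12)
  # zero-variance residual reported as missing
  expect_true(is.na(retinet:::.pcor_resid(z, 2 * z + 1, cbind(z))))
})
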