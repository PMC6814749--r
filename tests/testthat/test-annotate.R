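test_that("diffusion matches the closed-form solve and conserves mass", {
  net2 <- make_net(2, from = 1, to = 2, weight = 0.6)
  x <- c(1, 0)
  # alpha = 0 is the identity
  expect_identical(diffuse(net2, x, alpha = 0), x)
  # two-node closed form: P = [[0,1],[1,0]], s = (1-a)(I - aP)^-1 x
  a <- 0.5
  Pm <- matrix(c(0, 1, 1, 0), 2)
  ref <- as.numeric((1 - a) * solve(diag(2) - a * Pm, x))
  expect_equal(diffuse(net2, x, a), ref, tolerance = 1e-7)
  expect_equal(sum(diffuse(net2, x, a)), sum(x), tolerance = 1e-7)
  # conservation on a random weighted graph, including an isolated node
  set.seed(11)
  net <- make_net(12, from = sample(1:11, 20, TRUE),
                  to = sample(1:11, 20, TRUE), weight = runif(20))
  x2 <- runif(12)
  s <- diffuse(net, x2, 0.85)
  expect_equal(sum(s), sum(x2), tolerance = 1e-6)
  expect_error(diffuse(net, runif(5)), "aligned")
})

test_that("marker scores concentrate on the expressing clique", {
  # two 8-cliques; marker expressed only in the first
  n <- 16
  cl1 <- t(utils::combn(1:8, 2))
  cl2 <- t(utils::combn(9:16, 2))
  net <- make_net(n, from = c(cl1[, 1], cl2[, 1]), to = c(cl1[, 2], cl2[, 2]))
  set.seed(2)
  X <- matrix(rpois(20 * n, 2), 20, n)
  X[1, ] <- c(rep(6, 8), rep(0, 8))
  nm <- make_nm(log1p(X))
  sc <- score_cell_types(net, nm, markers = list(tt = "g1"))
  expect_true(all(rank(-sc[, "tt"])[1:8] <= 8))
  # identical marker lists give identical columns
  sc2 <- score_cell_types(net, nm, markers = list(a = "g1", b = "g1"))
  expect_identical(sc2[, "a"], sc2[, "b"])
  # constant gene yields all-zero scores
  Xc <- X
  Xc[2, ] <- 3
  scc <- score_cell_types(net, make_nm(log1p(Xc)),
                          markers = list(k = "g2"))
  expect_true(all(scc == 0))
  # unmatched types are dropped with a warning
  expect_warning(
    score_cell_types(net, nm, markers = list(tt = "g1", zz = "NOPE")),
    "zz")
})

test_that("permutation p-values are bounded and super-uniform under the null", {
  tiny <- tiny_dataset()
  set.seed(31)
  null_markers <- list(
    n1 = sample(sprintf("GENE%04d", 1:200), 4),
    n2 = sample(sprintf("GENE%04d", 1:200), 4))
  pt <- permutation_test(tiny$net, tiny$nm, null_markers,
                         n_perm = 1000, seed = 9)
  expect_gte(min(pt$perm_p), 1 / 1001)
  # random panels should rarely reach significance
  expect_lte(mean(pt$adj_p < 0.05), 0.07)
  # one-sided KS: the empirical CDF must not exceed uniformity
  ks <- suppressWarnings(
    stats::ks.test(as.numeric(pt$perm_p), "punif",
                   alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_error(permutation_test(tiny$net, tiny$nm, null_markers,
                                n_perm = 10), "n_perm")
})

test_that("label assignment implements the two filter rules", {
  sc <- rbind(c(2, 1, 0), c(3, 2.5, 0), c(0.1, 0.2, 0.3))
  colnames(sc) <- c("rods", "cones", "RGC")
  p <- rbind(c(0.01, 0.8, 0.9), c(0.01, 0.02, 0.9), c(0.8, 0.9, 0.7))
  dimnames(p) <- dimnames(sc)
  lab <- assign_labels(sc, p)
  expect_equal(unname(lab),
               c("rods", "unassigned_multi", "unassigned_none"))
  # all p = 1 gives unassigned_none
  lab1 <- assign_labels(sc, matrix(1, 3, 3, dimnames = dimnames(sc)))
  expect_true(all(lab1 == "unassigned_none"))
})

test_that("the coherence filter matches the hypergeometric tail oracle", {
  # 30 cells: 10 of label A in a clique, 20 of label B; one A-cell is
  # rewired to B-neighbors only
  cl <- t(utils::combn(1:10, 2))
  clB <- t(utils::combn(11:30, 2))
  net <- make_net(30, from = c(cl[, 1], clB[, 1], rep(10, 5)),
                  to = c(cl[, 2], clB[, 2], 25:29))
  labels <- rep(c("A", "B"), c(10, 20))
  out <- coherence_filter(net, labels, alpha_test = 0.05)
  expect_true(all(out[1:9] == "A"))
  expect_true(all(out[11:30] == "B"))
  # direct tail-sum oracle for cell 1: 9/9 same-label neighbors
  K <- 10; n_tot <- 30; k <- 9
  p_oracle <- sum(vapply(9:k, function(s)
    choose(K, s) * choose(n_tot - K, k - s), numeric(1))) /
    choose(n_tot, k)
  expect_equal(stats::phyper(8, K, n_tot - K, 9, lower.tail = FALSE),
               p_oracle, tolerance = 1e-12)
  # zero same-label neighbors is always flagged
  net0 <- make_net(5, from = c(1, 1, 2, 3), to = c(2, 3, 3, 4))
  lab0 <- c("A", "B", "B", "B", "B")
  out0 <- coherence_filter(net0, lab0)
  expect_equal(unname(out0[1]), "incoherent_neighborhood")
  # degree-zero node flagged by convention
  expect_equal(unname(out0[5]), "incoherent_neighborhood")
  # homogeneous labels are never flagged
  outh <- coherence_filter(net0, rep("A", 5))
  expect_equal(unname(outh[1:4]), rep("A", 4))
})

test_that("diffusion conserves mass inside the scoring machinery", {
  tiny <- tiny_dataset()
  x <- as.numeric(tiny$nm$values[5, ])
  s <- diffuse(tiny$net, x, 0.85)
  expect_equal(sum(s), sum(x), tolerance = 1e-6)
})
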