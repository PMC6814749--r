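test_that("truncated SVD reduction satisfies its contracts", {
  set.seed(3)
  # exact rank-2 matrix reconstructs exactly at d = 2
  U <- matrix(rnorm(40), 20, 2)
  V <- matrix(rnorm(60), 30, 2)
  X <- U %*% t(V)
  rp <- reduce_profile(X, d = 2)
  rec <- rp$basis %*% t(rp$scores) + rp$center
  expect_lt(max(abs(rec - X)), 1e-8)
  # orthonormal basis
  G <- crossprod(rp$basis)
  expect_lt(max(abs(G - diag(2))), 1e-8)
  # error is monotone in d
  Xn <- X + matrix(rnorm(600, sd = 0.3), 20, 30)
  err <- vapply(c(2, 5, 10), function(d) {
    r <- reduce_profile(Xn, d)
    sum((r$basis %*% t(r$scores) + r$center - Xn)^2)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-8))
  expect_error(reduce_profile(Xn, d = 25), "exceeds")
})

test_that("archetypes land on separated clusters and satisfy the simplex", {
  set.seed(4)
  ctr <- rbind(c(0, 0), c(5, 0), c(0, 5))
  S <- do.call(cbind, lapply(1:3, function(i)
    matrix(rnorm(2 * 100, sd = 0.1), 2) + ctr[i, ]))
  fit <- action_decompose(S, 3, restarts = 3, seed = 1)
  W <- S %*% fit$C
  # simplex feasibility
  expect_lt(max(abs(colSums(fit$C) - 1)), 1e-6)
  expect_lt(max(abs(colSums(fit$H) - 1)), 1e-6)
  expect_gte(min(fit$C), 0)
  expect_gte(min(fit$H), 0)
  # each archetype is a hull point of one cluster: within 0.1 cluster-sd
  # of its nearest data point, and near one center
  cl_of <- rep(1:3, each = 100)
  for (j in 1:3) {
    dmin <- min(sqrt(colSums((S - W[, j])^2)))
    expect_lt(dmin, 0.1 * 0.1 * sqrt(2) + 0.02)
    expect_lt(min(sqrt(rowSums((ctr - rep(W[, j], each = 3))^2))), 0.6)
  }
  # footprints give >=90% of each cluster majority weight on one archetype
  assign <- apply(fit$H, 2, which.max)
  for (cl in 1:3) {
    tab <- table(assign[cl_of == cl])
    expect_gte(max(tab) / 100, 0.9)
  }
  # k = n is exactly expressible
  S2 <- matrix(rnorm(12), 2, 6)
  expect_lt(action_decompose(S2, 6, restarts = 1, seed = 1)$rss, 1e-6)
})

test_that("the ladder records non-increasing reconstruction error", {
  tiny <- tiny_dataset()
  lad <- build_ladder(tiny$rp, 2, 5, restarts = 2, seed = 1)
  e <- ladder_errors(lad)
  expect_true(all(diff(e) <= 1e-8))
  for (f in lad$fits) {
    expect_lt(max(abs(colSums(f$C) - 1)), 1e-6)
    expect_lt(max(abs(colSums(f$H) - 1)), 1e-6)
  }
})

test_that("cell profiles concatenate footprints into a distribution", {
  tiny <- tiny_dataset()
  lad <- build_ladder(tiny$rp, 2, 3, restarts = 1, seed = 2)
  P <- cell_profiles(lad)
  expect_equal(ncol(P), 2 + 3)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # single depth k=2: profile equals the renormalized footprint
  l1 <- structure(list(fits = lad$fits[1], depths = 2,
                       cell_ids = lad$cell_ids),
                  class = "archetype_ladder")
  P1 <- cell_profiles(l1)
  expect_equal(unname(P1[5, ]), lad$fits[[1]]$H[, 5] /
                 sum(lad$fits[[1]]$H[, 5]), tolerance = 1e-12)
})

test_that("sqrt-JS distance matches direct entropy computation", {
  expect_equal(js_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1, tolerance = 1e-9)
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  ref <- sqrt(h(c(0.75, 0.25)) - 0.5 * (h(c(0.5, 0.5)) + h(c(1, 0))))
  expect_equal(js_distance(c(0.5, 0.5), c(1, 0)), ref, tolerance = 1e-9)
  expect_equal(ref, 0.5579, tolerance = 1e-4)
  expect_error(js_distance(c(-0.1, 1.1), c(0.5, 0.5)), "negative")
})

test_that("sqrt-JS is a metric on random probability triples", {
  set.seed(8)
  for (i in 1:1000) {
    p <- stats::runif(5); p <- p / sum(p)
    q <- stats::runif(5); q <- q / sum(q)
    r <- stats::runif(5); r <- r / sum(r)
    dpq <- js_distance(p, q)
    dqr <- js_distance(q, r)
    dpr <- js_distance(p, r)
    expect_lte(dpr, dpq + dqr + 1e-9)
    expect_equal(dpq, js_distance(q, p), tolerance = 1e-12)
  }
  # matrix form agrees with the scalar form
  P <- matrix(stats::runif(15), 3, 5)
  P <- P / rowSums(P)
  D <- js_distance_matrix(P)
  expect_equal(D[1, 2], js_distance(P[1, ], P[2, ]), tolerance = 1e-12)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
})

test_that("the k* rule truncates at gaps and saturates without them", {
  # ten identical cells plus one opposite-corner outlier
  P <- rbind(matrix(rep(c(1, 0), 10), 10, 2, byrow = TRUE), c(0, 1))
  ed <- retinet:::cpp_kstar_edges(P, 10L, 1.0)
  nb <- split(ed$to, ed$from)
  # twins keep all 9 co-twins (distance 0) and exclude the outlier at
  # distance 1 > beta_9 = sqrt(9 * lambda) / 9 = 1/3
  for (i in 1:10) {
    expect_setequal(nb[[as.character(i)]], setdiff(1:10, i))
  }
  # the outlier sees all distances equal -> no gap -> saturates at max_k
  expect_length(nb[["11"]], 10)
  net <- build_kstar_nn(P, max_k = 10)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
  # equal pairwise distances: every node saturates at max_k
  Q <- diag(4) * 0.7 + 0.1
  edq <- retinet:::cpp_kstar_edges(Q, 3L, 1.0)
  expect_equal(unname(lengths(split(edq$to, edq$from))), rep(3L, 4))
})

test_that("layout is reproducible and separates components", {
  net <- make_net(6, from = c(1, 1, 2, 4, 4, 5), to = c(2, 3, 3, 5, 6, 6))
  l1 <- net_layout(net, seed = 3)$layout
  l2 <- net_layout(net, seed = 3)$layout
  expect_identical(l1, l2)
  c1 <- colMeans(l1[1:3, ])
  c2 <- colMeans(l1[4:6, ])
  spread <- max(stats::dist(l1[1:3, ]), stats::dist(l1[4:6, ]))
  expect_gte(sqrt(sum((c1 - c2)^2)), spread)
})
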