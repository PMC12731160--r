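empty_graph <- function(n) similarity_graph(matrix(0, n, n), 1L)

test_that("GCN with empty graph and identity weights reproduces the input", {
  set.seed(1)
  X <- matrix(abs(rnorm(20)), 5, 4)
  g <- empty_graph(5)
  expect_equal(gcn_layer(g, X, diag(4)), X)
  expect_equal(gcn_layer(g, X, matrix(0, 4, 3)), matrix(0, 5, 3))
})

test_that("GCN matches the loop-based propagation rule", {
  set.seed(2)
  for (trial in 1:5) {
    g <- random_graph(6L)
    X <- matrix(rnorm(6 * 4), 6, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    expect_equal(gcn_layer(g, X, W), oracle_gcn(g$adjacency, X, W),
                 tolerance = 1e-6)
  }
})

test_that("GAT coefficients behave as softmax attention over neighborhoods", {
  # single neighbor (no self-loop): coefficient forced to 1
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  g <- similarity_graph(A, 1L)
  set.seed(3)
  X <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(6), 3, 2)
  a <- rnorm(4)
  res <- gat_layer(g, X, W, a, self_loop = FALSE)
  expect_equal(res$coeffs[1, 2], 1)
  # two neighbors with identical features split 0.5/0.5
  X2 <- rbind(c(1, 2, 0), c(5, 5, 5), c(1, 2, 0))
  A2 <- matrix(0, 3, 3)
  A2[2, c(1, 3)] <- A2[c(1, 3), 2] <- 1
  res2 <- gat_layer(similarity_graph(A2, 1L), X2, W, a, self_loop = FALSE)
  expect_equal(unname(res2$coeffs[2, c(1, 3)]), c(0.5, 0.5))
})

test_that("GAT matches the per-node loop oracle", {
  set.seed(4)
  for (self_loop in c(TRUE, FALSE)) {
    for (trial in 1:5) {
      g <- random_graph(5L)
      X <- matrix(rnorm(5 * 4), 5, 4)
      W <- matrix(rnorm(4 * 3), 4, 3)
      a <- rnorm(6)
      res <- gat_layer(g, X, W, a, self_loop = self_loop)
      orc <- oracle_gat(g$adjacency, X, W, a, self_loop = self_loop)
      expect_equal(res$out, orc$out, tolerance = 1e-6)
      expect_equal(res$coeffs, orc$coeffs, tolerance = 1e-6)
    }
  }
})

test_that("GAT coefficient rows sum to 1 for arbitrary parameters", {
  set.seed(5)
  for (trial in 1:40) {
    n <- sample(3:9, 1)
    g <- random_graph(n, 2L)
    X <- matrix(rnorm(n * 3, sd = 3), n, 3)
    W <- matrix(rnorm(3 * 4, sd = 2), 3, 4)
    a <- rnorm(8, sd = 2)
    res <- gat_layer(g, X, W, a)
    expect_lt(max(abs(rowSums(res$coeffs) - 1)), 1e-8)
  }
})

test_that("hybrid encoder equals sequential application of its layers", {
  set.seed(6)
  g <- random_graph(7L)
  X <- matrix(rnorm(7 * 5), 7, 5)
  enc <- init_encoder(5L, c(4L, 3L, 2L), n_classes = 2L)
  emb <- encode_omics(g, X, enc)
  Z1 <- gcn_layer(g, X, enc$layers[[1]]$W)
  Z2 <- gat_layer(g, Z1, enc$layers[[2]]$W, enc$layers[[2]]$a)$out
  Z3 <- gcn_layer(g, Z2, enc$layers[[3]]$W)
  expect_equal(emb$Z1, Z1)
  expect_equal(emb$Z2, Z2)
  expect_equal(emb$Z, Z3)
  expect_true(all(emb$Z >= 0))
  expect_equal(encode_omics(g, matrix(0, 7, 5), enc)$Z, matrix(0, 7, 2))
})

test_that("identity chain on an empty graph reduces to ReLU(X)", {
  X <- matrix(abs(rnorm(12)), 4, 3)
  enc <- init_encoder(3L, c(3L, 3L, 3L), 2L)
  enc$layers <- lapply(enc$layers, function(l) {
    l$W <- diag(3)
    if (!is.null(l$a)) l$a <- rep(0, 6)
    l
  })
  expect_equal(encode_omics(empty_graph(4), X, enc)$Z, X)
})

test_that("alternative layer orders are constructible and consistent", {
  set.seed(7)
  g <- random_graph(6L)
  X <- matrix(rnorm(6 * 4), 6, 4)
  for (ord in list(c("gat", "gat", "gcn"), c("gat", "gcn", "gat"),
                   c("gat", "gcn", "gcn"), c("gcn", "gat", "gat"))) {
    enc <- init_encoder(4L, c(3L, 3L, 2L), 2L, layer_order = ord)
    emb <- encode_omics(g, X, enc)
    expect_identical(dim(emb$Z), c(6L, 2L))
    cur <- X
    for (i in seq_along(ord)) {
      cur <- if (ord[i] == "gcn") {
        gcn_layer(g, cur, enc$layers[[i]]$W)
      } else {
        gat_layer(g, cur, enc$layers[[i]]$W, enc$layers[[i]]$a)$out
      }
    }
    expect_equal(emb$Z, cur)
  }
})

test_that("embeddings are permutation-equivariant", {
  set.seed(8)
  n <- 8L
  g <- random_graph(n)
  X <- matrix(rnorm(n * 5), n, 5)
  enc <- init_encoder(5L, c(4L, 3L, 2L), 2L)
  emb <- encode_omics(g, X, enc)
  perm <- sample(n)
  gp <- similarity_graph(g$adjacency[perm, perm], g$k)
  embp <- encode_omics(gp, X[perm, ], enc)
  expect_equal(embp$Z, emb$Z[perm, ], tolerance = 1e-10)
  expect_equal(embp$Z2, emb$Z2[perm, ], tolerance = 1e-10)
})
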