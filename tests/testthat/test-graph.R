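test_that("cosine similarity matches direct evaluation", {
  expect_equal(cosine_similarity_matrix(rbind(c(1, 0), c(1, 0)))[1, 2], 1)
  expect_equal(cosine_similarity_matrix(rbind(c(1, 0), c(0, 1)))[1, 2], 0)
  expect_equal(cosine_similarity_matrix(rbind(c(1, 1), c(1, 0)))[1, 2],
               0.70711, tolerance = 1e-5)
  set.seed(1)
  X <- matrix(rnorm(40), 8, 5)
  S <- cosine_similarity_matrix(X)
  expect_equal(S, oracle_cosine(X), tolerance = 1e-12)
  expect_identical(diag(S), rep(1, 8))
  expect_error(cosine_similarity_matrix(rbind(c(1, 2), c(0, 0))),
               "zero-norm")
})

test_that("top-k selection matches brute-force sort, including ties", {
  set.seed(2)
  for (n in c(4L, 8L, 12L, 20L)) {
    for (trial in 1:5) {
      # quantized similarities force plenty of ties
      sim <- matrix(sample(seq(0, 1, 0.25), n * n, replace = TRUE), n, n)
      sim <- (sim + t(sim)) / 2
      diag(sim) <- 1
      for (k in c(1L, 3L, n - 1L)) {
        g <- knn_adjacency(sim, k)
        expect_identical(g$adjacency, oracle_knn(sim, k))
        gd <- knn_adjacency(sim, k, symmetrize = FALSE)
        expect_identical(unname(rowSums(gd$adjacency)), rep(as.numeric(k), n))
      }
    }
  }
})

test_that("all-equal similarities link each node to the lowest other index", {
  sim <- matrix(0.5, 4, 4)
  diag(sim) <- 1
  g <- knn_adjacency(sim, 1L, symmetrize = FALSE)
  expect_identical(g$adjacency[1, ], c(0, 1, 0, 0))
  expect_identical(g$adjacency[2, ], c(1, 0, 0, 0))
  expect_identical(g$adjacency[3, ], c(1, 0, 0, 0))
})

test_that("k out of range is a config error", {
  sim <- diag(3)
  expect_error(knn_adjacency(sim, 0L), "k must be")
  expect_error(knn_adjacency(sim, 3L), "k must be")
})

test_that("adjacency ignores positive per-sample rescaling", {
  set.seed(3)
  X <- matrix(rnorm(60), 10, 6)
  g1 <- knn_adjacency(cosine_similarity_matrix(X), 3L)
  X2 <- X * runif(10, 0.1, 7)
  g2 <- knn_adjacency(cosine_similarity_matrix(X2), 3L)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("graph degree normalizer matches S + I degrees", {
  set.seed(4)
  g <- knn_adjacency(cosine_similarity_matrix(matrix(rnorm(35), 7, 5)), 2L)
  expect_identical(g$degree, rowSums(g$adjacency) + 1)
  dh <- 1 / sqrt(g$degree)
  Sl <- g$adjacency
  diag(Sl) <- 1
  expect_equal(g$norm_adj, outer(dh, dh) * Sl)
})

test_that("one graph per omics, each built only from its own layer", {
  sim <- simulate_multiomics(sim_config(n_samples = 15L, n_classes = 2L,
                                        n_features = c(8L, 8L, 5L),
                                        n_informative = 3L,
                                        class_proportions = c(0.5, 0.5),
                                        seed = 6))
  ds <- sim$dataset
  gs <- build_graphs(ds, 3L)
  expect_length(gs, 3L)
  # duplicated layer content gives an identical graph
  ds$omics$meth <- omics_matrix(unclass(ds$omics$mrna), "meth")
  gs2 <- build_graphs(ds, 3L)
  expect_identical(gs2$meth$adjacency, gs2$mrna$adjacency)
})

test_that("consistent sample permutation permutes every adjacency", {
  sim <- simulate_multiomics(sim_config(n_samples = 12L, n_classes = 2L,
                                        n_features = c(7L, 5L),
                                        n_informative = 2L,
                                        class_proportions = c(0.5, 0.5),
                                        seed = 7))
  ds <- sim$dataset
  gs <- build_graphs(ds, 2L)
  set.seed(8)
  perm <- sample(12L)
  dsp <- subset_dataset(ds, sample_idx = perm)
  gsp <- build_graphs(dsp, 2L)
  for (nm in names(gs)) {
    expect_identical(unname(gsp[[nm]]$adjacency),
                     unname(gs[[nm]]$adjacency[perm, perm]))
  }
})

test_that("edge-list export writes each undirected edge once", {
  A <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  g <- similarity_graph(A, 1L, "x")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist_tsv(g, p)
  df <- read.delim(p)
  expect_identical(nrow(df), 2L)
  expect_setequal(paste(df$source_id, df$target_id), c("a b", "b c"))
})
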