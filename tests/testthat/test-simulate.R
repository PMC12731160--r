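test_that("fixed seed reproduces the simulation bitwise", {
  cfg <- sim_config(n_samples = 40L, n_classes = 2L,
                    n_features = c(20L, 10L), n_informative = 4L,
                    class_proportions = c(0.6, 0.4), seed = 3)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a$dataset$omics$mrna, b$dataset$omics$mrna)
  expect_identical(a$truth$informative_mask, b$truth$informative_mask)
  expect_identical(a$dataset$labels$y, b$dataset$labels$y)
})

test_that("zero effect size leaves class-conditional means null", {
  sim <- simulate_multiomics(sim_config(n_samples = 400L, n_classes = 2L,
                                        n_features = c(30L, 20L),
                                        n_informative = 10L,
                                        effect_size = 0,
                                        shared_factor_dim = 0L,
                                        class_proportions = c(0.5, 0.5),
                                        seed = 4))
  X <- unclass(sim$dataset$omics$mrna)
  y <- sim$dataset$labels$y
  pvals <- apply(X[, 1:10], 2L, function(col) {
    stats::t.test(col[y == 0], col[y == 1])$p.value
  })
  # null features: no p-value extreme beyond multiple-testing luck
  expect_gt(min(pvals), 1e-4)
})

test_that("large effect size makes single informative features separating", {
  sim <- simulate_multiomics(sim_config(n_samples = 500L, n_classes = 2L,
                                        n_features = 30L, n_informative = 5L,
                                        effect_size = 8, noise_sd = 1,
                                        shared_factor_dim = 0L,
                                        class_proportions = c(0.5, 0.5),
                                        seed = 5))
  X <- unclass(sim$dataset$omics$mrna)
  y <- sim$dataset$labels$y
  mask <- sim$truth$informative_mask$mrna
  for (j in which(mask)) {
    m0 <- mean(X[y == 0, j])
    m1 <- mean(X[y == 1, j])
    thr <- (m0 + m1) / 2
    pred <- as.integer(if (m1 > m0) X[, j] > thr else X[, j] < thr)
    # midpoint threshold: error rate bounded by the Gaussian overlap
    expect_lt(mean(pred != y), 0.01)
  }
})

test_that("class proportions are respected within sampling error", {
  sim <- simulate_multiomics(sim_config(seed = 6))
  counts <- tabulate(sim$dataset$labels$y + 1L, 3L)
  p_hat <- counts / 300
  se <- sqrt(c(0.5, 0.3, 0.2) * c(0.5, 0.7, 0.8) / 300)
  expect_true(all(abs(p_hat - c(0.5, 0.3, 0.2)) < 4 * se))
})

test_that("shared factors correlate informative blocks across omics", {
  sim <- simulate_multiomics(sim_config(n_samples = 200L, n_classes = 2L,
                                        n_features = c(40L, 40L),
                                        n_informative = 8L,
                                        effect_size = 0,  # isolate the factors
                                        shared_factor_dim = 4L,
                                        class_proportions = c(0.5, 0.5),
                                        seed = 7))
  X1 <- unclass(sim$dataset$omics$mrna)
  X2 <- unclass(sim$dataset$omics$meth)
  m1 <- sim$truth$informative_mask$mrna
  m2 <- sim$truth$informative_mask$meth
  cc_inf <- stats::cancor(X1[, m1], X2[, m2])$cor
  cc_noise <- stats::cancor(X1[, !m1][, 1:8], X2[, !m2][, 1:8])$cor
  expect_gt(mean(abs(cc_inf)), mean(abs(cc_noise)))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_features = c(10L), n_informative = 11L),
               "exceeds")
  expect_error(sim_config(class_proportions = c(0.5, 0.4)))
})

test_that("simulation export writes the dataset layout plus truth.json", {
  sim <- simulate_multiomics(sim_config(n_samples = 15L, n_classes = 2L,
                                        n_features = c(6L, 5L),
                                        n_informative = 2L,
                                        class_proportions = c(0.5, 0.5),
                                        seed = 8))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  expect_setequal(list.files(d),
                  c("mrna.csv", "meth.csv", "labels.csv", "truth.json"))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$informative_mask$mrna,
                  names(which(sim$truth$informative_mask$mrna)))
})
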