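test_that("fixed seed reproduces training exactly", {
  sim <- tiny_sim()
  sp <- tiny_fit()$split
  cfg <- tiny_config(epochs_pretrain = 30L, epochs_main = 30L)
  m1 <- fit_mogola(sim$dataset, sp$train_idx, cfg)
  m2 <- fit_mogola(sim$dataset, sp$train_idx, cfg)
  expect_identical(m1$history$stage1, m2$history$stage1)
  expect_identical(m1$history$stage2, m2$history$stage2)
  expect_identical(m1$encoders, m2$encoders)
  expect_identical(m1$head, m2$head)
})

test_that("stage 2 never touches the frozen encoders", {
  sim <- tiny_sim()
  sp <- tiny_fit()$split
  short <- fit_mogola(sim$dataset, sp$train_idx,
                      tiny_config(epochs_pretrain = 25L, epochs_main = 1L))
  long <- fit_mogola(sim$dataset, sp$train_idx,
                     tiny_config(epochs_pretrain = 25L, epochs_main = 60L))
  # identical encoder weights regardless of how long stage 2 ran
  expect_identical(short$encoders, long$encoders)
  expect_false(identical(short$head, long$head))
})

test_that("stage-1 loss decreases with only stochastic wobble", {
  # deterministic descent without dropout noise
  sim <- tiny_sim()
  sp <- tiny_fit()$split
  m0 <- fit_mogola(sim$dataset, sp$train_idx,
                   tiny_config(dropout = 0, epochs_pretrain = 80L,
                               epochs_main = 1L))
  h0 <- m0$history$stage1
  ups <- diff(h0) / h0[-length(h0)]
  expect_lt(max(ups), 0.05)
  expect_lt(h0[length(h0)], h0[1L])
  # with dropout the trajectory is noisier but still trends down
  h <- tiny_fit()$model$history$stage1
  expect_lt(mean(tail(h, 20)), 0.5 * mean(head(h, 20)))
})

test_that("stage-2 fusion loss trends down", {
  h2 <- tiny_fit()$model$history$stage2
  expect_lt(mean(tail(h2$lola, 10)), mean(head(h2$lola, 10)))
  expect_lt(mean(tail(h2$lmse, 10)), mean(head(h2$lmse, 10)))
  expect_equal(h2$ltotal,
               h2$lgs + tiny_config()$lambda1 * (h2$lce + h2$lmse) +
                 tiny_config()$lambda2 * h2$lola)
})

test_that("the model separates the strongly planted classes", {
  fit <- tiny_fit()
  sim <- tiny_sim()
  train_idx <- fit$split$train_idx
  prob_tr <- predict_proba(fit$model, sim$dataset, train_idx)
  acc_tr <- mean(max.col(prob_tr) - 1L == sim$dataset$labels$y[train_idx])
  expect_gte(acc_tr, 0.95)
})

test_that("predicted probabilities are a proper, equivariant distribution", {
  fit <- tiny_fit()
  sim <- tiny_sim()
  test_idx <- fit$split$test_idx
  prob <- predict_proba(fit$model, sim$dataset, test_idx)
  expect_lt(max(abs(rowSums(prob) - 1)), 1e-6)
  expect_identical(rownames(prob), sim$dataset$labels$sample_ids[test_idx])
  perm <- rev(seq_along(test_idx))
  prob_perm <- predict_proba(fit$model, sim$dataset, test_idx[perm])
  expect_equal(prob_perm, prob[perm, ], ignore_attr = "confidence")
  conf <- attr(prob, "confidence")
  expect_identical(dim(conf), c(length(test_idx), 3L))
  expect_true(all(conf >= 0 & conf <= 1))
})

test_that("training-sample predictions reproduce the fitted labels", {
  fit <- tiny_fit()
  sim <- tiny_sim()
  pred <- predict_classes(fit$model, sim$dataset, fit$split$train_idx)
  truth <- sim$dataset$labels$class_names[
    sim$dataset$labels$y[fit$split$train_idx] + 1L]
  expect_gte(mean(pred == truth), 0.95)
})

test_that("restricting test edges to training samples still predicts", {
  sim <- tiny_sim()
  sp <- tiny_fit()$split
  cfg <- tiny_config(epochs_pretrain = 40L, epochs_main = 40L,
                     test_edges = "train_only")
  model <- fit_mogola(sim$dataset, sp$train_idx, cfg)
  prob <- predict_proba(model, sim$dataset, sp$test_idx)
  expect_lt(max(abs(rowSums(prob) - 1)), 1e-6)
  acc <- mean(max.col(prob) - 1L == sim$dataset$labels$y[sp$test_idx])
  expect_gt(acc, 0.5)
})

test_that("degenerate training inputs are rejected", {
  sim <- tiny_sim()
  one_class <- which(sim$dataset$labels$y == 0L)
  expect_error(fit_mogola(sim$dataset, one_class, tiny_config()),
               "fewer than 2 classes")
})

test_that("checkpoints round-trip through save/load", {
  fit <- tiny_fit()
  p <- withr::local_tempfile(fileext = ".rds")
  save_mogola(fit$model, p)
  m2 <- load_mogola(p)
  expect_identical(m2$head, fit$model$head)
  sim <- tiny_sim()
  expect_identical(predict_proba(m2, sim$dataset, fit$split$test_idx),
                   predict_proba(fit$model, sim$dataset, fit$split$test_idx))
  saveRDS(list(format = "other"), p)
  expect_error(load_mogola(p), "not a mogola checkpoint")
})

test_that("lambda weighting and mean reduction feed through the objective", {
  sim <- tiny_sim()
  sp <- tiny_fit()$split
  cfg <- tiny_config(epochs_pretrain = 10L, epochs_main = 5L,
                     lambda1 = 10, lambda2 = 0.1, reduce_mean = TRUE)
  m <- fit_mogola(sim$dataset, sp$train_idx, cfg)
  h2 <- m$history$stage2
  expect_equal(h2$ltotal, h2$lgs + 10 * (h2$lce + h2$lmse) + 0.1 * h2$lola)
  # mean reduction: per-sample scale, so lgs well below the sum version
  expect_lt(h2$lgs[1], tiny_fit()$model$history$stage2$lgs[1])
})
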