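# Two-stage training: (1) pretrain each omics-specific graph encoder
# with its own classifier under the class-weighted graph structure
# loss; (2) freeze the encoders and jointly optimize gating, confidence
# heads and the fusion module under the total objective.

#' Training configuration
#'
#' @param k Neighbor count for the KNN patient graph (single value or
#'   named per-omics vector).
#' @param hidden_dims Encoder layer widths (h1, h2, h3).
#' @param layer_order Encoder stack, e.g. `c("gcn","gat","gcn")`.
#' @param dropout Dropout probability on each encoder layer input
#'   during stage-1 training.
#' @param gat_self_loop Include each node in its own GAT neighborhood.
#' @param lambda1,lambda2 Loss balance weights for the gating/confidence
#'   and fusion terms.
#' @param lr Adam learning rate.
#' @param epochs_pretrain,epochs_main Epoch counts of the two stages.
#' @param ola_slots,ola_heads External-memory slot count S and head
#'   count H of the fusion module.
#' @param seed RNG seed controlling initialization and dropout.
#' @param class_weighting Use inverse-frequency class weights in the
#'   stage-1 loss.
#' @param standardize Z-score features before graph construction.
#' @param symmetrize Symmetrize the KNN graph (elementwise OR).
#' @param test_edges `"all"` lets test samples link to any sample in the
#'   transductive prediction graph; `"train_only"` restricts neighbor
#'   candidates to training samples.
#' @param reduce_mean Use mean instead of sum reduction in all losses.
#' @param use_gate Keep the feature gate (`FALSE` = gate ablation).
#' @param fusion One of `"ola"`, `"concat"`, `"self_attention"`,
#'   `"vcdn"`; all but `"ola"` exist for ablation comparisons.
#' @param encoder `"graph"` for the hybrid GCN/GAT stack, `"linear"`
#'   for the graph-free ablation encoder.
#' @return A `mogola_config` list.
#' @export
mogola_config <- function(k = 5L,
                          hidden_dims = c(400L, 400L, 200L),
                          layer_order = c("gcn", "gat", "gcn"),
                          dropout = 0.5,
                          gat_self_loop = TRUE,
                          lambda1 = 1, lambda2 = 1,
                          lr = 1e-3,
                          epochs_pretrain = 500L, epochs_main = 1000L,
                          ola_slots = 64L, ola_heads = 4L,
                          seed = 1L,
                          class_weighting = TRUE,
                          standardize = FALSE,
                          symmetrize = TRUE,
                          test_edges = c("all", "train_only"),
                          reduce_mean = FALSE,
                          use_gate = TRUE,
                          fusion = c("ola", "concat", "self_attention",
                                     "vcdn"),
                          encoder = c("graph", "linear")) {
  stopifnot(lambda1 > 0, lambda2 > 0, epochs_pretrain >= 1L,
            epochs_main >= 1L, dropout >= 0, dropout < 1)
  cfg <- list(k = k, hidden_dims = as.integer(hidden_dims),
              layer_order = layer_order, dropout = dropout,
              gat_self_loop = gat_self_loop,
              lambda1 = lambda1, lambda2 = lambda2, lr = lr,
              epochs_pretrain = as.integer(epochs_pretrain),
              epochs_main = as.integer(epochs_main),
              ola_slots = as.integer(ola_slots),
              ola_heads = as.integer(ola_heads),
              seed = as.integer(seed),
              class_weighting = class_weighting,
              standardize = standardize, symmetrize = symmetrize,
              test_edges = match.arg(test_edges),
              reduce_mean = reduce_mean, use_gate = use_gate,
              fusion = match.arg(fusion), encoder = match.arg(encoder))
  structure(cfg, class = "mogola_config")
}

#' Load a training configuration from YAML
#'
#' Keys mirror [mogola_config()] arguments; absent keys keep defaults.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file values.
#' @return A `mogola_config`.
#' @export
read_config_yaml <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals %||% list(), overrides)
  do.call(mogola_config, vals)
}

stage2_forward <- function(Zs, gates, fusion_type, fusion_params, head,
                           use_gate) {
  gh <- Map(function(Z, gp) gate_head_forward(Z, gp, use_gate), Zs, gates)
  Zbar <- concat_omics(lapply(gh, `[[`, "Z_ref"))
  fus <- switch(fusion_type,
    ola = ola_forward(Zbar, fusion_params),
    concat = list(Y = Zbar),
    self_attention = sa_forward(Zbar, fusion_params),
    vcdn = list(Y = vcdn_features(lapply(gh, `[[`, "rho"))))
  logits <- fuse_and_classify(fus$Y, head$W, head$b)
  list(gh = gh, Zbar = Zbar, fus = fus, logits = logits,
       prob = softmax_rows(logits))
}

fit_stage1 <- function(graphs, Xs, y, cfg, n_classes, class_weights) {
  encoders <- lapply(Xs, function(X) {
    if (cfg$encoder == "linear") {
      init_linear_encoder(ncol(X), cfg$hidden_dims[length(cfg$hidden_dims)],
                          n_classes)
    } else {
      init_encoder(ncol(X), cfg$hidden_dims, n_classes, cfg$layer_order)
    }
  })
  ptree <- lapply(encoders, function(enc) {
    list(layers = lapply(enc$layers,
                         function(l) l[intersect(names(l), c("W", "a"))]),
         W_cls = enc$W_cls, b_cls = enc$b_cls)
  })
  state <- adam_init(ptree)
  history <- numeric(cfg$epochs_pretrain)
  for (epoch in seq_len(cfg$epochs_pretrain)) {
    grads <- vector("list", length(encoders))
    lgs <- 0
    for (m in seq_along(encoders)) {
      enc <- encoders[[m]]
      fw <- encoder_forward(graphs[[m]], Xs[[m]], enc, training = TRUE,
                            dropout = cfg$dropout,
                            gat_self_loop = cfg$gat_self_loop)
      logits <- sweep(fw$Z %*% enc$W_cls, 2L, enc$b_cls, "+")
      ce <- cross_entropy(logits, y, class_weights, cfg$reduce_mean)
      lgs <- lgs + ce$loss
      dZ <- ce$grad %*% t(enc$W_cls)
      lg <- encoder_backward(graphs[[m]], enc, fw, dZ,
                             gat_self_loop = cfg$gat_self_loop)
      grads[[m]] <- list(layers = lg,
                         W_cls = crossprod(fw$Z, ce$grad),
                         b_cls = colSums(ce$grad))
    }
    if (!is.finite(lgs)) {
      stop("stage-1 loss diverged (non-finite) at epoch ", epoch,
           call. = FALSE)
    }
    history[epoch] <- lgs
    st <- adam_step(ptree, grads, state, lr = cfg$lr)
    ptree <- st$params
    state <- st$state
    for (m in seq_along(encoders)) {
      for (i in seq_along(encoders[[m]]$layers)) {
        encoders[[m]]$layers[[i]]$W <- ptree[[m]]$layers[[i]]$W
        if (!is.null(ptree[[m]]$layers[[i]]$a)) {
          encoders[[m]]$layers[[i]]$a <- drop(ptree[[m]]$layers[[i]]$a)
        }
      }
      encoders[[m]]$W_cls <- ptree[[m]]$W_cls
      encoders[[m]]$b_cls <- drop(ptree[[m]]$b_cls)
    }
  }
  list(encoders = encoders, history = history)
}

fit_stage2 <- function(Zs, y, cfg, n_classes, lgs_frozen) {
  M <- length(Zs)
  h <- ncol(Zs[[1L]])
  d_concat <- h * M
  gates <- lapply(Zs, function(Z) init_gate_params(h, n_classes))
  fusion_params <- switch(cfg$fusion,
    ola = init_ola(d_concat, cfg$ola_heads, cfg$ola_slots),
    concat = NULL,
    self_attention = init_self_attention(d_concat),
    vcdn = NULL)
  head_in <- if (cfg$fusion == "vcdn") n_classes^M else d_concat
  head <- list(W = glorot(head_in, n_classes), b = numeric(n_classes))
  ptree <- list(gates = lapply(gates, unclass), head = head)
  if (cfg$fusion %in% c("ola", "self_attention")) {
    ptree$fusion <- fusion_params[intersect(names(fusion_params),
                                            c("U_key", "U_val", "U_t",
                                              "Wq", "Wk", "Wv"))]
  }
  state <- adam_init(ptree)
  n <- length(y)
  hist <- matrix(0, cfg$epochs_main, 5L,
                 dimnames = list(NULL, c("lgs", "lce", "lmse", "lola",
                                         "ltotal")))
  for (epoch in seq_len(cfg$epochs_main)) {
    fw <- stage2_forward(Zs, gates, cfg$fusion, fusion_params, head,
                         cfg$use_gate)
    ce_f <- cross_entropy(fw$logits, y, NULL, cfg$reduce_mean)
    lce <- 0
    lmse <- 0
    ces <- vector("list", M)
    d_conf_mse <- vector("list", M)
    for (m in seq_len(M)) {
      logits_c <- sweep(Zs[[m]] %*% gates[[m]]$Wc, 2L, gates[[m]]$bc, "+")
      ces[[m]] <- cross_entropy(logits_c, y, NULL, cfg$reduce_mean)
      tcp <- tcp_targets(ces[[m]]$prob, y)          # detached target
      resid <- fw$gh[[m]]$conf - tcp
      lce <- lce + ces[[m]]$loss
      lmse <- lmse + sum(resid^2) / (if (cfg$reduce_mean) n else 1)
      d_conf_mse[[m]] <- cfg$lambda1 * 2 * resid /
        (if (cfg$reduce_mean) n else 1)
    }
    ltotal <- lgs_frozen + cfg$lambda1 * (lce + lmse) +
      cfg$lambda2 * ce_f$loss
    if (!is.finite(ltotal)) {
      stop("stage-2 loss diverged (non-finite) at epoch ", epoch,
           call. = FALSE)
    }
    hist[epoch, ] <- c(lgs_frozen, lce, lmse, ce_f$loss, ltotal)

    dlogits_f <- cfg$lambda2 * ce_f$grad
    dW_head <- crossprod(fw$fus$Y, dlogits_f)
    db_head <- colSums(dlogits_f)
    dY <- dlogits_f %*% t(head$W)
    d_rho_extra <- NULL
    fusion_grad <- NULL
    if (cfg$fusion == "ola") {
      bk <- ola_backward(fusion_params, fw$fus, dY)
      fusion_grad <- bk[c("U_key", "U_val", "U_t")]
      dZbar <- bk$dZ
    } else if (cfg$fusion == "self_attention") {
      bk <- sa_backward(fw$Zbar, fusion_params, fw$fus, dY)
      fusion_grad <- bk[c("Wq", "Wk", "Wv")]
      dZbar <- bk$dZ
    } else if (cfg$fusion == "concat") {
      dZbar <- dY
    } else {                                         # vcdn
      dZbar <- matrix(0, n, d_concat)
      d_rho_extra <- vcdn_rho_grads(lapply(fw$gh, `[[`, "rho"), dY)
    }
    gate_grads <- vector("list", M)
    for (m in seq_len(M)) {
      cols <- (m - 1L) * h + seq_len(h)
      d_ref <- dZbar[, cols, drop = FALSE]
      d_logits_c <- cfg$lambda1 * ces[[m]]$grad
      if (!is.null(d_rho_extra)) {
        rho <- fw$gh[[m]]$rho
        dr <- d_rho_extra[[m]]
        d_logits_c <- d_logits_c + rho * (dr - rowSums(rho * dr))
      }
      gate_grads[[m]] <- gate_head_backward(Zs[[m]], gates[[m]], fw$gh[[m]],
                                            d_ref, d_conf_mse[[m]],
                                            d_logits_c, cfg$use_gate)
    }
    grads <- list(gates = gate_grads, head = list(W = dW_head, b = db_head))
    if (!is.null(fusion_grad)) grads$fusion <- fusion_grad
    st <- adam_step(ptree, grads, state, lr = cfg$lr)
    ptree <- st$params
    state <- st$state
    for (m in seq_len(M)) {
      gates[[m]][names(ptree$gates[[m]])] <- ptree$gates[[m]]
      gates[[m]]$bt <- drop(gates[[m]]$bt)
      gates[[m]]$bl <- drop(gates[[m]]$bl)
      gates[[m]]$bc <- drop(gates[[m]]$bc)
    }
    head$W <- ptree$head$W
    head$b <- drop(ptree$head$b)
    if (!is.null(fusion_grad)) {
      fusion_params[names(ptree$fusion)] <- ptree$fusion
    }
  }
  list(gates = gates, fusion_params = fusion_params, head = head,
       history = as.data.frame(cbind(epoch = seq_len(cfg$epochs_main),
                                     hist)))
}

# gradient of the flattened per-sample tensor product wrt each factor,
# by backprop through the left-associated row-Kronecker chain
vcdn_rho_grads <- function(rhos, dC) {
  M <- length(rhos)
  if (M == 1L) return(list(dC))
  prefix <- vector("list", M)
  prefix[[1L]] <- rhos[[1L]]
  for (j in 2L:M) prefix[[j]] <- row_kron(prefix[[j - 1L]], rhos[[j]])
  out <- vector("list", M)
  d_cur <- dC
  for (j in M:2L) {
    bk <- row_kron_backward(prefix[[j - 1L]], rhos[[j]], d_cur)
    out[[j]] <- bk$dB
    d_cur <- bk$dA
  }
  out[[1L]] <- d_cur
  out
}

#' Fit the multi-omics integration model
#'
#' Stage 1 pretrains each omics-specific graph encoder together with a
#' per-omics linear classifier under the class-weighted graph structure
#' loss. Stage 2 freezes the encoders and optimizes the feature gates,
#' confidence heads, per-omics confidence classifiers, the fusion
#' module and the final classification head under
#' L = L_GS + lambda1 L_GC + lambda2 L_fusion.
#'
#' @param dataset A `multiomics_dataset`.
#' @param train_idx Integer indices of the training samples.
#' @param config A `mogola_config`.
#' @return A `mogola_model` holding all parameters, the training
#'   graphs, per-stage loss histories and a config snapshot.
#' @export
fit_mogola <- function(dataset, train_idx, config = mogola_config()) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  y <- dataset$labels$y[train_idx]
  n_classes <- length(dataset$labels$class_names)
  if (length(unique(y)) < 2L) {
    stop("training indices cover fewer than 2 classes", call. = FALSE)
  }
  set.seed(config$seed)
  train_ds <- subset_dataset(dataset, sample_idx = train_idx)
  graphs <- build_graphs(train_ds, config$k,
                         standardize = config$standardize,
                         symmetrize = config$symmetrize)
  Xs <- lapply(train_ds$omics, unclass)
  cw <- if (config$class_weighting) class_weight_vector(y, n_classes)
  s1 <- fit_stage1(graphs, Xs, y, config, n_classes, cw)

  # frozen, evaluation-mode embeddings feed stage 2
  Zs <- Map(function(g, X, enc) {
    encoder_forward(g, X, enc, training = FALSE,
                    gat_self_loop = config$gat_self_loop)$Z
  }, graphs, Xs, s1$encoders)
  lgs_frozen <- graph_structure_loss(
    Map(function(Z, enc) sweep(Z %*% enc$W_cls, 2L, enc$b_cls, "+"),
        Zs, s1$encoders),
    y, cw, config$reduce_mean)
  s2 <- fit_stage2(Zs, y, config, n_classes, lgs_frozen)

  structure(list(config = config,
                 encoders = s1$encoders,
                 gates = s2$gates,
                 fusion_params = s2$fusion_params,
                 head = s2$head,
                 graphs = graphs,
                 train_ids = train_ds$labels$sample_ids,
                 class_names = dataset$labels$class_names,
                 class_weights = cw,
                 history = list(stage1 = s1$history,
                                stage2 = s2$history)),
            class = "mogola_model")
}

#' @export
print.mogola_model <- function(x, ...) {
  cat(sprintf(paste0("<mogola_model> %d omics, %d classes, %d training",
                     " samples\n  encoder: %s | fusion: %s\n"),
              length(x$encoders), length(x$class_names),
              length(x$train_ids),
              paste(x$config$layer_order, collapse = "-"),
              x$config$fusion))
  invisible(x)
}

# forward pass over an assembled node set; Xs may be masked copies
model_forward <- function(model, Xs, graphs) {
  cfg <- model$config
  Zs <- Map(function(g, X, enc) {
    encoder_forward(g, X, enc, training = FALSE,
                    gat_self_loop = cfg$gat_self_loop)$Z
  }, graphs, Xs, model$encoders)
  fw <- stage2_forward(Zs, model$gates, cfg$fusion, model$fusion_params,
                       model$head, cfg$use_gate)
  list(prob = fw$prob,
       conf = do.call(cbind, lapply(fw$gh, `[[`, "conf")),
       Zs = Zs)
}

# build the transductive prediction context (graphs + matrices) over
# train-union-eval samples; returns row indices of the eval samples
prediction_context <- function(model, dataset, eval_idx) {
  cfg <- model$config
  all_ids <- dataset$labels$sample_ids
  eval_ids <- all_ids[eval_idx]
  node_ids <- union(model$train_ids, eval_ids)
  node_idx <- match(node_ids, all_ids)
  if (anyNA(node_idx)) {
    stop("training samples missing from dataset", call. = FALSE)
  }
  sub <- subset_dataset(dataset, omics = names(model$encoders),
                        sample_idx = node_idx)
  allowed <- NULL
  if (cfg$test_edges == "train_only") {
    is_train <- node_ids %in% model$train_ids
    allowed <- matrix(rep(is_train, each = length(node_ids)),
                      length(node_ids), length(node_ids), byrow = TRUE)
  }
  graphs <- build_graphs(sub, cfg$k, standardize = cfg$standardize,
                         symmetrize = cfg$symmetrize, allowed = allowed)
  list(sub = sub, graphs = graphs,
       eval_rows = match(eval_ids, node_ids))
}

#' Predict class probabilities transductively
#'
#' Rebuilds the patient-similarity graphs over the union of training
#' and evaluation samples, runs a gradient-free forward pass of the
#' trained model, and returns the predictive distribution of the
#' evaluation samples.
#'
#' @param model A fitted `mogola_model`.
#' @param dataset The `multiomics_dataset` containing both training and
#'   evaluation samples.
#' @param eval_idx Integer indices (into `dataset`) of the samples to
#'   score.
#' @return N_eval x Q matrix of class probabilities (rows sum to 1),
#'   with sample IDs as rownames and class names as colnames. The
#'   per-omics confidence scores of the evaluation samples are attached
#'   as attribute `"confidence"` (N_eval x M matrix).
#' @export
predict_proba <- function(model, dataset, eval_idx) {
  ctx <- prediction_context(model, dataset, eval_idx)
  fw <- model_forward(model, lapply(ctx$sub$omics, unclass), ctx$graphs)
  prob <- fw$prob[ctx$eval_rows, , drop = FALSE]
  dimnames(prob) <- list(ctx$sub$labels$sample_ids[ctx$eval_rows],
                         model$class_names)
  conf <- fw$conf[ctx$eval_rows, , drop = FALSE]
  rownames(conf) <- rownames(prob)
  colnames(conf) <- names(model$encoders)
  attr(prob, "confidence") <- conf
  prob
}

#' Predicted class labels
#'
#' @inheritParams predict_proba
#' @return Character vector of predicted class names.
#' @export
predict_classes <- function(model, dataset, eval_idx) {
  prob <- predict_proba(model, dataset, eval_idx)
  model$class_names[max.col(prob, ties.method = "first")]
}

#' Save a fitted model checkpoint
#'
#' Single-file checkpoint (RDS, format version 1) holding all
#' parameters, the config snapshot and the training graphs.
#'
#' @param model A `mogola_model`.
#' @param path Output file path.
#' @export
save_mogola <- function(model, path) {
  saveRDS(list(format = "mogola-checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' Load a model checkpoint written by [save_mogola()]
#' @param path Checkpoint file path.
#' @return The stored `mogola_model`.
#' @export
load_mogola <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mogola-checkpoint")) {
    stop("not a mogola checkpoint: ", path, call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported checkpoint version: ", obj$version, call. = FALSE)
  }
  obj$model
}
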