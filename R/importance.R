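# Masking-based biomarker importance: zero one feature at a time in
# the test samples, re-score, and record the macro-F1 drop.

#' Masking-based feature importance
#'
#' Computes a baseline test macro-F1 once, then for every (omics,
#' feature) pair zeroes that feature's column across the test samples
#' (training rows and the patient-similarity graph are untouched),
#' recomputes predictions, and records
#' importance = baseline_F1 - masked_F1. Only the masked layer's
#' encoder is re-run per feature; the other layers' embeddings are
#' reused.
#'
#' @param model A fitted `mogola_model`.
#' @param dataset The full `multiomics_dataset`.
#' @param test_idx Indices of the test samples.
#' @param omics Layers to scan (default: all in the model).
#' @param rebuild_graph Rebuild the similarity graph per mask (costly;
#'   off by default — masking is applied to the model input only).
#' @return An `importance_table` data frame with columns `omics`,
#'   `feature_id`, `importance`, sorted by decreasing importance (ties
#'   broken by omics then feature ID), with the baseline macro-F1 as
#'   attribute `"baseline_f1"`.
#' @export
feature_importance <- function(model, dataset, test_idx, omics = NULL,
                               rebuild_graph = FALSE) {
  cfg <- model$config
  if (is.null(omics)) omics <- names(model$encoders)
  ctx <- prediction_context(model, dataset, test_idx)
  Xs <- lapply(ctx$sub$omics, unclass)
  y_test <- ctx$sub$labels$y[ctx$eval_rows]
  q <- length(model$class_names)

  score <- function(prob) {
    y_pred <- max.col(prob, ties.method = "first") - 1L
    mean(f1_per_class(confusion_counts(y_test, y_pred, q)))
  }
  base_fw <- model_forward(model, Xs, ctx$graphs)
  baseline <- score(base_fw$prob[ctx$eval_rows, , drop = FALSE])

  rows <- vector("list", length(omics))
  for (nm in omics) {
    X0 <- Xs[[nm]]
    d <- ncol(X0)
    imp <- numeric(d)
    for (j in seq_len(d)) {
      Xm <- X0
      Xm[ctx$eval_rows, j] <- 0
      if (rebuild_graph) {
        Xs_m <- Xs
        Xs_m[[nm]] <- Xm
        sub_m <- ctx$sub
        sub_m$omics[[nm]] <- omics_matrix(Xm, nm)
        graphs_m <- build_graphs(sub_m, cfg$k,
                                 standardize = cfg$standardize,
                                 symmetrize = cfg$symmetrize)
        prob <- model_forward(model, Xs_m, graphs_m)$prob
      } else {
        Zs <- base_fw$Zs
        Zs[[nm]] <- encoder_forward(ctx$graphs[[nm]], Xm,
                                    model$encoders[[nm]],
                                    training = FALSE,
                                    gat_self_loop = cfg$gat_self_loop)$Z
        prob <- stage2_forward(Zs, model$gates, cfg$fusion,
                               model$fusion_params, model$head,
                               cfg$use_gate)$prob
      }
      imp[j] <- baseline - score(prob[ctx$eval_rows, , drop = FALSE])
    }
    rows[[match(nm, omics)]] <- data.frame(omics = nm,
                                           feature_id = colnames(X0),
                                           importance = imp)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$importance, tab$omics, tab$feature_id), ]
  rownames(tab) <- NULL
  attr(tab, "baseline_f1") <- baseline
  class(tab) <- c("importance_table", "data.frame")
  tab
}

#' Identified biomarkers
#'
#' Features whose masking importance exceeds a threshold (default 0:
#' any positive macro-F1 drop).
#'
#' @param importance An `importance_table`.
#' @param threshold Minimum importance.
#' @return Subset of the table.
#' @export
identified_biomarkers <- function(importance, threshold = 0) {
  importance[importance$importance > threshold, , drop = FALSE]
}

#' Write an importance table as CSV
#' @param importance An `importance_table`.
#' @param path Output CSV path (columns omics, feature_id, importance).
#' @export
write_importance_csv <- function(importance, path) {
  utils::write.csv(as.data.frame(importance), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
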