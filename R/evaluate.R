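# Repeated-split evaluation protocol, omics-combination experiments,
# ablation runner and the lambda grid-search utility.

#' Evaluate the model under the repeated stratified-split protocol
#'
#' For each of `n_repeats` stratified splits, fits the model on the
#' training partition and scores the held-out partition
#' transductively; reports per-repeat metrics plus mean and standard
#' deviation. Per-repeat seeds are derived from `config$seed` so the
#' whole protocol is reproducible from one integer.
#'
#' @param dataset A `multiomics_dataset`.
#' @param config A `mogola_config`.
#' @param test_fraction Held-out fraction per repeat.
#' @param n_repeats Number of splits.
#' @param binary Report binary metrics (ACC, F1, AUC) instead of the
#'   multi-class set (ACC, weighted F1, macro F1).
#' @param keep_models Also return the fitted models and splits.
#' @return A `metrics_report`: data frame with one row per repeat plus
#'   `mean` and `sd` summary rows.
#' @export
evaluate_mogola <- function(dataset, config = mogola_config(),
                            test_fraction = 0.3, n_repeats = 5L,
                            binary = NULL, keep_models = FALSE) {
  if (is.null(binary)) {
    binary <- length(dataset$labels$class_names) == 2L
  }
  plan <- make_splits(dataset$labels, test_fraction, n_repeats,
                      seed = config$seed)
  rows <- vector("list", n_repeats)
  extras <- if (keep_models) vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- plan$repeats[[r]]
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    model <- fit_mogola(dataset, sp$train_idx, cfg_r)
    prob <- predict_proba(model, dataset, sp$test_idx)
    met <- compute_metrics(dataset$labels$y[sp$test_idx], prob, binary)
    rows[[r]] <- data.frame(repeat_id = r, as.data.frame(met))
    if (keep_models) {
      extras[[r]] <- list(model = model, split = sp, prob = prob)
    }
  }
  df <- do.call(rbind, rows)
  metric_cols <- setdiff(names(df), "repeat_id")
  summary_df <- rbind(
    data.frame(repeat_id = "mean", t(colMeans(df[metric_cols]))),
    data.frame(repeat_id = "sd", t(apply(df[metric_cols], 2L, stats::sd))))
  df$repeat_id <- as.character(df$repeat_id)
  out <- rbind(df, summary_df)
  rownames(out) <- NULL
  class(out) <- c("metrics_report", "data.frame")
  if (keep_models) attr(out, "fits") <- extras
  out
}

#' Summary row of a metrics report
#' @param report A `metrics_report`.
#' @param which `"mean"` or `"sd"`.
#' @return Named numeric vector of metrics.
#' @export
report_summary <- function(report, which = "mean") {
  row <- report[report$repeat_id == which, , drop = FALSE]
  unlist(row[setdiff(names(row), "repeat_id")])
}

#' Omics-combination experiment
#'
#' Runs the full evaluation protocol on each requested subset of omics
#' layers (default: all layers together, then every pairwise
#' combination), mirroring the protocol used to show that integrating
#' all layers outperforms any pair.
#'
#' @param dataset A `multiomics_dataset`.
#' @param config A `mogola_config`.
#' @param combinations List of character vectors of layer names;
#'   default all-layers plus all pairs.
#' @param ... Passed to [evaluate_mogola()].
#' @return Long-format data frame: combination, repeat_id, metric,
#'   value.
#' @export
omics_combinations <- function(dataset, config = mogola_config(),
                               combinations = NULL, ...) {
  nms <- names(dataset$omics)
  if (is.null(combinations)) {
    combinations <- c(list(nms),
                      if (length(nms) > 2L) {
                        utils::combn(nms, 2L, simplify = FALSE)
                      })
  }
  out <- lapply(combinations, function(cmb) {
    sub <- subset_dataset(dataset, omics = cmb)
    rep_df <- evaluate_mogola(sub, config, ...)
    rep_df <- as.data.frame(rep_df)
    long <- stats::reshape(rep_df, direction = "long",
                           varying = setdiff(names(rep_df), "repeat_id"),
                           v.names = "value", times = setdiff(names(rep_df),
                                                              "repeat_id"),
                           timevar = "metric", idvar = "repeat_id")
    data.frame(combination = paste(cmb, collapse = "+"),
               long[c("repeat_id", "metric", "value")])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ablation runner
#'
#' Re-evaluates the model with one component removed or replaced:
#' `"gsl"` swaps the graph encoder for a linear layer, `"gate"` drops
#' the feature gate, `"ola"` bypasses fusion (plain concatenation),
#' `"self_attention"`/`"vcdn"` substitute those fusion mechanisms, and
#' `"layer_order:<a>-<b>-<c>"` rearranges the encoder stack.
#'
#' @param dataset A `multiomics_dataset`.
#' @param config Full-model `mogola_config`.
#' @param component One of the ablation labels above, or `"none"` for
#'   the unmodified model.
#' @param ... Passed to [evaluate_mogola()].
#' @return A `metrics_report` for the ablated configuration.
#' @export
ablate_mogola <- function(dataset, config = mogola_config(),
                          component = c("none", "gsl", "gate", "ola",
                                        "self_attention", "vcdn"), ...) {
  if (grepl("^layer_order:", component[1L])) {
    order <- strsplit(sub("^layer_order:", "", component[1L]), "-")[[1L]]
    stopifnot(all(order %in% c("gcn", "gat")),
              length(order) == length(config$hidden_dims))
    config$layer_order <- order
  } else {
    component <- match.arg(component)
    switch(component,
      none = NULL,
      gsl = { config$encoder <- "linear" },
      gate = { config$use_gate <- FALSE },
      ola = { config$fusion <- "concat" },
      self_attention = { config$fusion <- "self_attention" },
      vcdn = { config$fusion <- "vcdn" })
  }
  evaluate_mogola(dataset, config, ...)
}

#' Grid search over the loss balance weights
#'
#' Evaluates every (lambda1, lambda2) pair on a grid and reports the
#' mean metrics of each, mirroring the standard {0.01, 0.1, 1, 10, 100}
#' sweep.
#'
#' @param dataset A `multiomics_dataset`.
#' @param config Base `mogola_config`.
#' @param grid Candidate values for both weights.
#' @param metric Metric used to flag the best pair.
#' @param ... Passed to [evaluate_mogola()].
#' @return Data frame: lambda1, lambda2, mean metrics; attribute
#'   `"best"` holds the winning row.
#' @export
grid_search_lambda <- function(dataset, config = mogola_config(),
                               grid = c(0.01, 0.1, 1, 10, 100),
                               metric = "acc", ...) {
  combos <- expand.grid(lambda1 = grid, lambda2 = grid)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- config
    cfg$lambda1 <- combos$lambda1[i]
    cfg$lambda2 <- combos$lambda2[i]
    rep_df <- evaluate_mogola(dataset, cfg, ...)
    data.frame(lambda1 = cfg$lambda1, lambda2 = cfg$lambda2,
               t(report_summary(rep_df, "mean")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "best") <- out[which.max(out[[metric]]), , drop = FALSE]
  out
}

#' Write a metrics report as CSV
#' @param report A `metrics_report`.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
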