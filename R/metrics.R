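# Stratified repeated-split evaluation protocol and classification
# metrics (ACC, weighted/macro F1, AUC).

#' Stratified repeated train/test splits
#'
#' Each repeat holds out `test_fraction` of the samples, stratified so
#' the test set preserves the class distribution (per-class counts
#' `round(test_fraction * n_q)`, clamped so every class keeps at least
#' one sample on each side).
#'
#' @param labels A `label_vector`.
#' @param test_fraction Held-out fraction in (0, 1).
#' @param n_repeats Number of independent random splits.
#' @param seed RNG seed; fixed seed gives identical plans.
#' @return A `split_plan`: list with `repeats` (list of
#'   `list(train_idx, test_idx)`), `test_fraction`, `seed`.
#' @export
make_splits <- function(labels, test_fraction = 0.3, n_repeats = 5L,
                        seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_repeats >= 1L)
  y <- labels$y
  counts <- tabulate(y + 1L, nbins = length(labels$class_names))
  if (any(counts < 2L)) {
    stop("every class needs >= 2 samples to appear in both partitions; ",
         "smallest class has ", min(counts), call. = FALSE)
  }
  set.seed(seed)
  reps <- lapply(seq_len(n_repeats), function(r) {
    test_idx <- integer(0)
    for (q in seq_along(counts) - 1L) {
      idx <- which(y == q)
      n_test <- min(max(round(test_fraction * length(idx)), 1L),
                    length(idx) - 1L)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx <- sort(test_idx)
    list(train_idx = setdiff(seq_along(y), test_idx), test_idx = test_idx)
  })
  structure(list(repeats = reps, test_fraction = test_fraction,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "split_plan")
}

confusion_counts <- function(y_true, y_pred, n_classes) {
  tab <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    tab[y_true[i] + 1L, y_pred[i] + 1L] <- tab[y_true[i] + 1L,
                                               y_pred[i] + 1L] + 1L
  }
  tab
}

f1_per_class <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Area under the ROC curve (binary)
#'
#' Rank statistic with 0.5 credit for probability ties, equivalent to
#' the trapezoidal ROC integral.
#'
#' @param y_true 0/1 integer labels (1 = positive class).
#' @param score Positive-class score per sample.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(y_true, score) {
  pos <- score[y_true == 1L]
  neg <- score[y_true == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Classification metrics from predicted probabilities
#'
#' Multi-class: accuracy, weighted F1, macro F1. Binary
#' (`binary = TRUE`): accuracy, F1 of the positive class (class index
#' 1) and AUC from its predicted probability.
#'
#' @param y_true 0-based true class indices.
#' @param y_prob N x Q probability matrix (rows sum to 1).
#' @param binary Report the binary metric set.
#' @return Named list of metrics, all in [0, 1].
#' @export
compute_metrics <- function(y_true, y_prob, binary = FALSE) {
  q <- ncol(y_prob)
  if (binary && q != 2L) {
    stop("binary metrics require Q = 2, got Q = ", q, call. = FALSE)
  }
  y_pred <- max.col(y_prob, ties.method = "first") - 1L
  cm <- confusion_counts(y_true, y_pred, q)
  acc <- sum(diag(cm)) / sum(cm)
  f1s <- f1_per_class(cm)
  support <- rowSums(cm)
  if (binary) {
    list(acc = acc, f1 = f1s[2L],
         auc = auc_rank(as.integer(y_true == 1L), y_prob[, 2L]))
  } else {
    list(acc = acc,
         f1_weighted = sum(f1s * support) / sum(support),
         f1_macro = mean(f1s))
  }
}
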