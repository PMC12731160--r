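# Loss functions of the two training stages. Default reduction is the
# sum over samples (and over omics layers where applicable); a mean
# flag rescales by N for numerical comfort at large sample counts.

log_softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  x - log(rowSums(exp(x)))
}

#' Inverse-frequency class weights
#'
#' w_q = N / (Q * n_q); reduces to all-ones on a perfectly balanced
#' label vector.
#'
#' @param y 0-based integer class indices.
#' @param n_classes Number of classes Q.
#' @return Numeric weight vector of length Q.
#' @export
class_weight_vector <- function(y, n_classes) {
  counts <- tabulate(y + 1L, nbins = n_classes)
  if (any(counts == 0L)) {
    stop("class absent from training labels: ",
         paste(which(counts == 0L) - 1L, collapse = ", "), call. = FALSE)
  }
  length(y) / (n_classes * counts)
}

# weighted multinomial cross-entropy; returns loss and d/d_logits
cross_entropy <- function(logits, y, weights = NULL, reduce_mean = FALSE) {
  n <- nrow(logits)
  q <- ncol(logits)
  ls <- log_softmax_rows(logits)
  w <- if (is.null(weights)) rep(1, n) else weights[y + 1L]
  loss <- -sum(w * ls[cbind(seq_len(n), y + 1L)])
  P <- exp(ls)
  Yh <- matrix(0, n, q)
  Yh[cbind(seq_len(n), y + 1L)] <- 1
  grad <- w * (P - Yh)
  if (reduce_mean) {
    loss <- loss / n
    grad <- grad / n
  }
  list(loss = loss, grad = grad, prob = P)
}

#' Stage-1 graph structure loss
#'
#' Sum over omics layers of the class-weighted cross-entropy of each
#' layer's pretraining classifier.
#'
#' @param per_omics_logits List of N x Q logit matrices, one per layer.
#' @param y 0-based class indices of the N samples.
#' @param class_weights Length-Q weight vector (e.g.
#'   [class_weight_vector()]); `NULL` for unweighted.
#' @param reduce_mean Divide each layer's term by N.
#' @return Nonnegative scalar.
#' @export
graph_structure_loss <- function(per_omics_logits, y, class_weights = NULL,
                                 reduce_mean = FALSE) {
  if (!is.null(class_weights)) {
    stopifnot(length(class_weights) == ncol(per_omics_logits[[1L]]))
  }
  sum(vapply(per_omics_logits, function(lg) {
    cross_entropy(lg, y, class_weights, reduce_mean)$loss
  }, 0))
}

#' Stage-2 gating and confidence loss
#'
#' L_GC = L_ce + L_mse: cross-entropy of the per-omics confidence
#' classifiers plus squared error between each layer's confidence
#' scores and its true-class-probability targets.
#'
#' @param rho List of N x Q predictive distributions, one per layer.
#' @param conf List of length-N confidence score vectors, one per layer.
#' @param y 0-based class indices.
#' @param reduce_mean Divide both terms by N.
#' @return List with `loss`, `ce` and `mse` components.
#' @export
gating_confidence_loss <- function(rho, conf, y, reduce_mean = FALSE) {
  stopifnot(length(rho) == length(conf))
  n <- length(y)
  ce <- 0
  mse <- 0
  for (m in seq_along(rho)) {
    p <- rho[[m]][cbind(seq_len(n), y + 1L)]
    ce <- ce - sum(log(pmax(p, 1e-12)))
    mse <- mse + sum((conf[[m]] - tcp_targets(rho[[m]], y))^2)
  }
  if (reduce_mean) {
    ce <- ce / n
    mse <- mse / n
  }
  list(loss = ce + mse, ce = ce, mse = mse)
}

#' Total training objective
#'
#' L_total = L_GS + lambda1 * L_GC + lambda2 * L_OLA.
#'
#' @param lgs Graph structure loss.
#' @param lgc Gating and confidence loss.
#' @param lola Cross-entropy on the fused OLA output.
#' @param lambda1,lambda2 Positive balance weights.
#' @return Scalar.
#' @export
total_loss <- function(lgs, lgc, lola, lambda1 = 1, lambda2 = 1) {
  stopifnot(lambda1 > 0, lambda2 > 0)
  lgs + lambda1 * lgc + lambda2 * lola
}
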