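# Adaptive feature gating and true-class-probability (TCP) confidence
# weighting of an encoded omics layer. All three heads (gate l, conf t,
# classifier c) are linear maps on the frozen encoder output.

#' Initialize gate/confidence/classifier head parameters
#'
#' @param h Encoder output width (h3).
#' @param n_classes Number of classes Q.
#' @return A `gate_params` list: gate projection `Wl`/`bl` (h -> h),
#'   confidence head `wt`/`bt` (h -> 1), classifier `Wc`/`bc` (h -> Q).
#' @export
init_gate_params <- function(h, n_classes) {
  structure(list(Wl = glorot(h, h), bl = numeric(h),
                 wt = glorot(h, 1L), bt = 0,
                 Wc = glorot(h, n_classes), bc = numeric(n_classes)),
            class = "gate_params")
}

#' Gate an embedding
#'
#' Soft feature selection: sigmoid(l(Z)) elementwise-multiplied with Z.
#' The gate shrinks every coordinate (|output| <= |Z| entrywise).
#'
#' @param Z Embedding matrix (samples x h).
#' @param params A `gate_params`.
#' @return Gated matrix of the same shape.
#' @export
gate_features <- function(Z, params) {
  stopifnot(ncol(Z) == nrow(params$Wl))
  G <- sigmoid(sweep(Z %*% params$Wl, 2L, params$bl, "+"))
  G * Z
}

#' Confidence-weight an embedding
#'
#' A scalar confidence score per sample, sigmoid(t(Z)) in [0, 1],
#' broadcast-multiplied over that sample's embedding row. The score is
#' trained (see [fit_mogola()]) to regress the true-class probability.
#'
#' @inheritParams gate_features
#' @return List with `scores` (length-N vector) and `weighted`
#'   (scores * Z row-wise).
#' @export
confidence_weight <- function(Z, params) {
  stopifnot(ncol(Z) == nrow(params$wt))
  scores <- drop(sigmoid(Z %*% params$wt + params$bt))
  list(scores = scores, weighted = scores * Z)
}

#' Combine gated and confidence-weighted embeddings
#'
#' Elementwise product of the two refinements.
#'
#' @param Z_gate Gated embedding.
#' @param Z_tcp Confidence-weighted embedding, same shape.
#' @return Refined embedding matrix.
#' @export
refine_embedding <- function(Z_gate, Z_tcp) {
  stopifnot(identical(dim(Z_gate), dim(Z_tcp)))
  Z_gate * Z_tcp
}

#' True-class-probability targets
#'
#' For each sample, the probability its per-omics classifier assigns to
#' the true class: the regression target of the confidence head.
#'
#' @param rho N x Q matrix of predictive distributions (rows sum to 1).
#' @param y Integer class indices, 0-based, length N.
#' @return Numeric vector of length N in [0, 1].
#' @export
tcp_targets <- function(rho, y) {
  stopifnot(length(y) == nrow(rho), all(y >= 0L), all(y < ncol(rho)))
  rho[cbind(seq_len(nrow(rho)), y + 1L)]
}

## ---- stage-2 forward/backward over one omics ------------------------

gate_head_forward <- function(Z, params, use_gate = TRUE) {
  G <- sigmoid(sweep(Z %*% params$Wl, 2L, params$bl, "+"))
  conf <- drop(sigmoid(Z %*% params$wt + params$bt))
  Z_gate <- G * Z
  Z_tcp <- conf * Z
  Z_ref <- if (use_gate) Z_gate * Z_tcp else Z_tcp
  rho <- softmax_rows(sweep(Z %*% params$Wc, 2L, params$bc, "+"))
  list(G = G, conf = conf, Z_gate = Z_gate, Z_tcp = Z_tcp,
       Z_ref = Z_ref, rho = rho)
}

# d_ref: upstream gradient on Z_ref (from fusion); d_conf_extra: direct
# gradient on conf (from the MSE confidence loss); d_logits_c: gradient
# on the classifier logits (from the cross-entropy confidence loss).
# Z is frozen, so no gradient is returned for it.
gate_head_backward <- function(Z, params, fw, d_ref, d_conf_extra,
                               d_logits_c, use_gate = TRUE) {
  if (use_gate) {
    d_gate <- d_ref * fw$Z_tcp
    d_tcp <- d_ref * fw$Z_gate
  } else {
    d_gate <- matrix(0, nrow(Z), ncol(Z))
    d_tcp <- d_ref
  }
  dG <- d_gate * Z
  dLpre <- dG * fw$G * (1 - fw$G)
  d_conf <- rowSums(d_tcp * Z) + d_conf_extra
  dTpre <- d_conf * fw$conf * (1 - fw$conf)
  list(Wl = crossprod(Z, dLpre), bl = colSums(dLpre),
       wt = crossprod(Z, matrix(dTpre, ncol = 1L)), bt = sum(dTpre),
       Wc = crossprod(Z, d_logits_c), bc = colSums(d_logits_c))
}
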