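# Omics-Linked Attention: external-memory attention against learnable
# per-head key/value memory units, with softmax-then-L1 double
# normalization. The attention map is N x S (samples x memory slots),
# never N x N, so the cost is linear in the number of samples.

#' Concatenate refined omics embeddings
#'
#' @param refined List of matrices with equal row counts.
#' @return Column-wise concatenation in list order.
#' @export
concat_omics <- function(refined) {
  ns <- vapply(refined, nrow, 0L)
  if (length(unique(ns)) != 1L) {
    stop("refined embeddings differ in row count", call. = FALSE)
  }
  do.call(cbind, lapply(refined, unclass))
}

double_normalize_forward <- function(A_raw) {
  n <- nrow(A_raw)
  shifted <- A_raw - rep(apply(A_raw, 2L, max), each = n)
  e <- exp(shifted)
  A_col <- e / rep(colSums(e), each = n)   # columns sum to 1 (softmax)
  r <- rowSums(A_col)
  list(A = A_col / r, A_col = A_col, r = r)
}

double_normalize_backward <- function(fw, dA) {
  n <- nrow(dA)
  dA_col <- (dA - rowSums(dA * fw$A)) / fw$r
  fw$A_col * (dA_col - rep(colSums(fw$A_col * dA_col), each = n))
}

#' Double normalization of an attention score matrix
#'
#' Softmax down each column (over samples), then L1 normalization along
#' each row (over memory slots). Removes sensitivity to input scale:
#' the result has nonnegative entries and unit row sums, while the
#' intermediate column-softmaxed matrix has unit column sums.
#'
#' @param A_raw N x S matrix of raw attention scores.
#' @param full If `TRUE`, also return the intermediate column-softmaxed
#'   matrix `A_col`.
#' @return The doubly normalized N x S matrix (or a list when `full`).
#' @export
double_normalize <- function(A_raw, full = FALSE) {
  fw <- double_normalize_forward(as.matrix(A_raw))
  if (full) list(A = fw$A, A_col = fw$A_col) else fw$A
}

#' Initialize Omics-Linked Attention memory
#'
#' @param d_concat Width of the concatenated refined embedding.
#' @param heads Head count H; must divide `d_concat`.
#' @param slots Memory slot count S per head.
#' @return An `ola_memory` list: per-head `U_key` (d_head x S) and
#'   `U_val` (S x d_head), output transform `U_t` (d_concat square).
#' @export
init_ola <- function(d_concat, heads = 4L, slots = 64L) {
  if (d_concat %% heads != 0L) {
    stop("head count ", heads, " does not divide feature width ",
         d_concat, call. = FALSE)
  }
  dh <- d_concat %/% heads
  structure(list(
    H = as.integer(heads), S = as.integer(slots), d_head = dh,
    U_key = lapply(seq_len(heads), function(e) glorot(dh, slots)),
    U_val = lapply(seq_len(heads), function(e) glorot(slots, dh)),
    U_t = glorot(d_concat, d_concat)),
    class = "ola_memory")
}

ola_forward <- function(Z, memory) {
  H <- memory$H
  dh <- memory$d_head
  heads <- vector("list", H)
  for (e in seq_len(H)) {
    cols <- (e - 1L) * dh + seq_len(dh)
    ze <- Z[, cols, drop = FALSE]
    A_raw <- ze %*% memory$U_key[[e]]
    dn <- double_normalize_forward(A_raw)
    heads[[e]] <- list(ze = ze, dn = dn, Y = dn$A %*% memory$U_val[[e]])
  }
  Y_concat <- do.call(cbind, lapply(heads, `[[`, "Y"))
  list(Y = Y_concat %*% memory$U_t, Y_concat = Y_concat, heads = heads)
}

ola_backward <- function(memory, fw, dY) {
  H <- memory$H
  dh <- memory$d_head
  dU_t <- crossprod(fw$Y_concat, dY)
  dY_concat <- dY %*% t(memory$U_t)
  dZ <- matrix(0, nrow(dY), H * dh)
  dU_key <- vector("list", H)
  dU_val <- vector("list", H)
  for (e in seq_len(H)) {
    cols <- (e - 1L) * dh + seq_len(dh)
    hd <- fw$heads[[e]]
    dYe <- dY_concat[, cols, drop = FALSE]
    dA <- dYe %*% t(memory$U_val[[e]])
    dU_val[[e]] <- crossprod(hd$dn$A, dYe)
    dA_raw <- double_normalize_backward(hd$dn, dA)
    dU_key[[e]] <- crossprod(hd$ze, dA_raw)
    dZ[, cols] <- dA_raw %*% t(memory$U_key[[e]])
  }
  list(U_key = dU_key, U_val = dU_val, U_t = dU_t, dZ = dZ)
}

#' Multi-head Omics-Linked Attention
#'
#' Splits the concatenated features into H contiguous blocks; each head
#' computes a doubly normalized attention map against its own key
#' memory and reads from its value memory; head outputs are
#' concatenated and passed through the output transform U_t. Output
#' shape equals input shape.
#'
#' @param Z_concat N x d_concat matrix of concatenated refined
#'   embeddings.
#' @param memory An `ola_memory` from [init_ola()].
#' @return N x d_concat fused feature matrix.
#' @export
ola_multihead <- function(Z_concat, memory) {
  stopifnot(ncol(Z_concat) == memory$H * memory$d_head)
  ola_forward(as.matrix(Z_concat), memory)$Y
}

#' Final classification head
#'
#' Affine map from fused features to class logits; softmax of the
#' result is the model's predictive distribution.
#'
#' @param Y_fused N x d matrix of fused features.
#' @param W Weight matrix d x Q.
#' @param b Bias vector of length Q.
#' @return N x Q logits matrix.
#' @export
fuse_and_classify <- function(Y_fused, W, b = numeric(ncol(W))) {
  stopifnot(ncol(Y_fused) == nrow(W), length(b) == ncol(W))
  sweep(Y_fused %*% W, 2L, b, "+")
}

## ---- baseline fusion mechanisms (ablation only) ---------------------

init_self_attention <- function(d) {
  structure(list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d)),
            class = "sa_params")
}

sa_forward <- function(Z, params) {
  d <- ncol(Z)
  Q <- Z %*% params$Wq
  K <- Z %*% params$Wk
  V <- Z %*% params$Wv
  S <- tcrossprod(Q, K) / sqrt(d)
  A <- softmax_rows(S)
  list(Y = A %*% V, A = A, Q = Q, K = K, V = V)
}

sa_backward <- function(Z, params, fw, dY) {
  d <- ncol(Z)
  dA <- tcrossprod(dY, fw$V)
  dV <- crossprod(fw$A, dY)
  dS <- fw$A * (dA - rowSums(fw$A * dA))
  dQ <- (dS %*% fw$K) / sqrt(d)
  dK <- (crossprod(dS, fw$Q)) / sqrt(d)
  list(Wq = crossprod(Z, dQ), Wk = crossprod(Z, dK),
       Wv = crossprod(Z, dV),
       dZ = dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv))
}

# row-wise Kronecker product (per-sample outer product, flattened)
row_kron <- function(A, B) {
  a <- ncol(A)
  b <- ncol(B)
  A[, rep(seq_len(a), each = b), drop = FALSE] *
    B[, rep(seq_len(b), times = a), drop = FALSE]
}

row_kron_backward <- function(A, B, dC) {
  a <- ncol(A)
  b <- ncol(B)
  dA <- matrix(0, nrow(A), a)
  dB <- matrix(0, nrow(B), b)
  for (i in seq_len(a)) {
    block <- dC[, (i - 1L) * b + seq_len(b), drop = FALSE]
    dA[, i] <- rowSums(block * B)
    dB <- dB + block * A[, i]
  }
  list(dA = dA, dB = dB)
}

vcdn_features <- function(rhos) {
  C <- rhos[[1L]]
  if (length(rhos) > 1L) {
    for (m in 2L:length(rhos)) C <- row_kron(C, rhos[[m]])
  }
  C
}
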