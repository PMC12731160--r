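# Dense-matrix graph layers with explicit forward/backward passes.
# Graphs here are small (hundreds of patients), so every layer works on
# full N x N matrices and relies on BLAS; no sparse code paths.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

leaky_relu <- function(x, slope = 0.2) {
  ifelse(x > 0, x, slope * x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#' @param x Numeric matrix of scores.
#' @return Matrix of the same shape with rows summing to 1.
#' @export
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

dropout_mask <- function(n, d, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n * d, 1L, 1 - p) / (1 - p), n, d)
}

## ---- GCN ------------------------------------------------------------

gcn_forward <- function(graph, X, W) {
  AX <- graph$norm_adj %*% X          # D^-1/2 (S+I) D^-1/2 X
  pre <- AX %*% W
  list(out = relu(pre), AX = AX, pre = pre)
}

gcn_backward <- function(graph, X, W, cache, d_out) {
  g <- d_out * (cache$pre > 0)
  dW <- crossprod(cache$AX, g)
  dX <- graph$norm_adj %*% (g %*% t(W))   # norm_adj is symmetric
  list(dX = dX, dW = dW)
}

#' Graph convolution layer
#'
#' One GCN propagation step over the self-looped, symmetrically
#' normalized adjacency: ReLU(D^-1/2 (S+I) D^-1/2 X W).
#'
#' @param graph A `similarity_graph`.
#' @param X Node feature matrix (rows = graph nodes).
#' @param W Weight matrix, `ncol(X)` by output width.
#' @return Output feature matrix, entrywise nonnegative.
#' @export
gcn_layer <- function(graph, X, W) {
  stopifnot(nrow(X) == nrow(graph$adjacency), ncol(X) == nrow(W))
  gcn_forward(graph, X, W)$out
}

## ---- GAT ------------------------------------------------------------

gat_forward <- function(graph, X, W, a, self_loop = TRUE, slope = 0.2) {
  n <- nrow(X)
  h <- ncol(W)
  M <- graph$adjacency
  if (self_loop) diag(M) <- 1
  H <- X %*% W
  f <- drop(H %*% a[seq_len(h)])          # a^T [Wx_i ; .]
  g <- drop(H %*% a[h + seq_len(h)])      # a^T [. ; Wx_j]
  E <- matrix(f, n, n) + matrix(g, n, n, byrow = TRUE)
  S <- leaky_relu(E, slope)
  S[M == 0] <- -Inf
  theta <- softmax_rows(S)
  theta[M == 0] <- 0                      # exact zeros off-neighborhood
  pre <- theta %*% H
  list(out = relu(pre), coeffs = theta, H = H, E = E, M = M, pre = pre)
}

gat_backward <- function(graph, X, W, a, cache, d_out, slope = 0.2) {
  h <- ncol(W)
  g_up <- d_out * (cache$pre > 0)
  theta <- cache$coeffs
  H <- cache$H
  dH <- crossprod(theta, g_up)            # aggregation path
  dTheta <- tcrossprod(g_up, H)           # attention path
  dS <- theta * (dTheta - rowSums(theta * dTheta))
  dE <- dS * ifelse(cache$E > 0, 1, slope)
  dE[cache$M == 0] <- 0
  df <- rowSums(dE)
  dg <- colSums(dE)
  da <- c(crossprod(H, df), crossprod(H, dg))
  dH <- dH + outer(df, a[seq_len(h)]) + outer(dg, a[h + seq_len(h)])
  list(dX = dH %*% t(W), dW = crossprod(X, dH), da = drop(da))
}

#' Graph attention layer
#'
#' Single-head GAT: attention scores LeakyReLU(a^T [W x_i ; W x_j]) are
#' softmax-normalized over each node's neighborhood (including the node
#' itself by default), then used for weighted aggregation followed by
#' ReLU.
#'
#' @inheritParams gcn_layer
#' @param a Attention vector of length `2 * ncol(W)`.
#' @param self_loop Include the node in its own neighborhood.
#' @param slope LeakyReLU negative slope.
#' @return List with `out` (node features) and `coeffs` (N x N attention
#'   coefficients; each row sums to 1 over the neighborhood).
#' @export
gat_layer <- function(graph, X, W, a, self_loop = TRUE, slope = 0.2) {
  stopifnot(length(a) == 2L * ncol(W), ncol(X) == nrow(W))
  fw <- gat_forward(graph, X, W, a, self_loop = self_loop, slope = slope)
  list(out = fw$out, coeffs = fw$coeffs)
}

## ---- encoder --------------------------------------------------------

#' Initialize encoder parameters
#'
#' Glorot-uniform weights for a stack of GCN/GAT layers plus the
#' stage-1 linear classifier. Draws from the current RNG state.
#'
#' @param d_in Input feature count of the omics layer.
#' @param hidden_dims Integer vector of output widths, one per layer.
#' @param n_classes Number of classes Q for the stage-1 classifier.
#' @param layer_order Character vector of `"gcn"`/`"gat"`, same length
#'   as `hidden_dims`. Default: the hybrid GCN-GAT-GCN stack.
#' @return An `encoder_params` list.
#' @export
init_encoder <- function(d_in, hidden_dims = c(400L, 400L, 200L),
                         n_classes = 2L,
                         layer_order = c("gcn", "gat", "gcn")) {
  stopifnot(length(layer_order) == length(hidden_dims))
  dims <- c(d_in, hidden_dims)
  layers <- lapply(seq_along(layer_order), function(i) {
    lay <- list(type = layer_order[i], W = glorot(dims[i], dims[i + 1L]))
    if (layer_order[i] == "gat") {
      lay$a <- stats::runif(2L * dims[i + 1L], -0.1, 0.1)
    }
    lay
  })
  out_dim <- dims[length(dims)]
  structure(list(layers = layers,
                 W_cls = glorot(out_dim, n_classes),
                 b_cls = numeric(n_classes),
                 layer_order = layer_order,
                 hidden_dims = as.integer(hidden_dims)),
            class = "encoder_params")
}

init_linear_encoder <- function(d_in, out_dim, n_classes) {
  # graph-free stand-in used by the "no graph structure learning" ablation
  structure(list(layers = list(list(type = "linear",
                                    W = glorot(d_in, out_dim))),
                 W_cls = glorot(out_dim, n_classes),
                 b_cls = numeric(n_classes),
                 layer_order = "linear",
                 hidden_dims = as.integer(out_dim)),
            class = "encoder_params")
}

encoder_forward <- function(graph, X, params, training = FALSE,
                            dropout = 0, gat_self_loop = TRUE) {
  caches <- vector("list", length(params$layers))
  zs <- vector("list", length(params$layers))
  cur <- X
  for (i in seq_along(params$layers)) {
    lay <- params$layers[[i]]
    mask <- if (training && dropout > 0) {
      dropout_mask(nrow(cur), ncol(cur), dropout)
    }
    inp <- if (is.null(mask)) cur else cur * mask
    cache <- switch(lay$type,
      gcn = gcn_forward(graph, inp, lay$W),
      gat = gat_forward(graph, inp, lay$W, lay$a, self_loop = gat_self_loop),
      linear = {
        pre <- inp %*% lay$W
        list(out = relu(pre), pre = pre)
      },
      stop("unknown layer type: ", lay$type)
    )
    cache$input <- inp
    cache$mask <- mask
    caches[[i]] <- cache
    cur <- cache$out
    zs[[i]] <- cur
  }
  list(Z = cur, zs = zs, caches = caches)
}

encoder_backward <- function(graph, params, fw, d_Z,
                             gat_self_loop = TRUE) {
  grads <- vector("list", length(params$layers))
  d_cur <- d_Z
  for (i in rev(seq_along(params$layers))) {
    lay <- params$layers[[i]]
    cache <- fw$caches[[i]]
    bk <- switch(lay$type,
      gcn = gcn_backward(graph, cache$input, lay$W, cache, d_cur),
      gat = gat_backward(graph, cache$input, lay$W, lay$a, cache, d_cur),
      linear = {
        g <- d_cur * (cache$pre > 0)
        list(dX = g %*% t(lay$W), dW = crossprod(cache$input, g))
      }
    )
    gi <- list(W = bk$dW)
    if (!is.null(bk$da)) gi$a <- bk$da
    grads[[i]] <- gi
    d_cur <- bk$dX
    if (!is.null(cache$mask)) d_cur <- d_cur * cache$mask
  }
  grads
}

#' Encode one omics layer with the hybrid graph encoder
#'
#' Runs the layer stack (default GCN -> GAT -> GCN) over the
#' patient-similarity graph, retaining every intermediate embedding.
#'
#' @param graph A `similarity_graph` for this layer.
#' @param X Sample-by-feature matrix of the same layer.
#' @param params An `encoder_params` from [init_encoder()].
#' @param gat_self_loop Include each node in its own GAT neighborhood.
#' @return An `omics_embedding`: list with the per-stage embeddings
#'   `Z1`, `Z2`, ..., final `Z`, and `omics_name`.
#' @export
encode_omics <- function(graph, X, params, gat_self_loop = TRUE) {
  fw <- encoder_forward(graph, X, params, training = FALSE,
                        gat_self_loop = gat_self_loop)
  out <- list(Z = fw$Z, omics_name = graph$omics_name)
  for (i in seq_along(fw$zs)) out[[paste0("Z", i)]] <- fw$zs[[i]]
  structure(out, class = "omics_embedding")
}
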