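# Independent brute-force oracles: every one is a direct loop-based
# transcription of the corresponding formula, kept free of the
# vectorized implementation paths it checks.

oracle_cosine <- function(X) {
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- sum(X[i, ] * X[j, ]) /
        (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
    }
  }
  S
}

oracle_knn <- function(sim, k, symmetrize = TRUE) {
  n <- nrow(sim)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # sort by similarity descending, ties toward lower index
    ord <- others[order(-sim[i, others], others)]
    A[i, ord[seq_len(k)]] <- 1
  }
  if (symmetrize) A <- pmax(A, t(A))
  A
}

oracle_gcn <- function(adj, X, W) {
  n <- nrow(adj)
  S <- adj
  diag(S) <- diag(S) + 1
  deg <- rowSums(S)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    acc <- numeric(ncol(X))
    for (j in seq_len(n)) {
      acc <- acc + S[i, j] / sqrt(deg[i] * deg[j]) * X[j, ]
    }
    out[i, ] <- pmax(acc %*% W, 0)
  }
  out
}

oracle_gat <- function(adj, X, W, a, self_loop = TRUE, slope = 0.2) {
  n <- nrow(adj)
  h <- ncol(W)
  H <- X %*% W
  lr <- function(x) ifelse(x > 0, x, slope * x)
  theta <- matrix(0, n, n)
  out <- matrix(0, n, h)
  for (i in seq_len(n)) {
    nei <- which(adj[i, ] == 1)
    if (self_loop) nei <- sort(unique(c(nei, i)))
    e <- vapply(nei, function(j) {
      lr(sum(a * c(H[i, ], H[j, ])))
    }, 0)
    w <- exp(e - max(e))
    w <- w / sum(w)
    theta[i, nei] <- w
    acc <- numeric(h)
    for (idx in seq_along(nei)) acc <- acc + w[idx] * H[nei[idx], ]
    out[i, ] <- pmax(acc, 0)
  }
  list(out = out, coeffs = theta)
}

oracle_double_normalize <- function(A_raw) {
  n <- nrow(A_raw)
  s <- ncol(A_raw)
  Ab <- matrix(0, n, s)
  for (j in seq_len(s)) {
    e <- exp(A_raw[, j])
    Ab[, j] <- e / sum(e)
  }
  A <- matrix(0, n, s)
  for (i in seq_len(n)) A[i, ] <- Ab[i, ] / sum(Ab[i, ])
  A
}

oracle_ola <- function(Z, memory) {
  H <- memory$H
  dh <- memory$d_head
  Ys <- vector("list", H)
  for (e in seq_len(H)) {
    ze <- Z[, (e - 1L) * dh + seq_len(dh), drop = FALSE]
    A <- oracle_double_normalize(ze %*% memory$U_key[[e]])
    Ys[[e]] <- A %*% memory$U_val[[e]]
  }
  do.call(cbind, Ys) %*% memory$U_t
}

oracle_weighted_ce <- function(logits, y, weights = NULL) {
  total <- 0
  for (i in seq_len(nrow(logits))) {
    p <- exp(logits[i, ]) / sum(exp(logits[i, ]))
    w <- if (is.null(weights)) 1 else weights[y[i] + 1L]
    total <- total - w * log(p[y[i] + 1L])
  }
  total
}

oracle_gc_loss <- function(rho, conf, y) {
  ce <- 0
  mse <- 0
  for (m in seq_along(rho)) {
    for (i in seq_along(y)) {
      ce <- ce - log(rho[[m]][i, y[i] + 1L])
      mse <- mse + (conf[[m]][i] - rho[[m]][i, y[i] + 1L])^2
    }
  }
  list(ce = ce, mse = mse, loss = ce + mse)
}

oracle_confusion_metrics <- function(y_true, y_pred, q) {
  cm <- matrix(0, q, q)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L,
                                             y_pred[i] + 1L] + 1
  }
  f1 <- numeric(q)
  for (c in seq_len(q)) {
    tp <- cm[c, c]
    prec <- if (sum(cm[, c]) > 0) tp / sum(cm[, c]) else 0
    rec <- if (sum(cm[c, ]) > 0) tp / sum(cm[c, ]) else 0
    f1[c] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  list(acc = sum(diag(cm)) / length(y_true),
       f1_macro = mean(f1),
       f1_weighted = sum(f1 * rowSums(cm)) / length(y_true))
}

# AUC over all positive-negative pairs, 0.5 credit for ties
oracle_auc_pairs <- function(y, score) {
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  tot / (length(pos) * length(neg))
}

random_graph <- function(n, k = 2L) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, sample(setdiff(seq_len(n), i), min(k, n - 1L))] <- 1
  }
  A <- pmax(A, t(A))
  similarity_graph(A, k)
}
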