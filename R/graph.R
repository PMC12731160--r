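#' Pairwise cosine similarity between samples
#'
#' Cosine similarity between every pair of sample feature vectors,
#' dist(x_i, x_j) = (x_i . x_j) / (||x_i|| ||x_j||).
#'
#' @param X Numeric matrix, samples in rows.
#' @return Symmetric N x N matrix with unit diagonal, entries in [-1, 1].
#' @export
cosine_similarity_matrix <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0L) {
    who <- if (is.null(rownames(X))) as.character(zero) else rownames(X)[zero]
    stop("zero-norm sample(s), cosine similarity undefined: ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  Xn <- X / nrm
  S <- tcrossprod(Xn)
  S <- (S + t(S)) / 2          # kill asymmetric rounding noise
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  S
}

#' Binary KNN adjacency from a similarity matrix
#'
#' For each sample the k most similar other samples (ties broken toward
#' the lower column index) become edges; the directed top-k relation is
#' then symmetrized by elementwise maximum with its transpose, yielding
#' an undirected binary graph. Self-loops are excluded here; they enter
#' the GCN propagation via S + I.
#'
#' @param sim Symmetric N x N similarity matrix.
#' @param k Neighbor count, 1 <= k <= N-1.
#' @param omics_name Layer name stored on the graph.
#' @param symmetrize If `FALSE`, keep the directed top-k relation.
#' @param allowed Optional N x N logical matrix; `FALSE` entries are
#'   never selected as neighbors (used to forbid test-test edges in the
#'   transductive protocol).
#' @return A `similarity_graph`: list with binary `adjacency`, `k`,
#'   `omics_name`, `degree` of S + I, and the symmetrically normalized
#'   propagation matrix `norm_adj` = D^-1/2 (S+I) D^-1/2.
#' @export
knn_adjacency <- function(sim, k, omics_name = "", symmetrize = TRUE,
                          allowed = NULL) {
  n <- nrow(sim)
  if (k < 1L || k > n - 1L) {
    stop("k must be in [1, N-1]; got k=", k, " with N=", n, call. = FALSE)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- -Inf
    if (!is.null(allowed)) s[!allowed[i, ]] <- -Inf
    cand <- which(is.finite(s))
    ki <- min(k, length(cand))
    if (ki > 0L) {
      # stable order: ties resolved toward the lower column index
      top <- cand[order(-s[cand], cand)[seq_len(ki)]]
      A[i, top] <- 1
    }
  }
  if (symmetrize) A <- pmax(A, t(A))
  dimnames(A) <- dimnames(sim)
  similarity_graph(A, k, omics_name)
}

#' Construct a similarity_graph from a binary adjacency
#'
#' @param adjacency Binary N x N matrix, zero diagonal.
#' @param k Neighbor count used to build it.
#' @param omics_name Layer name.
#' @return A `similarity_graph` with the precomputed GCN normalizer.
#' @export
similarity_graph <- function(adjacency, k, omics_name = "") {
  stopifnot(nrow(adjacency) == ncol(adjacency),
            all(adjacency %in% c(0, 1)), all(diag(adjacency) == 0))
  deg <- rowSums(adjacency) + 1          # degree of S + I
  dhalf <- 1 / sqrt(deg)
  A_loop <- adjacency
  diag(A_loop) <- 1
  norm_adj <- dhalf * A_loop * rep(dhalf, each = nrow(adjacency))
  structure(list(adjacency = adjacency, k = as.integer(k),
                 omics_name = omics_name, degree = deg,
                 norm_adj = norm_adj),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph '%s'> %d nodes, %d undirected edges, k=%d\n",
              x$omics_name, nrow(x$adjacency), sum(x$adjacency) / 2, x$k))
  invisible(x)
}

#' Build one KNN patient-similarity graph per omics layer
#'
#' Each graph is computed only from its own layer's feature matrix, so
#' layers never interfere at the graph-construction stage.
#'
#' @param dataset A `multiomics_dataset`.
#' @param k Single neighbor count or a named vector/list keyed by layer.
#' @param standardize Z-score features before similarity (off by
#'   default: similarity is computed on the matrices as given).
#' @param symmetrize Passed to [knn_adjacency()].
#' @param allowed Optional N x N logical edge-candidate mask.
#' @return Named list of `similarity_graph`, one per layer.
#' @export
build_graphs <- function(dataset, k, standardize = FALSE, symmetrize = TRUE,
                         allowed = NULL) {
  lapply(dataset$omics, function(m) {
    nm <- attr(m, "omics_name")
    ki <- if (length(k) > 1L || !is.null(names(k))) {
      if (is.null(k[[nm]])) stop("no k given for omics '", nm, "'",
                                 call. = FALSE)
      k[[nm]]
    } else {
      k
    }
    X <- unclass(m)
    if (standardize) {
      sds <- apply(X, 2, stats::sd)
      sds[sds == 0] <- 1
      X <- scale(X, center = TRUE, scale = sds)
    }
    knn_adjacency(cosine_similarity_matrix(X), ki, omics_name = nm,
                  symmetrize = symmetrize, allowed = allowed)
  })
}

#' Export a graph as an edge-list TSV
#'
#' @param graph A `similarity_graph` with sample IDs as dimnames.
#' @param path Output TSV path (columns source_id, target_id; each
#'   undirected edge written once, source < target).
#' @export
write_edgelist_tsv <- function(graph, path) {
  A <- graph$adjacency
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  df <- data.frame(source_id = ids[idx[, 1L]], target_id = ids[idx[, 2L]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
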