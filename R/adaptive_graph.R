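# Adaptive, input-dependent channel adjacency. For node features
# x_1..x_N in R^{F_de} and a learnable weight vector w in R^{F_de}:
#
#   A[m, n] = exp(-ReLU(w^T |x_m - x_n|)) / sum_n' exp(-ReLU(w^T |x_m - x_n'|))
#
# i.e. a row-softmax of the negative weighted channel dissimilarity. The
# element-wise absolute difference keeps the ReLU argument a true
# dissimilarity (a signed difference would flip sign with the pair order).
# w is learned by minimizing the graph loss
#
#   L_gcn = tau * sum_{m,n} ||x_m - x_n||^2 * A[m, n]  +  ||A||_F^2
#
# (feature-smoothness term weighted by tau, plus a Frobenius sparsity term).

# |x_m - x_n| for all pairs as an (N*N) x F matrix, row index (m, n)
# column-major in m.
pairwise_absdiff <- function(x) {
  N <- nrow(x)
  F_de <- ncol(x)
  D <- matrix(0, N * N, F_de)
  for (f in seq_len(F_de)) {
    D[, f] <- abs(rep(x[, f], times = N) - rep(x[, f], each = N))
  }
  D
}

adjacency_scores <- function(x, w) {
  N <- nrow(x)
  u <- pairwise_absdiff(x) %*% w
  matrix(-relu(u), N, N)                          # S[m, n], symmetric in |.|
}

#' Input-dependent adjacency over channels
#'
#' Row-stochastic `N x N` affinity: similar channels (small weighted
#' absolute feature difference) get large entries. The diagonal is each
#' row's maximum whenever `w >= 0` (zero self-dissimilarity).
#'
#' @param x numeric matrix `N x F_de` of per-channel features.
#' @param w numeric length-`F_de` weight vector.
#' @return Row-stochastic `N x N` matrix.
#' @export
compute_adjacency <- function(x, w) {
  x <- as.matrix(x)
  stopifnot(length(w) == ncol(x))
  softmax_rows(adjacency_scores(x, w))
}

#' Graph-smoothness + sparsity loss of an adjacency
#'
#' `tau * sum_{m,n} ||x_m - x_n||^2 A[m,n] + ||A||_F^2`. The first term is
#' small when strong edges connect similar channels; the Frobenius term
#' penalizes concentrated (dense-in-mass) rows, pushing toward sparsity of
#' the represented graph.
#'
#' @param x numeric matrix `N x F_de`.
#' @param A adjacency `N x N`.
#' @param tau non-negative smoothness weight.
#' @return Scalar loss.
#' @export
graph_regularization_loss <- function(x, A, tau) {
  stopifnot(tau >= 0)
  x <- as.matrix(x)
  D2 <- as.matrix(stats::dist(x))^2
  tau * sum(D2 * A) + sum(A^2)
}

# Gradient of L_gcn w.r.t. w (through A's softmax). Also returns the loss.
graph_loss_grad_w <- function(x, w, tau) {
  x <- as.matrix(x)
  N <- nrow(x)
  Dabs <- pairwise_absdiff(x)                     # (m,n) pairs x F
  u <- as.numeric(Dabs %*% w)
  S <- matrix(-relu(u), N, N)
  A <- softmax_rows(S)
  D2 <- matrix(rowSums(Dabs^2), N, N)             # squared Euclidean (|.|^2)
  # dL/dA, back through the row softmax, then dS/dw = -1[u>0] * |x_m - x_n|.
  dA <- tau * D2 + 2 * A
  dS <- softmax_rows_backward(A, dA)
  gvec <- -as.numeric(dS) * (u > 0)
  grad <- as.numeric(crossprod(Dabs, gvec))
  list(loss = tau * sum(D2 * A) + sum(A^2), grad = grad, A = A)
}

#' Fixed k-nearest-neighbour adjacency (ablation graph)
#'
#' Each channel is connected to its `k` nearest Euclidean neighbours in
#' feature space; the edge set is symmetrized by union, self-loops added,
#' and rows normalized to stochastic form so the matrix is a drop-in
#' replacement for the adaptive adjacency. Ties are broken by lowest
#' channel index (stable order).
#'
#' @param x numeric matrix `N x F_de`.
#' @param k integer, `1 <= k < N`.
#' @param mode `"binary"` (unit edge weights) or `"distance"`
#'   (`exp(-dist^2)` weights on kept edges).
#' @return Row-stochastic `N x N` matrix.
#' @export
knn_adjacency <- function(x, k, mode = c("binary", "distance")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  N <- nrow(x)
  if (k < 1L || k >= N) {
    stop(sprintf("k must satisfy 1 <= k < N (got k=%d, N=%d)", k, N),
         call. = FALSE)
  }
  D <- as.matrix(stats::dist(x))
  A <- matrix(0, N, N)
  for (m in seq_len(N)) {
    ord <- order(D[m, -m], seq_len(N)[-m])        # ties: lowest index first
    nbr <- (seq_len(N)[-m])[ord[seq_len(k)]]
    A[m, nbr] <- if (mode == "binary") 1 else exp(-D[m, nbr]^2)
  }
  A <- pmax(A, t(A))                              # symmetrize by union
  diag(A) <- 1
  A / rowSums(A)
}

#' Distance-based initial adjacency from electrode positions
#'
#' Gaussian kernel on physical electrode distance,
#' `A[m,n] proportional to exp(-dist(m,n)^2 / theta^2)`, row-normalized.
#' Provided as the optional warm-start graph; the feature-driven adaptive
#' adjacency is the default.
#'
#' @param channel_positions numeric matrix `N x 3` of electrode coordinates.
#' @param theta kernel length scale (same units as the positions).
#' @return Row-stochastic `N x N` matrix.
#' @export
distance_initial_adjacency <- function(channel_positions, theta = 1) {
  pos <- as.matrix(channel_positions)
  stopifnot_finite(pos, "channel positions")
  D2 <- unname(as.matrix(stats::dist(pos)))^2
  A <- exp(-D2 / theta^2)
  A / rowSums(A)
}

#' Symmetrize a row-stochastic adjacency for spectral filtering
#'
#' The graph is undirected but the row-softmax adjacency is asymmetric;
#' the Laplacian needs a symmetric matrix for a real spectrum, so the
#' spectral path uses `(A + t(A)) / 2`. The raw `A` is kept for the graph
#' loss as defined.
#'
#' @param A adjacency `N x N`.
#' @return Symmetric `N x N` matrix.
#' @export
symmetrize_adjacency <- function(A) (A + t(A)) / 2

#' Export an adjacency as an edge list
#'
#' @param A adjacency `N x N`.
#' @param channel_names channel names (rows/cols of `A`).
#' @param path optional CSV output path.
#' @return `data.frame` with columns `channel_a`, `channel_b`, `weight`.
#' @export
adjacency_edge_list <- function(A, channel_names = NULL, path = NULL) {
  N <- nrow(A)
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(N))
  idx <- which(row(A) != col(A), arr.ind = TRUE)
  df <- data.frame(channel_a = channel_names[idx[, 1]],
                   channel_b = channel_names[idx[, 2]],
                   weight = A[idx])
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
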