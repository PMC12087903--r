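# Spatial-temporal attention over one window X in R^{T x N x F_de}.
#
# Temporal: Q = V_e * sigmoid( (X' U1) U2 (U3 X'') + b_e ), row-softmaxed to
# a row-stochastic T x T matrix Q'. Spatial (on the re-weighted window X^):
# P = V_s * sigmoid( (X^'' W1) W2 (W3 X^') + b_s ), row-softmaxed to N x N.
#
# Shape bookkeeping (the equations give shapes, not indices):
#   (X' U1):  contract channels  -> T x F_de
#   ... U2 :  F_de x N map       -> T x N
#   (U3 X''): contract bands     -> N x T
#   product:                      T x T
# and mirrored with (T <-> N, U <-> W) for the spatial score, giving N x N.

#' Initialize temporal attention parameters
#'
#' `V_e` starts identity-scaled (so attention is near-neutral at the start),
#' `U1`, `U2`, `U3` and `b_e` zero-mean uniform with fan-in scaling.
#'
#' @param T_len,n_channels,n_bands window shape (T, N, F_de).
#' @param scale multiplier on the uniform half-width.
#' @return List of parameter arrays `V_e, b_e, U1, U2, U3`.
#' @export
init_temporal_attention_params <- function(T_len, n_channels, n_bands,
                                           scale = 1) {
  runif_fan <- function(n, fan) (stats::runif(n) - 0.5) * 2 * scale / sqrt(fan)
  list(
    V_e = diag(T_len),
    b_e = matrix(runif_fan(T_len * T_len, T_len), T_len, T_len),
    U1 = runif_fan(n_channels, n_channels),
    U2 = matrix(runif_fan(n_bands * n_channels, n_bands), n_bands, n_channels),
    U3 = runif_fan(n_bands, n_bands))
}

#' Initialize spatial attention parameters
#'
#' @inheritParams init_temporal_attention_params
#' @return List of parameter arrays `V_s, b_s, W1, W2, W3`.
#' @export
init_spatial_attention_params <- function(T_len, n_channels, n_bands,
                                          scale = 1) {
  runif_fan <- function(n, fan) (stats::runif(n) - 0.5) * 2 * scale / sqrt(fan)
  list(
    V_s = diag(n_channels),
    b_s = matrix(runif_fan(n_channels * n_channels, n_channels),
                 n_channels, n_channels),
    W1 = runif_fan(T_len, T_len),
    W2 = matrix(runif_fan(n_bands * T_len, n_bands), n_bands, T_len),
    W3 = runif_fan(n_bands, n_bands))
}

temporal_attention_fwd <- function(X, params) {
  d <- dim(X)
  T_len <- d[1]; N <- d[2]; F_de <- d[3]
  M1 <- matrix(aperm(X, c(1, 3, 2)), T_len * F_de, N)   # (t,f) x n
  t1 <- matrix(M1 %*% params$U1, T_len, F_de)           # T x F
  t2 <- t1 %*% params$U2                                # T x N
  M3 <- matrix(aperm(X, c(2, 1, 3)), N * T_len, F_de)   # (n,t) x f
  t3 <- matrix(M3 %*% params$U3, N, T_len)              # N x T
  E <- t2 %*% t3 + params$b_e
  S <- sigmoid(E)
  Q <- params$V_e %*% S
  Q_norm <- softmax_rows(Q)
  list(Q_norm = Q_norm, cache = list(X = X, M1 = M1, M3 = M3, t1 = t1,
                                     t2 = t2, t3 = t3, S = S,
                                     Q_norm = Q_norm))
}

#' Temporal attention matrix of a window
#'
#' Scores pairwise interactions between the `T` one-second samples of a
#' window and normalizes each row to a probability vector (row-stochastic
#' `T x T` matrix).
#'
#' @param X numeric array `T x N x F_de`.
#' @param params parameters from [init_temporal_attention_params()].
#' @return Row-stochastic `T x T` matrix `Q_norm`.
#' @export
temporal_attention <- function(X, params) {
  stopifnot_finite(X, "attention input")
  temporal_attention_fwd(X, params)$Q_norm
}

temporal_attention_bwd <- function(dQ_norm, params, cache) {
  d <- dim(cache$X)
  T_len <- d[1]; N <- d[2]; F_de <- d[3]
  dQ <- softmax_rows_backward(cache$Q_norm, dQ_norm)
  dV_e <- dQ %*% t(cache$S)
  dS <- t(params$V_e) %*% dQ
  dE <- dS * cache$S * (1 - cache$S)
  db_e <- dE
  dt2 <- dE %*% t(cache$t3)
  dt3 <- t(cache$t2) %*% dE
  dt1 <- dt2 %*% t(params$U2)
  dU2 <- t(cache$t1) %*% dt2
  dU1 <- as.numeric(t(cache$M1) %*% as.numeric(dt1))
  dU3 <- as.numeric(t(cache$M3) %*% as.numeric(dt3))
  dX <- aperm(array(outer(as.numeric(dt1), params$U1), c(T_len, F_de, N)),
              c(1, 3, 2)) +
        aperm(array(outer(as.numeric(dt3), params$U3), c(N, T_len, F_de)),
              c(2, 1, 3))
  list(grads = list(V_e = dV_e, b_e = db_e, U1 = dU1, U2 = dU2, U3 = dU3),
       dX = dX)
}

#' Re-weight a window by its temporal attention
#'
#' `X_hat[t] = sum_s X[s] * Q_norm[s, t]`: each output time slice is a
#' convex combination of the input slices (columns of `Q_norm` index target
#' time).
#'
#' @param X numeric array `T x N x F_de`.
#' @param Q_norm row-stochastic `T x T` matrix.
#' @return Array `T x N x F_de`.
#' @export
apply_temporal_attention <- function(X, Q_norm) {
  d <- dim(X)
  if (nrow(Q_norm) != d[1] || ncol(Q_norm) != d[1]) {
    stop("Q_norm shape does not match the window's time axis", call. = FALSE)
  }
  Xm <- matrix(X, d[1], d[2] * d[3])
  array(t(Q_norm) %*% Xm, dim = d)
}

apply_temporal_attention_bwd <- function(dX_hat, X, Q_norm) {
  d <- dim(X)
  dXh_m <- matrix(dX_hat, d[1], d[2] * d[3])
  Xm <- matrix(X, d[1], d[2] * d[3])
  list(dX = array(Q_norm %*% dXh_m, dim = d),
       dQ_norm = Xm %*% t(dXh_m))
}

spatial_attention_fwd <- function(X_hat, params) {
  d <- dim(X_hat)
  T_len <- d[1]; N <- d[2]; F_de <- d[3]
  M1 <- matrix(aperm(X_hat, c(2, 3, 1)), N * F_de, T_len)  # (n,f) x t
  a1 <- matrix(M1 %*% params$W1, N, F_de)                  # N x F
  a2 <- a1 %*% params$W2                                   # N x T
  M3 <- matrix(X_hat, T_len * N, F_de)                     # (t,n) x f
  a3 <- matrix(M3 %*% params$W3, T_len, N)                 # T x N
  E <- a2 %*% a3 + params$b_s
  S <- sigmoid(E)
  P <- params$V_s %*% S
  P_norm <- softmax_rows(P)
  list(P_norm = P_norm, cache = list(X_hat = X_hat, M1 = M1, M3 = M3,
                                     a1 = a1, a2 = a2, a3 = a3, S = S,
                                     P_norm = P_norm))
}

#' Spatial attention matrix of a window
#'
#' Scores pairwise channel interactions of the (temporally re-weighted)
#' window and row-softmaxes them into a row-stochastic `N x N` matrix. One
#' matrix is computed per window and shared across its `T` segments.
#'
#' @param X_hat numeric array `T x N x F_de`.
#' @param params parameters from [init_spatial_attention_params()].
#' @return Row-stochastic `N x N` matrix `P_norm`.
#' @export
spatial_attention <- function(X_hat, params) {
  stopifnot_finite(X_hat, "attention input")
  spatial_attention_fwd(X_hat, params)$P_norm
}

spatial_attention_bwd <- function(dP_norm, params, cache) {
  d <- dim(cache$X_hat)
  T_len <- d[1]; N <- d[2]; F_de <- d[3]
  dP <- softmax_rows_backward(cache$P_norm, dP_norm)
  dV_s <- dP %*% t(cache$S)
  dS <- t(params$V_s) %*% dP
  dE <- dS * cache$S * (1 - cache$S)
  db_s <- dE
  da2 <- dE %*% t(cache$a3)
  da3 <- t(cache$a2) %*% dE
  da1 <- da2 %*% t(params$W2)
  dW2 <- t(cache$a1) %*% da2
  dW1 <- as.numeric(t(cache$M1) %*% as.numeric(da1))
  dW3 <- as.numeric(t(cache$M3) %*% as.numeric(da3))
  dX_hat <- aperm(array(outer(as.numeric(da1), params$W1), c(N, F_de, T_len)),
                  c(3, 1, 2)) +
            array(outer(as.numeric(da3), params$W3), c(T_len, N, F_de))
  list(grads = list(V_s = dV_s, b_s = db_s, W1 = dW1, W2 = dW2, W3 = dW3),
       dX_hat = dX_hat)
}
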