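# Chebyshev spectral graph convolution, attention-modulated, plus the
# temporal convolution that follows it.
#
# L = D - A (combinatorial Laplacian), L~ = (2/lambda_max) L - I rescales the
# spectrum into [-1, 1] so the Chebyshev recursion xi_k = 2 L~ xi_{k-1} -
# xi_{k-2} (xi_0 = I, xi_1 = L~) is a stable polynomial filter basis. The
# spatial filter is applied per time step with the spatial attention P' as an
# element-wise edge mask:
#
#   X_sgc[t] = sum_k ( xi_k(L~) (Hadamard) P' ) X_hat[t] theta_k
#
# where theta_k in R^{F_de x F_out} both mixes bands and sets the output
# width. The temporal stage is X_tgc = ReLU( Phi * ReLU(X_sgc) ) with a 1-D
# convolution along time (zero-padded, length-preserving).

#' Scaled graph Laplacian
#'
#' @param A_sym symmetric non-negative adjacency `N x N`.
#' @return List with `L_tilde` (`N x N`, spectrum in `[-1, 1]`) and
#'   `lambda_max`. An edgeless graph (`lambda_max ~ 0`) falls back to
#'   `lambda_max = 2` with a warning.
#' @export
scaled_laplacian <- function(A_sym) {
  A_sym <- as.matrix(A_sym)
  if (max(abs(A_sym - t(A_sym))) > 1e-8) {
    stop("adjacency must be symmetric; see symmetrize_adjacency()", call. = FALSE)
  }
  L <- diag(rowSums(A_sym)) - A_sym
  lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_max < 1e-9) {
    warning("edgeless graph: lambda_max ~ 0, falling back to lambda_max = 2",
            call. = FALSE)
    lambda_max <- 2
  }
  list(L_tilde = (2 / lambda_max) * L - diag(nrow(L)), lambda_max = lambda_max)
}

#' Chebyshev polynomial basis of the scaled Laplacian
#'
#' @param L_tilde scaled Laplacian `N x N`.
#' @param K number of basis matrices (polynomial order bound, `K >= 1`).
#' @return List `[xi_0 = I, xi_1 = L_tilde, ..., xi_{K-1}]`.
#' @export
cheb_basis <- function(L_tilde, K) {
  stopifnot(K >= 1)
  N <- nrow(L_tilde)
  basis <- vector("list", K)
  basis[[1]] <- diag(N)
  if (K >= 2) basis[[2]] <- L_tilde
  if (K >= 3) {
    for (k in 3:K) {
      basis[[k]] <- 2 * L_tilde %*% basis[[k - 1]] - basis[[k - 2]]
    }
  }
  basis
}

#' Attention-modulated Chebyshev spatial graph convolution
#'
#' Applies the `K`-term polynomial filter independently at each time step,
#' with the spatial attention matrix as an element-wise mask on each basis
#' matrix (edge re-weighting that preserves the polynomial's locality).
#'
#' @param X_hat numeric array `T x N x F_de`.
#' @param P_norm spatial attention `N x N` (all-ones to disable masking).
#' @param basis list of `K` matrices from [cheb_basis()].
#' @param theta list of `K` matrices `F_de x F_out`.
#' @return Array `T x N x F_out`.
#' @export
spatial_graph_conv <- function(X_hat, P_norm, basis, theta) {
  spatial_graph_conv_fwd(X_hat, P_norm, basis, theta)$out
}

# Batched over time: with X_rows = (N*T) x F_de (rows node-fastest) and
# Z_k = X_rows theta_k reshaped to N x (T*F_out), the per-step left
# multiplication by the masked basis becomes one matmul per k.
spatial_graph_conv_fwd <- function(X_hat, P_norm, basis, theta) {
  d <- dim(X_hat)
  T_len <- d[1]; N <- d[2]; F_de <- d[3]
  K <- length(basis)
  stopifnot(length(theta) == K, nrow(theta[[1]]) == F_de,
            nrow(P_norm) == N, ncol(P_norm) == N)
  F_out <- ncol(theta[[1]])
  masked <- lapply(basis, function(B) B * P_norm)
  X_rows <- matrix(aperm(X_hat, c(2, 1, 3)), N * T_len, F_de)
  Z_wide <- vector("list", K)                     # N x (T*F_out)
  out_wide <- matrix(0, N, T_len * F_out)
  for (k in seq_len(K)) {
    Z_wide[[k]] <- matrix(X_rows %*% theta[[k]], N, T_len * F_out)
    out_wide <- out_wide + masked[[k]] %*% Z_wide[[k]]
  }
  out <- aperm(array(out_wide, c(N, T_len, F_out)), c(2, 1, 3))
  list(out = out, cache = list(dims = d, X_rows = X_rows, masked = masked,
                               Z_wide = Z_wide, basis = basis, theta = theta))
}

spatial_graph_conv_bwd <- function(dout, cache) {
  d <- cache$dims
  T_len <- d[1]; N <- d[2]; F_de <- d[3]
  K <- length(cache$theta)
  F_out <- ncol(cache$theta[[1]])
  dwide <- matrix(aperm(dout, c(2, 1, 3)), N, T_len * F_out)
  dtheta <- vector("list", K)
  dX_rows <- matrix(0, N * T_len, F_de)
  dP <- matrix(0, N, N)
  for (k in seq_len(K)) {
    dZ_wide <- crossprod(cache$masked[[k]], dwide)
    dZ_rows <- matrix(dZ_wide, N * T_len, F_out)
    dtheta[[k]] <- crossprod(cache$X_rows, dZ_rows)
    dX_rows <- dX_rows + dZ_rows %*% t(cache$theta[[k]])
    dP <- dP + tcrossprod(dwide, cache$Z_wide[[k]]) * cache$basis[[k]]
  }
  dX_hat <- aperm(array(dX_rows, c(N, T_len, F_de)), c(2, 1, 3))
  list(dtheta = dtheta, dX_hat = dX_hat, dP_norm = dP)
}

#' Initialize temporal convolution parameters
#'
#' @param F_out channel width.
#' @param kernel_len odd kernel length along time (default 3, the smallest
#'   context-mixing kernel).
#' @param scale uniform init half-width multiplier.
#' @return List with `phi`, an array `kernel_len x F_out x F_out`.
#' @export
init_temporal_conv_params <- function(F_out, kernel_len = 3, scale = 1) {
  stopifnot(kernel_len %% 2 == 1)
  fan <- kernel_len * F_out
  phi <- array((stats::runif(kernel_len * F_out * F_out) - 0.5) * 2 * scale / sqrt(fan),
               dim = c(kernel_len, F_out, F_out))
  list(phi = phi)
}

#' Temporal convolution over the window's time axis
#'
#' `X_tgc = ReLU( Phi * ReLU(X_sgc) )`: ReLU, then a zero-padded 1-D
#' convolution along time whose kernel also mixes the `F_out` feature
#' channels (node axis pointwise), then ReLU. Length-preserving (`T' = T`).
#'
#' @param X_sgc numeric array `T x N x F_out`.
#' @param params list with `phi` from [init_temporal_conv_params()].
#' @return Non-negative array `T x N x F_out`.
#' @export
temporal_conv <- function(X_sgc, params) {
  temporal_conv_fwd(X_sgc, params)$out
}

# Batched over (time, node): rows of R1_mat = matrix(R1, T*N, F_out) index
# (t, n) with t fastest, so the time shift t -> t + off is a constant row
# offset within each node's stride-T block.
conv_row_index <- function(T_len, N, t_seq) {
  as.numeric(outer(t_seq, (seq_len(N) - 1L) * T_len, `+`))
}

conv_t_range <- function(T_len, off) {
  lo <- max(1L, 1L - off)
  hi <- min(T_len, T_len - off)
  if (lo > hi) integer(0) else lo:hi
}

temporal_conv_fwd <- function(X_sgc, params) {
  d <- dim(X_sgc)
  T_len <- d[1]; N <- d[2]; F_out <- d[3]
  phi <- params$phi
  k_t <- dim(phi)[1]
  c0 <- (k_t + 1L) %/% 2L
  R1 <- pmax(X_sgc, 0)
  R1_mat <- matrix(R1, T_len * N, F_out)
  Z_mat <- matrix(0, T_len * N, F_out)
  for (j in seq_len(k_t)) {
    off <- j - c0                                 # source s = t + off
    t_seq <- conv_t_range(T_len, off)
    if (length(t_seq) == 0L) next
    rows_t <- conv_row_index(T_len, N, t_seq)
    P_j <- R1_mat %*% matrix(phi[j, , ], F_out, F_out)
    Z_mat[rows_t, ] <- Z_mat[rows_t, ] + P_j[rows_t + off, ]
  }
  Z <- array(Z_mat, dim = d)
  out <- array(pmax(Z_mat, 0), dim = d)
  list(out = out, cache = list(X_sgc = X_sgc, R1_mat = R1_mat, Z = Z,
                               phi = phi))
}

temporal_conv_bwd <- function(dout, cache) {
  d <- dim(cache$X_sgc)
  T_len <- d[1]; N <- d[2]; F_out <- d[3]
  phi <- cache$phi
  k_t <- dim(phi)[1]
  c0 <- (k_t + 1L) %/% 2L
  dZ_mat <- matrix(dout * (cache$Z > 0), T_len * N, F_out)
  dphi <- phi * 0
  dR1_mat <- matrix(0, T_len * N, F_out)
  for (j in seq_len(k_t)) {
    off <- j - c0
    t_seq <- conv_t_range(T_len, off)
    if (length(t_seq) == 0L) next
    rows_t <- conv_row_index(T_len, N, t_seq)
    rows_s <- rows_t + off
    dphi[j, , ] <- crossprod(cache$R1_mat[rows_s, , drop = FALSE],
                             dZ_mat[rows_t, , drop = FALSE])
    dR1_mat[rows_s, ] <- dR1_mat[rows_s, ] +
      dZ_mat[rows_t, , drop = FALSE] %*% t(matrix(phi[j, , ], F_out, F_out))
  }
  dX_sgc <- array(dR1_mat, dim = d) * (cache$X_sgc > 0)
  list(dphi = dphi, dX_sgc = dX_sgc)
}

#' Collapse the time axis to a per-window feature vector
#'
#' Mean over time, then node-major flattening (node 1's `F_out` values
#' first), giving the extractor input of length `N * F_out` (310 at the
#' 62-channel, `F_out = 5` defaults).
#'
#' @param X_tgc numeric array `T x N x F_out`.
#' @return Numeric vector of length `N * F_out`.
#' @export
collapse_time <- function(X_tgc) {
  d <- dim(X_tgc)
  M <- matrix(colMeans(matrix(X_tgc, d[1], d[2] * d[3])), d[2], d[3])
  flatten_node_major(M)
}

collapse_time_bwd <- function(dvec, d) {
  M <- t(matrix(dvec, d[3], d[2]))                 # N x F_out
  array(rep(as.numeric(M) / d[1], each = d[1]), dim = d)
}
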