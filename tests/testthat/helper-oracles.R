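# Shared helpers: independent brute-force oracles (explicit index loops,
# no reuse of package internals) and a central finite-difference gradient
# checker.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_window <- function(T_len, N, F_de) {
  array(stats::rnorm(T_len * N * F_de), c(T_len, N, F_de))
}

finite_diff <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Eq-by-eq scalar evaluation of the temporal attention score, explicit loops.
oracle_temporal_attention <- function(X, p) {
  T_len <- dim(X)[1]; N <- dim(X)[2]; F_de <- dim(X)[3]
  E <- matrix(0, T_len, T_len)
  for (a in seq_len(T_len)) for (b in seq_len(T_len)) {
    acc <- 0
    for (n in seq_len(N)) {
      left <- 0
      for (f in seq_len(F_de)) {
        t1 <- 0
        for (np in seq_len(N)) t1 <- t1 + X[a, np, f] * p$U1[np]
        left <- left + t1 * p$U2[f, n]
      }
      right <- 0
      for (f in seq_len(F_de)) right <- right + p$U3[f] * X[b, n, f]
      acc <- acc + left * right
    }
    E[a, b] <- acc
  }
  Q <- p$V_e %*% (1 / (1 + exp(-(E + p$b_e))))
  t(apply(Q, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
}

oracle_spatial_attention <- function(Xh, p) {
  T_len <- dim(Xh)[1]; N <- dim(Xh)[2]; F_de <- dim(Xh)[3]
  E <- matrix(0, N, N)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    acc <- 0
    for (t in seq_len(T_len)) {
      left <- 0
      for (f in seq_len(F_de)) {
        a1 <- 0
        for (tp in seq_len(T_len)) a1 <- a1 + Xh[tp, a, f] * p$W1[tp]
        left <- left + a1 * p$W2[f, t]
      }
      right <- 0
      for (f in seq_len(F_de)) right <- right + p$W3[f] * Xh[t, b, f]
      acc <- acc + left * right
    }
    E[a, b] <- acc
  }
  P <- p$V_s %*% (1 / (1 + exp(-(E + p$b_s))))
  t(apply(P, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
}

# Double-loop softmax adjacency.
oracle_adjacency <- function(x, w) {
  N <- nrow(x)
  A <- matrix(0, N, N)
  for (m in seq_len(N)) {
    s <- numeric(N)
    for (n in seq_len(N)) {
      u <- sum(w * abs(x[m, ] - x[n, ]))
      s[n] <- exp(-max(u, 0))
    }
    A[m, ] <- s / sum(s)
  }
  A
}

oracle_graph_loss <- function(x, A, tau) {
  N <- nrow(x)
  sm <- 0
  for (m in seq_len(N)) for (n in seq_len(N)) {
    sm <- sm + sum((x[m, ] - x[n, ])^2) * A[m, n]
  }
  tau * sm + sum(A^2)
}

# Dense triple-loop Chebyshev spatial convolution.
oracle_spatial_conv <- function(X_hat, P, basis, theta) {
  d <- dim(X_hat)
  F_out <- ncol(theta[[1]])
  out <- array(0, c(d[1], d[2], F_out))
  for (t in seq_len(d[1])) for (k in seq_along(basis)) {
    M <- basis[[k]] * P
    for (i in seq_len(d[2])) for (o in seq_len(F_out)) {
      acc <- 0
      for (j in seq_len(d[2])) for (f in seq_len(d[3])) {
        acc <- acc + M[i, j] * X_hat[t, j, f] * theta[[k]][f, o]
      }
      out[t, i, o] <- out[t, i, o] + acc
    }
  }
  out
}

# Direct sliding-window temporal convolution (zero-padded, double ReLU).
oracle_temporal_conv <- function(X, phi) {
  d <- dim(X)
  k_t <- dim(phi)[1]
  c0 <- (k_t + 1) %/% 2
  R <- pmax(X, 0)
  out <- array(0, d)
  for (t in seq_len(d[1])) for (n in seq_len(d[2])) for (o in seq_len(d[3])) {
    acc <- 0
    for (j in seq_len(k_t)) {
      s <- t + j - c0
      if (s >= 1 && s <= d[1]) {
        for (f in seq_len(d[3])) acc <- acc + R[s, n, f] * phi[j, f, o]
      }
    }
    out[t, n, o] <- max(acc, 0)
  }
  out
}

# Small labeled dataset for protocol/CLI tests: quick to train on.
quick_sim <- function(seed = 1, n_subjects = 2, n_trials = 5, L = 8, N = 6) {
  generate_dataset(sim_config(
    n_subjects = n_subjects, n_trials_per_subject = n_trials, L = L, N = N,
    F_de = 3, C = 2, class_sep = 3, ar_coef = 0.3, block_corr = 0.5,
    subject_shift = 0.1, noise_sd = 1, seed = seed))
}

quick_config <- function(..., max_epochs = 3) {
  model_config(d = 1, max_epochs = max_epochs, batch_size = 32,
               hidden = c(16, 16, 16), disc_hidden = c(8, 8), ...)
}
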