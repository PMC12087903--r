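# Plain fully connected stacks used for the feature extractor f(.), the
# emotion classifier head and the domain discriminator d(.). ReLU between
# hidden layers; the output layer is linear (softmax applied by the loss or
# by the discriminator head).

init_mlp <- function(widths, scale = 1) {
  layers <- vector("list", length(widths) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- widths[i]
    layers[[i]] <- list(
      W = matrix((stats::runif(widths[i] * widths[i + 1]) - 0.5) *
                   2 * scale / sqrt(fan_in), widths[i], widths[i + 1]),
      b = numeric(widths[i + 1]))
  }
  layers
}

# X: B x in. Returns activations list; a[[i]] is input to layer i,
# a[[n+1]] the linear output of the last layer.
mlp_forward <- function(layers, X, final_relu = FALSE) {
  a <- vector("list", length(layers) + 1L)
  a[[1]] <- X
  n <- length(layers)
  for (i in seq_len(n)) {
    Z <- a[[i]] %*% layers[[i]]$W
    Z <- Z + rep(layers[[i]]$b, each = nrow(Z))
    a[[i + 1]] <- if (i < n || final_relu) pmax(Z, 0) else Z
  }
  a
}

# dout: gradient at the (linear or ReLU'd) output. Returns per-layer grads
# and gradient at the input.
mlp_backward <- function(layers, a, dout, final_relu = FALSE) {
  n <- length(layers)
  grads <- vector("list", n)
  dcur <- dout
  for (i in rev(seq_len(n))) {
    if (i < n || final_relu) dcur <- dcur * (a[[i + 1]] > 0)
    grads[[i]] <- list(W = t(a[[i]]) %*% dcur, b = colSums(dcur))
    dcur <- dcur %*% t(layers[[i]]$W)
  }
  list(grads = grads, dX = dcur)
}

# Row-wise softmax cross-entropy. labels are 0-based class ids.
# Returns mean loss and gradient w.r.t. logits (mean-reduced).
softmax_xent <- function(logits, labels) {
  B <- nrow(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(B), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, probs = P, dlogits = G / B)
}
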