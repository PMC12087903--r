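#' @keywords internal
"_PACKAGE"

# Numerically stable row-wise softmax (max-subtraction; output-identical).
softmax_rows <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Backward through a row-wise softmax: given y = softmax_rows(z) and
# dL/dy, returns dL/dz. Jacobian per row: diag(y) - y y^T.
softmax_rows_backward <- function(y, dy) {
  s <- rowSums(dy * y)
  y * (dy - s)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten an N x F matrix node-major (node 1's F values first).
flatten_node_major <- function(M) as.numeric(t(M))
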