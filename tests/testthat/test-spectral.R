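test_that("scaled Laplacian matches hand-worked spectra", {
  # path graph on 2 nodes: L = [[1,-1],[-1,1]], spectrum {0, 2}
  sl <- scaled_laplacian(matrix(c(0, 1, 1, 0), 2))
  expect_equal(sl$lambda_max, 2, tolerance = 1e-12)
  expect_equal(sl$L_tilde, matrix(c(0, -1, -1, 0), 2), tolerance = 1e-12)

  # uniform K3 with off-diagonal 1/2: spectrum {0, 1.5, 1.5}
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 0
  sl3 <- scaled_laplacian(A3)
  expect_equal(sl3$lambda_max, 1.5, tolerance = 1e-12)
  L3 <- diag(rowSums(A3)) - A3
  expect_equal(sl3$L_tilde, (4 / 3) * L3 - diag(3), tolerance = 1e-12)

  # scaled spectrum always lands in [-1, 1]
  set.seed(1)
  for (rep in 1:20) {
    N <- sample(2:8, 1)
    A <- matrix(runif(N^2), N); A <- (A + t(A)) / 2; diag(A) <- 0
    ev <- eigen(scaled_laplacian(A)$L_tilde, symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-6 & ev <= 1 + 1e-6))
  }

  expect_error(scaled_laplacian(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("an edgeless graph falls back to lambda_max = 2 with a warning", {
  expect_warning(sl <- scaled_laplacian(matrix(0, 3, 3)), "edgeless")
  expect_equal(sl$lambda_max, 2)
  expect_equal(sl$L_tilde, -diag(3))
})

test_that("the Chebyshev recursion starts at I, L and follows 2Lx - prev", {
  Lt <- matrix(c(0, -1, -1, 0), 2)
  expect_equal(cheb_basis(Lt, 1), list(diag(2)))
  expect_equal(cheb_basis(Lt, 2), list(diag(2), Lt))
  b3 <- cheb_basis(Lt, 3)
  expect_equal(b3[[3]], 2 * Lt %*% Lt - diag(2))  # = I for this L~
  expect_equal(b3[[3]], diag(2), tolerance = 1e-12)
})

test_that("spatial graph convolution matches identity cases and the dense oracle", {
  set.seed(2)
  X <- rand_window(3, 4, 4)
  theta_id <- list(diag(4))
  basis1 <- list(diag(4))
  expect_equal(spatial_graph_conv(X, diag(4), basis1, theta_id), X)
  expect_equal(spatial_graph_conv(X, matrix(1 / 4, 4, 4), basis1, theta_id),
               X / 4, tolerance = 1e-12)

  for (rep in 1:100) {
    T_len <- sample(1:4, 1); N <- sample(2:5, 1)
    F_de <- sample(1:3, 1); F_out <- sample(1:3, 1); K <- sample(1:3, 1)
    A <- matrix(runif(N^2), N); A <- (A + t(A)) / 2; diag(A) <- 0
    basis <- cheb_basis(scaled_laplacian(A)$L_tilde, K)
    theta <- lapply(seq_len(K), function(k) matrix(rnorm(F_de * F_out), F_de))
    P <- compute_adjacency(matrix(rnorm(N * F_de), N), abs(rnorm(F_de)))
    Xh <- rand_window(T_len, N, F_de)
    expect_equal(spatial_graph_conv(Xh, P, basis, theta),
                 oracle_spatial_conv(Xh, P, basis, theta), tolerance = 1e-10)
  }
})

test_that("polynomial filtering equals spectral-domain filtering", {
  # sum_k theta_k xi_k(L~) x == U (sum_k theta_k xi_k(Lambda)) U' x
  set.seed(3)
  for (rep in 1:30) {
    N <- sample(2:8, 1); K <- sample(1:5, 1)
    A <- matrix(runif(N^2), N); A <- (A + t(A)) / 2; diag(A) <- 0
    Lt <- scaled_laplacian(A)$L_tilde
    basis <- cheb_basis(Lt, K)
    coef <- rnorm(K)
    x <- rnorm(N)
    lhs <- Reduce(`+`, Map(function(c, B) c * B, coef, basis)) %*% x
    eg <- eigen(Lt, symmetric = TRUE)
    xi <- function(lam, k) {        # scalar Chebyshev recursion
      if (k == 0) rep(1, length(lam)) else if (k == 1) lam
      else 2 * lam * xi(lam, k - 1) - xi(lam, k - 2)
    }
    filt <- Reduce(`+`, lapply(seq_len(K), function(k) coef[k] * xi(eg$values, k - 1)))
    rhs <- eg$vectors %*% diag(filt, N) %*% t(eg$vectors) %*% x
    expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-8)
  }
})

test_that("K = 2 filtering is local: disconnected blocks do not mix", {
  set.seed(4)
  # two disconnected 3-node blocks
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 0.5; A[4:6, 4:6] <- 0.5; diag(A) <- 0
  basis <- cheb_basis(scaled_laplacian(A)$L_tilde, 2)
  theta <- lapply(1:2, function(k) matrix(rnorm(6), 3, 2))
  P <- matrix(1, 6, 6)
  X <- rand_window(2, 6, 3)
  X2 <- X
  X2[, 1:3, ] <- X2[, 1:3, ] + rnorm(length(X2[, 1:3, ]))
  out1 <- spatial_graph_conv(X, P, basis, theta)
  out2 <- spatial_graph_conv(X2, P, basis, theta)
  expect_equal(out1[, 4:6, ], out2[, 4:6, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out1[, 1:3, ], out2[, 1:3, ])))
})

test_that("temporal convolution matches the sliding-window oracle and is non-negative", {
  set.seed(5)
  X <- rand_window(5, 3, 2)
  expect_equal(temporal_conv(X, list(phi = array(0, c(3, 2, 2)))),
               array(0, dim(X)))
  phi_id <- array(0, c(3, 2, 2)); phi_id[2, , ] <- diag(2)
  expect_equal(temporal_conv(X, list(phi = phi_id)), pmax(X, 0))

  for (rep in 1:100) {
    T_len <- sample(1:6, 1); N <- sample(1:4, 1); F_out <- sample(1:3, 1)
    k_t <- sample(c(1, 3, 5), 1)
    X <- rand_window(T_len, N, F_out)
    phi <- array(rnorm(k_t * F_out^2), c(k_t, F_out, F_out))
    got <- temporal_conv(X, list(phi = phi))
    expect_equal(got, oracle_temporal_conv(X, phi), tolerance = 1e-10)
    expect_true(all(got >= 0))
  }
})

test_that("time collapse averages then flattens node-major", {
  set.seed(6)
  X1 <- rand_window(1, 3, 2)
  expect_equal(collapse_time(X1), as.numeric(t(matrix(X1[1, , ], 3, 2))))

  Xc <- rand_window(1, 4, 3)[rep(1, 5), , , drop = FALSE]  # constant in time
  expect_equal(collapse_time(Xc),
               as.numeric(t(matrix(Xc[3, , ], 4, 3))), tolerance = 1e-12)

  expect_length(collapse_time(rand_window(4, 62, 5)), 310)
})
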