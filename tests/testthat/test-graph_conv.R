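random_adjacency <- function(N, seed) {
  set.seed(seed)
  w <- matrix(runif(N * N), N, N)
  w <- (w + t(w)) / 2
  w[w < 0.3] <- 0                       # some sparsity
  diag(w) <- 0
  eegstgcn:::adjacency_matrix(w, "random_test")
}

test_that("the two-node Laplacian matches its closed form", {
  A <- eegstgcn:::adjacency_matrix(rbind(c(0, 1), c(1, 0)), "K2")
  op <- normalized_laplacian(A)
  expect_equal(op$laplacian, rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  ev <- eigen(op$laplacian, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, 2), tolerance = 1e-12)
})

test_that("edgeless graphs give the identity Laplacian", {
  A <- eegstgcn:::adjacency_matrix(matrix(0, 4, 4), "empty")
  expect_equal(normalized_laplacian(A)$laplacian, diag(4), ignore_attr = TRUE)
  expect_error(normalized_laplacian(rbind(c(0, 1), c(0.5, 0))), "asymmetric")
  expect_error(normalized_laplacian(rbind(c(0, -1), c(-1, 0))), "negative")
})

test_that("Laplacian spectra stay in [0, 2] and scaled spectra in [-1, 1]", {
  for (i in 1:200) {
    op <- scale_laplacian(normalized_laplacian(random_adjacency(6, i)))
    ev <- eigen(op$laplacian, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-8 & ev <= 2 + 1e-8))
    es <- eigen(op$scaled, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(es >= -1 - 1e-8 & es <= 1 + 1e-8))
  }
})

test_that("scaling substitutes lambda_max as stated", {
  A <- eegstgcn:::adjacency_matrix(rbind(c(0, 1), c(1, 0)), "K2")
  op <- normalized_laplacian(A)          # lambda_max = 2
  expect_equal(scale_laplacian(op)$scaled, op$laplacian - diag(2),
               ignore_attr = TRUE)
  op2 <- normalized_laplacian(eegstgcn:::adjacency_matrix(matrix(0, 3, 3), "e"))
  op2$lambda_max <- 1                    # L = I, lambda_max = 1 -> scaled = I
  expect_equal(scale_laplacian(op2)$scaled, diag(3), ignore_attr = TRUE)
})

test_that("the constant vector is in the Laplacian null space", {
  for (i in 1:20) {
    w <- unclass(random_adjacency(5, 100 + i))
    w[w == 0] <- 0.05; diag(w) <- 0       # ensure connectivity
    op <- normalized_laplacian(eegstgcn:::adjacency_matrix(w, "conn"))
    d <- diag(op$degree)
    expect_lt(max(abs(op$laplacian %*% sqrt(d))), 1e-8)
  }
})

test_that("Chebyshev recursion matches explicit matrix polynomials", {
  op <- scale_laplacian(normalized_laplacian(random_adjacency(5, 7)))
  B <- chebyshev_basis(op, 4)
  Lt <- op$scaled
  I <- diag(5)
  expect_identical(B[[1]], I)
  expect_identical(B[[2]], Lt)
  # T2 = 2x^2 - 1, T3 = 4x^3 - 3x
  expect_lt(max(abs(B[[3]] - (2 * Lt %*% Lt - I))), 1e-8)
  expect_lt(max(abs(B[[4]] - (4 * Lt %*% Lt %*% Lt - 3 * Lt))), 1e-8)
  expect_error(chebyshev_basis(op, 0), ">= 1")
})

test_that("graph convolution equals the spectral-domain form", {
  set.seed(41)
  for (rep in 1:10) {
    N <- 4; F_in <- 2; F_out <- 3; k <- 3
    op <- scale_laplacian(normalized_laplacian(random_adjacency(N, 200 + rep)))
    theta <- array(rnorm(F_in * F_out * k), c(F_in, F_out, k))
    x <- matrix(rnorm(N * F_in), N, F_in)
    y <- graph_convolution(x, cheb_filter(theta), op)
    # oracle: U g(Lambda) U^T x per input/output channel pair
    eg <- eigen(op$laplacian, symmetric = TRUE)
    lam_t <- 2 * eg$values / op$lambda_max - 1
    cheb_scalar <- function(l, p) {     # T_p on scalars by recursion
      if (p == 0) rep(1, length(l)) else if (p == 1) l
      else 2 * l * cheb_scalar(l, p - 1) - cheb_scalar(l, p - 2)
    }
    oracle <- matrix(0, N, F_out)
    for (j in seq_len(F_out)) for (i in seq_len(F_in)) {
      g_lam <- rep(0, N)
      for (p in seq_len(k)) g_lam <- g_lam + theta[i, j, p] * cheb_scalar(lam_t, p - 1)
      oracle[, j] <- oracle[, j] +
        eg$vectors %*% (g_lam * (t(eg$vectors) %*% x[, i]))
    }
    expect_lt(max(abs(y - oracle)), 1e-8)
  }
})

test_that("full-order truncation reproduces the spectral filter exactly", {
  # with k = N the Chebyshev expansion spans all polynomials of degree < N,
  # so recursion and spectral evaluation agree for any coefficients
  set.seed(42)
  for (N in 3:5) {
    op <- scale_laplacian(normalized_laplacian(random_adjacency(N, 300 + N)))
    theta <- array(rnorm(1 * 1 * N), c(1, 1, N))
    x <- matrix(rnorm(N), N, 1)
    y <- graph_convolution(x, cheb_filter(theta), op)
    eg <- eigen(op$laplacian, symmetric = TRUE)
    lam_t <- 2 * eg$values / op$lambda_max - 1
    tp <- rbind(rep(1, N), lam_t)
    if (N > 2) for (p in 3:N) tp <- rbind(tp, 2 * lam_t * tp[p - 1, ] - tp[p - 2, ])
    g_lam <- as.vector(theta[1, 1, ] %*% tp)
    oracle <- eg$vectors %*% (g_lam * (t(eg$vectors) %*% x))
    expect_lt(max(abs(y - oracle)), 1e-6)
  }
})

test_that("k = 1 with identity coefficients is the identity map", {
  op <- normalized_laplacian(random_adjacency(4, 9))
  theta <- array(0, c(2, 2, 1))
  theta[, , 1] <- diag(2)
  x <- matrix(rnorm(8), 4, 2)
  expect_equal(graph_convolution(x, cheb_filter(theta), op), x,
               tolerance = 1e-12, ignore_attr = TRUE)
  # shape contract
  th2 <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  expect_equal(dim(graph_convolution(x, cheb_filter(th2), op)), c(4, 5))
  expect_error(graph_convolution(matrix(0, 4, 3), cheb_filter(th2), op),
               "channels")
})

test_that("st_block output is nonnegative with preserved time length", {
  set.seed(43)
  N <- 5; C <- 4; Tn <- 6
  A <- random_adjacency(N, 11)
  params <- init_block_params(N, C, 3, Tn, k = 2)
  x <- array(rnorm(N * C * Tn), c(N, C, Tn))
  y <- st_block(x, A, params, k = 2)
  expect_equal(dim(y), c(N, 3, Tn))
  expect_true(all(y >= 0))
  # zero input with zero biases -> zero output
  params0 <- params
  params0$tbias[] <- 0
  y0 <- st_block(array(0, c(N, C, Tn)), A, params0, k = 2)
  expect_true(all(y0 == 0))
})

test_that("one st_block passes a finite-difference gradient check", {
  set.seed(44)
  N <- 4; C <- 3; Tn <- 3
  A <- random_adjacency(N, 12)
  basis <- chebyshev_basis(scale_laplacian(normalized_laplacian(A)), 2)
  params <- init_block_params(N, C, 2, Tn, k = 2)
  params$tbias <- params$tbias + 0.5     # keep pre-activations off ReLU kinks
  x <- array(rnorm(N * C * Tn), c(N, C, Tn))
  w <- array(rnorm(N * 2 * Tn), c(N, 2, Tn))
  tape <- eegstgcn:::ad_tape()
  pnodes <- eegstgcn:::leaves_from(tape, params)
  out <- eegstgcn:::st_block_node(tape, eegstgcn:::ad_leaf(tape, x), pnodes,
                                  basis, dims = c(N, C, Tn))
  s <- eegstgcn:::ad_mul(tape, out, eegstgcn:::ad_leaf(tape, w))
  eegstgcn:::ad_backward(tape, s, seed = 1)
  fp <- eegstgcn:::flatten_params(pnodes)
  fval <- function(p) {
    tape2 <- eegstgcn:::ad_tape()
    o <- eegstgcn:::st_block_node(tape2, eegstgcn:::ad_leaf(tape2, x),
                                  eegstgcn:::leaves_from(tape2, p), basis,
                                  dims = c(N, C, Tn))
    sum(o$value * w)
  }
  set.seed(45)
  for (nm in names(fp)) {
    g <- fp[[nm]]$grad
    if (is.null(g)) g <- array(0, dim(fp[[nm]]$value))
    for (i in sample(length(fp[[nm]]$value), min(3, length(fp[[nm]]$value)))) {
      fl <- eegstgcn:::flatten_params(params)
      fl[[nm]][i] <- fl[[nm]][i] + 1e-6
      up <- fval(eegstgcn:::unflatten_params(fl, params))
      fl[[nm]][i] <- fl[[nm]][i] - 2e-6
      dn <- fval(eegstgcn:::unflatten_params(fl, params))
      expect_lt(abs((up - dn) / 2e-6 - g[i]), 1e-4)
    }
  }
})
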