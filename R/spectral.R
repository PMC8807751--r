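# Spectral graph operators: symmetric normalized Laplacian, scaled
# Laplacian, Chebyshev polynomial basis, and the spectral graph
# convolution they define.  These are the forward-only building blocks;
# the trainable network wires the same math through the autodiff engine
# (see model.R).

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} A D^{-1/2}` for a symmetric nonnegative adjacency
#' with zero diagonal.  L is symmetric positive semidefinite with
#' eigenvalues in `[0, 2]`.  Isolated nodes (zero degree) get a
#' `D^{-1/2}` entry of 0, so their Laplacian row equals the identity row.
#'
#' @param A an `adjacency_matrix` (or plain symmetric nonnegative matrix
#'   with zero diagonal).
#' @return a `spectral_operator`: list with `laplacian`, `degree`,
#'   `lambda_max`, and `scaled` (`NULL` until [scale_laplacian()]).
#' @export
normalized_laplacian <- function(A) {
  w <- unclass(as.matrix(A))
  attributes(w) <- list(dim = dim(w))   # plain numeric operator from here on
  if (!is_square(w)) stop2("adjacency must be square")
  if (!check_symmetric(w)) stop2("asymmetric input")
  if (any(w < -1e-12)) stop2("negative input")
  if (any(abs(diag(w)) > 1e-12)) stop2("adjacency diagonal must be zero")
  d <- rowSums(w)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(w)) - (dis %o% dis) * w
  L <- (L + t(L)) / 2
  lam <- tryCatch(max(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
                  error = function(e) {
                    message("eigensolver failed; falling back to lambda_max = 2")
                    2
                  })
  structure(list(laplacian = L, degree = diag(d, nrow(w)),
                 lambda_max = max(lam, .eps), scaled = NULL),
            class = "spectral_operator")
}

#' @export
print.spectral_operator <- function(x, ...) {
  cat(sprintf("<spectral_operator> N = %d, lambda_max = %.4f, scaled: %s\n",
              nrow(x$laplacian), x$lambda_max, !is.null(x$scaled)))
  invisible(x)
}

#' Scale a Laplacian to the Chebyshev domain
#'
#' `L~ = 2 L / lambda_max - I`, whose spectrum lies in `[-1, 1]` — the
#' domain on which Chebyshev polynomials are an orthogonal basis.
#'
#' @param op a `spectral_operator` from [normalized_laplacian()].
#' @return the operator with its `scaled` field filled in.
#' @export
scale_laplacian <- function(op) {
  stopifnot(inherits(op, "spectral_operator"))
  op$scaled <- 2 * op$laplacian / op$lambda_max - diag(nrow(op$laplacian))
  op
}

#' Chebyshev polynomial basis of the scaled Laplacian
#'
#' The truncated basis `T_0 = I`, `T_1 = L~`,
#' `T_p = 2 L~ T_{p-1} - T_{p-2}` used by the spectral filter.
#'
#' @param op a `spectral_operator` (scaled on demand).
#' @param k number of terms (order), `k >= 1`.
#' @return list of `k` N x N matrices.
#' @export
chebyshev_basis <- function(op, k) {
  stopifnot(inherits(op, "spectral_operator"))
  if (k < 1) stop2("k must be >= 1")
  if (is.null(op$scaled)) op <- scale_laplacian(op)
  Lt <- op$scaled
  out <- vector("list", k)
  out[[1]] <- diag(nrow(Lt))
  if (k >= 2) out[[2]] <- Lt
  if (k >= 3) for (p in 3:k) out[[p]] <- 2 * Lt %*% out[[p - 1]] - out[[p - 2]]
  out
}

#' Chebyshev filter coefficients
#'
#' @param theta coefficient array of shape (F_in, F_out, k).
#' @return a `cheb_filter`.
#' @export
cheb_filter <- function(theta) {
  theta <- as.array(theta)
  if (length(dim(theta)) != 3L) stop2("theta must have shape (F_in, F_out, k)")
  if (!all(is.finite(theta))) stop2("non-finite filter coefficients")
  structure(list(theta = theta, k = dim(theta)[3],
                 f_in = dim(theta)[1], f_out = dim(theta)[2]),
            class = "cheb_filter")
}

#' Spectral graph convolution of one time slice
#'
#' `y_j = sum_i sum_p theta[i, j, p] * (T_p o S') %*% x_i`, where `T_p`
#' are the Chebyshev basis matrices of the scaled Laplacian, and `S'`
#' (optional row-stochastic spatial attention) reweights each basis term
#' elementwise.
#'
#' @param x node-feature matrix N x F_in (one time step).
#' @param f a [cheb_filter()].
#' @param op a `spectral_operator`.
#' @param S_prime optional N x N spatial attention matrix.
#' @return node-feature matrix N x F_out.
#' @export
graph_convolution <- function(x, f, op, S_prime = NULL) {
  stopifnot(inherits(f, "cheb_filter"), inherits(op, "spectral_operator"))
  x <- as.matrix(x)
  if (ncol(x) != f$f_in) stop2("x has ", ncol(x), " channels; filter expects ", f$f_in)
  basis <- chebyshev_basis(op, f$k)
  y <- matrix(0, nrow(x), f$f_out)
  for (p in seq_len(f$k)) {
    Tp <- if (is.null(S_prime)) basis[[p]] else basis[[p]] * S_prime
    y <- y + Tp %*% x %*% f$theta[, , p]
  }
  if (!all(is.finite(y))) stop2("non-finite convolution output")
  y
}

#' One spatial-temporal block (forward pass)
#'
#' A full block of the network applied to one trial's feature tensor:
#' temporal attention mixes the time axis, spatial attention reweights
#' the Chebyshev terms of the graph convolution, and a depthwise
#' temporal convolution with ReLU activations closes the block:
#' `out = ReLU(Phi * ReLU(g_theta *G x))`.
#'
#' @param x feature array N x C x T for one trial.
#' @param A an `adjacency_matrix`.
#' @param params block parameters from [init_block_params()].
#' @param k Chebyshev order (default 2).
#' @return feature array N x F_out x T, all entries >= 0.
#' @export
st_block <- function(x, A, params, k = 2) {
  op <- scale_laplacian(normalized_laplacian(A))
  basis <- chebyshev_basis(op, k)
  tape <- ad_tape()
  xn <- ad_leaf(tape, x)
  pn <- leaves_from(tape, params)
  out <- st_block_node(tape, xn, pn, basis)
  out$value
}
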