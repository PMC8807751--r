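# Spatial and temporal attention.  Each mechanism scores pairwise
# interactions from the block input x (an N x C x T feature tensor),
# squashes them through a logistic sigmoid, reweights with a learnable
# gate matrix, and row-normalizes with softmax:
#
#   S = V_p o sigmoid((x W1) W2 (W3 x)^T + b_p)    -> S' (N x N, rows sum 1)
#   E = V_e o sigmoid((x^T M1) M2 (M3 x) + b_q)    -> E' (T x T, rows sum 1)
#
# The public functions run the same autodiff graph the model trains
# through and return its value.

uniform_init <- function(dims, fan, gain = 1) {
  lim <- gain / sqrt(max(fan, 1))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Attention parameter initialisation
#'
#' Creates the learnable tensors for spatial attention
#' (`V_p`, `b_p` N x N; `W1` length T; `W2` C x T; `W3` length C) or
#' temporal attention (`V_e`, `b_q` T x T; `M1` length N; `M2` C x N;
#' `M3` length C).  Weights are uniform in `[-1/sqrt(fan), 1/sqrt(fan)]`,
#' biases start at zero.
#'
#' @param N,C,T block input dimensions (nodes, feature channels, time
#'   segments).
#' @return named list of parameter arrays.
#' @export
init_spatial_attention <- function(N, C, T) {
  list(Vp = uniform_init(c(N, N), N), bp = matrix(0, N, N),
       W1 = uniform_init(c(T, 1), T), W2 = uniform_init(c(C, T), C),
       W3 = uniform_init(c(C, 1), C))
}

#' @rdname init_spatial_attention
#' @export
init_temporal_attention <- function(N, C, T) {
  list(Ve = uniform_init(c(T, T), T), bq = matrix(0, T, T),
       M1 = uniform_init(c(N, 1), N), M2 = uniform_init(c(C, N), C),
       M3 = uniform_init(c(C, 1), C))
}

# ---- autodiff node versions (shared with the trainable model) --------

# contract x (N x C x T) with a vector along one axis via reshape+matmul
contract_axis <- function(tape, xn, vn, axis, dims) {
  N <- dims[1]; C <- dims[2]; Tn <- dims[3]
  if (axis == 1L) {            # sum_n v[n] x[n, , ]  -> C x T
    xm <- ad_reshape(tape, xn, c(N, C * Tn))
    r <- ad_matmul(tape, ad_transpose(tape, vn), xm)    # 1 x (C T)
    ad_reshape(tape, r, c(C, Tn))
  } else if (axis == 2L) {     # sum_c v[c] x[, c, ]  -> N x T
    xp <- ad_aperm(tape, xn, c(2, 1, 3))
    xm <- ad_reshape(tape, xp, c(C, N * Tn))
    r <- ad_matmul(tape, ad_transpose(tape, vn), xm)
    ad_reshape(tape, r, c(N, Tn))
  } else {                     # sum_t v[t] x[, , t]  -> N x C
    xm <- ad_reshape(tape, xn, c(N * C, Tn))
    r <- ad_matmul(tape, xm, vn)                        # (N C) x 1
    ad_reshape(tape, r, c(N, C))
  }
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), function(g) ad_accum(a, t(g)))
}

spatial_attention_node <- function(tape, xn, p, dims) {
  N <- dims[1]
  xW1 <- contract_axis(tape, xn, p$W1, 3L, dims)          # N x C
  left <- ad_matmul(tape, xW1, p$W2)                      # N x T
  W3x <- contract_axis(tape, xn, p$W3, 2L, dims)          # N x T
  raw <- ad_matmul(tape, left, ad_transpose(tape, W3x))   # N x N
  act <- ad_sigmoid(tape, ad_add(tape, raw, p$bp))
  S <- ad_mul(tape, p$Vp, act)
  ad_softmax_rows(tape, S)
}

temporal_attention_node <- function(tape, xn, p, dims) {
  xTM1 <- ad_transpose(tape, contract_axis(tape, xn, p$M1, 1L, dims)) # T x C
  left <- ad_matmul(tape, xTM1, p$M2)                     # T x N
  M3x <- contract_axis(tape, xn, p$M3, 2L, dims)          # N x T
  raw <- ad_matmul(tape, left, M3x)                       # T x T
  act <- ad_sigmoid(tape, ad_add(tape, raw, p$bq))
  E <- ad_mul(tape, p$Ve, act)
  ad_softmax_rows(tape, E)
}

# ---- public forward wrappers ------------------------------------------

#' Spatial attention matrix
#'
#' Computes the softmax-normalized N x N spatial attention matrix `S'`
#' for one trial's feature tensor.  Every row sums to 1; with all
#' parameters zero the matrix is uniform `1/N`.
#'
#' @param x feature array N x C x T.
#' @param params list from [init_spatial_attention()].
#' @return N x N matrix with rows summing to 1.
#' @export
spatial_attention <- function(x, params) {
  dims <- check_attention_shapes(x, params, spatial = TRUE)
  tape <- ad_tape()
  spatial_attention_node(tape, ad_leaf(tape, x),
                         leaves_from(tape, params), dims)$value
}

#' Temporal attention matrix
#'
#' Computes the softmax-normalized T x T temporal attention matrix `E'`,
#' which right-multiplies the time-unfolded block input.
#'
#' @param x feature array N x C x T.
#' @param params list from [init_temporal_attention()].
#' @return T x T matrix with rows summing to 1.
#' @export
temporal_attention <- function(x, params) {
  dims <- check_attention_shapes(x, params, spatial = FALSE)
  tape <- ad_tape()
  temporal_attention_node(tape, ad_leaf(tape, x),
                          leaves_from(tape, params), dims)$value
}

check_attention_shapes <- function(x, params, spatial) {
  d <- dim(x)
  if (length(d) != 3L) stop2("x must be an N x C x T array")
  ok <- if (spatial)
    all(dim(params$Vp) == c(d[1], d[1])) && nrow(params$W1) == d[3] &&
      all(dim(params$W2) == c(d[2], d[3])) && nrow(params$W3) == d[2]
  else
    all(dim(params$Ve) == c(d[3], d[3])) && nrow(params$M1) == d[1] &&
      all(dim(params$M2) == c(d[2], d[1])) && nrow(params$M3) == d[2]
  if (!ok) stop2("attention parameter shapes do not match input dims")
  d
}

leaves_from <- function(tape, params) {
  lapply(params, function(p) if (is.list(p)) leaves_from(tape, p)
         else ad_leaf(tape, p))
}
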