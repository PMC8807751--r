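# Reverse-mode automatic differentiation over dense arrays.
#
# A tape records every intermediate node created during a forward pass;
# ad_backward() walks the tape in reverse creation order and accumulates
# gradients into the leaves.  The op set is exactly what the attention /
# graph-convolution network needs: matrix product, elementwise arithmetic,
# sigmoid / ReLU, row softmax, axis permutation and reshape (both
# gradient-trivial), a depthwise temporal convolution, dropout, and a fused
# softmax cross-entropy head.  Everything is validated against central
# finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

# leaf: a parameter (gradient collected) or constant (gradient discarded)
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

# Seed the output node and sweep the tape backwards.  `seed` defaults to 1
# (scalar loss); a non-unit seed implements loss rescaling such as the
# flooding sign without touching the forward pass.
ad_backward <- function(tape, out, seed = 1) {
  out$grad <- if (length(out$value) == 1L) seed else array(seed, dim(out$value))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(out)
}

## ---- ops -------------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av %*% bv, function(g) {
    ad_accum(a, g %*% t(bv))
    ad_accum(b, crossprod(av, g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av * bv, function(g) {
    ad_accum(a, g * bv)
    ad_accum(b, g * av)
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, function(g) ad_accum(a, g * s))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, function(g) ad_accum(a, g * s * (1 - s)))
}

ad_relu <- function(tape, a) {
  v <- a$value
  mask <- v > 0
  ad_node(tape, v * mask, function(g) ad_accum(a, g * mask))
}

# row-wise softmax of a matrix
ad_softmax_rows <- function(tape, a) {
  v <- a$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  ad_node(tape, s, function(g) {
    ad_accum(a, s * (g - rowSums(g * s)))
  })
}

ad_aperm <- function(tape, a, perm) {
  ad_node(tape, aperm(a$value, perm), function(g) ad_accum(a, aperm(g, order(perm))))
}

ad_reshape <- function(tape, a, dims) {
  olddim <- dim(a$value) %||% length(a$value)
  ad_node(tape, array(a$value, dim = dims),
          function(g) ad_accum(a, array(g, dim = olddim)))
}

# depthwise convolution along the last (time) axis of an N x C x T array:
# y[n,c,t] = sum_d x[n,c,t+d-off] * ker[c,d] + bias[c], zero padded ("same").
ad_conv_time <- function(tape, x, ker, bias) {
  xv <- x$value; kv <- ker$value; bv <- bias$value
  dm <- dim(xv); N <- dm[1]; C <- dm[2]; Tn <- dm[3]
  K <- ncol(kv); off <- (K + 1L) %/% 2L
  y <- array(0, dm)
  for (d in seq_len(K)) {
    sh <- d - off                      # source index offset
    src <- seq_len(Tn) + sh
    ok <- src >= 1L & src <= Tn
    if (!any(ok)) next
    w <- array(rep(kv[, d], each = N), c(N, C))
    y[, , which(ok)] <- y[, , which(ok), drop = FALSE] +
      xv[, , src[ok], drop = FALSE] * as.vector(w)
  }
  y <- y + array(rep(bv, each = N), dm)
  ad_node(tape, y, function(g) {
    gx <- array(0, dm)
    gk <- matrix(0, C, K)
    for (d in seq_len(K)) {
      sh <- d - off
      src <- seq_len(Tn) + sh
      ok <- src >= 1L & src <= Tn
      if (!any(ok)) next
      w <- array(rep(kv[, d], each = N), c(N, C))
      gpart <- g[, , which(ok), drop = FALSE]
      gx[, , src[ok]] <- gx[, , src[ok], drop = FALSE] + gpart * as.vector(w)
      gk[, d] <- apply(gpart * xv[, , src[ok], drop = FALSE], 2L, sum)
    }
    ad_accum(x, gx)
    ad_accum(ker, gk)
    ad_accum(bias, apply(g, 2L, sum))
  })
}

# mean over node and time axes of an N x C x T array -> length-C vector
ad_mean_nt <- function(tape, x) {
  xv <- x$value
  dm <- dim(xv); N <- dm[1]; C <- dm[2]; Tn <- dm[3]
  v <- apply(xv, 2L, mean)
  ad_node(tape, v, function(g) {
    ad_accum(x, aperm(array(g, c(C, N, Tn)), c(2, 1, 3)) / (N * Tn))
  })
}

# inverted dropout with a fixed mask (drawn by the caller so that the
# training loop owns all randomness)
ad_dropout <- function(tape, x, mask) {
  ad_node(tape, x$value * mask, function(g) ad_accum(x, g * mask))
}

# fused softmax + cross-entropy for one logit vector; label is 1-based
ad_cross_entropy <- function(tape, logits, label) {
  z <- as.vector(logits$value)
  m <- max(z)
  lse <- m + log(sum(exp(z - m)))
  p <- exp(z - lse)
  ad_node(tape, lse - z[label], function(g) {
    gz <- p
    gz[label] <- gz[label] - 1
    ad_accum(logits, array(g * gz, dim(logits$value) %||% length(z)))
  })
}

# extract slab q along the third axis of a 3-D array node, kept 2-D
ad_slice3 <- function(tape, a, q) {
  dm <- dim(a$value)
  v <- a$value[, , q, drop = FALSE]
  dim(v) <- dm[1:2]
  ad_node(tape, v, function(g) {
    gfull <- array(0, dm)
    gfull[, , q] <- g
    ad_accum(a, gfull)
  })
}

# mean of a list of scalar nodes
ad_mean_scalars <- function(tape, nodes) {
  n <- length(nodes)
  v <- mean(vapply(nodes, function(nd) nd$value, numeric(1)))
  ad_node(tape, v, function(g) {
    for (nd in nodes) ad_accum(nd, g / n)
  })
}
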