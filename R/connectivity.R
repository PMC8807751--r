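# Adjacency-matrix construction toolbox: geometric distances, cosine and
# Jaccard similarity, histogram mutual information, structural schemes
# (kNN / distance threshold / random), hybrids, and the cosine-similarity
# dynamic update applied to learned node embeddings during training.

adjacency_matrix <- function(w, method, symmetric = TRUE, channel_names = NULL,
                             meta = NULL) {
  w <- as.matrix(w)
  if (!is_square(w)) stop2("adjacency must be square")
  if (!all(is.finite(w))) stop2("adjacency contains non-finite entries")
  if (symmetric && !check_symmetric(w)) stop2("adjacency not symmetric")
  if (!is.null(channel_names)) dimnames(w) <- list(channel_names, channel_names)
  structure(w, class = c("adjacency_matrix", "matrix", "array"),
            method = method, symmetric = symmetric, meta = meta)
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("<adjacency_matrix:%s> %d x %d, %d nonzero off-diagonal entries\n",
              attr(x, "method"), nrow(x), ncol(x),
              sum(unclass(x)[upper.tri(x)] != 0) * 2L))
  invisible(x)
}

#' Geometric electrode distance matrices
#'
#' Pairwise Euclidean (straight-line) or Chebyshev (maximum coordinate
#' difference) distances between montage electrode positions.
#'
#' @param m a [montage()] with at least 2 electrodes.
#' @param metric `"euclidean"` or `"chebyshev"`.
#' @return an `adjacency_matrix` of distances (zero diagonal, symmetric).
#' @export
geometry_distance_matrix <- function(m, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  xyz <- as.matrix(m[, c("x", "y", "z")])
  if (nrow(xyz) < 2) stop2("montage needs at least 2 electrodes")
  if (!all(is.finite(xyz))) stop2("non-finite coordinates")
  d <- as.matrix(stats::dist(xyz, method = if (metric == "euclidean")
    "euclidean" else "maximum"))
  adjacency_matrix(d, paste0("dist_", metric), channel_names = m$name)
}

#' Cosine similarity matrix
#'
#' Pairwise cosine similarity of per-node vectors:
#' `cos(x, y) = <x, y> / (||x|| * ||y||)`.  Direction only; magnitudes are
#' ignored.  Zero-norm vectors are epsilon-guarded (their similarities
#' collapse towards 0) with a message.
#'
#' @param X numeric matrix with one column per node.
#' @param eps norm guard.
#' @return an `adjacency_matrix` with entries in `[-1, 1]`, unit diagonal.
#' @export
cosine_matrix <- function(X, eps = .eps) {
  X <- as.matrix(X)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm < eps)) {
    message(sum(nrm < eps), " zero-norm node vector(s); epsilon guard applied")
    nrm <- pmax(nrm, eps)
  }
  C <- crossprod(sweep(X, 2L, nrm, "/"))
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  C <- (C + t(C)) / 2
  adjacency_matrix(C, "cosine", channel_names = colnames(X))
}

#' Jaccard similarity matrix
#'
#' Pairwise Jaccard index of per-node binary vectors:
#' `|x1 AND x2| / (|x1| + |x2| - |x1 AND x2|)`.  Pairs of all-zero
#' vectors are defined as 0 similarity (with a message).
#'
#' @param B binary matrix (0/1), one column per node.
#' @return an `adjacency_matrix` with entries in `[0, 1]`.
#' @export
jaccard_matrix <- function(B) {
  B <- as.matrix(B)
  if (!all(B %in% c(0, 1))) stop2("jaccard_matrix expects binary input")
  inter <- crossprod(B)
  sz <- colSums(B)
  uni <- outer(sz, sz, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  if (any(uni == 0)) message("both-empty pair(s) assigned similarity 0")
  adjacency_matrix(J, "jaccard", channel_names = colnames(B))
}

#' Equal-width discretization
#'
#' Maps a real sequence to integer symbols `1..n_bins` over equal-width
#' bins spanning `[min, max]`.  Bins are right-open except the last;
#' a value on an interior bin edge goes to the right bin.  Constant input
#' maps to the single symbol 1.
#'
#' @param x numeric vector.
#' @param n_bins number of bins (>= 2).
#' @return integer vector of symbols in `1..n_bins`.
#' @export
discretize <- function(x, n_bins = 16) {
  if (!length(x)) stop2("empty input")
  if (n_bins < 2) stop2("n_bins must be >= 2")
  lo <- min(x); hi <- max(x)
  if (hi - lo < .eps) return(rep(1L, length(x)))
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  pmin.int(findInterval(x, breaks), as.integer(n_bins))
}

#' Entropy of a symbol sequence
#'
#' Plug-in (empirical-frequency) Shannon entropy
#' `H = -sum(p * log(p))` with `0 log 0 = 0`.
#'
#' @param s integer/character symbol sequence.
#' @param base `"e"` (nats) or `"2"` (bits).
#' @return nonnegative entropy.
#' @export
discrete_entropy <- function(s, base = c("e", "2")) {
  base <- match.arg(as.character(base), c("e", "2"))
  if (!length(s)) stop2("empty input")
  p <- tabulate(as_symbols(s))
  p <- p / sum(p)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  if (base == "2") h / log(2) else h
}

#' Mutual information of two symbol sequences
#'
#' Plug-in mutual information over the empirical joint table:
#' `I = sum p(x, y) log[p(x, y) / (p(x) p(y))]`, clamped at 0 from below
#' against numerical noise.  Satisfies `I(X, X) = H(X)` and
#' `I = H(X) + H(Y) - H(X, Y)`.
#'
#' @param x,y equal-length symbol sequences.
#' @param base `"e"` or `"2"`.
#' @return nonnegative mutual information.
#' @export
mutual_information <- function(x, y, base = c("e", "2")) {
  base <- match.arg(as.character(base), c("e", "2"))
  if (length(x) != length(y)) stop2("length mismatch")
  if (!length(x)) stop2("empty input")
  fx <- as_symbols(x); fy <- as_symbols(y)
  kx <- max(fx); ky <- max(fy)
  joint <- tabulate((fy - 1L) * kx + fx, nbins = kx * ky) / length(x)
  jm <- matrix(joint, kx, ky)
  px <- rowSums(jm); py <- colSums(jm)
  nz <- jm > 0
  i <- sum(jm[nz] * log(jm[nz] / outer(px, py)[nz]))
  i <- max(i, 0)
  if (base == "2") i / log(2) else i
}

# map a symbol sequence to small positive integers; integer sequences
# already in 1..k (the discretize() output) pass through untouched,
# avoiding an expensive factor() on long pooled signals
as_symbols <- function(s) {
  if (is.integer(s) && length(s)) {
    mn <- min(s)
    if (mn >= 1L && max(s) <= 65536L) return(s)
  }
  as.integer(factor(s))
}

#' Mutual-information channel adjacency
#'
#' The initial channel graph of the classifier: each channel's samples
#' are pooled across trials, discretized into equal-width bins, and the
#' plug-in mutual information of every channel pair becomes the edge
#' weight.  The diagonal is set to 0 for graph use; per-channel entropies
#' `H(X_i)` are kept in the `meta` attribute.
#'
#' @param ts a [trial_set()] (or an N x S channel-by-sample matrix).
#' @param n_bins histogram bins per channel (default 16).
#' @param base `"e"` or `"2"`.
#' @return a symmetric nonnegative `adjacency_matrix` with zero diagonal.
#' @export
mi_adjacency <- function(ts, n_bins = 16, base = c("e", "2")) {
  base <- match.arg(as.character(base), c("e", "2"))
  if (inherits(ts, "trial_set")) {
    d <- dim(ts$trials)
    sig <- matrix(aperm(ts$trials, c(2, 1, 3)), d[2], d[1] * d[3])
    nms <- ts$channel_names
  } else {
    sig <- as.matrix(ts)
    nms <- rownames(sig)
  }
  N <- nrow(sig)
  if (N < 2) stop2("fewer than 2 channels")
  sym <- lapply(seq_len(N), function(i) discretize(sig[i, ], n_bins))
  A <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    A[i, j] <- A[j, i] <- mutual_information(sym[[i]], sym[[j]], base)
  }
  ent <- vapply(sym, discrete_entropy, numeric(1), base = base)
  adjacency_matrix(A, "mutual_information", channel_names = nms,
                   meta = list(n_bins = n_bins, base = base, entropy = ent))
}

#' Structural adjacency schemes
#'
#' Binary channel graphs built from electrode geometry or at random:
#' `knn` connects each electrode to its `k` nearest neighbours, `ed`
#' connects electrodes closer than `radius`, and `random` draws each edge
#' independently with probability `p`.  All schemes are symmetrized (an
#' edge kept if either direction selects it) with zero diagonal.
#'
#' @param m a [montage()].
#' @param scheme `"knn"`, `"ed"` or `"random"`.
#' @param k neighbours per node (knn), `1 <= k < N`.
#' @param radius connection radius (ed), positive.
#' @param p edge probability (random), in (0, 1].
#' @param seed RNG seed for the random scheme.
#' @return a binary `adjacency_matrix`.
#' @export
structural_adjacency <- function(m, scheme = c("knn", "ed", "random"),
                                 k = 3, radius = NULL, p = 0.2, seed = 1) {
  scheme <- match.arg(scheme)
  N <- nrow(m)
  A <- matrix(0, N, N)
  if (scheme == "knn") {
    if (k < 1 || k >= N) stop2("need 1 <= k < N")
    D <- unclass(geometry_distance_matrix(m))
    for (i in seq_len(N)) {
      nb <- order(D[i, -i])[seq_len(k)]
      nb <- setdiff(seq_len(N), i)[nb]
      A[i, nb] <- 1
    }
  } else if (scheme == "ed") {
    if (is.null(radius) || radius <= 0) stop2("need radius > 0")
    D <- unclass(geometry_distance_matrix(m))
    A[D <= radius] <- 1
  } else {
    if (p <= 0 || p > 1) stop2("edge probability must be in (0, 1]")
    with_seed(seed, {
      up <- which(upper.tri(A))
      A[up] <- as.numeric(stats::runif(length(up)) < p)
    })
  }
  A <- pmax(A, t(A))          # symmetrize: keep if either direction selects
  diag(A) <- 0
  adjacency_matrix(A, paste0("structural_", scheme), channel_names = m$name,
                   meta = list(k = k, radius = radius, p = p, seed = seed))
}

#' Hybrid (masked mutual-information) adjacency
#'
#' Restricts a mutual-information weight matrix to the edges of a binary
#' structural graph: kept entries carry their MI weight, masked entries
#' are 0.  This realises the Mut_KNN / Mut_ED / Mut_Euclidean variants.
#'
#' @param mi a weighted `adjacency_matrix` (e.g. [mi_adjacency()]).
#' @param structure a binary `adjacency_matrix` of the same size.
#' @return an `adjacency_matrix`.
#' @export
hybrid_adjacency <- function(mi, structure) {
  if (!all(dim(mi) == dim(structure))) stop2("shape mismatch")
  if (!all(unclass(structure) %in% c(0, 1))) stop2("structure must be binary")
  adjacency_matrix(unclass(mi) * unclass(structure),
                   paste0(attr(mi, "method"), "*", attr(structure, "method")),
                   channel_names = rownames(mi))
}

#' Dynamic adjacency update from node embeddings
#'
#' The cosine-similarity update that distinguishes the dynamic-graph
#' model from its frozen-matrix predecessor: the new edge weight between
#' nodes i and j is the cosine similarity of their embedding columns,
#' `a[i, j] = <e_i, e_j> / (||e_i|| ||e_j||)`.  Negative similarities are
#' rectified to 0 so the normalized Laplacian stays positive
#' semidefinite; the diagonal is 1 (re-zeroed by the Laplacian stage's
#' zero-diagonal convention when the graph is consumed).
#'
#' @param emb embedding matrix with one column per graph node.
#' @return an `adjacency_matrix` with entries in `[0, 1]`.
#' @export
update_adjacency <- function(emb) {
  C <- unclass(cosine_matrix(emb))
  C[C < 0] <- 0
  adjacency_matrix(C, "cosine_update", channel_names = colnames(emb))
}

#' Read and write adjacency matrices as TSV
#'
#' Square tab-separated matrices with a channel-name header row and
#' column.
#'
#' @param A an `adjacency_matrix`.
#' @param path file path.
#' @param method method tag recorded on read.
#' @return `write_adjacency` returns `path` invisibly; `read_adjacency`
#'   an `adjacency_matrix`.
#' @export
write_adjacency <- function(A, path) {
  m <- as.data.frame(unclass(A))
  names(m) <- rownames(A) %||% paste0("ch", seq_len(ncol(A)))
  utils::write.table(cbind(channel = names(m), m), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path, method = "file") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  w <- as.matrix(tab[, -1, drop = FALSE])
  adjacency_matrix(w, method, channel_names = tab[[1]])
}
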