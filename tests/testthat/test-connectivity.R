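test_that("geometric distances follow the euclidean and chebyshev formulas", {
  m <- montage(c("p", "q"), rbind(c(0, 0, 0), c(1, 2, 2)))
  expect_equal(unclass(geometry_distance_matrix(m, "euclidean"))[1, 2], 3)
  expect_equal(unclass(geometry_distance_matrix(m, "chebyshev"))[1, 2], 2)
  m2 <- montage(c("p", "q"), rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(unclass(geometry_distance_matrix(m2))[1, 2], 0)
  d <- geometry_distance_matrix(montage_bci22())
  expect_true(all(diag(d) == 0))
  expect_equal(unclass(d), t(unclass(d)))
})

test_that("cosine matrix captures direction only", {
  X <- cbind(c(1, 2), c(2, 4), c(1, 0), c(0, 1))
  C <- unclass(cosine_matrix(X))
  expect_equal(C[1, 2], 1)
  expect_equal(C[3, 4], 0)
  expect_true(all(diag(C) == 1))
  set.seed(14)
  Y <- matrix(rnorm(12), 3, 4)
  expect_equal(unclass(cosine_matrix(Y)),
               unclass(cosine_matrix(Y %*% diag(c(2, 5, 1, 0.3)))),
               tolerance = 1e-12)
  expect_true(all(abs(unclass(cosine_matrix(Y))) <= 1))
})

test_that("jaccard matrix matches the set-overlap formula", {
  B <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1),
             d = c(1, 0, 1, 0))
  J <- unclass(jaccard_matrix(B))
  expect_equal(J[1, 2], 1)          # identical nonempty sets
  expect_equal(J[1, 3], 0)          # disjoint
  expect_equal(J[1, 4], 1 / 3)      # |intersect| 1, sizes 2 and 2
  expect_message(j0 <- jaccard_matrix(cbind(c(0, 0), c(0, 0))), "both-empty")
  expect_equal(unclass(j0)[1, 2], 0)
})

test_that("discretize covers bins, handles constants and edge values", {
  set.seed(15)
  u <- runif(1e5)
  s <- discretize(u, 16)
  expect_equal(sort(unique(s)), 1:16)
  expect_identical(discretize(rep(3.3, 10), 8), rep(1L, 10))
  # interior edge goes to the right bin: breaks of 0..4 with 4 bins at 1,2,3
  s2 <- discretize(c(0, 1, 2, 3, 4), 4)
  expect_identical(s2, c(1L, 2L, 3L, 4L, 4L))
  expect_error(discretize(numeric(0), 4), "empty")
})

test_that("entropy matches closed forms and the log-cardinality bound", {
  expect_equal(discrete_entropy(rep(1:4, 25), base = "2"), 2)
  expect_equal(discrete_entropy(rep(7L, 10)), 0)
  set.seed(16)
  for (i in 1:20) {
    s <- sample.int(sample(2:8, 1), 200, replace = TRUE)
    expect_lte(discrete_entropy(s), log(length(unique(s))) + 1e-12)
  }
})

test_that("mutual information matches an independent brute-force double sum", {
  set.seed(17)
  for (rep in 1:25) {
    n <- 400
    x <- sample.int(5, n, replace = TRUE)
    y <- (x + sample.int(3, n, replace = TRUE)) %% 5L + 1L
    expect_equal(mutual_information(x, y), brute_force_mi(x, y),
                 tolerance = 1e-10)
    # symmetry is exact
    expect_identical(mutual_information(x, y), mutual_information(y, x))
    # information identities
    hx <- discrete_entropy(x); hy <- discrete_entropy(y)
    hxy <- discrete_entropy(paste(x, y))
    expect_equal(mutual_information(x, y), hx + hy - hxy, tolerance = 1e-10)
    expect_equal(mutual_information(x, x), hx, tolerance = 1e-10)
  }
  expect_error(mutual_information(1:3, 1:4), "length mismatch")
})

test_that("independent sequences have near-zero mutual information", {
  set.seed(18)
  x <- sample.int(4, 1e5, replace = TRUE)
  y <- sample.int(4, 1e5, replace = TRUE)
  expect_lt(mutual_information(x, y, base = "2"), 0.01)
})

test_that("mi_adjacency detects duplicated channels and independence", {
  set.seed(19)
  n <- 5000
  sig <- rbind(rnorm(n), rnorm(n), rnorm(n))
  sig <- rbind(sig, sig[1, ])                 # channel 4 copies channel 1
  A <- mi_adjacency(sig, n_bins = 8)
  w <- unclass(A)
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0))
  off <- w[upper.tri(w)]
  expect_equal(max(off), w[1, 4])             # the copy dominates strictly
  expect_gt(w[1, 4], max(off[off < max(off)]) * 5)
  # independent channels: all off-diagonals small (bits)
  B <- mi_adjacency(matrix(rnorm(3 * 1e5), 3), n_bins = 4, base = "2")
  expect_lt(max(unclass(B)), 0.02)
  expect_error(mi_adjacency(matrix(0, 1, 10)), "fewer than 2")
})

test_that("shuffling one channel lowers its mutual information", {
  set.seed(20)
  n <- 4000
  z <- rnorm(n)
  x <- discretize(z + rnorm(n, sd = 0.5), 8)
  y <- discretize(z + rnorm(n, sd = 0.5), 8)
  coupled <- mutual_information(x, y)
  shuffled <- mutual_information(x, sample(y))
  expect_gt(coupled, shuffled * 3)
})

test_that("structural schemes give the expected graphs", {
  # 3 collinear electrodes at x = 0, 1, 3 with k = 1
  m <- montage(c("a", "b", "c"), rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  A <- unclass(structural_adjacency(m, "knn", k = 1))
  expect_equal(A, rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 1) * c(0, 1, 0)),
               ignore_attr = TRUE)
  # radius below the minimum spacing -> edgeless
  expect_true(all(unclass(structural_adjacency(m, "ed", radius = 0.5)) == 0))
  # radius covering a-b only
  expect_equal(sum(unclass(structural_adjacency(m, "ed", radius = 1.5))), 2)
  # random graphs: seeded reproducibility
  mm <- montage_bci22()
  r1 <- structural_adjacency(mm, "random", p = 0.3, seed = 4)
  r2 <- structural_adjacency(mm, "random", p = 0.3, seed = 4)
  r3 <- structural_adjacency(mm, "random", p = 0.3, seed = 5)
  expect_identical(unclass(r1), unclass(r2))
  expect_false(identical(unclass(r1), unclass(r3)))
  expect_error(structural_adjacency(mm, "knn", k = 22), "k < N")
})

test_that("hybrid adjacency masks MI weights by structure", {
  set.seed(23)
  sig <- matrix(rnorm(4 * 2000), 4)
  mi <- mi_adjacency(sig, n_bins = 6)
  ones <- adjacency_ones <- matrix(1, 4, 4); diag(ones) <- 0
  keep <- eegstgcn:::adjacency_matrix(ones, "all")
  expect_equal(unclass(hybrid_adjacency(mi, keep)), unclass(mi),
               ignore_attr = TRUE)
  none <- eegstgcn:::adjacency_matrix(matrix(0, 4, 4), "none")
  expect_true(all(unclass(hybrid_adjacency(mi, none)) == 0))
  one <- matrix(0, 4, 4); one[1, 3] <- one[3, 1] <- 1
  h <- unclass(hybrid_adjacency(mi, eegstgcn:::adjacency_matrix(one, "one")))
  expect_equal(sum(h != 0), 2)
  expect_equal(h[1, 3], unclass(mi)[1, 3])
  expect_error(hybrid_adjacency(mi, eegstgcn:::adjacency_matrix(matrix(0, 3, 3), "x")),
               "shape mismatch")
})

test_that("embedding update rectifies cosine similarities", {
  e <- cbind(c(1, 1), c(2, 2), c(3, 3))
  A <- unclass(update_adjacency(e))
  expect_true(all(abs(A - 1) < 1e-12))
  # orthonormal basis -> identity pattern
  A2 <- unclass(update_adjacency(diag(3)))
  expect_equal(A2, diag(3), ignore_attr = TRUE)
  # rectification: anti-parallel columns map to 0
  A3 <- unclass(update_adjacency(cbind(c(1, 0), c(-1, 0))))
  expect_equal(A3[1, 2], 0)
  set.seed(24)
  A4 <- unclass(update_adjacency(matrix(rnorm(5 * 6), 5)))
  expect_true(all(A4 >= 0 & A4 <= 1))
})

test_that("every construction scheme feeds the Laplacian stage", {
  set.seed(25)
  m <- montage_bci22()
  ts <- tiny_trials(L = 4, N = 22, seed = 25)
  builders <- list(
    mi = mi_adjacency(ts, n_bins = 6),
    knn = structural_adjacency(m, "knn", k = 3),
    ed = structural_adjacency(m, "ed", radius = 0.8),
    rnd = structural_adjacency(m, "random", p = 0.3, seed = 1),
    upd = update_adjacency(matrix(rnorm(10 * 22), 10)))
  for (nm in names(builders)) {
    w <- unclass(builders[[nm]])
    diag(w) <- 0                               # graph-use convention
    op <- normalized_laplacian(eegstgcn:::adjacency_matrix(w, nm))
    ev <- eigen(op$laplacian, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8 & ev < 2 + 1e-8), label = nm)
  }
})

test_that("adjacency TSV round-trips weights and channel names", {
  set.seed(26)
  A <- update_adjacency(matrix(rnorm(4 * 5), 5, 4,
                               dimnames = list(NULL, c("w", "x", "y", "z"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency(A, path)
  back <- read_adjacency(path)
  expect_equal(unclass(back), unclass(A), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(back), c("w", "x", "y", "z"))
})
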