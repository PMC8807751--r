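# small helpers: a fast, fully in-memory classification fixture
toy_problem <- function(L = 24, N = 6, C = 6, Tn = 4, seed = 50) {
  set.seed(seed)
  y <- rep(0:3, length.out = L)
  x <- array(rnorm(L * N * C * Tn, sd = 0.1), c(L, N, C, Tn))
  for (i in seq_len(L)) x[i, , y[i] + 1, ] <- x[i, , y[i] + 1, ] + 2
  A <- matrix(0.4, N, N); diag(A) <- 0
  list(x = x, y = y, A = eegstgcn:::adjacency_matrix(A, "toy"),
       dims = c(N, C, Tn))
}

quick_cfg <- function(...) {
  args <- list(learning_rate = 5e-3, dropout = 0, epochs = 3, n_blocks = 1,
               batch_size = 8, seed = 6)
  do.call(train_config, utils::modifyList(args, list(...)))
}

test_that("flooding loss follows |raw - b| + b", {
  grid <- seq(0, 2, by = 0.1)
  expect_equal(flooding_loss(grid, 0.5), abs(grid - 0.5) + 0.5)
  expect_equal(flooding_loss(0.2, 0.5), 0.8)
  expect_equal(flooding_loss(0.7, 0.5), 0.7)
  expect_equal(flooding_loss(0.5, 0.5), 0.5)   # global minimum at raw = b
  expect_true(all(flooding_loss(grid, 0.5) >= 0.5))
  expect_error(flooding_loss(1, -0.1), ">= 0")
})

test_that("model assembly is deterministic with monotone parameter counts", {
  tp <- toy_problem()
  cfg <- quick_cfg()
  m1 <- build_model(cfg, tp$A, tp$dims)
  m2 <- build_model(cfg, tp$A, tp$dims)
  expect_identical(m1$params, m2$params)
  n1 <- eegstgcn:::n_params(build_model(quick_cfg(n_blocks = 1), tp$A, tp$dims)$params)
  n4 <- eegstgcn:::n_params(build_model(quick_cfg(n_blocks = 4), tp$A, tp$dims)$params)
  expect_gt(n4, n1)
  # forward: softmax rows
  prob <- predict(m1, tp$x[1:7, , , , drop = FALSE])
  expect_equal(dim(prob), c(7, 4))
  expect_lt(max(abs(rowSums(prob) - 1)), 1e-6)
})

test_that("training is seed-reproducible and respects the flooding floor", {
  tp <- toy_problem()
  cfg <- quick_cfg(epochs = 4)
  h1 <- train_model(build_model(cfg, tp$A, tp$dims), tp$x, tp$y)$history
  h2 <- train_model(build_model(cfg, tp$A, tp$dims), tp$x, tp$y)$history
  expect_identical(h1, h2)                      # bitwise history match
  expect_true(all(h1$flooded >= cfg$flood_level - 1e-8))
  # the optimized objective equals ce + recorded penalty
  expect_equal(h1$raw, h1$ce + h1$l1_penalty, tolerance = 1e-12)
  # with both penalty weights zero the objective reduces to plain ce
  cfg0 <- quick_cfg(epochs = 4, l1_weight = 0, l2_weight = 0)
  h0 <- train_model(build_model(cfg0, tp$A, tp$dims), tp$x, tp$y)$history
  expect_equal(h0$raw, h0$ce, tolerance = 1e-12)
  expect_true(all(h0$l1_penalty == 0))
})

test_that("loss trends down over the first epochs on a separable fixture", {
  tp <- toy_problem(L = 32)
  cfg <- quick_cfg(epochs = 5, learning_rate = 0.01)
  h <- train_model(build_model(cfg, tp$A, tp$dims), tp$x, tp$y)$history
  expect_lt(mean(tail(h$ce, 2)), mean(head(h$ce, 2)))
})

test_that("dynamic updates change the graph; frozen mode keeps it bitwise", {
  tp <- toy_problem()
  cfg <- quick_cfg(epochs = 2, update_adjacency = TRUE)
  mod <- train_model(build_model(cfg, tp$A, tp$dims), tp$x, tp$y)
  snaps <- mod$adjacency_snapshots
  expect_gt(max(abs(snaps[[2]] - snaps[[3]])), 0)
  for (s in snaps[-1]) {
    expect_equal(s, t(s))
    expect_true(all(s >= 0 & s <= 1))
  }
  cfg0 <- quick_cfg(epochs = 2, update_adjacency = FALSE)
  mod0 <- train_model(build_model(cfg0, tp$A, tp$dims), tp$x, tp$y)
  expect_identical(mod0$adjacency_snapshots[[1]],
                   mod0$adjacency_snapshots[[3]])
  expect_error(train_model(build_model(cfg, tp$A, tp$dims),
                           tp$x[0, , , , drop = FALSE], integer(0)),
               "empty")
})

test_that("metrics match hand-computed values on a fixed confusion fixture", {
  # hand-built 4-class outcome:
  # truth 0 (10 trials): 7 -> 0, 2 -> 1, 1 -> 2
  # truth 1 (8):         5 -> 1, 3 -> 0
  # truth 2 (6):         6 -> 2
  # truth 3 (6):         4 -> 3, 2 -> 1
  truth <- rep(0:3, c(10, 8, 6, 6))
  pred <- c(rep(0, 7), rep(1, 2), 2,
            rep(1, 5), rep(0, 3),
            rep(2, 6),
            rep(3, 4), rep(1, 2))
  r <- metrics_report(pred, truth)
  expect_equal(sum(r$confusion), 30)
  expect_equal(r$accuracy, (7 + 5 + 6 + 4) / 30)
  p0 <- 7 / 10; p1 <- 5 / 9; p2 <- 6 / 7; p3 <- 4 / 4
  expect_equal(r$macro_precision, mean(c(p0, p1, p2, p3)), tolerance = 1e-12)
  r0 <- 7 / 10; r1 <- 5 / 8; r2 <- 6 / 6; r3 <- 4 / 6
  f1s <- 2 * c(p0, p1, p2, p3) * c(r0, r1, r2, r3) /
    (c(p0, p1, p2, p3) + c(r0, r1, r2, r3))
  expect_equal(r$macro_f1, mean(f1s), tolerance = 1e-12)
  # perfect prediction
  rp <- metrics_report(truth, truth)
  expect_equal(rp$accuracy, 1)
  expect_equal(rp$macro_f1, 1)
  expect_equal(rp$macro_precision, 1)
  # absent classes are excluded from macro averages
  expect_message(r2c <- metrics_report(c(0, 1, 0), c(0, 1, 1)), "excluded")
  expect_equal(nrow(r2c$per_class), 4)
})

test_that("uniform random predictions score near chance", {
  set.seed(51)
  truth <- rep(0:3, 500)
  pred <- sample(0:3, 2000, replace = TRUE)
  acc <- metrics_report(pred, truth)$accuracy
  half_width <- 2.576 * sqrt(0.25 * 0.75 / 2000)
  expect_gt(acc, 0.25 - half_width)
  expect_lt(acc, 0.25 + half_width)
})

test_that("stratified folds partition trials with balanced classes", {
  labels <- rep(0:3, each = 25)
  fold <- stratified_folds(labels, 4, seed = 3)
  expect_equal(sort(unique(fold)), 1:4)
  expect_equal(as.vector(table(fold)), rep(25, 4))
  for (f in 1:4) {
    tb <- table(factor(labels[fold == f], levels = 0:3))
    expect_true(all(abs(tb - 25 / 4) <= 1))
  }
  # assignment is stable under trial reordering (by trial identity)
  perm <- sample(length(labels))
  fold_perm <- stratified_folds(labels[perm], 4, seed = 3)
  # same label multiset per fold
  for (f in 1:4)
    expect_equal(table(factor(labels[perm][fold_perm == f], levels = 0:3)),
                 table(factor(labels[fold == f], levels = 0:3)))
})

test_that("cross-validation tests every trial exactly once", {
  sp <- synthetic_spec(n_channels = 6, trials_per_class = 5,
                       trial_length = 1.5, blocks = list(1:2, 3:4, 5:6),
                       gain = matrix(1, 4, 3), seed = 31)
  ts <- simulate_trials(sp)
  cfg <- train_config(learning_rate = 5e-3, dropout = 0, epochs = 1,
                      n_blocks = 1, batch_size = 8, seed = 6)
  cv <- cross_validate(ts, cfg, n_folds = 4, bands = band_spec(4, 40, 3),
                       fold_seed = 9)
  expect_length(cv$folds, 4)
  expect_equal(sort(unique(cv$assignment)), 1:4)
  expect_equal(length(cv$assignment), 20)
  expect_equal(as.vector(table(cv$assignment)), rep(5, 4))
  expect_true(all(is.finite(cv$mean)))
  expect_error(cross_validate(subset_trials(ts, 1:3), cfg,
                              n_folds = 4), "fewer trials")
})
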