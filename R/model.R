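# The trainable network: stacked spatial-temporal blocks over a channel
# graph, a global-average linear softmax head, Adam with L1 + weight
# decay, flooding loss, and the per-epoch cosine-similarity adjacency
# update.  All gradients come from the autodiff engine in autodiff.R.

#' Training configuration
#'
#' Collects the model and optimisation hyperparameters.  Defaults follow
#' the reference setting: Adam at learning rate 9.6e-4 with no decay,
#' dropout 0.5, L1 weight 0.002, L2 weight 0.001 (as optimizer weight
#' decay), 500 epochs, batch size 32, Chebyshev order 2, flooding level
#' b = 0.5, and 4 spatial-temporal blocks.  `update_adjacency = TRUE` is
#' the dynamic-graph model; `FALSE` freezes the initial matrix
#' (the predecessor model's behaviour).
#'
#' @param learning_rate Adam step size.
#' @param lr_decay multiplicative per-epoch learning-rate decay (0 = none).
#' @param dropout dropout rate after each block, in [0, 1).
#' @param optimizer only `"adam"` is implemented.
#' @param l1_weight L1 penalty weight (added to the loss).
#' @param l2_weight L2 weight-decay coefficient (applied in the optimizer).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param cheb_order Chebyshev polynomial order k.
#' @param flood_level flooding level b (>= 0).
#' @param n_blocks number of spatial-temporal blocks.
#' @param hidden_channels feature channels inside each block; `NULL`
#'   keeps the input channel count.
#' @param update_adjacency recompute the adjacency each epoch from node
#'   embeddings (dynamic graph) or keep it frozen.
#' @param seed RNG seed controlling initialisation, batching and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 9.6e-4, lr_decay = 0, dropout = 0.5,
                         optimizer = "adam", l1_weight = 0.002,
                         l2_weight = 0.001, epochs = 500, batch_size = 32,
                         cheb_order = 2, flood_level = 0.5, n_blocks = 4,
                         hidden_channels = NULL, update_adjacency = TRUE,
                         seed = 1) {
  if (learning_rate <= 0) stop2("learning_rate must be > 0")
  if (dropout < 0 || dropout >= 1) stop2("dropout must be in [0, 1)")
  if (flood_level < 0) stop2("flood_level must be >= 0")
  if (n_blocks < 1 || epochs < 1) stop2("n_blocks and epochs must be >= 1")
  if (!identical(optimizer, "adam")) stop2("only the adam optimizer is implemented")
  structure(list(learning_rate = learning_rate, lr_decay = lr_decay,
                 dropout = dropout, optimizer = optimizer,
                 l1_weight = l1_weight, l2_weight = l2_weight,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 cheb_order = as.integer(cheb_order), flood_level = flood_level,
                 n_blocks = as.integer(n_blocks),
                 hidden_channels = hidden_channels,
                 update_adjacency = isTRUE(update_adjacency),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Flooding loss
#'
#' `flooded = |raw - b| + b`: keeps the optimised loss from sinking
#' below the flooding level b, so once the raw loss would drop under b
#' the gradient direction flips and training "floods" around it.  The
#' minimum value b is attained at `raw = b`.
#'
#' @param raw nonnegative raw loss value(s).
#' @param b flooding level (>= 0).
#' @return flooded loss, same shape as `raw`.
#' @export
flooding_loss <- function(raw, b) {
  if (any(b < 0)) stop2("flooding level must be >= 0")
  abs(raw - b) + b
}

#' Block parameter initialisation
#'
#' One spatial-temporal block holds temporal attention, spatial
#' attention, Chebyshev filter coefficients `theta` (C_in x C_out x k),
#' and a depthwise temporal convolution kernel (C_out x kernel) with
#' bias.
#'
#' @param N,C_in,C_out,T block dimensions.
#' @param k Chebyshev order.
#' @param t_kernel temporal kernel length (odd; default 3).
#' @return named list of parameter arrays.
#' @export
init_block_params <- function(N, C_in, C_out, T, k = 2, t_kernel = 3) {
  if (t_kernel %% 2 == 0) stop2("temporal kernel length must be odd")
  c(init_temporal_attention(N, C_in, T),
    init_spatial_attention(N, C_in, T),
    # He-style uniform (gain sqrt(6)) on the convolutional weights keeps
    # activation variance roughly constant through stacked ReLU blocks;
    # attention weights stay at the plain 1/sqrt(fan) scale.
    list(theta = uniform_init(c(C_in, C_out, k), C_in * k, gain = sqrt(6)),
         tker = uniform_init(c(C_out, t_kernel), t_kernel, gain = sqrt(6)),
         tbias = matrix(0.1, C_out, 1)))   # small positive: avoids dead ReLUs
}

# one block, autodiff version; basis is a list of constant N x N matrices
st_block_node <- function(tape, xn, p, basis, dims = dim(xn$value)) {
  N <- dims[1]; C <- dims[2]; Tn <- dims[3]
  k <- dim(p$theta$value)[3]; C_out <- dim(p$theta$value)[2]
  # temporal attention: unfold time, right-multiply by E'
  Ep <- temporal_attention_node(tape, xn, p, dims)
  xu <- ad_reshape(tape, xn, c(N * C, Tn))
  x1 <- ad_reshape(tape, ad_matmul(tape, xu, Ep), c(N, C, Tn))
  # spatial attention from the time-mixed input
  Sp <- spatial_attention_node(tape, x1, p, dims)
  # graph convolution, all time steps at once:
  #   for each order p: (T_p o S') X_(n) -> channel mix by theta[, , p]
  # S' is row-stochastic (entries ~ 1/N); inside the convolution the
  # mean-preserving form N * S' is used so uniform attention leaves the
  # Chebyshev operator unchanged (the constant is absorbable into theta).
  SpN <- ad_scale(tape, Sp, N)
  acc <- NULL
  for (q in seq_len(k)) {
    mask <- ad_mul(tape, ad_leaf(tape, basis[[q]]), SpN)
    z <- ad_matmul(tape, mask, ad_reshape(tape, x1, c(N, C * Tn)))
    z <- ad_aperm(tape, ad_reshape(tape, z, c(N, C, Tn)), c(1, 3, 2)) # N x T x C
    z <- ad_matmul(tape, ad_reshape(tape, z, c(N * Tn, C)),
                   ad_slice3(tape, p$theta, q))
    acc <- if (is.null(acc)) z else ad_add(tape, acc, z)
  }
  y <- ad_aperm(tape, ad_reshape(tape, acc, c(N, Tn, C_out)), c(1, 3, 2))
  y <- ad_relu(tape, y)                                      # N x C_out x T
  y <- ad_conv_time(tape, y, p$tker, p$tbias)
  ad_relu(tape, y)
}

#' Assemble the classifier
#'
#' Builds the full network: `n_blocks` spatial-temporal blocks over the
#' channel graph, a time-averaged node-by-channel readout, and a 4-way
#' linear softmax head.  The parameter count is a deterministic function
#' of the configuration and dimensions.
#'
#' @param cfg a [train_config()].
#' @param A_init initial `adjacency_matrix` (N x N, zero diagonal), e.g.
#'   from [mi_adjacency()].
#' @param dims integer vector `c(N, C, T)` of the input feature tensor.
#' @param n_classes number of classes (default 4).
#' @return a `stgcn_model` environment holding parameters, the current
#'   graph and its Chebyshev basis, and optimizer state.
#' @export
build_model <- function(cfg, A_init, dims, n_classes = 4) {
  stopifnot(inherits(cfg, "train_config"))
  N <- dims[1]; C <- dims[2]; Tn <- dims[3]
  if (!all(dim(A_init) == c(N, N))) stop2("A_init must be N x N")
  hid <- cfg$hidden_channels %||% C
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$dims <- c(N = N, C = C, T = Tn)
  model$n_classes <- n_classes
  with_seed(cfg$seed, {
    params <- list()
    c_in <- C
    for (b in seq_len(cfg$n_blocks)) {
      params[[paste0("block", b)]] <-
        init_block_params(N, c_in, hid, Tn, k = cfg$cheb_order)
      c_in <- hid
    }
    # readout: average over time, flatten nodes x channels, linear softmax
    params$head_W <- uniform_init(c(N * c_in, n_classes), N * c_in)
    params$head_b <- matrix(0, 1, n_classes)
    model$params <- params
  })
  install_adjacency(model, A_init)
  model$adam <- list(m = zero_like(model$params), v = zero_like(model$params),
                     t = 0L)
  model$history <- NULL
  class(model) <- "stgcn_model"
  model
}

#' @export
print.stgcn_model <- function(x, ...) {
  cat(sprintf("<stgcn_model> %d blocks, dims N=%d C=%d T=%d, k=%d, %d parameters\n",
              x$cfg$n_blocks, x$dims[1], x$dims[2], x$dims[3],
              x$cfg$cheb_order, n_params(x$params)))
  invisible(x)
}

zero_like <- function(p) lapply(p, function(q)
  if (is.list(q)) zero_like(q) else array(0, dim(q)))

n_params <- function(p) sum(vapply(p, function(q)
  if (is.list(q)) n_params(q) else length(q), numeric(1)))

install_adjacency <- function(model, A) {
  w <- unclass(as.matrix(A))
  diag(w) <- 0                      # constructor convention for graph use
  model$A <- w
  op <- scale_laplacian(normalized_laplacian(adjacency_matrix(w, "installed")))
  model$basis <- chebyshev_basis(op, model$cfg$cheb_order)
  invisible(model)
}

# forward pass for one trial; returns list(logits node, final block node)
forward_trial <- function(tape, x, pn, model, drop_masks = NULL) {
  dims <- as.integer(model$dims)
  xn <- ad_leaf(tape, x)
  c_cur <- dims[2]
  for (b in seq_len(model$cfg$n_blocks)) {
    p <- pn[[paste0("block", b)]]
    xn <- st_block_node(tape, xn, p, model$basis,
                        dims = c(dims[1], c_cur, dims[3]))
    c_cur <- dim(p$theta$value)[2]
    if (!is.null(drop_masks)) xn <- ad_dropout(tape, xn, drop_masks[[b]])
  }
  # average over time segments, keep node identity: N x C -> 1 x (N C)
  ones_t <- ad_leaf(tape, matrix(1 / dims[3], dims[3], 1))
  feat <- ad_matmul(tape, ad_reshape(tape, xn, c(dims[1] * c_cur, dims[3])),
                    ones_t)
  feat <- ad_reshape(tape, feat, c(1, dims[1] * c_cur))
  logits <- ad_add(tape, ad_matmul(tape, feat, pn$head_W), pn$head_b)
  list(logits = logits, embedding = xn)
}

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    q <- p[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(q) && !is.environment(q)) out <- c(out, flatten_params(q, key))
    else out[[key]] <- q
  }
  out
}

#' Train the classifier
#'
#' Minibatch training with Adam.  Each epoch shuffles the trials,
#' optimises `flood(CE + L1)` (cross-entropy plus the L1 penalty, passed
#' through the flooding transform; L2 is applied as optimizer weight
#' decay), and — when `cfg$update_adjacency` is on — recomputes the
#' channel graph as rectified cosine similarities between node
#' embeddings taken from the final block's output, averaged over the
#' epoch's training trials and excluded from gradient flow.
#'
#' @param model a `stgcn_model` from [build_model()].
#' @param x feature array L x N x C x T (e.g. from [prepare_inputs()]).
#' @param y integer labels 0..3, length L.
#' @param cfg optional [train_config()] overriding the one in the model.
#' @param verbose print per-epoch progress.
#' @return the model, with `model$history` (per-epoch data frame) and
#'   `model$adjacency_snapshots` filled in.
#' @export
train_model <- function(model, x, y, cfg = model$cfg, verbose = FALSE) {
  stopifnot(inherits(model, "stgcn_model"))
  L <- dim(x)[1]
  if (L == 0) stop2("empty training set")
  y <- as.integer(y)
  if (length(unique(y)) < 2) warning("single-class training set")
  model$cfg <- cfg
  lr <- cfg$learning_rate
  hist <- vector("list", cfg$epochs)
  model$adjacency_snapshots <- list(model$A)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(L)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_ce <- 0; ep_raw <- 0; ep_flood <- 0; ep_l1 <- 0; n_done <- 0
      emb_sum <- NULL
      for (bt in batches) {
        tape <- ad_tape()
        pn <- leaves_from(tape, model$params)
        flat_pn <- flatten_params(pn)
        drop_masks <- NULL
        if (cfg$dropout > 0) {
          hid <- dim(model$params$block1$theta)[2]
          drop_masks <- lapply(seq_len(cfg$n_blocks), function(b)
            array((stats::runif(prod(c(model$dims[1], hid, model$dims[3]))) >
                     cfg$dropout) / (1 - cfg$dropout),
                  c(model$dims[1], hid, model$dims[3])))
        }
        ces <- vector("list", length(bt))
        for (i in seq_along(bt)) {
          tr <- bt[i]
          fw <- forward_trial(tape, array(x[tr, , , ], dim(x)[-1]), pn,
                              model, drop_masks)
          ces[[i]] <- ad_cross_entropy(tape, fw$logits, y[tr] + 1L)
          if (cfg$update_adjacency) {
            e <- fw$embedding$value      # N x C x T, detached
            em <- t(matrix(e, dim(e)[1], prod(dim(e)[-1])))  # (C T) x N
            emb_sum <- if (is.null(emb_sum)) em else emb_sum + em
          }
        }
        ce_node <- ad_mean_scalars(tape, ces)
        l1 <- cfg$l1_weight * sum(vapply(flat_pn, function(nd)
          sum(abs(nd$value)), numeric(1)))
        raw <- ce_node$value + l1
        flood_sign <- sign(raw - cfg$flood_level)
        ad_backward(tape, ce_node, seed = flood_sign)
        grads <- lapply(flat_pn, function(nd) {
          g <- nd$grad
          if (is.null(g)) g <- array(0, dim(nd$value))
          g + flood_sign * cfg$l1_weight * sign(nd$value) +
            cfg$l2_weight * nd$value
        })
        model_step_adam(model, grads, lr)
        nb <- length(bt)
        ep_ce <- ep_ce + ce_node$value * nb
        ep_raw <- ep_raw + raw * nb
        ep_flood <- ep_flood + flooding_loss(raw, cfg$flood_level) * nb
        ep_l1 <- ep_l1 + l1 * nb
        n_done <- n_done + nb
      }
      if (cfg$update_adjacency && !is.null(emb_sum)) {
        A_new <- unclass(update_adjacency(emb_sum / L))
        install_adjacency(model, A_new)
        model$adjacency_snapshots[[ep + 1L]] <- model$A
      } else {
        model$adjacency_snapshots[[ep + 1L]] <- model$A
      }
      hist[[ep]] <- data.frame(epoch = ep, ce = ep_ce / n_done,
                               raw = ep_raw / n_done,
                               flooded = ep_flood / n_done,
                               l1_penalty = ep_l1 / n_done,
                               lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  raw %.4f  flooded %.4f", ep,
                        ep_raw / n_done, ep_flood / n_done))
      lr <- lr * (1 - cfg$lr_decay)
    }
  })
  model$history <- do.call(rbind, hist)
  model
}

model_step_adam <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  st <- model$adam
  st$t <- st$t + 1L
  flat_p <- flatten_params(model$params)
  flat_m <- flatten_params(st$m)
  flat_v <- flatten_params(st$v)
  for (nm in names(flat_p)) {
    g <- grads[[nm]]
    flat_m[[nm]] <- beta1 * flat_m[[nm]] + (1 - beta1) * g
    flat_v[[nm]] <- beta2 * flat_v[[nm]] + (1 - beta2) * g^2
    mhat <- flat_m[[nm]] / (1 - beta1^st$t)
    vhat <- flat_v[[nm]] / (1 - beta2^st$t)
    flat_p[[nm]] <- flat_p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$params <- unflatten_params(flat_p, model$params)
  st$m <- unflatten_params(flat_m, st$m)
  st$v <- unflatten_params(flat_v, st$v)
  model$adam <- st
  invisible(model)
}

unflatten_params <- function(flat, template, prefix = "") {
  for (nm in names(template)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(template[[nm]]))
      template[[nm]] <- unflatten_params(flat, template[[nm]], key)
    else template[[nm]] <- flat[[key]]
  }
  template
}

#' Predict class probabilities / labels
#'
#' @param object a trained `stgcn_model`.
#' @param x feature array L x N x C x T.
#' @param ... unused.
#' @return matrix L x n_classes of softmax probabilities.
#' @export
predict.stgcn_model <- function(object, x, ...) {
  L <- dim(x)[1]
  out <- matrix(0, L, object$n_classes)
  for (tr in seq_len(L)) {
    tape <- ad_tape()
    pn <- leaves_from(tape, object$params)
    fw <- forward_trial(tape, array(x[tr, , , ], dim(x)[-1]), pn, object)
    z <- as.vector(fw$logits$value)
    z <- z - max(z)
    out[tr, ] <- exp(z) / sum(exp(z))
  }
  out
}

#' Evaluation metrics
#'
#' Accuracy, macro-averaged F1 and precision, per-class
#' precision/recall, and the 4 x 4 confusion matrix.  Classes absent
#' from both truth and prediction are excluded from the macro averages
#' (with a message).
#'
#' @param model a trained `stgcn_model`.
#' @param x feature array L x N x C x T.
#' @param y integer labels 0..3.
#' @return a `metrics_report` list.
#' @export
evaluate_model <- function(model, x, y) {
  if (dim(x)[1] == 0) stop2("empty set")
  prob <- predict(model, x)
  pred <- max.col(prob) - 1L
  metrics_report(pred, as.integer(y), n_classes = model$n_classes)
}

#' @param pred,truth integer label vectors (0-based).
#' @param n_classes number of classes.
#' @rdname evaluate_model
#' @export
metrics_report <- function(pred, truth, n_classes = 4) {
  lv <- 0:(n_classes - 1)
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- unclass(cm)
  tp <- diag(cm)
  prec <- tp / pmax(colSums(cm), 1)
  rec <- tp / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(cm) > 0 | colSums(cm) > 0
  if (any(!present))
    message("class(es) ", paste(lv[!present], collapse = ","),
            " absent from truth and prediction; excluded from macro averages")
  structure(list(accuracy = sum(tp) / sum(cm),
                 macro_f1 = mean(f1[present]),
                 macro_precision = mean(prec[present]),
                 per_class = data.frame(class = lv, precision = prec,
                                        recall = rec, f1 = f1),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  macro F1 %.4f  macro precision %.4f\n",
              x$accuracy, x$macro_f1, x$macro_precision))
  invisible(x)
}

#' Prepare network inputs from a trial set
#'
#' The standard feature pipeline: differential-entropy features over
#' `bands`, double-folded to the adjacency side, plus the
#' mutual-information channel graph, both computed from the given
#' trials.  Feature channels can be standardized with statistics from a
#' reference set (pass `stats` from a previous call to apply training
#' statistics to test data).
#'
#' @param ts a [trial_set()] (band-passed).
#' @param bands a [band_spec()]; the doubled band count must equal the
#'   channel count.
#' @param segment segment length in seconds.
#' @param n_bins MI histogram bins.
#' @param scale standardize feature channels.
#' @param stats optional list(mean, sd) from a previous call.
#' @return list with `x` (L x N x C x T array), `A` (MI adjacency),
#'   `labels`, `dims`, and `stats`.
#' @export
prepare_inputs <- function(ts, bands = band_spec(), segment = 0.5,
                           n_bins = 16, scale = TRUE, stats = NULL) {
  de <- de_features(ts, bands = bands, segment = segment)
  n_nodes <- dim(de)[2]
  xf <- assemble_node_features(de, n_nodes)
  x <- unclass(xf)
  if (scale) {
    if (is.null(stats)) {
      mu <- apply(x, c(2, 3), mean)
      sd_ <- apply(x, c(2, 3), stats::sd)
      sd_[sd_ < .eps] <- 1
      stats <- list(mean = mu, sd = sd_)
    }
    x <- sweep(sweep(x, c(2, 3), stats$mean, "-"), c(2, 3), stats$sd, "/")
  }
  A <- mi_adjacency(ts, n_bins = n_bins)
  list(x = x, A = A, labels = ts$labels, dims = dim(x)[-1], stats = stats)
}

#' Stratified k-fold cross-validation
#'
#' Splits trials into stratified folds (per-fold class proportions
#' within one trial of the global proportions), then per fold runs the
#' full pipeline on the training portion only — MI adjacency, DE
#' features, feature scaling — trains a fresh model and evaluates on the
#' held-out fold.
#'
#' @param ts a [trial_set()].
#' @param cfg a [train_config()].
#' @param n_folds number of folds (default 4).
#' @param bands,segment,n_bins forwarded to [prepare_inputs()].
#' @param fold_seed seed for the fold assignment.
#' @param verbose print per-fold progress.
#' @return list with `folds` (per-fold `metrics_report`s), `assignment`
#'   (fold id per trial), `mean` and `sd` of accuracy / macro F1 /
#'   macro precision.
#' @export
cross_validate <- function(ts, cfg, n_folds = 4, bands = band_spec(),
                           segment = 0.5, n_bins = 16, fold_seed = 1,
                           verbose = FALSE) {
  L <- dim(ts$trials)[1]
  if (L < n_folds) stop2("fewer trials than folds")
  fold <- stratified_folds(ts$labels, n_folds, fold_seed)
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    ts_tr <- subset_trials(ts, tr_idx)
    ts_te <- subset_trials(ts, te_idx)
    inp_tr <- prepare_inputs(ts_tr, bands, segment, n_bins)
    inp_te <- prepare_inputs(ts_te, bands, segment, n_bins,
                             stats = inp_tr$stats)
    model <- build_model(cfg, inp_tr$A, inp_tr$dims)
    model <- train_model(model, inp_tr$x, inp_tr$labels)
    reports[[f]] <- evaluate_model(model, inp_te$x, inp_te$labels)
    if (verbose)
      message(sprintf("fold %d: accuracy %.4f", f, reports[[f]]$accuracy))
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  f1 <- vapply(reports, `[[`, numeric(1), "macro_f1")
  pr <- vapply(reports, `[[`, numeric(1), "macro_precision")
  list(folds = reports, assignment = fold,
       mean = c(accuracy = mean(acc), macro_f1 = mean(f1),
                macro_precision = mean(pr)),
       sd = c(accuracy = stats::sd(acc), macro_f1 = stats::sd(f1),
              macro_precision = stats::sd(pr)))
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `n_folds` folds, cycling within each
#' class so per-fold class counts differ from perfect proportionality by
#' at most one trial.  Assignment depends only on labels and the seed,
#' not on trial order: trials are ranked within class by a seeded random
#' key drawn per class size.
#'
#' @param labels integer labels.
#' @param n_folds number of folds.
#' @param seed fold seed.
#' @return integer fold id (1..n_folds) per trial.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1) {
  fold <- integer(length(labels))
  with_seed(seed, {
    off <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      ord <- sample.int(length(idx))      # random rank within class
      # rotate the cycle start per class so leftover trials spread evenly
      fold[idx] <- ((ord - 1L + off) %% n_folds) + 1L
      off <- off + 1L
    }
  })
  fold
}

#' Subset a trial set by trial index
#'
#' @param ts a [trial_set()].
#' @param idx integer trial indices to keep.
#' @return the subsetted [trial_set()].
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$trials[idx, , , drop = FALSE], ts$labels[idx],
            ts$sampling_rate, ts$channel_names)
}
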