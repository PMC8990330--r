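#' Configuration for the ConvLSTM classifier
#'
#' Architecture and training hyperparameters for the deep model: two
#' ConvLSTM layers (spatially convolutional LSTM cells over the 24 x 60
#' daily frames, 7 time steps, one per day) separated by max pooling, a
#' dropout layer, a dense tanh layer and a sigmoid output.
#'
#' @param filters integer length-2: filters in the first and second
#'   ConvLSTM layers.
#' @param kernel odd convolution kernel size (square).
#' @param pool max-pooling size applied between the ConvLSTM layers.
#' @param dropout_rate dropout rate after the second ConvLSTM layer.
#' @param dense width of the dense hidden layer.
#' @param learning_rate Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience on validation AUC.
#' @param seed integer seed for weight initialization and batching.
#' @return A `conv_lstm_config` object.
#' @export
conv_lstm_config <- function(filters = c(16L, 8L), kernel = 3L, pool = 2L,
                             dropout_rate = 0.2, dense = 16L,
                             learning_rate = 1e-3, epochs = 50L,
                             batch_size = 32L, patience = 5L, seed = 1L) {
  stopifnot(length(filters) == 2L, all(filters >= 1L), kernel %% 2L == 1L,
            pool >= 1L, dense >= 1L, epochs >= 1L, batch_size >= 1L)
  assert_prob(dropout_rate, "dropout_rate")
  if (dropout_rate >= 1) stop("dropout_rate must be < 1", call. = FALSE)
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), dropout_rate = dropout_rate,
                 dense = as.integer(dense), learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "conv_lstm_config")
}

#' Reduced desk-scale ConvLSTM configuration
#'
#' Smaller filters and fewer epochs for laptop-scale cohorts; full-scale
#' settings remain available through [conv_lstm_config()].
#' @param ... overrides passed to [conv_lstm_config()].
#' @export
conv_lstm_desk_config <- function(...) {
  args <- utils::modifyList(
    list(filters = c(8L, 4L), epochs = 6L, patience = 3L, batch_size = 32L),
    list(...))
  do.call(conv_lstm_config, args)
}

#' Build a ConvLSTM model with freshly initialized weights
#'
#' Layer order: ConvLSTM -> max pool -> ConvLSTM -> dropout -> flatten ->
#' (concatenate standardized PHQ-9 scalar, if enabled) -> dense (tanh) ->
#' sigmoid scalar. Weights are Glorot-uniform, forget-gate biases 1;
#' initialization is deterministic given `config$seed`.
#'
#' @param config a [conv_lstm_config()].
#' @param with_phq9 concatenate a PHQ-9 scalar into the dense layer input?
#' @return A `convlstm_model` object.
#' @export
build_model <- function(config = conv_lstm_config(), with_phq9 = FALSE) {
  stopifnot(inherits(config, "conv_lstm_config"))
  H <- 24L; W <- 60L
  if (H %% config$pool != 0L || W %% config$pool != 0L)
    stop("pool size must divide the 24 x 60 frame dimensions", call. = FALSE)
  H2 <- H %/% config$pool; W2 <- W %/% config$pool
  n_flat <- H2 * W2 * config$filters[2]
  params <- with_seed(config$seed, {
    l1 <- init_convlstm_layer(1L, config$filters[1], config$kernel)
    l2 <- init_convlstm_layer(config$filters[1], config$filters[2], config$kernel)
    list(
      l1 = list(Wx = l1$Wx, Wh = l1$Wh, b = l1$b),
      l2 = list(Wx = l2$Wx, Wh = l2$Wh, b = l2$b),
      d1 = init_dense(n_flat + as.integer(with_phq9), config$dense),
      out = init_dense(config$dense, 1L)
    )
  })
  meta <- list(
    H = H, W = W, H2 = H2, W2 = W2,
    l1 = list(kernel = config$kernel, filters = config$filters[1], c_in = 1L),
    l2 = list(kernel = config$kernel, filters = config$filters[2],
              c_in = config$filters[1])
  )
  structure(list(params = params, meta = meta, config = config,
                 with_phq9 = with_phq9),
            class = "convlstm_model")
}

#' Number of trainable parameters
#' @param model a `convlstm_model`.
#' @export
count_params <- function(model) length(flatten_params(model$params))

# slice a (n, 7, 24, 60) tensor into a list of 7 (B*HW) x 1 frame matrices
tensor_batch <- function(tensor, idx) {
  B <- length(idx)
  lapply(seq_len(DAYS_PER_WEEK), function(t) {
    x <- tensor[idx, t, , , drop = FALSE]
    dim(x) <- c(B, 24L, 60L)
    matrix(as.vector(aperm(x, c(2L, 3L, 1L))), ncol = 1L)
  })
}

# full network forward; returns probability plus caches for backprop.
# `drop_mask` (inverted-dropout mask on the second layer's last hidden
# state) is NULL at inference.
net_fwd <- function(model, X, phq9 = NULL, drop_mask = NULL) {
  m <- model$meta; p <- model$params
  B <- nrow(X[[1]]) / (m$H * m$W)
  L1 <- convlstm_fwd(X, c(p$l1, m$l1), m$H, m$W, B)
  pooled <- vector("list", length(X))
  argmaxes <- vector("list", length(X))
  for (t in seq_along(X)) {
    mp <- maxpool_fwd(L1$hs[[t]], m$H, m$W, B, model$config$pool)
    pooled[[t]] <- mp$out
    argmaxes[[t]] <- mp$argmax
  }
  L2 <- convlstm_fwd(pooled, c(p$l2, m$l2), m$H2, m$W2, B)
  h2 <- L2$hs[[length(X)]]
  if (!is.null(drop_mask)) h2 <- h2 * drop_mask
  feat <- to_sample_major(h2, m$H2 * m$W2, B)
  if (model$with_phq9) {
    stopifnot(!is.null(phq9), length(phq9) == B)
    feat <- cbind(feat, phq9)
  }
  pre1 <- sweep(feat %*% p$d1$W, 2L, p$d1$b, "+")
  a1 <- tanh(pre1)
  z <- drop(a1 %*% p$out$W + p$out$b)
  prob <- sigmoid(z)
  list(prob = prob, z = z, a1 = a1, feat = feat, h2 = h2, L1 = L1, L2 = L2,
       pooled = pooled, argmaxes = argmaxes, B = B)
}

# backward from dL/dz (gradient on the pre-sigmoid logit, length B).
# Returns parameter gradients in the params tree layout; with
# `need_dx = TRUE` also the gradient on the input frames.
net_bwd <- function(model, X, fwd, dz, drop_mask = NULL, need_dx = FALSE) {
  m <- model$meta; p <- model$params
  B <- fwd$B
  dz <- matrix(dz, ncol = 1L)
  d_out <- list(W = crossprod(fwd$a1, dz), b = sum(dz))
  da1 <- dz %*% t(p$out$W)
  dpre1 <- da1 * (1 - fwd$a1^2)
  d_d1 <- list(W = crossprod(fwd$feat, dpre1), b = colSums(dpre1))
  dfeat <- dpre1 %*% t(p$d1$W)
  if (model$with_phq9) dfeat <- dfeat[, -ncol(dfeat), drop = FALSE]
  dh2 <- from_sample_major(dfeat, m$H2 * m$W2, B, model$config$filters[2])
  if (!is.null(drop_mask)) dh2 <- dh2 * drop_mask
  Tn <- length(X)
  dH2 <- replicate(Tn, matrix(0, nrow(dh2), ncol(dh2)), simplify = FALSE)
  dH2[[Tn]] <- dh2
  g2 <- convlstm_bwd(fwd$pooled, fwd$L2$hs, fwd$L2$cache, c(p$l2, m$l2),
                     m$H2, m$W2, B, dH2, need_dx = TRUE)
  dH1 <- lapply(seq_len(Tn), function(t)
    maxpool_bwd(g2$dX[[t]], fwd$argmaxes[[t]], as.integer(B * m$H * m$W)))
  g1 <- convlstm_bwd(X, fwd$L1$hs, fwd$L1$cache, c(p$l1, m$l1),
                     m$H, m$W, B, dH1, need_dx = need_dx)
  list(grads = list(l1 = list(Wx = g1$dWx, Wh = g1$dWh, b = g1$db),
                    l2 = list(Wx = g2$dWx, Wh = g2$dWh, b = g2$db),
                    d1 = d_d1, out = d_out),
       dX = g1$dX)
}

#' Predict SSRI probabilities with a ConvLSTM model
#'
#' @param model a `convlstm_model`.
#' @param tensor standardized (n, 7, 24, 60) week tensor.
#' @param phq9 standardized PHQ-9 vector (required iff the model was built
#'   `with_phq9`).
#' @param batch_size evaluation batch size.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_convlstm <- function(model, tensor, phq9 = NULL, batch_size = 64L) {
  n <- dim(tensor)[1]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- tensor_batch(tensor, idx)
    out[idx] <- net_fwd(model, X, phq9 = phq9[idx])$prob
  }
  out
}

# gradient of the output probability w.r.t. the input frames, as an
# n x 10080 matrix (used by the attribution module)
input_gradient <- function(model, tensor, phq9 = NULL, batch_size = 32L) {
  n <- dim(tensor)[1]
  out <- matrix(0, n, MINUTES_PER_WEEK)
  m <- model$meta
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    B <- length(idx)
    X <- tensor_batch(tensor, idx)
    fwd <- net_fwd(model, X, phq9 = phq9[idx])
    dz <- fwd$prob * (1 - fwd$prob) # d sigmoid(z) / dz
    bwd <- net_bwd(model, X, fwd, dz, need_dx = TRUE)
    # dX[[t]] is (B*HW) x 1 with row r = (b-1)*HW + (w-1)*H + h; the
    # minute-of-week for frame pixel (h, w) on day t is
    # (t-1)*1440 + (h-1)*60 + w
    for (t in seq_len(DAYS_PER_WEEK)) {
      g <- array(bwd$dX[[t]], dim = c(m$H, m$W, B)) # [h, w, b]
      gm <- aperm(g, c(2L, 1L, 3L))                 # [w, h, b]
      cols <- (t - 1L) * MINUTES_PER_DAY + seq_len(MINUTES_PER_DAY)
      out[idx, cols] <- t(matrix(gm, m$H * m$W, B))
    }
  }
  out
}

train_one_fold <- function(model, tensor, y, train_idx, val_idx, cw,
                           phq9 = NULL, verbose = FALSE) {
  cfg <- model$config
  m <- model$meta
  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  wait <- 0L
  adam <- adam_init(model$params)
  theta <- flatten_params(model$params)
  w_all <- sample_weights(y, cw)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(train_idx)
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      B <- length(idx)
      if (B < 2L) next
      X <- tensor_batch(tensor, idx)
      drop_mask <- NULL
      if (cfg$dropout_rate > 0) {
        keep <- 1 - cfg$dropout_rate
        drop_mask <- matrix(
          (runif(B * m$H2 * m$W2 * cfg$filters[2]) < keep) / keep,
          B * m$H2 * m$W2, cfg$filters[2])
      }
      fwd <- net_fwd(model, X, phq9 = phq9[idx], drop_mask = drop_mask)
      loss <- weighted_bce(fwd$prob, y[idx], w_all[idx])
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
      p_clip <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
      dz <- w_all[idx] * (p_clip - y[idx]) / B
      bwd <- net_bwd(model, X, fwd, dz, drop_mask = drop_mask)
      upd <- adam_update(theta, flatten_params(bwd$grads), adam,
                         cfg$learning_rate)
      theta <- upd$theta
      adam <- upd$state
      model$params <- unflatten_params(theta, model$params)
    }
    val_prob <- predict_convlstm(model, tensor[val_idx, , , , drop = FALSE],
                                 phq9 = phq9[val_idx])
    val_auc <- roc_auc(val_prob, y[val_idx])
    if (verbose)
      message(sprintf("  epoch %d: val AUC %.3f", epoch, val_auc))
    if (val_auc > best$auc + 1e-6) {
      best <- list(auc = val_auc, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best$params
  list(model = model, best_epoch = best$epoch, best_auc = best$auc)
}

#' Train the ConvLSTM classifier under a cross-validation plan
#'
#' For each fold, a fresh model is initialized (seed = config seed + fold),
#' trained with minibatch Adam on class-weighted binary cross-entropy, and
#' early-stopped on validation AUC. Each fold model predicts its validation
#' fold and the held-out test set; the reported held-out prediction per
#' participant additionally includes the fold-averaged ensemble (fold 0).
#' When `phq9` is supplied (complete, e.g. after [impute_phq9()]), the model
#' concatenates the score — z-scored on each fold's training participants —
#' into the dense layer.
#'
#' @param tensor standardized (n, 7, 24, 60) week tensor.
#' @param labels binary vector of length n.
#' @param fold_plan a [make_fold_plan()] object.
#' @param class_weights a [compute_class_weights()] object; computed from
#'   the training labels when `NULL`.
#' @param config a [conv_lstm_config()].
#' @param phq9 optional complete PHQ-9 vector (enables the fusion variant).
#' @param verbose print per-epoch validation AUC?
#' @return An object of class `convlstm_fit` with the same prediction
#'   surface as [fit_wavelet_logistic()] plus the trained fold `models`.
#' @export
train_cv <- function(tensor, labels, fold_plan, class_weights = NULL,
                     config = conv_lstm_config(), phq9 = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(fold_plan, "fold_plan"), length(dim(tensor)) == 4L)
  y <- as_label01(labels)
  if (is.null(class_weights))
    class_weights <- compute_class_weights(y[-fold_plan$test])
  with_phq9 <- !is.null(phq9)
  if (with_phq9 && anyNA(phq9))
    stop("`phq9` must be complete; impute first with impute_phq9()", call. = FALSE)
  k <- fold_plan$k
  cv_rows <- list(); models <- vector("list", k)
  train_scores <- vector("list", k); fold_auc <- numeric(k)
  history <- vector("list", k)
  test_prob <- matrix(NA_real_, length(fold_plan$test), k)
  for (i in seq_len(k)) {
    tr <- fold_plan$folds[[i]]$train
    va <- fold_plan$folds[[i]]$validation
    phq_z <- NULL
    if (with_phq9) {
      mu <- mean(phq9[tr]); s <- sd(phq9[tr]); if (s == 0) s <- 1
      phq_z <- (phq9 - mu) / s
    }
    cfg_i <- config; cfg_i$seed <- config$seed + i
    model <- build_model(cfg_i, with_phq9 = with_phq9)
    res <- with_seed(cfg_i$seed, {
      train_one_fold(model, tensor, y, tr, va, class_weights,
                     phq9 = phq_z, verbose = verbose)
    })
    models[[i]] <- res$model
    history[[i]] <- list(best_epoch = res$best_epoch, best_auc = res$best_auc)
    pv <- predict_convlstm(res$model, tensor[va, , , , drop = FALSE],
                           phq9 = phq_z[va])
    cv_rows[[i]] <- tibble::tibble(index = va, fold = i, probability = pv,
                                   label = y[va])
    fold_auc[i] <- roc_auc(pv, y[va])
    train_scores[[i]] <- predict_convlstm(res$model,
                                          tensor[tr, , , , drop = FALSE],
                                          phq9 = phq_z[tr])
    test_prob[, i] <- predict_convlstm(res$model,
                                       tensor[fold_plan$test, , , , drop = FALSE],
                                       phq9 = phq_z[fold_plan$test])
    if (verbose) message(sprintf("fold %d: val AUC %.3f", i, fold_auc[i]))
  }
  test_predictions <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(seq_len(k), function(i)
      tibble::tibble(index = fold_plan$test, fold = i,
                     probability = test_prob[, i], label = y[fold_plan$test]))),
    tibble::tibble(index = fold_plan$test, fold = 0L,
                   probability = rowMeans(test_prob), label = y[fold_plan$test])
  )
  structure(list(cv_predictions = dplyr::bind_rows(cv_rows),
                 test_predictions = test_predictions,
                 fold_auc = fold_auc, train_scores = train_scores,
                 models = models, history = history,
                 class_weights = class_weights, fold_plan = fold_plan,
                 config = config, with_phq9 = with_phq9),
            class = "convlstm_fit")
}

#' @export
print.convlstm_fit <- function(x, ...) {
  ci <- fold_auc_ci(x$fold_auc)
  cat(sprintf("<convlstm_fit> %d folds%s; mean CV AUC %.3f (95%% CI %.3f-%.3f)\n",
              length(x$fold_auc),
              if (x$with_phq9) " (activity + PHQ-9)" else " (activity only)",
              ci$mean, ci$low, ci$high))
  invisible(x)
}

#' @rdname actiphen-tidiers
#' @method tidy convlstm_fit
#' @export
tidy.convlstm_fit <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_auc), auc = x$fold_auc,
                 best_epoch = vapply(x$history, `[[`, integer(1), "best_epoch"))
}

#' @rdname actiphen-tidiers
#' @method glance convlstm_fit
#' @export
glance.convlstm_fit <- function(x, ...) {
  ci <- fold_auc_ci(x$fold_auc)
  ens <- dplyr::filter(x$test_predictions, .data$fold == 0L)
  tibble::tibble(cv_auc_mean = ci$mean, cv_auc_low = ci$low,
                 cv_auc_high = ci$high,
                 test_auc = roc_auc(ens$probability, ens$label))
}

#' Impute missing PHQ-9 scores from demographics
#'
#' Iterative regression imputation: missing scores are initialized at the
#' observed mean, then repeatedly re-predicted from a linear model of the
#' observed scores on age, sex and race/ethnicity until the imputed values
#' stabilize. Observed entries are never altered; imputed values are
#' clipped to the valid `[0, 27]` range (clipping is reported). The
#' procedure is deterministic.
#'
#' @param phq9 numeric vector with `NA` for missing (at least one observed).
#' @param demographics tibble with `age`, `sex`, `race` (complete).
#' @param max_iter maximum refinement iterations.
#' @return Numeric vector with attribute `imputed_idx`.
#' @export
impute_phq9 <- function(phq9, demographics, max_iter = 10L) {
  if (all(is.na(phq9))) stop("all PHQ-9 scores missing; cannot impute", call. = FALSE)
  stopifnot(all(c("age", "sex", "race") %in% names(demographics)),
            nrow(demographics) == length(phq9))
  miss <- which(is.na(phq9))
  if (!length(miss)) return(phq9)
  # drop degenerate predictors (single observed level) before building the
  # design matrix
  preds <- c("age", "sex", "race")
  preds <- preds[vapply(preds, function(v)
    length(unique(demographics[[v]])) > 1L, logical(1))]
  form <- if (length(preds)) {
    stats::reformulate(preds)
  } else ~1
  X <- model.matrix(form, data = demographics)
  obs <- which(!is.na(phq9))
  fit <- lm.fit(X[obs, , drop = FALSE], phq9[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  out <- phq9
  out[miss] <- mean(phq9[obs])
  for (iter in seq_len(max_iter)) {
    pred <- drop(X[miss, , drop = FALSE] %*% beta)
    if (max(abs(pred - out[miss])) < 1e-8) { out[miss] <- pred; break }
    out[miss] <- pred
  }
  clipped <- out[miss] < 0 | out[miss] > 27
  if (any(clipped))
    message(sum(clipped), " imputed PHQ-9 value(s) clipped into [0, 27]")
  out[miss] <- pmin(pmax(out[miss], 0), 27)
  attr(out, "imputed_idx") <- miss
  out
}
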