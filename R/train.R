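#' Training configuration
#'
#' Phase presets mirror the reference training strategy: pretraining uses
#' SGD with momentum 0.9, initial learning rate 1e-4, 200 epochs;
#' fine-tuning uses Adam at 1e-5 (ten times smaller) for 100 epochs. Both
#' anneal the learning rate with a cosine schedule stepped once per epoch,
#' use batch size 32, label smoothing 0.1 and 5-fold stratified
#' cross-validation where cross-validation applies.
#'
#' @param phase `"pretrain"` or `"finetune"`; sets the optimizer family,
#'   initial learning rate and epoch count unless overridden.
#' @param optimizer `"sgd"` (with momentum) or `"adam"`.
#' @param lr_init initial learning rate (the cosine schedule's maximum).
#' @param lr_min final learning rate (default 0).
#' @param momentum SGD momentum.
#' @param epochs training epochs `T`.
#' @param batch_size minibatch size.
#' @param label_smoothing_eps label smoothing epsilon in `[0, 1)`.
#' @param k_folds folds `K` for stratified cross-validation.
#' @param seed integer seed governing fold assignment, shuffling, dropout
#'   and weight initialization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(phase = c("pretrain", "finetune"),
                         optimizer = NULL, lr_init = NULL, lr_min = 0,
                         momentum = 0.9, epochs = NULL, batch_size = 32,
                         label_smoothing_eps = 0.1, k_folds = 5, seed = 1L) {
  phase <- match.arg(phase)
  defaults <- list(
    pretrain = list(optimizer = "sgd", lr_init = 1e-4, epochs = 200L),
    finetune = list(optimizer = "adam", lr_init = 1e-5, epochs = 100L)
  )[[phase]]
  optimizer <- optimizer %||% defaults$optimizer
  lr_init <- lr_init %||% defaults$lr_init
  epochs <- as.integer(epochs %||% defaults$epochs)
  if (!optimizer %in% c("sgd", "adam")) stopf("optimizer must be sgd or adam")
  if (lr_min > lr_init) stopf("lr_min must not exceed lr_init")
  if (epochs < 0) stopf("epochs must be >= 0")
  if (k_folds < 2) stopf("k_folds must be >= 2")
  if (label_smoothing_eps < 0 || label_smoothing_eps >= 1) {
    stopf("label_smoothing_eps must lie in [0, 1)")
  }
  structure(
    list(phase = phase, optimizer = optimizer, lr_init = lr_init,
         lr_min = lr_min, momentum = momentum, epochs = epochs,
         batch_size = as.integer(batch_size),
         label_smoothing_eps = label_smoothing_eps,
         k_folds = as.integer(k_folds), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Stratified K-fold assignment
#'
#' Splits indices into `K` disjoint validation folds whose class
#' proportions match the full data within one sample per class, by
#' shuffling each class separately and dealing it into `K` chunks.
#'
#' @param labels class vector.
#' @param K number of folds.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return a list of `K` elements, each `list(train = <indices>,
#'   val = <indices>)`; validation folds are disjoint and cover all
#'   indices.
#' @export
stratified_kfold <- function(labels, K = 5, seed = 1L) {
  n <- length(labels)
  classes <- unique(labels)
  for (cl in classes) {
    if (sum(labels == cl) < K) {
      stopf("class %s has fewer samples (%d) than folds (%d)",
            cl, sum(labels == cl), K)
    }
  }
  val_folds <- replicate(K, integer(0), simplify = FALSE)
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      sizes <- rep(length(idx) %/% K, K)
      extra <- length(idx) %% K
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      at <- 0L
      for (k in seq_len(K)) {
        val_folds[[k]] <- c(val_folds[[k]], idx[at + seq_len(sizes[k])])
        at <- at + sizes[k]
      }
    }
  })
  lapply(val_folds, function(v) {
    v <- sort(v)
    list(train = setdiff(seq_len(n), v), val = v)
  })
}

#' Cosine learning-rate schedule
#'
#' `eta(t) = lr_min + (lr_init - lr_min) (1 + cos(pi t / T)) / 2`,
#' evaluated once per epoch: monotone nonincreasing from `lr_init` at
#' `t = 0` to `lr_min` at `t = T`.
#'
#' @param t epoch index in `[0, T]`.
#' @param config a [train_config()] supplying `lr_init`, `lr_min` and
#'   `epochs` (`T`).
#' @return the learning rate at epoch `t`.
#' @export
cosine_lr <- function(t, config) {
  T_ <- config$epochs
  if (any(t < 0 | t > T_)) stopf("epoch index must lie in [0, %d]", T_)
  config$lr_min + 0.5 * (config$lr_init - config$lr_min) * (1 + cos(pi * t / T_))
}

#' Label-smoothed cross-entropy
#'
#' Cross-entropy of predicted class probabilities against smoothed targets
#' `(1 - eps) * onehot + eps / n_classes`, averaged over the batch.
#'
#' @param probs `n x n_classes` matrix of probabilities; rows must sum
#'   to 1.
#' @param labels integer class labels (0-based).
#' @param eps smoothing parameter in `[0, 1)`.
#' @return scalar loss.
#' @export
smoothed_cross_entropy <- function(probs, labels, eps = 0.1) {
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6) || any(probs < -1e-12)) {
    stopf("rows of `probs` must be probability vectors")
  }
  tg <- smooth_targets(labels, ncol(probs), eps)
  -mean(rowSums(tg * log(pmax(probs, 1e-12))))
}

smooth_targets <- function(labels, n_classes, eps) {
  n <- length(labels)
  tg <- matrix(eps / n_classes, n, n_classes)
  tg[cbind(seq_len(n), as.integer(labels) + 1L)] <-
    1 - eps + eps / n_classes
  tg
}

## ---- optimizers -------------------------------------------------------

optimizer_init <- function(params, config) {
  zeros <- tree_map(function(p) array(0, dim(p) %||% length(p)), params)
  if (config$optimizer == "sgd") {
    list(kind = "sgd", v = zeros, momentum = config$momentum)
  } else {
    list(kind = "adam", m = zeros, v = zeros, t = 0L,
         beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  }
}

optimizer_step <- function(opt, params, grads, lr) {
  if (opt$kind == "sgd") {
    opt$v <- tree_map2(function(v, g) opt$momentum * v + g, opt$v, grads)
    params <- tree_map2(function(p, v) p - lr * v, params, opt$v)
  } else {
    opt$t <- opt$t + 1L
    opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g, opt$m, grads)
    opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2, opt$v, grads)
    c1 <- 1 - opt$beta1^opt$t
    c2 <- 1 - opt$beta2^opt$t
    mhat <- tree_map(function(m) m / c1, opt$m)
    vhat <- tree_map(function(v) v / c2, opt$v)
    upd <- tree_map2(function(m, v) m / (sqrt(v) + opt$eps), mhat, vhat)
    params <- tree_map2(function(p, u) p - lr * u, params, upd)
  }
  list(opt = opt, params = params)
}

## ---- core training loop -----------------------------------------------

#' Train a network on labelled epochs
#'
#' Minibatch training with the configured optimizer, cosine learning-rate
#' decay stepped per epoch, and label-smoothed cross-entropy. If a
#' validation set is supplied, per-epoch validation accuracy and AUC are
#' recorded in the returned log. Aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param network an `errp_network`.
#' @param x epochs, `(n, n_channels, n_samples)` array.
#' @param y integer labels (0/1).
#' @param config a [train_config()].
#' @param validation optional `list(x = , y = )` held-out data, never
#'   touched by the optimizer.
#' @return `list(network, log)` where `log` is a tibble with one row per
#'   epoch: `epoch`, `lr`, `train_loss`, `val_loss`, `val_accuracy`,
#'   `val_auc`.
#' @export
train_network <- function(network, x, y, config, validation = NULL) {
  stopifnot(inherits(network, "errp_network"), inherits(config, "train_config"))
  y <- as.integer(y)
  n <- dim(x)[1]
  if (length(y) != n) stopf("labels do not match the epoch count")
  if (config$epochs == 0L) {
    return(list(network = network, log = tibble::tibble(
      epoch = integer(), lr = numeric(), train_loss = numeric(),
      val_loss = numeric(), val_accuracy = numeric(), val_auc = numeric()
    )))
  }
  eps <- config$label_smoothing_eps
  opt <- optimizer_init(network$params, config)
  logs <- vector("list", config$epochs)
  with_seed(derive_seed(config$seed, "train-loop"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch - 1, config)
      perm <- sample(n)
      starts <- seq(1L, n, by = config$batch_size)
      total_loss <- 0
      for (s in starts) {
        bi <- perm[s:min(s + config$batch_size - 1L, n)]
        xb <- x[bi, , , drop = FALSE]
        yb <- y[bi]
        fwd <- network_forward(network, xb, training = TRUE, with_cache = TRUE)
        network$state <- fwd$state
        tg <- smooth_targets(yb, ncol(fwd$probs), eps)
        loss <- -mean(rowSums(tg * log(pmax(fwd$probs, 1e-12))))
        if (!is.finite(loss)) {
          stopf("training diverged: non-finite loss at epoch %d", epoch)
        }
        total_loss <- total_loss + loss * length(bi)
        dlogits <- (fwd$probs - tg) / length(bi)
        bwd <- network_backward(network, fwd$cache, dlogits)
        step <- optimizer_step(opt, network$params, bwd$dparams, lr)
        opt <- step$opt
        network$params <- step$params
      }
      row <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = total_loss / n,
        val_loss = NA_real_, val_accuracy = NA_real_, val_auc = NA_real_
      )
      if (!is.null(validation)) {
        vp <- network_forward(network, validation$x, training = FALSE)$probs
        row$val_loss <- smoothed_cross_entropy(vp, validation$y, eps)
        cell <- compute_metrics(vp[, 2], validation$y)
        row$val_accuracy <- cell$accuracy
        row$val_auc <- cell$auc
      }
      logs[[epoch]] <- row
    }
  })
  list(network = network, log = dplyr::bind_rows(logs))
}

## ---- pretraining with stratified CV and per-fold oversampling ---------

#' Pretrain with stratified K-fold cross-validation
#'
#' For each fold, the training partition alone is balanced with SVMSMOTE
#' (the validation partition is never oversampled, so no synthetic sample
#' can leak information about held-out epochs), a fresh network is built
#' and trained, and per-epoch validation metrics are recorded. The best
#' fold is the one with the highest final validation accuracy, ties broken
#' by lower final validation loss.
#'
#' @param source an [epoch_set()] of canonical training epochs.
#' @param model_cfg a [model_config()].
#' @param config a [train_config()] (pretrain phase by default).
#' @param oversample an [oversample_config()], or `NULL` to disable
#'   balancing.
#' @return an object of class `errp_cv`: per-fold networks, logs, fold
#'   indices and validation metrics, plus `best_fold`.
#' @export
pretrain <- function(source, model_cfg = model_config(),
                     config = train_config("pretrain"),
                     oversample = oversample_config()) {
  stopifnot(inherits(source, "epoch_set"))
  errp_log("info", "pretrain: n=%d, K=%d, optimizer=%s, lr=%g, epochs=%d, seed=%d",
           n_epochs(source), config$k_folds, config$optimizer, config$lr_init,
           config$epochs, config$seed)
  y <- source$info$label
  folds <- stratified_kfold(y, K = config$k_folds,
                            seed = derive_seed(config$seed, "folds"))
  fold_results <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    tr <- folds[[k]]$train
    va <- folds[[k]]$val
    xtr <- source$data[tr, , , drop = FALSE]
    ytr <- y[tr]
    if (!is.null(oversample) && length(unique(ytr)) == 2L &&
        sum(ytr == 0L) != sum(ytr == 1L)) {
      os_cfg <- oversample
      os_cfg$seed <- derive_seed(config$seed, "smote", k)
      fl <- svm_smote(flatten_epoch_array(xtr), ytr, os_cfg)
      xtr <- unflatten_epochs(fl$features)
      ytr <- fl$labels
    }
    net <- build_network(model_cfg, seed = derive_seed(config$seed, "init", k))
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, "fold", k)
    fit <- train_network(net, xtr, ytr, fold_cfg,
                         validation = list(x = source$data[va, , , drop = FALSE],
                                           y = y[va]))
    last <- fit$log[nrow(fit$log), ]
    fold_results[[k]] <- list(
      network = fit$network, log = fit$log,
      train_indices = tr, val_indices = va,
      n_augmented = length(ytr),
      val_accuracy = last$val_accuracy, val_auc = last$val_auc,
      val_loss = last$val_loss
    )
  }
  acc <- vapply(fold_results, function(f) f$val_accuracy, numeric(1))
  loss <- vapply(fold_results, function(f) f$val_loss, numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1) best <- best[which.min(loss[best])]
  structure(
    list(folds = fold_results, best_fold = best, model_config = model_cfg,
         train_config = config),
    class = "errp_cv"
  )
}

## flatten an (n, 2, 64) array the same way as flatten_for_oversampling
flatten_epoch_array <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 3, 2)), d[1], d[2] * d[3])
}

#' Best network of a cross-validation result
#' @param cv an `errp_cv` object.
#' @return the `errp_network` of the best fold.
#' @export
best_network <- function(cv) {
  stopifnot(inherits(cv, "errp_cv"))
  cv$folds[[cv$best_fold]]$network
}

#' @export
print.errp_cv <- function(x, ...) {
  acc <- vapply(x$folds, function(f) f$val_accuracy, numeric(1))
  cat(sprintf("<errp_cv> %d folds | val accuracy %s | best fold %d\n",
              length(x$folds),
              paste(sprintf("%.1f", acc), collapse = "/"), x$best_fold))
  invisible(x)
}

#' Fine-tune a pretrained network on target-task data
#'
#' Continues training of every weight (no freezing) on the target epochs
#' with the fine-tune optimizer settings (Adam at a learning rate ten
#' times below pretraining, cosine decay). With `epochs = 0` the input
#' network is returned unchanged. No internal validation split is made:
#' the fine-tuned model is meant to be tested on other participants.
#'
#' @param network a pretrained `errp_network`.
#' @param target an [epoch_set()] of the target participant's epochs.
#' @param config a [train_config()] (finetune phase by default).
#' @param oversample optional [oversample_config()] to balance the
#'   fine-tuning data; disabled by default.
#' @return the fine-tuned `errp_network` (final epoch).
#' @export
finetune <- function(network, target, config = train_config("finetune"),
                     oversample = NULL) {
  stopifnot(inherits(network, "errp_network"), inherits(target, "epoch_set"))
  errp_log("info", "finetune: n=%d, optimizer=%s, lr=%g, epochs=%d, seed=%d",
           n_epochs(target), config$optimizer, config$lr_init, config$epochs,
           config$seed)
  if (!identical(dim(target$data)[2:3],
                 c(network$config$n_channels, network$config$n_samples))) {
    stopf("target epochs do not match the network's input shape")
  }
  x <- target$data
  y <- target$info$label
  if (!is.null(oversample) && length(unique(y)) == 2L &&
      sum(y == 0L) != sum(y == 1L)) {
    fl <- svm_smote(flatten_epoch_array(x), y, oversample)
    x <- unflatten_epochs(fl$features)
    y <- fl$labels
  }
  train_network(network, x, y, config)$network
}

#' Tidy per-epoch training curves of a cross-validation result
#'
#' @param x an `errp_cv` object.
#' @param ... ignored.
#' @return a tibble with one row per (fold, epoch): learning rate, training
#'   loss and validation metrics.
#' @method tidy errp_cv
#' @export
tidy.errp_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$folds), function(k) {
    dplyr::mutate(x$folds[[k]]$log, fold = k, .before = 1)
  }))
}

#' One-row summary of a cross-validation result
#'
#' @param x an `errp_cv` object.
#' @param ... ignored.
#' @return a tibble with fold count, best fold, and mean/best validation
#'   accuracy and AUC.
#' @method glance errp_cv
#' @export
glance.errp_cv <- function(x, ...) {
  acc <- vapply(x$folds, function(f) f$val_accuracy, numeric(1))
  auc <- vapply(x$folds, function(f) f$val_auc, numeric(1))
  tibble::tibble(
    n_folds = length(x$folds), best_fold = x$best_fold,
    mean_val_accuracy = mean(acc), best_val_accuracy = acc[x$best_fold],
    mean_val_auc = mean(auc), best_val_auc = auc[x$best_fold]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot training curves of a cross-validation result
#'
#' @param object an `errp_cv` object.
#' @param ... ignored.
#' @return a ggplot object: training loss and validation accuracy per
#'   epoch, one line per fold.
#' @method autoplot errp_cv
#' @export
autoplot.errp_cv <- function(object, ...) {
  df <- tidy.errp_cv(object) |>
    tidyr::pivot_longer(c("train_loss", "val_accuracy"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(colour = "fold") +
    ggplot2::theme_minimal()
}
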