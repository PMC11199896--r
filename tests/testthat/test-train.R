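test_that("stratified folds preserve class proportions exactly", {
  labels <- rep(c(1L, 0L), c(20, 80))
  folds <- stratified_kfold(labels, K = 5, seed = 3)
  expect_length(folds, 5)
  all_val <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(all_val, seq_along(labels)) # union covers, disjoint
  for (f in folds) {
    expect_identical(sort(c(f$train, f$val)), seq_along(labels))
    expect_equal(sum(labels[f$val] == 1L), 4) # counting oracle: 20 / 5
    expect_equal(sum(labels[f$val] == 0L), 16)
  }
  ## proportions within one sample when counts do not divide evenly
  labels2 <- rep(c(1L, 0L), c(23, 81))
  folds2 <- stratified_kfold(labels2, K = 5, seed = 1)
  errs <- vapply(folds2, function(f) sum(labels2[f$val] == 1L), numeric(1))
  expect_true(all(abs(errs - 23 / 5) < 1))

  expect_identical(stratified_kfold(labels, 5, seed = 9),
                   stratified_kfold(labels, 5, seed = 9))
  expect_error(stratified_kfold(rep(c(1L, 0L), c(3, 90)), K = 5), "fewer samples")
})

test_that("the cosine schedule hits its endpoints and decreases monotonically", {
  cfg <- train_config("pretrain") # lr 1e-4, T = 200
  expect_equal(cosine_lr(0, cfg), 1e-4)
  expect_equal(cosine_lr(cfg$epochs, cfg), 0)
  expect_equal(cosine_lr(cfg$epochs / 2, cfg), (1e-4 + 0) / 2)
  lrs <- cosine_lr(0:cfg$epochs, cfg)
  expect_true(all(diff(lrs) <= 1e-15))
  expect_error(cosine_lr(cfg$epochs + 1, cfg), "must lie in")

  cfg2 <- train_config("pretrain", lr_min = 2e-5, epochs = 10)
  expect_equal(cosine_lr(10, cfg2), 2e-5)
  expect_equal(cosine_lr(5, cfg2), (1e-4 + 2e-5) / 2)
})

test_that("label-smoothed cross-entropy matches closed forms", {
  expect_equal(smoothed_cross_entropy(rbind(c(1, 0)), 0L, eps = 0), 0)
  expect_equal(smoothed_cross_entropy(rbind(c(0.5, 0.5)), 1L, eps = 0), log(2))
  expect_equal(smoothed_cross_entropy(rbind(c(0.7, 0.3)), 0L, eps = 0.1),
               -(0.95 * log(0.7) + 0.05 * log(0.3)))
  ## batch average
  p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(smoothed_cross_entropy(p, c(0L, 1L), eps = 0),
               mean(-log(c(0.8, 0.6))))
  expect_error(smoothed_cross_entropy(rbind(c(0.5, 0.2)), 0L), "probability")
})

test_that("phase presets carry the reference hyperparameters", {
  pre <- train_config("pretrain")
  expect_equal(pre$optimizer, "sgd")
  expect_equal(pre$lr_init, 1e-4)
  expect_equal(pre$momentum, 0.9)
  expect_equal(pre$epochs, 200L)
  expect_equal(pre$batch_size, 32L)
  expect_equal(pre$k_folds, 5L)
  ft <- train_config("finetune")
  expect_equal(ft$optimizer, "adam")
  expect_equal(ft$lr_init, 1e-5)
  expect_equal(ft$epochs, 100L)
  expect_error(train_config("pretrain", lr_init = 1e-5, lr_min = 1e-4), "lr_min")
})

test_that("training is reproducible and zero epochs is the identity", {
  es <- small_set(n_subjects = 1, n = 48, seed = 6)
  net <- build_network(model_config(), seed = 1)
  cfg <- quick_cfg(epochs = 2, seed = 11)
  f1 <- train_network(net, es$data, es$info$label, cfg)
  f2 <- train_network(net, es$data, es$info$label, cfg)
  expect_identical(f1$network$params, f2$network$params)
  expect_identical(f1$log, f2$log)

  f0 <- train_network(net, es$data, es$info$label, quick_cfg(epochs = 0))
  expect_identical(f0$network, net)
})

test_that("training reduces the loss on learnable data", {
  es <- small_set(n_subjects = 1, n = 128, seed = 7)
  net <- build_network(model_config(), seed = 2)
  fit <- train_network(net, es$data, es$info$label,
                       quick_cfg(epochs = 8, seed = 3, lr_init = 1e-3))
  expect_lt(fit$log$train_loss[8], fit$log$train_loss[1])
})

test_that("per-fold oversampling never leaks into validation", {
  es <- small_set(n_subjects = 1, n = 80, seed = 9)
  cv <- pretrain(es, config = quick_cfg(epochs = 2, seed = 5))
  expect_s3_class(cv, "errp_cv")
  expect_length(cv$folds, 5)
  for (f in cv$folds) {
    expect_length(intersect(f$train_indices, f$val_indices), 0)
    ## augmented training size: exactly two balanced classes of the
    ## training majority count
    n_maj <- sum(es$info$label[f$train_indices] == 0L)
    expect_equal(f$n_augmented, 2 * n_maj)
  }
  all_val <- sort(unlist(lapply(cv$folds, `[[`, "val_indices")))
  expect_identical(all_val, seq_len(n_epochs(es)))
  ## best fold maximizes validation accuracy
  acc <- vapply(cv$folds, `[[`, numeric(1), "val_accuracy")
  expect_equal(acc[cv$best_fold], max(acc))
})

test_that("tidy/glance/autoplot summarise a cross-validation result", {
  es <- small_set(n_subjects = 1, n = 60, seed = 10)
  cv <- pretrain(es, config = quick_cfg(epochs = 2, seed = 2))
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5 * 2)
  expect_true(all(c("fold", "epoch", "lr", "train_loss", "val_accuracy") %in% names(td)))
  gl <- glance(cv)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$best_fold, cv$best_fold)
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
})

test_that("fine-tuning updates weights and honours a zero budget", {
  es <- small_set(n_subjects = 1, n = 48, seed = 12)
  net <- build_network(model_config(), seed = 3)
  same <- finetune(net, es, quick_cfg("finetune", epochs = 0))
  expect_identical(same$params, net$params)

  ft <- finetune(net, es, quick_cfg("finetune", epochs = 2, seed = 4))
  expect_false(identical(ft$params$fc2$W, net$params$fc2$W))
  expect_false(identical(ft$params$fe_e$conv1$W, net$params$fe_e$conv1$W))

  wrong <- small_set(n_subjects = 1, n = 4)
  wrong$data <- wrong$data[, , 1:32, drop = FALSE]
  expect_error(finetune(net, wrong), "input shape")
})

test_that("fine-tuning a pretrained network reduces the target loss", {
  pair <- generate_task_pair(
    synth_config(n_subjects = 2, epochs_per_subject = 100,
                 sessions_per_subject = 1, task = "speller", seed = 31),
    synth_config(n_subjects = 1, epochs_per_subject = 100,
                 sessions_per_subject = 1, task = "cursor", seed = 31,
                 task_shift = list(amplitude_scale = 0.8,
                                   latency_offset_s = 0.03,
                                   noise_multiplier = 1.2))
  )
  cv <- pretrain(pair$source, config = quick_cfg(epochs = 10, seed = 1, k_folds = 2))
  pre <- best_network(cv)
  eps <- 0.1
  loss_before <- smoothed_cross_entropy(
    forward(pre, pair$target$data), pair$target$info$label, eps)
  ft <- finetune(pre, pair$target, train_config("finetune", seed = 2))
  loss_after <- smoothed_cross_entropy(
    forward(ft, pair$target$data), pair$target$info$label, eps)
  expect_lt(loss_after, loss_before)
})
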