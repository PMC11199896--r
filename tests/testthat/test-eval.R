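test_that("metric cells match hand-derived and brute-force values", {
  cell <- compute_metrics(c(0.9, 0.4, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(cell$accuracy, 75)
  expect_equal(cell$error_rate, 50)
  expect_equal(cell$correct_rate, 100)
  expect_equal(cell$auc, 100)
  expect_equal(cell$auc, auc_bruteforce(c(0.9, 0.4, 0.3, 0.2), c(1, 1, 0, 0)))

  perfect <- compute_metrics(c(0.99, 0.98, 0.01, 0.02), c(1, 1, 0, 0))
  expect_equal(unlist(perfect[c("accuracy", "auc", "error_rate", "correct_rate")]),
               c(accuracy = 100, auc = 100, error_rate = 100, correct_rate = 100))

  ties <- compute_metrics(rep(0.4, 10), rep(c(1, 0), 5))
  expect_equal(ties$auc, 50)

  expect_warning(one <- compute_metrics(c(0.2, 0.8), c(0, 0)), "single-class")
  expect_true(is.na(one$auc))
  expect_error(compute_metrics(c(1.5, 0), c(1, 0)), "\\[0, 1\\]")
})

test_that("midrank AUC equals brute-force concordance on random batches", {
  set.seed(42)
  for (r in 1:20) {
    n <- sample(20:400, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2) # coarse grid forces ties
    expect_equal(compute_metrics(scores, labels)$auc,
                 auc_bruteforce(scores, labels))
  }
})

test_that("AUC agrees with an independent implementation", {
  set.seed(7)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.25)
  ours <- compute_metrics(scores, labels)$auc
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("accuracy is the prevalence-weighted mean of the class recalls", {
  set.seed(8)
  for (r in 1:10) {
    n <- 150
    labels <- rbinom(n, 1, 0.2)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    cell <- compute_metrics(runif(n), labels)
    weighted <- (cell$error_rate * cell$n_error + cell$correct_rate * cell$n_correct) /
      (cell$n_error + cell$n_correct)
    expect_equal(cell$accuracy, weighted)
  }
})

test_that("the LDA baseline is Bayes-like on Gaussian classes and null on noise", {
  make_set <- function(sep, n = 450, seed = 1) {
    set.seed(seed)
    labels <- rep(c(1L, 0L), c(n / 3, n - n / 3))
    data <- array(rnorm(n * 2 * 64, sd = 1), c(n, 2, 64))
    data[labels == 1L, , 10:20] <- data[labels == 1L, , 10:20] + sep
    epoch_set(data, tibble::tibble(label = labels, subject = "s01",
                                   session = "session1", task = "t"))
  }
  tr <- make_set(1.5, seed = 1)
  te <- make_set(1.5, seed = 2)
  cell <- lda_baseline(tr, te)
  expect_gte(cell$accuracy, 95)

  ## no-signal null: AUC close to chance over replicates
  aucs <- vapply(1:10, function(r) {
    lda_baseline(make_set(0, n = 300, seed = 20 + r),
                 make_set(0, n = 300, seed = 40 + r))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 50), 5)

  ## deterministic
  expect_identical(lda_baseline(tr, te), lda_baseline(tr, te))
  one_class <- tr[tr$info$label == 0L]
  expect_error(lda_baseline(one_class, te), "both classes")
})

test_that("the LDA baseline agrees with the reference implementation", {
  set.seed(3)
  n <- 300
  labels <- rep(c(1L, 0L), c(100, 200))
  ## low-dimensional structure keeps the pooled covariance well-conditioned
  base <- matrix(rnorm(n * 2 * 64, sd = 0.5), n, 128)
  base[labels == 1L, 1:10] <- base[labels == 1L, 1:10] + 1
  tr_idx <- c(1:70, 101:240)
  te_idx <- c(71:100, 241:300)
  as_set <- function(idx) {
    epoch_set(array(base[idx, ], c(length(idx), 2, 64))[, , ],
              tibble::tibble(label = labels[idx], subject = "s",
                             session = "x", task = "t"))
  }
  ## errpnet stores epochs channel-major; rebuild identically for MASS
  tr <- as_set(tr_idx)
  te <- as_set(te_idx)
  ours <- lda_baseline(tr, te)
  ref <- MASS::lda(flatten_for_oversampling(tr)$features,
                   grouping = factor(labels[tr_idx]))
  ref_post <- predict(ref, flatten_for_oversampling(te)$features)$posterior[, "1"]
  theirs <- compute_metrics(ref_post, labels[te_idx])
  expect_equal(ours$accuracy, theirs$accuracy, tolerance = 1e-6)
  expect_equal(ours$auc, theirs$auc, tolerance = 1e-6)
})

test_that("scenario grids have the documented structure", {
  es <- small_set(n_subjects = 3, n = 40, sessions = 2, seed = 14)
  cfg <- quick_cfg(epochs = 1, seed = 1)

  loso <- run_loso(es, config = cfg, session = "session1")
  expect_s3_class(loso, "metrics_report")
  expect_equal(nrow(loso), 3)
  expect_setequal(loso$test_unit, c("s01", "s02", "s03"))

  oto <- run_one_train_one_test(es, config = quick_cfg("finetune", epochs = 1),
                                session = "session1")
  expect_equal(nrow(oto), 3 * 2)
  expect_true(all(oto$train_unit != oto$test_unit))

  within <- run_within_session(es[es$info$subject != "s03"], config = cfg)
  expect_equal(nrow(within), 2 * 2)

  cross <- run_cross_session(es[es$info$subject == "s01"], config = cfg)
  expect_equal(nrow(cross), 2)
  expect_setequal(cross$train_unit, c("s01/session1", "s01/session2"))

  summ <- metrics_summary(oto)
  expect_equal(nrow(summ), 3)
  expect_true(all(summ$n_cells == 2))
  tab <- report_table(oto)
  expect_true(any(grepl("Average", tab)))
  expect_s3_class(ggplot2::autoplot(loso), "ggplot")
})

test_that("no scenario lets test epochs reach its training partitions", {
  es <- small_set(n_subjects = 3, n = 40, sessions = 2, seed = 15)
  cfg <- quick_cfg(epochs = 1, seed = 2)

  loso <- run_loso(es, config = cfg, session = "session1")
  prov <- attr(loso, "provenance")
  for (i in seq_along(prov)) {
    expect_length(intersect(prov[[i]]$train, prov[[i]]$test), 0)
    held_out <- loso$test_unit[i]
    expect_false(any(es$info$subject[prov[[i]]$train] == held_out))
  }

  within <- run_within_session(es[es$info$subject == "s01"], config = cfg)
  for (cell in attr(within, "provenance")) {
    for (k in seq_along(cell$train)) {
      expect_length(intersect(cell$train[[k]], cell$test[[k]]), 0)
    }
  }

  cross <- run_cross_session(es[es$info$subject == "s02"], config = cfg)
  for (cell in attr(cross, "provenance")) {
    expect_length(intersect(cell$train, cell$test), 0)
    expect_length(unique(es$info$session[cell$train]), 1)
    expect_false(any(es$info$session[cell$test] %in%
                       es$info$session[cell$train]))
  }
})

test_that("cross-task transfer reuses one pretrained checkpoint per column", {
  pair <- generate_task_pair(
    synth_config(n_subjects = 2, epochs_per_subject = 50,
                 sessions_per_subject = 1, task = "speller", seed = 5),
    synth_config(n_subjects = 2, epochs_per_subject = 50,
                 sessions_per_subject = 1, task = "cursor", seed = 5)
  )
  rep <- run_cross_task(pair$source, pair$target,
                        pretrain_cfg = quick_cfg(epochs = 1, seed = 1),
                        finetune_cfg = quick_cfg("finetune", epochs = 1, seed = 1))
  expect_s3_class(attr(rep, "pretrained_network"), "errp_network")
  df <- tibble::as_tibble(rep)
  expect_setequal(unique(df$model), c("pretrained", "non_pretrained"))
  ## paired baseline: same grid cells in both blocks
  pre <- df[df$model == "pretrained", c("train_unit", "test_unit")]
  base <- df[df$model == "non_pretrained", c("train_unit", "test_unit")]
  expect_equal(dplyr::arrange(pre, train_unit, test_unit),
               dplyr::arrange(base, train_unit, test_unit))
  expect_error(run_cross_task(pair$source, pair$source), "distinct tasks")

  ## scenario dispatcher reaches the same runners
  spec <- scenario_spec("leave_one_subject_out", pair$target,
                        train_cfg = quick_cfg(epochs = 1))
  expect_s3_class(run_scenario(spec), "metrics_report")
  expect_error(scenario_spec("bogus", pair$target), "unknown scenario")
})

test_that("scenario output is reproducible under a fixed seed", {
  es <- small_set(n_subjects = 2, n = 60, sessions = 1, seed = 16)
  a <- run_loso(es, config = quick_cfg(epochs = 1, seed = 7))
  b <- run_loso(es, config = quick_cfg(epochs = 1, seed = 7))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("more background noise never helps within-session accuracy", {
  ## non-strict monotonicity (1-point tolerance) of mean accuracy in
  ## noise_sd, averaged over 10 seeded replicates at a small budget
  mean_acc <- function(noise_sd) {
    accs <- vapply(1:10, function(r) {
      es <- generate_epochset(synth_config(
        n_subjects = 1, epochs_per_subject = 50, sessions_per_subject = 1,
        noise_sd = noise_sd, seed = 200 + r))
      rep <- run_within_session(es, config = quick_cfg(epochs = 5, seed = r))
      rep$accuracy
    }, numeric(1))
    mean(accs)
  }
  low <- mean_acc(0.002)
  high <- mean_acc(0.02)
  expect_gte(low + 1, high)
})
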