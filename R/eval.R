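#' Classification metrics for one evaluation cell
#'
#' Computes, on the percent scale used throughout the reporting tables:
#' accuracy at the 0.5 threshold on the error-class probability, the
#' error-class detection rate (recall on label 1), the correct-class
#' detection rate (recall on label 0) and the AUC — the probability that a
#' random error epoch outscores a random correct epoch, ties credited 1/2
#' (computed by midrank, identical to brute-force pair counting).
#'
#' @param scores per-sample error-class probabilities in `[0, 1]`.
#' @param labels binary labels (1 = error).
#' @param threshold decision threshold on the error-class probability.
#' @return a one-row tibble: `accuracy`, `auc`, `error_rate`,
#'   `correct_rate`, `n_error`, `n_correct` (rates in percent). With
#'   single-class labels the AUC is `NA` with a warning.
#' @export
#' @examples
#' compute_metrics(c(0.9, 0.4, 0.3, 0.2), c(1, 1, 0, 0))
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (any(scores < -1e-9 | scores > 1 + 1e-9)) stopf("scores must lie in [0, 1]")
  pred <- as.integer(scores > threshold)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  err_rate <- if (n1 > 0) 100 * sum(pred == 1L & labels == 1L) / n1 else NA_real_
  cor_rate <- if (n0 > 0) 100 * sum(pred == 0L & labels == 0L) / n0 else NA_real_
  acc <- 100 * mean(pred == labels)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined for single-class labels; reporting NA")
    auc <- NA_real_
  } else {
    r <- rank(scores, ties.method = "average")
    auc <- 100 * (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tibble::tibble(accuracy = acc, auc = auc, error_rate = err_rate,
                 correct_rate = cor_rate, n_error = n1, n_correct = n0)
}

## score an epoch subset with a network (inference mode)
score_epochs <- function(network, set, idx = seq_len(n_epochs(set))) {
  network_forward(network, set$data[idx, , , drop = FALSE])$probs[, 2]
}

## CV-select the best network for a training subset of `set`
fit_cv_best <- function(set, idx, model_cfg, config, oversample) {
  cv <- pretrain(set[idx], model_cfg = model_cfg, config = config,
                 oversample = oversample)
  best_network(cv)
}

new_metrics_report <- function(rows, scenario, provenance = NULL) {
  out <- dplyr::bind_rows(rows)
  out <- tibble::new_tibble(out, class = "metrics_report")
  attr(out, "scenario") <- scenario
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> scenario: %s\n", attr(x, "scenario") %||% "?"))
  NextMethod()
  invisible(x)
}

#' Within-session evaluation
#'
#' For every subject x session cell, runs stratified K-fold
#' cross-validation entirely inside that cell: each fold's training
#' partition is balanced with SVMSMOTE, a fresh network is trained, and
#' the held-out fold is scored; the cell's metrics are the unweighted mean
#' over folds.
#'
#' @param target a canonical [epoch_set()].
#' @param model_cfg a [model_config()].
#' @param config a [train_config()]; pretrain-phase optimizer settings by
#'   default.
#' @param oversample an [oversample_config()] or `NULL`.
#' @param sessions optional character vector restricting the sessions
#'   evaluated.
#' @return a `metrics_report` tibble, one row per (subject, session).
#' @export
run_within_session <- function(target, model_cfg = model_config(),
                               config = train_config("pretrain"),
                               oversample = oversample_config(),
                               sessions = NULL) {
  stopifnot(inherits(target, "epoch_set"))
  cells <- dplyr::distinct(target$info[c("subject", "session")])
  if (!is.null(sessions)) cells <- cells[cells$session %in% sessions, ]
  rows <- list()
  prov <- list()
  for (i in seq_len(nrow(cells))) {
    subj <- cells$subject[i]
    sess <- cells$session[i]
    idx <- which(target$info$subject == subj & target$info$session == sess)
    sub <- target[idx]
    cv <- pretrain(sub, model_cfg = model_cfg, config = config,
                   oversample = oversample)
    fold_cells <- lapply(cv$folds, function(f) {
      sc <- score_epochs(f$network, sub, f$val_indices)
      compute_metrics(sc, sub$info$label[f$val_indices])
    })
    cell <- dplyr::summarise(dplyr::bind_rows(fold_cells),
                             dplyr::across(c("accuracy", "auc", "error_rate",
                                             "correct_rate"), mean),
                             n_error = sum(.data$n_error),
                             n_correct = sum(.data$n_correct))
    rows[[i]] <- dplyr::mutate(cell,
                               train_unit = paste(subj, sess, sep = "/"),
                               test_unit = paste(subj, sess, sep = "/"),
                               .before = 1)
    prov[[i]] <- list(cell = rows[[i]]$test_unit,
                      train = lapply(cv$folds, function(f) idx[f$train_indices]),
                      test = lapply(cv$folds, function(f) idx[f$val_indices]))
  }
  new_metrics_report(rows, "within_session", prov)
}

#' Cross-session evaluation
#'
#' Per subject and ordered session pair: the model is selected by
#' stratified K-fold cross-validation on the training session and tested
#' on every epoch of the other session. Both directions are reported.
#'
#' @inheritParams run_within_session
#' @return a `metrics_report`, one row per (subject, train session, test
#'   session).
#' @export
run_cross_session <- function(target, model_cfg = model_config(),
                              config = train_config("pretrain"),
                              oversample = oversample_config()) {
  stopifnot(inherits(target, "epoch_set"))
  rows <- list()
  prov <- list()
  for (subj in unique(target$info$subject)) {
    sessions <- unique(target$info$session[target$info$subject == subj])
    if (length(sessions) < 2) {
      stopf("subject %s has fewer than two sessions", subj)
    }
    for (tr_sess in sessions) for (te_sess in setdiff(sessions, tr_sess)) {
      tr_idx <- which(target$info$subject == subj & target$info$session == tr_sess)
      te_idx <- which(target$info$subject == subj & target$info$session == te_sess)
      net <- fit_cv_best(target, tr_idx, model_cfg, config, oversample)
      sc <- score_epochs(net, target, te_idx)
      cell <- compute_metrics(sc, target$info$label[te_idx])
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        cell,
        train_unit = paste(subj, tr_sess, sep = "/"),
        test_unit = paste(subj, te_sess, sep = "/"), .before = 1)
      prov[[length(prov) + 1L]] <- list(train = tr_idx, test = te_idx)
    }
  }
  new_metrics_report(rows, "cross_session", prov)
}

#' Leave-one-subject-out evaluation
#'
#' Within one session, each subject in turn is held out entirely; the
#' remaining subjects' data is used for stratified K-fold
#' cross-validation (pretrain-phase optimizer settings) and the best fold
#' model is tested on the held-out subject.
#'
#' @inheritParams run_within_session
#' @param session the session evaluated (default: first session present).
#' @return a `metrics_report`, one row per held-out subject.
#' @export
run_loso <- function(target, model_cfg = model_config(),
                     config = train_config("pretrain"),
                     oversample = oversample_config(),
                     session = NULL) {
  stopifnot(inherits(target, "epoch_set"))
  session <- session %||% sort(unique(target$info$session))[1]
  in_sess <- target$info$session == session
  subjects <- unique(target$info$subject[in_sess])
  if (length(subjects) < 2) stopf("leave-one-subject-out needs at least 2 subjects")
  rows <- list()
  prov <- list()
  for (subj in subjects) {
    tr_idx <- which(in_sess & target$info$subject != subj)
    te_idx <- which(in_sess & target$info$subject == subj)
    net <- fit_cv_best(target, tr_idx, model_cfg, config, oversample)
    sc <- score_epochs(net, target, te_idx)
    cell <- compute_metrics(sc, target$info$label[te_idx])
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      cell, train_unit = paste0("all-but-", subj), test_unit = subj,
      .before = 1)
    prov[[length(prov) + 1L]] <- list(train = tr_idx, test = te_idx)
  }
  new_metrics_report(rows, "leave_one_subject_out", prov)
}

#' One-train-one-test evaluation
#'
#' A randomly initialized model is trained on a single subject's data
#' (stratified K-fold model selection with fine-tune-phase optimizer
#' settings) and tested separately on every other subject, giving an
#' `n x (n - 1)` grid.
#'
#' @inheritParams run_within_session
#' @param session optional session filter; by default all sessions are
#'   pooled.
#' @return a `metrics_report`, one row per (train subject, test subject)
#'   ordered pair.
#' @export
run_one_train_one_test <- function(target, model_cfg = model_config(),
                                   config = train_config("finetune"),
                                   oversample = oversample_config(),
                                   session = NULL) {
  stopifnot(inherits(target, "epoch_set"))
  keep <- if (is.null(session)) rep(TRUE, n_epochs(target)) else
    target$info$session %in% session
  subjects <- unique(target$info$subject[keep])
  if (length(subjects) < 2) stopf("one-train-one-test needs at least 2 subjects")
  rows <- list()
  prov <- list()
  for (tr_subj in subjects) {
    tr_idx <- which(keep & target$info$subject == tr_subj)
    net <- fit_cv_best(target, tr_idx, model_cfg, config, oversample)
    for (te_subj in setdiff(subjects, tr_subj)) {
      te_idx <- which(keep & target$info$subject == te_subj)
      sc <- score_epochs(net, target, te_idx)
      cell <- compute_metrics(sc, target$info$label[te_idx])
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        cell, train_unit = tr_subj, test_unit = te_subj, .before = 1)
      prov[[length(prov) + 1L]] <- list(train = tr_idx, test = te_idx)
    }
  }
  new_metrics_report(rows, "one_train_one_test", prov)
}

#' Cross-task transfer evaluation
#'
#' Pretrains on the source task (stratified K-fold, best fold model), then
#' for each target subject fine-tunes a copy of that single pretrained
#' checkpoint on the subject's data and tests it on every remaining
#' subject. Optionally pairs each column with the non-pretrained baseline
#' (one-train-one-test from random initialization under the same
#' fine-tune budget), reported in the `model` column for per-column
#' comparison.
#'
#' @param source source-task [epoch_set()] (distinct task identifier).
#' @param target target-task [epoch_set()].
#' @param model_cfg a [model_config()].
#' @param pretrain_cfg a [train_config()] for the pretraining stage.
#' @param finetune_cfg a [train_config()] for fine-tuning.
#' @param oversample an [oversample_config()] or `NULL`.
#' @param baseline if `TRUE`, also compute the non-pretrained baseline
#'   grid.
#' @param session optional session filter on the target.
#' @return a `metrics_report` with a `model` column
#'   (`"pretrained"` / `"non_pretrained"`); attribute `"pretrained_network"`
#'   carries the shared checkpoint.
#' @export
run_cross_task <- function(source, target, model_cfg = model_config(),
                           pretrain_cfg = train_config("pretrain"),
                           finetune_cfg = train_config("finetune"),
                           oversample = oversample_config(),
                           baseline = TRUE, session = NULL) {
  stopifnot(inherits(source, "epoch_set"), inherits(target, "epoch_set"))
  if (any(source$info$task %in% target$info$task)) {
    stopf("source and target must come from distinct tasks")
  }
  cv <- pretrain(source, model_cfg = model_cfg, config = pretrain_cfg,
                 oversample = oversample)
  pre_net <- best_network(cv)
  keep <- if (is.null(session)) rep(TRUE, n_epochs(target)) else
    target$info$session %in% session
  subjects <- unique(target$info$subject[keep])
  rows <- list()
  prov <- list()
  for (ft_subj in subjects) {
    ft_idx <- which(keep & target$info$subject == ft_subj)
    net <- finetune(pre_net, target[ft_idx], config = finetune_cfg)
    for (te_subj in setdiff(subjects, ft_subj)) {
      te_idx <- which(keep & target$info$subject == te_subj)
      sc <- score_epochs(net, target, te_idx)
      cell <- compute_metrics(sc, target$info$label[te_idx])
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        cell, model = "pretrained", train_unit = ft_subj,
        test_unit = te_subj, .before = 1)
      prov[[length(prov) + 1L]] <- list(train = ft_idx, test = te_idx,
                                        model = "pretrained")
    }
  }
  if (baseline) {
    oto <- run_one_train_one_test(target, model_cfg = model_cfg,
                                  config = finetune_cfg,
                                  oversample = oversample, session = session)
    oto <- dplyr::mutate(tibble::as_tibble(oto), model = "non_pretrained",
                         .before = 1)
    rows <- c(rows, list(oto))
  }
  out <- new_metrics_report(rows, "cross_task", prov)
  attr(out, "pretrained_network") <- pre_net
  out
}

#' Marginal means of a metrics report
#'
#' Unweighted column means (per training unit), matching the "Average"
#' rows of the standard reporting tables.
#'
#' @param report a `metrics_report`.
#' @return a tibble of per-train-unit means of all metric columns, split
#'   by `model` when that column is present.
#' @export
metrics_summary <- function(report) {
  groups <- intersect(c("model", "train_unit"), names(report))
  tibble::as_tibble(report) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(dplyr::across(c("accuracy", "auc", "error_rate",
                                     "correct_rate"), mean),
                     n_cells = dplyr::n(), .groups = "drop")
}

#' Render a metrics grid as an aligned text table
#'
#' @param report a `metrics_report`.
#' @param metric metric column to tabulate.
#' @param digits decimals shown.
#' @return a character vector of table lines (invisibly printed with
#'   `cat`).
#' @export
report_table <- function(report, metric = "accuracy", digits = 2) {
  df <- tibble::as_tibble(report)
  if ("model" %in% names(df)) df <- df[df$model == df$model[1], ]
  wide <- tidyr::pivot_wider(
    df[c("train_unit", "test_unit", metric)],
    names_from = "train_unit", values_from = dplyr::all_of(metric)
  )
  mat <- as.matrix(wide[-1])
  body <- matrix(ifelse(is.na(mat), "-", formatC(mat, digits = digits, format = "f")),
                 nrow(mat), ncol(mat))
  avg <- formatC(colMeans(mat, na.rm = TRUE), digits = digits, format = "f")
  tab <- rbind(cbind(c(wide$test_unit, "Average"), rbind(body, avg)))
  tab <- rbind(c("test\\train", colnames(mat)), tab)
  widths <- apply(nchar(tab), 2, max)
  lines <- apply(tab, 1, function(r) {
    paste(mapply(formatC, r, width = widths, MoreArgs = list(flag = "-")),
          collapse = "  ")
  })
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Linear discriminant baseline
#'
#' Reference comparator: a linear discriminant with pooled covariance
#' (pseudo-inverse when singular) on the flattened 128-dimensional epochs,
#' class priors estimated from the training data, scored by the posterior
#' probability of the error class.
#'
#' @param train,test canonical [epoch_set()]s; training data must contain
#'   both classes.
#' @return a one-row metrics tibble as from [compute_metrics()].
#' @export
lda_baseline <- function(train, test) {
  ftr <- flatten_for_oversampling(train)
  fte <- flatten_for_oversampling(test)
  y <- ftr$labels
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  X0 <- ftr$features[y == 0L, , drop = FALSE]
  X1 <- ftr$features[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S <- ((n0 - 1) * stats::cov(X0) + (n1 - 1) * stats::cov(X1)) / (n0 + n1 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) MASS::ginv(S))
  w <- Sinv %*% (mu1 - mu0)
  b <- -0.5 * (mu1 + mu0) %*% w + log(n1 / n0)
  z <- fte$features %*% w + as.numeric(b)
  scores <- 1 / (1 + exp(-z))
  compute_metrics(as.numeric(scores), fte$labels)
}

#' Scenario specification and dispatcher
#'
#' Declarative front-end over the five protocol runners, used by the
#' command-line interface.
#'
#' @param kind one of `"within_session"`, `"cross_session"`,
#'   `"leave_one_subject_out"`, `"one_train_one_test"`, `"cross_task"`.
#' @param target target [epoch_set()].
#' @param source source [epoch_set()] (cross-task only).
#' @param model_cfg,train_cfg,finetune_cfg,oversample configurations
#'   forwarded to the runner.
#' @param session optional session filter.
#' @return `scenario_spec` returns the spec object; `run_scenario` the
#'   runner's `metrics_report`.
#' @export
scenario_spec <- function(kind, target, source = NULL,
                          model_cfg = model_config(),
                          train_cfg = NULL, finetune_cfg = NULL,
                          oversample = oversample_config(),
                          session = NULL) {
  kinds <- c("within_session", "cross_session", "leave_one_subject_out",
             "one_train_one_test", "cross_task")
  if (!kind %in% kinds) stopf("unknown scenario kind: %s", kind)
  if (kind == "cross_task" && is.null(source)) stopf("cross_task needs a source set")
  structure(list(kind = kind, target = target, source = source,
                 model_cfg = model_cfg, train_cfg = train_cfg,
                 finetune_cfg = finetune_cfg, oversample = oversample,
                 session = session),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param spec a `scenario_spec`.
#' @export
run_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  switch(
    spec$kind,
    within_session = run_within_session(
      spec$target, spec$model_cfg,
      spec$train_cfg %||% train_config("pretrain"), spec$oversample,
      sessions = spec$session),
    cross_session = run_cross_session(
      spec$target, spec$model_cfg,
      spec$train_cfg %||% train_config("pretrain"), spec$oversample),
    leave_one_subject_out = run_loso(
      spec$target, spec$model_cfg,
      spec$train_cfg %||% train_config("pretrain"), spec$oversample,
      session = spec$session),
    one_train_one_test = run_one_train_one_test(
      spec$target, spec$model_cfg,
      spec$train_cfg %||% train_config("finetune"), spec$oversample,
      session = spec$session),
    cross_task = run_cross_task(
      spec$source, spec$target, spec$model_cfg,
      spec$train_cfg %||% train_config("pretrain"),
      spec$finetune_cfg %||% train_config("finetune"),
      spec$oversample, session = spec$session)
  )
}

#' Plot a metrics report as an accuracy grid
#'
#' @param object a `metrics_report`.
#' @param metric metric column to display.
#' @param ... ignored.
#' @return a ggplot tile map, one tile per (train unit, test unit) cell.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, metric = "accuracy", ...) {
  df <- tibble::as_tibble(object)
  if ("model" %in% names(df)) df <- df[df$model == df$model[1], ]
  ggplot2::ggplot(df, ggplot2::aes(.data$train_unit, .data$test_unit,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data[[metric]])),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "training unit", y = "test unit", fill = metric,
                  title = attr(object, "scenario")) +
    ggplot2::theme_minimal()
}
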