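#' SVMSMOTE oversampling configuration
#'
#' Defaults follow the reference implementation of the technique:
#' 5 minority neighbors for interpolation, 10 neighbors for danger-zone
#' estimation, an RBF-kernel SVM with regularization 1, and extrapolation
#' step 0.5.
#'
#' @param k_neighbors minority neighbors used to synthesize samples; must
#'   be smaller than the minority class count.
#' @param m_neighbors neighbors (over all samples) used to classify each
#'   minority support vector as noise / danger / safe.
#' @param svm_regularization SVM cost parameter.
#' @param extrapolation_step upper bound of the extrapolation coefficient,
#'   in `[0, 1]`.
#' @param seed integer seed making the synthesis deterministic.
#' @return an object of class `oversample_config`.
#' @export
oversample_config <- function(k_neighbors = 5, m_neighbors = 10,
                              svm_regularization = 1,
                              extrapolation_step = 0.5, seed = 1L) {
  if (k_neighbors < 1 || m_neighbors < 1) stopf("neighbor counts must be positive")
  if (svm_regularization <= 0) stopf("svm_regularization must be positive")
  if (extrapolation_step < 0 || extrapolation_step > 1) {
    stopf("extrapolation_step must lie in [0, 1]")
  }
  structure(
    list(k_neighbors = as.integer(k_neighbors),
         m_neighbors = as.integer(m_neighbors),
         svm_regularization = svm_regularization,
         extrapolation_step = extrapolation_step,
         seed = as.integer(seed)),
    class = "oversample_config"
  )
}

#' Flatten canonical epochs for oversampling
#'
#' Row `i` of the feature matrix is epoch `i` flattened channel-major:
#' element `(c, t)` (0-based) maps to column `c * 64 + t`. The inverse,
#' [unflatten_epochs()], reconstructs the `(2, 64)` epochs exactly.
#'
#' @param x a canonical [epoch_set()].
#' @return a list with `features` (n x 128 matrix) and `labels` (integer
#'   vector).
#' @export
flatten_for_oversampling <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  if (!is_canonical(x)) stopf("epochs must be canonical (2, 64)")
  d <- dim(x$data)
  features <- matrix(aperm(x$data, c(1, 3, 2)), d[1], d[2] * d[3])
  list(features = features, labels = x$info$label)
}

#' @rdname flatten_for_oversampling
#' @param features an `n x 128` matrix produced by
#'   [flatten_for_oversampling()] (possibly with synthetic rows appended).
#' @return `unflatten_epochs` returns an `(n, 2, 64)` array.
#' @export
unflatten_epochs <- function(features) {
  if (ncol(features) != 128L) stopf("expected 128 columns (2 x 64 epochs)")
  arr <- array(features, c(nrow(features), 64L, 2L))
  aperm(arr, c(1, 3, 2))
}

## k smallest entries (indices) of each row of a distance matrix,
## excluding entries marked Inf
knn_from_dist <- function(d2, k) {
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

#' SVM-guided synthetic minority oversampling (SVMSMOTE)
#'
#' Balances a binary dataset by synthesizing minority samples near the
#' class boundary. An SVM is fitted to the data and its minority-class
#' support vectors become seeds. Seeds whose `m_neighbors`-neighborhood is
#' majority-dominated (the danger zone) generate samples by interpolation
#' toward a random one of their `k_neighbors` nearest minority neighbors;
#' safe seeds extrapolate away from the neighbor by at most
#' `extrapolation_step`; seeds whose whole neighborhood is majority are
#' treated as noise and skipped. Original rows are preserved verbatim and
#' first; the majority class is untouched; output classes are exactly
#' balanced.
#'
#' @param features `n x d` numeric matrix.
#' @param labels length-`n` binary vector (0/1).
#' @param config an [oversample_config()].
#' @return a list with `features`, `labels`, and attributes on `features`:
#'   `synthetic_mode` (per synthetic row, `"interpolation"` or
#'   `"extrapolation"`) and `svm` (the fitted boundary model).
#' @export
svm_smote <- function(features, labels, config = oversample_config()) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stopf("both classes must be present")
  counts <- table(factor(labels, levels = classes))
  minority <- classes[which.min(counts)]
  majority <- classes[which.max(counts)]
  n_min <- sum(labels == minority)
  n_maj <- sum(labels == majority)
  if (n_min == n_maj) {
    return(list(features = features, labels = labels))
  }
  if (n_min <= config$k_neighbors) {
    stopf("minority count (%d) must exceed k_neighbors (%d)",
          n_min, config$k_neighbors)
  }
  fit <- e1071::svm(x = features, y = factor(labels, levels = classes),
                    kernel = "radial", cost = config$svm_regularization,
                    scale = FALSE)
  sv_rows <- fit$index
  sv_min <- sv_rows[labels[sv_rows] == minority]
  if (length(sv_min) == 0) sv_min <- which(labels == minority)
  min_idx <- which(labels == minority)
  X_min <- features[min_idx, , drop = FALSE]
  ## danger / safe / noise classification of each minority support vector
  m <- min(config$m_neighbors, nrow(features) - 1L)
  d2_all <- cross_dist2(features[sv_min, , drop = FALSE], features)
  d2_all[cbind(seq_along(sv_min), sv_min)] <- Inf
  modes <- character(length(sv_min))
  for (i in seq_along(sv_min)) {
    nn <- order(d2_all[i, ])[seq_len(m)]
    n_maj_nn <- sum(labels[nn] == majority)
    modes[i] <- if (n_maj_nn == m) "noise"
      else if (n_maj_nn > m / 2) "interpolation"
      else "extrapolation"
  }
  eligible <- which(modes != "noise")
  if (length(eligible) == 0) {
    ## every support vector looks like noise; fall back to plain SMOTE
    ## over all minority points
    warn("all minority support vectors are noise; falling back to plain SMOTE")
    sv_min <- min_idx
    modes <- rep("interpolation", length(sv_min))
    eligible <- seq_along(sv_min)
  }
  ## k nearest minority neighbors of each eligible seed (excluding itself)
  k <- config$k_neighbors
  d2_min <- cross_dist2(features[sv_min, , drop = FALSE], X_min)
  self <- match(sv_min, min_idx)
  for (i in seq_along(sv_min)) {
    if (!is.na(self[i])) d2_min[i, self[i]] <- Inf
  }
  n_new <- n_maj - n_min
  synth <- matrix(0, n_new, ncol(features))
  mode_out <- character(n_new)
  with_seed(config$seed, {
    seed_draw <- sample(eligible, n_new, replace = TRUE)
    for (j in seq_len(n_new)) {
      i <- seed_draw[j]
      nns <- order(d2_min[i, ])[seq_len(k)]
      nn <- X_min[sample(nns, 1L), ]
      x0 <- features[sv_min[i], ]
      if (modes[i] == "interpolation") {
        lambda <- runif(1)
      } else {
        lambda <- -runif(1, 0, config$extrapolation_step)
      }
      synth[j, ] <- x0 + lambda * (nn - x0)
      mode_out[j] <- modes[i]
    }
  })
  out_features <- rbind(features, synth)
  attr(out_features, "synthetic_mode") <- mode_out
  attr(out_features, "svm") <- fit
  list(features = out_features,
       labels = c(labels, rep(minority, n_new)))
}

#' Balance an epoch set with SVMSMOTE
#'
#' Convenience wrapper: flattens the epochs, oversamples, and rebuilds a
#' canonical epoch set. Synthetic epochs inherit the subject/session/task
#' identifiers of the set's first minority epoch and are flagged in
#' `metadata$n_synthetic`.
#'
#' @param x a canonical [epoch_set()].
#' @param config an [oversample_config()].
#' @return a balanced [epoch_set()]; original epochs first, in order.
#' @export
oversample_epochset <- function(x, config = oversample_config()) {
  fl <- flatten_for_oversampling(x)
  res <- svm_smote(fl$features, fl$labels, config)
  n_new <- length(res$labels) - n_epochs(x)
  if (n_new == 0) return(x)
  minority <- res$labels[length(res$labels)]
  proto <- x$info[x$info$label == minority, ][1, ]
  info <- dplyr::bind_rows(
    x$info,
    tibble::tibble(label = rep(as.integer(minority), n_new),
                   subject = proto$subject, session = proto$session,
                   task = proto$task)
  )
  epoch_set(unflatten_epochs(res$features), info,
            channel_names = x$channel_names, sampling_rate = x$sampling_rate,
            metadata = c(x$metadata, list(n_synthetic = n_new)))
}
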