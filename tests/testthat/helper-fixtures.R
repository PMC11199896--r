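## Small fixture builders shared across the test files. All synthetic data
## is generated in code under fixed seeds; nothing is read from disk.

## compact labelled set: `n` epochs per subject per session
small_set <- function(n_subjects = 2, n = 40, sessions = 1, noise_sd = 0.005,
                      seed = 1, ...) {
  generate_epochset(synth_config(
    n_subjects = n_subjects, epochs_per_subject = n,
    sessions_per_subject = sessions, noise_sd = noise_sd, seed = seed, ...
  ))
}

## noiseless, perfectly separable set (error epochs = exact template,
## correct epochs = flat zero)
separable_set <- function(n_subjects = 1, n = 80, sessions = 1, seed = 1) {
  generate_epochset(synth_config(
    n_subjects = n_subjects, epochs_per_subject = n,
    sessions_per_subject = sessions, noise_sd = 0,
    subject_jitter = list(latency_sd = 0, amplitude_sd = 0), seed = seed
  ))
}

## short training budget for smoke tests
quick_cfg <- function(phase = "pretrain", epochs = 2, seed = 1, ...) {
  train_config(phase, epochs = epochs, seed = seed, ...)
}

## brute-force AUC oracle: all error/correct pairs, ties credited 1/2
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  100 * total / (length(pos) * length(neg))
}

## random two-cluster toy features for the oversampler / LDA tests
toy_clusters <- function(n_min = 20, n_maj = 80, d = 5, sep = 6, seed = 1) {
  set.seed(seed)
  features <- rbind(
    matrix(rnorm(n_maj * d), n_maj, d),
    matrix(rnorm(n_min * d, mean = sep), n_min, d)
  )
  list(features = features, labels = c(rep(0L, n_maj), rep(1L, n_min)))
}
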