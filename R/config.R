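## allowed keys per config-file section; unknown keys are rejected so a
## typo cannot silently fall back to a default
CONFIG_SECTIONS <- list(
  preprocess = c("profile", "filter", "filter_low_hz", "filter_high_hz",
                 "filter_order", "duration_s", "target_rate_hz", "channels",
                 "substitution", "scale_factor"),
  synth = c("n_subjects", "epochs_per_subject", "error_fraction", "noise_sd",
            "noise_spectrum", "subject_jitter", "task_shift",
            "sessions_per_subject", "template", "degraded_subjects", "task",
            "seed"),
  model = c("n_channels", "n_samples", "conv_filters", "fe_e_kernel1",
            "fe_e_pool1", "fe_e_kernel2", "fe_t_kernel", "fe_t_pool",
            "d_model", "n_heads", "ffn_dim", "dropout_rate", "n_classes"),
  train = c("pretrain", "finetune"),
  eval = c("scenario", "session", "baseline", "out"),
  imbalance = c("enabled", "k_neighbors", "m_neighbors", "svm_regularization",
                "extrapolation_step")
)
TRAIN_KEYS <- c("phase", "optimizer", "lr_init", "lr_min", "momentum",
                "epochs", "batch_size", "label_smoothing_eps", "k_folds",
                "seed")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0) {
    stopf("unknown key(s) in %s: %s", where, paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' Nested run configuration
#'
#' One document covering the preprocessing profile, the synthetic
#' generator, the model, the two training phases, the oversampler and the
#' evaluation scenario, plus a top-level seed. Round-trips losslessly
#' through YAML; unknown keys anywhere are rejected.
#'
#' @param preprocess,synth,model,train,eval,imbalance named lists for each
#'   section; see [read_run_config()] for the accepted keys.
#' @param seed top-level integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(preprocess = list(), synth = list(), model = list(),
                       train = list(), eval = list(), imbalance = list(),
                       seed = 1L) {
  cfg <- list(preprocess = preprocess, synth = synth, model = model,
              train = train, eval = eval, imbalance = imbalance,
              seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  check_keys(cfg, c(names(CONFIG_SECTIONS), "seed"), "run config")
  for (sec in names(CONFIG_SECTIONS)) {
    if (!is.null(cfg[[sec]])) check_keys(cfg[[sec]], CONFIG_SECTIONS[[sec]], sec)
  }
  for (phase in c("pretrain", "finetune")) {
    sub <- cfg$train[[phase]]
    if (!is.null(sub)) check_keys(sub, TRAIN_KEYS, paste0("train$", phase))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) stopf("seed must be a single integer")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration file
#'
#' The file is a single YAML document with sections `preprocess`, `synth`,
#' `model`, `train` (subsections `pretrain` / `finetune`), `imbalance` and
#' `eval`, and a top-level `seed`. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  raw <- yaml::read_yaml(path)
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## ---- section materializers -------------------------------------------

#' Materialize configuration sections into package objects
#'
#' Resolve the free-form lists of a [run_config()] into the typed
#' configuration objects the pipeline consumes; section defaults fall back
#' to the package defaults, and the top-level seed seeds every component
#' that does not set its own.
#'
#' @param cfg a `run_config`.
#' @return the corresponding configuration object.
#' @export
config_synth <- function(cfg) {
  args <- cfg$synth %||% list()
  if (!is.null(args$template)) args$template <- do.call(erp_template, args$template)
  args$seed <- args$seed %||% cfg$seed
  do.call(synth_config, args)
}

#' @rdname config_synth
#' @export
config_model <- function(cfg) do.call(model_config, cfg$model %||% list())

#' @rdname config_synth
#' @param phase `"pretrain"` or `"finetune"`.
#' @export
config_train <- function(cfg, phase = "pretrain") {
  args <- cfg$train[[phase]] %||% list()
  args$phase <- phase
  args$seed <- args$seed %||% cfg$seed
  do.call(train_config, args)
}

#' @rdname config_synth
#' @export
config_oversample <- function(cfg) {
  args <- cfg$imbalance %||% list()
  enabled <- args$enabled %||% TRUE
  if (!enabled) return(NULL)
  args$enabled <- NULL
  args$seed <- cfg$seed
  do.call(oversample_config, args)
}

#' @rdname config_synth
#' @export
config_preprocess <- function(cfg) {
  args <- cfg$preprocess %||% list()
  if (!is.null(args$profile)) {
    return(switch(args$profile,
                  bnci_cursor = profile_bnci_cursor(),
                  lsc_speller = profile_lsc_speller(),
                  gaze_speller = profile_gaze_speller(),
                  stopf("unknown preprocessing profile: %s", args$profile)))
  }
  filt <- if (isFALSE(args$filter)) NULL else
    filter_spec(args$filter_low_hz %||% 1, args$filter_high_hz %||% 10,
                args$filter_order %||% 4)
  preprocess_profile(
    name = "custom", filter = filt,
    window = epoch_window(args$duration_s %||% 1),
    target_rate_hz = args$target_rate_hz %||% 64,
    channels = args$channels %||% c("FCz", "Cz"),
    substitution = unlist(args$substitution) %||% character(0),
    scale_factor = args$scale_factor %||% 1000
  )
}

## ---- structured logging ----------------------------------------------

LOG_LEVELS <- c(debug = 1, info = 2, warn = 3, error = 4)

#' Leveled package logging
#'
#' Messages at or above the level in `options(errpnet.log_level = )`
#' (default `"warn"`) are emitted with a timestamp; training and
#' evaluation entry points log their resolved configuration and seed at
#' `"info"` so every run is reproducible from its log.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param fmt `sprintf` format string.
#' @param ... format arguments.
#' @return invisibly, the formatted message.
#' @export
errp_log <- function(level = "info", fmt, ...) {
  threshold <- getOption("errpnet.log_level", "warn")
  msg <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[threshold]]) message(msg)
  invisible(msg)
}
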