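#' Labelled collection of fixed-shape EEG epochs
#'
#' An `epoch_set` is the universal currency of the package: an array of
#' equally shaped epochs (`n_epochs x n_channels x n_samples`) together with
#' a per-epoch annotation table (binary label, subject, session and task
#' identifiers), the channel names and the sampling rate. After
#' preprocessing every epoch is canonical: 2 channels x 64 samples, sampled
#' at 64 Hz (or 128 Hz for 0.5-s paradigms), amplitude in volts scaled by
#' 1,000.
#'
#' @param data numeric array of shape `(n_epochs, n_channels, n_samples)`,
#'   all values finite.
#' @param info data frame with one row per epoch and columns `label`
#'   (0 = correct, 1 = error), `subject`, `session`, `task` (non-empty
#'   strings).
#' @param channel_names character vector naming the channels, length equal
#'   to `dim(data)[2]`.
#' @param sampling_rate sampling rate in Hz.
#' @param metadata free-form named list carried along verbatim.
#' @return an object of class `epoch_set`.
#' @export
#' @examples
#' es <- epoch_set(
#'   data = array(rnorm(5 * 2 * 64), c(5, 2, 64)),
#'   info = tibble::tibble(
#'     label = c(0L, 1L, 0L, 0L, 1L), subject = "s01",
#'     session = "session1", task = "synthetic"
#'   )
#' )
#' es
epoch_set <- function(data, info,
                      channel_names = c("FCz", "Cz"),
                      sampling_rate = 64,
                      metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("`data` must be a 3-d array (n_epochs x n_channels x n_samples)")
  }
  storage.mode(data) <- "double"
  info <- tibble::as_tibble(info)
  required <- c("label", "subject", "session", "task")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols) > 0) {
    stopf("`info` is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(info) != dim(data)[1]) {
    stopf("`info` has %d rows but `data` has %d epochs", nrow(info), dim(data)[1])
  }
  info$label <- as.integer(info$label)
  for (col in c("subject", "session", "task")) info[[col]] <- as.character(info[[col]])
  x <- structure(
    list(
      data = data,
      info = info,
      channel_names = as.character(channel_names),
      sampling_rate = as.numeric(sampling_rate),
      metadata = metadata
    ),
    class = "epoch_set"
  )
  validate_epoch_set(x)
}

#' Validate the epoch_set invariants
#'
#' Checks finiteness, label coding, identifier non-emptiness and channel
#' name consistency; errors on the first violation.
#'
#' @param x an `epoch_set`.
#' @return `x`, invisibly usable, after validation.
#' @export
validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (length(x$channel_names) != d[2]) {
    stopf("%d channel names for %d channels", length(x$channel_names), d[2])
  }
  if (d[1] > 0 && !all(is.finite(x$data))) stopf("epoch data contains non-finite values")
  if (!all(x$info$label %in% c(0L, 1L))) stopf("labels must be 0 (correct) or 1 (error)")
  for (col in c("subject", "session", "task")) {
    v <- x$info[[col]]
    if (anyNA(v) || any(!nzchar(v))) stopf("`%s` identifiers must be non-empty", col)
  }
  if (!is_scalar_number(x$sampling_rate) || x$sampling_rate <= 0) {
    stopf("sampling_rate must be a positive number")
  }
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs | %d channel(s): %s | %d samples @ %g Hz\n",
    d[1], d[2], paste(x$channel_names, collapse = ", "), d[3], x$sampling_rate
  ))
  if (d[1] > 0) {
    cat(sprintf(
      "  labels: %d error / %d correct | subjects: %d | sessions: %d | tasks: %d\n",
      sum(x$info$label == 1L), sum(x$info$label == 0L),
      dplyr::n_distinct(x$info$subject),
      dplyr::n_distinct(x$info$session),
      dplyr::n_distinct(x$info$task)
    ))
  }
  invisible(x)
}

#' Number of epochs in an epoch_set
#' @param x an `epoch_set`.
#' @return integer count.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Subset an epoch_set by epoch index
#'
#' @param x an `epoch_set`.
#' @param i integer or logical index over epochs.
#' @param ... ignored.
#' @return an `epoch_set` containing the selected epochs, order preserved as
#'   indexed.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  i <- seq_len(n_epochs(x))[i]
  epoch_set(
    data = x$data[i, , , drop = FALSE],
    info = x$info[i, , drop = FALSE],
    channel_names = x$channel_names,
    sampling_rate = x$sampling_rate,
    metadata = x$metadata
  )
}

#' Concatenate epoch sets
#'
#' @param ... `epoch_set` objects sharing channel names, sample counts and
#'   sampling rate.
#' @return the combined `epoch_set`.
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "epoch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channel_names, ref$channel_names) ||
        !identical(dim(s$data)[-1], dim(ref$data)[-1]) ||
        !identical(s$sampling_rate, ref$sampling_rate)) {
      stopf("epoch sets are not compatible for binding")
    }
  }
  n <- sum(vapply(sets, n_epochs, integer(1)))
  d <- dim(ref$data)
  data <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (s in sets) {
    if (n_epochs(s) > 0) data[at + seq_len(n_epochs(s)), , ] <- s$data
    at <- at + n_epochs(s)
  }
  epoch_set(
    data = data,
    info = dplyr::bind_rows(lapply(sets, function(s) s$info)),
    channel_names = ref$channel_names,
    sampling_rate = ref$sampling_rate,
    metadata = ref$metadata
  )
}

#' Is an epoch_set in canonical (2, 64) form?
#' @param x an `epoch_set`.
#' @return logical.
#' @export
is_canonical <- function(x) {
  d <- dim(x$data)
  d[2] == 2L && d[3] == 64L
}

#' Long-format view of an epoch_set
#'
#' Returns one row per (epoch, channel, sample) with the per-epoch
#' annotations repeated, convenient for ggplot2 summaries.
#'
#' @param x an `epoch_set`.
#' @param ... ignored.
#' @return a tibble with columns `epoch`, `channel`, `time_s`, `amplitude`,
#'   `label`, `subject`, `session`, `task`.
#' @method as_tibble epoch_set
#' @export
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  if (d[1] == 0) {
    return(tibble::tibble(
      epoch = integer(), channel = character(), time_s = numeric(),
      amplitude = numeric(), label = integer(), subject = character(),
      session = character(), task = character()
    ))
  }
  tt <- (seq_len(d[3]) - 1) / x$sampling_rate
  tibble::tibble(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channel_names, each = d[1]), times = d[3]),
    time_s = rep(tt, each = d[1] * d[2]),
    amplitude = as.vector(x$data),
    label = x$info$label[rep(seq_len(d[1]), times = d[2] * d[3])],
    subject = x$info$subject[rep(seq_len(d[1]), times = d[2] * d[3])],
    session = x$info$session[rep(seq_len(d[1]), times = d[2] * d[3])],
    task = x$info$task[rep(seq_len(d[1]), times = d[2] * d[3])]
  )
}

#' Plot class-average waveforms of an epoch_set
#'
#' Grand-average amplitude per channel and class (error vs correct) over the
#' epoch window; the classic way to eyeball the Ne/Pe complex.
#'
#' @param object an `epoch_set`.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot epoch_set
#' @export
autoplot.epoch_set <- function(object, ...) {
  df <- as_tibble.epoch_set(object) |>
    dplyr::mutate(class = ifelse(.data$label == 1L, "error", "correct")) |>
    dplyr::group_by(.data$channel, .data$class, .data$time_s) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(
      x = "time from event onset (s)", y = "amplitude (scaled)",
      colour = NULL, title = "Class-average waveforms"
    ) +
    ggplot2::theme_minimal()
}
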