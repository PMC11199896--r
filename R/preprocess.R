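#' Butterworth bandpass specification
#'
#' Defaults follow standard ErrP practice: 1-10 Hz, 4th-order Butterworth,
#' applied forward-backward (zero phase) so the Ne/Pe peak latencies are not
#' distorted.
#'
#' @param low_hz lower passband edge (Hz).
#' @param high_hz upper passband edge (Hz).
#' @param order filter order.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 1, high_hz = 10, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz)) stopf("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "filter_spec")
}

## Butterworth bandpass as cascaded biquad sections, designed analytically
## (prototype poles -> bandpass transform -> bilinear). A narrow low-frequency
## band at a high sampling rate makes the single 2N-order recursion badly
## conditioned; second-order sections keep it numerically exact.
butter_bandpass_sos <- function(low, high, fs, order = 4) {
  k <- seq_len(order)
  pa <- exp(1i * (pi * (2 * k - 1) / (2 * order) + pi / 2)) # prototype poles
  wl <- 2 * fs * tan(pi * low / fs) # prewarped edges
  wh <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  poles <- complex(0)
  for (p in pa) {
    s <- bw * p / 2
    disc <- sqrt(s^2 - w0^2 + 0i)
    poles <- c(poles, s + disc, s - disc)
  }
  zp <- (1 + poles / (2 * fs)) / (1 - poles / (2 * fs)) # bilinear
  upper <- zp[Im(zp) > 1e-12]
  sections <- lapply(upper, function(p) {
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2))
  })
  ## unit gain at the (prewarped) centre frequency
  wc <- 2 * atan(w0 / (2 * fs))
  zc <- exp(1i * wc)
  H <- prod(vapply(sections, function(s) {
    abs(sum(s$b * zc^(0:-2)) / sum(s$a * zc^(0:-2)))
  }, numeric(1)))
  list(sections = sections, gain = 1 / H)
}

sos_cascade <- function(sos, x) {
  for (s in sos$sections) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
  }
  sos$gain * x
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters every channel (row) of a continuous recording or epoch matrix
#' forward and backward with a Butterworth bandpass, giving a zero-phase
#' response whose magnitude is the squared one-pass response. The filter is
#' applied as a cascade of second-order sections for numerical stability,
#' with short odd-reflection padding at the edges.
#'
#' @param x numeric matrix, channels x samples.
#' @param fs sampling rate in Hz; must exceed twice the upper band edge.
#' @param spec a [filter_spec()].
#' @return matrix of the same shape.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stopf("input contains non-finite values")
  if (fs <= 2 * spec$high_hz) {
    stopf("sampling rate %g Hz too low for a %g Hz upper band edge", fs, spec$high_hz)
  }
  np <- 3 * (2 * spec$order + 1)
  if (ncol(x) <= np + 1) {
    stopf("signal too short (%d samples) for stable filtering", ncol(x))
  }
  sos <- butter_bandpass_sos(spec$low_hz, spec$high_hz, fs, spec$order)
  out <- x
  n <- ncol(x)
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    ext <- c(2 * v[1] - v[(np + 1):2], v, 2 * v[n] - v[(n - 1):(n - np)])
    ext <- sos_cascade(sos, ext)
    ext <- rev(sos_cascade(sos, rev(ext)))
    out[ch, ] <- ext[(np + 1):(np + n)]
  }
  out
}

#' Epoch extraction window
#'
#' Epochs are time-locked to event onset and span exactly one trial
#' duration: the half-open sample interval `[onset, onset + duration)` with
#' 0-based onsets.
#'
#' @param duration_s trial duration in seconds (1 or 0.5 in the supported
#'   paradigms).
#' @return an object of class `epoch_window`.
#' @export
epoch_window <- function(duration_s = 1) {
  if (duration_s <= 0) stopf("duration must be positive")
  structure(list(duration_s = duration_s), class = "epoch_window")
}

#' Cut event-locked epochs from a continuous recording
#'
#' @param x channels x samples matrix of continuous data.
#' @param fs sampling rate in Hz.
#' @param events data frame with columns `onset` (0-based sample index of
#'   event onset) and `label` (0/1); optional `subject`, `session`, `task`
#'   columns are carried through (defaulting to `"s01"`, `"session1"`,
#'   `"task"`).
#' @param window an [epoch_window()].
#' @param channel_names channel names, defaulting to `ch1..chN`.
#' @return an [epoch_set()] with one epoch per event, in event order, each
#'   of shape `(n_channels, round(duration * fs))`.
#' @export
extract_epochs <- function(x, fs, events, window = epoch_window(),
                           channel_names = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  events <- tibble::as_tibble(events)
  n_samp <- as.integer(round(window$duration_s * fs))
  n_ch <- nrow(x)
  channel_names <- channel_names %||% paste0("ch", seq_len(n_ch))
  n_ev <- nrow(events)
  data <- array(0, c(n_ev, n_ch, n_samp))
  for (i in seq_len(n_ev)) {
    onset <- events$onset[i]
    if (onset < 0 || onset + n_samp > ncol(x)) {
      stopf("event %d (onset sample %d) exceeds the recording bounds", i, onset)
    }
    data[i, , ] <- x[, onset + seq_len(n_samp), drop = FALSE]
  }
  info <- tibble::tibble(
    label = if (n_ev) as.integer(events$label) else integer(),
    subject = if ("subject" %in% names(events) && n_ev) events$subject else rep("s01", n_ev),
    session = if ("session" %in% names(events) && n_ev) events$session else rep("session1", n_ev),
    task = if ("task" %in% names(events) && n_ev) events$task else rep("task", n_ev)
  )
  epoch_set(data, info, channel_names = channel_names, sampling_rate = fs)
}

## downsample one channels x samples matrix
downsample_matrix <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stopf("fs_out (%g) must not exceed fs_in (%g)", fs_out, fs_in)
  if (fs_out == fs_in) return(x)
  n_in <- ncol(x)
  n_out <- as.integer(round(n_in * fs_out / fs_in))
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, by = as.integer(round(ratio)), length.out = n_out)
    return(x[, idx, drop = FALSE])
  }
  ## non-integer ratio: polyphase resampling
  out <- matrix(0, nrow(x), n_out)
  for (ch in seq_len(nrow(x))) {
    y <- signal::resample(x[ch, ], p = fs_out, q = fs_in)
    out[ch, ] <- y[seq_len(n_out)]
  }
  out
}

#' Downsample an epoch set or epoch matrix
#'
#' Integer rate ratios use plain decimation (every r-th sample, starting at
#' the first); the preceding 1-10 Hz bandpass makes this alias-free at the
#' 64 Hz target. Non-integer ratios fall back to polyphase resampling.
#' Duration is preserved: the output has `round(n_in * fs_out / fs_in)`
#' samples.
#'
#' @param x an [epoch_set()] or a channels x samples matrix.
#' @param fs_in input sampling rate (taken from the epoch set if omitted).
#' @param fs_out target sampling rate, at most `fs_in`.
#' @return same type as the input, downsampled.
#' @export
downsample <- function(x, fs_out, fs_in = NULL) {
  if (inherits(x, "epoch_set")) {
    fs_in <- fs_in %||% x$sampling_rate
    if (fs_out > fs_in) stopf("fs_out (%g) must not exceed fs_in (%g)", fs_out, fs_in)
    d <- dim(x$data)
    if (fs_out == fs_in) return(x)
    n_out <- as.integer(round(d[3] * fs_out / fs_in))
    data <- array(0, c(d[1], d[2], n_out))
    for (i in seq_len(d[1])) {
      data[i, , ] <- downsample_matrix(matrix(x$data[i, , ], d[2], d[3]), fs_in, fs_out)
    }
    return(epoch_set(data, x$info, channel_names = x$channel_names,
                     sampling_rate = fs_out, metadata = x$metadata))
  }
  if (is.null(fs_in)) stopf("fs_in is required for matrix input")
  downsample_matrix(x, fs_in, fs_out)
}

#' Select (and substitute) named channels
#'
#' Reduces an epoch set to the requested channels in the requested order.
#' Where a requested channel is absent, an entry in `substitution`
#' (e.g. `c(FCz = "Fz")`) may name a stand-in channel; each substitution is
#' reported via `message()`. Anything else is an error.
#'
#' @param x an [epoch_set()].
#' @param requested ordered character vector of channel names to keep.
#' @param substitution named character vector mapping a missing requested
#'   name to the channel used in its place.
#' @return an [epoch_set()] with `length(requested)` channels; channel names
#'   record the channels actually used.
#' @export
select_channels <- function(x, requested = c("FCz", "Cz"), substitution = character(0)) {
  used <- character(length(requested))
  idx <- integer(length(requested))
  for (i in seq_along(requested)) {
    want <- requested[i]
    if (want %in% x$channel_names) {
      used[i] <- want
    } else if (want %in% names(substitution) && substitution[[want]] %in% x$channel_names) {
      used[i] <- substitution[[want]]
      message(sprintf("channel %s not present; using %s in its place", want, used[i]))
    } else {
      stopf("channel %s not present and no substitution applies", want)
    }
    idx[i] <- match(used[i], x$channel_names)
  }
  epoch_set(x$data[, idx, , drop = FALSE], x$info, channel_names = used,
            sampling_rate = x$sampling_rate, metadata = x$metadata)
}

#' Scale epoch amplitudes
#'
#' Multiplies every sample by a positive factor; the canonical pipeline uses
#' 1,000, moving volt-scale recordings onto a numerically convenient range.
#'
#' @param x an [epoch_set()].
#' @param factor positive scale factor (default 1,000).
#' @return the scaled [epoch_set()].
#' @export
scale_amplitude <- function(x, factor = 1000) {
  if (!is_scalar_number(factor) || factor <= 0) stopf("factor must be a positive number")
  x$data <- x$data * factor
  x
}

#' Continuous multichannel recording with an event list
#'
#' Light container for raw data entering [run_pipeline()].
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per row of `signal`.
#' @param events data frame with `onset` (0-based sample) and `label`
#'   columns, optionally `subject`, `session`, `task`.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, channel_names, events) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  stopifnot(length(channel_names) == nrow(signal))
  structure(
    list(signal = signal, fs = fs, channel_names = as.character(channel_names),
         events = tibble::as_tibble(events)),
    class = "raw_recording"
  )
}

#' Preprocessing profile for a dataset family
#'
#' Bundles the per-dataset preprocessing choices: whether to bandpass
#' (already-epoched, pre-filtered corpora skip it), the epoch window, the
#' post-downsampling rate, the channels to keep with any substitutions, and
#' the amplitude scale factor.
#'
#' @param name profile name.
#' @param filter a [filter_spec()], or `NULL` to skip filtering.
#' @param window an [epoch_window()].
#' @param target_rate_hz sampling rate after downsampling.
#' @param channels ordered channel names to keep.
#' @param substitution named character vector of channel substitutions.
#' @param scale_factor amplitude scale factor.
#' @return an object of class `preprocess_profile`.
#' @export
preprocess_profile <- function(name,
                               filter = filter_spec(),
                               window = epoch_window(1),
                               target_rate_hz = 64,
                               channels = c("FCz", "Cz"),
                               substitution = character(0),
                               scale_factor = 1000) {
  structure(
    list(name = name, filter = filter, window = window,
         target_rate_hz = target_rate_hz, channels = channels,
         substitution = substitution, scale_factor = scale_factor),
    class = "preprocess_profile"
  )
}

#' @rdname preprocess_profile
#' @export
profile_bnci_cursor <- function() {
  preprocess_profile("bnci_cursor", filter = filter_spec(), window = epoch_window(1),
                     target_rate_hz = 64, channels = c("FCz", "Cz"))
}

#' @rdname preprocess_profile
#' @export
profile_lsc_speller <- function() {
  preprocess_profile("lsc_speller", filter = filter_spec(), window = epoch_window(1),
                     target_rate_hz = 64, channels = c("FCz", "Cz"),
                     substitution = c(FCz = "Fz"))
}

#' @rdname preprocess_profile
#' @export
profile_gaze_speller <- function() {
  preprocess_profile("gaze_speller", filter = NULL, window = epoch_window(0.5),
                     target_rate_hz = 128, channels = c("FCz", "Cz"))
}

#' Run the canonical preprocessing pipeline
#'
#' Composes, in order: zero-phase bandpass of the continuous recording
#' (skipped when the profile carries no filter or the input is already
#' epoched and pre-filtered), event-locked epoch extraction, downsampling to
#' the profile's target rate, channel selection, and amplitude scaling.
#' Every supported profile ends with canonical `(2, 64)` epochs.
#'
#' @param x a [raw_recording()] or an already-epoched [epoch_set()].
#' @param profile a [preprocess_profile()].
#' @return a canonical [epoch_set()].
#' @export
run_pipeline <- function(x, profile) {
  stopifnot(inherits(profile, "preprocess_profile"))
  if (inherits(x, "raw_recording")) {
    sig <- x$signal
    if (!is.null(profile$filter)) {
      sig <- bandpass_filter(sig, x$fs, profile$filter)
    }
    es <- extract_epochs(sig, x$fs, x$events, window = profile$window,
                         channel_names = x$channel_names)
  } else if (inherits(x, "epoch_set")) {
    es <- x
    if (!is.null(profile$filter)) {
      d <- dim(es$data)
      data <- es$data
      for (i in seq_len(d[1])) {
        data[i, , ] <- bandpass_filter(matrix(es$data[i, , ], d[2], d[3]),
                                       es$sampling_rate, profile$filter)
      }
      es$data <- data
    }
  } else {
    stopf("input must be a raw_recording or an epoch_set")
  }
  es <- downsample(es, profile$target_rate_hz)
  es <- select_channels(es, profile$channels, profile$substitution)
  scale_amplitude(es, profile$scale_factor)
}
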