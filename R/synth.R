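#' ERP template for synthetic error epochs
#'
#' Parametric description of the error-related waveform injected into
#' synthetic error epochs: a sharp negative deflection (the error-related
#' negativity, Ne) followed by a positive deflection (the error positivity,
#' Pe), each modelled as a Gaussian-windowed bump, projected onto the two
#' channels with per-channel gains. Amplitudes are on the canonical scale
#' (volts multiplied by 1,000), so `-0.01` corresponds to a -10 microvolt
#' peak.
#'
#' @param ne_latency_s Ne peak latency in seconds after event onset.
#' @param ne_width_s Ne Gaussian width (sd) in seconds.
#' @param ne_amplitude Ne peak amplitude, strictly negative.
#' @param pe_latency_s Pe peak latency in seconds, after the Ne.
#' @param pe_width_s Pe Gaussian width in seconds.
#' @param pe_amplitude Pe peak amplitude, strictly positive.
#' @param channel_gains length-2 positive weights projecting the waveform
#'   onto the two channels (frontocentral electrodes see the largest ErrP).
#' @return an object of class `erp_template`.
#' @export
erp_template <- function(ne_latency_s = 0.26, ne_width_s = 0.04,
                         ne_amplitude = -0.010,
                         pe_latency_s = 0.38, pe_width_s = 0.06,
                         pe_amplitude = 0.012,
                         channel_gains = c(1.0, 0.8)) {
  tpl <- structure(
    list(
      ne_latency_s = ne_latency_s, ne_width_s = ne_width_s,
      ne_amplitude = ne_amplitude,
      pe_latency_s = pe_latency_s, pe_width_s = pe_width_s,
      pe_amplitude = pe_amplitude,
      channel_gains = as.numeric(channel_gains)
    ),
    class = "erp_template"
  )
  validate_erp_template(tpl)
}

validate_erp_template <- function(tpl, duration_s = 1) {
  if (!(tpl$ne_latency_s < tpl$pe_latency_s)) stopf("Ne latency must precede Pe latency")
  if (!(tpl$ne_amplitude < 0)) stopf("Ne amplitude must be negative")
  if (!(tpl$pe_amplitude > 0)) stopf("Pe amplitude must be positive")
  if (length(tpl$channel_gains) != 2L || any(tpl$channel_gains <= 0)) {
    stopf("channel_gains must be two positive weights")
  }
  if (tpl$ne_latency_s - 2 * tpl$ne_width_s < 0 ||
      tpl$pe_latency_s + 2 * tpl$pe_width_s > duration_s) {
    stopf("template components must lie within the epoch window")
  }
  tpl
}

#' Evaluate an ERP template on a sample grid
#'
#' @param template an [erp_template()].
#' @param n_samples samples per epoch.
#' @param sampling_rate Hz.
#' @return a `(2, n_samples)` matrix: the noiseless error waveform.
#' @export
template_waveform <- function(template, n_samples = 64, sampling_rate = 64) {
  t <- (seq_len(n_samples) - 1) / sampling_rate
  bump <- function(lat, width, amp) amp * exp(-0.5 * ((t - lat) / width)^2)
  w <- bump(template$ne_latency_s, template$ne_width_s, template$ne_amplitude) +
    bump(template$pe_latency_s, template$pe_width_s, template$pe_amplitude)
  rbind(template$channel_gains[1] * w, template$channel_gains[2] * w)
}

#' Configuration of the synthetic ErrP generator
#'
#' Defaults emulate the observation-ErrP study conditions the package's
#' evaluation protocols assume: 6 subjects, 2 sessions each, roughly 537
#' epochs per subject per session, and a 20.5% error prevalence (1,322
#' error events out of 6,437 in the reference corpus).
#'
#' @param n_subjects number of simulated participants.
#' @param epochs_per_subject epochs per subject per session.
#' @param error_fraction fraction of error epochs, in (0, 1); the per-cell
#'   error count is exactly `round(error_fraction * epochs_per_subject)`.
#' @param noise_sd background noise standard deviation on the canonical
#'   amplitude scale (0.005 is about 5 microvolts).
#' @param noise_spectrum `"one_over_f"` (EEG-like pink background) or
#'   `"white"`.
#' @param subject_jitter list with `latency_sd` (seconds) and `amplitude_sd`
#'   (relative) controlling per-subject template variability.
#' @param task_shift list with `amplitude_scale`, `latency_offset_s` and
#'   `noise_multiplier` describing how this task's ERP statistics differ
#'   from the reference template; identity by default.
#' @param sessions_per_subject number of recording sessions per subject.
#' @param template population [erp_template()].
#' @param degraded_subjects integer indices of subjects generated with a
#'   near-zero template and doubled noise, emulating a participant whose
#'   recordings carry almost no usable error signal.
#' @param task task identifier stamped on every epoch.
#' @param seed integer seed; the full output is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 6,
                         epochs_per_subject = 537,
                         error_fraction = 0.205,
                         noise_sd = 0.005,
                         noise_spectrum = c("one_over_f", "white"),
                         subject_jitter = list(latency_sd = 0.02, amplitude_sd = 0.15),
                         task_shift = list(amplitude_scale = 1, latency_offset_s = 0,
                                           noise_multiplier = 1),
                         sessions_per_subject = 2,
                         template = erp_template(),
                         degraded_subjects = integer(0),
                         task = "synthetic",
                         seed = 1L) {
  noise_spectrum <- match.arg(noise_spectrum)
  if (!(error_fraction > 0 && error_fraction < 1)) stopf("error_fraction must be in (0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (epochs_per_subject < 0) stopf("epochs_per_subject must be >= 0")
  if (subject_jitter$latency_sd < 0 || subject_jitter$amplitude_sd < 0) {
    stopf("jitter standard deviations must be >= 0")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      epochs_per_subject = as.integer(epochs_per_subject),
      error_fraction = error_fraction,
      noise_sd = noise_sd,
      noise_spectrum = noise_spectrum,
      subject_jitter = subject_jitter,
      task_shift = task_shift,
      sessions_per_subject = as.integer(sessions_per_subject),
      template = template,
      degraded_subjects = as.integer(degraded_subjects),
      task = task,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

## apply a task shift to a template
shift_template <- function(template, shift) {
  tpl <- template
  tpl$ne_amplitude <- tpl$ne_amplitude * shift$amplitude_scale
  tpl$pe_amplitude <- tpl$pe_amplitude * shift$amplitude_scale
  tpl$ne_latency_s <- tpl$ne_latency_s + shift$latency_offset_s
  tpl$pe_latency_s <- tpl$pe_latency_s + shift$latency_offset_s
  tpl
}

#' Draw a per-subject ERP template
#'
#' Jitters the population template's latencies (additively, normal with sd
#' `latency_sd`) and amplitudes (multiplicatively, normal with mean 1 and sd
#' `amplitude_sd`), resampling up to 100 times if a draw violates the
#' template invariants (component ordering, sign, window bounds).
#'
#' @param config a [synth_config()].
#' @param subject_seed integer seed for this subject's draw.
#' @return an `erp_template`, deterministic given the seed.
#' @export
make_template <- function(config, subject_seed) {
  jit <- config$subject_jitter
  base <- shift_template(config$template, config$task_shift)
  with_seed(subject_seed, {
    for (attempt in 1:100) {
      tpl <- base
      dlat <- rnorm(1, 0, jit$latency_sd)
      amp <- rnorm(1, 1, jit$amplitude_sd)
      tpl$ne_latency_s <- tpl$ne_latency_s + dlat
      tpl$pe_latency_s <- tpl$pe_latency_s + dlat
      tpl$ne_amplitude <- tpl$ne_amplitude * amp
      tpl$pe_amplitude <- tpl$pe_amplitude * amp
      ok <- tryCatch({
        validate_erp_template(tpl)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(tpl)
    }
    stopf("could not draw a valid subject template within 100 attempts")
  })
}

## n x n_samples matrix of background noise rows with sd `sd`
draw_noise <- function(n, n_samples, sd, spectrum) {
  if (sd == 0 || n == 0) return(matrix(0, n, n_samples))
  w <- matrix(rnorm(n * n_samples), n, n_samples)
  if (spectrum == "white") return(sd * w)
  ## pink background: shape the white spectrum by 1/sqrt(f), then rescale
  freq <- c(1, seq_len(n_samples - 1))
  freq <- pmin(freq, n_samples - freq + 1) # symmetric fold for real signals
  gain <- 1 / sqrt(freq)
  shaped <- t(apply(w, 1, function(row) Re(fft(fft(row) * gain, inverse = TRUE)) / n_samples))
  shaped <- shaped - rowMeans(shaped)
  sds <- apply(shaped, 1, stats::sd)
  sds[sds == 0] <- 1
  sd * shaped / sds
}

#' Generate a labelled synthetic epoch set
#'
#' Produces canonical `(2, 64)` epochs at 64 Hz: error epochs carry the
#' subject's jittered Ne/Pe template plus background noise, correct epochs
#' carry background noise only. Every subject x session cell contains
#' exactly `round(error_fraction * epochs_per_subject)` error epochs in a
#' seeded random order. Identical configurations (including the seed) give
#' bit-identical output; subject streams are derived by stable hashing so
#' the result does not depend on generation order.
#'
#' @param config a [synth_config()].
#' @return a canonical [epoch_set()].
#' @export
#' @examples
#' es <- generate_epochset(synth_config(n_subjects = 2, epochs_per_subject = 20))
#' es
generate_epochset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_samples <- 64L
  fs <- 64
  sets <- list()
  for (subj in seq_len(config$n_subjects)) {
    degraded <- subj %in% config$degraded_subjects
    tpl <- make_template(config, derive_seed(config$seed, "template", subj))
    if (degraded) {
      tpl$ne_amplitude <- tpl$ne_amplitude * 0.05
      tpl$pe_amplitude <- tpl$pe_amplitude * 0.05
    }
    wave <- template_waveform(tpl, n_samples, fs)
    noise_sd <- config$noise_sd * config$task_shift$noise_multiplier *
      (if (degraded) 2 else 1)
    for (sess in seq_len(config$sessions_per_subject)) {
      n <- config$epochs_per_subject
      if (n == 0) next
      n_err <- round(config$error_fraction * n)
      cell <- with_seed(derive_seed(config$seed, "epochs", subj, sess), {
        labels <- sample(rep(c(1L, 0L), c(n_err, n - n_err)))
        data <- array(0, c(n, 2L, n_samples))
        for (ch in 1:2) {
          data[, ch, ] <- draw_noise(n, n_samples, noise_sd, config$noise_spectrum)
        }
        err_idx <- which(labels == 1L)
        for (ch in 1:2) {
          data[err_idx, ch, ] <- data[err_idx, ch, , drop = FALSE] +
            rep(wave[ch, ], each = length(err_idx))
        }
        list(labels = labels, data = data)
      })
      sets[[length(sets) + 1L]] <- epoch_set(
        data = cell$data,
        info = tibble::tibble(
          label = cell$labels,
          subject = sprintf("s%02d", subj),
          session = sprintf("session%d", sess),
          task = config$task
        ),
        channel_names = c("FCz", "Cz"),
        sampling_rate = fs,
        metadata = list(generator = "errpnet_synth", seed = config$seed)
      )
    }
  }
  if (length(sets) == 0) {
    return(epoch_set(
      data = array(0, c(0, 2, n_samples)),
      info = tibble::tibble(
        label = integer(), subject = character(),
        session = character(), task = character()
      ),
      sampling_rate = fs,
      metadata = list(generator = "errpnet_synth", seed = config$seed)
    ))
  }
  bind_epoch_sets(sets)
}

#' Generate a source/target task pair with controlled distribution shift
#'
#' The two sets share the population template; the target configuration's
#' `task_shift` (amplitude scale, latency offset, noise multiplier) is the
#' only systematic difference, emulating pretraining on one EEG paradigm
#' and transfer to another. The random streams of the two tasks are split
#' deterministically from the source seed so the pair is reproducible.
#'
#' @param source_config,target_config [synth_config()] objects; the target's
#'   task identifier must differ from the source's.
#' @return a named list with elements `source` and `target`, both canonical
#'   [epoch_set()]s.
#' @export
generate_task_pair <- function(source_config, target_config) {
  stopifnot(inherits(source_config, "synth_config"), inherits(target_config, "synth_config"))
  if (identical(source_config$task, target_config$task)) {
    stopf("source and target must carry distinct task identifiers")
  }
  src <- source_config
  tgt <- target_config
  src$seed <- derive_seed(source_config$seed, "pair", "source")
  tgt$seed <- derive_seed(source_config$seed, "pair", "target")
  list(source = generate_epochset(src), target = generate_epochset(tgt))
}
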