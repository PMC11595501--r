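# Synthetic imagined-speech-like EEG.
#
# Signal model: rank-1 spatiotemporal source per class -- a fixed unit-norm
# spatial pattern over the electrodes times a smooth Hann temporal envelope
# centered at a class-specific latency -- plus white Gaussian noise scaled to
# a requested signal-to-noise ratio. The model makes no claim of
# physiological fidelity; it exists so that the full pipeline (topomap
# transform + spatiotemporal classifiers) is exercised end to end with a
# known, recoverable class structure.

#' Specification of a synthetic trial collection
#'
#' @param classes character vector of class identifiers (default two words).
#' @param n_trials_per_class trials per class (default 70, the reference
#'   per-word trial count).
#' @param rate sampling rate in Hz (default 256).
#' @param duration_s trial length in seconds (default 2).
#' @param snr linear signal-to-noise power ratio (> 0; default 5).
#' @param seed integer RNG seed.
#' @param channel_names electrode labels (default the 15-channel
#'   \code{\link{frontal_subset}}).
#' @param amplitude peak source amplitude in microvolts (default 10, a
#'   typical scalp EEG scale).
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(classes = c("hello", "stop"),
                           n_trials_per_class = 70,
                           rate = 256, duration_s = 2, snr = 5, seed = 0,
                           channel_names = frontal_subset(),
                           amplitude = 10) {
  stopifnot(length(classes) >= 1, n_trials_per_class >= 1, rate > 0,
            duration_s > 0, snr > 0)
  structure(list(classes = as.character(classes),
                 n_trials_per_class = as.integer(n_trials_per_class),
                 rate = rate, duration_s = duration_s, snr = snr,
                 seed = as.integer(seed),
                 channel_names = as.character(channel_names),
                 amplitude = amplitude),
            class = "synthetic_spec")
}

# sub-seed derivation, kept below 2^31
.sub_seed <- function(seed, a, b = 0) {
  (as.double(seed) * 7919 + a * 104729 + b * 131) %% 2147483647
}

#' Class-specific spatial amplitude pattern
#'
#' Deterministic unit-norm weight vector over the electrodes for class
#' \code{class_id} (1-based index). Patterns are drawn sequentially from a
#' seeded stream; a candidate correlating at |r| >= 0.7 with any
#' earlier class's pattern is redrawn, so distinct classes stay spatially
#' distinguishable.
#'
#' @param class_id integer class index (1-based).
#' @param n_channels number of electrodes.
#' @param seed integer RNG seed shared by all classes of one collection.
#' @return Numeric unit-norm vector of length \code{n_channels}.
#' @export
class_pattern <- function(class_id, n_channels, seed = 0) {
  stopifnot(n_channels >= 1, class_id >= 1)
  .class_patterns(as.integer(class_id), n_channels, seed)[, class_id]
}

.class_patterns <- function(n_classes, n_channels, seed) {
  pats <- matrix(0, n_channels, n_classes)
  for (k in seq_len(n_classes)) {
    attempt <- 0
    repeat {
      v <- .with_seed(.sub_seed(seed, k, attempt), function() rnorm(n_channels))
      v <- v / sqrt(sum(v^2))
      ok <- k == 1 || n_channels < 3 ||
        all(abs(apply(pats[, seq_len(k - 1), drop = FALSE], 2,
                      function(p) stats::cor(p, v))) < 0.7)
      if (ok) break
      attempt <- attempt + 1
      if (attempt > 1000) stop("could not find a decorrelated pattern", call. = FALSE)
    }
    pats[, k] <- v
  }
  pats
}

# Hann envelope of width w centered at mu, evaluated at times t (seconds)
.hann_envelope <- function(t, mu, w) {
  out <- numeric(length(t))
  inside <- abs(t - mu) < w / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * (t[inside] - mu) / w))
  out
}

#' Generate synthetic imagined-speech-like EEG trials
#'
#' Sample \code{(e, t)} of a class-\code{c} trial is
#' \code{amplitude * pattern_c[e] * env_c(t) + noise}, where \code{env_c} is
#' a 1 s Hann window centered at a class-specific latency (latencies are
#' spread over \code{[0.25, 0.75] * duration} so classes differ in both
#' where and when activity peaks) and the white Gaussian noise variance is
#' set so that mean signal power over the class's noiseless trial divided by
#' noise power equals \code{spec$snr}. With the same seed the generation is
#' fully reproducible.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param subject subject identifier attached to every trial (default
#'   "S01").
#' @return A balanced \code{\link{trial_set}} of
#'   \code{\link{trial_recording}}s,
#'   \code{length(classes) * n_trials_per_class} trials in total.
#' @examples
#' ts <- generate_trials(synthetic_spec(n_trials_per_class = 2, seed = 1))
#' length(ts)
#' @export
generate_trials <- function(spec, subject = "S01") {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_ch <- length(spec$channel_names)
  n_s <- round(spec$rate * spec$duration_s)
  k_cl <- length(spec$classes)
  pats <- .class_patterns(k_cl, n_ch, spec$seed)
  t_sec <- (seq_len(n_s) - 1) / spec$rate
  env_w <- min(1.0, spec$duration_s / 2)
  latency <- if (k_cl == 1) 0.5 * spec$duration_s else
    spec$duration_s * (0.25 + 0.5 * (seq_len(k_cl) - 1) / (k_cl - 1))
  trials <- vector("list", k_cl * spec$n_trials_per_class)
  i <- 0
  for (k in seq_len(k_cl)) {
    sig <- spec$amplitude * outer(pats[, k], .hann_envelope(t_sec, latency[k], env_w))
    p_sig <- mean(sig^2)
    sd_noise <- sqrt(p_sig / spec$snr)
    for (tr in seq_len(spec$n_trials_per_class)) {
      noise <- .with_seed(.sub_seed(spec$seed, k * 100000 + tr, 7), function() {
        matrix(rnorm(n_ch * n_s, sd = sd_noise), n_ch, n_s)
      })
      i <- i + 1
      trials[[i]] <- trial_recording(sig + noise, spec$rate, spec$classes[k],
                                     subject, spec$channel_names)
    }
  }
  trial_set(trials, classes = spec$classes)
}

#' Generate a multi-subject synthetic collection
#'
#' Calls \code{\link{generate_trials}} once per subject with a
#' subject-offset seed, so subjects share the class patterns' generative
#' model but have independent noise.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param n_subjects number of subjects.
#' @return Named list mapping subject ID ("S01", ...) to a
#'   \code{trial_set}, the per-subject input of
#'   \code{\link{run_experiment}}.
#' @export
generate_subjects <- function(spec, n_subjects = 1) {
  stopifnot(n_subjects >= 1)
  out <- lapply(seq_len(n_subjects), function(s) {
    sp <- spec
    sp$seed <- as.integer(.sub_seed(spec$seed, s, 13) %% 2147483647)
    generate_trials(sp, subject = sprintf("S%02d", s))
  })
  names(out) <- sprintf("S%02d", seq_len(n_subjects))
  out
}
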