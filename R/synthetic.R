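#' Synthetic multichannel EEG configuration
#'
#' Describes a labelled multiclass dataset with the statistical structure
#' the pipeline assumes: class-distinct amplitude scales and spectral
#' content, and nonzero inter-channel correlation (channels are noisy
#' mixtures of a shared latent source and a channel-private source).
#' Three archetypes are available:
#' \describe{
#'   \item{`"background"`}{awake background rhythm: a sinusoid at
#'     `rhythm_freq` with random phase plus 1/f-shaped noise.}
#'   \item{`"interictal"`}{background plus sparse biphasic spikes arriving
#'     as a Poisson process at `spike_rate` per second with amplitude
#'     `spike_amplitude`.}
#'   \item{`"ictal"`}{a high-amplitude ~3 Hz spike-and-wave train, the
#'     classic generalized seizure morphology.}
#' }
#' The default three classes mirror the normal / interictal / ictal
#' ordering of clinical EEG: amplitude scales 1, 5, 25 reproduce the
#' normal << interictal < ictal amplitude hierarchy without claiming
#' physiological fidelity.
#'
#' @param n_classes Number of classes (default 3).
#' @param p Channels per record (default 16).
#' @param n_total Samples per channel (default 2048).
#' @param fs Sampling rate in Hz (default 173.61).
#' @param archetypes Character vector of length `n_classes` from
#'   `"background"`, `"interictal"`, `"ictal"`.
#' @param amplitude_scales Per-class amplitude scale (default 1, 5, 25).
#' @param rhythm_freq Background rhythm frequency in Hz (default 10,
#'   the alpha band).
#' @param spike_rate Interictal spike rate per second (default 1).
#' @param spike_amplitude Spike size relative to the background (default 6).
#' @param spike_wave_freq Ictal spike-and-wave frequency in Hz (default 3).
#' @param common_source_weight Mixing weight in [0, 1] of the shared
#'   latent source (default 0.6, giving the moderate-to-high pairwise
#'   channel correlations of scalp EEG and a multi-component
#'   eigenspectrum rather than a single dominant direction).
#' @param noise_sd Additive white sensor noise sd (default 0.1).
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_classes = 3L, p = 16L, n_total = 2048L,
                             fs = 173.61,
                             archetypes = c("background", "interictal",
                                            "ictal")[seq_len(n_classes)],
                             amplitude_scales = c(1, 5, 25)[seq_len(n_classes)],
                             rhythm_freq = 10, spike_rate = 1,
                             spike_amplitude = 6, spike_wave_freq = 3,
                             common_source_weight = 0.6, noise_sd = 0.1,
                             seed = 42L) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 1L, p >= 1L, n_total >= 2L, fs > 0,
            length(archetypes) == n_classes,
            all(archetypes %in% c("background", "interictal", "ictal")),
            length(amplitude_scales) == n_classes,
            all(amplitude_scales > 0),
            common_source_weight >= 0, common_source_weight <= 1,
            noise_sd >= 0, rhythm_freq > 0, spike_rate >= 0,
            spike_amplitude >= 0, spike_wave_freq > 0)
  structure(list(n_classes = n_classes, p = as.integer(p),
                 n_total = as.integer(n_total), fs = fs,
                 archetypes = archetypes,
                 amplitude_scales = amplitude_scales,
                 rhythm_freq = rhythm_freq, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude,
                 spike_wave_freq = spike_wave_freq,
                 common_source_weight = common_source_weight,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# 1/f-shaped noise via FFT amplitude shaping of white noise
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  shaped <- sp / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x / stats::sd(x)
}

# biphasic spike template: derivative-of-Gaussian, ~70 ms wide at fs
spike_template <- function(fs, width_s = 0.07) {
  half <- max(3L, round(width_s * fs / 2))
  t <- seq(-half, half) / half
  w <- -t * exp(-4 * t^2)
  w / max(abs(w))
}

# Instantaneous phase of a narrowband stochastic oscillation: linear
# phase advance at freq Hz plus a random-walk drift, so two independent
# draws decorrelate within a fraction of a second (a pure deterministic
# sinusoid would keep |cor| = |cos dphi| forever). jitter_sd = 0.3
# rad/sample broadens a 10 Hz peak to roughly the width of the alpha
# band at the default sampling rate.
drifting_phase <- function(n, freq, fs, jitter_sd = 0.3) {
  2 * pi * freq * (seq_len(n) - 1) / fs +
    stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(n, sd = jitter_sd))
}

# one latent source of the given archetype, unit-ish scale, length n
latent_source <- function(archetype, cfg) {
  n <- cfg$n_total
  background <- function()
    sin(drifting_phase(n, cfg$rhythm_freq, cfg$fs)) + 0.5 * pink_noise(n)
  switch(
    archetype,
    background = background(),
    interictal = {
      base <- background()
      n_spikes <- stats::rpois(1, cfg$spike_rate * n / cfg$fs)
      tpl <- spike_template(cfg$fs)
      if (n_spikes > 0) {
        at <- sample.int(n, min(n_spikes, n), replace = FALSE)
        for (a in at) {
          lo <- a; hi <- min(n, a + length(tpl) - 1L)
          seg <- seq_len(hi - lo + 1L)
          base[lo:hi] <- base[lo:hi] +
            cfg$spike_amplitude * stats::runif(1, 0.8, 1.2) * tpl[seg]
        }
      }
      base
    },
    ictal = {
      # slow wave plus one sharp transient per cycle, locked to the
      # same drifting phase
      psi <- drifting_phase(n, cfg$spike_wave_freq, cfg$fs)
      cyc <- (psi / (2 * pi)) %% 1
      sin(psi) + 2 * exp(-0.5 * ((cyc - 0.5) / 0.04)^2) +
        0.25 * pink_noise(n)
    },
    stop("unknown archetype: ", archetype, call. = FALSE))
}

#' Generate one synthetic class record
#'
#' Each channel is
#' `amplitude_scale * (w * shared + (1 - w) * private) + N(0, noise_sd)`
#' with `w = common_source_weight`; `shared` is one latent source drawn
#' per record and `private` is drawn independently per channel from the
#' same archetype, so channels are correlated copies of a common source,
#' the redundancy structure that motivates PCA on multichannel EEG.
#'
#' The record is a pure function of `(cfg, class_index)`: the RNG is
#' seeded from `cfg$seed` and the class index, so repeated calls are
#' bit-identical and records of different classes are independent.
#'
#' @param cfg A [synthetic_config()].
#' @param class_index Class to generate, in `1..cfg$n_classes`.
#' @return An [eeg_record] with `class_label = class_index`.
#' @export
generate_class_signal <- function(cfg, class_index) {
  stopifnot(inherits(cfg, "synthetic_config"))
  class_index <- as.integer(class_index)
  if (is.na(class_index) || class_index < 1L ||
        class_index > cfg$n_classes)
    stop("class_index must be in 1..", cfg$n_classes, call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((cfg$seed %% 100000L) * 101L + class_index)  # < 2^31
  arch <- cfg$archetypes[class_index]
  scale <- cfg$amplitude_scales[class_index]
  w <- cfg$common_source_weight
  shared <- latent_source(arch, cfg)
  data <- matrix(0, cfg$n_total, cfg$p)
  for (j in seq_len(cfg$p)) {
    private <- latent_source(arch, cfg)
    data[, j] <- scale * (w * shared + (1 - w) * private) +
      stats::rnorm(cfg$n_total, sd = cfg$noise_sd)
  }
  eeg_record(data, fs = cfg$fs, class_label = class_index,
             source_id = sprintf("synthetic:%s:class%d:seed%d",
                                 arch, class_index, cfg$seed))
}

#' Generate a full synthetic dataset
#'
#' One record per class, labels `1..n_classes`. Optionally writes each
#' record as a Bonn-dialect directory (`<out_dir>/class<i>/chanNNN.txt`)
#' for end-to-end command-line tests.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Optional directory to write Bonn-dialect sets into.
#' @return List of [eeg_record]s, one per class.
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  records <- lapply(seq_len(cfg$n_classes),
                    function(i) generate_class_signal(cfg, i))
  if (!is.null(out_dir)) {
    for (i in seq_along(records))
      write_bonn_set(records[[i]],
                     file.path(out_dir, sprintf("class%d", i)))
  }
  records
}
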