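#' Configuration for the synthetic two-class EEG generator
#'
#' Describes a desk-scale two-class syllable-imagery-like experiment: an
#' open-loop offline block followed by a closed-loop online block, with the
#' class difference expressed as elevated band-limited oscillatory power on a
#' subset of channels, on top of a 1/f background. Non-stationarity across the
#' online block is controlled by three drift rates.
#'
#' The class effect is parameterised on the log-amplitude scale: each trial's
#' oscillation amplitude is `noise_floor * exp(a)` with
#' `a ~ N(m_class, log_amp_sd)`, and the two class means are separated by
#' `class_power_gap * log_amp_sd`. `class_power_gap` is therefore a
#' dimensionless effect size in units of the trial-to-trial log-amplitude SD.
#'
#' Drift acts linearly in the online trial index `j`:
#' * `mean_drift_rate` moves the class-1 log-amplitude mean upward and the
#'   class-2 mean downward by `mean_drift_rate * log_amp_sd` per trial, so the
#'   class centroids converge and eventually swap;
#' * `bias_drift_asymmetry` in `[0, 1]` is the fraction of the drift carried by
#'   class 1 alone (1 = only class 1 drifts, inducing a growing classifier
#'   bias);
#' * `cov_drift_rate` inflates the log-amplitude SD by a factor
#'   `1 + cov_drift_rate * j`.
#'
#' @param n_channels Number of channels.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_trials_offline,n_trials_online Trial counts per phase (must be
#'   even: classes are balanced within each phase).
#' @param trial_duration Trial length in seconds (the imagery window).
#' @param discriminative_channels Integer indices of channels carrying the
#'   class-dependent oscillation.
#' @param discriminative_band Two-element numeric, band (low, high) in Hz.
#' @param class_power_gap Dimensionless class separation on log band power
#'   (units of `log_amp_sd`).
#' @param log_amp_sd Trial-to-trial SD of the oscillation log-amplitude.
#' @param mean_drift_rate Per-online-trial drift of the class log-amplitude
#'   means, in units of `log_amp_sd`.
#' @param cov_drift_rate Per-online-trial relative inflation of `log_amp_sd`.
#' @param bias_drift_asymmetry Fraction of the mean drift applied to class 1
#'   only, in `[0, 1]`.
#' @param noise_floor Amplitude scale of the 1/f background (arbitrary
#'   microvolt-like units).
#' @param seed RNG seed; a fixed seed makes the generated dataset
#'   byte-identical across calls.
#'
#' @return A list of class `synth_config`.
#' @seealso [generate_dataset()], [generate_drift_scenario()]
#' @export
synth_config <- function(n_channels = 8,
                         sampling_rate = 256,
                         n_trials_offline = 80,
                         n_trials_online = 40,
                         trial_duration = 5,
                         discriminative_channels = 1:4,
                         discriminative_band = c(8, 16),
                         class_power_gap = 2,
                         log_amp_sd = 0.4,
                         mean_drift_rate = 0,
                         cov_drift_rate = 0,
                         bias_drift_asymmetry = 0,
                         noise_floor = 1,
                         seed = NULL) {
  cfg <- list(
    n_channels = n_channels,
    sampling_rate = sampling_rate,
    n_trials_offline = n_trials_offline,
    n_trials_online = n_trials_online,
    trial_duration = trial_duration,
    discriminative_channels = as.integer(discriminative_channels),
    discriminative_band = as.numeric(discriminative_band),
    class_power_gap = class_power_gap,
    log_amp_sd = log_amp_sd,
    mean_drift_rate = mean_drift_rate,
    cov_drift_rate = cov_drift_rate,
    bias_drift_asymmetry = bias_drift_asymmetry,
    noise_floor = noise_floor,
    seed = seed
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  for (f in c("n_channels", "n_trials_offline", "n_trials_online")) {
    if (!is_count(cfg[[f]])) abort_bad(sprintf("`%s` must be a positive integer.", f))
  }
  if (!is_number(cfg$sampling_rate) || cfg$sampling_rate <= 0) {
    abort_bad("`sampling_rate` must be positive.")
  }
  if (!is_number(cfg$trial_duration) || cfg$trial_duration <= 0) {
    abort_bad("`trial_duration` must be positive.")
  }
  if (cfg$n_trials_offline %% 2L != 0L || cfg$n_trials_online %% 2L != 0L) {
    abort_bad("trial counts must be even so each phase holds balanced classes.")
  }
  dc <- cfg$discriminative_channels
  if (length(dc) < 1L || any(dc < 1L) || any(dc > cfg$n_channels)) {
    abort_bad("`discriminative_channels` must be valid channel indices.")
  }
  band <- cfg$discriminative_band
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= cfg$sampling_rate / 2) {
    abort_bad("`discriminative_band` must satisfy 0 < low < high < sampling_rate/2.")
  }
  if (!is_number(cfg$class_power_gap) || cfg$class_power_gap < 0) {
    abort_bad("`class_power_gap` must be >= 0.")
  }
  if (!is_number(cfg$log_amp_sd) || cfg$log_amp_sd <= 0) {
    abort_bad("`log_amp_sd` must be positive.")
  }
  check_fraction(cfg$bias_drift_asymmetry, "bias_drift_asymmetry")
  if (!is_number(cfg$mean_drift_rate) || cfg$mean_drift_rate < 0) {
    abort_bad("`mean_drift_rate` must be >= 0.")
  }
  if (!is_number(cfg$cov_drift_rate) || cfg$cov_drift_rate < 0) {
    abort_bad("`cov_drift_rate` must be >= 0.")
  }
  if (!is_number(cfg$noise_floor) || cfg$noise_floor <= 0) {
    abort_bad("`noise_floor` must be positive.")
  }
  invisible(cfg)
}

# 1/f ("pink"-like) background noise of length ns, RMS-normalised to `amplitude`.
colored_noise <- function(ns, fs, amplitude) {
  nf <- ns %/% 2L
  f <- (1:nf) * fs / ns
  mag <- 1 / sqrt(f)
  re <- stats::rnorm(nf)
  im <- stats::rnorm(nf)
  half <- complex(real = re, imaginary = im) * mag
  spec <- complex(length.out = ns)
  spec[2:(nf + 1L)] <- half
  # Hermitian symmetry for a real signal; keep the Nyquist line real for even ns.
  if (ns %% 2L == 0L) {
    spec[nf + 1L] <- complex(real = re[nf] * mag[nf], imaginary = 0)
    if (nf > 1L) spec[(nf + 2L):ns] <- Conj(half[(nf - 1L):1L])
  } else {
    spec[(nf + 2L):ns] <- Conj(half[nf:1L])
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / ns
  x <- x - mean(x)
  amplitude * x / stats::sd(x)
}

# Band-limited Gaussian noise, unit RMS. FFT brick-wall mask over `band`.
band_noise_unit <- function(ns, fs, band) {
  w <- stats::rnorm(ns)
  spec <- stats::fft(w)
  f <- c(0, (1:(ns - 1L)) * fs / ns)
  f_fold <- pmin(f, fs - f)
  spec[f_fold < band[1] | f_fold > band[2]] <- 0 + 0i
  x <- Re(stats::fft(spec, inverse = TRUE)) / ns
  x <- x - mean(x)
  x / stats::sd(x)
}

balanced_labels <- function(n) {
  sample(rep(c(1L, 2L), n %/% 2L))
}

generate_impl <- function(config) {
  fs <- config$sampling_rate
  ns <- round(fs * config$trial_duration)
  n_off <- config$n_trials_offline
  n_on <- config$n_trials_online
  n_tot <- n_off + n_on
  sd0 <- config$log_amp_sd
  gap <- config$class_power_gap

  # Baseline class means on the log-amplitude scale, symmetric about 0.
  m_base <- c(-gap * sd0 / 2, +gap * sd0 / 2)

  with_seed_opt(config$seed, {
    labels <- c(balanced_labels(n_off), balanced_labels(n_on))
    phase <- rep(c("offline", "online"), c(n_off, n_on))

    data <- array(0, dim = c(n_tot, config$n_channels, ns))
    gt <- tibble::tibble(
      trial = seq_len(n_tot),
      online_index = pmax(0L, seq_len(n_tot) - n_off),
      mean_class1 = NA_real_, mean_class2 = NA_real_,
      log_amp_sd = NA_real_, log_amp = NA_real_
    )

    for (t in seq_len(n_tot)) {
      j <- max(0L, t - n_off) # online trial index; 0 during offline
      drift1 <- config$mean_drift_rate * sd0 * j
      drift2 <- (1 - config$bias_drift_asymmetry) * config$mean_drift_rate * sd0 * j
      m1 <- m_base[1] + drift1
      m2 <- m_base[2] - drift2
      sd_t <- sd0 * (1 + config$cov_drift_rate * j)

      m_trial <- if (labels[t] == 1L) m1 else m2
      log_amp <- stats::rnorm(1, m_trial, sd_t)
      amp <- config$noise_floor * exp(log_amp)

      for (ch in seq_len(config$n_channels)) {
        x <- colored_noise(ns, fs, config$noise_floor)
        if (ch %in% config$discriminative_channels) {
          x <- x + amp * band_noise_unit(ns, fs, config$discriminative_band)
        }
        data[t, ch, ] <- x
      }
      gt$mean_class1[t] <- m1
      gt$mean_class2[t] <- m2
      gt$log_amp_sd[t] <- sd_t
      gt$log_amp[t] <- log_amp
    }

    eeg_epochs(
      data = data,
      labels = labels,
      sampling_rate = fs,
      phase = phase,
      ground_truth = gt
    )
  })
}

#' Generate a synthetic two-class epoched EEG dataset
#'
#' Produces trials in acquisition order (offline block first, then online
#' block), with balanced classes within each phase. The class separation is
#' realised as elevated oscillatory power inside `discriminative_band` on the
#' `discriminative_channels`, scaled by `class_power_gap`; any configured
#' drift shifts the generating distributions linearly across online trials.
#' Per-trial generating parameters are attached as `ground_truth` so tests can
#' build oracles against the known distributions.
#'
#' @param config A [synth_config()] object.
#' @return An [eeg_epochs] object.
#' @examples
#' eeg <- generate_dataset(synth_config(
#'   n_trials_offline = 4, n_trials_online = 4,
#'   trial_duration = 1, seed = 1
#' ))
#' eeg
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  generate_impl(config)
}

#' Generate a drifting (non-stationary) synthetic dataset
#'
#' Identical generative model to [generate_dataset()], but requires at least
#' one nonzero drift rate: offline trials are drawn from the initial class
#' distributions while online trials drift monotonically with the online
#' trial index. As the drift rates tend to zero, the output converges to the
#' stationary dataset produced with the same seed.
#'
#' @inheritParams generate_dataset
#' @return An [eeg_epochs] object with ground-truth generating parameters.
#' @export
generate_drift_scenario <- function(config) {
  validate_synth_config(config)
  if (config$mean_drift_rate == 0 && config$cov_drift_rate == 0) {
    abort_bad(paste(
      "all drift rates are zero; use generate_dataset() for a stationary",
      "dataset (bias_drift_asymmetry only shapes a nonzero mean drift)."
    ))
  }
  generate_impl(config)
}

#' Drift rate that swaps the class centroids by the end of the online block
#'
#' Convenience for constructing the centroid-swap scenario: returns the
#' `mean_drift_rate` for which the two class log-amplitude means, initially
#' `class_power_gap` SDs apart, have fully exchanged positions by the last
#' online trial (separation equal to minus the initial gap).
#'
#' @param config A [synth_config()] object.
#' @return A single numeric drift rate (per online trial, in SD units).
#' @export
centroid_swap_rate <- function(config) {
  validate_synth_config(config)
  # separation(j) = gap*sd - (2 - asym) * rate * sd * j; solve separation(n) = -gap*sd
  2 * config$class_power_gap /
    ((2 - config$bias_drift_asymmetry) * config$n_trials_online)
}
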